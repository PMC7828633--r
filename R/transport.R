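#' Renkin hindrance factor for diffusion through a cylindrical pore
#'
#' Hindered-diffusion factor for a spherical solute of radius `r` moving
#' through a water-filled cylindrical pore of radius `r_pore`, as a function
#' of `lambda = r / r_pore`:
#' `(1 - lambda)^2 * (1 - 2.104 lambda + 2.09 lambda^3 - 0.95 lambda^5)`,
#' clipped to `[0, 1]`. Solutes at or above the pore radius are fully
#' excluded (factor 0).
#'
#' @param lambda Ratio of solute radius to pore radius, `>= 0`. Vectorized.
#' @return Hindrance factor in `[0, 1]`.
#' @examples
#' renkin_hindrance(c(0, 0.5, 1))
#' @export
renkin_hindrance <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("lambda must be non-negative and finite", call. = FALSE)
  }
  h <- (1 - lambda)^2 *
    (1 - 2.104 * lambda + 2.09 * lambda^3 - 0.95 * lambda^5)
  h[lambda >= 1] <- 0
  pmin(pmax(h, 0), 1)
}

#' Aqueous diffusivity from molecular weight
#'
#' Empirical correlation `D_aq = coef * Mwt^exponent` in cm^2/s, fitted for
#' small solutes in water at ambient conditions.
#'
#' @param Mwt Molecular weight, g/mol (> 0). Vectorized.
#' @param coef,exponent Correlation constants; defaults
#'   `9.9e-5 * Mwt^-0.453`.
#' @return Diffusivity in cm^2/s.
#' @examples
#' aqueous_diffusivity(194.2)
#' @export
aqueous_diffusivity <- function(Mwt, coef = 9.9e-5, exponent = -0.453) {
  if (!is.numeric(Mwt) || any(!is.finite(Mwt)) || any(Mwt <= 0)) {
    stop("Mwt must be strictly positive", call. = FALSE)
  }
  coef * Mwt^exponent
}

#' Hydrodynamic (Stokes--Einstein) solute radius
#'
#' Converts the aqueous diffusivity of [aqueous_diffusivity()] to a
#' hydrodynamic radius via the Stokes--Einstein relation
#' `r = kB T / (6 pi eta D)`. Defaults use 298.15 K and the viscosity of
#' water at that temperature (0.89 mPa s), the conditions aqueous
#' diffusivity correlations are fitted at; both are configurable.
#'
#' @param Mwt Molecular weight, g/mol (> 0). Vectorized.
#' @param temperature Kelvin.
#' @param viscosity Pa s.
#' @param ... Passed to [aqueous_diffusivity()].
#' @return Radius in um (strictly increasing in `Mwt`).
#' @examples
#' solute_radius(c(150, 500))
#' @export
solute_radius <- function(Mwt, temperature = 298.15, viscosity = 8.9e-4, ...) {
  d_m2s <- aqueous_diffusivity(Mwt, ...) * 1e-4   # cm^2/s -> m^2/s
  kB <- 1.380649e-23                              # J/K
  r_m <- kB * temperature / (6 * pi * viscosity * d_m2s)
  r_m * 1e6                                       # m -> um
}

#' Rescale a paracellular clearance to a new tight-junction pore radius
#'
#' The paracellular route is modelled as a fixed number of water-filled
#' cylindrical pores. Changing the pore radius changes the aperture area
#' (proportional to `r^2`) and the Renkin hindrance experienced by the
#' solute, so
#' `CL_P(r_new) = CL_P(r_ref) * (r_new / r_ref)^2 *
#'  H(r_drug / r_new) / H(r_drug / r_ref)`.
#' A drug whose hydrodynamic radius reaches `r_new` is fully excluded
#' (clearance 0).
#'
#' @param CL_P_ref Paracellular clearance at the reference radius, mL/min.
#' @param drug A [drug_parameters()] object (its `Mwt` sets the solute
#'   radius).
#' @param r_new,r_ref New and reference pore radii, um (> 0).
#' @return Rescaled clearance, mL/min.
#' @examples
#' drug <- builtin_drugs()[["caffeine"]]
#' scale_paracellular(48.9, drug, r_new = 0.0035, r_ref = 0.0007)
#' @export
scale_paracellular <- function(CL_P_ref, drug, r_new, r_ref) {
  stopifnot(inherits(drug, "drug_parameters"))
  if (!is.numeric(CL_P_ref) || CL_P_ref < 0) {
    stop("CL_P_ref must be non-negative", call. = FALSE)
  }
  if (!is.numeric(r_new) || r_new <= 0 || !is.numeric(r_ref) || r_ref <= 0) {
    stop("pore radii must be strictly positive", call. = FALSE)
  }
  r_drug <- solute_radius(drug$Mwt)
  if (r_drug >= r_ref) {
    stop("drug '", drug$name, "' (hydrodynamic radius ",
         signif(r_drug, 4), " um) is excluded at the reference pore radius ",
         r_ref, " um; its paracellular clearance is undefined",
         call. = FALSE)
  }
  h_ref <- renkin_hindrance(r_drug / r_ref)
  h_new <- renkin_hindrance(r_drug / r_new)
  CL_P_ref * (r_new / r_ref)^2 * h_new / h_ref
}

#' Steady-state unbound partition coefficient across the BBB
#'
#' Closed-form `Kp_uu,BBB` implied by the brain-ECF mass balance of the
#' linear model: integrating the ECF balance from 0 to infinity (dead-end
#' cell/lysosome fluxes integrate to zero) gives
#' `Kp_uu,BBB = (CL_P + CL_in) / (CL_P + CL_ef + Q_bulk)`.
#'
#' @param CL_P Paracellular (symmetric) BBB clearance, mL/min.
#' @param CL_in_eff Effective transcellular influx clearance, mL/min.
#' @param CL_ef_eff Effective transcellular efflux clearance, mL/min.
#' @param Q_bulk Brain ECF bulk flow, mL/min.
#' @return Dimensionless AUC ratio brain ECF / microvascular plasma.
#' @examples
#' steady_state_kpuu(48.9, 2.38, 4.28, 0.2) # caffeine, ~0.96
#' @export
steady_state_kpuu <- function(CL_P, CL_in_eff, CL_ef_eff, Q_bulk) {
  vals <- c(CL_P, CL_in_eff, CL_ef_eff, Q_bulk)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("clearances must be non-negative and finite", call. = FALSE)
  }
  den <- CL_P + CL_ef_eff + Q_bulk
  if (den == 0) stop("Kp_uu denominator is zero", call. = FALSE)
  (CL_P + CL_in_eff) / den
}

#' Calibrate transcellular asymmetry factors to a target Kp_uu,BBB
#'
#' Net active transport is represented by a multiplier (asymmetry factor,
#' AF >= 1) on exactly one side of the transcellular route, chosen so that
#' [steady_state_kpuu()] reproduces the drug's target `Kpuu_ECF`. If the
#' passive prediction already matches within `tol`, both factors are 1; if
#' it overshoots, the efflux factor is solved for; if it undershoots, the
#' influx factor. Calibration is infeasible when the clearance on the
#' required side is 0.
#'
#' @param drug A [drug_parameters()] object.
#' @param physiology A `cns_physiology` (supplies `Q_ECF_bulk`).
#' @param tol Relative tolerance within which the passive prediction is
#'   accepted (default 2%).
#' @param on_infeasible `"error"` to fail on an unsatisfiable target,
#'   `"passive"` to fall back to `AF = (1, 1)` with `feasible = FALSE`.
#' @return A list with `AF_in`, `AF_ef` (both `>= 1`), `feasible`, and the
#'   passive prediction `kpuu_passive`.
#' @examples
#' calibrate_asymmetry(builtin_drugs()[["morphine"]], default_physiology())
#' @export
calibrate_asymmetry <- function(drug, physiology, tol = 0.02,
                                on_infeasible = c("error", "passive")) {
  stopifnot(inherits(drug, "drug_parameters"))
  on_infeasible <- match.arg(on_infeasible)
  q <- physiology$Q_ECF_bulk
  target <- drug$Kpuu_ECF
  passive <- steady_state_kpuu(drug$CL_P, drug$CL_T_in, drug$CL_T_ef, q)
  res <- list(AF_in = 1, AF_ef = 1, feasible = TRUE, kpuu_passive = passive)
  if (abs(passive - target) / target <= tol) {
    return(res)
  }
  infeasible <- function(side) {
    msg <- paste0("drug '", drug$name, "': target Kp_uu,ECF ", target,
                  " requires ", side, " asymmetry but CL_T,", side,
                  " is 0; calibration impossible")
    if (on_infeasible == "error") stop(msg, call. = FALSE)
    res$feasible <- FALSE
    res$note <- msg
    res
  }
  if (passive > target) {
    if (drug$CL_T_ef == 0) return(infeasible("ef"))
    res$AF_ef <- ((drug$CL_P + drug$CL_T_in) / target - drug$CL_P - q) /
      drug$CL_T_ef
  } else {
    if (drug$CL_T_in == 0) return(infeasible("in"))
    res$AF_in <- (target * (drug$CL_P + drug$CL_T_ef + q) - drug$CL_P) /
      drug$CL_T_in
  }
  res
}

#' Assemble all inter-compartment clearances for a drug
#'
#' Builds the directed clearance set (mL/min) of the CNS model under a given
#' (possibly perturbed) physiology:
#' \itemize{
#'   \item BBB paracellular clearance, rescaled via [scale_paracellular()]
#'     if the pore radius differs from the reference physiology;
#'   \item BBB transcellular influx/efflux with asymmetry factors and
#'     source-compartment pH rescaling relative to the reference pH
#'     (microvascular plasma for influx, brain ECF for efflux);
#'   \item brain cell membrane: the symmetric neutral-species permeability
#'     clearance `PS_BCM = mean(CL_T_in, CL_T_ef) * SA_BCM / SA_BBB`, with
#'     each direction multiplied by the unionized fraction at its source
#'     compartment's current pH (pH-partitioning / ion trapping);
#'   \item lysosomal membrane: analogous with `SA_LYS`;
#'   \item BCSFB paracellular: BBB paracellular permeability per effective
#'     area re-evaluated at the BCSFB pore radius and effective area, split
#'     50/50 between the LV and TFV interfaces;
#'   \item BCSFB transcellular: BBB transcellular clearances scaled by the
#'     area ratio `SA_BCSFB / SA_BBB`, with asymmetry calibrated to
#'     `Kpuu_LV` when it differs from `Kpuu_ECF` (else the BBB factors);
#'   \item convection: ECF bulk flow into the LV, the CSF chain
#'     LV -> TFV -> CM -> SAS at `Q_CSF + Q_ECF_bulk`, and SAS absorption
#'     to plasma at the same rate.
#' }
#'
#' @param drug A [drug_parameters()] object.
#' @param physiology Current (possibly scenario-perturbed) physiology.
#' @param af Asymmetry factors as returned by [calibrate_asymmetry()];
#'   computed at the *reference* physiology when `NULL`.
#' @param reference Reference physiology defining reference pore radius and
#'   pH values (default [default_physiology()]).
#' @param on_infeasible Passed to [calibrate_asymmetry()].
#' @return An object of class `clearance_set`.
#' @examples
#' cl <- build_clearances(builtin_drugs()[["caffeine"]], default_physiology())
#' steady_state_kpuu(cl$bbb_para, cl$bbb_in, cl$bbb_ef, cl$q_ecf_bulk)
#' @export
build_clearances <- function(drug, physiology, af = NULL,
                             reference = default_physiology(),
                             on_infeasible = c("error", "passive")) {
  stopifnot(inherits(drug, "drug_parameters"))
  on_infeasible <- match.arg(on_infeasible)
  bad <- validate_physiology(physiology)
  if (length(bad) > 0) {
    stop("invalid physiology:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  if (is.null(af)) {
    af <- calibrate_asymmetry(drug, reference, on_infeasible = on_infeasible)
  }
  ion <- drug$ionization
  fu <- function(pH) fraction_unionized(ion, pH)

  # BBB paracellular, rescaled for the current pore radius
  bbb_para <- scale_paracellular(drug$CL_P, drug,
                                 r_new = physiology$para_radius_BBB,
                                 r_ref = reference$para_radius_BBB)

  # BBB transcellular: printed clearances are defined at reference pH of
  # their source compartment; perturbation rescales by the fu ratio.
  bbb_in <- af$AF_in * drug$CL_T_in *
    ph_scaling_factor(ion, physiology$pH_plasma, reference$pH_plasma)
  bbb_ef <- af$AF_ef * drug$CL_T_ef *
    ph_scaling_factor(ion, physiology$pH_ECF, reference$pH_ECF)

  # Cell and lysosomal membranes: symmetric neutral-species PS, directional
  # clearances carry the absolute unionized fraction at the source pH.
  ps_bcm <- mean(c(drug$CL_T_in, drug$CL_T_ef)) *
    physiology$SA_BCM / physiology$SA_BBB
  ps_lys <- mean(c(drug$CL_T_in, drug$CL_T_ef)) *
    physiology$SA_LYS / physiology$SA_BBB
  bcm_in  <- ps_bcm * fu(physiology$pH_ECF)
  bcm_out <- ps_bcm * fu(physiology$pH_ICF)
  lys_in  <- ps_lys * fu(physiology$pH_ICF)
  lys_out <- ps_lys * fu(physiology$pH_LYS)

  # BCSFB paracellular: permeability per effective paracellular area at the
  # BBB, re-evaluated at the BCSFB pore radius and effective area.
  r_drug <- solute_radius(drug$Mwt)
  a_para_bbb <- reference$SA_BBB * reference$frac_SA_para_BBB / 100
  a_para_bcsfb <- physiology$SA_BCSFB * physiology$frac_SA_para_BCSFB / 100
  h_ratio <- renkin_hindrance(r_drug / physiology$para_radius_BCSFB) /
    renkin_hindrance(r_drug / reference$para_radius_BBB)
  bcsfb_para_total <- drug$CL_P * (a_para_bcsfb / a_para_bbb) * h_ratio

  # BCSFB transcellular: area-scaled BBB clearances, asymmetry from Kpuu_LV
  # when it deviates from Kpuu_ECF, else the BBB factors.
  sa_ratio <- physiology$SA_BCSFB / physiology$SA_BBB
  af_b <- af
  if (is.finite(drug$Kpuu_LV) &&
      abs(drug$Kpuu_LV - drug$Kpuu_ECF) / drug$Kpuu_ECF > 0.02) {
    drug_b <- drug
    drug_b$Kpuu_ECF <- drug$Kpuu_LV
    drug_b$CL_P <- bcsfb_para_total
    drug_b$CL_T_in <- drug$CL_T_in * sa_ratio
    drug_b$CL_T_ef <- drug$CL_T_ef * sa_ratio
    af_b <- calibrate_asymmetry(drug_b, reference,
                                on_infeasible = on_infeasible)
  }
  bcsfb_in_total <- af_b$AF_in * drug$CL_T_in * sa_ratio *
    ph_scaling_factor(ion, physiology$pH_plasma, reference$pH_plasma)
  bcsfb_ef_total <- af_b$AF_ef * drug$CL_T_ef * sa_ratio *
    ph_scaling_factor(ion, physiology$pH_CSF, reference$pH_CSF)

  q_chain <- physiology$Q_CSF + physiology$Q_ECF_bulk

  structure(list(
    q_cbf = physiology$Q_CBF,
    bbb_para = bbb_para, bbb_in = bbb_in, bbb_ef = bbb_ef,
    bcm_in = bcm_in, bcm_out = bcm_out,
    lys_in = lys_in, lys_out = lys_out,
    bcsfb_para_lv = bcsfb_para_total / 2,
    bcsfb_para_tfv = bcsfb_para_total / 2,
    bcsfb_in_lv = bcsfb_in_total / 2, bcsfb_ef_lv = bcsfb_ef_total / 2,
    bcsfb_in_tfv = bcsfb_in_total / 2, bcsfb_ef_tfv = bcsfb_ef_total / 2,
    q_ecf_bulk = physiology$Q_ECF_bulk,
    q_csf_chain = q_chain,
    af = list(AF_in = af$AF_in, AF_ef = af$AF_ef, feasible = af$feasible)
  ), class = "clearance_set")
}

#' @export
print.clearance_set <- function(x, ...) {
  cat("<clearance_set> (mL/min)\n")
  cat(sprintf("  BBB: paracellular %.4g, transcellular in %.4g / ef %.4g\n",
              x$bbb_para, x$bbb_in, x$bbb_ef))
  cat(sprintf("  cell membrane: in %.4g / out %.4g; lysosome: in %.4g / out %.4g\n",
              x$bcm_in, x$bcm_out, x$lys_in, x$lys_out))
  cat(sprintf("  BCSFB (LV+TFV): paracellular %.4g, in %.4g / ef %.4g\n",
              x$bcsfb_para_lv + x$bcsfb_para_tfv,
              x$bcsfb_in_lv + x$bcsfb_in_tfv,
              x$bcsfb_ef_lv + x$bcsfb_ef_tfv))
  cat(sprintf("  flows: CBF %.4g, ECF bulk %.4g, CSF chain %.4g\n",
              x$q_cbf, x$q_ecf_bulk, x$q_csf_chain))
  cat(sprintf("  asymmetry: AF_in %.4g, AF_ef %.4g%s\n",
              x$af$AF_in, x$af$AF_ef,
              if (x$af$feasible) "" else " (infeasible target; passive)"))
  invisible(x)
}
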