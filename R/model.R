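#' Intravenous dosing regimen and one-compartment plasma model
#'
#' The plasma model that drives the CNS: a one-compartment model with
#' first-order elimination receiving a constant-rate intravenous infusion.
#' The same fixed regimen is used for every drug so that differences between
#' simulations reflect CNS parameters only. Plasma acts as a forcing
#' function: CNS uptake (a few mg at most) does not deplete the gram-scale
#' dose.
#'
#' @param dose_g Dose, g.
#' @param infusion_min Infusion duration, min.
#' @param cl_L_h Plasma clearance, L/h.
#' @param v_L Central volume of distribution, L.
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen() # 1 g over 15 min, CL 297 L/h, V 108 L
#' @export
dose_regimen <- function(dose_g = 1, infusion_min = 15,
                         cl_L_h = 297, v_L = 108) {
  vals <- c(dose_g = dose_g, infusion_min = infusion_min,
            cl_L_h = cl_L_h, v_L = v_L)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all dose regimen fields must be strictly positive", call. = FALSE)
  }
  structure(list(dose_g = dose_g, infusion_min = infusion_min,
                 cl_L_h = cl_L_h, v_L = v_L),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> %g g IV over %g min; CL %g L/h, V %g L\n",
              x$dose_g, x$infusion_min, x$cl_L_h, x$v_L))
  invisible(x)
}

# Internal: plasma concentration in mg/mL at time t (min).
plasma_conc_mg_ml <- function(t, regimen) {
  cl <- regimen$cl_L_h * 1000 / 60      # mL/min
  v <- regimen$v_L * 1000               # mL
  k <- cl / v                           # 1/min
  r0 <- regimen$dose_g * 1000 / regimen$infusion_min  # mg/min
  tau <- regimen$infusion_min
  c_end <- (r0 / cl) * (1 - exp(-k * tau))
  ifelse(t <= 0, 0,
         ifelse(t <= tau,
                (r0 / cl) * (1 - exp(-k * t)),
                c_end * exp(-k * (t - tau))))
}

#' Closed-form plasma concentration
#'
#' Analytic infusion/washout solution of the one-compartment plasma model:
#' during the infusion `C(t) = (R0/CL) (1 - e^{-kt})` with `k = CL/V`;
#' afterwards mono-exponential decay from the end-of-infusion concentration.
#'
#' @param t Time, min (vectorized, `>= 0`).
#' @param regimen A [dose_regimen()].
#' @return Concentration in mg/L.
#' @examples
#' plasma_concentration(15, dose_regimen()) # ~6.70 mg/L at end of infusion
#' @export
plasma_concentration <- function(t, regimen = dose_regimen()) {
  stopifnot(inherits(regimen, "dose_regimen"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  plasma_conc_mg_ml(t, regimen) * 1000
}

cns_compartments <- function() {
  c("brain_MV", "brain_ECF", "brain_ICF", "lysosome",
    "CSF_LV", "CSF_TFV", "CSF_CM", "CSF_SAS")
}

#' Assemble the linear CNS ODE system
#'
#' Builds the state equations of the nine-compartment CNS model in
#' compartment amounts (mg). Each barrier or membrane flux is
#' `clearance x source concentration`; the CSF chain is one-way convective;
#' the plasma concentration is an analytic forcing function. Two audit
#' states track cumulative drug input from plasma and cumulative return to
#' plasma for the mass-balance check.
#'
#' The rate matrix `K` (clearances, mL/min; entry `[i, j]` carries flux from
#' compartment `j` into `i`) has non-negative off-diagonal entries, and each
#' column sums to minus the compartment's loss to plasma (a Metzler,
#' mass-conservative matrix).
#'
#' @param drug A [drug_parameters()] object.
#' @param physiology A validated `cns_physiology`.
#' @param clearances A `clearance_set` from [build_clearances()].
#' @return An object of class `cns_system` with elements `K`, `volumes`,
#'   `input` (plasma-to-CNS clearance vector), `loss` (CNS-to-plasma
#'   clearance vector), and `compartments`.
#' @examples
#' drug <- builtin_drugs()[["caffeine"]]
#' sys <- build_system(drug, default_physiology(),
#'                     build_clearances(drug, default_physiology()))
#' colSums(sys$K) + sys$loss   # ~0: mass-conservative
#' @export
build_system <- function(drug, physiology, clearances) {
  stopifnot(inherits(clearances, "clearance_set"))
  comps <- cns_compartments()
  n <- length(comps)
  need <- c("q_cbf", "bbb_para", "bbb_in", "bbb_ef", "bcm_in", "bcm_out",
            "lys_in", "lys_out", "bcsfb_para_lv", "bcsfb_para_tfv",
            "bcsfb_in_lv", "bcsfb_ef_lv", "bcsfb_in_tfv", "bcsfb_ef_tfv",
            "q_ecf_bulk", "q_csf_chain")
  for (f in need) {
    v <- clearances[[f]]
    if (is.null(v) || !is.finite(v) || v < 0) {
      stop("clearance set lacks a valid '", f, "' entry", call. = FALSE)
    }
  }
  V <- c(physiology$V_MV, physiology$V_ECF, physiology$V_ICF,
         physiology$V_LYS, physiology$V_LV, physiology$V_TFV,
         physiology$V_CM, physiology$V_SAS)
  names(V) <- comps

  K <- matrix(0, n, n, dimnames = list(comps, comps))
  input <- stats::setNames(numeric(n), comps)  # plasma -> compartment
  loss <- stats::setNames(numeric(n), comps)   # compartment -> plasma
  cl <- clearances

  input["brain_MV"] <- cl$q_cbf
  loss["brain_MV"] <- cl$q_cbf
  K["brain_ECF", "brain_MV"] <- cl$bbb_para + cl$bbb_in
  K["brain_MV", "brain_ECF"] <- cl$bbb_para + cl$bbb_ef
  K["brain_ICF", "brain_ECF"] <- cl$bcm_in
  K["brain_ECF", "brain_ICF"] <- cl$bcm_out
  K["lysosome", "brain_ICF"] <- cl$lys_in
  K["brain_ICF", "lysosome"] <- cl$lys_out
  input["CSF_LV"] <- cl$bcsfb_para_lv + cl$bcsfb_in_lv
  loss["CSF_LV"] <- cl$bcsfb_para_lv + cl$bcsfb_ef_lv
  input["CSF_TFV"] <- cl$bcsfb_para_tfv + cl$bcsfb_in_tfv
  loss["CSF_TFV"] <- cl$bcsfb_para_tfv + cl$bcsfb_ef_tfv
  K["CSF_LV", "brain_ECF"] <- K["CSF_LV", "brain_ECF"] + cl$q_ecf_bulk
  K["CSF_TFV", "CSF_LV"] <- K["CSF_TFV", "CSF_LV"] + cl$q_csf_chain
  K["CSF_CM", "CSF_TFV"] <- K["CSF_CM", "CSF_TFV"] + cl$q_csf_chain
  K["CSF_SAS", "CSF_CM"] <- K["CSF_SAS", "CSF_CM"] + cl$q_csf_chain
  loss["CSF_SAS"] <- loss["CSF_SAS"] + cl$q_csf_chain

  diag(K) <- -(colSums(K) + loss)

  structure(list(K = K, volumes = V, input = input, loss = loss,
                 compartments = comps, drug = drug$name),
            class = "cns_system")
}

#' Simulate the CNS model
#'
#' Integrates the linear CNS system under the analytic plasma forcing with
#' `deSolve::lsoda` (stiff-capable) on a fixed output grid. If the maximum
#' of a monitored compartment's trace falls on the final grid point (the
#' profile has not peaked within the horizon), the simulation is re-run once
#' with a 20,000 min horizon and flagged as extended.
#'
#' @param system A `cns_system` from [build_system()].
#' @param regimen A [dose_regimen()].
#' @param t_end Observation horizon, min (default 600).
#' @param dt Output grid spacing, min (`<= 1`).
#' @param rtol,atol Solver tolerances (relative / absolute, amount units).
#' @param monitor Compartments whose completeness triggers the horizon
#'   extension.
#' @param auto_extend Re-simulate at 20,000 min when a monitored trace has
#'   not peaked (default `TRUE`).
#' @param t_extend Extension horizon, min.
#' @return An object of class `cns_simulation`: `time` (min), matrix
#'   `conc` of unbound concentrations (mg/L) with one column per compartment
#'   plus `plasma`, matrix `amounts` (mg), and `diagnostics` (tolerances,
#'   horizon, extension flag, mass-balance error).
#' @examples
#' drug <- builtin_drugs()[["caffeine"]]
#' sim <- simulate_cns(
#'   build_system(drug, default_physiology(),
#'                build_clearances(drug, default_physiology())))
#' sim$diagnostics$extended
#' @export
simulate_cns <- function(system, regimen = dose_regimen(), t_end = 600,
                         dt = 1, rtol = 1e-8, atol = 1e-10,
                         monitor = c("brain_ECF", "brain_ICF"),
                         auto_extend = TRUE, t_extend = 20000) {
  stopifnot(inherits(system, "cns_system"), inherits(regimen, "dose_regimen"))
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (dt <= 0 || dt > 1) stop("dt must lie in (0, 1] min", call. = FALSE)
  monitor <- match.arg(monitor, cns_compartments(), several.ok = TRUE)

  run <- function(horizon) {
    times <- seq(0, horizon, by = dt)
    K <- system$K
    V <- system$volumes
    b <- system$input
    loss <- system$loss
    b_sum <- sum(b)
    n <- length(V)
    rhs <- function(t, y, parms) {
      conc <- y[seq_len(n)] / V
      cp <- plasma_conc_mg_ml(t, regimen)
      dA <- as.vector(K %*% conc) + b * cp
      list(c(dA, b_sum * cp, sum(loss * conc)))
    }
    y0 <- c(stats::setNames(numeric(n), system$compartments),
            cum_in = 0, cum_out = 0)
    out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0) {
      stop("ODE integration failed for drug '", system$drug,
           "' (lsoda istate ", attr(out, "istate")[1L], ")", call. = FALSE)
    }
    out
  }

  finish <- function(out, horizon, extended) {
    times <- out[, "time"]
    amounts <- out[, system$compartments, drop = FALSE]
    neg <- min(amounts)
    if (neg < -1000 * atol) {
      stop("negative compartment amounts beyond solver tolerance (",
           signif(neg, 3), " mg) for drug '", system$drug, "'",
           call. = FALSE)
    }
    amounts[amounts < 0] <- 0
    conc <- sweep(amounts, 2, system$volumes, "/") * 1000  # mg/mL -> mg/L
    conc <- cbind(plasma = plasma_concentration(times, regimen), conc)
    # mass-balance audit: total CNS content must equal cumulative input
    # minus cumulative return, relative to all drug presented to the CNS
    balance <- rowSums(amounts) - (out[, "cum_in"] - out[, "cum_out"])
    denom <- max(out[, "cum_in"], .Machine$double.eps)
    structure(list(
      time = times, conc = conc, amounts = amounts,
      cum_in = out[, "cum_in"], cum_out = out[, "cum_out"],
      regimen = regimen, drug = system$drug,
      diagnostics = list(rtol = rtol, atol = atol, dt = dt,
                         horizon = horizon, extended = extended,
                         mass_balance_error = max(abs(balance)) / denom)
    ), class = "cns_simulation")
  }

  out <- run(t_end)
  extended <- FALSE
  if (auto_extend && t_end < t_extend) {
    # extend when a monitored trace has not peaked, or its AUC would need
    # more than the acceptable extrapolated fraction
    needs <- vapply(monitor, function(cp) {
      tr <- out[, cp]
      if (max(tr) <= 0) return(FALSE)
      if (which.max(tr) == length(tr)) return(TRUE)
      tryCatch(
        auc_infinity(pmax(tr, 0), out[, "time"],
                     on_excess = "flag")$flagged,
        error = function(e) TRUE)
    }, logical(1))
    if (any(needs)) {
      out <- run(t_extend)
      t_end <- t_extend
      extended <- TRUE
    }
  }
  finish(out, t_end, extended)
}

#' @export
print.cns_simulation <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<cns_simulation> %s: %d time points over %g min%s\n",
              x$drug, length(x$time), d$horizon,
              if (d$extended) " (extended horizon)" else ""))
  cat(sprintf("  mass balance error %.2e (rtol %g, atol %g)\n",
              d$mass_balance_error, d$rtol, d$atol))
  invisible(x)
}

#' Tidy data frame of simulated concentrations
#'
#' @param x A `cns_simulation`.
#' @param ... Unused.
#' @return A long data frame with columns `time` (min), `compartment`,
#'   `conc` (mg/L), round-trippable through CSV.
#' @export
as.data.frame.cns_simulation <- function(x, ...) {
  comps <- colnames(x$conc)
  data.frame(
    time = rep(x$time, times = length(comps)),
    compartment = rep(comps, each = length(x$time)),
    conc = as.vector(x$conc),
    stringsAsFactors = FALSE
  )
}

#' One-call simulation of a drug under a scenario
#'
#' Convenience wrapper: calibrates asymmetry at the reference physiology,
#' applies an optional scenario, assembles clearances and the ODE system,
#' and integrates.
#'
#' @param drug A [drug_parameters()] object.
#' @param physiology Reference physiology (default [default_physiology()]).
#' @param scenario Optional [scenario()] perturbation.
#' @param regimen A [dose_regimen()].
#' @param af Optional pre-computed asymmetry factors; calibrated when `NULL`.
#' @param on_infeasible Passed to [calibrate_asymmetry()].
#' @param ... Passed to [simulate_cns()].
#' @return A `cns_simulation`.
#' @examples
#' sim <- simulate_drug(builtin_drugs()[["caffeine"]])
#' pk_summary(sim)
#' @export
simulate_drug <- function(drug, physiology = default_physiology(),
                          scenario = NULL, regimen = dose_regimen(),
                          af = NULL, on_infeasible = c("error", "passive"),
                          ...) {
  on_infeasible <- match.arg(on_infeasible)
  if (is.null(af)) {
    af <- calibrate_asymmetry(drug, physiology, on_infeasible = on_infeasible)
  }
  current <- if (is.null(scenario)) physiology else
    apply_scenario(physiology, scenario)
  cl <- build_clearances(drug, current, af = af, reference = physiology)
  sys <- build_system(drug, current, cl)
  simulate_cns(sys, regimen = regimen, ...)
}
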