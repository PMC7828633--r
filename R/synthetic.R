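#' Built-in eight-drug reference panel
#'
#' The eight drugs with fully published physicochemistry, Kp,uu values and
#' BBB clearances (caffeine, cephalexin, codeine, gabapentin, genistein,
#' levetiracetam, morphine, thiopental), shipped as a CSV fixture in
#' `inst/extdata/drug_panel_8.csv` and parsed with [read_drug_table()].
#'
#' @return A named list of eight [drug_parameters()] objects.
#' @examples
#' builtin_drugs()[["morphine"]]$Kpuu_ECF # 0.23
#' @export
builtin_drugs <- function() {
  path <- system.file("extdata", "drug_panel_8.csv", package = "cnspbpk",
                      mustWork = TRUE)
  read_drug_table(path)
}

#' Specification of a virtual drug panel
#'
#' Sampling ranges and class mix for [generate_virtual_drugs()]. Defaults
#' span the physicochemical space of the 46-drug study panel: Mwt 150--500
#' g/mol, logP -3.7--4.3, pk_a 3--16, pk_b -9--10, and Kp_uu,ECF targets
#' log-uniform in `[0.01, 3]`.
#'
#' @param n Panel size.
#' @param seed Integer RNG seed; the panel is reproducible under
#'   `(seed, n)`.
#' @param Mwt_range,logP_range,pka_range,pkb_range,Kpuu_range Sampling
#'   ranges (`Kpuu_range` is sampled log-uniformly).
#' @param class_mix Named proportions over
#'   `acid`, `base`, `neutral`, `zwitterion`; must sum to 1.
#' @return An object of class `virtual_drug_spec`.
#' @export
virtual_drug_spec <- function(n = 46, seed = 1,
                              Mwt_range = c(150, 500),
                              logP_range = c(-3.7, 4.3),
                              pka_range = c(3, 16),
                              pkb_range = c(-9, 10),
                              Kpuu_range = c(0.01, 3),
                              class_mix = c(acid = 0.3, base = 0.3,
                                            neutral = 0.25,
                                            zwitterion = 0.15)) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  rng <- function(r, lab, lo_ok) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] >= r[2]) {
      stop(lab, " must be a finite increasing range", call. = FALSE)
    }
    if (!lo_ok && r[1] <= 0) stop(lab, " must be positive", call. = FALSE)
    r
  }
  Mwt_range <- rng(Mwt_range, "Mwt_range", FALSE)
  if (Mwt_range[1] < 100 || Mwt_range[2] > 1000) {
    stop("Mwt_range must lie within [100, 1000]", call. = FALSE)
  }
  logP_range <- rng(logP_range, "logP_range", TRUE)
  pka_range <- rng(pka_range, "pka_range", TRUE)
  pkb_range <- rng(pkb_range, "pkb_range", TRUE)
  Kpuu_range <- rng(Kpuu_range, "Kpuu_range", FALSE)
  classes <- c("acid", "base", "neutral", "zwitterion")
  if (!setequal(names(class_mix), classes) ||
      abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    stop("class_mix must be non-negative proportions over ",
         paste(classes, collapse = ", "), " summing to 1", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 Mwt_range = Mwt_range, logP_range = logP_range,
                 pka_range = pka_range, pkb_range = pkb_range,
                 Kpuu_range = Kpuu_range,
                 class_mix = class_mix[classes]),
            class = "virtual_drug_spec")
}

#' Generate a virtual drug panel
#'
#' Samples a reproducible panel of plausible small-molecule CNS drugs with
#' the physicochemical spread of the 46-drug study set, so that every
#' pipeline stage is testable without external data. Physicochemistry is
#' uniform within the spec ranges, the ionization class is drawn from the
#' class mix, and the Kp_uu,ECF target is log-uniform. Clearances are
#' synthesized by documented monotone formulas (they exercise the pipeline
#' and are not property predictions): the paracellular clearance follows
#' the pore model (diffusivity x Renkin hindrance, anchored at 48.9 mL/min
#' for Mwt 194.2, hence decreasing in Mwt), and the symmetric transcellular
#' clearance is `2 * 10^(0.6 logP)` mL/min, increasing in lipophilicity.
#' Net active transport is then implied by the sampled Kp_uu via
#' [calibrate_asymmetry()], which is feasible for every generated drug
#' (both transcellular clearances are positive).
#'
#' @param spec A [virtual_drug_spec()]; or pass its arguments via `...`.
#' @param ... Arguments forwarded to [virtual_drug_spec()] when `spec` is
#'   missing.
#' @return A named list of [drug_parameters()] objects, length `spec$n`.
#' @examples
#' panel <- generate_virtual_drugs(virtual_drug_spec(n = 5, seed = 42))
#' vapply(panel, function(d) d$Mwt, numeric(1))
#' @export
generate_virtual_drugs <- function(spec = virtual_drug_spec(...), ...) {
  stopifnot(inherits(spec, "virtual_drug_spec"))
  set.seed(spec$seed)
  n <- spec$n
  runifr <- function(r) stats::runif(n, r[1], r[2])
  Mwt <- runifr(spec$Mwt_range)
  logP <- runifr(spec$logP_range)
  classes <- sample(names(spec$class_mix), n, replace = TRUE,
                    prob = spec$class_mix)
  pka <- runifr(spec$pka_range)
  pkb <- runifr(spec$pkb_range)
  kpuu <- exp(stats::runif(n, log(spec$Kpuu_range[1]),
                           log(spec$Kpuu_range[2])))
  # pore-model paracellular clearance, anchored at the caffeine value
  cl_p_anchor <- 48.9 /
    (aqueous_diffusivity(194.2) *
       renkin_hindrance(solute_radius(194.2) / 0.0007))
  cl_p <- cl_p_anchor * aqueous_diffusivity(Mwt) *
    renkin_hindrance(pmin(solute_radius(Mwt) / 0.0007, 1))
  cl_t <- 2 * 10^(0.6 * logP)
  drugs <- lapply(seq_len(n), function(i) {
    ion <- switch(classes[i],
      neutral = ionization_spec("neutral"),
      acid = ionization_spec("acid", pka = pka[i]),
      base = ionization_spec("base", pkb = pkb[i]),
      zwitterion = ionization_spec("zwitterion", pka = pka[i],
                                   pkb = pkb[i]))
    passive <- steady_state_kpuu(cl_p[i], cl_t[i], cl_t[i], 0.2)
    drug_parameters(
      name = sprintf("virtual_%03d", i),
      Mwt = Mwt[i], logP = logP[i], ionization = ion,
      Kpuu_ECF = kpuu[i],
      # notional substrate flags: efflux- vs influx-dominated calibration
      p_gp = kpuu[i] < passive * 0.98,
      OAT3 = kpuu[i] > passive * 1.02,
      CL_P = cl_p[i], CL_T_ef = cl_t[i], CL_T_in = cl_t[i]
    )
  })
  stats::setNames(drugs, vapply(drugs, `[[`, character(1), "name"))
}
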