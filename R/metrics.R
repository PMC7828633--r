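#' Peak concentration and its time
#'
#' Maximum of a concentration trace and the time at which it occurs; ties
#' are broken to the earliest time. An all-zero trace yields `(0, 0)` with a
#' warning.
#'
#' @param conc Concentration trace.
#' @param time Matching time grid, strictly increasing, min.
#' @return A list with `Cmax` and `Tmax`.
#' @examples
#' cmax_tmax(c(0, 1, 3, 2), 0:3)
#' @export
cmax_tmax <- function(conc, time) {
  check_trace(conc, time)
  if (all(conc == 0)) {
    warning("all-zero concentration trace; Cmax and Tmax set to 0")
    return(list(Cmax = 0, Tmax = 0))
  }
  i <- which.max(conc)  # which.max returns the first maximum
  list(Cmax = conc[i], Tmax = time[i])
}

check_trace <- function(conc, time) {
  if (length(conc) == 0 || length(conc) != length(time)) {
    stop("conc and time must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Linear trapezoidal area under the curve
#'
#' AUC of a trace over `[t_start, t_end]` by the linear trapezoid rule on
#' the stored grid; the window bounds must be grid points.
#'
#' @param conc Concentration trace (mass/volume).
#' @param time Time grid, min.
#' @param t_start,t_end Integration window (defaults: whole grid).
#' @return AUC in concentration x min units.
#' @examples
#' auc_trapz(c(0, 1, 0), c(0, 1, 2)) # triangle, 1.0
#' @export
auc_trapz <- function(conc, time, t_start = time[1],
                      t_end = time[length(time)]) {
  check_trace(conc, time)
  i0 <- match(TRUE, abs(time - t_start) < 1e-9)
  i1 <- match(TRUE, abs(time - t_end) < 1e-9)
  if (is.na(i0) || is.na(i1) || i0 >= i1) {
    stop("integration window [", t_start, ", ", t_end,
         "] must span distinct grid points", call. = FALSE)
  }
  idx <- i0:i1
  sum(diff(time[idx]) * (conc[idx][-1] + conc[idx][-length(idx)]) / 2)
}

#' AUC extrapolated to infinity
#'
#' `AUC_0-T` plus the extrapolated tail `C_last / k_el`, with the terminal
#' elimination rate constant `k_el` from a log-linear regression over the
#' terminal phase. The terminal window is the last `n_terminal` grid points
#' after `Tmax` that lie above a noise floor (`floor_frac x Cmax`), so the
#' regression is not run on solver noise once a trace has fully decayed.
#' A non-decaying terminal phase is refused; an extrapolated fraction above
#' `max_extrap` is an error (or a flag, the pipeline's cue to extend the
#' horizon).
#'
#' @param conc,time Trace and grid (min).
#' @param n_terminal Number of terminal points to regress on (default 5).
#' @param floor_frac Noise floor as a fraction of Cmax.
#' @param max_extrap Maximum acceptable extrapolated fraction (default 0.2).
#' @param on_excess `"error"` or `"flag"` when the fraction exceeds
#'   `max_extrap`.
#' @return A list with `auc_inf`, `auc_0_T`, `k_el` (1/min),
#'   `extrap_frac`, and `flagged`.
#' @examples
#' t <- 0:300
#' auc_infinity(5 * exp(-0.05 * t), t)$auc_inf # ~5 / 0.05
#' @export
auc_infinity <- function(conc, time, n_terminal = 5, floor_frac = 1e-8,
                         max_extrap = 0.2, on_excess = c("error", "flag")) {
  check_trace(conc, time)
  on_excess <- match.arg(on_excess)
  cmax <- max(conc)
  if (cmax <= 0) stop("cannot extrapolate an all-zero trace", call. = FALSE)
  imax <- which.max(conc)
  cand <- which(seq_along(conc) > imax & conc > floor_frac * cmax)
  if (length(cand) < 3) {
    stop("fewer than 3 usable post-Tmax points; cannot estimate the ",
         "terminal phase", call. = FALSE)
  }
  idx <- utils::tail(cand, n_terminal)
  fit <- stats::lm.fit(cbind(1, time[idx]), log(conc[idx]))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) {
    stop("terminal phase is not decaying (slope ", signif(slope, 3),
         "); cannot extrapolate to infinity", call. = FALSE)
  }
  k_el <- -slope
  t_last <- time[max(idx)]
  c_last <- conc[max(idx)]
  auc_0_T <- auc_trapz(conc, time)
  auc_inf <- auc_trapz(conc, time, time[1], t_last) + c_last / k_el
  auc_inf <- max(auc_inf, auc_0_T)
  extrap <- (auc_inf - auc_trapz(conc, time, time[1], t_last)) / auc_inf
  flagged <- extrap > max_extrap
  if (flagged && on_excess == "error") {
    stop("extrapolated AUC fraction ", signif(extrap, 3), " exceeds ",
         max_extrap, "; extend the simulation horizon", call. = FALSE)
  }
  list(auc_inf = unname(auc_inf), auc_0_T = unname(auc_0_T),
       k_el = unname(k_el), extrap_frac = unname(extrap), flagged = flagged)
}

#' Unbound partition coefficient from two traces
#'
#' Ratio of the `AUC_0-inf` of two concentration traces on a common grid:
#' `Kp_uu,BBB` for brain ECF over microvascular plasma, `Kp_uu,cell` for
#' brain ICF over brain ECF.
#'
#' @param num_conc,den_conc Numerator and denominator traces.
#' @param time Common time grid, min.
#' @param ... Passed to [auc_infinity()].
#' @return Dimensionless AUC ratio.
#' @examples
#' t <- 0:300; tr <- 5 * exp(-0.05 * t) * (1 - exp(-0.5 * t))
#' kpuu(tr, tr, t) # 1
#' @export
kpuu <- function(num_conc, den_conc, time, ...) {
  auc_infinity(num_conc, time, ...)$auc_inf /
    auc_infinity(den_conc, time, ...)$auc_inf
}

#' Two-fold-change statistic
#'
#' `log2(perturbed / reference)` of a PK metric; a value of 1 reflects a
#' two-fold change, and the statistic is antisymmetric in its arguments.
#'
#' @param metric_perturbed,metric_reference Strictly positive metric values.
#' @return log2 fold change.
#' @examples
#' two_fold_change(10, 5) # 1
#' @export
two_fold_change <- function(metric_perturbed, metric_reference) {
  if (any(!is.finite(metric_perturbed)) || any(metric_perturbed <= 0) ||
      any(!is.finite(metric_reference)) || any(metric_reference <= 0)) {
    stop("two_fold_change requires strictly positive metric values",
         call. = FALSE)
  }
  log2(metric_perturbed / metric_reference)
}

#' PK summary of a CNS simulation
#'
#' Per-compartment non-compartmental metrics of a simulated run: `Cmax`
#' (mg/L), `Tmax` (min), `AUC_0_T` over the simulated horizon and
#' `AUC_0_inf` (mg min/L), plus the partition coefficients `Kpuu_BBB`
#' (brain ECF / microvascular AUC ratio) and `Kpuu_cell` (brain ICF / brain
#' ECF). Compartments whose extrapolation fails or exceeds the guard are
#' reported with `NA` metrics and `flagged = TRUE` rather than aborting.
#'
#' @param sim A `cns_simulation`.
#' @param compartments Compartments to summarize (default brain ECF and
#'   ICF).
#' @param ... Passed to [auc_infinity()].
#' @return A data frame with one row per compartment.
#' @examples
#' pk_summary(simulate_drug(builtin_drugs()[["caffeine"]]))
#' @export
pk_summary <- function(sim, compartments = c("brain_ECF", "brain_ICF"), ...) {
  stopifnot(inherits(sim, "cns_simulation"))
  compartments <- match.arg(compartments, colnames(sim$conc),
                            several.ok = TRUE)
  safe_auc <- function(cp) {
    tryCatch(auc_infinity(sim$conc[, cp], sim$time, on_excess = "error", ...),
             error = function(e) NULL)
  }
  aucs <- lapply(c("brain_MV", "brain_ECF", "brain_ICF"), safe_auc)
  names(aucs) <- c("brain_MV", "brain_ECF", "brain_ICF")
  kp_bbb <- if (!is.null(aucs$brain_ECF) && !is.null(aucs$brain_MV)) {
    aucs$brain_ECF$auc_inf / aucs$brain_MV$auc_inf
  } else NA_real_
  kp_cell <- if (!is.null(aucs$brain_ICF) && !is.null(aucs$brain_ECF)) {
    aucs$brain_ICF$auc_inf / aucs$brain_ECF$auc_inf
  } else NA_real_
  rows <- lapply(compartments, function(cp) {
    tr <- sim$conc[, cp]
    pk <- withCallingHandlers(
      cmax_tmax(tr, sim$time),
      warning = function(w) invokeRestart("muffleWarning"))
    a <- if (cp %in% names(aucs)) aucs[[cp]] else safe_auc(cp)
    data.frame(
      drug = sim$drug, compartment = cp,
      Cmax = pk$Cmax, Tmax = pk$Tmax,
      AUC_0_T = if (max(tr) > 0) auc_trapz(tr, sim$time) else 0,
      AUC_0_inf = if (is.null(a)) NA_real_ else a$auc_inf,
      Kpuu_BBB = kp_bbb, Kpuu_cell = kp_cell,
      flagged = is.null(a) || is.na(kp_bbb) || is.na(kp_cell),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
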