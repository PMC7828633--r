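#' A pathophysiological what-if scenario
#'
#' One named perturbation of a single CNS physiology parameter, either as a
#' multiplier on the reference value (flows, volumes, pore radius) or as an
#' absolute value (pH only).
#'
#' @param name Scenario identifier.
#' @param target One of `"Q_CBF"`, `"para_radius_BBB"`, `"V_ECF"`,
#'   `"pH_ECF"`, `"pH_ICF"`, or `NA` for the unperturbed reference.
#' @param mode `"multiplier"` or `"absolute"`; absolute mode is only valid
#'   for pH targets.
#' @param value Multiplier (> 0) or absolute pH.
#' @return An object of class `cns_scenario`.
#' @examples
#' scenario("CBF_low", "Q_CBF", "multiplier", 0.7)
#' @export
scenario <- function(name, target = NA_character_,
                     mode = c("multiplier", "absolute"), value = 1) {
  if (is.na(target)) {
    return(structure(list(name = name, target = NA_character_,
                          mode = "reference", value = NA_real_),
                     class = "cns_scenario"))
  }
  targets <- c("Q_CBF", "para_radius_BBB", "V_ECF", "pH_ECF", "pH_ICF")
  target <- match.arg(target, targets)
  mode <- match.arg(mode)
  value <- as.numeric(value)
  if (!is.finite(value)) stop("scenario value must be finite", call. = FALSE)
  if (mode == "multiplier" && value <= 0) {
    stop("scenario multipliers must be strictly positive", call. = FALSE)
  }
  if (mode == "absolute" && !startsWith(target, "pH")) {
    stop("absolute mode is only valid for pH targets", call. = FALSE)
  }
  structure(list(name = name, target = target, mode = mode, value = value),
            class = "cns_scenario")
}

#' @export
print.cns_scenario <- function(x, ...) {
  if (x$mode == "reference") {
    cat("<cns_scenario>", x$name, "(reference)\n")
  } else {
    cat(sprintf("<cns_scenario> %s: %s %s %g\n", x$name, x$target,
                if (x$mode == "multiplier") "x" else "=", x$value))
  }
  invisible(x)
}

#' The standard what-if scenario set
#'
#' The reference plus ten one-at-a-time pathophysiological perturbations
#' spanning reported CNS disease ranges: cerebral blood flow at 70% and
#' 150%, BBB tight-junction pore radius at 50% and 500%, brain ECF volume
#' at 70% and 150%, brain ECF pH set to 5 and 8, and brain ICF pH set to
#' 6 and 7.6.
#'
#' @return A named list of 11 [scenario()] objects; the first is the
#'   reference.
#' @examples
#' names(default_scenarios())
#' @export
default_scenarios <- function() {
  scns <- list(
    scenario("reference"),
    scenario("CBF_low", "Q_CBF", "multiplier", 0.7),
    scenario("CBF_high", "Q_CBF", "multiplier", 1.5),
    scenario("para_radius_low", "para_radius_BBB", "multiplier", 0.5),
    scenario("para_radius_high", "para_radius_BBB", "multiplier", 5),
    scenario("V_ECF_low", "V_ECF", "multiplier", 0.7),
    scenario("V_ECF_high", "V_ECF", "multiplier", 1.5),
    scenario("pH_ECF_low", "pH_ECF", "absolute", 5),
    scenario("pH_ECF_high", "pH_ECF", "absolute", 8),
    scenario("pH_ICF_low", "pH_ICF", "absolute", 6),
    scenario("pH_ICF_high", "pH_ICF", "absolute", 7.6)
  )
  stats::setNames(scns, vapply(scns, `[[`, character(1), "name"))
}

#' Apply a scenario to a physiology
#'
#' Returns a modified copy of the physiology with exactly one parameter
#' changed. A brain-ECF volume change does not alter brain ICF volume,
#' flows, or surface areas (the volume effect is isolated); pore-radius and
#' pH changes take effect downstream, at clearance build time.
#'
#' @param physiology A `cns_physiology`.
#' @param scn A [scenario()].
#' @return A `cns_physiology`; errors (listing the violations) if the
#'   perturbed physiology is invalid.
#' @examples
#' apply_scenario(default_physiology(),
#'                scenario("CBF_low", "Q_CBF", "multiplier", 0.7))$Q_CBF
#' @export
apply_scenario <- function(physiology, scn) {
  stopifnot(inherits(scn, "cns_scenario"))
  if (scn$mode == "reference") return(physiology)
  out <- physiology
  out[[scn$target]] <- if (scn$mode == "multiplier") {
    physiology[[scn$target]] * scn$value
  } else {
    scn$value
  }
  bad <- validate_physiology(out)
  if (length(bad) > 0) {
    stop("scenario '", scn$name, "' yields an invalid physiology:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  out
}

#' Run the drug x scenario what-if grid
#'
#' Simulates every drug under every scenario with the same fixed plasma
#' model and dosing regimen, summarizes each run per compartment, and
#' converts the summaries to two-fold-change (log2 ratio) values against
#' the reference scenario. Asymmetry factors are calibrated once per drug
#' at the reference physiology. Per-cell failures (e.g. a drug excluded
#' from a shrunken pore, or an inextrapolatable trace) are recorded as
#' flagged rows, not run-aborting. Deterministic given its inputs.
#'
#' @param drugs A list of [drug_parameters()] (or a single one).
#' @param scenarios A list of [scenario()]s including the reference
#'   (default [default_scenarios()]).
#' @param physiology Reference physiology.
#' @param regimen A [dose_regimen()].
#' @param on_infeasible Calibration fallback, see [calibrate_asymmetry()];
#'   the grid default is `"passive"`.
#' @param ... Passed to [simulate_cns()] (e.g. `dt`, `t_end`).
#' @return An object of class `whatif_grid`: `summary` (per drug x scenario
#'   x compartment PK metrics), `heatmap` (long-format two-fold changes),
#'   and `flags` (notes on flagged cells and infeasible calibrations).
#' @examples
#' grid <- run_whatif_grid(builtin_drugs()[c("caffeine", "codeine")],
#'                         default_scenarios()[c("reference", "CBF_low")])
#' subset(grid$heatmap, metric == "Tmax")
#' @export
run_whatif_grid <- function(drugs, scenarios = default_scenarios(),
                            physiology = default_physiology(),
                            regimen = dose_regimen(),
                            on_infeasible = "passive", ...) {
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  stopifnot(length(drugs) >= 1)
  is_ref <- vapply(scenarios, function(s) s$mode == "reference", logical(1))
  if (!any(is_ref)) {
    stop("the scenario set must include the reference scenario",
         call. = FALSE)
  }
  flags <- character()
  rows <- list()
  for (drug in drugs) {
    af <- calibrate_asymmetry(drug, physiology,
                              on_infeasible = on_infeasible)
    if (!af$feasible) flags <- c(flags, af$note)
    for (scn in scenarios) {
      res <- tryCatch({
        sim <- simulate_drug(drug, physiology, scenario = scn,
                             regimen = regimen, af = af, ...)
        cbind(pk_summary(sim), scenario = scn$name,
              stringsAsFactors = FALSE)
      }, error = function(e) {
        flags <<- c(flags, paste0(drug$name, " / ", scn$name, ": ",
                                  conditionMessage(e)))
        data.frame(drug = drug$name,
                   compartment = c("brain_ECF", "brain_ICF"),
                   Cmax = NA_real_, Tmax = NA_real_, AUC_0_T = NA_real_,
                   AUC_0_inf = NA_real_, Kpuu_BBB = NA_real_,
                   Kpuu_cell = NA_real_, flagged = TRUE,
                   scenario = scn$name, stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  summary <- do.call(rbind, rows)
  structure(list(summary = summary,
                 heatmap = heatmap_table(summary),
                 flags = flags),
            class = "whatif_grid")
}

#' Two-fold-change heatmap table from grid summaries
#'
#' Converts a per-run PK summary table into the long-format heatmap of
#' log2 fold changes against the reference scenario, for the metrics Cmax,
#' Tmax, AUC_0-T, Kp_uu,BBB and Kp_uu,cell, keyed by (drug, compartment,
#' scenario, metric). Cells whose metric is missing, zero or negative in
#' either arm are `NA` (flagged).
#'
#' @param summary The `summary` data frame of [run_whatif_grid()].
#' @return A long data frame with a `log2fc` column; the reference scenario
#'   column is identically 0.
#' @export
heatmap_table <- function(summary) {
  metrics <- c("Cmax", "Tmax", "AUC_0_T", "Kpuu_BBB", "Kpuu_cell")
  ref <- summary[summary$scenario == "reference", ]
  if (nrow(ref) == 0) stop("summary lacks the reference scenario",
                           call. = FALSE)
  key <- function(d) paste(d$drug, d$compartment, sep = "\r")
  out <- list()
  for (m in metrics) {
    ref_vals <- stats::setNames(ref[[m]], key(ref))
    r <- ref_vals[key(summary)]
    x <- summary[[m]]
    ok <- is.finite(x) & is.finite(r) & x > 0 & r > 0
    fc <- rep(NA_real_, nrow(summary))
    fc[ok] <- log2(x[ok] / r[ok])
    out[[m]] <- data.frame(
      drug = summary$drug, compartment = summary$compartment,
      scenario = summary$scenario, metric = m, log2fc = fc,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.whatif_grid <- function(x, ...) {
  cat(sprintf("<whatif_grid> %d drugs x %d scenarios\n",
              length(unique(x$summary$drug)),
              length(unique(x$summary$scenario))))
  if (length(x$flags) > 0) {
    cat("  flags:\n")
    for (f in x$flags) cat("   -", f, "\n")
  }
  invisible(x)
}

#' Heatmap of two-fold changes
#'
#' Tile plot of the what-if grid's log2 fold changes for one compartment,
#' drugs on the rows and scenario x metric on the columns, diverging colour
#' scale centred at 0 (no change); +/-1 is a doubling/halving.
#'
#' @param grid A `whatif_grid`.
#' @param compartment `"brain_ECF"` or `"brain_ICF"`.
#' @return A `ggplot` object.
#' @export
plot_whatif_heatmap <- function(grid, compartment = "brain_ECF") {
  stopifnot(inherits(grid, "whatif_grid"))
  hm <- grid$heatmap
  hm <- hm[hm$compartment == compartment & hm$scenario != "reference", ]
  hm$metric <- factor(hm$metric,
                      c("Cmax", "Tmax", "AUC_0_T", "Kpuu_BBB", "Kpuu_cell"))
  lim <- max(abs(hm$log2fc), 1, na.rm = TRUE)
  ggplot2::ggplot(hm, ggplot2::aes(x = .data$scenario, y = .data$drug,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$metric)) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-lim, lim),
                                  na.value = "grey60",
                                  name = "log2 fold change") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("What-if two-fold changes,", compartment)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
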