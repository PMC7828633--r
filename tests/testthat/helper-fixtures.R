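# Shared fixtures for the test suite. Heavy objects (the full drug x
# scenario grid) are built once per session and cached.

.cache <- new.env(parent = emptyenv())

panel_drugs <- function() {
  if (is.null(.cache$drugs)) .cache$drugs <- builtin_drugs()
  .cache$drugs
}

# Asymmetry factors disabled: simulate the printed clearances as-is.
af_passive <- list(AF_in = 1, AF_ef = 1, feasible = TRUE)

# Full 8-drug x 11-scenario grid at default settings (built on first use).
full_grid <- function() {
  if (is.null(.cache$grid)) {
    .cache$elapsed <- system.time(
      .cache$grid <- run_whatif_grid(panel_drugs())
    )[["elapsed"]]
  }
  .cache$grid
}

full_grid_elapsed <- function() {
  full_grid()
  .cache$elapsed
}

# Percent change in a metric between a scenario and the reference, per drug.
pct_change <- function(summary, scn, metric, compartment = "brain_ECF") {
  s <- summary[summary$compartment == compartment, ]
  ref <- s[s$scenario == "reference", c("drug", metric)]
  per <- s[s$scenario == scn, c("drug", metric)]
  m <- merge(ref, per, by = "drug", suffixes = c("_ref", "_scn"))
  stats::setNames(
    100 * (m[[paste0(metric, "_scn")]] - m[[paste0(metric, "_ref")]]) /
      m[[paste0(metric, "_ref")]],
    m$drug)
}
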