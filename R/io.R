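drug_table_columns <- function() {
  c("Drug", "Mwt", "logP", "ion_class", "pk_a", "pk_b",
    "Kpuu_ECF", "Kpuu_LV", "Kpuu_CM", "BCRP", "p_gp", "OAT3", "MRP4",
    "CL_P", "CL_T_ef", "CL_T_in")
}

# "<0.01" -> 0 (below detection), "NA"/"" -> NA, else numeric
parse_clearance_cell <- function(x, file, row, col) {
  x <- trimws(as.character(x))
  if (is.na(x) || x %in% c("NA", "")) return(NA_real_)
  if (grepl("^<", x)) return(0)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) && !x %in% c("NA", "")) {
    stop("non-numeric value '", x, "' in column ", col, ", data row ", row,
         " of ", file, call. = FALSE)
  }
  v
}

parse_flag_cell <- function(x) {
  toupper(trimws(as.character(x))) %in% c("X", "TRUE", "1", "YES")
}

#' Read a drug parameter table
#'
#' Parses a CSV with the standard drug-table schema (columns `Drug`, `Mwt`,
#' `logP`, `ion_class`, `pk_a`, `pk_b`, `Kpuu_ECF`, `Kpuu_LV`, `Kpuu_CM`,
#' `BCRP`, `p_gp`, `OAT3`, `MRP4`, `CL_P`, `CL_T_ef`, `CL_T_in`). The
#' dialect is comma-separated UTF-8 with a mandatory header and "."
#' decimals; transporter flags are `"X"`/`"-"`; `"NA"` is accepted for
#' absent pk values; clearances below detection (`"<0.01"`) are coerced
#' to 0. Unknown ionization classes and out-of-range values are rejected
#' with the offending row.
#'
#' @param path CSV file path.
#' @return A named list of [drug_parameters()] objects.
#' @examples
#' length(builtin_drugs()) # parses the shipped 8-drug panel
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(drug_table_columns(), names(tab))
  if (length(missing) > 0) {
    stop("drug table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) stop("drug table ", path, " has no rows",
                           call. = FALSE)
  drugs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    num <- function(col) parse_clearance_cell(row[[col]], path, i, col)
    ion <- tryCatch(
      ionization_spec(row$ion_class, pka = num("pk_a"), pkb = num("pk_b")),
      error = function(e) stop("data row ", i, " of ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    tryCatch(
      drug_parameters(
        name = row$Drug, Mwt = num("Mwt"), logP = num("logP"),
        ionization = ion,
        Kpuu_ECF = num("Kpuu_ECF"), Kpuu_LV = num("Kpuu_LV"),
        Kpuu_CM = num("Kpuu_CM"),
        BCRP = parse_flag_cell(row$BCRP), p_gp = parse_flag_cell(row$p_gp),
        OAT3 = parse_flag_cell(row$OAT3), MRP4 = parse_flag_cell(row$MRP4),
        CL_P = num("CL_P"), CL_T_ef = num("CL_T_ef"),
        CL_T_in = num("CL_T_in")),
      error = function(e) stop("data row ", i, " of ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  stats::setNames(drugs, vapply(drugs, `[[`, character(1), "name"))
}

#' Write a drug parameter table
#'
#' Inverse of [read_drug_table()]: serializes a list of
#' [drug_parameters()] to the standard CSV schema (flags as `"X"`/`"-"`,
#' absent pk values as `"NA"`), so virtual panels and curated tables are
#' interchangeable inputs.
#'
#' @param drugs A list of [drug_parameters()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(drugs, path) {
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  flag <- function(x) ifelse(x, "X", "-")
  tab <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(
      Drug = d$name, Mwt = d$Mwt, logP = d$logP,
      ion_class = d$ionization$ion_class,
      pk_a = ifelse(is.finite(d$ionization$pka), d$ionization$pka, NA),
      pk_b = ifelse(is.finite(d$ionization$pkb), d$ionization$pkb, NA),
      Kpuu_ECF = d$Kpuu_ECF, Kpuu_LV = d$Kpuu_LV, Kpuu_CM = d$Kpuu_CM,
      BCRP = flag(d$BCRP), p_gp = flag(d$p_gp),
      OAT3 = flag(d$OAT3), MRP4 = flag(d$MRP4),
      CL_P = d$CL_P, CL_T_ef = d$CL_T_ef, CL_T_in = d$CL_T_in,
      stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the outputs of a what-if run
#'
#' Writes the per-run PK summaries (`pk_summary.csv`), the two-fold-change
#' heatmap table (`heatmap.csv`), optionally tidy concentration traces
#' (`traces.csv`), a heatmap figure per compartment, and a JSON run
#' manifest (`manifest.json`) echoing the configuration, solver settings,
#' package version and timestamp. Everything except the timestamp is a
#' deterministic function of the inputs, so re-running from the manifest
#' reproduces bit-identical CSVs.
#'
#' @param grid A `whatif_grid` from [run_whatif_grid()].
#' @param dir Output directory (created if needed).
#' @param config Optional named list echoed into the manifest (e.g. file
#'   paths, horizon, seed).
#' @param traces Optional named list of `cns_simulation` objects to write
#'   as a tidy CSV.
#' @param figures Write heatmap PNGs (default `TRUE`).
#' @return Invisible character vector of the files written.
#' @export
write_outputs <- function(grid, dir, config = list(), traces = NULL,
                          figures = TRUE) {
  stopifnot(inherits(grid, "whatif_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir,
                             call. = FALSE)
  files <- character()
  path <- function(f) file.path(dir, f)
  utils::write.csv(grid$summary, path("pk_summary.csv"), row.names = FALSE)
  utils::write.csv(grid$heatmap, path("heatmap.csv"), row.names = FALSE)
  files <- c(files, path("pk_summary.csv"), path("heatmap.csv"))
  if (!is.null(traces)) {
    tidy <- do.call(rbind, lapply(names(traces), function(nm) {
      cbind(run = nm, as.data.frame(traces[[nm]]),
            stringsAsFactors = FALSE)
    }))
    utils::write.csv(tidy, path("traces.csv"), row.names = FALSE)
    files <- c(files, path("traces.csv"))
  }
  if (figures) {
    for (cp in intersect(c("brain_ECF", "brain_ICF"),
                         unique(grid$heatmap$compartment))) {
      f <- path(paste0("heatmap_", cp, ".png"))
      ggplot2::ggsave(f, plot_whatif_heatmap(grid, cp),
                      width = 10, height = 6, dpi = 150)
      files <- c(files, f)
    }
  }
  manifest <- list(
    package = "cnspbpk",
    version = as.character(utils::packageVersion("cnspbpk")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    solver = list(rtol = 1e-8, atol = 1e-10),
    flags = grid$flags
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, path("manifest.json"))
  invisible(files)
}
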