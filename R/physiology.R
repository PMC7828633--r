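#' Reference human CNS physiology
#'
#' Central literature values for the adult human CNS: compartment volumes,
#' fluid flows, barrier surface areas, tight-junction pore radii, effective
#' paracellular/transcellular surface-area fractions, and compartment pH.
#' Derived quantities follow the stated conventions: lysosomal volume is
#' 1/80 of brain ICF volume, the blood--CSF barrier (BCSFB) area is 10% of
#' the blood--brain barrier (BBB) area (split equally between the lateral
#' ventricles and the third+fourth ventricles), and ECF bulk flow is half
#' the CSF bulk flow.
#'
#' Units: volumes mL, flows mL/min, surface areas cm^2, radii and barrier
#' width um, surface-area fractions percent, pH dimensionless.
#'
#' @return An object of class `cns_physiology` (a named list of parameters).
#' @examples
#' phys <- default_physiology()
#' phys$Q_CBF
#' validate_physiology(phys)
#' @export
default_physiology <- function() {
  phys <- list(
    V_brain_total = 1250,     # mL
    V_ECF   = 253,            # mL, brain extracellular fluid
    V_ICF   = 1000,           # mL, brain intracellular fluid (cytosol)
    V_LYS   = 1000 / 80,      # mL, lysosomes = V_ICF / 80
    V_MV    = 45,             # mL, brain microvascular plasma
    V_LV    = 20,             # mL, lateral ventricles CSF
    V_TFV   = 3,              # mL, third + fourth ventricles CSF
    V_CM    = 1,              # mL, cisterna magna CSF
    V_SAS   = 116,            # mL, subarachnoid space CSF
    Q_CBF      = 689,         # mL/min, cerebral blood flow
    Q_ECF_bulk = 0.2,         # mL/min, brain ECF bulk flow
    Q_CSF      = 0.42,        # mL/min, CSF bulk flow
    SA_BBB   = 150000,        # cm^2
    SA_BCSFB = 15000,         # cm^2, 0.1 * SA_BBB
    SA_BCM   = 2666520,       # cm^2, brain cell membrane
    SA_LYS   = 1980260,       # cm^2, lysosomal membrane
    width_barrier = 0.5,      # um
    para_radius_BBB   = 0.0007,  # um, tight-junction pore radius
    para_radius_BCSFB = 0.0027,  # um
    frac_SA_trans      = 99.8,   # % of barrier area, transcellular route
    frac_SA_para_BBB   = 0.004,  # % of SA_BBB, paracellular route
    frac_SA_para_BCSFB = 0.016,  # % of SA_BCSFB, paracellular route
    pH_plasma = 7.4,
    pH_ECF    = 7.3,
    pH_CSF    = 7.3,
    pH_ICF    = 7.0,
    pH_LYS    = 5.0,
    N_cells   = 1.71e11
  )
  structure(phys, class = "cns_physiology")
}

#' @export
print.cns_physiology <- function(x, ...) {
  cat("<cns_physiology>\n")
  cat(sprintf("  volumes (mL): ECF %g, ICF %g, LYS %g, MV %g, CSF %g\n",
              x$V_ECF, x$V_ICF, x$V_LYS, x$V_MV,
              x$V_LV + x$V_TFV + x$V_CM + x$V_SAS))
  cat(sprintf("  flows (mL/min): CBF %g, CSF %g, ECF bulk %g\n",
              x$Q_CBF, x$Q_CSF, x$Q_ECF_bulk))
  cat(sprintf("  BBB: SA %g cm^2, pore radius %g um (paracellular %g%% of SA)\n",
              x$SA_BBB, x$para_radius_BBB, x$frac_SA_para_BBB))
  cat(sprintf("  pH: plasma %g, ECF %g, CSF %g, ICF %g, lysosome %g\n",
              x$pH_plasma, x$pH_ECF, x$pH_CSF, x$pH_ICF, x$pH_LYS))
  n <- length(validate_physiology(x))
  cat(if (n == 0) "  valid\n" else sprintf("  %d invariant violation(s)\n", n))
  invisible(x)
}

#' Lysosomal volume from brain ICF volume
#'
#' Lysosomes occupy 1.25% (1/80) of the brain intracellular fluid volume.
#'
#' @param V_ICF Brain ICF volume, mL (> 0).
#' @return Lysosomal volume, mL.
#' @examples
#' derive_lysosome_volume(1000) # 12.5
#' @export
derive_lysosome_volume <- function(V_ICF) {
  if (!is.numeric(V_ICF) || any(!is.finite(V_ICF)) || any(V_ICF <= 0)) {
    stop("V_ICF must be strictly positive", call. = FALSE)
  }
  V_ICF / 80
}

#' Blood--CSF barrier surface area from BBB surface area
#'
#' The BCSFB area is taken as 10% of the BBB area, split equally between the
#' lateral-ventricle and third+fourth-ventricle interfaces.
#'
#' @param SA_BBB BBB surface area, cm^2 (> 0).
#' @return A list with `total`, `LV` and `TFV` areas in cm^2.
#' @examples
#' derive_bcsfb_area(150000)
#' @export
derive_bcsfb_area <- function(SA_BBB) {
  if (!is.numeric(SA_BBB) || any(!is.finite(SA_BBB)) || any(SA_BBB <= 0)) {
    stop("SA_BBB must be strictly positive", call. = FALSE)
  }
  total <- 0.1 * SA_BBB
  list(total = total, LV = total / 2, TFV = total / 2)
}

physiology_fields <- function() names(default_physiology())

#' Validate a CNS physiology parameter set
#'
#' Checks the hard structural invariants: strict positivity of volumes,
#' flows, areas, radii and barrier width; pH within `[0, 14]`; the
#' lysosomal-volume rule `V_LYS == V_ICF / 80`; the BCSFB-area rule
#' `SA_BCSFB == 0.1 * SA_BBB`; and `Q_ECF_bulk <= Q_CSF`. Violations are
#' returned as data, not raised as errors.
#'
#' @param physiology A `cns_physiology` object or compatible named list.
#' @param tol Relative tolerance for the derived-quantity rules (the printed
#'   reference values are rounded).
#' @return Character vector of violation messages; empty if valid.
#' @examples
#' validate_physiology(default_physiology())
#' @export
validate_physiology <- function(physiology, tol = 0.05) {
  p <- physiology
  missing <- setdiff(physiology_fields(), names(p))
  if (length(missing) > 0) {
    return(paste0("missing field: ", missing))
  }
  out <- character()
  positive <- c("V_brain_total", "V_ECF", "V_ICF", "V_LYS", "V_MV", "V_LV",
                "V_TFV", "V_CM", "V_SAS", "Q_CBF", "Q_ECF_bulk", "Q_CSF",
                "SA_BBB", "SA_BCSFB", "SA_BCM", "SA_LYS", "width_barrier",
                "para_radius_BBB", "para_radius_BCSFB", "frac_SA_trans",
                "frac_SA_para_BBB", "frac_SA_para_BCSFB", "N_cells")
  for (f in positive) {
    v <- p[[f]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0) {
      out <- c(out, paste0(f, ": must be strictly positive"))
    }
  }
  for (f in c("pH_plasma", "pH_ECF", "pH_CSF", "pH_ICF", "pH_LYS")) {
    v <- p[[f]]
    if (!is.numeric(v) || !is.finite(v) || v < 0 || v > 14) {
      out <- c(out, paste0(f, ": pH must be within [0, 14]"))
    }
  }
  relerr <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.eps)
  if (is.numeric(p$V_LYS) && is.numeric(p$V_ICF) && p$V_ICF > 0 &&
      relerr(p$V_LYS, p$V_ICF / 80) > tol) {
    out <- c(out, "V_LYS: must equal V_ICF / 80")
  }
  if (is.numeric(p$SA_BCSFB) && is.numeric(p$SA_BBB) && p$SA_BBB > 0 &&
      relerr(p$SA_BCSFB, 0.1 * p$SA_BBB) > tol) {
    out <- c(out, "SA_BCSFB: must equal 0.1 * SA_BBB")
  }
  if (is.numeric(p$Q_ECF_bulk) && is.numeric(p$Q_CSF) &&
      p$Q_ECF_bulk > p$Q_CSF) {
    out <- c(out, "Q_ECF_bulk: must not exceed Q_CSF")
  }
  out
}

#' Read / write a CNS physiology parameter set
#'
#' Physiology sets are stored as flat key--value YAML with keys named exactly
#' as in [default_physiology()]. Units (mL, mL/min, cm^2, um, %, pH) are
#' fixed by the schema and never auto-converted.
#'
#' @param path File path.
#' @return `read_physiology()` returns a `cns_physiology`;
#'   `write_physiology()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_physiology(default_physiology(), f)
#' identical(unclass(read_physiology(f)), unclass(default_physiology()))
#' @export
read_physiology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  missing <- setdiff(physiology_fields(), names(raw))
  if (length(missing) > 0) {
    stop("physiology file ", path, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  phys <- structure(lapply(raw[physiology_fields()], as.numeric),
                    class = "cns_physiology")
  bad <- validate_physiology(phys)
  if (length(bad) > 0) {
    stop("invalid physiology in ", path, ":\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  phys
}

#' @param physiology A `cns_physiology` object.
#' @rdname read_physiology
#' @export
write_physiology <- function(physiology, path) {
  header <- paste(
    "# CNS physiology parameter set.",
    "# Units: V_* mL; Q_* mL/min; SA_* cm^2; width/radii um;",
    "# frac_SA_* percent of barrier area; pH_* pH units; N_cells count.",
    sep = "\n")
  body <- yaml::as.yaml(unclass(physiology), precision = 15)
  writeLines(c(header, body), path)
  invisible(path)
}
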