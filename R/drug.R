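#' Drug parameter set
#'
#' One drug's physicochemistry, ionization, unbound partition-coefficient
#' targets and BBB transport clearances. The three clearances are whole-BBB
#' values at reference physiology (pore radius 0.0007 um, compartment pH at
#' reference): `CL_P` the symmetric paracellular clearance, `CL_T_ef` and
#' `CL_T_in` the transcellular efflux (brain-to-blood) and influx
#' (blood-to-brain) clearances. Values reported below a detection bound
#' ("<0.01") are stored as 0. Transporter substrate flags are descriptive
#' metadata: net active transport enters the model through asymmetry factors
#' calibrated against `Kpuu_ECF` (see [calibrate_asymmetry()]).
#'
#' @param name Drug identifier.
#' @param Mwt Molecular weight, g/mol, within `[100, 1000]`.
#' @param logP Octanol--water partition coefficient (log10).
#' @param ionization An [ionization_spec()].
#' @param Kpuu_ECF Target unbound brain-ECF-to-plasma AUC ratio (> 0).
#' @param Kpuu_LV,Kpuu_CM Analogous targets at the lateral-ventricle and
#'   cisterna-magna CSF; default to `Kpuu_ECF`.
#' @param BCRP,p_gp,OAT3,MRP4 Logical transporter substrate flags.
#' @param CL_P,CL_T_ef,CL_T_in BBB clearances, mL/min, all `>= 0`.
#'
#' @return An object of class `drug_parameters`.
#' @examples
#' drug_parameters("caffeine", Mwt = 194.2, logP = -0.07,
#'                 ionization = ionization_spec("neutral"),
#'                 Kpuu_ECF = 0.96, CL_P = 48.9,
#'                 CL_T_ef = 4.28, CL_T_in = 2.38)
#' @export
drug_parameters <- function(name, Mwt, logP, ionization,
                            Kpuu_ECF, Kpuu_LV = Kpuu_ECF, Kpuu_CM = Kpuu_ECF,
                            BCRP = FALSE, p_gp = FALSE,
                            OAT3 = FALSE, MRP4 = FALSE,
                            CL_P, CL_T_ef, CL_T_in) {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) {
    stop("drug name must be a non-empty string", call. = FALSE)
  }
  fail <- function(field, msg) {
    stop("drug '", name, "', field '", field, "': ", msg, call. = FALSE)
  }
  num1 <- function(x, field) {
    x <- as.numeric(x)
    if (length(x) != 1L || !is.finite(x)) fail(field, "must be a finite number")
    x
  }
  Mwt <- num1(Mwt, "Mwt")
  if (Mwt < 100 || Mwt > 1000) fail("Mwt", "must lie within [100, 1000] g/mol")
  logP <- num1(logP, "logP")
  if (!inherits(ionization, "ionization_spec")) {
    fail("ionization", "must be an ionization_spec")
  }
  for (f in c("Kpuu_ECF", "Kpuu_LV", "Kpuu_CM")) {
    v <- num1(get(f), f)
    if (v <= 0) fail(f, "must be strictly positive")
    assign(f, v)
  }
  for (f in c("CL_P", "CL_T_ef", "CL_T_in")) {
    v <- num1(get(f), f)
    if (v < 0) fail(f, "must be non-negative (mL/min)")
    assign(f, v)
  }
  flags <- vapply(list(BCRP = BCRP, p_gp = p_gp, OAT3 = OAT3, MRP4 = MRP4),
                  function(x) isTRUE(as.logical(x)), logical(1))
  structure(list(
    name = name, Mwt = Mwt, logP = logP, ionization = ionization,
    Kpuu_ECF = Kpuu_ECF, Kpuu_LV = Kpuu_LV, Kpuu_CM = Kpuu_CM,
    BCRP = flags[["BCRP"]], p_gp = flags[["p_gp"]],
    OAT3 = flags[["OAT3"]], MRP4 = flags[["MRP4"]],
    CL_P = CL_P, CL_T_ef = CL_T_ef, CL_T_in = CL_T_in
  ), class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters> %s: Mwt %g, logP %g, %s\n",
              x$name, x$Mwt, x$logP, x$ionization$ion_class))
  cat(sprintf("  Kp_uu,ECF %g | CL_P %g, CL_T,ef %g, CL_T,in %g mL/min\n",
              x$Kpuu_ECF, x$CL_P, x$CL_T_ef, x$CL_T_in))
  subs <- c("BCRP", "p-gp", "OAT3", "MRP4")[c(x$BCRP, x$p_gp, x$OAT3, x$MRP4)]
  if (length(subs) > 0) cat("  substrate of:", paste(subs, collapse = ", "), "\n")
  invisible(x)
}
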