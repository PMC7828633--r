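#' Ionization specification of a drug
#'
#' Describes the ionizable groups of a small molecule: its ionization class
#' and up to one acidic and one basic group. `pkb` is the pKa of the
#' conjugate acid of the basic group (the "strongest basic pKa" convention of
#' common pKa calculators), so a negative `pkb` describes a group that is
#' essentially never protonated at physiological pH.
#'
#' Only the neutral microspecies is assumed to permeate lipid membranes;
#' ionized species are restricted to the paracellular route and bulk fluid
#' flows. Multiprotic behaviour beyond one acid plus one base group is not
#' modelled.
#'
#' @param ion_class One of `"acid"`, `"base"`, `"neutral"`, `"zwitterion"`
#'   (case-insensitive).
#' @param pka Acid dissociation constant (pH units). Required for acids and
#'   zwitterions; may be `NA` otherwise.
#' @param pkb Conjugate-acid pKa of the basic group (pH units). Required for
#'   bases and zwitterions; may be `NA` otherwise.
#'
#' @return An object of class `ionization_spec`.
#' @examples
#' fraction_unionized(ionization_spec("acid", pka = 7.2), pH = 7.4)
#' @export
ionization_spec <- function(ion_class, pka = NA_real_, pkb = NA_real_) {
  ion_class <- tolower(as.character(ion_class))
  classes <- c("acid", "base", "neutral", "zwitterion")
  if (length(ion_class) != 1L || !ion_class %in% classes) {
    stop("unknown ionization class: ", paste(ion_class, collapse = ", "),
         " (expected one of ", paste(classes, collapse = ", "), ")",
         call. = FALSE)
  }
  pka <- as.numeric(pka)
  pkb <- as.numeric(pkb)
  if (ion_class %in% c("acid", "zwitterion") && !is.finite(pka)) {
    stop("ionization class '", ion_class, "' requires a finite pk_a",
         call. = FALSE)
  }
  if (ion_class %in% c("base", "zwitterion") && !is.finite(pkb)) {
    stop("ionization class '", ion_class, "' requires a finite pk_b",
         call. = FALSE)
  }
  structure(list(ion_class = ion_class, pka = pka, pkb = pkb),
            class = "ionization_spec")
}

#' @export
print.ionization_spec <- function(x, ...) {
  cat("<ionization_spec>", x$ion_class)
  if (is.finite(x$pka)) cat("  pk_a =", x$pka)
  if (is.finite(x$pkb)) cat("  pk_b =", x$pkb)
  cat("\n")
  invisible(x)
}

check_ph <- function(pH, what = "pH") {
  if (!is.numeric(pH) || any(!is.finite(pH)) || any(pH < 0) || any(pH > 14)) {
    stop(what, " must be numeric and within [0, 14]", call. = FALSE)
  }
  invisible(pH)
}

#' Fraction of drug in the unionized (membrane-permeant) form
#'
#' Henderson--Hasselbalch fraction of the neutral microspecies at a given pH.
#' Acids: `1 / (1 + 10^(pH - pk_a))`; bases: `1 / (1 + 10^(pk_b - pH))`;
#' zwitterions: the product of the two factors; neutral drugs: exactly 1 at
#' every pH.
#'
#' @param spec An [ionization_spec()].
#' @param pH Compartment pH, in `[0, 14]`. Vectorized.
#'
#' @return Fraction in `(0, 1]`.
#' @examples
#' fraction_unionized(ionization_spec("base", pkb = 9.12), pH = 7.0)
#' @export
fraction_unionized <- function(spec, pH) {
  stopifnot(inherits(spec, "ionization_spec"))
  check_ph(pH)
  switch(spec$ion_class,
    neutral    = rep(1, length(pH)),
    acid       = 1 / (1 + 10^(pH - spec$pka)),
    base       = 1 / (1 + 10^(spec$pkb - pH)),
    zwitterion = (1 / (1 + 10^(pH - spec$pka))) *
                 (1 / (1 + 10^(spec$pkb - pH)))
  )
}

#' pH rescaling factor for a transcellular clearance
#'
#' Ratio of the unionized fractions at a perturbed versus a reference pH.
#' Multiplies every membrane (transcellular) clearance whose *source*
#' compartment's pH has been perturbed, since only the neutral species
#' crosses the membrane. Equals 1 for neutral drugs, decreases with rising
#' `pH_new` for acids, increases for bases.
#'
#' @param spec An [ionization_spec()].
#' @param pH_new Perturbed source-compartment pH.
#' @param pH_ref Reference source-compartment pH.
#'
#' @return A positive ratio; 1 when `pH_new == pH_ref`.
#' @examples
#' ph_scaling_factor(ionization_spec("acid", pka = 7.2), 8.0, 7.3)
#' @export
ph_scaling_factor <- function(spec, pH_new, pH_ref) {
  fraction_unionized(spec, pH_new) / fraction_unionized(spec, pH_ref)
}
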