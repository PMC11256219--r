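# Scattering-length-density bookkeeping for interfacial components and
# solvent isotopic contrasts. All SLDs are in units of 1e-6 / Angstrom^2.

# Pure-water endpoint SLDs (1e-6 A^-2), from sum(b)/V with the measured
# molecular volumes of light and heavy water at room temperature.
SLD_H2O <- -0.56
SLD_D2O <- 6.36

#' Default material table
#'
#' Scattering length densities (SLD, units of \eqn{10^{-6}\ \AA^{-2}}) for the
#' components of the silicon / permalloy / gold / SAM / water / membrane
#' interface. Materials whose labile hydrogens exchange with the solvent carry
#' distinct H2O and D2O endpoint values; the SLD at intermediate isotopic
#' contrast is interpolated linearly in the D2O volume fraction (complete,
#' instantaneous exchange). Non-exchanging materials (metals, oxide, lipid
#' tails) have equal endpoints. Values are conventional literature numbers and
#' are fully user-overridable: pass a modified copy of this table to any
#' function accepting a `materials` argument.
#'
#' @return A tibble with columns `material`, `sld_h2o`, `sld_d2o`.
#' @examples
#' default_materials()
#' @export
default_materials <- function() {
  tibble::tribble(
    ~material,      ~sld_h2o, ~sld_d2o,
    "si",               2.07,     2.07,
    "sio2",             3.47,     3.47,
    "permalloy",        8.50,     8.50,
    "gold",             4.50,     4.50,
    "sam",              0.30,     0.60,
    "lipid_heads",      1.85,     1.92,
    "lipid_tails",     -0.40,    -0.40,
    "protein",          1.90,     3.20
  )
}

#' Standard solvent contrasts
#'
#' The four isotopic contrasts used throughout: pure D2O, gold-matched water
#' (AuMW, 75\% v/v D2O), protein-matched water (PrMW, 42\% v/v D2O) and pure
#' H2O.
#'
#' @return A tibble with columns `contrast`, `d2o_fraction`.
#' @export
standard_contrasts <- function() {
  tibble::tribble(
    ~contrast, ~d2o_fraction,
    "D2O",  1.00,
    "AuMW", 0.75,
    "PrMW", 0.42,
    "H2O",  0.00
  )
}

# Resolve a contrast given as a name ("D2O"), a bare fraction, or a
# list/one-row data frame with a d2o_fraction field.
resolve_d2o_fraction <- function(contrast, contrasts = standard_contrasts()) {
  if (is.numeric(contrast)) {
    f <- as.numeric(contrast)
  } else if (is.character(contrast)) {
    i <- match(contrast, contrasts$contrast)
    if (anyNA(i)) {
      stop("unknown contrast name(s): ",
           paste(contrast[is.na(i)], collapse = ", "), call. = FALSE)
    }
    f <- contrasts$d2o_fraction[i]
  } else if (is.list(contrast) && !is.null(contrast$d2o_fraction)) {
    f <- as.numeric(contrast$d2o_fraction)
  } else {
    stop("cannot interpret `contrast`", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f < 0 | f > 1)) {
    stop("d2o_fraction must lie in [0, 1]", call. = FALSE)
  }
  f
}

#' Solvent scattering length density
#'
#' SLD of an H2O/D2O mixture as a linear volume-fraction mixture of the pure
#' endpoint values (-0.56 and 6.36 in units of \eqn{10^{-6}\ \AA^{-2}}).
#'
#' @param d2o_fraction Volume fraction of D2O, in `[0, 1]`. Vectorised.
#' @return SLD in \eqn{10^{-6}\ \AA^{-2}}.
#' @examples
#' water_sld(c(0, 0.42, 0.75, 1))
#' @export
water_sld <- function(d2o_fraction) {
  if (any(!is.finite(d2o_fraction)) || any(d2o_fraction < 0 | d2o_fraction > 1)) {
    stop("d2o_fraction must lie in [0, 1]", call. = FALSE)
  }
  SLD_H2O + d2o_fraction * (SLD_D2O - SLD_H2O)
}

# Look up one material's endpoint SLDs from the table; `material` may also be
# a list/one-row data frame carrying sld_h2o/sld_d2o directly.
material_endpoints <- function(material, materials = default_materials()) {
  if (is.character(material)) {
    i <- match(material, materials$material)
    if (anyNA(i)) {
      stop("unknown material(s): ", paste(material[is.na(i)], collapse = ", "),
           call. = FALSE)
    }
    list(h2o = materials$sld_h2o[i], d2o = materials$sld_d2o[i])
  } else if (is.list(material) && !is.null(material$sld_h2o)) {
    list(h2o = as.numeric(material$sld_h2o),
         d2o = as.numeric(material$sld_d2o %||% material$sld_h2o))
  } else {
    stop("cannot interpret `material`", call. = FALSE)
  }
}

#' Material SLD at a given solvent contrast
#'
#' Linear interpolation between a material's H2O and D2O endpoint SLDs by the
#' solvent D2O volume fraction, modelling complete exchange of labile
#' hydrogens. Non-exchanging materials have equal endpoints and are constant
#' across contrasts.
#'
#' @param material A material name from the `materials` table, or a list with
#'   `sld_h2o` (and optionally `sld_d2o`) fields.
#' @param contrast A contrast name (`"D2O"`, `"AuMW"`, `"PrMW"`, `"H2O"`), a
#'   D2O volume fraction in `[0, 1]`, or a list with a `d2o_fraction` field.
#' @param materials,contrasts Lookup tables; see [default_materials()] and
#'   [standard_contrasts()].
#' @return SLD in \eqn{10^{-6}\ \AA^{-2}}.
#' @examples
#' material_sld("protein", "PrMW")
#' material_sld("gold", 0.3)
#' @export
material_sld <- function(material, contrast,
                         materials = default_materials(),
                         contrasts = standard_contrasts()) {
  ep <- material_endpoints(material, materials)
  f <- resolve_d2o_fraction(contrast, contrasts)
  ep$h2o + f * (ep$d2o - ep$h2o)
}

#' Volume-fraction-weighted SLD of a composite layer
#'
#' Computes the mean SLD of a layer composed of several materials at given
#' volume fractions, with solvent filling the unoccupied remainder. The
#' component fractions must not exceed unity: the total volume fraction of
#' the components cannot exceed nor be less than 100\% once the solvent
#' remainder is included.
#'
#' @param composition A named numeric vector of volume fractions (names are
#'   materials in the `materials` table), or a data frame with columns
#'   `material` and `fraction`. An empty composition is pure solvent.
#' @inheritParams material_sld
#' @return SLD in \eqn{10^{-6}\ \AA^{-2}}.
#' @examples
#' layer_sld(c(lipid_tails = 0.61, protein = 0.24), "D2O")
#' layer_sld(c(), "D2O")   # pure solvent
#' @export
layer_sld <- function(composition, contrast,
                      materials = default_materials(),
                      contrasts = standard_contrasts()) {
  f <- resolve_d2o_fraction(contrast, contrasts)
  if (is.data.frame(composition)) {
    nm <- composition$material
    fr <- composition$fraction
  } else {
    nm <- names(composition)
    fr <- as.numeric(composition)
  }
  if (length(fr) == 0) {
    return(water_sld(f))
  }
  if (any(fr < 0)) stop("volume fractions must be >= 0", call. = FALSE)
  tot <- sum(fr)
  if (tot > 1 + 1e-9) {
    stop("component volume fractions sum to ", signif(tot, 6),
         " > 1; the layer cannot be over-filled", call. = FALSE)
  }
  slds <- material_sld(nm, f, materials, contrasts)
  sum(fr * slds) + (1 - tot) * water_sld(f)
}
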