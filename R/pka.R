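#' Physical constants of the thermochemistry
#'
#' `HARTREE_TO_J_MOL` converts Hartree to J/mol; `GAS_CONSTANT` is R in
#' J mol^-1 K^-1; `PKA_WATER_298` is the pKa of water at 298.15 K, the additive
#' anchor of the pKa equation; `LOG10_FACTOR` is the literal 2.302 prefactor of
#' the denominator (see [pka_from_delta_g()] for the `ln10` switch).
#'
#' @name pka-constants
NULL

#' @rdname pka-constants
#' @export
HARTREE_TO_J_MOL <- 2625499.6

#' @rdname pka-constants
#' @export
GAS_CONSTANT <- 8.31446

#' @rdname pka-constants
#' @export
PKA_WATER_298 <- 15.74

#' @rdname pka-constants
#' @export
LOG10_FACTOR <- 2.302

.ref_temperature <- 298.15

.log_factor <- function(ln10) if (isTRUE(ln10)) log(10) else LOG10_FACTOR

.check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)", call. = FALSE)
  }
  if (abs(temperature - .ref_temperature) > 1e-6) {
    warning("the ", PKA_WATER_298, " water-pKa anchor is valid at 298.15 K only; ",
            "results at T = ", temperature, " K use it unchanged", call. = FALSE)
  }
  invisible(temperature)
}

#' Deprotonation Gibbs free energy from per-species energies
#'
#' Assembles the reaction free energy of the explicit dissociation
#' `acid + OH- -> base + H2O` (every species micro-solvated by two waters) from
#' the four per-species Gibbs free energies and converts it from Hartree to
#' J/mol.
#'
#' @param g_base,g_water,g_hydroxide,g_acid Gibbs free energies in Hartree of
#'   the conjugate-base, water-trimer, hydroxide and acid clusters.
#' @return Reaction free energy in J/mol:
#'   `(g_base + g_water - g_hydroxide - g_acid) * HARTREE_TO_J_MOL`.
#' @examples
#' delta_g_dep(-495.1, -76.9, -76.7, -495.3) # == 0 only if the sums cancel
#' @export
delta_g_dep <- function(g_base, g_water, g_hydroxide, g_acid) {
  vals <- c(g_base, g_water, g_hydroxide, g_acid)
  if (!is.numeric(vals) || length(vals) != 4L || !all(is.finite(vals))) {
    stop("all four species energies must be finite numbers (Hartree)", call. = FALSE)
  }
  (g_base + g_water - g_hydroxide - g_acid) * HARTREE_TO_J_MOL
}

#' Convert a deprotonation free energy to pKa
#'
#' `pka = delta_g / (2.302 * R * T) + 15.74`. The offset 15.74 is the pKa of
#' water at 298.15 K; one pKa unit corresponds to 2.302*R*298.15 = 5706.6 J/mol.
#'
#' @param delta_g Deprotonation free energy in J/mol (vectorised).
#' @param temperature Absolute temperature in kelvin (default 298.15). A value
#'   other than 298.15 K triggers a warning because the water anchor is only
#'   valid there.
#' @param ln10 Use exact `ln(10) = 2.302585...` instead of the literal
#'   constant 2.302. The difference grows with distance from the water
#'   anchor and stays below 0.005 pKa units on this panel — under the 0.01
#'   reporting grain either way.
#' @return Dimensionless pKa.
#' @examples
#' pka_from_delta_g(0)       # 15.74, the water anchor
#' pka_from_delta_g(5706.6)  # one unit above: 16.74
#' @export
pka_from_delta_g <- function(delta_g, temperature = 298.15, ln10 = FALSE) {
  .check_temperature(temperature)
  if (!is.numeric(delta_g) || !all(is.finite(delta_g))) {
    stop("`delta_g` must be finite (J/mol)", call. = FALSE)
  }
  delta_g / (.log_factor(ln10) * GAS_CONSTANT * temperature) + PKA_WATER_298
}

#' Invert the pKa equation
#'
#' Exact algebraic inverse of [pka_from_delta_g()]:
#' `(pka - 15.74) * 2.302 * R * T`. Used by the mock engine to back-derive
#' species energies from target pKa values.
#'
#' @inheritParams pka_from_delta_g
#' @param pka Dimensionless pKa (vectorised).
#' @return Deprotonation free energy in J/mol.
#' @export
delta_g_from_pka <- function(pka, temperature = 298.15, ln10 = FALSE) {
  .check_temperature(temperature)
  if (!is.numeric(pka) || !all(is.finite(pka))) {
    stop("`pka` must be finite", call. = FALSE)
  }
  (pka - PKA_WATER_298) * .log_factor(ln10) * GAS_CONSTANT * temperature
}

#' Build a table of pKa records
#'
#' One row per compound x functional, holding the assembled deprotonation free
#' energy and the derived pKa. The pKa column always satisfies the pKa
#' equation against the stored free energy and temperature.
#'
#' @param compound,functional Character vectors (recycled to a common length).
#' @param delta_g_dep Deprotonation free energies in J/mol.
#' @param temperature Kelvin, default 298.15.
#' @param ln10 See [pka_from_delta_g()].
#' @return A data.frame with columns `compound`, `functional`,
#'   `delta_g_dep_J_per_mol`, `pka`, `temperature_K`.
#' @export
pka_records <- function(compound, functional, delta_g_dep, temperature = 298.15,
                        ln10 = FALSE) {
  data.frame(
    compound = as.character(compound),
    functional = as.character(functional),
    delta_g_dep_J_per_mol = as.numeric(delta_g_dep),
    pka = pka_from_delta_g(delta_g_dep, temperature, ln10),
    temperature_K = rep_len(temperature, length(delta_g_dep)),
    stringsAsFactors = FALSE
  )
}

#' Write / read pKa record tables
#'
#' CSV or JSON serialization of the table produced by [pka_records()].
#'
#' @param records Data.frame from [pka_records()].
#' @param path Output (input) file path.
#' @param format `"csv"` or `"json"`.
#' @return `write_pka_records()` returns `path` invisibly; `read_pka_records()`
#'   returns the records data.frame.
#' @export
write_pka_records <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' @rdname write_pka_records
#' @export
read_pka_records <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
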