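# Physical constants. Internal list for speed; exported accessor for users.
.const <- list(
  R = 8.314,              # gas constant, J/(mol K)
  N_A = 6.02214076e23,    # Avogadro constant, 1/mol
  unit_factor = 1e-23     # 1 Angstrom^2 x mN/m = 1e-20 m^2 x 1e-3 N/m = 1e-23 J
)

#' Physical constants used by the package
#'
#' Returns the gas constant `R` (J mol^-1 K^-1), the Avogadro constant `N_A`
#' (mol^-1) and `unit_factor`, the energy equivalent of one Angstrom squared
#' times one mN/m (1e-23 J). Per-molecule work integrals in \eqn{\AA^2} mN/m
#' convert to J/mol as `value * unit_factor * N_A` (about 6.022 J/mol per
#' \eqn{\AA^2} mN/m).
#'
#' @return Named list with elements `R`, `N_A` and `unit_factor`.
#' @examples
#' k <- monolayer_constants()
#' k$unit_factor * k$N_A   # J/mol per (Angstrom^2 mN/m)
#' @export
monolayer_constants <- function() .const

#' Round half away from zero at printed precision
#'
#' Publication tables conventionally round half away from zero (0.0085, 0.011,
#' 0.048 ...), unlike [round()]'s round-half-even. Used when comparing computed
#' mole fractions and moduli ratios against printed values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties going away from zero.
#' @examples
#' round_printed(1 / 91, 3)   # 0.011
#' round_printed(0.0085, 3)   # 0.009, not 0.008
#' @export
round_printed <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
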