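#' Convert a molar ratio to pseudo-binary mole fractions
#'
#' A ternary protein/lipid1/lipid2 film spread at molar ratio `1:m:m` is
#' treated as a pseudo-binary system of protein versus the (equimolar) lipid
#' mixture: the protein mole fraction is `ratio[1] / sum(ratio)` and the lipid
#' fraction counts every lipid molecule, so `1:45:45` gives
#' \eqn{X_{protein} = 1/91}. Division is exact; use [round_printed()] to match
#' publication-precision values (1/91 prints as 0.011).
#'
#' @param ratio numeric vector of non-negative molar parts, protein first;
#'   e.g. `c(1, 45, 45)`.
#' @return A `composition`: list with `ratio`, `x_protein` and `x_lipids`.
#' @examples
#' ratio_to_molefractions(c(1, 45, 45))$x_protein   # 1/91
#' @export
ratio_to_molefractions <- function(ratio) {
  ratio <- as.numeric(ratio)
  if (any(ratio < 0) || !any(ratio > 0))
    abort_domain("ratio parts must be non-negative with a positive sum")
  x <- ratio[1] / sum(ratio)
  structure(list(ratio = ratio, x_protein = x, x_lipids = 1 - x),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> ratio %s : X_protein = %.6g (prints %.3g), X_lipids = %.6g\n",
              paste(x$ratio, collapse = ":"), x$x_protein,
              round_printed(x$x_protein, 3), x$x_lipids))
  invisible(x)
}

#' Parse a molar-ratio string such as "1:45:45"
#'
#' @param s a string of `:`-separated non-negative numbers.
#' @return A `composition` (see [ratio_to_molefractions()]).
#' @export
parse_ratio <- function(s) {
  parts <- suppressWarnings(as.numeric(strsplit(trimws(s), ":", fixed = TRUE)[[1]]))
  if (anyNA(parts)) abort_parse(sprintf("cannot parse ratio string '%s'", s))
  ratio_to_molefractions(parts)
}

resample_named <- function(iso, grid, what) {
  tryCatch(resample_area_on_pressure(iso, grid),
           monolayer_range_error = function(e)
             abort_range(sprintf("%s: %s", what, conditionMessage(e))))
}

#' Additivity-rule mean molecular area of a mixed film
#'
#' For ideal mixing (or complete immiscibility) the mixture's mean molecular
#' area at a given surface pressure is the mole-fraction-weighted sum of the
#' component areas, \eqn{A_{add}(\pi) = \sum_i X_i A_i(\pi)}.
#'
#' @param components list of compression-branch `isotherm`s.
#' @param fractions mole fractions, same length, summing to 1 within 1e-9.
#' @param pressure numeric vector of surface pressures, mN/m.
#' @return Numeric vector of additive areas, \eqn{\AA^2}/molecule.
#' @export
additive_area <- function(components, fractions, pressure) {
  if (length(components) != length(fractions))
    abort_param("one mole fraction per component is required")
  if (abs(sum(fractions) - 1) > 1e-9) abort_param("fractions must sum to 1")
  out <- numeric(length(pressure))
  for (i in seq_along(components)) {
    if (fractions[i] == 0) next
    out <- out + fractions[i] *
      as.vector(resample_named(components[[i]], pressure,
                               sprintf("component '%s'", components[[i]]$name)))
  }
  out
}

#' Deviation of the experimental area from the additivity rule
#'
#' \eqn{\Delta A(\pi) = A_{exp}(\pi) - A_{add}(\pi)}. Negative values indicate
#' that protein-lipid attraction exceeds the like-like interactions (film
#' compaction, miscibility); positive values indicate like-like attraction and
#' a tendency towards phase separation; values on the additive line are
#' compatible with either ideal mixing or complete demixing.
#'
#' @param mixture compression-branch `isotherm` of the mixed film.
#' @param components list of component `isotherm`s.
#' @param fractions mole fractions of the components in the mixture.
#' @param pressures surface pressures at which to evaluate, mN/m.
#' @return data.frame with columns `pressure`, `a_exp`, `a_add`, `delta_a`.
#' @export
area_deviation <- function(mixture, components, fractions, pressures) {
  a_exp <- as.vector(resample_named(mixture, pressures,
                                    sprintf("mixture '%s'", mixture$name)))
  a_add <- additive_area(components, fractions, pressures)
  data.frame(pressure = pressures, a_exp = a_exp,
             a_add = a_add, delta_a = a_exp - a_add)
}

# integral of A(pi') d pi' from 0 to pi on a deterministic merged grid:
# the union of all curves' retained knots within [0, pi] plus a uniform
# refinement. Returns per-curve totals and the below-lift-off (constant
# extension) share of each.
goodrich_integrals <- function(curves, pressure, n_grid = 201) {
  knots <- unlist(lapply(curves, function(iso) {
    k <- monotone_knots(iso)
    k$pressure[k$pressure <= pressure]
  }))
  grid <- sort(unique(c(0, pressure, seq(0, pressure, length.out = n_grid), knots)))
  lapply(curves, function(iso) {
    a <- resample_named(iso, grid, sprintf("isotherm '%s'", iso$name))
    k <- monotone_knots(iso)
    p_lift <- min(k$pressure)
    list(total = pracma::trapz(grid, as.numeric(a)),
         extension = k$area[1] * max(0, min(p_lift, pressure)))
  })
}

#' Goodrich excess free energy of mixing at a surface pressure
#'
#' Integrates the pi/A isotherms of the mixed film and of its components from
#' zero up to the working surface pressure:
#' \deqn{\Delta G_{exc}^{\pi} = N_A \left( \int_0^{\pi} A_{mix}\,d\pi
#'   - X_1 \int_0^{\pi} A_1\,d\pi - X_2 \int_0^{\pi} A_2\,d\pi \right),}
#' with the per-molecule work in \eqn{\AA^2} mN/m converted to J/mol via
#' 1e-23 J and the Avogadro constant. Each integral uses the composite
#' trapezoid rule on the union of the curves' knots plus a uniform refinement
#' (deterministic). Curves that lift off above pi = 0 are extended at constant
#' lift-off area down to zero; the net contribution of those flat segments is
#' returned in the attribute `extension_J_mol`.
#'
#' @param mixture compression-branch `isotherm` of the mixed film.
#' @param components list of component `isotherm`s (for the pseudo-binary
#'   treatment: the protein film and the lipid-mixture film).
#' @param fractions mole fractions `(X_protein, X_lipids)` summing to 1.
#' @param pressure upper integration limit, mN/m, within every curve's
#'   retained range.
#' @param n_grid minimum number of uniform refinement nodes (default 201).
#' @return \eqn{\Delta G_{exc}^{\pi}} in J/mol, with attribute
#'   `extension_J_mol`.
#' @export
excess_free_energy <- function(mixture, components, fractions, pressure,
                               n_grid = 201) {
  if (abs(sum(fractions) - 1) > 1e-9) abort_param("fractions must sum to 1")
  use <- fractions != 0
  ints <- goodrich_integrals(c(list(mixture), components[use]), pressure, n_grid)
  w <- c(1, -fractions[use])
  area_term <- sum(w * vapply(ints, `[[`, 0, "total"))
  ext_term <- sum(w * vapply(ints, `[[`, 0, "extension"))
  f <- .const$unit_factor * .const$N_A
  structure(area_term * f, extension_J_mol = ext_term * f)
}

#' Ideal (entropic) free energy of mixing
#'
#' \eqn{\Delta G_{ideal} = RT\,[x \ln x + (1-x)\ln(1-x)]} with the convention
#' \eqn{0 \ln 0 = 0}. Always non-positive; zero only for a pure film;
#' symmetric in \eqn{x \leftrightarrow 1-x} and minimal at \eqn{x = 1/2}.
#'
#' @param x mole fraction of the first (protein) pseudo-component, in \[0,1\];
#'   vectorised.
#' @param temperature_K temperature, kelvin.
#' @return \eqn{\Delta G_{ideal}} in J/mol.
#' @examples
#' ideal_free_energy(0.5, 308.15)   # -RT log 2 = -1775.8 J/mol
#' @export
ideal_free_energy <- function(x, temperature_K = 308.15) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort_domain("mole fraction must lie in [0, 1]")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    abort_domain("temperature must be positive")
  xlx <- function(z) ifelse(z == 0, 0, z * log(z))
  .const$R * temperature_K * (xlx(x) + xlx(1 - x))
}

#' Total free energy of mixing at one surface pressure
#'
#' Assembles the full mixing record at a single (pressure, composition) point:
#' experimental and additive areas, their deviation, and
#' \eqn{\Delta G_{mix}^{\pi} = \Delta G_{exc}^{\pi} + \Delta G_{ideal}}
#' (the two parts summed as the same floats, so the identity is exact).
#' Negative \eqn{\Delta G_{mix}^{\pi}} means the mixed film is more stable
#' than the pure films: mixing is spontaneous.
#'
#' @inheritParams excess_free_energy
#' @param temperature_K temperature, kelvin.
#' @return A `mixing_result`: list with `pressure`, `x_protein`, `a_exp`,
#'   `a_add`, `delta_a`, `dg_exc`, `dg_ideal`, `dg_mix`,
#'   `extension_contribution` (all energies J/mol, areas
#'   \eqn{\AA^2}/molecule).
#' @export
mixing_free_energy <- function(mixture, components, fractions, pressure,
                               temperature_K = 308.15, n_grid = 201) {
  dev <- area_deviation(mixture, components, fractions, pressure)
  exc <- excess_free_energy(mixture, components, fractions, pressure, n_grid)
  ide <- ideal_free_energy(fractions[1], temperature_K)
  structure(list(
    pressure = pressure, x_protein = fractions[1],
    a_exp = dev$a_exp, a_add = dev$a_add, delta_a = dev$delta_a,
    dg_exc = as.numeric(exc), dg_ideal = ide,
    dg_mix = as.numeric(exc) + ide,
    extension_contribution = attr(exc, "extension_J_mol")
  ), class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("<mixing_result> pi = %g mN/m, X_protein = %.4g\n",
              x$pressure, x$x_protein))
  cat(sprintf("  A_exp = %.4g, A_add = %.4g, dA = %+.4g A2/molecule\n",
              x$a_exp, x$a_add, x$delta_a))
  cat(sprintf("  dG_exc = %+.6g, dG_ideal = %+.6g, dG_mix = %+.6g J/mol\n",
              x$dg_exc, x$dg_ideal, x$dg_mix))
  invisible(x)
}

#' Mixing thermodynamics over a pressure-by-composition table
#'
#' Runs [mixing_free_energy()] for every mixture at every requested pressure,
#' producing the machine-readable equivalent of the classic
#' \eqn{\Delta A(X)} and \eqn{\Delta G_{mix}^{\pi}(X)} panels.
#'
#' @param mixtures list where each element is a list with `isotherm` (the
#'   mixed-film compression branch) and either `composition` (a `composition`)
#'   or `fractions` `(X_protein, X_lipids)`.
#' @param components list of the two pseudo-component `isotherm`s (protein,
#'   lipid mixture).
#' @param pressures surface pressures for the scan, mN/m.
#' @param temperature_K temperature, kelvin.
#' @param n_grid integration refinement (see [excess_free_energy()]).
#' @return A `mixing_scan` data.frame with one row per (pressure, mixture),
#'   columns `pressure`, `x_protein`, `a_exp`, `a_add`, `delta_a`, `dg_exc`,
#'   `dg_ideal`, `dg_mix`, `extension_contribution`.
#' @export
mixing_scan <- function(mixtures, components, pressures,
                        temperature_K = 308.15, n_grid = 201) {
  rows <- list()
  for (m in mixtures) {
    fr <- if (!is.null(m$fractions)) m$fractions
          else c(m$composition$x_protein, m$composition$x_lipids)
    for (p in pressures) {
      r <- mixing_free_energy(m$isotherm, components, fr, p,
                              temperature_K, n_grid)
      rows[[length(rows) + 1L]] <- as.data.frame(unclass(r))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mixing_scan", "data.frame")
  attr(out, "temperature_K") <- temperature_K
  out
}

#' @export
summary.mixing_scan <- function(object, ...) {
  cat(sprintf("<mixing_scan> %d rows, %d pressures x %d compositions, T = %g K\n",
              nrow(object), length(unique(object$pressure)),
              length(unique(object$x_protein)), attr(object, "temperature_K")))
  cat(sprintf("  delta_a in [%+.3g, %+.3g] A2, dG_mix in [%+.5g, %+.5g] J/mol\n",
              min(object$delta_a), max(object$delta_a),
              min(object$dg_mix), max(object$dg_mix)))
  invisible(object)
}

#' @export
plot.mixing_scan <- function(x, which = c("delta_a", "dg_mix"), ...) {
  which <- match.arg(which)
  y <- x[[which]]
  ps <- sort(unique(x$pressure))
  graphics::plot(range(x$x_protein), range(y), type = "n",
                 xlab = expression(X[protein]),
                 ylab = if (which == "delta_a")
                   expression(Delta * A ~ (ring(A)^2 / molecule))
                 else expression(Delta * G[mix]^pi ~ (J/mol)), ...)
  for (i in seq_along(ps)) {
    s <- x[x$pressure == ps[i], ]
    s <- s[order(s$x_protein), ]
    graphics::lines(s$x_protein, s[[which]], type = "b", pch = i, lty = i)
  }
  graphics::abline(h = 0, lty = 3)
  graphics::legend("bottomleft", legend = sprintf("%g mN/m", ps),
                   pch = seq_along(ps), lty = seq_along(ps), bty = "n")
  invisible(x)
}

#' Write a mixing scan as TSV
#'
#' Columns: `pressure_mN_m`, `x_protein`, `a_exp_A2`, `a_add_A2`,
#' `delta_a_A2`, `dg_exc_J_mol`, `dg_ideal_J_mol`, `dg_mix_J_mol`,
#' `extension_J_mol`.
#'
#' @param scan a `mixing_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mixing_table <- function(scan, path) {
  hdr <- paste("pressure_mN_m", "x_protein", "a_exp_A2", "a_add_A2",
               "delta_a_A2", "dg_exc_J_mol", "dg_ideal_J_mol", "dg_mix_J_mol",
               "extension_J_mol", sep = "\t")
  rows <- sprintf("%.10g\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g",
                  scan$pressure, scan$x_protein, scan$a_exp, scan$a_add,
                  scan$delta_a, scan$dg_exc, scan$dg_ideal, scan$dg_mix,
                  scan$extension_contribution)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Interaction-amplitude diagnostic from the area deviation
#'
#' For mixtures whose non-ideality follows the exponential interaction model
#' \eqn{\Delta A(\pi) = \beta X_1 X_2 e^{-\pi/\pi_d}}, the amplitude
#' \eqn{\beta} equals \eqn{\Delta A(0)/(X_1 X_2)}. This diagnostic recovers it
#' by least squares of the measured \eqn{\Delta A(\pi)} on the known basis
#' \eqn{X_1 X_2 e^{-\pi/\pi_d}} over a low-pressure grid, i.e.
#' \eqn{\Delta A(0)/(X_1 X_2)} extrapolated along the model's own decay law,
#' which averages out pressure noise. Isotherms are Savitzky-Golay smoothed
#' first when `smooth = TRUE`.
#'
#' @param mixture,components,fractions as in [area_deviation()].
#' @param pi_d interaction decay pressure of the model, mN/m.
#' @param pressures evaluation grid; defaults to 41 points on
#'   \[0, 2 pi_d\] clipped to the curves' shared range.
#' @param smooth,window,order smoothing control (see [smooth_pressure()]).
#' @return Estimate of \eqn{\beta}, \eqn{\AA^2}.
#' @export
estimate_beta <- function(mixture, components, fractions, pi_d,
                          pressures = NULL, smooth = TRUE,
                          window = 11, order = 2) {
  if (smooth) {
    mixture <- smooth_pressure(mixture, window, order)
    components <- lapply(components, smooth_pressure, window = window, order = order)
  }
  if (is.null(pressures)) {
    hi <- min(vapply(c(list(mixture), components),
                     function(iso) max(monotone_knots(iso)$pressure), 0))
    pressures <- seq(0, min(2 * pi_d, hi), length.out = 41)
  }
  dev <- area_deviation(mixture, components, fractions, pressures)
  b <- fractions[1] * fractions[2] * exp(-pressures / pi_d)
  sum(b * dev$delta_a) / sum(b * b)
}
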