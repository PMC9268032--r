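#' Specification of a synthetic single-component isotherm
#'
#' The generator uses an exponential two-dimensional equation of state,
#' \deqn{A(\pi) = A_\infty + (A_0 - A_\infty)\,e^{-\pi/\pi_c},}
#' which has a finite area at zero pressure (so Goodrich integrals from
#' \eqn{\pi = 0} are exact without any extension) and closed forms for every
#' derived quantity: \eqn{\int_0^\pi A\,d\pi} and
#' \eqn{C_s^{-1}(\pi) = \pi_c A/(A - A_\infty)}.
#'
#' @param a0 area at zero pressure, \eqn{\AA^2}/molecule.
#' @param a_inf asymptotic high-pressure area, \eqn{\AA^2}/molecule;
#'   `0 < a_inf < a0`.
#' @param pi_c decay pressure, mN/m, positive.
#' @param pi_max final compression pressure, mN/m (ignored when `collapse`
#'   is given, where compression runs to the collapse pressure).
#' @param collapse optional list `list(pressure =, drop =, n_points = 10)`
#'   describing a post-collapse decline: after reaching `pressure` the film
#'   sheds `drop` mN/m over `n_points` extra points of decreasing area.
#' @param n_points points per branch, at least 20 (default 200).
#' @param noise_sigma standard deviation of seeded Gaussian pressure noise,
#'   mN/m (pressure is the measured signal on a Wilhelmy balance); noisy
#'   pressures are clipped at zero.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return A `component_spec`.
#' @export
component_spec <- function(a0, a_inf, pi_c, pi_max = 45, collapse = NULL,
                           n_points = 200, noise_sigma = 0, seed = NULL) {
  if (!(a0 > a_inf && a_inf > 0)) abort_spec("require a0 > a_inf > 0")
  if (pi_c <= 0) abort_spec("pi_c must be positive")
  if (pi_max <= 0) abort_spec("pi_max must be positive")
  if (n_points < 20) abort_spec("n_points must be at least 20")
  if (noise_sigma < 0) abort_spec("noise_sigma must be non-negative")
  if (!is.null(collapse)) {
    if (is.null(collapse$pressure) || is.null(collapse$drop))
      abort_spec("collapse needs elements 'pressure' and 'drop'")
    if (is.null(collapse$n_points)) collapse$n_points <- 10L
    if (collapse$pressure <= 0 || collapse$drop < 0)
      abort_spec("collapse pressure must be positive and drop non-negative")
  }
  structure(list(a0 = a0, a_inf = a_inf, pi_c = pi_c, pi_max = pi_max,
                 collapse = collapse, n_points = as.integer(n_points),
                 noise_sigma = noise_sigma, seed = seed),
            class = "component_spec")
}

#' Closed-form area of the exponential equation of state
#' @param spec a `component_spec`.
#' @param pressure surface pressure(s), mN/m.
#' @return \eqn{A(\pi)} in \eqn{\AA^2}/molecule.
#' @export
eos_area <- function(spec, pressure) {
  spec$a_inf + (spec$a0 - spec$a_inf) * exp(-pressure / spec$pi_c)
}

#' Closed-form compressibility modulus of the exponential equation of state
#' @inheritParams eos_area
#' @return \eqn{C_s^{-1}(\pi) = \pi_c A/(A - A_\infty)} in mN/m.
#' @export
eos_cs_inv <- function(spec, pressure) {
  a <- eos_area(spec, pressure)
  spec$pi_c * a / (a - spec$a_inf)
}

#' Closed-form Goodrich integral of the exponential equation of state
#' @inheritParams eos_area
#' @return \eqn{\int_0^\pi A\,d\pi'} in \eqn{\AA^2} mN/m.
#' @export
eos_integral <- function(spec, pressure) {
  spec$a_inf * pressure +
    (spec$a0 - spec$a_inf) * spec$pi_c * (1 - exp(-pressure / spec$pi_c))
}

#' Generate a synthetic compression isotherm
#'
#' Samples the exponential equation of state of `spec` on a uniform pressure
#' grid from 0 to `pi_max` (or to the collapse pressure), optionally appends a
#' post-collapse pressure decline at continuing compression, adds seeded
#' Gaussian noise to the pressure signal and clips it at zero. Areas decrease
#' strictly by construction. Deterministic for a fixed seed.
#'
#' @param spec a `component_spec`.
#' @param name,components,mole_fractions,subphase,temperature_K metadata
#'   passed to [isotherm()].
#' @return A compression-branch `isotherm` carrying `spec` as attribute
#'   `"spec"`.
#' @examples
#' iso <- generate_component(component_spec(100, 40, 10, seed = 1))
#' max(iso$area)   # a0 = 100 at pi = 0 (noiseless)
#' @export
generate_component <- function(spec, name = "synthetic component",
                               components = "component", mole_fractions = 1,
                               subphase = "150 mM NaCl",
                               temperature_K = 308.15) {
  if (!inherits(spec, "component_spec")) abort_spec("not a component_spec")
  pi_end <- if (!is.null(spec$collapse)) spec$collapse$pressure else spec$pi_max
  p <- seq(0, pi_end, length.out = spec$n_points)
  a <- eos_area(spec, p)
  if (!is.null(spec$collapse)) {
    k <- spec$collapse$n_points
    da <- a[spec$n_points - 1] - a[spec$n_points]
    a_post <- a[spec$n_points] - seq_len(k) * da
    if (any(a_post <= 0)) abort_spec("post-collapse areas would be non-positive")
    p_post <- spec$collapse$pressure - seq_len(k) / k * spec$collapse$drop
    a <- c(a, a_post); p <- c(p, p_post)
  }
  if (spec$noise_sigma > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    p <- pmax(p + stats::rnorm(length(p), 0, spec$noise_sigma), 0)
  }
  out <- isotherm(area = a, pressure = p, name = name,
                  components = components, mole_fractions = mole_fractions,
                  subphase = subphase, temperature_K = temperature_K,
                  branch = "compression")
  attr(out, "spec") <- spec
  out
}

#' Specification of a synthetic mixed-film isotherm
#'
#' The mixture follows the additivity rule plus an exponentially decaying
#' interaction term,
#' \deqn{A_{mix}(\pi) = \sum_i X_i A_i(\pi) + \beta X_1 X_2 e^{-\pi/\pi_d},}
#' so the area deviation and the Goodrich excess free energy have closed
#' forms: \eqn{\Delta A(\pi) = \beta X_1 X_2 e^{-\pi/\pi_d}} and
#' \eqn{\Delta G_{exc}^{\pi} = N_A\,\beta X_1 X_2\,\pi_d (1 - e^{-\pi/\pi_d})
#' \times 10^{-23}} J/mol. Negative \eqn{\beta} is condensing
#' (attraction, miscibility), positive \eqn{\beta} expanding (separation
#' tendency).
#'
#' @param component_specs list of `component_spec`s (interaction applies to
#'   the first two fractions).
#' @param fractions mole fractions, summing to 1.
#' @param beta interaction amplitude, \eqn{\AA^2}.
#' @param pi_d interaction decay pressure, mN/m, positive.
#' @param pi_max compression end, mN/m; defaults to the smallest component
#'   `pi_max`.
#' @param n_points,noise_sigma,seed as in [component_spec()].
#' @return A `mixture_spec`.
#' @export
mixture_spec <- function(component_specs, fractions, beta = 0, pi_d = 10,
                         pi_max = NULL, n_points = 200, noise_sigma = 0,
                         seed = NULL) {
  if (length(component_specs) != length(fractions))
    abort_spec("one fraction per component spec")
  if (abs(sum(fractions) - 1) > 1e-9) abort_spec("fractions must sum to 1")
  if (pi_d <= 0) abort_spec("pi_d must be positive")
  if (noise_sigma < 0) abort_spec("noise_sigma must be non-negative")
  if (n_points < 20) abort_spec("n_points must be at least 20")
  if (is.null(pi_max))
    pi_max <- min(vapply(component_specs, `[[`, 0, "pi_max"))
  structure(list(component_specs = component_specs, fractions = fractions,
                 beta = beta, pi_d = pi_d, pi_max = pi_max,
                 n_points = as.integer(n_points), noise_sigma = noise_sigma,
                 seed = seed),
            class = "mixture_spec")
}

#' Generate a synthetic mixed-film isotherm with closed-form oracles
#'
#' @param spec a `mixture_spec`.
#' @param name,components,subphase,temperature_K metadata for the isotherm;
#'   `mole_fractions` are taken from the spec.
#' @return A compression-branch `isotherm` with attribute `"oracle"`: a list
#'   holding `beta`, `pi_d`, `x1x2`, and functions `delta_a(pi)` and
#'   `dg_exc(pi)` (J/mol) evaluating the closed forms.
#' @export
generate_mixture <- function(spec, name = "synthetic mixture",
                             components = NULL, subphase = "150 mM NaCl",
                             temperature_K = 308.15) {
  if (!inherits(spec, "mixture_spec")) abort_spec("not a mixture_spec")
  p <- seq(0, spec$pi_max, length.out = spec$n_points)
  a <- Reduce(`+`, Map(function(cs, f) f * eos_area(cs, p),
                       spec$component_specs, spec$fractions))
  x1x2 <- spec$fractions[1] * spec$fractions[2]
  a <- a + spec$beta * x1x2 * exp(-p / spec$pi_d)
  if (any(diff(a) >= 0))
    abort_spec("interaction term breaks monotone compression; reduce |beta|")
  if (spec$noise_sigma > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    p <- pmax(p + stats::rnorm(length(p), 0, spec$noise_sigma), 0)
  }
  if (is.null(components))
    components <- sprintf("component%d", seq_along(spec$fractions))
  out <- isotherm(area = a, pressure = p, name = name,
                  components = components, mole_fractions = spec$fractions,
                  subphase = subphase, temperature_K = temperature_K,
                  branch = "compression")
  beta <- spec$beta; pi_d <- spec$pi_d
  attr(out, "spec") <- spec
  attr(out, "oracle") <- list(
    beta = beta, pi_d = pi_d, x1x2 = x1x2,
    delta_a = function(pi) beta * x1x2 * exp(-pi / pi_d),
    dg_exc = function(pi) .const$N_A * beta * x1x2 * pi_d *
      (1 - exp(-pi / pi_d)) * .const$unit_factor
  )
  out
}

#' Specification of a synthetic compression-decompression cycle
#'
#' @param component_spec a `component_spec` for the base (compression) curve.
#' @param offset_delta branch offset \eqn{\delta(\pi)} in \eqn{\AA^2}: the
#'   decompression branch runs at `area - offset_delta(pressure)`. A single
#'   number or a function of pressure.
#' @param seed integer seed for the pressure noise of both branches.
#' @return A `cycle_spec`.
#' @export
cycle_spec <- function(component_spec, offset_delta = 0, seed = NULL) {
  if (!inherits(component_spec, "component_spec")) abort_spec("not a component_spec")
  f <- if (is.function(offset_delta)) offset_delta
       else { v <- as.numeric(offset_delta); function(p) rep(v, length(p)) }
  structure(list(component_spec = component_spec, offset_delta = f, seed = seed),
            class = "cycle_spec")
}

#' Generate a synthetic compression-decompression cycle
#'
#' The decompression branch retraces the base equation of state with its area
#' reduced by `offset_delta(pressure)`; the enclosed-loop oracle
#' \eqn{\int \delta\,d\pi} over the compression range is attached as attribute
#' `"oracle_loop_area"` (computed by adaptive quadrature, independent of the
#' trapezoid path in [hysteresis_area()]).
#'
#' @param spec a `cycle_spec`.
#' @param ... metadata passed to [generate_component()].
#' @return A `compression_cycle` with the oracle attribute.
#' @export
generate_cycle <- function(spec, ...) {
  if (!inherits(spec, "cycle_spec")) abort_spec("not a cycle_spec")
  cs <- spec$component_spec
  if (!is.null(spec$seed)) set.seed(spec$seed)
  comp <- generate_component(cs, ...)
  p <- seq(0, cs$pi_max, length.out = cs$n_points)
  a <- eos_area(cs, p) - spec$offset_delta(p)
  if (any(a <= 0)) abort_spec("offset yields non-positive decompression areas")
  if (cs$noise_sigma > 0) p <- pmax(p + stats::rnorm(length(p), 0, cs$noise_sigma), 0)
  dec <- comp
  dec$branch <- "decompression"
  dec$area <- rev(a)
  dec$pressure <- rev(p)
  validate_isotherm(dec)
  out <- compression_cycle(comp, dec)
  attr(out, "oracle_loop_area") <-
    stats::integrate(spec$offset_delta, 0, cs$pi_max,
                     rel.tol = 1e-10)$value
  out
}

#' Write a cycle as a single plain-text trace file
#'
#' Same dialect as [write_isotherm()] but with `branch = cycle` and the
#' compression rows followed by the decompression rows; read back with
#' [read_cycle()].
#'
#' @param cycle a complete `compression_cycle`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cycle <- function(cycle, path) {
  if (!inherits(cycle, "compression_cycle") || !cycle$complete)
    abort_format("a complete compression_cycle is required")
  co <- cycle$compression; de <- cycle$decompression
  lines <- c(
    sprintf("# name = %s", co$name),
    sprintf("# components = %s", paste(co$components, collapse = ", ")),
    sprintf("# mole_fractions = %s",
            paste(sprintf("%.17g", co$mole_fractions), collapse = ", ")),
    sprintf("# subphase = %s", co$subphase),
    sprintf("# temperature_K = %.17g", co$temperature_K),
    "# branch = cycle",
    "area_A2,pressure_mN_m",
    sprintf("%.17g,%.17g", c(co$area, de$area), c(co$pressure, de$pressure))
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write cycle file '%s'", path))
  invisible(path)
}

#' Read a cycle trace file
#'
#' @param path path to a file written by [write_cycle()].
#' @return List of `compression_cycle`s (see [split_cycles()]).
#' @export
read_cycle <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  meta <- parse_header(lines, path)
  missing <- setdiff(.mandatory_keys, names(meta))
  if (length(missing))
    abort_format(sprintf("'%s': missing mandatory metadata key(s): %s",
                         path, paste(missing, collapse = ", ")))
  if (meta$branch != "cycle")
    abort_format(sprintf("'%s': expected branch = cycle", path))
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body) || trimws(lines[body[1]]) != "area_A2,pressure_mN_m")
    abort_format(sprintf("'%s': expected data header 'area_A2,pressure_mN_m'", path))
  vals <- do.call(rbind, lapply(strsplit(trimws(lines[body[-1]]), ","), as.numeric))
  if (anyNA(vals)) abort_parse(sprintf("'%s': non-numeric value in data rows", path))
  split_cycles(vals[, 1], vals[, 2],
               name = meta$name,
               components = strsplit(meta$components, ",\\s*")[[1]],
               mole_fractions = as.numeric(strsplit(meta$mole_fractions, ",\\s*")[[1]]),
               subphase = meta$subphase,
               temperature_K = as.numeric(meta$temperature_K))
}

# Molar-ratio series of the ternary protein/lipid/lipid films: 1:m:m with an
# equimolar lipid pair, giving protein fractions 1/173 ... 1/3.
.ratio_series <- list(c(1, 86, 86), c(1, 58.5, 58.5), c(1, 45, 45),
                      c(1, 10, 10), c(1, 2, 2), c(1, 1, 1))

#' Generate a complete synthetic study as a fixture directory
#'
#' Writes a deterministic synthetic dataset emulating a protein/lipid
#' monolayer study: an expanded protein-like component compressed to 35 mN/m
#' without collapse, a condensed lipid-like component collapsing at 45 mN/m,
#' six mixed films at the molar-ratio series 1:86:86 ... 1:1:1 (protein
#' fractions 1/173, 1/118, 1/91, 1/21, 1/5, 1/3) with a condensing interaction
#' (beta = -5 \eqn{\AA^2}, pi_d = 10 mN/m), and one compression-decompression
#' cycle - nine isotherm files plus `manifest.json` recording every spec and
#' the closed-form oracle values (area deviation and excess free energy at the
#' scan pressures, loop area).
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; sub-seeds are derived deterministically.
#' @param noise_sigma Gaussian pressure noise, mN/m (default 0.1).
#' @param pressures oracle/scan pressures, mN/m (default 3, 6, 9, 12 - four
#'   pressures below the transition region).
#' @param beta,pi_d interaction parameters of the mixtures.
#' @param n_points points per branch (default 200).
#' @return Invisibly, the manifest as a list (also written as JSON).
#' @export
study_dataset <- function(dir, seed = 1, noise_sigma = 0.1,
                              pressures = c(3, 6, 9, 12),
                              beta = -5, pi_d = 10, n_points = 200) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  protein <- component_spec(a0 = 250, a_inf = 40, pi_c = 15, pi_max = 35,
                            n_points = n_points, noise_sigma = noise_sigma,
                            seed = seed + 100L)
  lipid <- component_spec(a0 = 60, a_inf = 38, pi_c = 18,
                          collapse = list(pressure = 45, drop = 3),
                          n_points = n_points, noise_sigma = noise_sigma,
                          seed = seed + 101L)
  files <- character()
  p_iso <- generate_component(protein, name = "protein",
                              components = "protein")
  write_isotherm(p_iso, file.path(dir, "protein.csv"))
  l_iso <- generate_component(lipid, name = "lipids",
                              components = c("lipid1", "lipid2"),
                              mole_fractions = c(0.5, 0.5))
  write_isotherm(l_iso, file.path(dir, "lipids.csv"))
  files <- c(files, "protein.csv", "lipids.csv")

  mixtures <- list()
  for (i in seq_along(.ratio_series)) {
    comp <- ratio_to_molefractions(.ratio_series[[i]])
    ms <- mixture_spec(list(protein, lipid),
                       fractions = c(comp$x_protein, comp$x_lipids),
                       beta = beta, pi_d = pi_d, n_points = n_points,
                       noise_sigma = noise_sigma, seed = seed + i)
    tag <- paste(gsub("\\.", "p", .ratio_series[[i]]), collapse = "_")
    fn <- sprintf("mixture_%s.csv", tag)
    iso <- generate_mixture(ms, name = sprintf("mixture %s",
                                               paste(.ratio_series[[i]], collapse = ":")),
                            components = c("protein", "lipids"))
    write_isotherm(iso, file.path(dir, fn))
    orc <- attr(iso, "oracle")
    mixtures[[i]] <- list(
      file = fn, ratio = .ratio_series[[i]],
      x_protein = comp$x_protein,
      beta = beta, pi_d = pi_d,
      oracle_delta_a = orc$delta_a(pressures),
      oracle_dg_exc_J_mol = orc$dg_exc(pressures)
    )
    files <- c(files, fn)
  }

  cyc_spec <- cycle_spec(component_spec(a0 = 60, a_inf = 38, pi_c = 18,
                                        pi_max = 40, n_points = n_points,
                                        noise_sigma = noise_sigma,
                                        seed = seed + 200L),
                         offset_delta = function(p) 2 * exp(-p / 10),
                         seed = seed + 200L)
  cyc <- generate_cycle(cyc_spec, name = "lipids cycle",
                        components = c("lipid1", "lipid2"),
                        mole_fractions = c(0.5, 0.5))
  write_cycle(cyc, file.path(dir, "cycle.csv"))
  files <- c(files, "cycle.csv")

  manifest <- list(
    seed = seed, noise_sigma = noise_sigma, pressures = pressures,
    temperature_K = 308.15,
    components = list(protein = unclass(protein)[!vapply(unclass(protein), is.null, TRUE)],
                      lipids = unclass(lipid)[!vapply(unclass(lipid), is.null, TRUE)]),
    mixtures = mixtures,
    cycle = list(file = "cycle.csv",
                 oracle_loop_area_A2mNm = attr(cyc, "oracle_loop_area")),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
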