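#' Pair compression and decompression branches into a cycle
#'
#' @param compression compression-branch `isotherm`.
#' @param decompression decompression-branch `isotherm` of the same film, or
#'   `NULL` for an incomplete (compression-only) cycle.
#' @param cycle_index positive integer index of the cycle within a run.
#' @return A `compression_cycle` with a `complete` flag.
#' @export
compression_cycle <- function(compression, decompression = NULL, cycle_index = 1L) {
  validate_isotherm(compression)
  if (compression$branch != "compression")
    abort_format("first branch must be tagged compression")
  if (!is.null(decompression)) {
    validate_isotherm(decompression)
    if (decompression$branch != "decompression")
      abort_format("second branch must be tagged decompression")
    same <- identical(compression$name, decompression$name) &&
      identical(compression$components, decompression$components) &&
      isTRUE(all.equal(compression$mole_fractions, decompression$mole_fractions)) &&
      identical(compression$subphase, decompression$subphase) &&
      isTRUE(all.equal(compression$temperature_K, decompression$temperature_K))
    if (!same) abort_format("cycle branches must share name, composition, subphase and temperature")
  }
  if (cycle_index < 1) abort_param("cycle_index must be >= 1")
  structure(list(compression = compression, decompression = decompression,
                 cycle_index = as.integer(cycle_index),
                 complete = !is.null(decompression)),
            class = "compression_cycle")
}

#' @export
print.compression_cycle <- function(x, ...) {
  cat(sprintf("<compression_cycle> #%d %s%s\n", x$cycle_index,
              x$compression$name, if (x$complete) "" else " (incomplete)"))
  invisible(x)
}

#' @export
plot.compression_cycle <- function(x, ...) {
  ar <- range(x$compression$area, if (x$complete) x$decompression$area)
  pr <- range(x$compression$pressure, if (x$complete) x$decompression$pressure)
  graphics::plot(x$compression$area, x$compression$pressure, type = "l",
                 xlim = rev(ar), ylim = pr,
                 xlab = expression(A ~ (ring(A)^2 / molecule)),
                 ylab = expression(pi ~ (mN/m)),
                 main = x$compression$name, ...)
  if (x$complete)
    graphics::lines(x$decompression$area, x$decompression$pressure, lty = 2)
  invisible(x)
}

# single-valued A(pi) knots of a decompression branch: pressure falls as area
# grows, so sort on pressure and average ties, keeping from its pressure
# maximum onwards.
monotone_knots_decompression <- function(iso) {
  i <- which.max(iso$pressure)
  p <- iso$pressure[i:length(iso$pressure)]
  a <- iso$area[i:length(iso$area)]
  o <- order(p)
  p <- p[o]; a <- a[o]
  if (anyDuplicated(p)) {
    a <- as.numeric(tapply(a, p, mean))
    p <- sort(unique(p))
  }
  list(pressure = p, area = a)
}

#' Enclosed area of a compression-decompression hysteresis loop
#'
#' Integrates the signed area difference between the compression and
#' decompression branches over their shared pressure range,
#' \deqn{\mathrm{loop} = \int_{\pi_{lo}}^{\pi_{hi}} \left[A_{comp}(\pi) - A_{dec}(\pi)\right] d\pi,}
#' by the trapezoid rule on the merged knot grid of both branches. The loop
#' area (\eqn{\AA^2} mN/m per molecule) is the irreversible work of the
#' cycle; it converts to J/molecule via 1e-23 and to J/mol via the Avogadro
#' constant. Negative values signal branch crossing and are reported, not
#' clipped. `relative` normalises by the compression work over the same range.
#'
#' @param cycle a complete `compression_cycle`.
#' @return A `hysteresis_result`: list with `loop_area` (\eqn{\AA^2} mN/m),
#'   `loop_energy` (J/molecule), `loop_energy_molar` (J/mol), `relative`
#'   (dimensionless) and `pressure_range` (mN/m).
#' @export
hysteresis_area <- function(cycle) {
  if (!inherits(cycle, "compression_cycle")) abort_format("not a compression_cycle")
  if (!cycle$complete) abort_domain("cycle has no decompression branch")
  kc <- monotone_knots(cycle$compression)
  kd <- monotone_knots_decompression(cycle$decompression)
  lo <- max(min(kc$pressure), min(kd$pressure))
  hi <- min(max(kc$pressure), max(kd$pressure))
  if (!(hi > lo)) abort_domain("branches share no pressure range")
  grid <- sort(unique(c(lo, hi,
                        kc$pressure[kc$pressure >= lo & kc$pressure <= hi],
                        kd$pressure[kd$pressure >= lo & kd$pressure <= hi])))
  ac <- stats::approx(kc$pressure, kc$area, xout = grid, ties = "ordered")$y
  ad <- stats::approx(kd$pressure, kd$area, xout = grid, ties = "ordered")$y
  loop <- pracma::trapz(grid, ac - ad)
  work <- pracma::trapz(grid, ac)
  structure(list(
    loop_area = loop,
    loop_energy = loop * .const$unit_factor,
    loop_energy_molar = loop * .const$unit_factor * .const$N_A,
    relative = if (work != 0) loop / work else NA_real_,
    pressure_range = c(lo, hi)
  ), class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat("<hysteresis_result>\n")
  cat(sprintf("  pi range [%.2f, %.2f] mN/m\n",
              x$pressure_range[1], x$pressure_range[2]))
  cat(sprintf("  loop area = %.4g A2 mN/m  (%.4g J/molecule, %.4g J/mol)\n",
              x$loop_area, x$loop_energy, x$loop_energy_molar))
  cat(sprintf("  relative to compression work: %.4g\n", x$relative))
  invisible(x)
}

#' Split an alternating pi/A trace into compression-decompression cycles
#'
#' Segments an ordered trough record at the turning points of the area signal:
#' monotone decreasing segments become compression branches, increasing ones
#' decompression branches, paired in order of occurrence. A trailing
#' compression without a matching decompression is returned as an incomplete
#' cycle with a warning.
#'
#' @param area,pressure the ordered trace.
#' @param ... metadata (`name`, `components`, `mole_fractions`, `subphase`,
#'   `temperature_K`) passed to [isotherm()] for every branch.
#' @return List of `compression_cycle` objects with `cycle_index` 1, 2, ...
#' @export
split_cycles <- function(area, pressure, ...) {
  if (length(area) != length(pressure) || length(area) < 3)
    abort_format("trace needs equal-length area and pressure with >= 3 points")
  s <- sign(diff(area))
  if (any(s == 0)) abort_format("trace has repeated consecutive areas")
  r <- rle(s)
  ends <- cumsum(r$lengths)
  # segment k spans the points of run k plus the shared turning knot
  seg <- lapply(seq_along(r$values), function(k) {
    from <- if (k == 1) 1L else ends[k - 1] + 1L
    to <- ends[k] + 1L
    list(idx = from:to, dir = r$values[k])
  })
  cycles <- list(); ci <- 0L; k <- 1L
  while (k <= length(seg)) {
    if (seg[[k]]$dir > 0) {   # decompression with no preceding compression
      warning("leading decompression segment ignored")
      k <- k + 1L
      next
    }
    ci <- ci + 1L
    comp <- isotherm(area = area[seg[[k]]$idx], pressure = pressure[seg[[k]]$idx],
                     branch = "compression", ...)
    dec <- NULL
    if (k + 1L <= length(seg) && seg[[k + 1L]]$dir > 0) {
      dec <- isotherm(area = area[seg[[k + 1L]]$idx],
                      pressure = pressure[seg[[k + 1L]]$idx],
                      branch = "decompression", ...)
      k <- k + 2L
    } else {
      warning("trailing compression has no decompression branch")
      k <- k + 1L
    }
    cycles[[ci]] <- compression_cycle(comp, dec, cycle_index = ci)
  }
  cycles
}

#' Write a per-cycle hysteresis summary table as TSV
#'
#' @param results list of `hysteresis_result` objects (one per cycle, in
#'   cycle order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hysteresis_table <- function(results, path) {
  rows <- vapply(seq_along(results), function(i) {
    h <- results[[i]]
    sprintf("%d\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g",
            i, h$pressure_range[1], h$pressure_range[2], h$loop_area,
            h$loop_energy, h$loop_energy_molar, h$relative)
  }, "")
  writeLines(c(paste("cycle_index", "pi_lo", "pi_hi", "loop_area_A2mNm",
                     "loop_energy_J", "loop_energy_J_per_mol", "relative",
                     sep = "\t"), rows), path)
  invisible(path)
}
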