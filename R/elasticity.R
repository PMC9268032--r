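#' Surface compressibility modulus profile
#'
#' Computes the in-plane elasticity (compressibility modulus)
#' \deqn{C_s^{-1} = -A \left(\frac{\partial \pi}{\partial A}\right)_T}
#' along a compression isotherm. The branch is truncated at its global
#' pressure maximum, the pressure signal is (optionally) Savitzky-Golay
#' smoothed, and the derivative is taken by central differences; endpoints are
#' excluded. The profile is reported against surface pressure, together with
#' its maximum, the pressure at the maximum (ties resolved to the lowest
#' pressure) and the transition pressure located by
#' [detect_transition_pressure()].
#'
#' @param iso compression-branch `isotherm` with at least 11 points after
#'   truncation.
#' @param window,order Savitzky-Golay parameters passed to
#'   [smooth_pressure()]; `window = 11`, `order = 2` by default.
#' @param smooth logical; smooth before differentiating (default TRUE). Turn
#'   off for noiseless synthetic curves.
#' @return An `elasticity_profile`: list with `pressure`, `cs_inv` (both
#'   mN/m), `cs_inv_max`, `pressure_at_max`, `transition_pressure` (NA when
#'   absent) and `source` (the isotherm's name).
#' @examples
#' iso <- with(list(a = seq(100, 40, length.out = 200)),
#'             isotherm(area = a, pressure = 0.5 * (100 - a)))
#' pr <- compressibility_modulus(iso, smooth = FALSE)
#' pr$cs_inv[which.min(abs(pr$pressure - 20))]   # ~ 30 mN/m
#' @export
compressibility_modulus <- function(iso, window = 11, order = 2, smooth = TRUE) {
  validate_isotherm(iso)
  if (iso$branch != "compression")
    abort_domain("the compressibility modulus is computed on compression branches")
  t <- truncate_at_pressure_max(iso)
  n <- length(t$area)
  if (n < max(11, if (smooth) window else 0))
    abort_insufficient(sprintf(
      "only %d points after truncation; need at least %d", n, max(11, window)))
  p <- if (smooth) polysmooth(t$pressure, window, order) else t$pressure
  a <- t$area
  i <- 2:(n - 1)
  dpda <- (p[i + 1] - p[i - 1]) / (a[i + 1] - a[i - 1])
  cs <- -a[i] * dpda
  pg <- p[i]
  o <- order(pg)
  pg <- pg[o]; cs <- cs[o]
  if (anyDuplicated(pg)) {
    # a run of tied pressures is a plateau; its edge secants are contaminated
    # by the neighbouring regimes, so summarise the run by its median modulus
    # (0 on an ideal plateau)
    cs <- as.numeric(tapply(cs, pg, stats::median))
    pg <- sort(unique(pg))
  }
  keep <- c(TRUE, diff(pg) > 0)   # enforce a strictly increasing pressure grid
  pg <- pg[keep]; cs <- cs[keep]
  imax <- which.max(cs)           # which.max takes the first (lowest pi) tie
  prof <- structure(list(
    pressure = pg, cs_inv = cs,
    cs_inv_max = cs[imax], pressure_at_max = pg[imax],
    transition_pressure = NA_real_,
    source = iso$name
  ), class = "elasticity_profile")
  prof$transition_pressure <- detect_transition_pressure(prof)
  prof
}

#' @export
print.elasticity_profile <- function(x, ...) {
  cat(sprintf("<elasticity_profile> %s\n", x$source))
  cat(sprintf("  %d points, pi %.2f..%.2f mN/m\n",
              length(x$pressure), min(x$pressure), max(x$pressure)))
  cat(sprintf("  Cs^-1 max = %.2f mN/m at pi = %.2f mN/m  [%s]\n",
              x$cs_inv_max, x$pressure_at_max, classify_phase(x$cs_inv_max)$label))
  cat(sprintf("  transition pressure pi_tr = %s\n",
              if (is.na(x$transition_pressure)) "absent"
              else sprintf("%.2f mN/m", x$transition_pressure)))
  invisible(x)
}

#' @export
plot.elasticity_profile <- function(x, ...) {
  graphics::plot(x$pressure, x$cs_inv, type = "l",
                 xlab = expression(pi ~ (mN/m)),
                 ylab = expression(C[s]^{-1} ~ (mN/m)), main = x$source, ...)
  graphics::abline(v = x$pressure_at_max, lty = 3)
  invisible(x)
}

#' Export an elasticity profile as TSV
#'
#' Writes a tab-separated table (`pressure_mN_m`, `cs_inv_mN_m`) preceded by a
#' '#'-prefixed summary (maximum, pressure at maximum, transition pressure,
#' phase label).
#'
#' @param profile an `elasticity_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_elasticity_profile <- function(profile, path) {
  ph <- classify_phase(profile$cs_inv_max)
  hdr <- c(
    sprintf("# source = %s", profile$source),
    sprintf("# cs_inv_max_mN_m = %.6g", profile$cs_inv_max),
    sprintf("# pressure_at_max_mN_m = %.6g", profile$pressure_at_max),
    sprintf("# transition_pressure_mN_m = %s",
            if (is.na(profile$transition_pressure)) "NA"
            else sprintf("%.6g", profile$transition_pressure)),
    sprintf("# phase = %s", ph$label),
    "pressure_mN_m\tcs_inv_mN_m"
  )
  writeLines(c(hdr, sprintf("%.10g\t%.10g", profile$pressure, profile$cs_inv)), path)
  invisible(path)
}

# Davies-Rideal style band table; right-closed where stated.
.phase_bands <- data.frame(
  label = c("G", "LE", "LE-LC", "LC", "S"),
  low   = c(0, 12.5, 50, 100, 250),
  high  = c(12.5, 50, 100, 250, Inf)
)

#' Classify the monolayer phase state from the maximal compressibility modulus
#'
#' Davies-Rideal convention: gaseous (G) up to 12.5 mN/m, liquid-expanded
#' (LE) up to 50 mN/m, a transitional LE-LC band in (50, 100), liquid-condensed
#' (LC) in \[100, 250\], solid (S) above 250 mN/m. The LE upper limit (50) and
#' the LC band (100-250) are the classical quoted boundaries; the G cutoff and
#' the LE-LC label fill the conventional gaps. Total, deterministic step
#' function of its input.
#'
#' @param cs_inv_max maximal compressibility modulus, mN/m, non-negative.
#' @return A `phase_state`: list with `label` (one of G, LE, LE-LC, LC, S) and
#'   `band`, the `(low, high]` interval applied.
#' @examples
#' classify_phase(152)$label   # "LC"
#' classify_phase(56)$label    # "LE-LC"
#' @export
classify_phase <- function(cs_inv_max) {
  if (!is.finite(cs_inv_max) || cs_inv_max < 0)
    abort_domain("cs_inv_max must be a non-negative number")
  b <- .phase_bands
  i <- if (cs_inv_max == 0) 1L
       else which(cs_inv_max > b$low & (cs_inv_max <= b$high |
                  (b$label == "LC" & cs_inv_max == b$low)))[1]
  # LC is closed on both ends [100, 250]; handle the 100 boundary explicitly
  if (cs_inv_max == 100) i <- which(b$label == "LC")
  structure(list(label = b$label[i], band = c(b$low[i], b$high[i])),
            class = "phase_state")
}

#' @export
print.phase_state <- function(x, ...) {
  cat(sprintf("<phase_state> %s (Cs^-1 in (%g, %g] mN/m)\n",
              x$label, x$band[1], x$band[2]))
  invisible(x)
}

#' Locate the phase-transition pressure on a compressibility-modulus profile
#'
#' The transition pressure pi_tr separates a gradual low-pressure rise of
#' \eqn{C_s^{-1}} from a much steeper high-pressure rise. It is located as the
#' deepest interior local minimum of the profile; when the profile has no
#' interior local minimum, a two-segment piecewise-linear fit is tried and its
#' breakpoint is reported if the second segment is more than twice as steep as
#' the first. `NA` (absent) is a legal result for single-regime profiles.
#'
#' @param profile an `elasticity_profile`.
#' @return pi_tr in mN/m, or `NA_real_` when no transition is found.
#' @export
detect_transition_pressure <- function(profile) {
  p <- profile$pressure; cs <- profile$cs_inv
  n <- length(cs)
  if (n < 5) return(NA_real_)
  d <- diff(cs)
  mins <- which(d[-(n - 1)] < 0 & d[-1] > 0) + 1L   # strict interior minima
  if (length(mins)) return(p[mins[which.min(cs[mins])]])
  # two-segment piecewise-linear fit on the pressure grid
  best <- NULL; best_sse <- Inf
  for (k in 3:(n - 2)) {
    f1 <- stats::lm.fit(cbind(1, p[1:k]), cs[1:k])
    f2 <- stats::lm.fit(cbind(1, p[k:n]), cs[k:n])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(k = k, s1 = f1$coefficients[2], s2 = f2$coefficients[2])
    }
  }
  ratio <- if (best$s1 <= 0) { if (best$s2 > 0) Inf else 0 } else best$s2 / best$s1
  if (is.finite(ratio) && ratio > 2 || identical(ratio, Inf)) p[best$k] else NA_real_
}

#' Detect the collapse point of a compression isotherm
#'
#' A film has collapsed when its recorded pressure maximum is followed either
#' by at least 3 points whose pressure lies more than `tol` below the maximum
#' (buckling drop), or by at least 3 inter-point slopes
#' \eqn{|\partial\pi/\partial A|} below `plateau_frac` of the pre-maximum
#' median slope (constant-pressure plateau). The collapse point
#' (pi_col, A_col) is the recorded maximum. A strictly rising isotherm is
#' legally collapse-free.
#'
#' @param iso untruncated compression-branch `isotherm`.
#' @param tol pressure drop tolerance, mN/m (default 0.5).
#' @param plateau_frac plateau slope fraction of the pre-maximum median slope
#'   (default 0.05).
#' @return A `collapse_point`: list with `pressure`, `area` and `detected`.
#' @export
detect_collapse <- function(iso, tol = 0.5, plateau_frac = 0.05) {
  validate_isotherm(iso)
  if (iso$branch != "compression")
    abort_domain("collapse detection applies to compression branches")
  p <- iso$pressure; a <- iso$area
  n <- length(p)
  i <- which.max(p)
  res <- structure(list(pressure = NA_real_, area = NA_real_, detected = FALSE),
                   class = "collapse_point")
  if (n - i < 3) return(res)
  drop_n <- sum(p[i] - p[(i + 1):n] > tol)
  pre <- seq_len(i)
  med_slope <- stats::median(abs(diff(p[pre]) / diff(a[pre])))
  post_slopes <- abs(diff(p[i:n]) / diff(a[i:n]))
  plateau_n <- if (is.finite(med_slope) && med_slope > 0)
    sum(post_slopes < plateau_frac * med_slope) else 0L
  if (drop_n >= 3 || plateau_n >= 3) {
    res$pressure <- p[i]; res$area <- a[i]; res$detected <- TRUE
  }
  res
}

#' @export
print.collapse_point <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<collapse_point> pi_col = %.2f mN/m, A_col = %.2f A2\n",
                x$pressure, x$area))
  else cat("<collapse_point> no collapse detected\n")
  invisible(x)
}
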