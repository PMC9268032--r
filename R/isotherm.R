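#' Construct a surface pressure/area isotherm
#'
#' An `isotherm` is one branch of a Langmuir-trough pi/A record: surface
#' pressure `pressure` (mN/m) against mean molecular area `area`
#' (\eqn{\AA^2}/molecule), with the film's composition and the measurement
#' conditions as metadata. Compression branches are stored with strictly
#' decreasing area, decompression branches with strictly increasing area.
#'
#' @param area numeric vector of mean molecular areas, \eqn{\AA^2}/molecule,
#'   all positive, ordered per `branch`.
#' @param pressure numeric vector of surface pressures, mN/m, same length as
#'   `area`, all non-negative.
#' @param name free-text film label.
#' @param components character vector of component labels.
#' @param mole_fractions numeric vector, same length as `components`, each in
#'   \[0, 1\], summing to 1 within 1e-9.
#' @param subphase free-text subphase label (e.g. "150 mM NaCl").
#' @param temperature_K subphase temperature, kelvin. Default 308.15 K (35 C).
#' @param branch `"compression"` or `"decompression"`.
#' @param liftoff_pressure optional equilibrium-spreading surface pressure
#'   (pi_0 surrogate), mN/m; carried as metadata only.
#' @return An object of class `isotherm`.
#' @examples
#' iso <- isotherm(area = c(100, 80, 60), pressure = c(0, 5, 15),
#'                 name = "demo", components = "X", mole_fractions = 1)
#' iso
#' @seealso [read_isotherm()], [resample_area_on_pressure()],
#'   [compressibility_modulus()]
#' @export
isotherm <- function(area, pressure, name = "isotherm",
                     components = "component", mole_fractions = 1,
                     subphase = "150 mM NaCl", temperature_K = 308.15,
                     branch = c("compression", "decompression"),
                     liftoff_pressure = NULL) {
  branch <- match.arg(branch)
  x <- structure(list(
    name = as.character(name)[1],
    components = as.character(components),
    mole_fractions = as.numeric(mole_fractions),
    subphase = as.character(subphase)[1],
    temperature_K = as.numeric(temperature_K)[1],
    branch = branch,
    area = as.numeric(area),
    pressure = as.numeric(pressure),
    liftoff_pressure = if (is.null(liftoff_pressure)) NULL else as.numeric(liftoff_pressure)[1]
  ), class = "isotherm")
  validate_isotherm(x)
}

#' Validate an isotherm object
#'
#' Checks the structural invariants: equal-length finite `area`/`pressure`
#' with at least 3 points, positive areas, non-negative pressures, mole
#' fractions in \[0,1\] summing to 1 within 1e-9, positive temperature, and
#' the branch's canonical area ordering (strictly decreasing for compression,
#' strictly increasing for decompression).
#'
#' @param x an `isotherm`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_isotherm <- function(x) {
  if (!inherits(x, "isotherm")) abort_format("not an isotherm object")
  n <- length(x$area)
  if (length(x$pressure) != n)
    abort_format("area and pressure differ in length")
  if (n < 3) abort_insufficient("an isotherm needs at least 3 points")
  if (anyNA(x$area) || anyNA(x$pressure) ||
      !all(is.finite(x$area)) || !all(is.finite(x$pressure)))
    abort_format("area and pressure must be finite and non-missing")
  if (any(x$area <= 0)) abort_format("all areas must be positive")
  if (any(x$pressure < 0)) abort_format("all pressures must be non-negative")
  mf <- x$mole_fractions
  if (length(mf) != length(x$components))
    abort_format("mole_fractions and components differ in length")
  if (any(mf < 0) || any(mf > 1) || abs(sum(mf) - 1) > 1e-9)
    abort_format("mole_fractions must lie in [0,1] and sum to 1 (tol 1e-9)")
  if (!is.finite(x$temperature_K) || x$temperature_K <= 0)
    abort_format("temperature_K must be positive")
  d <- diff(x$area)
  if (x$branch == "compression" && any(d >= 0))
    abort_format("compression branch requires strictly decreasing area")
  if (x$branch == "decompression" && any(d <= 0))
    abort_format("decompression branch requires strictly increasing area")
  invisible(x)
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("<isotherm> %s [%s]\n", x$name, x$branch))
  cat(sprintf("  components: %s (X = %s)\n",
              paste(x$components, collapse = "/"),
              paste(signif(x$mole_fractions, 4), collapse = ", ")))
  cat(sprintf("  subphase: %s, T = %.2f K\n", x$subphase, x$temperature_K))
  cat(sprintf("  %d points, area %.2f..%.2f A2, pi %.2f..%.2f mN/m\n",
              length(x$area), min(x$area), max(x$area),
              min(x$pressure), max(x$pressure)))
  if (!is.null(x$liftoff_pressure))
    cat(sprintf("  lift-off pressure pi0 = %.2f mN/m\n", x$liftoff_pressure))
  invisible(x)
}

#' @export
summary.isotherm <- function(object, ...) {
  print(object)
  cp <- detect_collapse(object)
  if (isTRUE(cp$detected))
    cat(sprintf("  collapse: pi_col = %.2f mN/m at A_col = %.2f A2\n",
                cp$pressure, cp$area))
  invisible(object)
}

#' @export
plot.isotherm <- function(x, ...) {
  graphics::plot(x$area, x$pressure, type = "l",
                 xlab = expression(A ~ (ring(A)^2 / molecule)),
                 xlim = rev(range(x$area)),
                 ylab = expression(pi ~ (mN/m)), main = x$name, ...)
  invisible(x)
}

#' @export
as.data.frame.isotherm <- function(x, ...) {
  data.frame(area_A2 = x$area, pressure_mN_m = x$pressure)
}

# ---- file format -----------------------------------------------------------

.mandatory_keys <- c("name", "components", "mole_fractions", "subphase",
                     "temperature_K", "branch")

#' Write an isotherm to a plain-text CSV file
#'
#' Emits a '#'-prefixed `key = value` metadata header (name, components,
#' mole_fractions, subphase, temperature_K, branch, optionally
#' liftoff_pressure_mN_m), the column header `area_A2,pressure_mN_m`, and
#' comma-separated data rows at full float precision ("%.17g", so a read
#' round-trips bit-exactly). Output is deterministic for a fixed input.
#'
#' @param iso a valid `isotherm`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(iso, path) {
  validate_isotherm(iso)
  lines <- c(
    sprintf("# name = %s", iso$name),
    sprintf("# components = %s", paste(iso$components, collapse = ", ")),
    sprintf("# mole_fractions = %s",
            paste(sprintf("%.17g", iso$mole_fractions), collapse = ", ")),
    sprintf("# subphase = %s", iso$subphase),
    sprintf("# temperature_K = %.17g", iso$temperature_K),
    sprintf("# branch = %s", iso$branch),
    if (!is.null(iso$liftoff_pressure))
      sprintf("# liftoff_pressure_mN_m = %.17g", iso$liftoff_pressure),
    "area_A2,pressure_mN_m",
    sprintf("%.17g,%.17g", iso$area, iso$pressure)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write isotherm file '%s'", path))
  invisible(path)
}

parse_header <- function(lines, path) {
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", hdr))
  keys <- vapply(m, function(g) if (length(g) == 3) g[2] else NA_character_, "")
  vals <- vapply(m, function(g) if (length(g) == 3) trimws(g[3]) else NA_character_, "")
  ok <- !is.na(keys)
  stats::setNames(as.list(vals[ok]), keys[ok])
}

#' Read an isotherm from a plain-text CSV file
#'
#' Parses the dialect written by [write_isotherm()]. Rows are re-ordered to
#' the branch's canonical area ordering and rows with duplicate area are
#' averaged on pressure before validation.
#'
#' @param path path to an isotherm file.
#' @return A validated `isotherm`.
#' @export
read_isotherm <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  meta <- parse_header(lines, path)
  missing <- setdiff(.mandatory_keys, names(meta))
  if (length(missing))
    abort_format(sprintf("'%s': missing mandatory metadata key(s): %s",
                         path, paste(missing, collapse = ", ")))
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body) || trimws(lines[body[1]]) != "area_A2,pressure_mN_m")
    abort_format(sprintf("'%s': expected data header 'area_A2,pressure_mN_m'", path))
  rows <- body[-1]
  if (length(rows) < 3)
    abort_insufficient(sprintf("'%s': fewer than 3 data rows", path))
  parts <- strsplit(trimws(lines[rows]), ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    abort_parse(sprintf("'%s' line %d: expected two comma-separated values",
                        path, rows[bad[1]]))
  vals <- suppressWarnings(vapply(parts, function(p) as.numeric(p), numeric(2)))
  badnum <- which(apply(is.na(vals), 2, any))
  if (length(badnum))
    abort_parse(sprintf("'%s' line %d: non-numeric value", path, rows[badnum[1]]))
  area <- vals[1, ]; pressure <- vals[2, ]

  # average pressures at duplicated areas, then canonical ordering
  if (anyDuplicated(area)) {
    pressure <- as.numeric(tapply(pressure, area, mean))
    area <- sort(unique(area))
  }
  branch <- meta$branch
  if (!branch %in% c("compression", "decompression"))
    abort_format(sprintf("'%s': branch must be compression or decompression", path))
  o <- order(area, decreasing = (branch == "compression"))
  mf <- as.numeric(strsplit(meta$mole_fractions, ",\\s*")[[1]])
  tK <- suppressWarnings(as.numeric(meta$temperature_K))
  if (is.na(tK)) abort_format(sprintf("'%s': temperature_K is not numeric", path))
  isotherm(
    area = area[o], pressure = pressure[o],
    name = meta$name,
    components = strsplit(meta$components, ",\\s*")[[1]],
    mole_fractions = mf,
    subphase = meta$subphase,
    temperature_K = tK,
    branch = branch,
    liftoff_pressure = if (!is.null(meta$liftoff_pressure_mN_m))
      as.numeric(meta$liftoff_pressure_mN_m) else NULL
  )
}

# ---- truncation and resampling --------------------------------------------

# Keep a compression branch up to its (first) global pressure maximum so that
# pi is invertible; everything past the maximum is post-collapse material.
truncate_at_pressure_max <- function(iso) {
  i <- which.max(iso$pressure)
  out <- iso
  out$area <- iso$area[seq_len(i)]
  out$pressure <- iso$pressure[seq_len(i)]
  attr(out, "truncated_points") <- length(iso$area) - i
  out
}

# Monotone (pressure, area) knots of a compression branch: truncated at the
# pressure maximum, sorted on pressure, areas averaged at tied pressures.
monotone_knots <- function(iso) {
  t <- truncate_at_pressure_max(iso)
  o <- order(t$pressure)
  p <- t$pressure[o]; a <- t$area[o]
  if (anyDuplicated(p)) {
    a <- as.numeric(tapply(a, p, mean))
    p <- sort(unique(p))
  }
  list(pressure = p, area = a)
}

#' Interpolate mean molecular area at given surface pressures
#'
#' Evaluates A(pi) on a compression branch by piecewise-linear interpolation,
#' exact at recorded knots. The branch is first truncated at its global
#' pressure maximum (post-collapse material makes pi non-invertible); tied
#' pressures contribute their mean area. Pressures below the recorded minimum
#' are, when `extend = TRUE`, answered with the lift-off area (the area at the
#' lowest recorded pressure), the convention used to extend the Goodrich
#' integrals down to pi = 0; the result carries a logical attribute
#' `"extended"` flagging such grid points.
#'
#' @param iso compression-branch `isotherm`.
#' @param grid numeric vector of surface pressures, mN/m.
#' @param extend logical; extend below lift-off at constant area (default TRUE).
#' @return Numeric vector of areas (\eqn{\AA^2}/molecule) with attribute
#'   `extended`.
#' @examples
#' iso <- isotherm(area = c(100, 90, 80, 60), pressure = c(0, 5, 10, 20))
#' resample_area_on_pressure(iso, c(7.5, 10))   # 85, 80
#' @export
resample_area_on_pressure <- function(iso, grid, extend = TRUE) {
  validate_isotherm(iso)
  if (iso$branch != "compression")
    abort_domain("resampling is defined on compression branches")
  k <- monotone_knots(iso)
  if (any(grid > max(k$pressure) + 1e-9))
    abort_range(sprintf("grid pressure %.4g mN/m above maximum retained pressure %.4g",
                        max(grid), max(k$pressure)))
  below <- grid < min(k$pressure)
  if (any(below) && !extend)
    abort_range(sprintf("grid pressure %.4g mN/m below minimum recorded pressure %.4g and extension disabled",
                        min(grid), min(k$pressure)))
  out <- stats::approx(k$pressure, k$area,
                       xout = pmin(pmax(grid, min(k$pressure)), max(k$pressure)),
                       ties = "ordered")$y
  out[below] <- k$area[1]
  attr(out, "extended") <- below
  out
}

# ---- smoothing -------------------------------------------------------------

# Local least-squares polynomial (Savitzky-Golay) smoother. Interior points
# use centred windows; near the ends the window slides one-sided so that a
# full `window` points are always fitted, which keeps the smoother exact on
# polynomials of degree <= order everywhere.
polysmooth <- function(y, window, order) {
  n <- length(y)
  if (window %% 2 == 0) abort_param("smoothing window must be odd")
  if (window < order + 2) abort_param("smoothing window must be at least order + 2")
  if (window > n) abort_param("smoothing window exceeds number of points")
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1L, i - half), n - window + 1L)
    idx <- lo:(lo + window - 1L)
    x <- idx - i
    X <- outer(x, 0:order, `^`)
    out[i] <- qr.solve(X, y[idx])[1]
  }
  out
}

#' Savitzky-Golay smoothing of the pressure signal
#'
#' Local polynomial least-squares smoothing of pressure against point index,
#' used to stabilise the numerical derivative in
#' [compressibility_modulus()]. Areas are left untouched. Endpoints are fitted
#' with one-sided windows, so data already on a polynomial of degree
#' `order` or less are reproduced exactly.
#'
#' @param iso an `isotherm`.
#' @param window odd window length, at least `order + 2`, at most the number
#'   of points (default 11).
#' @param order polynomial order (default 2).
#' @return The smoothed `isotherm`.
#' @export
smooth_pressure <- function(iso, window = 11, order = 2) {
  validate_isotherm(iso)
  out <- iso
  out$pressure <- pmax(polysmooth(iso$pressure, window, order), 0)
  out
}
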