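test_that("write/read round-trips isotherms field by field", {
  set.seed(42)
  for (branch in c("compression", "decompression")) {
    a <- sort(runif(50, 30, 120), decreasing = (branch == "compression"))
    iso <- isotherm(area = a, pressure = cumsum(runif(50, 0, 1)),
                    name = "round trip, with punctuation: 1:45:45",
                    components = c("protein", "lipids"),
                    mole_fractions = c(1 / 91, 90 / 91),
                    subphase = "150 mM NaCl + 0.5 uM CaCl2",
                    temperature_K = 308.15, branch = branch,
                    liftoff_pressure = 2.6)
    f <- withr::local_tempfile(fileext = ".csv")
    write_isotherm(iso, f)
    back <- read_isotherm(f)
    expect_equal(back$area, iso$area)
    expect_equal(back$pressure, iso$pressure)
    expect_identical(back$name, iso$name)
    expect_identical(back$components, iso$components)
    expect_equal(back$mole_fractions, iso$mole_fractions)
    expect_identical(back$subphase, iso$subphase)
    expect_equal(back$temperature_K, iso$temperature_K)
    expect_identical(back$branch, branch)
    expect_equal(back$liftoff_pressure, 2.6)
  }
})

test_that("writing is deterministic and validates before touching disk", {
  iso <- linear_isotherm(n = 20)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_isotherm(iso, f1); write_isotherm(iso, f2)
  expect_identical(readLines(f1), readLines(f2))
  bad <- iso; bad$pressure[3] <- NaN
  expect_error(write_isotherm(bad, f1), class = "monolayer_format_error")
})

test_that("parsing reports missing keys, bad rows and short files", {
  f <- withr::local_tempfile()
  base <- c("# name = x", "# components = a", "# mole_fractions = 1",
            "# subphase = water", "# temperature_K = 308.15",
            "# branch = compression", "area_A2,pressure_mN_m",
            "100,0.0", "80,5.0", "60,15.0")
  writeLines(base, f)
  iso <- read_isotherm(f)
  expect_equal(iso$area, c(100, 80, 60))
  expect_equal(iso$pressure, c(0, 5, 15))

  writeLines(base[-5], f)
  expect_error(read_isotherm(f), "temperature_K",
               class = "monolayer_format_error")
  writeLines(c(base[1:8], "80,oops", "60,15.0"), f)
  expect_error(read_isotherm(f), "line 9", class = "monolayer_parse_error")
  writeLines(base[1:9], f)
  expect_error(read_isotherm(f), class = "monolayer_insufficient_data_error")
})

test_that("duplicate-area rows are averaged on pressure and order is canonical", {
  f <- withr::local_tempfile()
  writeLines(c("# name = x", "# components = a", "# mole_fractions = 1",
               "# subphase = w", "# temperature_K = 300",
               "# branch = compression", "area_A2,pressure_mN_m",
               "60,15.0", "80,4.0", "100,0.0", "80,6.0"), f)
  iso <- read_isotherm(f)
  expect_equal(iso$area, c(100, 80, 60))
  expect_equal(iso$pressure, c(0, 5, 15))
})

test_that("isotherm invariants are enforced", {
  expect_error(isotherm(area = c(3, 2), pressure = c(0, 1)),
               class = "monolayer_insufficient_data_error")
  expect_error(isotherm(area = c(3, 2, 2.5), pressure = c(0, 1, 2)),
               class = "monolayer_format_error")
  expect_error(isotherm(area = c(3, 2, 1), pressure = c(0, -1, 2)),
               class = "monolayer_format_error")
  expect_error(isotherm(area = c(3, 2, 1), pressure = c(0, 1, 2),
                        mole_fractions = c(0.6, 0.5),
                        components = c("a", "b")),
               class = "monolayer_format_error")
  expect_error(isotherm(area = c(3, 2, 1), pressure = c(0, 1, 2),
                        temperature_K = -1),
               class = "monolayer_format_error")
})

test_that("resampling is exact on lines and knots, close on curves", {
  iso <- isotherm(area = 100 - 2 * c(0, 5, 10, 20), pressure = c(0, 5, 10, 20))
  expect_equal(as.numeric(resample_area_on_pressure(iso, 7.5)), 85)
  expect_equal(as.numeric(resample_area_on_pressure(iso, c(0, 5, 10, 20))),
               100 - 2 * c(0, 5, 10, 20))
  g <- generate_component(exp_spec(n = 200))
  expect_equal(as.numeric(resample_area_on_pressure(g, 10)), 40 + 60 / exp(1),
               tolerance = 0.05 / 62)
  expect_error(resample_area_on_pressure(g, 31), class = "monolayer_range_error")
})

test_that("resampling extends at constant lift-off area below range", {
  a <- seq(90, 50, length.out = 50)
  iso <- isotherm(area = a, pressure = seq(2, 20, length.out = 50))
  v <- resample_area_on_pressure(iso, c(0, 1, 2))
  expect_equal(as.numeric(v), c(90, 90, 90))
  expect_equal(attr(v, "extended"), c(TRUE, TRUE, FALSE))
  expect_error(resample_area_on_pressure(iso, 1, extend = FALSE),
               class = "monolayer_range_error")
})

test_that("resampling preserves monotonicity of A(pi)", {
  set.seed(7)
  for (k in 1:5) {
    g <- generate_component(exp_spec(a0 = runif(1, 80, 150),
                                     a_inf = runif(1, 20, 40),
                                     pi_c = runif(1, 5, 20), n = 100))
    grid <- sort(runif(40, 0, 30))
    v <- as.numeric(resample_area_on_pressure(g, grid))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("smoothing reproduces polynomial data and reduces noise", {
  n <- 101
  idx <- seq_len(n)
  a <- seq(120, 40, length.out = n)
  quad <- 30 - 0.002 * (idx - 50)^2 + 0.1 * idx
  iso <- isotherm(area = a, pressure = quad - min(quad) + 1)
  sm <- smooth_pressure(iso, window = 11, order = 2)
  expect_equal(sm$pressure, iso$pressure, tolerance = 1e-9)
  expect_identical(sm$area, iso$area)

  clean <- generate_component(exp_spec(n = 200))
  noisy <- generate_component(exp_spec(n = 200, noise_sigma = 0.1, seed = 11))
  smn <- smooth_pressure(noisy, window = 11, order = 2)
  rms <- function(x) sqrt(mean((x - clean$pressure)^2))
  expect_lt(rms(smn$pressure), rms(noisy$pressure))

  expect_error(smooth_pressure(iso, window = 4), class = "monolayer_parameter_error")
  expect_error(smooth_pressure(iso, window = 3, order = 2),
               class = "monolayer_parameter_error")
  expect_error(smooth_pressure(iso, window = 201), class = "monolayer_parameter_error")
})
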