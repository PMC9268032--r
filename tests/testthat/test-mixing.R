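# shared noiseless fixtures: exponential protein- and lipid-like curves plus
# mixtures with a known interaction amplitude
mix_fixture <- function(beta = -5, x = c(0.5, 0.5), pi_d = 10, n = 300) {
  s1 <- exp_spec(a0 = 100, a_inf = 40, pi_c = 10, pi_max = 30, n = n)
  s2 <- exp_spec(a0 = 60, a_inf = 30, pi_c = 15, pi_max = 30, n = n)
  list(
    mixture = generate_mixture(mixture_spec(list(s1, s2), x, beta = beta,
                                            pi_d = pi_d, n_points = n)),
    components = list(generate_component(s1, name = "protein"),
                      generate_component(s2, name = "lipids")),
    specs = list(s1, s2), x = x, beta = beta, pi_d = pi_d
  )
}

test_that("molar ratios convert to exact pseudo-binary mole fractions", {
  c1 <- ratio_to_molefractions(c(1, 45, 45))
  expect_identical(c1$x_protein, 1 / 91)
  expect_equal(c1$x_protein + c1$x_lipids, 1, tolerance = 1e-12)
  expect_identical(ratio_to_molefractions(c(1, 0, 0))$x_protein, 1)
  expect_identical(ratio_to_molefractions(c(1, 86, 86))$x_protein, 1 / 173)
  expect_error(ratio_to_molefractions(c(0, 0, 0)), class = "monolayer_domain_error")
  expect_error(ratio_to_molefractions(c(1, -1, 1)), class = "monolayer_domain_error")
  expect_identical(parse_ratio("1:45:45")$x_protein, 1 / 91)
  expect_error(parse_ratio("1:x:45"), class = "monolayer_parse_error")
})

test_that("additive areas are mole-fraction weighted component areas", {
  p <- seq(0, 20, length.out = 100)
  c1 <- isotherm(area = 100 - 2 * p, pressure = p, name = "c1")
  c2 <- isotherm(area = 60 - 2 * p, pressure = p, name = "c2")
  expect_equal(additive_area(list(c1, c1), c(0.3, 0.7), 10),
               as.numeric(resample_area_on_pressure(c1, 10)))
  # A1(10) = 80, A2(10) = 40, X = (0.25, 0.75) -> 50
  expect_equal(additive_area(list(c1, c2), c(0.25, 0.75), 10), 50)
  # exponential pair, closed forms summed
  e1 <- generate_component(exp_spec(100, 40, 10, n = 200))
  e2 <- generate_component(exp_spec(60, 30, 15, n = 200))
  expect_equal(additive_area(list(e1, e2), c(0.5, 0.5), 10),
               0.5 * (40 + 60 * exp(-1)) + 0.5 * (30 + 30 * exp(-10 / 15)),
               tolerance = 0.05 / 53.7)
  expect_error(additive_area(list(c1, c2), c(0.5, 0.6), 10),
               class = "monolayer_parameter_error")
  expect_error(additive_area(list(c1, c2), c(0.5, 0.5), 25),
               class = "monolayer_range_error")
})

test_that("area deviation recovers the constructed interaction term", {
  fx <- mix_fixture()
  d <- area_deviation(fx$mixture, fx$components, fx$x, c(0, 10))
  expect_equal(d$delta_a[1], -1.25, tolerance = 1e-9)
  expect_equal(d$delta_a[2], -1.25 * exp(-1), tolerance = 1e-3 / 0.46)
  # exactly additive mixture: zero deviation everywhere
  fx0 <- mix_fixture(beta = 0)
  d0 <- area_deviation(fx0$mixture, fx0$components, fx0$x, c(0, 5, 10, 20))
  expect_equal(d0$delta_a, rep(0, 4), tolerance = 1e-9)
})

test_that("excess free energy matches the closed-form perturbation integral", {
  fx <- mix_fixture()
  e <- excess_free_energy(fx$mixture, fx$components, fx$x, 20)
  oracle <- 6.02214076e23 * (-1.25 * 10 * (1 - exp(-2))) * 1e-23   # -65.1 J/mol
  expect_equal(as.numeric(e), oracle, tolerance = 0.01)
  # additive mixture integrates to zero
  fx0 <- mix_fixture(beta = 0)
  e0 <- excess_free_energy(fx0$mixture, fx0$components, fx0$x, 20)
  expect_lt(abs(as.numeric(e0)), 0.1)
  # X_protein = 0: the "mixture" is the lipid film, Eq. collapses to zero
  lip <- fx$components[[2]]
  ez <- excess_free_energy(lip, fx$components, c(0, 1), 20)
  expect_lt(abs(as.numeric(ez)), 1e-9)
})

test_that("ideal mixing free energy follows RT(x ln x + (1-x) ln(1-x))", {
  expect_equal(ideal_free_energy(0.5, 308.15), -8.314 * 308.15 * log(2),
               tolerance = 1e-12)
  expect_equal(ideal_free_energy(0.5, 308.15), -1775.8, tolerance = 0.1 / 1775.8)
  expect_identical(ideal_free_energy(1, 308.15), 0)
  expect_identical(ideal_free_energy(0, 308.15), 0)
  expect_equal(ideal_free_energy(0.006, 308.15), -94.0, tolerance = 0.1 / 94)
  expect_error(ideal_free_energy(1.2), class = "monolayer_domain_error")
  expect_error(ideal_free_energy(0.5, -3), class = "monolayer_domain_error")
  # symmetric in x <-> 1-x, minimal at 1/2, non-positive
  xs <- seq(0, 1, by = 0.05)
  g <- ideal_free_energy(xs, 310)
  expect_equal(g, rev(g), tolerance = 1e-12)
  expect_true(all(g <= 0))
  expect_equal(which.min(g), which(xs == 0.5))
})

test_that("total mixing energy assembles its parts with an exact identity", {
  fx <- mix_fixture()
  r <- mixing_free_energy(fx$mixture, fx$components, fx$x, 20, 308.15)
  expect_identical(r$dg_mix, r$dg_exc + r$dg_ideal)
  expect_equal(r$dg_mix, -65.1 + -8.314 * 308.15 * log(2), tolerance = 0.01)
  # additive mixture: dg_mix reduces to the ideal term
  fx0 <- mix_fixture(beta = 0)
  r0 <- mixing_free_energy(fx0$mixture, fx0$components, fx0$x, 15, 308.15)
  expect_equal(r0$dg_mix, r0$dg_ideal, tolerance = 1e-4)
})

test_that("mixing scan covers the pressure-composition table", {
  s1 <- exp_spec(a0 = 250, a_inf = 40, pi_c = 15, pi_max = 35, n = 150)
  s2 <- exp_spec(a0 = 60, a_inf = 38, pi_c = 18, pi_max = 35, n = 150)
  comps <- list(generate_component(s1, name = "protein"),
                generate_component(s2, name = "lipids"))
  ratios <- list(c(1, 86, 86), c(1, 58.5, 58.5), c(1, 45, 45),
                 c(1, 10, 10), c(1, 2, 2), c(1, 1, 1))
  mixtures <- lapply(ratios, function(r) {
    cmp <- ratio_to_molefractions(r)
    list(isotherm = generate_mixture(mixture_spec(
           list(s1, s2), c(cmp$x_protein, cmp$x_lipids),
           beta = -5, pi_d = 10, n_points = 150)),
         composition = cmp)
  })
  scan <- mixing_scan(mixtures, comps, c(3, 6, 9, 12), 308.15)
  expect_s3_class(scan, "mixing_scan")
  expect_identical(nrow(scan), 24L)
  expect_true(all(vapply(scan, function(col) all(is.finite(col)), TRUE)))
  # condensing interaction: negative deviation in every row
  expect_true(all(scan$delta_a < 0))
  # identity holds row by row, exactly
  expect_identical(scan$dg_mix, scan$dg_exc + scan$dg_ideal)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mixing_table(scan, f)
  tab <- utils::read.delim(f)
  expect_identical(nrow(tab), 24L)
  expect_identical(names(tab)[1], "pressure_mN_m")
})

test_that("|dG_exc| grows with the interaction amplitude and with pressure", {
  vals <- vapply(c(-2, -4, -6, -8), function(b) {
    fx <- mix_fixture(beta = b, n = 150)
    as.numeric(excess_free_energy(fx$mixture, fx$components, fx$x, 10))
  }, 0)
  expect_true(all(diff(abs(vals)) > 0))
  fx <- mix_fixture(n = 150)
  along_pi <- vapply(c(2, 5, 10, 15, 20),
                     function(p) as.numeric(excess_free_energy(
                       fx$mixture, fx$components, fx$x, p)), 0)
  expect_true(all(diff(abs(along_pi)) > 0))
})

test_that("the trapezoid integral converges under grid refinement", {
  fx <- mix_fixture(n = 200)
  e1 <- as.numeric(excess_free_energy(fx$mixture, fx$components, fx$x, 20,
                                      n_grid = 201))
  e2 <- as.numeric(excess_free_energy(fx$mixture, fx$components, fx$x, 20,
                                      n_grid = 402))
  expect_equal(e1, e2, tolerance = 0.001)
})

test_that("below-lift-off extension is applied and reported", {
  p <- seq(2, 20, length.out = 100)         # lifts off at pi = 2
  mix <- isotherm(area = 70 - p, pressure = p, name = "mix")
  c1 <- isotherm(area = 100 - seq(0, 20, length.out = 100),
                 pressure = seq(0, 20, length.out = 100), name = "c1")
  e <- excess_free_energy(mix, list(c1, c1), c(0.5, 0.5), 10)
  ext <- attr(e, "extension_J_mol")
  # mixture extension: 68 A2 x 2 mN/m, components lift off at zero
  expect_equal(ext, 68 * 2 * 1e-23 * 6.02214076e23, tolerance = 1e-9)
})

test_that("the interaction amplitude is recovered from the area deviation", {
  fx <- mix_fixture(beta = -5)
  d0 <- area_deviation(fx$mixture, fx$components, fx$x, 0)
  expect_equal(d0$delta_a / (0.5 * 0.5), -5, tolerance = 1e-6 / 5)
  est <- estimate_beta(fx$mixture, fx$components, fx$x, pi_d = 10,
                       smooth = FALSE)
  expect_equal(est, -5, tolerance = 1e-3)
})
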