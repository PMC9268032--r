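# Fixtures built in code; no data files.

linear_isotherm <- function(slope = 0.5, a0 = 100, a_end = 40, n = 200, ...) {
  a <- seq(a0, a_end, length.out = n)
  isotherm(area = a, pressure = slope * (a0 - a), name = "linear", ...)
}

exp_spec <- function(a0 = 100, a_inf = 40, pi_c = 10, pi_max = 30, n = 300, ...) {
  component_spec(a0 = a0, a_inf = a_inf, pi_c = pi_c, pi_max = pi_max,
                 n_points = n, ...)
}

# an elasticity profile object from raw vectors, for detector tests
profile_from <- function(pressure, cs_inv) {
  i <- which.max(cs_inv)
  structure(list(pressure = pressure, cs_inv = cs_inv,
                 cs_inv_max = cs_inv[i], pressure_at_max = pressure[i],
                 transition_pressure = NA_real_, source = "constructed"),
            class = "elasticity_profile")
}
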