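# Shared fixtures: all built in code, no files.

quick_config <- function(t_end = 72, dt = 0.5) {
  simulation_config(t_end = t_end, dt = dt, rtol = 1e-6, atol = 1e-8)
}

tight_config <- function(t_end = 72, dt = 0.25) {
  simulation_config(t_end = t_end, dt = dt, rtol = 1e-8, atol = 1e-10)
}

nominal_pair <- function(...) build_scenario("pair_twoway_symmetric", ...)
nominal_mono <- function(...) build_scenario("mono_producer", ...)

# A plain prototroph monoculture (no production).
plain_prototroph <- function(v_max = 10, k_m = 10, yield = 0.5, eta = 0,
                             G0 = 20, N0 = 0.1) {
  s <- strain_spec("y1", glucose_uptake = uptake_kinetics(v_max, k_m),
                   yield_glucose = yield, death_rate = eta,
                   fluor_channel = "RFP")
  list(model = community_model(list(s)),
       init = initial_condition(glucose_0 = G0, total_density_0 = N0,
                                ratios_0 = c(y1 = 1)))
}

# Ishigami benchmark function (vectorised over rows).
ishigami <- function(X, a = 7, b = 0.1) {
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}

# Closed-form Ishigami variance decomposition, recomputed from the
# analytic partial variances.
ishigami_closed_form <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * 8 / 225
  V <- V1 + V2 + V13
  list(S1 = V1 / V, S2 = V2 / V, S3 = 0,
       ST1 = (V1 + V13) / V, ST3 = V13 / V)
}
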