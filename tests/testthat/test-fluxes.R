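test_that("Monod uptake saturates and rejects negative substrate", {
  expect_equal(monod_uptake(uptake_kinetics(10, 10), 10), 5)
  expect_equal(monod_uptake(uptake_kinetics(30, 100), 0), 0)
  expect_equal(monod_uptake(uptake_kinetics(30, 1), 1e6), 29.99997,
               tolerance = 1e-7)
  # strictly increasing, bounded by v_max
  s <- seq(0, 500, by = 5)
  v <- monod_uptake(uptake_kinetics(12, 40), s)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 12))
  expect_error(monod_uptake(uptake_kinetics(10, 10), -1, "x.ade"),
               "x\\.ade")
})

test_that("leak flux is proportional to the glucose flux", {
  expect_equal(leak_flux(0.5, 1, 8), 4)
  expect_equal(leak_flux(0, 1, 8), 0)
  expect_equal(leak_flux(0.2, 2, 10), 4)
  expect_error(leak_flux(1, 1, 8), "phi")
  expect_error(leak_flux(-0.1, 1, 8), "phi")
})

test_that("growth rate is the limiting-resource minimum", {
  kin <- uptake_kinetics(10, 10)
  s <- strain_spec("a", auxotrophies = "x1", productions = c(x2 = 0.2),
                   glucose_uptake = kin,
                   metabolite_uptake = list(x1 = kin),
                   yield_glucose = 0.5, yield_metabolite = c(x1 = 0.3))
  g <- growth_rate(s, j_upt_glucose = 10, j_upt_metabolites = c(x1 = 5))
  expect_equal(g$rate, 1.5) # min(0.5*0.8*10, 0.3*5)
  expect_equal(g$limiting, "x1")

  proto <- strain_spec("p", glucose_uptake = kin, yield_glucose = 0.5)
  g2 <- growth_rate(proto, 10)
  expect_equal(g2$rate, 5)
  expect_equal(g2$limiting, "glucose")

  # full diversion kills glucose-supported growth
  nearly1 <- strain_spec("q", productions = c(x2 = 1 - 1e-12),
                         glucose_uptake = kin, yield_glucose = 0.5)
  expect_equal(growth_rate(nearly1, 10)$rate, 0, tolerance = 1e-9)
})

test_that("toxicity attenuation is a Hill factor with half-point at the threshold", {
  kin <- uptake_kinetics(10, 10)
  s <- strain_spec("a", productions = c(x1 = 0.2), glucose_uptake = kin,
                   yield_glucose = 0.5)
  m <- community_model(list(s),
                       metabolites = list(metabolite_spec("x1",
                                            toxicity_threshold = 40)),
                       toxicity_enabled = TRUE)
  expect_equal(apply_toxicity(1, c(x1 = 0), m), 1)
  expect_equal(apply_toxicity(1, c(x1 = 40), m), 0.5)
  expect_lt(apply_toxicity(1, c(x1 = 4e5), m), 1e-6)
  # monotone non-increasing in the toxic concentration
  f <- sapply(seq(0, 200, by = 10), function(x)
    apply_toxicity(1, c(x1 = x), m))
  expect_true(all(diff(f) < 0))
  # disabled => identity
  m2 <- community_model(list(s),
                        metabolites = list(metabolite_spec("x1",
                                             toxicity_threshold = 40)))
  expect_identical(apply_toxicity(1, c(x1 = 100), m2), 1)
})

test_that("system derivatives match a hand evaluation on a prototroph", {
  pr <- plain_prototroph(v_max = 10, k_m = 10, yield = 0.5, eta = 0,
                         G0 = 20, N0 = 0.1)
  st <- crossfeed:::build_state0(pr$model, pr$init)
  d <- system_rhs(st, pr$model)
  # J_upt_G = 10*20/30; dG = -J*y; dy = 0.5*J*y
  expect_equal(unname(d["G"]), -10 * (20 / 30) * 0.1, tolerance = 1e-12)
  expect_equal(unname(d["y.y1"]), 0.5 * 10 * (20 / 30) * 0.1,
               tolerance = 1e-12)
})

test_that("mirrored strains and washout give the expected symmetries", {
  sc <- nominal_pair()
  st <- crossfeed:::build_state0(sc$model, sc$init)
  st["x.x1"] <- 10; st["x.x2"] <- 10
  d <- system_rhs(st, sc$model)
  expect_equal(unname(d["y.y1"]), unname(d["y.y2"]), tolerance = 1e-14)
  # washout fixed point: all biomasses zero => nothing changes
  st0 <- crossfeed:::build_state0(sc$model, sc$init)
  st0[grep("^y\\.", names(st0))] <- 0
  expect_true(all(system_rhs(st0, sc$model) == 0))
})

test_that("compiled and reference right-hand sides integrate identically", {
  for (name in c("pair_twoway_symmetric", "trio_twoway", "dol_resveratrol")) {
    sc <- build_scenario(name)
    cfg <- quick_config(t_end = 24)
    a <- simulate_batch(sc$model, sc$init, cfg, use_compiled = TRUE)
    b <- simulate_batch(sc$model, sc$init, cfg, use_compiled = FALSE)
    expect_equal(as.matrix(a$trajectory), as.matrix(b$trajectory),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("the soft-min variant approaches the hard minimum as sharpness grows", {
  sc <- nominal_pair()
  cfg <- quick_config(t_end = 24)
  hard <- simulate_batch(sc$model, sc$init, cfg, use_compiled = FALSE)
  soft <- simulate_batch(sc$model, sc$init, cfg, smooth_min_k = 2000)
  fin <- nrow(hard$trajectory)
  expect_equal(hard$trajectory$y.y1[fin], soft$trajectory$y.y1[fin],
               tolerance = 1e-2)
})
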