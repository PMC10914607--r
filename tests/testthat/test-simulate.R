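test_that("trajectories respect non-negativity and glucose monotonicity", {
  for (name in c("pair_twoway_symmetric", "trio_oneway", "dol_resveratrol")) {
    sc <- build_scenario(name)
    res <- simulate_batch(sc$model, sc$init, tight_config())
    tr <- as.matrix(res$trajectory[-1])
    expect_true(all(tr >= -10 * res$config$atol),
                label = paste(name, "non-negativity"))
    expect_true(all(diff(res$trajectory$G) <= 1e-10),
                label = paste(name, "glucose monotonicity"))
  }
})

test_that("metabolite production obeys the leak stoichiometry (mass balance)", {
  # with no consumer, accumulated metabolite = phi * delta * glucose used
  sc <- nominal_mono(phi = 0.3)
  res <- simulate_batch(sc$model, sc$init, tight_config())
  tr <- res$trajectory
  n <- nrow(tr)
  produced <- tr$x.x1[n]
  consumed <- sc$init$glucose_0 - tr$G[n]
  expect_equal(produced, 0.3 * 1 * consumed, tolerance = 1e-4)
  # delta rescales the stoichiometry
  m2 <- community_model(sc$model$strains,
                        metabolites = list(metabolite_spec("x1", delta = 2)))
  res2 <- simulate_batch(m2, sc$init, tight_config())
  tr2 <- res2$trajectory
  expect_equal(tr2$x.x1[nrow(tr2)],
               0.3 * 2 * (sc$init$glucose_0 - tr2$G[nrow(tr2)]),
               tolerance = 1e-4)
})

test_that("a mirrored pair at 1:1 stays exactly balanced", {
  sc <- nominal_pair()
  res <- simulate_batch(sc$model, sc$init, tight_config())
  expect_lt(max(abs(res$trajectory$y.y1 - res$trajectory$y.y2)), 1e-8)
  ms <- compute_metrics(res)
  expect_equal(unname(ms$final_ratios), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("a non-producing prototroph converts all glucose to biomass", {
  pr <- plain_prototroph(eta = 0, G0 = 20, N0 = 0.1)
  res <- simulate_batch(pr$model, pr$init, tight_config())
  final <- res$trajectory$y.y1[nrow(res$trajectory)]
  expect_equal(final, 0.5 * 20 + 0.1, tolerance = 1e-3)
})

test_that("batch time is the interpolated glucose-exhaustion crossing", {
  pr <- plain_prototroph(eta = 0)
  coarse <- simulate_batch(pr$model, pr$init, quick_config(dt = 1))
  fine <- simulate_batch(pr$model, pr$init, quick_config(dt = 0.1))
  bt_coarse <- compute_metrics(coarse)$batch_time
  bt_fine <- compute_metrics(fine)$batch_time
  # refined-grid oracle agrees within one coarse output step
  expect_lt(abs(bt_coarse - bt_fine), 1)
  expect_lt(bt_coarse, 72)
  # never-exhausted batches report the window end
  sc0 <- nominal_pair(promoter = 6) # no exchange: no growth
  ms0 <- compute_metrics(simulate_batch(sc0$model, sc0$init, quick_config()))
  expect_equal(ms0$batch_time, 72)
})

test_that("metrics are stable under output-grid refinement", {
  sc <- nominal_pair()
  m1 <- compute_metrics(simulate_batch(sc$model, sc$init,
                                       tight_config(dt = 0.25)))
  m2 <- compute_metrics(simulate_batch(sc$model, sc$init,
                                       tight_config(dt = 0.125)))
  for (f in c("final_total_population", "batch_time")) {
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-3)
  }
  expect_equal(m1$max_growth_rate, m2$max_growth_rate, tolerance = 1e-3)
})

test_that("a washed-out culture reports inoculum composition with a flag", {
  sc <- nominal_pair(ratio = "10:1")
  init0 <- sc$init
  init0$total_density_0 <- 0
  ms <- compute_metrics(simulate_batch(sc$model, init0, quick_config()))
  expect_true(ms$degenerate_composition)
  expect_equal(unname(ms$final_ratios), c(10 / 11, 1 / 11))
  # pathway metrics are absent, not zero, without a pathway
  expect_null(ms$productivity)
  expect_null(ms$yield_ratio)
})

test_that("co-auxotrophs without exchange only decay", {
  sc <- nominal_pair(promoter = 6) # phi = 0 on both sides
  res <- simulate_batch(sc$model, sc$init, quick_config())
  ms <- compute_metrics(res)
  expect_lte(ms$final_total_population, sc$init$total_density_0)
})

test_that("growth-strength classification follows the OD700 thresholds", {
  expect_equal(classify_growth(c(0.6, 0.5, 0.3, 0.29, 0.1)),
               c("strong", "strong", "medium", "weak", "weak"))
  expect_error(classify_growth(-0.1), ">= 0")
})

test_that("simulation is deterministic", {
  sc <- build_scenario("trio_twoway")
  a <- simulate_batch(sc$model, sc$init, quick_config())
  b <- simulate_batch(sc$model, sc$init, quick_config())
  expect_identical(a$trajectory, b$trajectory)
})

test_that("batch time lengthens with increasing diversion in monoculture", {
  sc <- nominal_mono()
  tab <- sweep_metrics(sc$model, sc$init, quick_config(),
                       paths = "strains.y1.productions.x1",
                       values = list(seq(0.1, 0.9, by = 0.1)))
  expect_true(all(diff(tab$batch_time) >= -1e-6))
})
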