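test_that("noise-free readings equal the model trajectories exactly", {
  sc <- nominal_pair()
  ds <- generate_platereader(sc$model, sc$init, noise_sd = 0, seed = 4,
                             config = quick_config())
  expect_equal(ds$od_total, rowSums(ds$truth))
  expect_equal(unname(ds$channels[, "RFP"]), unname(ds$truth[, "y1"]))
  expect_equal(unname(ds$channels[, "BFP"]), unname(ds$truth[, "y2"]))
})

test_that("datasets are reproducible by seed and respect the noise model", {
  sc <- nominal_pair()
  a <- generate_platereader(sc$model, sc$init, noise_sd = 0.05, seed = 11,
                            config = quick_config())
  b <- generate_platereader(sc$model, sc$init, noise_sd = 0.05, seed = 11,
                            config = quick_config())
  expect_identical(a$od_total, b$od_total)
  expect_identical(a$channels, b$channels)
  c. <- generate_platereader(sc$model, sc$init, noise_sd = 0.05, seed = 12,
                             config = quick_config())
  expect_false(identical(a$od_total, c.$od_total))

  # relative residuals across many readings match the nominal sigma
  fine <- generate_platereader(sc$model, sc$init, noise_sd = 0.05, seed = 5,
                               config = quick_config(dt = 0.05))
  truth_tot <- rowSums(fine$truth)
  keep <- truth_tot > 1e-6
  resid <- c(fine$od_total[keep] / truth_tot[keep] - 1,
             fine$channels[keep, "RFP"] / fine$truth[keep, "y1"] - 1)
  expect_gt(length(resid), 1000)
  expect_equal(stats::sd(resid), 0.05, tolerance = 0.1 * 0.05 / 0.05)
})

test_that("subpopulation unmixing reconstructs the tagged populations", {
  sc <- nominal_pair(ratio = "10:1")
  ds0 <- generate_platereader(sc$model, sc$init, noise_sd = 0, seed = 3,
                              gains = c(RFP = 2.5, BFP = 0.7),
                              backgrounds = c(RFP = 0.2, BFP = 0.05),
                              config = quick_config())
  est <- estimate_subpopulations(ds0)
  expect_equal(est, ds0$truth, tolerance = 1e-10, ignore_attr = TRUE)

  # estimates sum to the observed total at every time point
  ds <- generate_platereader(sc$model, sc$init, noise_sd = 0.05, seed = 6,
                             config = quick_config())
  est2 <- estimate_subpopulations(ds)
  expect_equal(rowSums(est2), ds$od_total, tolerance = 1e-10)
  expect_true(all(est2 >= 0))

  # 5% noise: time-averaged relative error under 10% per strain
  errs <- sapply(1:5, function(seed) {
    d <- generate_platereader(sc$model, sc$init, noise_sd = 0.05,
                              seed = seed, config = quick_config())
    e <- estimate_subpopulations(d)
    keep <- rowSums(d$truth) > 0.02
    colMeans(abs(e[keep, ] - d$truth[keep, ]) / pmax(d$truth[keep, ], 0.01))
  })
  expect_lt(max(rowMeans(errs)), 0.10)

  ds$gains <- NULL
  expect_error(estimate_subpopulations(ds), "gains")
})

test_that("growth parameters are recovered from clean monoculture data", {
  mono <- nominal_mono()
  ds <- generate_platereader(mono$model, mono$init, noise_sd = 0, seed = 1,
                             config = quick_config(t_end = 24, dt = 0.25))
  fit <- fit_growth_parameters(
    ds, mono$model, mono$init,
    free = list("strains.y1.yield_glucose" = c(0.01, 1),
                "strains.y1.glucose_uptake.v_max" = c(1, 30)),
    n_starts = 3, seed = 2)
  expect_true(fit$converged)
  truth <- c(0.505, 15.5)
  expect_lt(max(abs(fit$estimates - truth) / truth), 0.01)
})

test_that("a zero leak fraction is recovered at the boundary", {
  pr <- nominal_mono(promoter = 6) # true phi = 0
  ds <- generate_platereader(pr$model, pr$init, noise_sd = 0, seed = 2,
                             config = quick_config(t_end = 24, dt = 0.25))
  fit <- fit_growth_parameters(
    ds, pr$model, pr$init,
    free = list("strains.y1.productions.x1" = c(0, 0.49)),
    n_starts = 3, seed = 3)
  expect_lt(fit$estimates[[1]], 0.02)
})

test_that("recovery error shrinks as measurement noise decreases", {
  mono <- nominal_mono()
  err_at <- function(sigma) {
    errs <- sapply(1:3, function(seed) {
      ds <- generate_platereader(mono$model, mono$init, noise_sd = sigma,
                                 seed = seed,
                                 config = quick_config(t_end = 24, dt = 0.5))
      fit <- fit_growth_parameters(
        ds, mono$model, mono$init,
        free = list("strains.y1.yield_glucose" = c(0.01, 1),
                    "strains.y1.glucose_uptake.v_max" = c(1, 30)),
        n_starts = 2, seed = seed + 100)
      truth <- c(0.505, 15.5)
      mean(abs(fit$estimates - truth) / truth)
    })
    mean(errs)
  }
  errs <- vapply(c(0.1, 0.05, 0.01), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})
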