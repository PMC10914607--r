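make_null_config <- function(n = 3, ns = 65, nr = 3, seed = 1, bounds = NULL) {
  ps <- lapply(seq_len(n - 1), function(i)
    gsa_parameter(paste0("z", i), "null",
                  if (is.null(bounds)) 0 else bounds[1],
                  if (is.null(bounds)) 1 else bounds[2]))
  ps <- c(ps, list(gsa_parameter("dummy", "dummy", 0, 1)))
  gsa_config(ps, samples_per_search = ns, resamplings = nr, seed = seed)
}

test_that("search-curve sampling spans ranges and respects the simplex", {
  # the transform sits at the midpoint for s = 0, phase = 0
  expect_equal(crossfeed:::search_curve(0, 11, 0), 0.5)
  cfg <- make_null_config(n = 4, ns = 257, seed = 3)
  X <- efast_sample(cfg, 2, 1)
  expect_equal(dim(X), c(257L, 4L))
  for (j in 1:3) {
    expect_gte(min(X[, j]), 0)
    expect_lte(max(X[, j]), 1)
    expect_lt(min(X[, j]), 0.05) # whole range searched
    expect_gt(max(X[, j]), 0.95)
  }
  # ratio-simplex columns renormalise to sum exactly one
  ps <- list(gsa_parameter("r1", "null", 0.01, 1, group = "ratio-simplex"),
             gsa_parameter("r2", "null", 0.01, 1, group = "ratio-simplex"),
             gsa_parameter("r3", "null", 0.01, 1, group = "ratio-simplex"),
             gsa_parameter("dummy", "dummy", 0, 1))
  cfg2 <- gsa_config(ps, samples_per_search = 129, resamplings = 2, seed = 2)
  X2 <- efast_sample(cfg2, 1, 1)
  expect_lt(max(abs(rowSums(X2[, 1:3]) - 1)), 1e-12)
})

test_that("sampling is deterministic in (seed, resample, focus)", {
  cfg <- make_null_config(n = 5, ns = 129, seed = 9)
  expect_identical(efast_sample(cfg, 2, 3), efast_sample(cfg, 2, 3))
  expect_false(identical(efast_sample(cfg, 2, 3), efast_sample(cfg, 2, 4)))
  expect_false(identical(efast_sample(cfg, 2, 3), efast_sample(cfg, 3, 3)))
})

test_that("configuration guards reject unusable designs", {
  ps <- list(gsa_parameter("a", "null", 0, 1),
             gsa_parameter("dummy", "dummy", 0, 1))
  expect_error(gsa_config(ps, samples_per_search = 9, resamplings = 2),
               "Nyquist|at least")
  expect_error(gsa_config(ps, samples_per_search = 64, resamplings = 2),
               "odd")
  expect_error(gsa_config(ps, samples_per_search = 65, resamplings = 1),
               "resamplings")
  expect_error(gsa_config(list(ps[[1]], ps[[1]]), 65, 2), "dummy")
  expect_error(gsa_parameter("a", "null", 1, 1), "lower")
})

test_that("indices recover closed forms for an additive linear model", {
  cfg <- make_null_config(n = 3, ns = 1285, nr = 5, seed = 21)
  si <- matrix(NA_real_, 5, 2)
  for (r in 1:5) {
    for (k in 1:2) {
      X <- efast_sample(cfg, k, r)
      si[r, k] <- efast_indices(2 * X[, 1] + X[, 2], cfg, k)$Si
    }
  }
  # var = 4/12 + 1/12; S1 = 0.8, S2 = 0.2
  expect_equal(mean(si[, 1]), 0.8, tolerance = 0.05)
  expect_equal(mean(si[, 2]), 0.2, tolerance = 0.05)
})

test_that("indices recover the Ishigami variance decomposition", {
  cf <- ishigami_closed_form()
  cfg <- make_null_config(n = 4, ns = 1285, nr = 5, seed = 13,
                          bounds = c(-pi, pi))
  res <- matrix(NA_real_, 3, 2)
  for (k in 1:3) {
    si <- st <- numeric(5)
    for (r in 1:5) {
      X <- efast_sample(cfg, k, r)
      idx <- efast_indices(ishigami(X), cfg, k)
      si[r] <- idx$Si; st[r] <- idx$ST
    }
    res[k, ] <- c(mean(si), mean(st))
  }
  expect_equal(res[1, 1], cf$S1, tolerance = 0.05)
  expect_equal(res[2, 1], cf$S2, tolerance = 0.05)
  expect_equal(res[3, 1], cf$S3, tolerance = 0.05)
  # the interaction-only parameter carries total-order weight
  expect_gt(res[3, 2], 0.1)
  # Si <= ST within estimator tolerance, everywhere
  expect_true(all(res[, 1] <= res[, 2] + 0.02))
})

test_that("constant output yields zero indices with a flag", {
  cfg <- make_null_config(ns = 65)
  idx <- efast_indices(rep(3.2, 65), cfg, 1)
  expect_equal(idx$Si, 0)
  expect_equal(idx$ST, 0)
  expect_true(idx$constant)
  expect_error(efast_indices(rep(1, 10), cfg, 1), "length")
  expect_error(efast_indices(c(rep(1, 64), NA), cfg, 1), "finite")
})

test_that("a full analysis is reproducible and sane on the nominal pair", {
  sc <- nominal_pair()
  params <- gsa_default_parameters(sc$model)
  cfg <- gsa_config(params, samples_per_search = 65, resamplings = 4,
                    seed = 17)
  sens <- efast_run(sc$model, sc$init, cfg,
                    metrics = c("final_total_population", "batch_time"))
  tab <- sens$table
  # one row per (parameter, metric)
  expect_equal(nrow(tab), length(params) * 2L)
  expect_equal(sens$n_failed, 0L)
  # indices live in [0, 1.05] and Si <= ST within estimator tolerance
  expect_true(all(tab$Si_mean >= 0 & tab$Si_mean <= 1.05))
  expect_true(all(tab$ST_mean >= 0 & tab$ST_mean <= 1.05))
  expect_true(all(tab$Si_mean <= tab$ST_mean + 0.02))
  expect_true(all(tab$Si_sd >= 0 & tab$ST_sd >= 0))
  # the dummy is never flagged against itself
  drow <- tab[tab$parameter == "dummy", ]
  expect_true(all(!drow$significant))
  expect_true(all(is.na(drow$p_value)))
  # reproducibility
  sens2 <- efast_run(sc$model, sc$init, cfg,
                     metrics = c("final_total_population", "batch_time"))
  expect_identical(sens$table, sens2$table)
})

test_that("resampling spread shrinks with more samples per curve", {
  # averaged over parameters of the Ishigami benchmark, the s.d. of the
  # first-order index over resamplings decreases along 257 -> 513 -> 1285
  sds <- sapply(c(257, 513, 1285), function(ns) {
    cfg <- make_null_config(n = 4, ns = ns, nr = 6, seed = 31,
                            bounds = c(-pi, pi))
    mean(sapply(1:3, function(k) {
      stats::sd(sapply(1:6, function(r) {
        X <- efast_sample(cfg, k, r)
        efast_indices(ishigami(X), cfg, k)$Si
      }))
    }))
  })
  expect_true(all(diff(sds) < 0))
})
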