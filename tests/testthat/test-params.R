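test_that("parameter paths resolve for reading and writing", {
  sc <- build_scenario("dol_resveratrol")
  expect_equal(get_param(sc$model, sc$init,
                         "strains.y1.productions.x1"), 0.25)
  expect_equal(get_param(sc$model, sc$init, "init.total_density_0"), 0.102)
  expect_equal(get_param(sc$model, sc$init, "pathway.phi_upstream"), 0.3)

  mi <- set_param(sc$model, sc$init, "strains.y2.glucose_uptake.v_max", 22)
  expect_equal(get_param(mi$model, mi$init,
                         "strains.y2.glucose_uptake.v_max"), 22)
  # originals untouched
  expect_equal(get_param(sc$model, sc$init,
                         "strains.y2.glucose_uptake.v_max"), 15.5)

  mi <- set_param(sc$model, sc$init, "init.supplements_0.x1", 30)
  st <- crossfeed:::build_state0(mi$model, mi$init)
  expect_equal(unname(st["x.x1"]), 30)

  err <- tryCatch(get_param(sc$model, sc$init, "strains.y1.nope"),
                  error = conditionMessage)
  expect_match(err, "valid paths")
  expect_match(err, "strains.y1.glucose_uptake.v_max", fixed = TRUE)
  expect_error(set_param(sc$model, sc$init, "bad.path", 1), "valid paths")
})

test_that("parameter setting agrees between object surgery and packed setters", {
  sc <- nominal_pair()
  params <- gsa_default_parameters(sc$model)
  gcfg <- gsa_config(params, samples_per_search = 65, resamplings = 2,
                     seed = 5)
  prob <- crossfeed:::compile_gsa_problem(sc$model, sc$init, gcfg)
  X <- efast_sample(gcfg, 1, 1)
  row <- X[7, ]
  fast <- crossfeed:::apply_gsa_row(prob, row)
  # slow route: set every parameter through the public path interface
  mi <- list(model = sc$model, init = sc$init)
  for (j in seq_along(params)) {
    if (params[[j]]$path %in% c("dummy", "null")) next
    if (!is.null(params[[j]]$group)) next # ratios handled jointly below
    mi <- set_param(mi$model, mi$init, params[[j]]$path, row[j])
  }
  ridx <- which(!vapply(params, function(p) is.null(p$group), logical(1)))
  r <- row[ridx] / sum(row[ridx])
  mi$init$ratios_0 <- stats::setNames(r, c("y1", "y2"))
  expect_equal(fast$parms, crossfeed:::pack_parms(mi$model),
               tolerance = 1e-12)
  expect_equal(fast$y0,
               unname(crossfeed:::build_state0(mi$model, mi$init)),
               tolerance = 1e-12)
})

test_that("sweeps preserve grid order and handle empty and 2-D grids", {
  sc <- nominal_mono()
  empty <- sweep_metrics(sc$model, sc$init, quick_config(),
                         paths = "strains.y1.productions.x1",
                         values = list(numeric()))
  expect_equal(nrow(empty), 0L)

  vals <- c(0.4, 0.1, 0.3)
  tab <- sweep_metrics(sc$model, sc$init, quick_config(),
                       paths = "strains.y1.productions.x1",
                       values = list(vals))
  expect_equal(tab[[1]], vals) # order preserved, not sorted

  scp <- nominal_pair()
  grid <- sweep_metrics(scp$model, scp$init, quick_config(),
                        paths = c("strains.y1.productions.x1",
                                  "strains.y2.productions.x2"),
                        values = list(c(0.1, 0.3), c(0.2, 0.4)))
  expect_equal(nrow(grid), 4L)
  expect_equal(grid[[1]], c(0.1, 0.3, 0.1, 0.3))
  expect_error(
    sweep_metrics(sc$model, sc$init, quick_config(), "no.such", list(1)),
    "valid paths")
})

test_that("metabolite production rate is unimodal in the leak fraction", {
  sc <- nominal_mono()
  tab <- sweep_metrics(sc$model, sc$init, quick_config(),
                       paths = "strains.y1.productions.x1",
                       values = list(seq(0.05, 0.95, by = 0.05)))
  peak <- tab$max_production_rate.y1.x1
  k <- which.max(peak)
  expect_gt(k, 1)
  expect_lt(k, length(peak))
  expect_true(all(diff(peak[seq_len(k)]) > 0))
  expect_true(all(diff(peak[k:length(peak)]) < 0))
})
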