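#' Declare a parameter for global sensitivity analysis
#'
#' @param name Display name.
#' @param path Dotted parameter path into the model/init (see
#'   [valid_param_paths()]) or `"dummy"` for the inert null parameter
#'   that is varied but never written into the model.
#' @param lower,upper Range bounds on a linear uniform scale
#'   (`lower < upper`).
#' @param group Optional group tag; all parameters tagged
#'   `"ratio-simplex"` are renormalised to sum to 1 after sampling (the
#'   inoculum-ratio constraint).
#' @return An object of class `gsa_parameter`.
#' @export
gsa_parameter <- function(name, path, lower, upper, group = NULL) {
  stopifnot(is.character(name), is.character(path),
            is.numeric(lower), is.numeric(upper))
  if (lower >= upper) stop("gsa_parameter '", name, "': lower must be < upper",
                           call. = FALSE)
  structure(list(name = name, path = path, lower = lower, upper = upper,
                 group = group),
            class = "gsa_parameter")
}

#' Configure an eFAST analysis
#'
#' Defaults follow the reference protocol: 1285 samples per search
#' curve, 100 random-phase resamplings, 4 Fourier harmonics retained,
#' and a 1% significance threshold Bonferroni-corrected by the number
#' of varied parameters.
#'
#' @param parameters List of [gsa_parameter]s; exactly one must have
#'   path `"dummy"` (additional inert parameters may use path
#'   `"null"`).
#' @param samples_per_search Points per search curve (odd). Default
#'   1285.
#' @param resamplings Number of random-phase resamplings (>= 2; the
#'   t-test needs at least two index draws). Default 100.
#' @param harmonics Fourier harmonics retained (interference factor M).
#'   Default 4.
#' @param alpha Significance level before Bonferroni correction.
#'   Default 0.01.
#' @param seed Integer seed controlling all random phases.
#' @return An object of class `gsa_config`.
#' @export
gsa_config <- function(parameters, samples_per_search = 1285,
                       resamplings = 100, harmonics = 4, alpha = 0.01,
                       seed = 1L) {
  stopifnot(is.list(parameters), length(parameters) >= 2L)
  if (!all(vapply(parameters, inherits, logical(1), "gsa_parameter"))) {
    stop("parameters must be a list of gsa_parameter objects", call. = FALSE)
  }
  paths <- vapply(parameters, `[[`, character(1), "path")
  if (sum(paths == "dummy") != 1L) {
    stop("exactly one parameter must have path \"dummy\"", call. = FALSE)
  }
  nms <- vapply(parameters, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("parameter names must be unique",
                               call. = FALSE)
  if (samples_per_search %% 2 == 0) {
    stop("samples_per_search must be odd", call. = FALSE)
  }
  if (resamplings < 2) stop("resamplings must be >= 2 (the t-test needs at ",
                            "least two index draws)", call. = FALSE)
  fr <- efast_frequencies(length(parameters), samples_per_search, harmonics)
  cfg <- structure(
    list(parameters = parameters, samples_per_search = samples_per_search,
         resamplings = resamplings, harmonics = harmonics, alpha = alpha,
         seed = as.integer(seed)),
    class = "gsa_config")
  cfg
}

# Classical frequency assignment: the focus parameter carries a single
# high driving frequency omega = floor((Ns - 1) / (2 M)); the
# complementary set carries distinct low frequencies bounded by
# omega / (2 M), recycled when there are more parameters than available
# low frequencies.
efast_frequencies <- function(n_params, samples_per_search, harmonics) {
  omega <- floor((samples_per_search - 1) / (2 * harmonics))
  # the complementary band (integer frequencies below omega / (2 M)) must
  # be non-empty, so omega >= 2 M, i.e. Ns >= 4 M^2 + 1
  if (omega < 2 * harmonics) {
    stop("Nyquist violation: samples_per_search must be at least ",
         4 * harmonics^2 + 1, " for ", harmonics, " harmonics",
         call. = FALSE)
  }
  max_comp <- max(1L, floor(omega / (2 * harmonics)))
  comp_pool <- seq_len(max_comp)
  comp <- rep_len(comp_pool, n_params - 1L)
  # spread the complementary set across [1, max_comp] when room allows
  if (max_comp >= n_params - 1L && n_params > 1L) {
    comp <- unique(round(seq(1, max_comp, length.out = n_params - 1L)))
    comp <- rep_len(comp, n_params - 1L)
  }
  list(focus = omega, complementary = comp)
}

# Deterministic per-(seed, resample, focus) RNG scope.
with_curve_seed <- function(seed, resample, focus, expr) {
  s <- (as.numeric(seed) * 2654435 + resample * 40503 + focus * 9973) %%
    2147483629
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(s))
  force(expr)
}

# The search-curve transform: maps curve coordinate s and phase phi to
# [0, 1] via 0.5 + asin(sin(omega * s + phi)) / pi.
search_curve <- function(s, omega, phase) {
  0.5 + asin(sin(omega * s + phase)) / pi
}

#' Sample one eFAST search curve
#'
#' Builds the matrix of parameter vectors for one (focus parameter,
#' resample) pair. Each parameter follows a sinusoidal search curve
#' `x = lower + range * (1/2 + asin(sin(omega s + phase)) / pi)` with a
#' random phase per resampling; the focus parameter carries the high
#' driving frequency and the complementary parameters low distinct
#' frequencies. Parameters grouped `"ratio-simplex"` are renormalised
#' row-wise to sum to 1. Deterministic given `(config$seed, resample)`.
#'
#' @param config A [gsa_config].
#' @param focus Index (or name) of the focus parameter.
#' @param resample Resample number (1-based).
#' @return Numeric matrix, `samples_per_search` rows, one column per
#'   parameter (named).
#' @export
efast_sample <- function(config, focus, resample = 1L) {
  stopifnot(inherits(config, "gsa_config"))
  nms <- vapply(config$parameters, `[[`, character(1), "name")
  if (is.character(focus)) focus <- match(focus, nms)
  np <- length(config$parameters)
  stopifnot(!is.na(focus), focus >= 1L, focus <= np)
  ns <- config$samples_per_search
  fr <- efast_frequencies(np, ns, config$harmonics)
  omega <- numeric(np)
  omega[focus] <- fr$focus
  omega[-focus] <- fr$complementary
  phases <- with_curve_seed(config$seed, resample, focus,
                            stats::runif(np, 0, 2 * pi))
  s <- pi * (2 * seq_len(ns) - ns - 1) / ns
  X <- matrix(0, ns, np, dimnames = list(NULL, nms))
  for (j in seq_len(np)) {
    p <- config$parameters[[j]]
    X[, j] <- p$lower + (p$upper - p$lower) *
      search_curve(s, omega[j], phases[j])
  }
  groups <- vapply(config$parameters, function(p)
    if (is.null(p$group)) "" else p$group, character(1))
  simplex <- which(groups == "ratio-simplex")
  if (length(simplex) >= 2L) {
    tot <- rowSums(X[, simplex, drop = FALSE])
    X[, simplex] <- X[, simplex, drop = FALSE] / tot
  }
  X
}

#' Variance-decomposition indices from one search curve
#'
#' Fourier-analyses the model output along a search curve: the
#' first-order index is the output variance concentrated at the focus
#' frequency and its first `harmonics` harmonics divided by the total
#' variance; the total-order index is one minus the share of variance
#' in the complementary low-frequency band (frequencies up to
#' `omega / 2` and, for robustness, their harmonics fall inside that
#' band by construction). Indices are clipped to `[0, 1.05]`. A
#' constant output yields `(0, 0)` with `constant = TRUE`.
#'
#' @param outputs Numeric vector of metric values along the curve;
#'   length must equal `config$samples_per_search`.
#' @param config A [gsa_config].
#' @param focus Index or name of the focus parameter (determines the
#'   driving frequency).
#' @return List with `Si`, `ST` and flag `constant`.
#' @export
efast_indices <- function(outputs, config, focus = 1L) {
  stopifnot(inherits(config, "gsa_config"))
  ns <- config$samples_per_search
  if (length(outputs) != ns) {
    stop("outputs must have length samples_per_search = ", ns, call. = FALSE)
  }
  if (any(!is.finite(outputs))) {
    stop("outputs must be finite (impute or drop failures first)",
         call. = FALSE)
  }
  fr <- efast_frequencies(length(config$parameters), ns, config$harmonics)
  omega <- fr$focus
  M <- config$harmonics
  total_var <- stats::var(outputs) * (ns - 1) / ns
  if (total_var <= .Machine$double.eps * max(1, mean(outputs)^2)) {
    return(list(Si = 0, ST = 0, constant = TRUE))
  }
  co <- stats::fft(outputs) / ns
  nyq <- (ns - 1) %/% 2
  spec <- 2 * Mod(co[2:(nyq + 1)])^2 # variance at frequencies 1..nyq
  focus_freqs <- seq_len(M) * omega
  focus_freqs <- focus_freqs[focus_freqs <= nyq]
  Vi <- sum(spec[focus_freqs])
  low_band <- seq_len(floor(omega / 2))
  Vc <- sum(spec[low_band])
  Si <- max(0, min(Vi / total_var, 1.05))
  ST <- max(0, min(1 - Vc / total_var, 1.05))
  list(Si = Si, ST = ST, constant = FALSE)
}

#' Default sensitivity-parameter set for a community model
#'
#' Builds the standard varied-parameter list: every leak fraction phi
#' (range 0.01-0.5), every initial metabolite concentration (0-75
#' mg l^-1), the inoculum ratio of every strain (0.01-1, simplex
#' constrained), every strain's maximum glucose uptake rate (1-30
#' g h^-1) and every auxotrophic uptake V_max (1-120 mg h^-1), plus the
#' dummy parameter. With `extended = TRUE` the remaining kinetic ranges
#' (N0 0.01-1, yields 0.01-1, k_M,G 1-100 g, k_M,j 1-1000 mg) are
#' included as well.
#'
#' @param model A [community_model].
#' @param extended Include the full kinetic range set. Default `FALSE`
#'   (the figure-level dial set).
#' @return List of [gsa_parameter]s ending with the dummy.
#' @export
gsa_default_parameters <- function(model, extended = FALSE) {
  ps <- list()
  add <- function(...) ps[[length(ps) + 1L]] <<- gsa_parameter(...)
  for (s in model$strains) {
    for (m in names(s$productions)) {
      add(paste0("phi_", s$id, ".", m),
          paste0("strains.", s$id, ".productions.", m), 0.01, 0.5)
    }
  }
  for (m in metabolite_ids(model)) {
    add(paste0("x0_", m), paste0("init.supplements_0.", m), 0, 75)
  }
  for (s in strain_ids(model)) {
    add(paste0("r0_", s), paste0("init.ratios_0.", s), 0.01, 1,
        group = "ratio-simplex")
  }
  for (s in model$strains) {
    add(paste0("vmaxG_", s$id),
        paste0("strains.", s$id, ".glucose_uptake.v_max"), 1, 30)
    for (m in s$auxotrophies) {
      add(paste0("vmax_", s$id, ".", m),
          paste0("strains.", s$id, ".metabolite_uptake.", m, ".v_max"),
          1, 120)
    }
  }
  if (extended) {
    add("N0", "init.total_density_0", 0.01, 1)
    for (s in model$strains) {
      add(paste0("yieldG_", s$id),
          paste0("strains.", s$id, ".yield_glucose"), 0.01, 1)
      add(paste0("kmG_", s$id),
          paste0("strains.", s$id, ".glucose_uptake.k_m"), 1, 100)
      for (m in s$auxotrophies) {
        add(paste0("yield_", s$id, ".", m),
            paste0("strains.", s$id, ".yield_metabolite.", m), 0.01, 1)
        add(paste0("km_", s$id, ".", m),
            paste0("strains.", s$id, ".metabolite_uptake.", m, ".k_m"),
            1, 1000)
      }
    }
  }
  add("dummy", "dummy", 0, 1)
  ps
}

# Compile a GSA problem into fast row setters over the packed parameter
# vector and the initial state, avoiding per-row model rebuilding.
compile_gsa_problem <- function(model, init, config) {
  parms0 <- pack_parms(model)
  mids <- metabolite_ids(model)
  sids <- strain_ids(model)
  nm <- length(mids)
  ns <- length(sids)
  setters <- lapply(config$parameters, function(p) {
    if (p$path %in% c("dummy", "null")) return(list(type = "noop"))
    parts <- strsplit(p$path, ".", fixed = TRUE)[[1]]
    if (parts[1] == "init") {
      if (parts[2] == "total_density_0") return(list(type = "density"))
      if (parts[2] == "glucose_0") return(list(type = "glucose"))
      if (parts[2] == "ratios_0")
        return(list(type = "ratio", strain = match(parts[3], sids)))
      if (parts[2] == "supplements_0")
        return(list(type = "supplement", met = match(parts[3], mids)))
    }
    if (parts[1] == "strains") {
      sid <- parts[2]
      si <- match(sid, sids)
      if (parts[3] == "productions") {
        k <- match(parts[4], mids)
        delta <- model$metabolites[[k]]$delta
        return(list(type = "phi",
                    leak_pos = parms_index(model, sid, "leak", parts[4]),
                    sum_pos = parms_index(model, sid, "sum_phi"),
                    delta = delta,
                    phi0 = model$strains[[si]]$productions[[parts[4]]]))
      }
      if (parts[3] == "glucose_uptake") {
        f <- if (parts[4] == "v_max") "vmax_glucose" else "km_glucose"
        return(list(type = "parms", pos = parms_index(model, sid, f)))
      }
      if (parts[3] == "metabolite_uptake") {
        f <- if (parts[5] == "v_max") "vmax_metabolite" else "km_metabolite"
        return(list(type = "parms",
                    pos = parms_index(model, sid, f, parts[4])))
      }
      if (parts[3] == "yield_glucose")
        return(list(type = "parms",
                    pos = parms_index(model, sid, "yield_glucose")))
      if (parts[3] == "yield_metabolite")
        return(list(type = "parms",
                    pos = parms_index(model, sid, "yield_metabolite",
                                      parts[4])))
      if (parts[3] == "death_rate")
        return(list(type = "parms",
                    pos = parms_index(model, sid, "death_rate")))
    }
    stop("GSA parameter path not supported for the compiled backend: '",
         p$path, "'", call. = FALSE)
  })
  r0 <- stats::setNames(numeric(ns), sids)
  r0[names(init$ratios_0)] <- init$ratios_0
  x0 <- stats::setNames(numeric(nm), mids)
  x0[names(init$supplements_0)] <- init$supplements_0
  list(parms0 = parms0, nm = nm, ns = ns,
       has_path = !is.null(model$pathway),
       toxicity = isTRUE(model$toxicity_enabled),
       sids = sids, mids = mids,
       G0 = init$glucose_0, N0 = init$total_density_0,
       r0 = unname(r0), x0 = unname(x0),
       setters = setters)
}

# Apply one sampled row; returns list(parms, y0, G0).
apply_gsa_row <- function(prob, row) {
  parms <- prob$parms0
  G0 <- prob$G0
  N0 <- prob$N0
  r <- prob$r0
  x0 <- prob$x0
  for (j in seq_along(prob$setters)) {
    st <- prob$setters[[j]]
    v <- row[j]
    switch(st$type,
      noop = NULL,
      density = N0 <- v,
      glucose = G0 <- v,
      ratio = r[st$strain] <- v,
      supplement = x0[st$met] <- v,
      parms = parms[st$pos] <- v,
      phi = {
        parms[st$leak_pos] <- v * st$delta
        parms[st$sum_pos] <- parms[st$sum_pos] - st$phi0 + v
      })
  }
  rn <- r / sum(r)
  y0 <- c(G0, x0, N0 * rn)
  if (prob$has_path) y0 <- c(y0, 0, 0)
  list(parms = parms, y0 = y0, G0 = G0, ratios = rn)
}

#' Run a full eFAST sensitivity analysis
#'
#' For every resampling and every focus parameter, samples a search
#' curve, runs the batch simulator for each sampled parameter vector,
#' extracts the requested output metrics and Fourier-decomposes each
#' metric trace into first-order and total-order indices. Indices are
#' aggregated as mean +/- s.d. over resamplings and each parameter is
#' compared against the dummy parameter with a Welch two-sample t-test
#' at the Bonferroni-corrected threshold `alpha / n_k`. A parameter is
#' flagged significant when either its first-order or its total-order
#' index differs significantly from the dummy's. Fully seeded and
#' reproducible; failed simulations are mean-imputed and counted, and
#' the run aborts if more than `max_fail_frac` of rows fail.
#'
#' @param model A [community_model].
#' @param init An [initial_condition].
#' @param config A [gsa_config].
#' @param metrics Character vector of metric names as produced by
#'   [flatten_metrics()] naming (e.g. `"final_total_population"`,
#'   `"batch_time"`, `"max_growth_rate.y1"`, `"productivity"`).
#' @param sim_config A [simulation_config]. A coarser default grid
#'   (dt = 0.5 h, tolerances 1e-6/1e-8) keeps ensemble runs tractable;
#'   metric refinement error is bounded by the refinement-stability
#'   property of the simulator.
#' @param t_test `"welch"` (default) or `"pooled"`.
#' @param max_fail_frac Abort threshold on the failed-row fraction.
#'   Default 0.01.
#' @param progress Print per-resample progress. Default `FALSE`.
#' @return An object of class `sensitivity_result`: a data.frame
#'   `table` with one row per (parameter, metric) holding
#'   `Si_mean`, `Si_sd`, `ST_mean`, `ST_sd`, `p_Si`, `p_ST`, `p_value`
#'   (the smaller), and `significant`, plus fields `config`,
#'   `n_failed`, `n_runs` and the raw per-resample index arrays.
#' @export
efast_run <- function(model, init, config,
                      metrics = c("final_total_population", "batch_time"),
                      sim_config = simulation_config(dt = 0.5, rtol = 1e-6,
                                                     atol = 1e-8),
                      t_test = c("welch", "pooled"),
                      max_fail_frac = 0.01, progress = FALSE) {
  stopifnot(inherits(config, "gsa_config"))
  t_test <- match.arg(t_test)
  prob <- compile_gsa_problem(model, init, config)
  np <- length(config$parameters)
  nms <- vapply(config$parameters, `[[`, character(1), "name")
  dummy_idx <- which(vapply(config$parameters, `[[`, character(1),
                            "path") == "dummy")
  nr <- config$resamplings
  ns_curve <- config$samples_per_search
  times <- seq(0, sim_config$t_end, by = sim_config$dt)
  nmet <- length(metrics)
  Si <- array(NA_real_, c(np, nmet, nr), dimnames = list(nms, metrics, NULL))
  ST <- array(NA_real_, c(np, nmet, nr), dimnames = list(nms, metrics, NULL))
  n_failed <- 0L
  n_runs <- 0L
  for (r in seq_len(nr)) {
    for (k in seq_len(np)) {
      X <- efast_sample(config, k, r)
      out <- matrix(NA_real_, ns_curve, nmet)
      for (i in seq_len(ns_curve)) {
        rowp <- apply_gsa_row(prob, X[i, ])
        n_runs <- n_runs + 1L
        tr <- try(integrate_packed(rowp$parms, rowp$y0, times, sim_config,
                                   use_compiled = TRUE), silent = TRUE)
        if (inherits(tr, "try-error") || nrow(tr) < length(times) ||
            any(!is.finite(tr[nrow(tr), ]))) {
          n_failed <- n_failed + 1L
          next
        }
        ms <- metrics_from_matrix(tr, rowp$parms, prob$nm, prob$ns,
                                  G0 = rowp$G0,
                                  inoculum_ratios = rowp$ratios,
                                  eps_G = sim_config$eps_G,
                                  has_path = prob$has_path,
                                  toxicity = prob$toxicity,
                                  strain_names = prob$sids,
                                  met_names = prob$mids)
        fv <- flatten_metrics(ms)
        out[i, ] <- fv[metrics]
      }
      if (n_failed / n_runs > max_fail_frac && n_runs > 100L) {
        stop("eFAST aborted: ", n_failed, " of ", n_runs,
             " simulations failed (> ", 100 * max_fail_frac, "%)",
             call. = FALSE)
      }
      for (m in seq_len(nmet)) {
        v <- out[, m]
        bad <- !is.finite(v)
        if (all(bad)) next
        if (any(bad)) v[bad] <- mean(v[!bad])
        idx <- efast_indices(v, config, k)
        Si[k, m, r] <- idx$Si
        ST[k, m, r] <- idx$ST
      }
    }
    if (progress) message("resample ", r, "/", nr, " done (",
                          n_failed, " failed rows)")
  }
  if (n_failed / n_runs > max_fail_frac) {
    stop("eFAST aborted: ", n_failed, " of ", n_runs,
         " simulations failed (> ", 100 * max_fail_frac, "%)",
         call. = FALSE)
  }
  n_k <- np # every varied parameter counts toward the correction
  thr <- config$alpha / n_k
  rows <- list()
  for (m in seq_len(nmet)) {
    for (k in seq_len(np)) {
      si <- Si[k, m, ]
      st_ <- ST[k, m, ]
      dsi <- Si[dummy_idx, m, ]
      dst <- ST[dummy_idx, m, ]
      p_si <- p_st <- NA_real_
      if (k != dummy_idx) {
        p_si <- safe_t_test(si, dsi, t_test)
        p_st <- safe_t_test(st_, dst, t_test)
      }
      p <- suppressWarnings(min(p_si, p_st, na.rm = TRUE))
      if (!is.finite(p)) p <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nms[k], metric = metrics[m],
        Si_mean = mean(si, na.rm = TRUE), Si_sd = stats::sd(si),
        ST_mean = mean(st_, na.rm = TRUE), ST_sd = stats::sd(st_),
        p_Si = p_si, p_ST = p_st, p_value = p,
        significant = !is.na(p) && p < thr,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(table = do.call(rbind, rows), config = config, metrics = metrics,
         Si = Si, ST = ST, threshold = thr, n_failed = n_failed,
         n_runs = n_runs, dummy = nms[dummy_idx]),
    class = "sensitivity_result")
}

safe_t_test <- function(a, b, variant) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  out <- try(stats::t.test(a, b, var.equal = (variant == "pooled")),
             silent = TRUE)
  if (inherits(out, "try-error")) NA_real_ else out$p.value
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> ", length(unique(x$table$parameter)),
      " parameters x ", length(x$metrics), " metrics, ",
      dim(x$Si)[3], " resamplings (", x$n_failed, "/", x$n_runs,
      " failed runs)\n", sep = "")
  cat("  significance threshold: ", signif(x$threshold, 3),
      " (Bonferroni-corrected)\n", sep = "")
  tab <- x$table
  tab <- tab[order(tab$metric, -tab$ST_mean), ]
  print(utils::head(tab, 12), row.names = FALSE, digits = 3)
  invisible(x)
}
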