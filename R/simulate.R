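#' Batch simulation settings
#'
#' @param t_end End of the batch window (h). Default 72.
#' @param dt Output grid step for dense output (h). Default 0.25.
#' @param rtol,atol Relative and absolute solver tolerances. Defaults
#'   1e-8 and 1e-10; the hard minimum in the growth law is integrated
#'   with a stiff solver at tight tolerances rather than smoothed.
#' @param eps_G Glucose-exhaustion fraction: the batch is considered
#'   complete when `G(t) <= eps_G * G0`. Default 1e-3.
#' @param method deSolve integration method. Default `"lsoda"`, which
#'   switches automatically between stiff (BDF) and non-stiff modes.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(t_end = 72, dt = 0.25, rtol = 1e-8,
                              atol = 1e-10, eps_G = 1e-3,
                              method = "lsoda") {
  stopifnot(is.numeric(t_end), t_end > 0, is.numeric(dt), dt > 0,
            is.numeric(eps_G), eps_G > 0, eps_G < 1)
  structure(list(t_end = as.numeric(t_end), dt = as.numeric(dt),
                 rtol = rtol, atol = atol, eps_G = eps_G, method = method),
            class = "simulation_config")
}

# Integrate a packed problem. Internal fast path shared by simulate_batch
# and the sensitivity machinery.
integrate_packed <- function(parms, y0, times, config, use_compiled = TRUE,
                             model = NULL, smooth_min_k = NULL) {
  if (use_compiled && is.null(smooth_min_k)) {
    deSolve::ode(y = y0, times = times, func = "crossfeed_derivs",
                 parms = parms, dllname = "crossfeed",
                 initfunc = "crossfeed_initmod",
                 method = config$method, rtol = config$rtol,
                 atol = config$atol)
  } else {
    stopifnot(!is.null(model))
    deSolve::ode(y = y0, times = times,
                 func = function(t, state, p) {
                   list(system_rhs(state, model, smooth_min_k = smooth_min_k))
                 },
                 parms = NULL, method = config$method, rtol = config$rtol,
                 atol = config$atol)
  }
}

#' Simulate a batch co-culture
#'
#' Integrates the cross-feeding ODE system over the batch window with a
#' stiff-capable solver and returns dense trajectories on the output
#' grid. Identical inputs give identical outputs on one platform.
#'
#' @param model A validated [community_model].
#' @param init An [initial_condition].
#' @param config A [simulation_config].
#' @param use_compiled Use the compiled right-hand side (default). The
#'   R reference implementation is used when `FALSE` or when
#'   `smooth_min_k` is given.
#' @param smooth_min_k Optional soft-min sharpness; see [system_rhs()].
#' @return An object of class `simulation_result` with elements
#'   `trajectory` (data.frame: time plus one column per state
#'   component), `model`, `init`, `config` and `diagnostics`.
#' @export
simulate_batch <- function(model, init, config = simulation_config(),
                           use_compiled = TRUE, smooth_min_k = NULL) {
  stopifnot(inherits(model, "community_model"),
            inherits(init, "initial_condition"),
            inherits(config, "simulation_config"))
  y0 <- build_state0(model, init)
  times <- seq(0, config$t_end, by = config$dt)
  if (times[length(times)] < config$t_end) times <- c(times, config$t_end)
  parms <- pack_parms(model)
  out <- try(integrate_packed(parms, y0, times, config,
                              use_compiled = use_compiled, model = model,
                              smooth_min_k = smooth_min_k), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    last <- if (inherits(out, "try-error")) NULL else out[nrow(out), ]
    stop("batch integration failed",
         if (!is.null(last)) paste0(" at t = ", signif(last[[1]], 6),
                                    " h (last valid state retained)"),
         call. = FALSE)
  }
  diag <- attributes(out)[c("istate", "rstate")]
  traj <- as.data.frame(unclass(out))
  names(traj) <- c("time", state_names(model))
  structure(list(trajectory = traj, model = model, init = init,
                 config = config, y0 = y0, parms = parms,
                 diagnostics = diag),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  tr <- x$trajectory
  cat("<simulation_result> ", nrow(tr), " time points over [0, ",
      max(tr$time), "] h, ", ncol(tr) - 1L, " state components\n", sep = "")
  ycols <- grep("^y\\.", names(tr))
  cat("  final total population: ",
      signif(sum(tr[nrow(tr), ycols]), 5), " OD700\n", sep = "")
  invisible(x)
}

# Vectorised per-strain flux series over a trajectory matrix; reads
# kinetics straight from the packed parameter vector so the sensitivity
# machinery can reuse it without rebuilding model objects.
flux_series <- function(traj_mat, parms, nm, ns, toxicity = FALSE) {
  G <- pmax(traj_mat[, 2L], 0)
  X <- pmax(traj_mat[, 2L + seq_len(nm), drop = FALSE], 0)
  Y <- pmax(traj_mat[, 2L + nm + seq_len(ns), drop = FALSE], 0)
  base0 <- 8L + 2L * nm
  stride <- strain_stride(nm)
  toxf <- 1
  if (toxicity) {
    hill <- parms[5]
    toxf <- rep(1, length(G))
    for (k in seq_len(nm)) {
      thr <- parms[8L + nm + k]
      if (thr > 0) toxf <- toxf / (1 + (X[, k] / thr)^hill)
    }
  }
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    b <- base0 + (i - 1L) * stride
    jg <- parms[b + 1L] * G / (parms[b + 2L] + G)
    grow <- parms[b + 3L] * (1 - parms[b + 5L]) * jg
    upt <- matrix(0, nrow(traj_mat), nm)
    prodn <- matrix(0, nrow(traj_mat), nm)
    for (k in seq_len(nm)) {
      leak <- parms[b + 7L + k]
      vm <- parms[b + 7L + nm + k]
      km <- parms[b + 7L + 2L * nm + k]
      gam <- parms[b + 7L + 3L * nm + k]
      if (leak > 0) prodn[, k] <- leak * jg * Y[, i]
      if (km > 0) {
        jm <- vm * X[, k] / (km + X[, k])
        upt[, k] <- jm * Y[, i]
        grow <- pmin(grow, gam * jm)
      }
    }
    out[[i]] <- list(growth = grow * toxf, uptake = upt, production = prodn,
                     glucose_uptake = jg * Y[, i])
  }
  out
}

# First time G(t) drops to eps_G * G0, linearly interpolated between
# grid points; t_end when the threshold is never reached.
batch_time_from <- function(time, G, G0, eps_G) {
  thr <- eps_G * G0
  below <- which(G <= thr)
  if (!length(below)) return(time[length(time)])
  k <- below[1L]
  if (k == 1L) return(time[1L])
  t0 <- time[k - 1L]; t1 <- time[k]
  g0 <- G[k - 1L]; g1 <- G[k]
  if (g0 == g1) return(t1)
  t0 + (g0 - thr) / (g0 - g1) * (t1 - t0)
}

metrics_from_matrix <- function(traj_mat, parms, nm, ns, G0,
                                inoculum_ratios, eps_G, has_path, toxicity,
                                strain_names, met_names) {
  time <- traj_mat[, 1L]
  G <- traj_mat[, 2L]
  Y <- traj_mat[, 2L + nm + seq_len(ns), drop = FALSE]
  n <- nrow(traj_mat)
  yfin <- pmax(Y[n, ], 0)
  tot <- sum(yfin)
  degenerate <- tot <= 1e-9
  ratios <- if (degenerate) inoculum_ratios else yfin / tot
  names(ratios) <- strain_names
  fl <- flux_series(traj_mat, parms, nm, ns, toxicity = toxicity)
  maxg <- vapply(fl, function(f) max(f$growth), numeric(1))
  names(maxg) <- strain_names
  maxu <- do.call(rbind, lapply(fl, function(f) apply(f$uptake, 2, max)))
  maxp <- do.call(rbind, lapply(fl, function(f) apply(f$production, 2, max)))
  dimnames(maxu) <- dimnames(maxp) <- list(strain_names, met_names)
  ms <- list(final_total_population = tot,
             batch_time = batch_time_from(time, G, G0, eps_G),
             final_ratios = ratios,
             degenerate_composition = degenerate,
             max_growth_rate = maxg,
             max_uptake_rate = maxu,
             max_production_rate = maxp)
  if (has_path) {
    prod_fin <- traj_mat[n, 2L + nm + ns + 2L]
    t_end <- time[n]
    ms$productivity <- prod_fin / t_end
    consumed <- G0 - G[n]
    ms$yield_ratio <- if (consumed > 0) prod_fin / consumed else 0
  } else {
    ms$productivity <- NULL
    ms$yield_ratio <- NULL
  }
  structure(ms, class = "metric_set")
}

#' Performance metrics of a batch run
#'
#' Extracts the standard batch performance metrics from a dense
#' trajectory: final total population, batch culture time (glucose
#' exhaustion crossing, linearly interpolated, capped at the window
#' end), final composition, per-strain maximum growth rate, maximum
#' volumetric uptake and production rate per (strain, metabolite), and
#' -- for pathway runs -- productivity (product per hour) and yield
#' ratio (product per g glucose consumed). Maxima are taken over the
#' dense output grid. If the total population is ~0 throughout, the
#' final composition falls back to the inoculum ratios and
#' `degenerate_composition` is set.
#'
#' @param result A [simulate_batch()] result.
#' @return An object of class `metric_set`.
#' @export
compute_metrics <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  model <- result$model
  nm <- length(model$metabolites)
  ns <- length(model$strains)
  traj_mat <- as.matrix(result$trajectory)
  r0 <- stats::setNames(numeric(ns), strain_ids(model))
  r0[names(result$init$ratios_0)] <- result$init$ratios_0
  metrics_from_matrix(traj_mat, result$parms, nm, ns,
                      G0 = result$init$glucose_0,
                      inoculum_ratios = unname(r0),
                      eps_G = result$config$eps_G,
                      has_path = !is.null(model$pathway),
                      toxicity = isTRUE(model$toxicity_enabled),
                      strain_names = strain_ids(model),
                      met_names = metabolite_ids(model))
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n",
      "  final total population: ", signif(x$final_total_population, 5),
      " OD700\n",
      "  batch time: ", signif(x$batch_time, 5), " h\n",
      "  final ratios: ",
      paste(sprintf("%s=%.4g", names(x$final_ratios), x$final_ratios),
            collapse = ", "),
      if (isTRUE(x$degenerate_composition)) "  (degenerate: inoculum ratios)",
      "\n  max growth rates (1/h): ",
      paste(sprintf("%s=%.4g", names(x$max_growth_rate), x$max_growth_rate),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$productivity)) {
    cat("  productivity: ", signif(x$productivity, 5),
        "  yield ratio: ", signif(x$yield_ratio, 5), "\n", sep = "")
  }
  invisible(x)
}

#' Classify co-culture growth strength
#'
#' Growth-strength classes for the maximum optical density reached by a
#' cross-feeding culture: strong (OD700 >= 0.5), medium
#' (0.3 <= OD700 < 0.5), weak (OD700 < 0.3).
#'
#' @param max_od Maximum OD700 (>= 0), vectorised.
#' @return Character vector in `{"strong", "medium", "weak"}`.
#' @export
classify_growth <- function(max_od) {
  if (any(max_od < 0)) stop("max_od must be >= 0", call. = FALSE)
  ifelse(max_od >= 0.5, "strong", ifelse(max_od >= 0.3, "medium", "weak"))
}

# Flatten a metric_set to a named numeric vector (one row of a metrics
# table); names are stable across runs of the same model.
flatten_metrics <- function(ms) {
  v <- c(final_total_population = ms$final_total_population,
         batch_time = ms$batch_time)
  v <- c(v, stats::setNames(as.numeric(ms$final_ratios),
                            paste0("final_ratio.", names(ms$final_ratios))))
  v <- c(v, stats::setNames(as.numeric(ms$max_growth_rate),
                            paste0("max_growth_rate.",
                                   names(ms$max_growth_rate))))
  for (s in rownames(ms$max_uptake_rate)) {
    for (m in colnames(ms$max_uptake_rate)) {
      if (ms$max_uptake_rate[s, m] > 0 || ms$max_production_rate[s, m] > 0) {
        v[paste0("max_uptake_rate.", s, ".", m)] <- ms$max_uptake_rate[s, m]
        v[paste0("max_production_rate.", s, ".", m)] <-
          ms$max_production_rate[s, m]
      }
    }
  }
  if (!is.null(ms$productivity)) {
    v["productivity"] <- ms$productivity
    v["yield_ratio"] <- ms$yield_ratio
  }
  v
}
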