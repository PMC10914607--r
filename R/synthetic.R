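#' Generate a synthetic plate-reader dataset
#'
#' Emulates a microplate growth assay over a simulated community: the
#' observed total OD700 is the summed strain biomass corrupted by
#' multiplicative Gaussian noise (plate-reader OD error grows with
#' signal), and each fluorescence channel reads
#' `(gain_c * y_c + background_c) * (1 + eps)` for its tagged strain.
#' Ground-truth trajectories are retained for testing and
#' parameter-recovery studies.
#'
#' @param model A [community_model] whose strains carry distinct
#'   `fluor_channel` tags.
#' @param init An [initial_condition].
#' @param noise_sd Multiplicative noise s.d. per reading (>= 0).
#'   Default 0.05.
#' @param gains,backgrounds Named vectors (by channel) of fluorescence
#'   gain and background; defaults gain 1, background 0 for every
#'   channel present.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param config A [simulation_config].
#' @return An object of class `platereader_dataset` with `time`,
#'   `od_total` (observed), `channels` (matrix of observed fluorescence,
#'   one column per channel), `gains`, `backgrounds`, `noise_sd`,
#'   `seed`, `truth` (noise-free per-strain OD trajectories) and
#'   `channel_map` (channel -> strain id).
#' @export
generate_platereader <- function(model, init, noise_sd = 0.05,
                                 gains = NULL, backgrounds = NULL,
                                 seed = 1L,
                                 config = simulation_config()) {
  stopifnot(noise_sd >= 0)
  channels <- vapply(model$strains, function(s)
    if (is.null(s$fluor_channel)) NA_character_ else s$fluor_channel,
    character(1))
  if (any(is.na(channels)) || anyDuplicated(channels)) {
    stop("every strain needs a distinct fluor_channel tag", call. = FALSE)
  }
  sids <- strain_ids(model)
  if (is.null(gains)) gains <- stats::setNames(rep(1, length(channels)),
                                               channels)
  if (is.null(backgrounds)) backgrounds <-
      stats::setNames(rep(0, length(channels)), channels)
  res <- simulate_batch(model, init, config)
  tr <- res$trajectory
  Y <- as.matrix(tr[, paste0("y.", sids), drop = FALSE])
  colnames(Y) <- sids
  n <- nrow(Y)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  od_total <- rowSums(Y) * (1 + stats::rnorm(n, 0, noise_sd))
  F <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
  for (j in seq_along(channels)) {
    ch <- channels[j]
    signal <- gains[[ch]] * Y[, j] + backgrounds[[ch]]
    F[, j] <- signal * (1 + stats::rnorm(n, 0, noise_sd))
  }
  od_total <- pmax(od_total, 0)
  F <- pmax(F, 0)
  structure(
    list(time = tr$time, od_total = od_total, channels = F,
         gains = gains, backgrounds = backgrounds, noise_sd = noise_sd,
         seed = as.integer(seed), truth = Y,
         channel_map = stats::setNames(sids, channels),
         model = model, init = init, config = config),
    class = "platereader_dataset")
}

#' @export
print.platereader_dataset <- function(x, ...) {
  cat("<platereader_dataset> ", length(x$time), " readings over [0, ",
      max(x$time), "] h, channels: ",
      paste(colnames(x$channels), collapse = ", "),
      ", noise sd = ", x$noise_sd, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Estimate per-strain OD trajectories from fluorescence channels
#'
#' Linear unmixing of channel fluorescence into subpopulation optical
#' densities: each channel is background-subtracted and divided by its
#' gain, then the estimates are rescaled at every time point so their
#' sum matches the observed total OD. Outputs are clipped at 0.
#'
#' @param dataset A [generate_platereader()] dataset.
#' @param gains,backgrounds Channel calibration; defaults to the values
#'   stored in the dataset (in practice calibrated from monoculture
#'   wells). Supply explicitly when the dataset's are unknown.
#' @return Matrix of estimated per-strain OD700 (one column per strain,
#'   named by strain id).
#' @export
estimate_subpopulations <- function(dataset, gains = dataset$gains,
                                    backgrounds = dataset$backgrounds) {
  stopifnot(inherits(dataset, "platereader_dataset"))
  if (is.null(gains) || is.null(backgrounds)) {
    stop("channel gains and backgrounds are required (calibrate from ",
         "monoculture wells or supply them)", call. = FALSE)
  }
  ch <- colnames(dataset$channels)
  est <- sapply(ch, function(c.)
    pmax((dataset$channels[, c.] - backgrounds[[c.]]) / gains[[c.]], 0))
  est <- matrix(est, nrow = length(dataset$time),
                dimnames = list(NULL, unname(dataset$channel_map[ch])))
  tot <- rowSums(est)
  scale <- ifelse(tot > 0, dataset$od_total / tot, 0)
  est * scale
}

#' Fit growth parameters to observed total OD
#'
#' Least-squares fit of the simulated total OD trajectory to an
#' observed plate-reader series by Levenberg-Marquardt minimisation
#' with seeded multi-starts (the hard minimum in the growth law can
#' create local optima). Free parameters are addressed by dotted paths
#' restricted to glucose yield/kinetics, death rate and leak fractions.
#'
#' @param dataset A [platereader_dataset] (only `time` and `od_total`
#'   are used).
#' @param model,init Template model and initial condition; fitted
#'   parameters are written into copies.
#' @param free Named list mapping parameter path -> c(lower, upper)
#'   box. Starting points are drawn uniformly inside the box.
#' @param n_starts Number of multi-starts. Default 5.
#' @param seed Seed for the start draws. Default 1.
#' @param config Simulation configuration used during fitting.
#' @return List with `estimates` (named by path), `residual_norm`,
#'   `converged`, `starts` tried and the fitted `model`/`init`.
#' @export
fit_growth_parameters <- function(dataset, model, init, free,
                                  n_starts = 5L, seed = 1L,
                                  config = simulation_config(dt = 0.5,
                                                             rtol = 1e-6,
                                                             atol = 1e-8)) {
  stopifnot(is.list(free), length(free) >= 1L, !is.null(names(free)))
  allowed <- valid_param_paths(model, init)
  bad <- setdiff(names(free), allowed)
  if (length(bad)) {
    stop("free parameters not addressable in this model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  obs_t <- dataset$time
  obs <- dataset$od_total
  keep <- is.finite(obs)
  if (!any(keep)) stop("dataset has no finite OD readings", call. = FALSE)
  obs_t <- obs_t[keep]
  obs <- obs[keep]
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  paths <- names(free)
  sim_cfg <- config
  sim_cfg$t_end <- max(obs_t)
  residuals_fn <- function(theta) {
    mi <- list(model = model, init = init)
    for (j in seq_along(paths)) {
      mi <- set_param(mi$model, mi$init, paths[j], theta[j])
    }
    res <- try(simulate_batch(mi$model, mi$init, sim_cfg), silent = TRUE)
    if (inherits(res, "try-error")) return(rep(1e6, length(obs)))
    tr <- res$trajectory
    ycols <- grep("^y\\.", names(tr))
    tot <- rowSums(tr[, ycols, drop = FALSE])
    pred <- stats::approx(tr$time, tot, xout = obs_t, rule = 2)$y
    pred - obs
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  starts <- matrix(stats::runif(n_starts * length(free), lower, upper),
                   nrow = n_starts, byrow = TRUE,
                   dimnames = list(NULL, paths))
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[s, ], lower = lower, upper = upper, fn = residuals_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) {
      best <- list(fit = fit, rn = rn, start = starts[s, ])
    }
  }
  if (is.null(best)) {
    stop("all multi-starts failed to converge", call. = FALSE)
  }
  est <- stats::setNames(as.numeric(best$fit$par), paths)
  converged <- best$fit$info %in% 1:4
  mi <- list(model = model, init = init)
  for (j in seq_along(paths)) {
    mi <- set_param(mi$model, mi$init, paths[j], est[j])
  }
  list(estimates = est, residual_norm = best$rn, converged = converged,
       info = best$fit$info, starts = starts, model = mi$model,
       init = mi$init)
}
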