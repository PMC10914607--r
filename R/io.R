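CONFIG_SCHEMA <- "crossfeed/community-v1"

# ---- community/init <-> plain-list schema -----------------------------------

to_config_list <- function(model, init) {
  list(
    schema = CONFIG_SCHEMA,
    metabolites = lapply(model$metabolites, function(m) {
      out <- list(id = m$id, delta = m$delta)
      if (!is.null(m$toxicity_threshold))
        out$toxicity_threshold <- m$toxicity_threshold
      out
    }),
    strains = lapply(model$strains, function(s) {
      out <- list(
        id = s$id,
        auxotrophies = as.list(s$auxotrophies),
        productions = as.list(s$productions),
        glucose_uptake = list(v_max = s$glucose_uptake$v_max,
                              k_m = s$glucose_uptake$k_m),
        metabolite_uptake = lapply(s$metabolite_uptake, function(k)
          list(v_max = k$v_max, k_m = k$k_m)),
        yield_glucose = s$yield_glucose,
        yield_metabolite = as.list(s$yield_metabolite),
        death_rate = s$death_rate,
        pathway_stage = s$pathway_stage)
      if (!is.null(s$fluor_channel)) out$fluor_channel <- s$fluor_channel
      out
    }),
    pathway = if (is.null(model$pathway)) NULL else
      unclass(model$pathway),
    toxicity_enabled = model$toxicity_enabled,
    toxicity_hill = model$toxicity_hill,
    init = list(glucose_0 = init$glucose_0,
                total_density_0 = init$total_density_0,
                ratios_0 = as.list(init$ratios_0),
                supplements_0 = as.list(init$supplements_0))
  )
}

named_numeric <- function(lst) {
  if (is.null(lst) || !length(lst)) return(numeric())
  stats::setNames(vapply(lst, as.numeric, numeric(1)), names(lst))
}

from_config_list <- function(cfg) {
  if (is.null(cfg$schema) || !identical(cfg$schema, CONFIG_SCHEMA)) {
    stop("config schema must be '", CONFIG_SCHEMA, "' (got '",
         if (is.null(cfg$schema)) "<missing>" else cfg$schema, "')",
         call. = FALSE)
  }
  mets <- lapply(cfg$metabolites, function(m)
    metabolite_spec(m$id, delta = m$delta %||% 1,
                    toxicity_threshold = m$toxicity_threshold))
  strains <- lapply(cfg$strains, function(s)
    strain_spec(
      id = s$id,
      auxotrophies = unlist(s$auxotrophies) %||% character(),
      productions = named_numeric(s$productions),
      glucose_uptake = uptake_kinetics(s$glucose_uptake$v_max,
                                       s$glucose_uptake$k_m),
      metabolite_uptake = stats::setNames(
        lapply(s$metabolite_uptake, function(k)
          uptake_kinetics(k$v_max, k$k_m)),
        names(s$metabolite_uptake)),
      yield_glucose = s$yield_glucose,
      yield_metabolite = named_numeric(s$yield_metabolite),
      death_rate = s$death_rate %||% 0.01,
      pathway_stage = s$pathway_stage %||% "none",
      fluor_channel = s$fluor_channel))
  pathway <- if (is.null(cfg$pathway)) NULL else
    pathway_spec(cfg$pathway$phi_upstream, cfg$pathway$conversion_vmax,
                 cfg$pathway$conversion_km,
                 intermediate_id = cfg$pathway$intermediate_id %||%
                   "p-coumaric",
                 product_id = cfg$pathway$product_id %||% "resveratrol")
  model <- community_model(strains, metabolites = mets, pathway = pathway,
                           toxicity_enabled = isTRUE(cfg$toxicity_enabled),
                           toxicity_hill = cfg$toxicity_hill %||% 2)
  init <- initial_condition(
    glucose_0 = cfg$init$glucose_0 %||% 20,
    total_density_0 = cfg$init$total_density_0,
    ratios_0 = named_numeric(cfg$init$ratios_0),
    supplements_0 = named_numeric(cfg$init$supplements_0))
  list(model = model, init = init)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a community configuration file
#'
#' Community models and initial conditions serialise to a versioned
#' YAML/JSON schema (`crossfeed/community-v1`) with keys
#' `metabolites[]`, `strains[]`, `pathway`, `init`. A config file may
#' instead name a scenario preset (`scenario:` plus dial keys), which
#' is expanded through [build_scenario()].
#'
#' @param path File path; format follows the extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `read_community_config()`: list with `model` and `init`.
#' @export
read_community_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$scenario)) {
    args <- cfg[setdiff(names(cfg), "scenario")]
    if (!is.null(args$supplements)) args$supplements <-
        named_numeric(args$supplements)
    return(do.call(build_scenario, c(list(name = cfg$scenario), args)))
  }
  from_config_list(cfg)
}

#' @rdname read_community_config
#' @param model A [community_model].
#' @param init An [initial_condition].
#' @export
write_community_config <- function(model, init, path) {
  cfg <- to_config_list(model, init)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

# ---- tabular outputs --------------------------------------------------------

#' Write a trajectory as tidy CSV
#'
#' Long format with columns `time`, `component`, `value`; numeric
#' values use full double-precision round-trip formatting.
#'
#' @param result A [simulate_batch()] result.
#' @param path Output CSV path.
#' @export
write_trajectories_csv <- function(result, path) {
  tr <- result$trajectory
  comp <- setdiff(names(tr), "time")
  long <- data.frame(
    time = rep(tr$time, times = length(comp)),
    component = rep(comp, each = nrow(tr)),
    value = unlist(tr[comp], use.names = FALSE))
  write_full_csv(long, path)
}

#' @rdname write_trajectories_csv
#' @return `read_trajectories_csv()`: wide data.frame, one column per
#'   component.
#' @export
read_trajectories_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::reshape(long, idvar = "time", timevar = "component",
                 direction = "wide") -> wide
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

write_full_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a one-row-per-run metrics table
#'
#' @param metrics A `metric_set` (or list of them) from
#'   [compute_metrics()], or an already-flattened data.frame from
#'   [sweep_metrics()].
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- if (inherits(metrics, "metric_set")) {
    as.data.frame(t(flatten_metrics(metrics)))
  } else if (is.data.frame(metrics)) {
    metrics
  } else {
    as.data.frame(do.call(rbind, lapply(metrics, flatten_metrics)))
  }
  write_full_csv(df, path)
}

#' Write a sensitivity table with its provenance sidecar
#'
#' The CSV holds one row per (parameter, metric) with index means,
#' standard deviations, p-values and significance flags; the JSON
#' sidecar records the analysis configuration and seed.
#'
#' @param sens A [efast_run()] result.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_sensitivity_csv <- function(sens, path) {
  stopifnot(inherits(sens, "sensitivity_result"))
  write_full_csv(sens$table, path)
  sidecar <- list(
    schema = "crossfeed/sensitivity-v1",
    samples_per_search = sens$config$samples_per_search,
    resamplings = sens$config$resamplings,
    harmonics = sens$config$harmonics,
    alpha = sens$config$alpha,
    seed = sens$config$seed,
    threshold = sens$threshold,
    metrics = sens$metrics,
    n_failed = sens$n_failed,
    n_runs = sens$n_runs,
    parameters = lapply(sens$config$parameters, function(p)
      list(name = p$name, path = p$path, lower = p$lower, upper = p$upper,
           group = p$group)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline output directory carries exactly one `manifest.json`
#' recording the command, configuration hash, seed, package version and
#' output paths, so a run can be reproduced from its outputs alone.
#'
#' @param dir Output directory.
#' @param command Command name.
#' @param config_path Path of the configuration file used (hashed into
#'   the manifest), or `NULL`.
#' @param seed Seed used, or `NULL`.
#' @param outputs Character vector of output file names.
#' @export
write_manifest <- function(dir, command, config_path = NULL, seed = NULL,
                           outputs = character()) {
  hash <- if (!is.null(config_path) && file.exists(config_path)) {
    bytes <- utf8ToInt(paste(readLines(config_path, warn = FALSE),
                             collapse = "\n"))
    sum(bytes * seq_along(bytes)) %% 2147483647
  } else NULL
  manifest <- list(
    schema = "crossfeed/manifest-v1",
    command = command,
    config_hash = hash,
    seed = seed,
    tool_version = as.character(utils::packageVersion("crossfeed")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, "manifest.json"))
}

#' Serialise a plate-reader dataset to CSV plus JSON sidecar
#'
#' Long format (`time`, `well`, `channel`, `value`): the OD channel is
#' `"OD700"`, fluorescence channels use their tag names. The sidecar
#' records gains, backgrounds, noise level and seed.
#'
#' @param dataset A [generate_platereader()] dataset.
#' @param path Output CSV path.
#' @export
write_platereader_csv <- function(dataset, path) {
  ch <- colnames(dataset$channels)
  long <- rbind(
    data.frame(time = dataset$time, well = "A1", channel = "OD700",
               value = dataset$od_total),
    do.call(rbind, lapply(ch, function(c.)
      data.frame(time = dataset$time, well = "A1", channel = c.,
                 value = dataset$channels[, c.]))))
  write_full_csv(long, path)
  sidecar <- list(schema = "crossfeed/platereader-v1",
                  gains = as.list(dataset$gains),
                  backgrounds = as.list(dataset$backgrounds),
                  noise_sd = dataset$noise_sd, seed = dataset$seed,
                  channel_map = as.list(dataset$channel_map))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_platereader_csv
#' @return `read_platereader_csv()`: list with `time`, `od_total`,
#'   `channels` and the sidecar fields (no ground truth).
#' @export
read_platereader_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(long)) stop("plate-reader CSV is empty: ", path, call. = FALSE)
  side <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list()
  od <- long[long$channel == "OD700", ]
  ch_names <- setdiff(unique(long$channel), "OD700")
  channels <- sapply(ch_names, function(c.)
    long$value[long$channel == c.])
  list(time = od$time, od_total = od$value,
       channels = matrix(channels, ncol = length(ch_names),
                         dimnames = list(NULL, ch_names)),
       gains = unlist(side$gains), backgrounds = unlist(side$backgrounds),
       noise_sd = side$noise_sd, seed = side$seed,
       channel_map = unlist(side$channel_map))
}
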