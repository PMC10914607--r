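# Dotted parameter paths address scalars inside a (model, init) pair,
# e.g. "strains.y1.productions.x2" (a leak fraction phi),
# "strains.y1.glucose_uptake.v_max", "init.total_density_0",
# "init.ratios_0.y1", "init.supplements_0.x1", "pathway.phi_upstream".

#' List the addressable scalar parameters of a model/init pair
#'
#' @param model A [community_model].
#' @param init An [initial_condition].
#' @return Character vector of valid dotted paths.
#' @export
valid_param_paths <- function(model, init) {
  p <- c("init.glucose_0", "init.total_density_0",
         paste0("init.ratios_0.", strain_ids(model)),
         paste0("init.supplements_0.", metabolite_ids(model)))
  for (s in model$strains) {
    b <- paste0("strains.", s$id, ".")
    p <- c(p,
           paste0(b, "glucose_uptake.", c("v_max", "k_m")),
           paste0(b, "yield_glucose"),
           paste0(b, "death_rate"),
           if (length(s$productions))
             paste0(b, "productions.", names(s$productions)),
           if (length(s$auxotrophies)) c(
             paste0(b, "metabolite_uptake.", rep(s$auxotrophies, each = 2),
                    ".", c("v_max", "k_m")),
             paste0(b, "yield_metabolite.", s$auxotrophies)))
  }
  if (!is.null(model$pathway)) {
    p <- c(p, paste0("pathway.",
                     c("phi_upstream", "conversion_vmax", "conversion_km")))
  }
  p
}

path_error <- function(path, model, init) {
  stop("cannot resolve parameter path '", path, "'; valid paths are:\n  ",
       paste(valid_param_paths(model, init), collapse = "\n  "),
       call. = FALSE)
}

#' Read a scalar parameter by path
#'
#' @inheritParams valid_param_paths
#' @param path Dotted parameter path; see [valid_param_paths()].
#' @return The scalar value.
#' @export
get_param <- function(model, init, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  v <- tryCatch({
    if (parts[1] == "init") {
      obj <- unclass(init)
      for (k in parts[-1]) obj <- obj[[k]]
      obj
    } else if (parts[1] == "strains") {
      s <- model$strains[[match(parts[2], strain_ids(model))]]
      obj <- unclass(s)
      for (k in parts[-(1:2)]) obj <- if (is.list(obj)) obj[[k]] else obj[[k]]
      obj
    } else if (parts[1] == "pathway") {
      model$pathway[[parts[2]]]
    } else NULL
  }, error = function(e) NULL)
  if (is.null(v) || !is.numeric(v) || length(v) != 1L) {
    path_error(path, model, init)
  }
  as.numeric(v)
}

#' Set a scalar parameter by path
#'
#' Returns modified copies; the originals are untouched. Setting one
#' inoculum ratio does not renormalise the others (the sensitivity
#' machinery applies its own simplex normalisation).
#'
#' @inheritParams get_param
#' @param value New scalar value.
#' @return List with modified `model` and `init`.
#' @export
set_param <- function(model, init, path, value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  ok <- path %in% valid_param_paths(model, init)
  if (!ok) path_error(path, model, init)
  if (parts[1] == "init") {
    if (length(parts) == 2L) {
      init[[parts[2]]] <- value
    } else {
      vec <- init[[parts[2]]]
      vec[parts[3]] <- value
      init[[parts[2]]] <- vec
    }
  } else if (parts[1] == "strains") {
    i <- match(parts[2], strain_ids(model))
    s <- model$strains[[i]]
    if (parts[3] %in% c("yield_glucose", "death_rate")) {
      s[[parts[3]]] <- value
    } else if (parts[3] == "glucose_uptake") {
      s$glucose_uptake[[parts[4]]] <- value
    } else if (parts[3] == "productions") {
      s$productions[parts[4]] <- value
    } else if (parts[3] == "yield_metabolite") {
      s$yield_metabolite[parts[4]] <- value
    } else if (parts[3] == "metabolite_uptake") {
      s$metabolite_uptake[[parts[4]]][[parts[5]]] <- value
    }
    model$strains[[i]] <- s
  } else if (parts[1] == "pathway") {
    model$pathway[[parts[2]]] <- value
  }
  list(model = model, init = init)
}

#' Sweep one or two parameters and tabulate metrics
#'
#' Runs [simulate_batch()] and [compute_metrics()] at every point of a
#' 1-D or 2-D parameter grid, preserving grid order.
#'
#' @inheritParams get_param
#' @param config A [simulation_config].
#' @param paths Character vector of one or two dotted parameter paths.
#' @param values List of numeric vectors, one per path (a bare numeric
#'   vector is accepted for a single path). A full factorial grid is
#'   swept for two paths.
#' @param use_compiled Passed to [simulate_batch()].
#' @return Data frame: one column per swept path (named by path), then
#'   the flattened metrics, one row per grid point. Empty values give an
#'   empty table.
#' @export
sweep_metrics <- function(model, init, config = simulation_config(),
                          paths, values, use_compiled = TRUE) {
  if (is.numeric(values)) values <- list(values)
  stopifnot(length(paths) %in% 1:2, length(values) == length(paths))
  for (p in paths) {
    if (!p %in% valid_param_paths(model, init)) path_error(p, model, init)
  }
  grid <- do.call(expand.grid,
                  c(stats::setNames(values, paths),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  if (nrow(grid) == 0L) return(grid)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    mi <- list(model = model, init = init)
    for (j in seq_along(paths)) {
      mi <- set_param(mi$model, mi$init, paths[j], grid[r, j])
    }
    res <- simulate_batch(mi$model, mi$init, config,
                          use_compiled = use_compiled)
    rows[[r]] <- flatten_metrics(compute_metrics(res))
  }
  met <- do.call(rbind, rows)
  cbind(grid, as.data.frame(met, optional = TRUE))
}
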