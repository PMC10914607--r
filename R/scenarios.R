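#' Nominal kinetic parameter set
#'
#' Mid-range values of the biologically permissible parameter ranges
#' used by the sensitivity analysis, plus the standard batch inoculum:
#' glucose uptake V_max,G = 15.5 g h^-1, k_M,G = 50.5 g l^-1, biomass
#' yields gamma_G = gamma_j = 0.505, metabolite uptake V_max,j = 60.5
#' mg h^-1, k_M,j = 500.5 mg l^-1, leak fraction phi = 0.25, decay
#' eta = 0.01 h^-1, glucose G0 = 20 g l^-1 and total inoculum
#' N0 = 0.102 OD700 (the standard microplate inoculum density).
#'
#' @return Named list of nominal values.
#' @export
nominal_parameters <- function() {
  list(v_max_G = 15.5, k_m_G = 50.5, yield_G = 0.505,
       v_max_met = 60.5, k_m_met = 500.5, yield_met = 0.505,
       phi = 0.25, death_rate = 0.01,
       glucose_0 = 20, density_0 = 0.102)
}

#' Promoter strength scale
#'
#' Maps ordinal promoter rank 1 (strongest) to 6 (no expression) to a
#' multiplicative factor on the leak fraction phi. Defaults to a
#' geometric series `(1, 0.5, 0.25, 0.125, 0.0625, 0)`; rank 6 always
#' yields factor 0.
#'
#' @param factors Numeric vector of 6 strictly decreasing factors with
#'   the last equal to 0.
#' @return An object of class `promoter_scale`.
#' @export
promoter_scale <- function(factors = c(1, 0.5, 0.25, 0.125, 0.0625, 0)) {
  stopifnot(length(factors) == 6L)
  if (any(diff(factors) >= 0)) {
    stop("promoter factors must be strictly decreasing with level",
         call. = FALSE)
  }
  if (factors[6] != 0) stop("level 6 means no expression: factor must be 0",
                            call. = FALSE)
  structure(list(factors = as.numeric(factors)), class = "promoter_scale")
}

#' @rdname promoter_scale
#' @param level Integer promoter level(s) in 1..6.
#' @param scale A `promoter_scale`.
#' @export
promoter_factor <- function(level, scale = promoter_scale()) {
  stopifnot(inherits(scale, "promoter_scale"))
  if (any(!level %in% 1:6)) stop("promoter level must be in 1..6",
                                 call. = FALSE)
  scale$factors[level]
}

parse_ratio_dial <- function(ratio, n_strains) {
  if (is.character(ratio)) {
    parts <- suppressWarnings(as.numeric(strsplit(ratio, ":")[[1]]))
    if (any(is.na(parts)) || any(parts < 0) || sum(parts) == 0) {
      stop("ratio dial must look like \"10:1\" (supported e.g. 20:1, 10:1, ",
           "6:1, 1:1, 1:6, 1:10, 1:20)", call. = FALSE)
    }
    ratio <- parts
  }
  if (length(ratio) != n_strains) {
    stop("ratio dial has ", length(ratio), " entries for ", n_strains,
         " strains", call. = FALSE)
  }
  ratio / sum(ratio)
}

DENSITY_CATALOGUE <- c(0.067, 0.078, 0.102, 0.125, 0.148)

scenario_names <- c("mono_producer", "pair_oneway", "pair_twoway_symmetric",
                    "trio_oneway", "trio_twoway", "dol_resveratrol",
                    "dol_no_crossfeed")

nominal_strain <- function(id, aux = character(), prod = character(),
                           phi = nominal_parameters()$phi,
                           pathway_stage = "none", fluor = NULL,
                           pars = nominal_parameters()) {
  productions <- if (length(prod))
    stats::setNames(rep(phi, length(prod)), prod) else numeric()
  strain_spec(
    id = id,
    auxotrophies = aux,
    productions = productions,
    glucose_uptake = uptake_kinetics(pars$v_max_G, pars$k_m_G),
    metabolite_uptake = stats::setNames(
      lapply(aux, function(.) uptake_kinetics(pars$v_max_met, pars$k_m_met)),
      aux),
    yield_glucose = pars$yield_G,
    yield_metabolite = stats::setNames(rep(pars$yield_met, length(aux)), aux),
    death_rate = pars$death_rate,
    pathway_stage = pathway_stage,
    fluor_channel = fluor
  )
}

#' Build a named community scenario
#'
#' Presets cover the community architectures studied with the model:
#' a producer monoculture, commensal and mutual two-member
#' cross-feeders, three-member communities with one-way (cyclic) or
#' two-way communication, and the division-of-labour bioproduction
#' pair (with and without cross-feeding). Experimental dials map onto
#' model quantities: promoter level scales phi through
#' [promoter_scale()], the ratio dial sets the inoculum fractions, the
#' supplement dial sets initial metabolite concentrations and the
#' density dial sets the total inoculum N0.
#'
#' @param name One of `r paste0('"', scenario_names, '"', collapse = ", ")`.
#' @param phi Base leak fraction before promoter scaling. Default the
#'   nominal 0.25.
#' @param promoter Optional promoter level dial: a single level in 1..6
#'   applied to every producing strain, or a named vector keyed by
#'   strain id.
#' @param ratio Optional inoculum ratio dial, e.g. `"10:1"` or a
#'   numeric vector (normalised to sum 1).
#' @param supplements Optional named vector of initial metabolite
#'   concentrations (mg l^-1).
#' @param density Optional total inoculum OD700; must be one of the
#'   calibrated densities `r paste(DENSITY_CATALOGUE, collapse = ", ")`.
#' @param scale A [promoter_scale()].
#' @param pars Nominal parameter list, see [nominal_parameters()].
#' @return List with elements `model` ([community_model]) and `init`
#'   ([initial_condition]).
#' @export
build_scenario <- function(name, phi = nominal_parameters()$phi,
                           promoter = NULL, ratio = NULL,
                           supplements = NULL, density = NULL,
                           scale = promoter_scale(),
                           pars = nominal_parameters()) {
  if (!name %in% scenario_names) {
    stop("unknown scenario '", name, "'; available: ",
         paste(scenario_names, collapse = ", "), call. = FALSE)
  }
  pathway <- NULL
  strains <- switch(
    name,
    mono_producer = list(
      nominal_strain("y1", prod = "x1", phi = phi, fluor = "RFP",
                     pars = pars)),
    pair_oneway = list(
      nominal_strain("y1", prod = "x1", phi = phi, fluor = "RFP",
                     pars = pars),
      nominal_strain("y2", aux = "x1", fluor = "BFP", pars = pars)),
    pair_twoway_symmetric = list(
      nominal_strain("y1", aux = "x2", prod = "x1", phi = phi,
                     fluor = "RFP", pars = pars),
      nominal_strain("y2", aux = "x1", prod = "x2", phi = phi,
                     fluor = "BFP", pars = pars)),
    trio_oneway = list(
      nominal_strain("y1", aux = "x2", prod = "x1", phi = phi,
                     fluor = "RFP", pars = pars),
      nominal_strain("y2", aux = "x3", prod = "x2", phi = phi,
                     fluor = "BFP", pars = pars),
      nominal_strain("y3", aux = "x1", prod = "x3", phi = phi,
                     fluor = "GFP", pars = pars)),
    trio_twoway = list(
      nominal_strain("y1", aux = c("x2", "x3"), prod = "x1", phi = phi,
                     fluor = "RFP", pars = pars),
      nominal_strain("y2", aux = c("x1", "x3"), prod = "x2", phi = phi,
                     fluor = "BFP", pars = pars),
      nominal_strain("y3", aux = c("x1", "x2"), prod = "x3", phi = phi,
                     fluor = "GFP", pars = pars)),
    dol_resveratrol = {
      pathway <- pathway_spec(phi_upstream = 0.3, conversion_vmax = 0.5,
                               conversion_km = 50)
      list(
        nominal_strain("y1", aux = "x2", prod = "x1", phi = phi,
                       pathway_stage = "upstream", fluor = "RFP",
                       pars = pars),
        nominal_strain("y2", aux = "x1", prod = "x2", phi = phi,
                       pathway_stage = "downstream", fluor = "BFP",
                       pars = pars))
    },
    dol_no_crossfeed = {
      pathway <- pathway_spec(phi_upstream = 0.3, conversion_vmax = 0.5,
                               conversion_km = 50)
      list(
        nominal_strain("y1", pathway_stage = "upstream", fluor = "RFP",
                       pars = pars),
        nominal_strain("y2", pathway_stage = "downstream", fluor = "BFP",
                       pars = pars))
    })
  if (!is.null(promoter)) {
    if (is.null(names(promoter))) {
      promoter <- stats::setNames(
        rep(promoter[1], length(strains)),
        vapply(strains, `[[`, character(1), "id"))
    }
    for (i in seq_along(strains)) {
      s <- strains[[i]]
      if (s$id %in% names(promoter) && length(s$productions)) {
        s$productions[] <- phi * promoter_factor(promoter[[s$id]], scale)
        strains[[i]] <- s
      }
    }
  }
  model <- community_model(strains, pathway = pathway)
  sids <- strain_ids(model)
  r <- if (is.null(ratio)) rep(1 / length(sids), length(sids)) else
    parse_ratio_dial(ratio, length(sids))
  n0 <- pars$density_0
  if (!is.null(density)) {
    if (!any(abs(density - DENSITY_CATALOGUE) < 1e-9)) {
      stop("density dial must be one of ",
           paste(DENSITY_CATALOGUE, collapse = ", "), call. = FALSE)
    }
    n0 <- density
  }
  supp <- numeric()
  if (!is.null(supplements)) {
    bad <- setdiff(names(supplements), metabolite_ids(model))
    if (length(bad)) {
      stop("supplement dial references unknown metabolites: ",
           paste(bad, collapse = ", "), "; available: ",
           paste(metabolite_ids(model), collapse = ", "), call. = FALSE)
    }
    supp <- supplements
  }
  init <- initial_condition(glucose_0 = pars$glucose_0,
                            total_density_0 = n0,
                            ratios_0 = stats::setNames(r, sids),
                            supplements_0 = supp)
  list(model = model, init = init)
}

#' List available scenario presets
#' @return Character vector of preset names.
#' @export
list_scenarios <- function() scenario_names

# Calibration pairs relating spectrophotometer OD600 to microplate
# OD700 readings for the standard inoculation densities.
default_od_pairs <- function() {
  data.frame(od600 = c(0.2, 0.4, 0.8, 1.2, 1.6),
             od700 = c(0.067, 0.078, 0.102, 0.125, 0.148))
}

#' Convert between OD600 and OD700 scales
#'
#' Piecewise-linear monotone interpolation through calibration pairs
#' (exact at the knots); values outside the calibrated range are
#' linearly extrapolated from the end segments and flagged via the
#' `"extrapolated"` attribute.
#'
#' @param value Numeric OD value(s) to convert.
#' @param direction `"od600_to_od700"` or `"od700_to_od600"`.
#' @param pairs Data frame with columns `od600` and `od700`, both
#'   strictly increasing; at least two rows.
#' @return Converted OD values with attribute `extrapolated` (logical
#'   vector).
#' @export
od_convert <- function(value,
                       direction = c("od600_to_od700", "od700_to_od600"),
                       pairs = default_od_pairs()) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 2L,
            all(c("od600", "od700") %in% names(pairs)))
  if (any(diff(pairs$od600) <= 0) || any(diff(pairs$od700) <= 0)) {
    stop("calibration pairs must be strictly monotone", call. = FALSE)
  }
  from <- if (direction == "od600_to_od700") pairs$od600 else pairs$od700
  to <- if (direction == "od600_to_od700") pairs$od700 else pairs$od600
  n <- length(from)
  out <- stats::approx(from, to, xout = value, rule = 2)$y
  lo <- value < from[1]
  hi <- value > from[n]
  slope_lo <- (to[2] - to[1]) / (from[2] - from[1])
  slope_hi <- (to[n] - to[n - 1]) / (from[n] - from[n - 1])
  out[lo] <- to[1] + (value[lo] - from[1]) * slope_lo
  out[hi] <- to[n] + (value[hi] - from[n]) * slope_hi
  attr(out, "extrapolated") <- lo | hi
  out
}
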