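#' Describe an exchanged metabolite
#'
#' An exchanged metabolite is an essential compound (amino acid or
#' nucleotide) that one community member overproduces and leaks into the
#' medium while auxotrophic partners consume it.
#'
#' @param id Short metabolite name, e.g. `"ade"` or `"lys"`.
#' @param delta Stoichiometric constant: glucose molecules required per
#'   metabolite unit. Defaults to 1.
#' @param toxicity_threshold Optional non-negative concentration
#'   (mg l^-1) above which growth inhibition applies when toxicity is
#'   enabled on the community; `NULL` disables toxicity for this
#'   metabolite.
#' @return An object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(id, delta = 1, toxicity_threshold = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0) {
    stop("metabolite '", id, "': delta must be a positive number",
         call. = FALSE)
  }
  if (!is.null(toxicity_threshold)) {
    if (!is.numeric(toxicity_threshold) || length(toxicity_threshold) != 1L ||
        !is.finite(toxicity_threshold) || toxicity_threshold < 0) {
      stop("metabolite '", id,
           "': toxicity_threshold must be a non-negative number",
           call. = FALSE)
    }
  }
  structure(
    list(id = id, delta = as.numeric(delta),
         toxicity_threshold = if (is.null(toxicity_threshold)) NULL else
           as.numeric(toxicity_threshold)),
    class = "metabolite_spec"
  )
}

#' Monod uptake kinetics
#'
#' @param v_max Maximum uptake rate per unit biomass (g h^-1 for
#'   glucose; mg h^-1 for exchanged metabolites). Must be >= 0.
#' @param k_m Half-saturation concentration in the substrate's units
#'   (g l^-1 for glucose, mg l^-1 for metabolites). Must be > 0.
#' @return An object of class `uptake_kinetics`.
#' @export
uptake_kinetics <- function(v_max, k_m) {
  if (!is.numeric(v_max) || length(v_max) != 1L || !is.finite(v_max) ||
      v_max < 0) {
    stop("v_max must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(k_m) || length(k_m) != 1L || !is.finite(k_m) || k_m <= 0) {
    stop("k_m must be a positive number", call. = FALSE)
  }
  structure(list(v_max = as.numeric(v_max), k_m = as.numeric(k_m)),
            class = "uptake_kinetics")
}

#' Describe a community member strain
#'
#' A strain takes up glucose, may be auxotrophic for (require) exchanged
#' metabolites, and may overproduce (leak) metabolites it donates to the
#' community. The leak fraction phi of each produced metabolite is the
#' proportion of the strain's glucose uptake flux diverted to that
#' metabolite's biosynthesis instead of growth.
#'
#' @param id Short unique strain name.
#' @param auxotrophies Character vector of metabolite ids the strain
#'   requires for growth (empty = prototroph).
#' @param productions Named numeric vector mapping produced metabolite
#'   id to its leak fraction phi in `[0, 1)`; the sum of leak fractions
#'   (plus any pathway diversion) must stay below 1.
#' @param glucose_uptake [uptake_kinetics] for glucose.
#' @param metabolite_uptake Named list of [uptake_kinetics], one entry
#'   per auxotrophic metabolite.
#' @param yield_glucose Biomass yield per g glucose (gamma_G).
#' @param yield_metabolite Named numeric vector of biomass yields per mg
#'   metabolite (gamma_j), one entry per auxotrophic metabolite.
#' @param death_rate Decay rate eta (h^-1), >= 0. Default 0.01.
#' @param pathway_stage One of `"none"`, `"upstream"`, `"downstream"`
#'   for the division-of-labour pathway extension.
#' @param fluor_channel Optional fluorescent tag (`"RFP"`, `"BFP"`,
#'   `"GFP"`) used by the synthetic plate-reader generator.
#' @return An object of class `strain_spec`.
#' @export
strain_spec <- function(id,
                        auxotrophies = character(),
                        productions = numeric(),
                        glucose_uptake,
                        metabolite_uptake = list(),
                        yield_glucose,
                        yield_metabolite = numeric(),
                        death_rate = 0.01,
                        pathway_stage = c("none", "upstream", "downstream"),
                        fluor_channel = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  pathway_stage <- match.arg(pathway_stage)
  auxotrophies <- as.character(auxotrophies)
  if (length(productions)) {
    if (is.null(names(productions)) || any(!nzchar(names(productions)))) {
      stop("strain '", id, "': productions must be a named numeric vector",
           call. = FALSE)
    }
    if (any(productions < 0 | productions >= 1)) {
      stop("strain '", id, "': every leak fraction phi must lie in [0, 1)",
           call. = FALSE)
    }
  }
  if (!inherits(glucose_uptake, "uptake_kinetics")) {
    stop("strain '", id, "': glucose_uptake must be an uptake_kinetics object",
         call. = FALSE)
  }
  if (!is.numeric(yield_glucose) || yield_glucose <= 0) {
    stop("strain '", id, "': yield_glucose must be positive", call. = FALSE)
  }
  if (!is.numeric(death_rate) || death_rate < 0) {
    stop("strain '", id, "': death_rate must be >= 0", call. = FALSE)
  }
  both <- intersect(auxotrophies, names(productions))
  if (length(both)) {
    stop("strain '", id, "' both produces and is auxotrophic for: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  missing_upt <- setdiff(auxotrophies, names(metabolite_uptake))
  if (length(missing_upt)) {
    stop("strain '", id, "': missing metabolite_uptake kinetics for ",
         paste(missing_upt, collapse = ", "), call. = FALSE)
  }
  missing_yld <- setdiff(auxotrophies, names(yield_metabolite))
  if (length(missing_yld)) {
    stop("strain '", id, "': missing yield_metabolite for ",
         paste(missing_yld, collapse = ", "), call. = FALSE)
  }
  if (length(metabolite_uptake) &&
      !all(vapply(metabolite_uptake, inherits, logical(1), "uptake_kinetics"))) {
    stop("strain '", id,
         "': every metabolite_uptake entry must be an uptake_kinetics object",
         call. = FALSE)
  }
  if (!is.null(fluor_channel)) {
    fluor_channel <- match.arg(fluor_channel, c("RFP", "BFP", "GFP"))
  }
  structure(
    list(id = id,
         auxotrophies = auxotrophies,
         productions = productions,
         glucose_uptake = glucose_uptake,
         metabolite_uptake = metabolite_uptake,
         yield_glucose = as.numeric(yield_glucose),
         yield_metabolite = yield_metabolite,
         death_rate = as.numeric(death_rate),
         pathway_stage = pathway_stage,
         fluor_channel = fluor_channel),
    class = "strain_spec"
  )
}

#' Division-of-labour pathway specification
#'
#' Splits a heterologous product pathway across two community members:
#' the upstream strain diverts a fraction of its glucose flux to an
#' intermediate (e.g. p-coumaric acid) and the downstream strain
#' converts the intermediate to the product (e.g. resveratrol) with
#' Monod-type kinetics scaled by its biomass. The product is inert.
#'
#' @param phi_upstream Fraction of the upstream strain's glucose flux
#'   diverted to intermediate synthesis, in `[0, 1)`.
#' @param conversion_vmax Maximum conversion rate (uM h^-1 per unit
#'   downstream biomass).
#' @param conversion_km Half-saturation of the intermediate (uM).
#' @param intermediate_id,product_id Species names for reporting.
#' @return An object of class `pathway_spec`.
#' @export
pathway_spec <- function(phi_upstream,
                         conversion_vmax,
                         conversion_km,
                         intermediate_id = "p-coumaric",
                         product_id = "resveratrol") {
  if (!is.numeric(phi_upstream) || phi_upstream < 0 || phi_upstream >= 1) {
    stop("phi_upstream must lie in [0, 1)", call. = FALSE)
  }
  kin <- uptake_kinetics(conversion_vmax, conversion_km)
  structure(
    list(phi_upstream = as.numeric(phi_upstream),
         conversion_vmax = kin$v_max,
         conversion_km = kin$k_m,
         intermediate_id = intermediate_id,
         product_id = product_id),
    class = "pathway_spec"
  )
}

#' Assemble a cross-feeding community model
#'
#' @param strains List of [strain_spec] objects with unique ids.
#' @param metabolites List of [metabolite_spec] objects; every
#'   metabolite referenced by a strain must appear exactly once. If
#'   omitted, default specs (delta = 1) are created for all referenced
#'   metabolite ids.
#' @param pathway Optional [pathway_spec]; requires exactly one upstream
#'   and one downstream strain.
#' @param toxicity_enabled Apply Hill growth inhibition for metabolites
#'   that carry a toxicity threshold. Default `FALSE`.
#' @param toxicity_hill Hill coefficient of the inhibition factor
#'   `1 / (1 + (x / threshold)^n)`. Default 2.
#' @return An object of class `community_model`.
#' @export
community_model <- function(strains, metabolites = NULL, pathway = NULL,
                            toxicity_enabled = FALSE, toxicity_hill = 2) {
  stopifnot(is.list(strains), length(strains) >= 1L)
  if (!all(vapply(strains, inherits, logical(1), "strain_spec"))) {
    stop("strains must be a list of strain_spec objects", call. = FALSE)
  }
  sids <- vapply(strains, `[[`, character(1), "id")
  if (anyDuplicated(sids)) {
    stop("strain ids must be unique; duplicated: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "),
         call. = FALSE)
  }
  referenced <- unique(unlist(lapply(strains, function(s)
    c(s$auxotrophies, names(s$productions)))))
  if (is.null(metabolites)) {
    metabolites <- lapply(referenced, metabolite_spec)
  }
  stopifnot(is.list(metabolites))
  if (length(metabolites) &&
      !all(vapply(metabolites, inherits, logical(1), "metabolite_spec"))) {
    stop("metabolites must be a list of metabolite_spec objects",
         call. = FALSE)
  }
  mids <- vapply(metabolites, `[[`, character(1), "id")
  if (anyDuplicated(mids)) {
    stop("metabolite ids must be unique; duplicated: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(referenced, mids)
  if (length(unknown)) {
    stop("strains reference undeclared metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(pathway)) {
    if (!inherits(pathway, "pathway_spec")) {
      stop("pathway must be a pathway_spec object", call. = FALSE)
    }
    stages <- vapply(strains, `[[`, character(1), "pathway_stage")
    if (sum(stages == "upstream") != 1L || sum(stages == "downstream") != 1L) {
      stop("a pathway model needs exactly one upstream and one downstream ",
           "strain", call. = FALSE)
    }
  }
  # combined diversion (leak + pathway) must leave a positive growth flux
  for (s in strains) {
    tot <- sum(s$productions)
    if (!is.null(pathway) && s$pathway_stage == "upstream") {
      tot <- tot + pathway$phi_upstream
    }
    if (tot >= 1) {
      stop("strain '", s$id, "': total diverted glucose fraction (leak + ",
           "pathway) must stay below 1 (got ", signif(tot, 4), ")",
           call. = FALSE)
    }
  }
  structure(
    list(metabolites = metabolites,
         strains = strains,
         pathway = pathway,
         toxicity_enabled = isTRUE(toxicity_enabled),
         toxicity_hill = as.numeric(toxicity_hill)),
    class = "community_model"
  )
}

#' Initial conditions for a batch culture
#'
#' @param glucose_0 Initial glucose (g l^-1), default 20.
#' @param total_density_0 Total initial biomass N0 (OD700 units).
#' @param ratios_0 Named numeric vector of inoculum fractions per
#'   strain; must sum to 1 (tolerance 1e-12). Values are the fraction of
#'   `total_density_0` allotted to each strain.
#' @param supplements_0 Named numeric vector of initial metabolite
#'   concentrations (mg l^-1); metabolites not listed start at 0.
#' @return An object of class `initial_condition`.
#' @export
initial_condition <- function(glucose_0 = 20,
                              total_density_0 = 0.102,
                              ratios_0,
                              supplements_0 = numeric()) {
  stopifnot(is.numeric(glucose_0), glucose_0 >= 0,
            is.numeric(total_density_0), total_density_0 >= 0)
  if (is.null(names(ratios_0)) || any(!nzchar(names(ratios_0)))) {
    stop("ratios_0 must be a named numeric vector keyed by strain id",
         call. = FALSE)
  }
  if (any(ratios_0 < 0)) stop("ratios_0 entries must be >= 0", call. = FALSE)
  if (abs(sum(ratios_0) - 1) > 1e-12) {
    stop("ratios_0 must sum to 1 (got ", format(sum(ratios_0), digits = 15),
         ")", call. = FALSE)
  }
  if (length(supplements_0)) {
    if (is.null(names(supplements_0)) || any(!nzchar(names(supplements_0)))) {
      stop("supplements_0 must be a named numeric vector keyed by ",
           "metabolite id", call. = FALSE)
    }
    if (any(supplements_0 < 0)) {
      stop("supplements_0 entries must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(glucose_0 = as.numeric(glucose_0),
         total_density_0 = as.numeric(total_density_0),
         ratios_0 = ratios_0,
         supplements_0 = supplements_0),
    class = "initial_condition"
  )
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", length(x$strains), " strain(s), ",
      length(x$metabolites), " exchanged metabolite(s)\n", sep = "")
  for (s in x$strains) {
    cat("  ", s$id, ": aux={", paste(s$auxotrophies, collapse = ","),
        "} produces={",
        paste(sprintf("%s(phi=%.3g)", names(s$productions), s$productions),
              collapse = ","),
        "}", if (s$pathway_stage != "none") paste0(" [", s$pathway_stage, "]"),
        "\n", sep = "")
  }
  if (!is.null(x$pathway)) {
    cat("  pathway: ", x$pathway$intermediate_id, " -> ",
        x$pathway$product_id, " (phi_upstream=", x$pathway$phi_upstream,
        ")\n", sep = "")
  }
  if (x$toxicity_enabled) cat("  toxicity: enabled (Hill n=",
                              x$toxicity_hill, ")\n", sep = "")
  invisible(x)
}

#' @export
print.initial_condition <- function(x, ...) {
  cat("<initial_condition> G0=", x$glucose_0, " g/l, N0=",
      x$total_density_0, " OD700\n  ratios: ",
      paste(sprintf("%s=%.4g", names(x$ratios_0), x$ratios_0),
            collapse = ", "), "\n", sep = "")
  if (length(x$supplements_0)) {
    cat("  supplements (mg/l): ",
        paste(sprintf("%s=%.4g", names(x$supplements_0), x$supplements_0),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

strain_ids <- function(model) vapply(model$strains, `[[`, character(1), "id")
metabolite_ids <- function(model)
  vapply(model$metabolites, `[[`, character(1), "id")
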