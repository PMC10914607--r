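#' Monod uptake rate
#'
#' Saturating uptake rate per unit biomass,
#' `v_max * S / (k_m + S)`: zero at `S = 0`, strictly increasing in the
#' substrate and bounded above by `v_max`.
#'
#' @param kinetics An [uptake_kinetics] object.
#' @param substrate Substrate concentration (>= 0), vectorised.
#' @param component Name used in the error message when the
#'   concentration is negative.
#' @return Uptake rate(s) per unit biomass.
#' @export
monod_uptake <- function(kinetics, substrate, component = "substrate") {
  stopifnot(inherits(kinetics, "uptake_kinetics"))
  if (any(substrate < 0)) {
    stop("negative concentration for state component '", component, "'",
         call. = FALSE)
  }
  kinetics$v_max * substrate / (kinetics$k_m + substrate)
}

#' Metabolite leak (production) flux
#'
#' Production of an exchanged metabolite is proportional to the
#' producer's glucose uptake flux: `phi * delta * J_upt_G`, where `phi`
#' is the leak fraction and `delta` the glucose-per-metabolite
#' stoichiometry.
#'
#' @param phi Leak fraction in `[0, 1)`.
#' @param delta Stoichiometric constant (> 0).
#' @param j_upt_glucose Glucose uptake flux per unit biomass (>= 0).
#' @return Metabolite production rate per unit biomass.
#' @export
leak_flux <- function(phi, delta, j_upt_glucose) {
  if (any(phi < 0) || any(phi >= 1)) {
    stop("leak fraction phi must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(all(delta > 0), all(j_upt_glucose >= 0))
  phi * delta * j_upt_glucose
}

#' Growth rate of a strain given its uptake fluxes
#'
#' Growth is limited by the scarcest resource: the glucose-supported
#' term `gamma_G * (1 - sum(phi)) * J_upt_G` (glucose flux not diverted
#' to metabolite overproduction) or, for each auxotrophic metabolite j,
#' `gamma_j * J_upt_j`. The realised growth rate is the minimum of these
#' terms.
#'
#' @param strain A [strain_spec].
#' @param j_upt_glucose Glucose uptake flux per unit biomass.
#' @param j_upt_metabolites Named numeric vector of metabolite uptake
#'   fluxes per unit biomass, one entry per auxotrophic metabolite.
#' @param phi_extra Additional diverted glucose fraction (the pathway
#'   diversion of an upstream division-of-labour strain). Default 0.
#' @return List with `rate` (h^-1) and `limiting` (`"glucose"` or the
#'   limiting metabolite id).
#' @export
growth_rate <- function(strain, j_upt_glucose, j_upt_metabolites = numeric(),
                        phi_extra = 0) {
  stopifnot(inherits(strain, "strain_spec"), j_upt_glucose >= 0,
            all(j_upt_metabolites >= 0))
  terms <- strain$yield_glucose * (1 - sum(strain$productions) - phi_extra) *
    j_upt_glucose
  names(terms) <- "glucose"
  for (m in strain$auxotrophies) {
    if (is.na(strain$yield_metabolite[m])) {
      stop("strain '", strain$id, "': missing yield for metabolite '", m, "'",
           call. = FALSE)
    }
    j <- if (m %in% names(j_upt_metabolites)) j_upt_metabolites[[m]] else 0
    terms[m] <- strain$yield_metabolite[[m]] * j
  }
  k <- which.min(terms)
  list(rate = unname(terms[k]), limiting = names(terms)[k])
}

#' Toxicity attenuation factor
#'
#' Hill inhibition of growth by toxic metabolite accumulation:
#' `prod_i 1 / (1 + (x_i / threshold_i)^n)` over metabolites that carry
#' a toxicity threshold. Equals 1 when all concentrations are far below
#' their thresholds, 0.5 at the threshold, and tends to 0 as any toxic
#' concentration grows. Identity when toxicity is disabled.
#'
#' @param growth Growth rate (h^-1).
#' @param metabolite_concentrations Named numeric vector of metabolite
#'   concentrations (mg l^-1).
#' @param model A [community_model].
#' @return Attenuated growth rate.
#' @export
apply_toxicity <- function(growth, metabolite_concentrations, model) {
  if (!isTRUE(model$toxicity_enabled)) return(growth)
  f <- 1
  for (m in model$metabolites) {
    if (is.null(m$toxicity_threshold) || m$toxicity_threshold <= 0) next
    x <- metabolite_concentrations[[m$id]]
    if (is.null(x) || is.na(x)) x <- 0
    f <- f / (1 + (max(x, 0) / m$toxicity_threshold)^model$toxicity_hill)
  }
  growth * f
}

# Names of the state vector, in integration order.
state_names <- function(model) {
  nm <- c("G", paste0("x.", metabolite_ids(model), recycle0 = TRUE),
          paste0("y.", strain_ids(model), recycle0 = TRUE))
  if (!is.null(model$pathway)) nm <- c(nm, "intermediate", "product")
  nm
}

# Build the numeric initial-state vector from an initial_condition.
build_state0 <- function(model, init) {
  mids <- metabolite_ids(model)
  sids <- strain_ids(model)
  unknown <- setdiff(names(init$ratios_0), sids)
  if (length(unknown)) {
    stop("ratios_0 references unknown strains: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(init$supplements_0), mids)
  if (length(unknown)) {
    stop("supplements_0 references unknown metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  x0 <- stats::setNames(numeric(length(mids)), mids)
  x0[names(init$supplements_0)] <- init$supplements_0
  r <- stats::setNames(numeric(length(sids)), sids)
  r[names(init$ratios_0)] <- init$ratios_0
  y0 <- init$total_density_0 * r
  s <- c(init$glucose_0, unname(x0), unname(y0))
  if (!is.null(model$pathway)) s <- c(s, 0, 0)
  stats::setNames(s, state_names(model))
}

#' Time derivatives of the batch co-culture system
#'
#' Reference implementation of the coupled ODE right-hand side: glucose
#' is consumed by all strains (`dG/dt = -sum(J_upt_G * y)`), each strain
#' grows at its limiting-resource rate minus decay
#' (`dy/dt = (J_grow - eta) * y`), and each exchanged metabolite is
#' produced by its donor's leak flux and consumed by its auxotrophic
#' receivers (`dx/dt = sum(J_leak * y) - sum(J_upt * y)`). Optional
#' toxicity attenuation and division-of-labour pathway species are
#' appended when enabled. Fluxes are evaluated on `max(component, 0)` to
#' guard against tiny negative solver excursions.
#'
#' @param state Named numeric state vector as produced by the simulator
#'   (`G`, `x.<metabolite>`, `y.<strain>`, optionally `intermediate`,
#'   `product`).
#' @param model A [community_model].
#' @param smooth_min_k Optional positive sharpness of a soft-min
#'   (log-sum-exp) replacement for the hard minimum in the growth law,
#'   for solver-robustness comparisons. `NULL` (default) uses the exact
#'   minimum.
#' @return Named numeric vector of time derivatives, same order as
#'   `state`.
#' @export
system_rhs <- function(state, model, smooth_min_k = NULL) {
  mids <- metabolite_ids(model)
  sids <- strain_ids(model)
  nm <- length(mids)
  ns <- length(sids)
  G <- max(state[[1L]], 0)
  x <- pmax(state[1L + seq_len(nm)], 0)
  names(x) <- mids
  y <- pmax(state[1L + nm + seq_len(ns)], 0)
  names(y) <- sids
  has_path <- !is.null(model$pathway)
  I <- if (has_path) max(state[[2L + nm + ns]], 0) else 0

  dG <- 0
  dx <- stats::setNames(numeric(nm), mids)
  dy <- stats::setNames(numeric(ns), sids)
  dI <- 0
  dP <- 0
  deltas <- stats::setNames(
    vapply(model$metabolites, `[[`, numeric(1), "delta"), mids)

  for (s in model$strains) {
    yi <- y[[s$id]]
    j_g <- monod_uptake(s$glucose_uptake, G, "G")
    dG <- dG - j_g * yi
    phi_extra <- 0
    if (has_path && s$pathway_stage == "upstream") {
      phi_extra <- model$pathway$phi_upstream
      dI <- dI + phi_extra * j_g * yi
    }
    j_m <- stats::setNames(numeric(length(s$auxotrophies)), s$auxotrophies)
    for (m in s$auxotrophies) {
      j_m[m] <- monod_uptake(s$metabolite_uptake[[m]], x[[m]],
                             paste0("x.", m))
      dx[m] <- dx[m] - j_m[m] * yi
    }
    for (m in names(s$productions)) {
      dx[m] <- dx[m] + leak_flux(s$productions[[m]], deltas[[m]], j_g) * yi
    }
    if (is.null(smooth_min_k)) {
      jg <- growth_rate(s, j_g, j_m, phi_extra = phi_extra)$rate
    } else {
      terms <- c(s$yield_glucose * (1 - sum(s$productions) - phi_extra) * j_g,
                 s$yield_metabolite[s$auxotrophies] * j_m)
      jg <- -log(sum(exp(-smooth_min_k * terms))) / smooth_min_k
    }
    jg <- apply_toxicity(jg, x, model)
    dy[s$id] <- (jg - s$death_rate) * yi
    if (has_path && s$pathway_stage == "downstream") {
      conv <- model$pathway$conversion_vmax * I /
        (model$pathway$conversion_km + I) * yi
      dI <- dI - conv
      dP <- dP + conv
    }
  }
  d <- c(dG, unname(dx), unname(dy))
  if (has_path) d <- c(d, dI, dP)
  stats::setNames(d, state_names(model))
}

# ---- compiled-parameter packing ---------------------------------------------
# Flat layout consumed by src/crossfeed_rhs.c, padded to PARMS_LEN doubles:
#   [0..7]  nS, nM, toxicity flag, pathway flag, Hill n, kappa,
#           conversion vmax, conversion km
#   [8 ..]  per metabolite: delta (nM), toxicity threshold (nM; <=0 = none)
#   then per strain, stride 7 + 4*nM:
#           vmaxG, kmG, gammaG, eta, sum(phi)+phi_pathway, phi_pathway,
#           is_downstream, leak[nM] (= phi*delta), uptake vmax[nM],
#           uptake km[nM] (<=0 marks "not auxotrophic"), gamma_j[nM]
PARMS_LEN <- 4096L

strain_stride <- function(nm) 7L + 4L * nm

pack_parms <- function(model) {
  mids <- metabolite_ids(model)
  nm <- length(mids)
  ns <- length(model$strains)
  has_path <- !is.null(model$pathway)
  stride <- strain_stride(nm)
  need <- 8L + 2L * nm + ns * stride
  if (need > PARMS_LEN) {
    stop("community too large for the compiled backend (needs ", need,
         " parameter slots); use use_compiled = FALSE", call. = FALSE)
  }
  p <- numeric(PARMS_LEN)
  p[1] <- ns
  p[2] <- nm
  p[3] <- as.numeric(isTRUE(model$toxicity_enabled))
  p[4] <- as.numeric(has_path)
  p[5] <- model$toxicity_hill
  p[6] <- 1 # intermediate unit conversion kappa
  p[7] <- if (has_path) model$pathway$conversion_vmax else 0
  p[8] <- if (has_path) model$pathway$conversion_km else 1
  for (k in seq_len(nm)) {
    m <- model$metabolites[[k]]
    p[8L + k] <- m$delta
    p[8L + nm + k] <- if (is.null(m$toxicity_threshold)) -1 else
      m$toxicity_threshold
  }
  base0 <- 8L + 2L * nm
  for (i in seq_len(ns)) {
    s <- model$strains[[i]]
    b <- base0 + (i - 1L) * stride
    sumphi <- sum(s$productions)
    phi_path <- 0
    if (has_path && s$pathway_stage == "upstream") {
      phi_path <- model$pathway$phi_upstream
      sumphi <- sumphi + phi_path
    }
    p[b + 1L] <- s$glucose_uptake$v_max
    p[b + 2L] <- s$glucose_uptake$k_m
    p[b + 3L] <- s$yield_glucose
    p[b + 4L] <- s$death_rate
    p[b + 5L] <- sumphi
    p[b + 6L] <- phi_path
    p[b + 7L] <- as.numeric(has_path && s$pathway_stage == "downstream")
    leak <- b + 7L
    vmax <- leak + nm
    km <- vmax + nm
    gam <- km + nm
    for (k in seq_len(nm)) {
      id <- mids[k]
      p[leak + k] <- if (id %in% names(s$productions))
        s$productions[[id]] * model$metabolites[[k]]$delta else 0
      if (id %in% s$auxotrophies) {
        p[vmax + k] <- s$metabolite_uptake[[id]]$v_max
        p[km + k] <- s$metabolite_uptake[[id]]$k_m
        p[gam + k] <- s$yield_metabolite[[id]]
      } else {
        p[vmax + k] <- 0
        p[km + k] <- -1
        p[gam + k] <- 0
      }
    }
  }
  p
}

# Positions (1-based, in the packed vector) of tunable scalars, used by the
# sensitivity machinery to write sampled values without re-packing.
parms_index <- function(model, strain_id, field, metabolite_id = NULL) {
  mids <- metabolite_ids(model)
  nm <- length(mids)
  i <- match(strain_id, strain_ids(model))
  if (is.na(i)) stop("unknown strain '", strain_id, "'", call. = FALSE)
  b <- 8L + 2L * nm + (i - 1L) * strain_stride(nm)
  if (!is.null(metabolite_id)) {
    k <- match(metabolite_id, mids)
    if (is.na(k)) stop("unknown metabolite '", metabolite_id, "'",
                       call. = FALSE)
  }
  switch(field,
    vmax_glucose = b + 1L,
    km_glucose = b + 2L,
    yield_glucose = b + 3L,
    death_rate = b + 4L,
    sum_phi = b + 5L,
    leak = b + 7L + k,
    vmax_metabolite = b + 7L + nm + k,
    km_metabolite = b + 7L + 2L * nm + k,
    yield_metabolite = b + 7L + 3L * nm + k,
    stop("unknown parms field '", field, "'", call. = FALSE))
}
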