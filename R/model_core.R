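#' Species specification
#'
#' Describes one species in a community model. Producers grow logistically
#' (intrinsic rate \code{r} and self-limitation \code{s} give per-capita
#' growth \code{r - s*N}); consumers experience a linear per-capita mortality
#' at rate \code{intrinsic_rate} plus optional self-limitation.
#'
#' @param id Short unique token identifying the species.
#' @param intrinsic_rate Per-time growth rate (producers) or death rate
#'   (consumers, given as a positive number).
#' @param self_limitation Intraspecific density dependence coefficient,
#'   per (density x time); must be >= 0.
#' @param role Either \code{"producer"} or \code{"consumer"}.
#' @param name Free-text name; defaults to \code{id}.
#' @return An object of class \code{species_spec}.
#' @export
species_spec <- function(id, intrinsic_rate, self_limitation = 0,
                         role = c("producer", "consumer"), name = id) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.finite(intrinsic_rate)) stop("intrinsic_rate must be finite")
  if (!is.finite(self_limitation) || self_limitation < 0)
    stop("self_limitation must be finite and >= 0")
  structure(list(id = id, name = name,
                 intrinsic_rate = as.numeric(intrinsic_rate),
                 self_limitation = as.numeric(self_limitation),
                 role = role),
            class = "species_spec")
}

#' Trophic link specification
#'
#' A consumer-resource feeding link with its functional response. Supported
#' functional response forms: \code{"linear"} (type I, flux
#' \eqn{a R C}), \code{"holling2"} (type II, flux \eqn{a R C / (1 + a h R)})
#' and \code{"holling2_interference"} (Beddington-DeAngelis, flux
#' \eqn{a R C / (1 + a h R + w C)} with interference coefficient \eqn{w}).
#' All fluxes are per unit time, multiplied by consumer density.
#'
#' @param resource,consumer Species id tokens (resource is eaten by consumer).
#' @param fr_form Functional response form (see Details).
#' @param attack_rate Attack (capture) rate \code{a > 0}, per (density x time).
#' @param handling_time Handling time \code{h >= 0}; must be 0 for
#'   \code{"linear"}.
#' @param interference Intraspecific interference coefficient (>= 0); only
#'   used by \code{"holling2_interference"}.
#' @param conversion_efficiency Fraction of consumed biomass converted to
#'   consumer biomass, in (0, 1].
#' @return An object of class \code{trophic_link}.
#' @export
trophic_link <- function(resource, consumer,
                         fr_form = c("linear", "holling2",
                                     "holling2_interference"),
                         attack_rate, handling_time = 0, interference = 0,
                         conversion_efficiency = 0.5) {
  fr_form <- match.arg(fr_form)
  if (identical(resource, consumer))
    stop("resource and consumer must differ: ", resource)
  if (!is.finite(attack_rate) || attack_rate <= 0)
    stop("attack_rate must be > 0")
  if (!is.finite(handling_time) || handling_time < 0)
    stop("handling_time must be >= 0")
  if (fr_form == "linear" && handling_time != 0)
    stop("linear functional response requires handling_time = 0")
  if (!is.finite(interference) || interference < 0)
    stop("interference must be >= 0")
  if (!is.finite(conversion_efficiency) ||
      conversion_efficiency <= 0 || conversion_efficiency > 1)
    stop("conversion_efficiency must be in (0, 1]")
  structure(list(resource = resource, consumer = consumer, fr_form = fr_form,
                 attack_rate = as.numeric(attack_rate),
                 handling_time = as.numeric(handling_time),
                 interference = as.numeric(interference),
                 conversion_efficiency = as.numeric(conversion_efficiency)),
            class = "trophic_link")
}

#' Trophic interaction modification (TIM) specification
#'
#' Attaches a modifier species k to an existing trophic link (i eaten by j):
#' one functional response parameter of the link is multiplied by a
#' modification term \eqn{f(c, k)} that depends on the modifier's density k
#' and the modification parameter \eqn{c = c_{ijk}} (sign gives direction,
#' positive strengthening the interaction).
#'
#' Implemented forms for \eqn{f(c, k)}:
#' \describe{
#'   \item{exponential}{\eqn{e^{c k}}: unbounded, sign-symmetric, always
#'     positive. The default.}
#'   \item{linear_clipped}{\eqn{\max(0, 1 + c k)}: linear with a floor at 0.}
#'   \item{hyperbolic}{piecewise one-parameter family: \eqn{1 + c k} for
#'     \eqn{c \ge 0} and \eqn{1 / (1 + |c| k)} for \eqn{c < 0}; strictly
#'     positive for all \eqn{k \ge 0}.}
#'   \item{sigmoid}{\eqn{1 + c\, k^s / (k^s + m^s)} with midpoint \code{m}
#'     and steepness \code{s} from \code{form_params}; requires
#'     \eqn{c > -1} so the term stays strictly positive.}
#' }
#' Every form equals exactly 1 at \eqn{c = 0}.
#'
#' In \code{"dynamic"} mode the modifier density is read from the system
#' state; in \code{"forced"} (cue) mode it is held at \code{forced_density},
#' representing a modification introduced without the modifier being
#' trophically coupled to the system.
#'
#' @param tim_id Token identifying this TIM.
#' @param modifier Modifier species id (k); may be NA for forced mode.
#' @param resource,consumer Ids naming the target link (i, j).
#' @param affected_parameter Which functional response parameter is scaled:
#'   \code{"attack_rate"} (default), \code{"handling_time"} or
#'   \code{"interference"}.
#' @param form Modification functional form (see Details).
#' @param strength The modification parameter \eqn{c_{ijk}}, per modifier
#'   density.
#' @param form_params Named list of extra shape constants: \code{midpoint}
#'   and \code{steepness} for the sigmoid form.
#' @param mode \code{"dynamic"} or \code{"forced"}.
#' @param forced_density Modifier density used when \code{mode = "forced"}.
#' @return An object of class \code{tim_spec}.
#' @export
tim_spec <- function(tim_id, modifier, resource, consumer,
                     affected_parameter = c("attack_rate", "handling_time",
                                            "interference"),
                     form = c("exponential", "linear_clipped", "hyperbolic",
                              "sigmoid"),
                     strength, form_params = list(),
                     mode = c("dynamic", "forced"), forced_density = NULL) {
  affected_parameter <- match.arg(affected_parameter)
  form <- match.arg(form)
  mode <- match.arg(mode)
  if (!is.finite(strength)) stop("strength must be finite")
  if (mode == "forced") {
    if (is.null(forced_density) || !is.finite(forced_density) ||
        forced_density < 0)
      stop("forced mode requires forced_density >= 0")
    forced_density <- as.numeric(forced_density)
  }
  if (form == "sigmoid") {
    m <- form_params$midpoint; s <- form_params$steepness
    if (is.null(m) || is.null(s) || !is.finite(m) || !is.finite(s) ||
        m <= 0 || s <= 0)
      stop("sigmoid form needs form_params$midpoint > 0 and $steepness > 0")
    if (strength <= -1)
      stop("sigmoid form requires strength > -1 for strict positivity")
  }
  structure(list(tim_id = tim_id, modifier = modifier,
                 resource = resource, consumer = consumer,
                 affected_parameter = affected_parameter, form = form,
                 strength = as.numeric(strength), form_params = form_params,
                 mode = mode, forced_density = forced_density),
            class = "tim_spec")
}

#' Assemble a community model
#'
#' Collects species, trophic links and TIM specifications into a validated
#' community dynamics model. The species order given here is the canonical
#' index assignment for all state vectors and matrices.
#'
#' The dynamics are: for a producer i,
#' \deqn{dN_i/dt = N_i (r_i - s_i N_i) - \sum outgoing fluxes,}
#' and for a consumer j,
#' \deqn{dN_j/dt = \sum \epsilon F_{in} - \sum F_{out} - d_j N_j - s_j N_j^2,}
#' where fluxes F are the (TIM-modified) functional responses of
#' \code{\link{trophic_link}}.
#'
#' @param species List of \code{\link{species_spec}} objects.
#' @param links List of \code{\link{trophic_link}} objects.
#' @param tims Optional list of \code{\link{tim_spec}} objects.
#' @return An object of class \code{community_model} with element
#'   \code{species_order} (character vector of ids).
#' @export
community_model <- function(species, links, tims = list()) {
  if (inherits(species, "species_spec")) species <- list(species)
  if (inherits(links, "trophic_link")) links <- list(links)
  if (inherits(tims, "tim_spec")) tims <- list(tims)
  model <- structure(list(species = species, links = links, tims = tims,
                          species_order = vapply(species, `[[`, "", "id")),
                     class = "community_model")
  errs <- validate_model(model)
  if (length(errs)) stop("invalid community model:\n  - ",
                         paste(errs, collapse = "\n  - "))
  model
}

#' Validate a community model, collecting all violations
#'
#' @param model A \code{community_model} (or a bare list with the same
#'   elements).
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_model <- function(model) {
  errs <- character()
  ids <- vapply(model$species, `[[`, "", "id")
  if (anyDuplicated(ids))
    errs <- c(errs, paste("duplicated species ids:",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  pair_keys <- character()
  for (ln in model$links) {
    for (sp in c(ln$resource, ln$consumer))
      if (!sp %in% ids)
        errs <- c(errs, paste0("link ", ln$resource, "->", ln$consumer,
                               ": unknown species '", sp, "'"))
    key <- paste(ln$resource, ln$consumer, sep = "->")
    if (key %in% pair_keys)
      errs <- c(errs, paste("duplicated trophic link:", key))
    pair_keys <- c(pair_keys, key)
  }
  tim_ids <- vapply(model$tims, `[[`, "", "tim_id")
  if (anyDuplicated(tim_ids))
    errs <- c(errs, paste("duplicated TIM ids:",
                          paste(unique(tim_ids[duplicated(tim_ids)]),
                                collapse = ", ")))
  for (tm in model$tims) {
    key <- paste(tm$resource, tm$consumer, sep = "->")
    if (!key %in% pair_keys)
      errs <- c(errs, paste0("TIM '", tm$tim_id, "' targets missing link ",
                             key))
    if (tm$mode == "dynamic" && !isTRUE(tm$modifier %in% ids))
      errs <- c(errs, paste0("TIM '", tm$tim_id, "': dynamic modifier '",
                             tm$modifier, "' is not a model species"))
  }
  errs
}

#' @export
print.community_model <- function(x, ...) {
  cat("Community model:", length(x$species), "species,",
      length(x$links), "trophic links,", length(x$tims), "TIMs\n")
  for (sp in x$species)
    cat(sprintf("  %s  [%s]  rate=%g  self_lim=%g\n", sp$id, sp$role,
                sp$intrinsic_rate, sp$self_limitation))
  for (ln in x$links)
    cat(sprintf("  %s -> %s  (%s, a=%g, h=%g, eps=%g)\n", ln$resource,
                ln$consumer, ln$fr_form, ln$attack_rate, ln$handling_time,
                ln$conversion_efficiency))
  for (tm in x$tims)
    cat(sprintf("  TIM %s: %s ~> (%s->%s).%s  [%s, c=%g, %s]\n", tm$tim_id,
                if (tm$mode == "forced")
                  sprintf("forced K=%g", tm$forced_density) else tm$modifier,
                tm$resource, tm$consumer, tm$affected_parameter, tm$form,
                tm$strength, tm$mode))
  invisible(x)
}

# index of species id in canonical order
species_index <- function(model, id) {
  ix <- match(id, model$species_order)
  if (is.na(ix)) stop("unknown species id: ", id)
  ix
}

find_link <- function(model, resource, consumer) {
  for (ln in model$links)
    if (ln$resource == resource && ln$consumer == consumer) return(ln)
  stop("no trophic link ", resource, " -> ", consumer, " in model")
}

find_tim <- function(model, tim_id) {
  for (tm in model$tims) if (tm$tim_id == tim_id) return(tm)
  stop("no TIM with id '", tim_id, "' in model (available: ",
       paste(vapply(model$tims, `[[`, "", "tim_id"), collapse = ", "), ")")
}

#' Construct a state vector
#'
#' @param model A \code{community_model}.
#' @param densities Numeric vector of densities, either unnamed (aligned with
#'   \code{model$species_order}) or named by species id.
#' @return Named numeric vector aligned with the model's species order.
#' @export
state_vector <- function(model, densities) {
  n <- length(model$species_order)
  if (!is.null(names(densities))) {
    if (!setequal(names(densities), model$species_order))
      stop("state names do not match species_order")
    densities <- densities[model$species_order]
  } else if (length(densities) != n) {
    stop("state length ", length(densities), " != ", n, " species")
  }
  if (any(!is.finite(densities)) || any(densities < 0))
    stop("densities must be finite and >= 0")
  stats::setNames(as.numeric(densities), model$species_order)
}

#' Evaluate a TIM's modification term
#'
#' Computes the multiplier \eqn{f(c, k)} applied to the target functional
#' response parameter, given the modifier density \code{k}. See
#' \code{\link{tim_spec}} for the form catalogue. The term is exactly 1 when
#' \code{strength == 0} for every form.
#'
#' @param tim A \code{\link{tim_spec}}.
#' @param modifier_density Modifier density k (>= 0).
#' @return A single non-negative multiplier (strictly positive for all forms
#'   except \code{linear_clipped}, which can clip to 0).
#' @export
modification_term <- function(tim, modifier_density) {
  k <- modifier_density
  if (!is.finite(k) || k < 0) stop("modifier_density must be finite and >= 0")
  c_ <- tim$strength
  val <- switch(tim$form,
    exponential = exp(c_ * k),
    linear_clipped = max(0, 1 + c_ * k),
    hyperbolic = if (c_ >= 0) 1 + c_ * k else 1 / (1 + abs(c_) * k),
    sigmoid = {
      m <- tim$form_params$midpoint; s <- tim$form_params$steepness
      if (k == 0) 1 else 1 + c_ * k^s / (k^s + m^s)
    },
    stop("unknown TIM form: ", tim$form))
  if (!is.finite(val)) stop("non-finite modification term (c=", c_,
                            ", k=", k, ", form=", tim$form, ")")
  val
}

# modifier density of a TIM at a state (forced or dynamic)
tim_modifier_density <- function(model, tim, state) {
  if (tim$mode == "forced") tim$forced_density
  else unname(state[[species_index(model, tim$modifier)]])
}

#' Combined modification of several TIMs on one link
#'
#' Multiple TIMs acting on the same functional response parameter of the same
#' link combine multiplicatively: the total multiplier is the product of the
#' individual modification terms (an empty list gives 1). The combiner is a
#' single function so that alternative combination hypotheses can be swapped
#' in.
#'
#' @param model A \code{community_model} (used to resolve dynamic modifier
#'   densities).
#' @param tims_on_link List of \code{\link{tim_spec}} objects targeting the
#'   same link and the same affected parameter.
#' @param state State vector (see \code{\link{state_vector}}).
#' @return A single non-negative multiplier.
#' @export
combined_modification <- function(model, tims_on_link, state) {
  if (length(tims_on_link) == 0L) return(1)
  pars <- unique(vapply(tims_on_link, `[[`, "", "affected_parameter"))
  keys <- unique(vapply(tims_on_link, function(t)
    paste(t$resource, t$consumer), ""))
  if (length(pars) > 1L || length(keys) > 1L)
    stop("combined_modification: TIMs must share one link and one ",
         "affected_parameter")
  prod(vapply(tims_on_link, function(tm)
    modification_term(tm, tim_modifier_density(model, tm, state)), 0))
}

# TIMs targeting a given link and parameter, optionally excluding one focal
# TIM (used by the flux-change metric, which forces the focal term to 1)
tims_for <- function(model, link, param, exclude_tim = NULL) {
  Filter(function(tm)
    tm$resource == link$resource && tm$consumer == link$consumer &&
      tm$affected_parameter == param &&
      (is.null(exclude_tim) || tm$tim_id != exclude_tim),
    model$tims)
}

# effective (TIM-modified) functional response parameters of a link
effective_link_params <- function(model, link, state, exclude_tim = NULL) {
  mods <- vapply(c("attack_rate", "handling_time", "interference"),
                 function(p) {
                   tms <- tims_for(model, link, p, exclude_tim)
                   if (length(tms)) combined_modification(model, tms, state)
                   else 1
                 }, 0)
  list(a = link$attack_rate * mods[["attack_rate"]],
       h = link$handling_time * mods[["handling_time"]],
       w = link$interference * mods[["interference"]])
}

#' Biomass flux through a trophic link
#'
#' Total biomass flux per unit time from resource to consumer, with all TIMs
#' targeting the link applied (each affected parameter scaled by its combined
#' modification term).
#'
#' @param model A \code{community_model}.
#' @param link A \code{\link{trophic_link}} belonging to the model, or a
#'   character vector \code{c(resource, consumer)}.
#' @param state State vector.
#' @param exclude_tim Optional TIM id whose modification term is forced to 1
#'   (its modifier's trophic role is unaffected).
#' @return Non-negative flux (biomass density per time).
#' @export
link_flux <- function(model, link, state, exclude_tim = NULL) {
  if (is.character(link)) link <- find_link(model, link[1], link[2])
  state <- state_vector(model, state)
  R <- unname(state[[species_index(model, link$resource)]])
  C <- unname(state[[species_index(model, link$consumer)]])
  p <- effective_link_params(model, link, state, exclude_tim)
  switch(link$fr_form,
         linear = p$a * R * C,
         holling2 = p$a * R * C / (1 + p$a * p$h * R),
         holling2_interference =
           p$a * R * C / (1 + p$a * p$h * R + p$w * C))
}

#' Per-species rates of density change
#'
#' Evaluates the model's ODE right-hand side at a state: logistic growth for
#' producers, linear mortality (plus optional self-limitation) for consumers,
#' and TIM-modified functional response fluxes along every trophic link.
#'
#' @param model A \code{community_model}.
#' @param state State vector (non-negative densities).
#' @return Named numeric vector of per-species rates, aligned with
#'   \code{model$species_order}.
#' @export
rhs <- function(model, state) {
  state <- state_vector(model, state)
  n <- length(model$species_order)
  out <- numeric(n)
  for (ix in seq_len(n)) {
    sp <- model$species[[ix]]
    N <- unname(state[[ix]])
    out[ix] <- if (sp$role == "producer")
      N * (sp$intrinsic_rate - sp$self_limitation * N)
    else
      -sp$intrinsic_rate * N - sp$self_limitation * N^2
  }
  for (ln in model$links) {
    fl <- link_flux(model, ln, state)
    ir <- species_index(model, ln$resource)
    ic <- species_index(model, ln$consumer)
    out[ir] <- out[ir] - fl
    out[ic] <- out[ic] + ln$conversion_efficiency * fl
  }
  if (any(!is.finite(out)))
    stop("non-finite rate in rhs evaluation")
  stats::setNames(out, model$species_order)
}

#' Remove all TIMs (or zero their strengths)
#'
#' @param model A \code{community_model}.
#' @return The model with \code{tims} emptied.
#' @export
strip_tims <- function(model) {
  model$tims <- list()
  model
}

#' Set the strength of one or all TIMs
#'
#' @param model A \code{community_model}.
#' @param strength New value(s) of the modification parameter c.
#' @param tim_id TIM to update; NULL updates all TIMs.
#' @return The updated model.
#' @export
set_tim_strength <- function(model, strength, tim_id = NULL) {
  for (i in seq_along(model$tims)) {
    if (is.null(tim_id) || model$tims[[i]]$tim_id == tim_id)
      model$tims[[i]]$strength <- as.numeric(strength)
  }
  if (!is.null(tim_id) &&
      !tim_id %in% vapply(model$tims, `[[`, "", "tim_id"))
    stop("no TIM with id '", tim_id, "'")
  model
}
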