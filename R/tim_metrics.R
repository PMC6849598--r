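# Metrics of TIM strength. Indices follow the field's convention:
# i = prey/resource, j = predator/consumer, k = modifier.
#
# All derivative-based metrics are direct partials: the modifier density K
# is perturbed as a coordinate at the evaluation state, with no
# re-equilibration. Equilibrium-shift effects are explored separately with
# sweep_tim_parameter().

#' Flux change due to a TIM
#'
#' Evaluates the biomass flux through the TIM's target link twice at the same
#' state: once with the focal TIM's modification term forced to 1 (the
#' unmodified flux, "k = 0" in the term only -- other TIMs and the modifier's
#' own trophic role remain active) and once as-is. Returns the ratio
#' \eqn{\Delta_{rel} = f(i,j,k=0) / f(i,j,k)} (unmodified over modified) and
#' the difference \eqn{\Delta_{abs} = f(i,j,k=0) - f(i,j,k)}.
#'
#' @param model A \code{community_model}.
#' @param tim A \code{tim_spec} in the model, or its id.
#' @param state State vector.
#' @return List with \code{flux_ratio}, \code{flux_difference},
#'   \code{flux_unmodified}, \code{flux_modified} and \code{ratio_infinite}
#'   (flag set when the modified flux is 0 with nonzero unmodified flux).
#' @export
metric_flux_change <- function(model, tim, state) {
  tim <- resolve_tim(model, tim)
  link <- find_link(model, tim$resource, tim$consumer)
  f_mod <- link_flux(model, link, state)
  f_unmod <- link_flux(model, link, state, exclude_tim = tim$tim_id)
  inf_flag <- (f_mod == 0 && f_unmod != 0)
  ratio <- if (f_mod == 0 && f_unmod == 0) 1 else f_unmod / f_mod
  list(flux_ratio = ratio, flux_difference = f_unmod - f_mod,
       flux_unmodified = f_unmod, flux_modified = f_mod,
       ratio_infinite = inf_flag)
}

#' Change in resource equilibrium (B_CR ratio)
#'
#' The TIM-induced change in the biomass conversion ratio of the modified
#' interaction reduces to the ratio of the resource's equilibrium density
#' with the TIM active over its equilibrium density with the modification
#' parameter set to 0. Both equilibria are solved independently from the same
#' initial guess and must be interior-feasible.
#'
#' @inheritParams metric_flux_change
#' @param guess Shared initial guess for both equilibrium solves.
#' @param ... Passed to \code{\link{find_equilibrium}}.
#' @return Single ratio \eqn{I^* / I^*_{c=0}}.
#' @export
metric_bcr_change <- function(model, tim, guess = NULL, ...) {
  tim <- resolve_tim(model, tim)
  eq_with <- find_equilibrium(model, guess = guess, ...)
  model0 <- set_tim_strength(model, 0, tim$tim_id)
  eq_without <- find_equilibrium(model0, guess = guess, ...)
  for (side in list(list(eq_with, "with the TIM active"),
                    list(eq_without, "with the TIM strength set to 0"))) {
    if (!side[[1]]$converged)
      stop("equilibrium solve ", side[[2]], " did not converge")
    if (!side[[1]]$feasible)
      stop("equilibrium ", side[[2]], " is not interior-feasible")
  }
  ii <- species_index(model, tim$resource)
  unname(eq_with$state[[ii]] / eq_without$state[[ii]])
}

#' TMII metric: direct effect of the modifier on each interactor
#'
#' The pairwise (trait-mediated indirect interaction) metric: the Jacobian
#' entries \eqn{\partial \dot I / \partial K} and
#' \eqn{\partial \dot J / \partial K} -- the direct effect of modifier
#' density on the growth rate of the resource and of the consumer. Requires
#' the modifier to be a state coordinate (dynamic mode).
#'
#' @inheritParams metric_flux_change
#' @param method Differentiation method for the Jacobian.
#' @return Named numeric vector \code{c(dIdot_dK, dJdot_dK)}.
#' @export
metric_tmii <- function(model, tim, state,
                        method = c("symbolic", "finite_difference")) {
  tim <- resolve_tim(model, tim)
  if (tim$mode != "dynamic")
    stop("the TMII (Jacobian element) metric needs the modifier as a state ",
         "coordinate; TIM '", tim$tim_id, "' is forced-mode")
  A <- jacobian(model, state, method = match.arg(method))$entries
  ik <- species_index(model, tim$modifier)
  c(dIdot_dK = A[species_index(model, tim$resource), ik],
    dJdot_dK = A[species_index(model, tim$consumer), ik])
}

#' Sensitivity of the direct interaction to the modifier
#'
#' Mixed second partials of the rhs: the change of the Jacobian entries
#' describing the modified interaction, \eqn{A_{ij} = \partial \dot I /
#' \partial J} and \eqn{A_{ji} = \partial \dot J / \partial I}, with respect
#' to modifier density K -- a direct partial holding all other coordinates
#' fixed. This isolates the TIM's effect on the interaction itself and is 0
#' when no explicit modification is present, regardless of the modifier's
#' trophic links.
#'
#' @inheritParams metric_flux_change
#' @param method \code{"symbolic"} (default) or nested central
#'   \code{"finite_difference"}.
#' @return Named numeric vector \code{c(dAij_dK, dAji_dK)}.
#' @export
metric_jacobian_sensitivity <- function(model, tim, state,
                                        method = c("symbolic",
                                                   "finite_difference")) {
  tim <- resolve_tim(model, tim)
  M <- dA_dK_matrix(model, tim, state, match.arg(method))
  i <- species_index(model, tim$resource)
  j <- species_index(model, tim$consumer)
  c(dAij_dK = M[i, j], dAji_dK = M[j, i])
}

dA_dK_matrix <- function(model, tim, state, method) {
  if (method == "symbolic") dA_dK_symbolic(model, tim, state)
  else dA_dK_fd(model, tim, state)
}

#' Sensitivity of the net (total) interaction to the modifier
#'
#' The change of the net-effects matrix entries \eqn{(-A^{-1})_{ij}} and
#' \eqn{(-A^{-1})_{ji}} with respect to modifier density, via the matrix
#' calculus identity \eqn{d(-A^{-1})/dK = A^{-1} (\partial A/\partial K)
#' A^{-1}}. Because indirect pathways are included, this can be nonzero even
#' when the explicit modification parameter is 0, through density-mediated
#' effects of a trophically connected modifier.
#'
#' @inheritParams metric_jacobian_sensitivity
#' @param max_condition Condition-number threshold for the Jacobian inverse.
#' @return Named numeric vector \code{c(dNij_dK, dNji_dK)}.
#' @export
metric_net_sensitivity <- function(model, tim, state,
                                   method = c("symbolic",
                                              "finite_difference"),
                                   max_condition = 1e12) {
  tim <- resolve_tim(model, tim)
  method <- match.arg(method)
  A <- jacobian(model, state, method = method)$entries
  kap <- tryCatch(kappa(A, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > max_condition)
    stop("Jacobian ill-conditioned (condition ", format(kap),
         "); net sensitivity undefined")
  Ainv <- solve(A)
  dA <- dA_dK_matrix(model, tim, state, method)
  dN <- Ainv %*% dA %*% Ainv
  i <- species_index(model, tim$resource)
  j <- species_index(model, tim$consumer)
  c(dNij_dK = dN[i, j], dNji_dK = dN[j, i])
}

#' Coefficient of variation of the modification term along a trajectory
#'
#' For non-stationary systems: the ratio of the standard deviation of the
#' modification term to its mean, over a stated time window. Time-weighted
#' (trapezoidal) moments are used so irregular solver grids are handled. Can
#' also report the CV of the target link's flux under the same contract.
#'
#' @inheritParams metric_flux_change
#' @param trajectory A \code{trajectory} from \code{\link{simulate_model}}.
#' @param window Length-2 numeric time window; default discards the first
#'   half of the trajectory span as transient.
#' @param of \code{"modification"} (the term f(c, k(t))) or \code{"flux"}.
#' @param mean_tol Means smaller than this in absolute value make the CV
#'   undefined.
#' @return The coefficient of variation (sd/mean).
#' @export
metric_cv <- function(model, tim, trajectory, window = NULL,
                      of = c("modification", "flux"), mean_tol = 1e-12) {
  tim <- resolve_tim(model, tim)
  of <- match.arg(of)
  tt <- trajectory$times
  if (is.null(window))
    window <- c(tt[1] + 0.5 * (tt[length(tt)] - tt[1]), tt[length(tt)])
  keep <- tt >= window[1] & tt <= window[2]
  if (sum(keep) < 3L) stop("window contains too few trajectory points")
  tt <- tt[keep]
  S <- trajectory$states[keep, , drop = FALSE]
  vals <- vapply(seq_along(tt), function(r) {
    st <- state_vector(model, pmax(S[r, ], 0))
    if (of == "modification")
      modification_term(tim, tim_modifier_density(model, tim, st))
    else link_flux(model, c(tim$resource, tim$consumer), st)
  }, 0)
  mu <- trapz_mean(tt, vals)
  if (abs(mu) < mean_tol)
    stop("mean of the series is below tolerance; CV undefined")
  sig <- sqrt(max(0, trapz_mean(tt, (vals - mu)^2)))
  sig / mu
}

# time-weighted (trapezoidal) average of a sampled series
trapz_mean <- function(t, y) {
  dt <- diff(t)
  sum(dt * (y[-1] + y[-length(y)]) / 2) / (t[length(t)] - t[1])
}

resolve_tim <- function(model, tim) {
  if (is.character(tim)) find_tim(model, tim) else tim
}

#' Compute the full metric suite for one TIM
#'
#' Evaluates every applicable TIM-strength metric at the requested context
#' and assembles a \code{metric_report}. Inapplicable fields are absent
#' (NULL), not zero; per-metric failures are caught and recorded in
#' \code{$errors} without aborting the whole report.
#'
#' @param model A \code{community_model}.
#' @param tim A \code{tim_spec} or its id.
#' @param at Context: \code{"equilibrium"} (solve for the interior fixed
#'   point; no CV), \code{"state"} (user-supplied state; no CV) or
#'   \code{"trajectory"} (state-based metrics at the trajectory endpoint,
#'   plus the CV over its late window).
#' @param state State vector (required for \code{at = "state"}).
#' @param trajectory A \code{trajectory} (required for
#'   \code{at = "trajectory"}).
#' @param guess Initial guess for equilibrium solves.
#' @param method Differentiation method for derivative metrics.
#' @param ... Passed to \code{\link{find_equilibrium}}.
#' @return A \code{metric_report} (list; see fields in the source and
#'   \code{\link{metric_report_row}}).
#' @export
compute_all_metrics <- function(model, tim,
                                at = c("equilibrium", "state", "trajectory"),
                                state = NULL, trajectory = NULL, guess = NULL,
                                method = "symbolic", ...) {
  at <- match.arg(at)
  tim <- resolve_tim(model, tim)
  errors <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  if (at == "equilibrium") {
    eq <- find_equilibrium(model, guess = guess, ...)
    if (!eq$converged || !eq$feasible)
      stop("no feasible interior equilibrium found (converged = ",
           eq$converged, ", feasible = ", eq$feasible, ")")
    state <- eq$state
  } else if (at == "trajectory") {
    if (is.null(trajectory)) stop("trajectory context needs a trajectory")
    state <- state_vector(model,
                          pmax(trajectory$states[nrow(trajectory$states), ],
                               0))
  } else if (is.null(state)) {
    stop("state context needs a state")
  }
  state <- state_vector(model, state)
  k_now <- grab("modification_term",
                tim_modifier_density(model, tim, state))
  fc <- grab("flux_change", metric_flux_change(model, tim, state))
  report <- list(
    tim_id = tim$tim_id,
    context = at,
    evaluation_state = state,
    modification_parameter = tim$strength,
    modification_term = if (!is.null(k_now))
      grab("modification_term", modification_term(tim, k_now)) else NULL,
    flux_ratio = fc$flux_ratio,
    flux_difference = fc$flux_difference,
    bcr_change = grab("bcr_change",
                      metric_bcr_change(model, tim, guess = guess, ...)),
    cv_modification = if (at == "trajectory")
      grab("cv_modification", metric_cv(model, tim, trajectory)) else NULL,
    tmii_pair = if (tim$mode == "dynamic")
      grab("tmii_pair", metric_tmii(model, tim, state, method)) else NULL,
    jacobian_sensitivity_pair =
      grab("jacobian_sensitivity_pair",
           metric_jacobian_sensitivity(model, tim, state, method)),
    net_sensitivity_pair =
      grab("net_sensitivity_pair",
           metric_net_sensitivity(model, tim, state, method)),
    settings = list(method = method, at = at))
  report$errors <- errors
  class(report) <- "metric_report"
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat("TIM metric report for '", x$tim_id, "' (context: ", x$context,
      ")\n", sep = "")
  print(metric_report_row(x))
  if (length(x$errors))
    cat("field errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a metric report to a one-row data frame
#'
#' Column names are fixed: \code{tim_id}, \code{context},
#' \code{modification_parameter}, \code{modification_term},
#' \code{flux_ratio}, \code{flux_difference}, \code{bcr_change},
#' \code{cv_modification}, \code{dIdot_dK}, \code{dJdot_dK}, \code{dAij_dK},
#' \code{dAji_dK}, \code{dNij_dK}, \code{dNji_dK}. Absent fields are NA.
#'
#' @param report A \code{metric_report}.
#' @return A one-row \code{data.frame}.
#' @export
metric_report_row <- function(report) {
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  pair <- function(x, n) if (is.null(x)) NA_real_ else unname(x[[n]])
  data.frame(
    tim_id = report$tim_id,
    context = report$context,
    modification_parameter = num(report$modification_parameter),
    modification_term = num(report$modification_term),
    flux_ratio = num(report$flux_ratio),
    flux_difference = num(report$flux_difference),
    bcr_change = num(report$bcr_change),
    cv_modification = num(report$cv_modification),
    dIdot_dK = pair(report$tmii_pair, "dIdot_dK"),
    dJdot_dK = pair(report$tmii_pair, "dJdot_dK"),
    dAij_dK = pair(report$jacobian_sensitivity_pair, "dAij_dK"),
    dAji_dK = pair(report$jacobian_sensitivity_pair, "dAji_dK"),
    dNij_dK = pair(report$net_sensitivity_pair, "dNij_dK"),
    dNji_dK = pair(report$net_sensitivity_pair, "dNji_dK"),
    stringsAsFactors = FALSE)
}

#' Serialise a metric report to JSON
#'
#' @param report A \code{metric_report}.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @export
metric_report_json <- function(report, path = NULL) {
  payload <- report
  class(payload) <- NULL
  payload$evaluation_state <- as.list(payload$evaluation_state)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
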