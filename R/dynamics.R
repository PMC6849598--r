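#' Integrate a community model trajectory
#'
#' Stiff-capable integration (\code{deSolve::ode}, lsoda) of the model's
#' dynamics. Densities are clamped at 0: the rhs is evaluated on the clamped
#' state and a species at the boundary with a negative rate is held at 0;
#' clamp events are counted in \code{solver_info}.
#'
#' @param model A \code{community_model}.
#' @param initial Initial state.
#' @param t_span Length-2 numeric \code{c(t0, t1)}.
#' @param n_steps Number of output points (uniform grid).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param method deSolve method name.
#' @return A \code{trajectory}: list with \code{times} (vector),
#'   \code{states} (matrix, one column per species) and \code{solver_info}.
#' @export
simulate_model <- function(model, initial, t_span, n_steps = 1000,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  initial <- state_vector(model, initial)
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  clamp_events <- 0L
  deriv <- function(t, y, parms) {
    yc <- pmax(y, 0)
    if (any(y < 0)) clamp_events <<- clamp_events + 1L
    dy <- unname(rhs(model, yc))
    dy[yc <= 0 & dy < 0] <- 0
    list(dy)
  }
  times <- seq(t_span[1], t_span[2], length.out = n_steps + 1L)
  sol <- deSolve::ode(y = unname(initial), times = times, func = deriv,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed at t = ", max(sol[, 1]),
         "; last valid state: ",
         paste(signif(sol[nrow(sol), -1], 6), collapse = ", "))
  states <- pmax(unname(sol[, -1, drop = FALSE]), 0)
  colnames(states) <- model$species_order
  if (any(!is.finite(states))) stop("non-finite state in trajectory")
  structure(list(times = sol[, 1], states = states,
                 solver_info = list(method = method, rtol = rtol, atol = atol,
                                    clamp_events = clamp_events)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d points over t = [%g, %g], %d species\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              ncol(x$states)))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns: \code{time} plus one column per species (header = species ids).
#'
#' @param trajectory A \code{trajectory}.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(time = trajectory$times, trajectory$states,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Classify the asymptotic behaviour of a model
#'
#' Integrates past a transient (the first half of the span) and inspects the
#' late window: \code{extinction} if any species ends below the feasibility
#' tolerance, \code{divergent} if any density exceeds the cap,
#' \code{stable_point} if every species' late relative amplitude
#' (peak-to-trough over window mean) is below the threshold and the endpoint
#' is near a root of the rhs. Persistent bounded oscillations are
#' \code{cycling} when the interior equilibrium is decisively unstable and
#' \code{marginal} when its spectrum is neutral (the classic Lotka-Volterra
#' centre).
#'
#' @param model A \code{community_model}.
#' @param initial Initial state.
#' @param t_span Integration span; default c(0, 500).
#' @param amp_threshold Relative amplitude above which a species counts as
#'   oscillating (default 1\%).
#' @param div_cap Density cap for divergence (default 1e8).
#' @param feas_tol Extinction threshold on final densities.
#' @param ... Passed to \code{\link{simulate_model}}.
#' @return List with \code{classification}, \code{trajectory},
#'   \code{amplitudes} and (when computed) \code{equilibrium}.
#' @export
classify_dynamics <- function(model, initial, t_span = c(0, 500),
                              amp_threshold = 0.01, div_cap = 1e8,
                              feas_tol = 1e-8, ...) {
  tr <- simulate_model(model, initial, t_span, ...)
  late <- tr$times >= t_span[1] + 0.5 * diff(t_span)
  S <- tr$states[late, , drop = FALSE]
  final <- S[nrow(S), ]
  out <- list(trajectory = tr, equilibrium = NULL)
  if (any(S > div_cap)) {
    out$classification <- "divergent"
    return(out)
  }
  if (any(final < feas_tol)) {
    out$classification <- "extinction"
    return(out)
  }
  mid <- apply(S, 2, mean)
  amp <- (apply(S, 2, max) - apply(S, 2, min)) / pmax(mid, feas_tol)
  out$amplitudes <- amp
  if (all(amp < amp_threshold)) {
    resid <- max(abs(rhs(model, pmax(final, 0))))
    out$classification <- if (resid < 1e-4) "stable_point" else "marginal"
    return(out)
  }
  # persistent oscillation: let the interior equilibrium's spectrum decide
  eq <- find_equilibrium(model, guess = mid)
  out$equilibrium <- eq
  out$classification <- if (eq$converged && eq$feasible) {
    switch(eq$stability, unstable = "cycling", marginal = "marginal",
           stable = "marginal")
  } else "cycling"
  out
}

#' Static replacement of a TIM
#'
#' Replaces a dynamic modification by a fixed parameter change: the focal TIM
#' is removed and the affected functional response parameter of its target
#' link is multiplied by the modification term evaluated at the reference
#' state's modifier density. The original and replaced vector fields agree
#' exactly at the reference state, so a shared equilibrium is preserved --
#' but their Jacobians generally differ.
#'
#' @param model A \code{community_model}.
#' @param tim A \code{tim_spec} in the model, or its id.
#' @param reference_state Reference state (normally the interior
#'   equilibrium).
#' @return A new \code{community_model} with the TIM statically absorbed.
#' @export
static_replacement <- function(model, tim, reference_state) {
  tim <- resolve_tim(model, tim)
  reference_state <- state_vector(model, reference_state)
  term <- modification_term(tim,
                            tim_modifier_density(model, tim, reference_state))
  for (i in seq_along(model$links)) {
    ln <- model$links[[i]]
    if (ln$resource == tim$resource && ln$consumer == tim$consumer) {
      field <- tim$affected_parameter
      model$links[[i]][[field]] <- ln[[field]] * term
    }
  }
  model$tims <- Filter(function(tm) tm$tim_id != tim$tim_id, model$tims)
  model
}

#' Scan TIM strength for stabilisation of a cycling system
#'
#' For each strength c in the grid, sets the focal TIM's modification
#' parameter, classifies the asymptotic dynamics, and (when an interior
#' equilibrium exists) records the leading eigenvalue real part. Warns when
#' the c = 0 system is not cycling.
#'
#' @param model A \code{community_model} that cycles at c = 0.
#' @param tim A \code{tim_spec} or its id.
#' @param c_grid Ordered numeric grid of strengths.
#' @param initial Initial state for classification runs.
#' @param ... Passed to \code{\link{classify_dynamics}}.
#' @return A \code{data.frame} with columns \code{c},
#'   \code{classification}, \code{leading_re} (NA where no interior
#'   equilibrium), \code{eq_feasible}.
#' @export
stabilization_scan <- function(model, tim, c_grid, initial, ...) {
  tim <- resolve_tim(model, tim)
  rows <- lapply(c_grid, function(cc) {
    m <- set_tim_strength(model, cc, tim$tim_id)
    cl <- classify_dynamics(m, initial, ...)
    endpoint <- cl$trajectory$states[nrow(cl$trajectory$states), ]
    eq <- if (!is.null(cl$equilibrium)) cl$equilibrium
          else find_equilibrium(m, guess = pmax(endpoint, 1e-6))
    lead <- if (eq$converged && eq$feasible && length(eq$eigenvalues))
      max(Re(eq$eigenvalues)) else NA_real_
    data.frame(c = cc, classification = cl$classification,
               leading_re = lead,
               eq_feasible = eq$converged && eq$feasible,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (0 %in% c_grid &&
      tab$classification[match(0, tab$c)] != "cycling")
    warning("system is not classified as cycling at c = 0")
  tab
}
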