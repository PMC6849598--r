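# central-difference step: cube-root(machine eps) scaling per coordinate
fd_step <- function(x) .Machine$double.eps^(1/3) * max(abs(x), 1)

# finite-difference Jacobian of rhs; one-sided (forward) at the clamp
# boundary, since densities below 0 are outside the model's domain
jacobian_fd_matrix <- function(model, state) {
  state <- state_vector(model, state)
  n <- length(state)
  A <- matrix(0, n, n, dimnames = list(model$species_order,
                                       model$species_order))
  boundary <- FALSE
  for (j in seq_len(n)) {
    h <- fd_step(state[[j]])
    if (state[[j]] - h < 0) {
      boundary <- TRUE
      sp <- sm <- state
      sp[j] <- state[[j]] + h
      A[, j] <- (rhs(model, sp) - rhs(model, state)) / h
    } else {
      sp <- sm <- state
      sp[j] <- state[[j]] + h
      sm[j] <- state[[j]] - h
      A[, j] <- (rhs(model, sp) - rhs(model, sm)) / (2 * h)
    }
  }
  if (boundary)
    warning("state on the clamp boundary (density ~ 0): one-sided ",
            "differences used")
  A
}

#' Community (Jacobian) matrix at a state
#'
#' The community matrix A has entries \eqn{A_{xy} = \partial \dot N_x /
#' \partial N_y}: the partial derivatives of each species' rate of density
#' change with respect to each species' density, at the evaluation state.
#'
#' @param model A \code{community_model}.
#' @param state State vector.
#' @param method \code{"symbolic"} differentiates the closed-form rhs;
#'   \code{"finite_difference"} uses central differences with per-coordinate
#'   step \eqn{\epsilon^{1/3} \max(|x|, 1)} (one-sided at the density-0
#'   boundary, with a warning).
#' @return A \code{community_matrix} object (list with \code{entries},
#'   \code{species_order}, \code{evaluation_state}, \code{kind}).
#' @export
jacobian <- function(model, state,
                     method = c("symbolic", "finite_difference")) {
  method <- match.arg(method)
  state <- state_vector(model, state)
  A <- if (method == "symbolic") jacobian_symbolic_matrix(model, state)
       else jacobian_fd_matrix(model, state)
  community_matrix(A, model$species_order, state, "jacobian")
}

community_matrix <- function(entries, species_order, evaluation_state,
                             kind = c("jacobian", "net_effects")) {
  kind <- match.arg(kind)
  stopifnot(nrow(entries) == ncol(entries),
            nrow(entries) == length(species_order))
  structure(list(entries = entries, species_order = species_order,
                 evaluation_state = evaluation_state, kind = kind),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix (%s), %d species\n", x$kind,
              length(x$species_order)))
  print(x$entries)
  invisible(x)
}

#' Net-effects matrix
#'
#' The inverse negative Jacobian \eqn{-A^{-1}}: the combined direct and
#' indirect (press-perturbation) effects between all species pairs.
#'
#' @param A A \code{community_matrix} of kind \code{"jacobian"}.
#' @param max_condition Condition number above which the Jacobian is treated
#'   as singular.
#' @return A \code{community_matrix} of kind \code{"net_effects"}.
#' @export
net_effects <- function(A, max_condition = 1e12) {
  stopifnot(inherits(A, "community_matrix"), A$kind == "jacobian")
  kap <- tryCatch(kappa(A$entries, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > max_condition)
    stop("Jacobian matrix is singular or ill-conditioned (condition ",
         format(kap), "); net-effects matrix undefined")
  N <- -solve(A$entries)
  community_matrix(N, A$species_order, A$evaluation_state, "net_effects")
}

#' Classify local stability from a Jacobian spectrum
#'
#' @param eigenvalues Complex (or numeric) eigenvalues of the community
#'   matrix at a fixed point.
#' @param margin Real parts within \code{margin} of zero are treated as
#'   neutral; separates the classic neutrally stable Lotka-Volterra centre
#'   from decisive classifications.
#' @return One of \code{"stable"}, \code{"unstable"}, \code{"marginal"}.
#' @export
classify_stability <- function(eigenvalues, margin = 1e-7) {
  if (length(eigenvalues) == 0L) stop("empty spectrum")
  re <- Re(eigenvalues)
  if (any(!is.finite(re))) stop("non-finite eigenvalue")
  if (all(re < -margin)) "stable"
  else if (any(re > margin)) "unstable"
  else "marginal"
}

#' Locate a fixed point of the community dynamics
#'
#' Damped Newton iteration on \code{rhs = 0} from the supplied guess, with
#' seeded random restarts (log-uniform positive guesses) when the iteration
#' fails or leaves the positive orthant. Non-convergence is reported in the
#' result, never silently.
#'
#' @param model A \code{community_model}.
#' @param guess Initial state; defaults to all densities 1.
#' @param tol Residual tolerance on \eqn{\max |\dot N|}.
#' @param max_iter Newton iterations per start.
#' @param restarts Number of random restarts after the initial guess fails.
#' @param feas_tol Densities above this count as non-extinct (feasibility).
#' @param seed Seed for the restart generator.
#' @param guess_range Log-uniform range for restart guesses.
#' @return An \code{equilibrium_result}: list with \code{state},
#'   \code{residual_norm}, \code{eigenvalues}, \code{stability},
#'   \code{feasible}, \code{converged}.
#' @export
find_equilibrium <- function(model, guess = NULL, tol = 1e-10,
                             max_iter = 100, restarts = 20,
                             feas_tol = 1e-8, seed = 1,
                             guess_range = c(1e-2, 1e2)) {
  n <- length(model$species_order)
  if (is.null(guess)) guess <- rep(1, n)
  guess <- state_vector(model, guess)
  starts <- list(unname(guess))
  # log-uniform restarts from a seeded stream, global RNG state preserved
  starts <- c(starts, with_preserved_rng(seed, function()
    lapply(seq_len(restarts), function(r)
      exp(stats::runif(n, log(guess_range[1]), log(guess_range[2]))))))
  feasible_pt <- function(x) all(x > feas_tol)
  best <- NULL        # converged feasible > converged > lowest residual
  rank_of <- function(r)
    if (r$converged && feasible_pt(r$x)) 3 else if (r$converged) 2 else 1
  # a guess that is already a fixed point (e.g. the origin) is returned
  # as-is; otherwise restarts also fire on convergence to a boundary
  # (extinction) root, since the interior root is the target
  f0 <- tryCatch(max(abs(rhs(model, guess))), error = function(e) Inf)
  if (f0 < tol) {
    best <- list(x = unname(guess), residual = f0, converged = TRUE)
  } else {
    for (s in starts) {
      res <- newton_solve(model, s, tol, max_iter)
      if (is.null(best) || rank_of(res) > rank_of(best) ||
          (rank_of(res) == rank_of(best) && res$residual < best$residual))
        best <- res
      if (rank_of(best) == 3) break
    }
    if (rank_of(best) < 3) {
      # dynamics-informed fallback: a short integration from the guess
      # lands near the attractor, whose mean/endpoint seed Newton inside
      # the interior root's basin when one exists
      tr <- tryCatch(simulate_model(model, guess, c(0, 200), n_steps = 100,
                                    rtol = 1e-6, atol = 1e-8),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        late <- tr$states[tr$times >= 100, , drop = FALSE]
        for (s in list(pmax(tr$states[nrow(tr$states), ], 0),
                       pmax(colMeans(late), 0))) {
          res <- newton_solve(model, s, tol, max_iter)
          if (rank_of(res) > rank_of(best) ||
              (rank_of(res) == rank_of(best) && res$residual < best$residual))
            best <- res
          if (rank_of(best) == 3) break
        }
      }
    }
  }
  st <- state_vector(model, pmax(best$x, 0))
  eig <- tryCatch(eigen(jacobian_fd_matrix(model, st),
                        only.values = TRUE)$values,
                  error = function(e) complex(0), warning = function(w)
                    suppressWarnings(eigen(jacobian_fd_matrix(model, st),
                                           only.values = TRUE)$values))
  structure(list(state = st,
                 residual_norm = best$residual,
                 eigenvalues = eig,
                 stability = if (length(eig)) classify_stability(eig)
                             else NA_character_,
                 feasible = all(st > feas_tol),
                 converged = best$converged),
            class = "equilibrium_result")
}

newton_solve <- function(model, x, tol, max_iter) {
  x <- pmax(as.numeric(x), 0)
  f <- tryCatch(unname(rhs(model, x)), error = function(e) NULL)
  if (is.null(f)) return(list(x = x, residual = Inf, converged = FALSE))
  for (it in seq_len(max_iter)) {
    res <- max(abs(f))
    if (res < tol) return(list(x = x, residual = res, converged = TRUE))
    J <- suppressWarnings(tryCatch(jacobian_fd_matrix(model, x),
                                   error = function(e) NULL))
    if (is.null(J)) break
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # damped line search; steps that would leave the positive orthant are
    # shrunk rather than clamped, so the absorbing origin (an exact root)
    # cannot swallow iterates aimed at the interior root
    lambda <- 1
    improved <- FALSE
    for (ls in 1:30) {
      xn <- x + lambda * step
      if (all(xn >= 0)) {
        fn <- tryCatch(unname(rhs(model, xn)), error = function(e) NULL)
        if (!is.null(fn) && max(abs(fn)) < max(abs(f))) {
          x <- xn; f <- fn; improved <- TRUE; break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(x = x, residual = max(abs(f)), converged = max(abs(f)) < tol)
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Equilibrium result (converged:", x$converged,
      "| feasible:", x$feasible, "| stability:", x$stability, ")\n")
  print(x$state)
  cat("residual_norm:", format(x$residual_norm), "\n")
  invisible(x)
}

#' Export a community matrix to CSV
#'
#' Writes a square CSV with species ids as header row and first column.
#'
#' @param x A \code{community_matrix}.
#' @param path Output file path.
#' @export
write_matrix_csv <- function(x, path) {
  stopifnot(inherits(x, "community_matrix"))
  df <- data.frame(species = x$species_order, x$entries,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
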