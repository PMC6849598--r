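# Demonstration systems, the TIM-strength sweep engine, seeded random model
# fixtures, and the multi-level functional response experiment generator and
# fitter.
#
# Demo parameter values are package constants, chosen so that every demo
# admits a feasible, locally stable interior equilibrium at c = 0 (a
# property the test suite re-verifies rather than assumes).

demo_defaults <- list(
  chain_linear = list(
    r = 1.0, plant_self_lim = 0.05, pred_self_lim = 0,
    a1 = 0.5, a2 = 0.4, eps1 = 0.5, eps2 = 0.5, d1 = 0.1, d2 = 0.1,
    tim_strength = 0.5),
  chain_nonlinear = list(
    r = 1.0, plant_self_lim = 0.2, pred_self_lim = 0,
    a1 = 0.5, a2 = 0.4, h1 = 0.1, h2 = 0.1,
    eps1 = 0.5, eps2 = 0.5, d1 = 0.1, d2 = 0.1,
    tim_strength = 0.5),
  aphid_parasitoid = list(
    r1 = 1.0, r2 = 1.0, host_self_lim = 0.2,
    a1 = 0.8, a2 = 0.8, eps = 0.3, d = 0.2,
    tim_strength = -0.5)
)

#' Build a named demonstration system
#'
#' Three stock systems used throughout the package:
#' \describe{
#'   \item{chain_linear}{Plant-herbivore-predator chain with linear (type I)
#'     consumption and an exponential TIM in which the predator's density
#'     modifies the plant-herbivore attack rate.}
#'   \item{chain_nonlinear}{The same topology with Holling type II links.}
#'   \item{aphid_parasitoid}{Two logistic hosts sharing one parasitoid
#'     (mass-action parasitism), with a TIM from host 1's density onto the
#'     parasitoid's attack on host 2 -- the structure of classic
#'     host-parasitoid interaction-modification experiments.}
#' }
#' Each uses package-default parameters verified (in the test suite) to
#' admit a feasible stable interior equilibrium at c = 0. The TIM on each
#' demo is \code{"T1"}, affecting the attack rate, exponential form.
#'
#' @param name One of \code{"chain_linear"}, \code{"chain_nonlinear"},
#'   \code{"aphid_parasitoid"}.
#' @param overrides Named list replacing individual default parameters
#'   (names must exist in the defaults); see
#'   \code{timweb:::demo_defaults} for the parameter names.
#' @param tim_affected_parameter Which functional response parameter the
#'   demo TIM modifies (exposed as configuration; \code{"attack_rate"} by
#'   default).
#' @return A \code{community_model}.
#' @export
build_demo <- function(name = c("chain_linear", "chain_nonlinear",
                                "aphid_parasitoid"),
                       overrides = list(),
                       tim_affected_parameter = "attack_rate") {
  if (!is.character(name) || !name[1] %in% names(demo_defaults))
    stop("unknown demo '", name[1], "'; options: ",
         paste(names(demo_defaults), collapse = ", "))
  name <- name[1]
  p <- demo_defaults[[name]]
  bad <- setdiff(names(overrides), names(p))
  if (length(bad))
    stop("unknown demo parameter(s): ", paste(bad, collapse = ", "))
  p[names(overrides)] <- overrides
  if (name %in% c("chain_linear", "chain_nonlinear")) {
    fr <- if (name == "chain_linear") "linear" else "holling2"
    h1 <- if (name == "chain_linear") 0 else p$h1
    h2 <- if (name == "chain_linear") 0 else p$h2
    community_model(
      species = list(
        species_spec("P", p$r, p$plant_self_lim, "producer", "plant"),
        species_spec("H", p$d1, 0, "consumer", "herbivore"),
        species_spec("C", p$d2, p$pred_self_lim, "consumer", "predator")),
      links = list(
        trophic_link("P", "H", fr, p$a1, h1,
                     conversion_efficiency = p$eps1),
        trophic_link("H", "C", fr, p$a2, h2,
                     conversion_efficiency = p$eps2)),
      tims = list(
        tim_spec("T1", "C", "P", "H",
                 affected_parameter = tim_affected_parameter,
                 form = "exponential", strength = p$tim_strength)))
  } else {
    community_model(
      species = list(
        species_spec("H1", p$r1, p$host_self_lim, "producer", "host 1"),
        species_spec("H2", p$r2, p$host_self_lim, "producer", "host 2"),
        species_spec("W", p$d, 0, "consumer", "parasitoid")),
      links = list(
        trophic_link("H1", "W", "linear", p$a1,
                     conversion_efficiency = p$eps),
        trophic_link("H2", "W", "linear", p$a2,
                     conversion_efficiency = p$eps)),
      tims = list(
        tim_spec("T1", "H1", "H2", "W",
                 affected_parameter = tim_affected_parameter,
                 form = "exponential", strength = p$tim_strength)))
  }
}

#' Two-species Lotka-Volterra model with a forced (cue) TIM
#'
#' Resource I (exponential growth r), consumer J (mortality d), linear
#' consumption with attack rate a and efficiency eps, and a forced-mode
#' exponential TIM of strength c at cue density K on the attack rate. The
#' interior equilibrium is available in closed form:
#' \eqn{I^* = d / (\epsilon a e^{cK})}, \eqn{J^* = r / (a e^{cK})}, so the
#' resource-equilibrium ratio with/without the TIM is exactly
#' \eqn{e^{-cK}}.
#'
#' @param r,a,eps,d Demographic and interaction parameters.
#' @param c TIM strength.
#' @param K Forced cue density.
#' @return A \code{community_model}.
#' @export
lv_cue_model <- function(r = 1, a = 0.5, eps = 0.5, d = 0.2, c = 0, K = 0) {
  community_model(
    species = list(species_spec("I", r, 0, "producer", "resource"),
                   species_spec("J", d, 0, "consumer", "consumer")),
    links = list(trophic_link("I", "J", "linear", a,
                              conversion_efficiency = eps)),
    tims = list(tim_spec("T1", NA_character_, "I", "J",
                         form = "exponential", strength = c,
                         mode = "forced", forced_density = K)))
}

#' Rosenzweig-MacArthur demo for TIM-driven stabilisation of cycles
#'
#' An enriched resource-consumer pair (logistic resource, Holling type II
#' consumption) whose interior equilibrium sits past the Hopf point, so the
#' c = 0 system settles on a limit cycle. The TIM makes the consumer's own
#' density reduce its attack rate (exponential form, c < 0), a
#' density-dependent interference that can restabilise the equilibrium.
#'
#' @param c TIM strength (0 gives the cycling baseline).
#' @return A \code{community_model}.
#' @export
build_stabilization_demo <- function(c = 0) {
  community_model(
    species = list(
      species_spec("R", 1.0, 0.05, "producer", "resource"),
      species_spec("C", 0.3, 0, "consumer", "consumer")),
    links = list(
      trophic_link("R", "C", "holling2", attack_rate = 1.0,
                   handling_time = 1.0, conversion_efficiency = 0.5)),
    tims = list(
      tim_spec("T1", "C", "R", "C", form = "exponential", strength = c)))
}

#' Sweep a TIM's strength across a grid
#'
#' For each strength c on the grid the focal TIM is set to c, the interior
#' equilibrium re-solved (continuation: the grid is walked from 0 outward in
#' both directions, each solve seeded with the previous equilibrium) and the
#' full metric suite computed at it. Rows where the solve fails or leaves
#' the feasible interior are flagged and their metric fields are NA.
#'
#' @param model A \code{community_model}.
#' @param tim A \code{tim_spec} or its id.
#' @param c_grid Finite, ordered numeric grid of strengths.
#' @param guess Starting guess for the c closest to 0.
#' @param jump_bound Relative jump in equilibrium densities between adjacent
#'   grid points above which a continuity break is flagged.
#' @param ... Passed to \code{\link{find_equilibrium}}.
#' @return A \code{data.frame} (class \code{sweep_table}) with one row per
#'   grid point: \code{c}, \code{converged}, \code{feasible},
#'   \code{stability}, \code{jump_flag}, equilibrium densities
#'   (\code{eq_<id>}) and all \code{\link{metric_report_row}} columns.
#' @export
sweep_tim_parameter <- function(model, tim, c_grid, guess = NULL,
                                jump_bound = 0.5, ...) {
  tim <- resolve_tim(model, tim)
  stopifnot(all(is.finite(c_grid)), length(c_grid) >= 1)
  # walk from |c| = 0 outward, splitting the two signs into separate arms
  pos_arm <- sort(c_grid[c_grid >= 0])
  neg_arm <- sort(c_grid[c_grid < 0], decreasing = TRUE)
  n_sp <- length(model$species_order)
  results <- list()
  run_arm <- function(arm) {
    g <- guess
    prev_eq <- NULL
    for (cc in arm) {
      m <- set_tim_strength(model, cc, tim$tim_id)
      eq <- find_equilibrium(m, guess = g, ...)
      ok <- eq$converged && eq$feasible
      jump <- FALSE
      if (ok && !is.null(prev_eq)) {
        rel <- abs(eq$state - prev_eq) / pmax(abs(prev_eq), 1e-8)
        jump <- any(rel > jump_bound)
      }
      rep_row <- if (ok)
        metric_report_row(compute_all_metrics(m, tim$tim_id,
                                              at = "equilibrium",
                                              guess = eq$state, ...))
      else metric_report_row(empty_metric_report(tim$tim_id))
      eqd <- if (ok) as.list(eq$state) else
        stats::setNames(as.list(rep(NA_real_, n_sp)), model$species_order)
      names(eqd) <- paste0("eq_", names(eqd))
      row <- cbind(data.frame(c = cc, converged = eq$converged,
                              feasible = eq$feasible,
                              stability = eq$stability,
                              jump_flag = jump, stringsAsFactors = FALSE),
                   as.data.frame(eqd), rep_row[, -(1:2)])
      results[[length(results) + 1L]] <<- row
      if (ok) { g <- eq$state; prev_eq <- eq$state }
    }
  }
  run_arm(pos_arm)
  run_arm(neg_arm)
  tab <- do.call(rbind, results)
  tab <- tab[order(tab$c), ]
  rownames(tab) <- NULL
  attr(tab, "tim_id") <- tim$tim_id
  attr(tab, "model_json") <- model_to_json(model)
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

empty_metric_report <- function(tim_id) {
  structure(list(tim_id = tim_id, context = "equilibrium",
                 modification_parameter = NULL, modification_term = NULL,
                 flux_ratio = NULL, flux_difference = NULL,
                 bcr_change = NULL, cv_modification = NULL,
                 tmii_pair = NULL, jacobian_sensitivity_pair = NULL,
                 net_sensitivity_pair = NULL, errors = list()),
            class = "metric_report")
}

#' Seeded random tri-trophic chain fixture
#'
#' Draws chain parameters from the configured ranges and rejection-samples
#' until the c = 0 model has a feasible, locally stable interior equilibrium
#' (re-verified with \code{\link{find_equilibrium}}). The accepted model
#' carries a TIM of the top predator on the bottom link whose strength is
#' drawn from \code{c_range}. Fully reproducible: same seed and config give
#' the same model.
#'
#' @param seed Integer seed.
#' @param fr_form Functional response form for both links.
#' @param ranges Named list of length-2 parameter ranges: \code{r},
#'   \code{self_lim}, \code{a}, \code{eps}, \code{d}, \code{h} (holling2
#'   only) and \code{c_range}.
#' @param max_attempts Rejection-sampling budget.
#' @return A \code{community_model} with attribute \code{attempts}.
#' @export
generate_random_chain <- function(seed, fr_form = c("linear", "holling2"),
                                  ranges = list(), max_attempts = 200) {
  fr_form <- match.arg(fr_form)
  rg <- utils::modifyList(list(
    r = c(0.5, 1.5), self_lim = c(0.03, 0.1), a = c(0.3, 0.8),
    eps = c(0.3, 0.7), d = c(0.05, 0.15), h = c(0.05, 0.3),
    c_range = c(-0.5, 0.5)), ranges)
  draw <- function(rng) stats::runif(1, rng[1], rng[2])
  with_preserved_rng(seed, function() {
    for (attempt in seq_len(max_attempts)) {
      h1 <- if (fr_form == "holling2") draw(rg$h) else 0
      h2 <- if (fr_form == "holling2") draw(rg$h) else 0
      model <- tryCatch(community_model(
        species = list(
          species_spec("P", draw(rg$r), draw(rg$self_lim), "producer"),
          species_spec("H", draw(rg$d), 0, "consumer"),
          species_spec("C", draw(rg$d), 0, "consumer")),
        links = list(
          trophic_link("P", "H", fr_form, draw(rg$a), h1,
                       conversion_efficiency = draw(rg$eps)),
          trophic_link("H", "C", fr_form, draw(rg$a), h2,
                       conversion_efficiency = draw(rg$eps))),
        tims = list(
          tim_spec("T1", "C", "P", "H", form = "exponential",
                   strength = draw(rg$c_range)))), error = function(e) NULL)
      if (is.null(model)) next
      eq <- find_equilibrium(strip_tims(model), guess = rep(1, 3))
      if (eq$converged && eq$feasible && identical(eq$stability, "stable")) {
        attr(model, "attempts") <- attempt
        return(model)
      }
    }
    stop("generate_random_chain: no feasible stable chain accepted in ",
         max_attempts, " attempts (seed = ", seed, ", fr_form = ", fr_form,
         ")")
  })
}

# per-consumer-capita consumption rate surface for the experiment generator
# and fitter: rate(R, K) with TIM-modified parameters
fr_surface <- function(fr_form, affected_parameter, tim_form, form_params) {
  force(fr_form); force(affected_parameter)
  function(a, h, c_, R, K) {
    tm <- tim_spec("fit", NA_character_, "r", "c",
                   affected_parameter = affected_parameter,
                   form = tim_form, strength = c_,
                   form_params = form_params,
                   mode = "forced", forced_density = 0)
    m <- vapply(K, function(k) modification_term(tm, k), 0)
    a_eff <- if (affected_parameter == "attack_rate") a * m else a
    h_eff <- if (affected_parameter == "handling_time") h * m else h
    switch(fr_form,
           linear = a_eff * R,
           holling2 = a_eff * R / (1 + a_eff * h_eff * R))
  }
}

#' Generate a synthetic multi-level functional response experiment
#'
#' Emulates short-term feeding trials crossing multiple prey densities with
#' multiple modifier densities: the per-consumer consumption rate is the
#' true (TIM-modified) functional response surface times multiplicative
#' lognormal noise in the mean-one parameterisation (so the expected
#' observed rate equals the true rate).
#'
#' @param true_spec List with \code{fr_form} ("linear"/"holling2"),
#'   \code{attack_rate}, \code{handling_time}, \code{tim_form},
#'   \code{strength}, optional \code{form_params} and
#'   \code{affected_parameter}.
#' @param design List with \code{prey_levels}, \code{modifier_levels}
#'   (at least 2 distinct values) and \code{replicates}.
#' @param noise_cv Coefficient of variation of the lognormal noise (0 for a
#'   noiseless surface).
#' @param seed Integer seed.
#' @return A \code{data.frame} (class \code{experiment_data}) with columns
#'   \code{prey_density}, \code{modifier_density}, \code{consumption_rate};
#'   design, noise and seed recorded as attributes.
#' @export
generate_fr_experiment <- function(true_spec, design, noise_cv = 0.05,
                                   seed = 1) {
  if (length(unique(design$modifier_levels)) < 2L)
    stop("design needs at least 2 distinct modifier levels to identify a TIM")
  spec <- utils::modifyList(list(affected_parameter = "attack_rate",
                                 tim_form = "exponential",
                                 form_params = list(),
                                 handling_time = 0), true_spec)
  surf <- fr_surface(spec$fr_form, spec$affected_parameter, spec$tim_form,
                     spec$form_params)
  grid <- expand.grid(prey_density = design$prey_levels,
                      modifier_density = design$modifier_levels,
                      rep = seq_len(design$replicates))
  mu <- surf(spec$attack_rate, spec$handling_time, spec$strength,
             grid$prey_density, grid$modifier_density)
  noise <- if (noise_cv > 0) {
    sg <- sqrt(log(1 + noise_cv^2))
    with_preserved_rng(seed, function()
      exp(stats::rnorm(nrow(grid), -sg^2 / 2, sg)))
  } else rep(1, nrow(grid))
  out <- data.frame(prey_density = grid$prey_density,
                    modifier_density = grid$modifier_density,
                    consumption_rate = mu * noise)
  attr(out, "design") <- design
  attr(out, "noise_cv") <- noise_cv
  attr(out, "seed") <- seed
  attr(out, "true_spec") <- spec
  class(out) <- c("experiment_data", "data.frame")
  out
}

#' Fit a TIM-modified functional response to experiment data
#'
#' Nonlinear least squares (Levenberg-Marquardt, multi-start) of the stated
#' consumption-rate surface to (prey density, modifier density, rate) data.
#' Box bounds keep a > 0 and h >= 0; the modification parameter c is
#' unbounded. All start outcomes are reported alongside the best fit.
#'
#' @param data An \code{experiment_data} (or any data.frame with columns
#'   \code{prey_density}, \code{modifier_density}, \code{consumption_rate}).
#' @param spec List with \code{fr_form}, \code{tim_form}, optional
#'   \code{affected_parameter} (default attack_rate) and
#'   \code{form_params}.
#' @param n_starts Number of seeded random multi-starts.
#' @param seed Seed for the start generator.
#' @return A \code{fit_result}: list with \code{par} (a, h, c),
#'   \code{se}, \code{rss}, \code{converged}, \code{starts} (per-start
#'   outcomes) and the fitted \code{model} object.
#' @export
fit_tim_model <- function(data, spec, n_starts = 8, seed = 1) {
  stopifnot(all(c("prey_density", "modifier_density", "consumption_rate")
                %in% names(data)))
  if (length(unique(data$modifier_density)) < 2L)
    stop("need at least 2 distinct modifier levels to identify the TIM")
  spec <- utils::modifyList(list(affected_parameter = "attack_rate",
                                 tim_form = "exponential",
                                 form_params = list()), spec)
  surf <- fr_surface(spec$fr_form, spec$affected_parameter, spec$tim_form,
                     spec$form_params)
  use_h <- spec$fr_form != "linear"
  R <- data$prey_density; K <- data$modifier_density
  y <- data$consumption_rate
  starts <- with_preserved_rng(seed, function()
    data.frame(a = exp(stats::runif(n_starts, log(0.05), log(5))),
               h = exp(stats::runif(n_starts, log(0.01), log(2))),
               c = stats::runif(n_starts, -1.5, 1.5)))
  outcomes <- list()
  for (s in seq_len(n_starts)) {
    st <- if (use_h) list(a = starts$a[s], h = starts$h[s], c_ = starts$c[s])
          else list(a = starts$a[s], c_ = starts$c[s])
    fit <- tryCatch({
      if (use_h)
        minpack.lm::nlsLM(y ~ surf(a, h, c_, R, K), start = st,
                          lower = c(a = 1e-8, h = 0, c_ = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ surf(a, 0, c_, R, K), start = st,
                          lower = c(a = 1e-8, c_ = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL, warning = function(w) suppressWarnings({
      if (use_h)
        minpack.lm::nlsLM(y ~ surf(a, h, c_, R, K), start = st,
                          lower = c(a = 1e-8, h = 0, c_ = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ surf(a, 0, c_, R, K), start = st,
                          lower = c(a = 1e-8, c_ = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }))
    outcomes[[s]] <- if (is.null(fit)) list(ok = FALSE, rss = Inf,
                                            fit = NULL)
      else list(ok = TRUE, rss = sum(stats::resid(fit)^2), fit = fit)
  }
  rss <- vapply(outcomes, `[[`, 0, "rss")
  if (all(!is.finite(rss)))
    stop("fit_tim_model: no start converged (", n_starts, " starts, seed ",
         seed, ")")
  best <- outcomes[[which.min(rss)]]
  cf <- stats::coef(best$fit)
  par <- c(a = unname(cf["a"]),
           h = if (use_h) unname(cf["h"]) else 0,
           c = unname(cf["c_"]))
  se <- tryCatch({
    sm <- summary(best$fit)$coefficients
    c(a = unname(sm["a", "Std. Error"]),
      h = if (use_h) unname(sm["h", "Std. Error"]) else NA_real_,
      c = unname(sm["c_", "Std. Error"]))
  }, error = function(e) c(a = NA_real_, h = NA_real_, c = NA_real_))
  structure(list(par = par, se = se, rss = min(rss),
                 converged = TRUE,
                 starts = data.frame(starts,
                                     ok = vapply(outcomes, `[[`, TRUE, "ok"),
                                     rss = rss),
                 model = best$fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("TIM functional response fit (RSS =", format(x$rss), ")\n")
  print(rbind(estimate = x$par, std_error = x$se))
  invisible(x)
}

#' Write a sweep table or experiment data to CSV
#'
#' @param x A \code{sweep_table} or \code{experiment_data} (any data.frame).
#' @param path Output file path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
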