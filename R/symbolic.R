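# Closed-form (symbolic) representation of the model's right-hand side.
#
# Species densities are the variables x1..xS (canonical species order);
# each forced-mode TIM contributes an extra variable K<t> (its cue density),
# so sensitivities with respect to a forced modifier are ordinary partials.
# Piecewise forms (linear_clipped clip; hyperbolic sign branch) are resolved
# to the branch active at the supplied evaluation state, so derivatives are
# those of the active smooth piece.

num_str <- function(x) deparse(as.numeric(x))

sym_species_var <- function(model, id) paste0("x", species_index(model, id))

tim_index <- function(model, tim_id) {
  ix <- match(tim_id, vapply(model$tims, `[[`, "", "tim_id"))
  if (is.na(ix)) stop("no TIM with id '", tim_id, "'")
  ix
}

# symbolic variable carrying the modifier density of a TIM
sym_modifier_var <- function(model, tim) {
  if (tim$mode == "forced") paste0("K", tim_index(model, tim$tim_id))
  else sym_species_var(model, tim$modifier)
}

# modification term as an expression string in the modifier variable;
# state picks the active branch of non-smooth forms
tim_term_str <- function(model, tim, state) {
  v <- sym_modifier_var(model, tim)
  c_ <- tim$strength
  k0 <- tim_modifier_density(model, tim, state)
  switch(tim$form,
    exponential = sprintf("exp(%s * %s)", num_str(c_), v),
    linear_clipped = {
      if (1 + c_ * k0 > 0) sprintf("(1 + %s * %s)", num_str(c_), v)
      else {
        warning("linear_clipped TIM '", tim$tim_id,
                "' is clipped at the evaluation state; symbolic ",
                "derivatives use the zero branch")
        "0"
      }
    },
    hyperbolic = if (c_ >= 0) sprintf("(1 + %s * %s)", num_str(c_), v)
                 else sprintf("(1 / (1 + %s * %s))", num_str(abs(c_)), v),
    sigmoid = {
      m <- tim$form_params$midpoint; s <- tim$form_params$steepness
      sprintf("(1 + %s * %s^%s / (%s^%s + %s))", num_str(c_), v, num_str(s),
              v, num_str(s), num_str(m^s))
    })
}

# effective parameter strings (base value times product of TIM terms)
effective_param_str <- function(model, link, param, base, state,
                                exclude_tim = NULL) {
  tms <- tims_for(model, link, param, exclude_tim)
  if (!length(tms)) return(num_str(base))
  terms <- vapply(tms, function(tm) tim_term_str(model, tm, state), "")
  paste0("(", num_str(base), " * ", paste(terms, collapse = " * "), ")")
}

link_flux_str <- function(model, link, state, exclude_tim = NULL) {
  R <- sym_species_var(model, link$resource)
  C <- sym_species_var(model, link$consumer)
  a <- effective_param_str(model, link, "attack_rate", link$attack_rate,
                           state, exclude_tim)
  h <- effective_param_str(model, link, "handling_time", link$handling_time,
                           state, exclude_tim)
  w <- effective_param_str(model, link, "interference", link$interference,
                           state, exclude_tim)
  switch(link$fr_form,
         linear = sprintf("(%s * %s * %s)", a, R, C),
         holling2 = sprintf("(%s * %s * %s / (1 + %s * %s * %s))",
                            a, R, C, a, h, R),
         holling2_interference =
           sprintf("(%s * %s * %s / (1 + %s * %s * %s + %s * %s))",
                   a, R, C, a, h, R, w, C))
}

# character vector of rhs expressions, one per species
rhs_strs <- function(model, state) {
  state <- state_vector(model, state)
  n <- length(model$species_order)
  strs <- character(n)
  for (ix in seq_len(n)) {
    sp <- model$species[[ix]]
    x <- paste0("x", ix)
    strs[ix] <- if (sp$role == "producer")
      sprintf("%s * (%s - %s * %s)", x, num_str(sp$intrinsic_rate),
              num_str(sp$self_limitation), x)
    else
      sprintf("(-%s * %s - %s * %s^2)", num_str(sp$intrinsic_rate), x,
              num_str(sp$self_limitation), x)
  }
  for (ln in model$links) {
    fl <- link_flux_str(model, ln, state)
    ir <- species_index(model, ln$resource)
    ic <- species_index(model, ln$consumer)
    strs[ir] <- paste0(strs[ir], " - ", fl)
    strs[ic] <- paste0(strs[ic], " + ",
                       num_str(ln$conversion_efficiency), " * ", fl)
  }
  strs
}

rhs_exprs <- function(model, state) {
  lapply(rhs_strs(model, state), function(s) parse(text = s)[[1]])
}

# evaluation environment: species variables plus forced-TIM cue variables
sym_env <- function(model, state) {
  state <- state_vector(model, state)
  e <- new.env(parent = baseenv())
  for (ix in seq_along(state)) assign(paste0("x", ix), unname(state[[ix]]), e)
  for (t in seq_along(model$tims)) {
    tm <- model$tims[[t]]
    if (tm$mode == "forced") assign(paste0("K", t), tm$forced_density, e)
  }
  e
}

# Jacobian from symbolic differentiation of the closed-form rhs
jacobian_symbolic_matrix <- function(model, state) {
  exprs <- rhs_exprs(model, state)
  env <- sym_env(model, state)
  n <- length(exprs)
  A <- matrix(0, n, n, dimnames = list(model$species_order,
                                       model$species_order))
  for (i in seq_len(n)) for (j in seq_len(n))
    A[i, j] <- eval(stats::D(exprs[[i]], paste0("x", j)), env)
  A
}

# elementwise dA/dK (K = the focal TIM's modifier variable), symbolically
dA_dK_symbolic <- function(model, tim, state) {
  exprs <- rhs_exprs(model, state)
  env <- sym_env(model, state)
  kv <- sym_modifier_var(model, tim)
  n <- length(exprs)
  M <- matrix(0, n, n, dimnames = list(model$species_order,
                                       model$species_order))
  for (i in seq_len(n)) for (j in seq_len(n))
    M[i, j] <- eval(stats::D(stats::D(exprs[[i]], paste0("x", j)), kv), env)
  M
}

# rhs re-evaluated with the focal TIM's modifier density overridden (used by
# finite-difference sensitivities; works for forced and dynamic modifiers)
rhs_with_modifier <- function(model, tim, state, k) {
  if (tim$mode == "forced") {
    ti <- tim_index(model, tim$tim_id)
    model$tims[[ti]]$forced_density <- k
    rhs(model, state)
  } else {
    ix <- species_index(model, tim$modifier)
    state[ix] <- k
    rhs(model, state)
  }
}

# elementwise dA/dK by nested central differences (independent oracle path).
# The outer step balances the inner Jacobian's rounding error (~eps^(2/3))
# against truncation, giving h ~ eps^(2/9) ~ 1e-4 per unit scale -- much
# larger than a first-derivative step.
dA_dK_fd <- function(model, tim, state) {
  state <- state_vector(model, state)
  k0 <- tim_modifier_density(model, tim, state)
  hk <- 1e-4 * max(abs(k0), 1)
  if (k0 - hk < 0) {  # one-sided near the clamp boundary
    A_p <- jacobian_at_modifier(model, tim, state, k0 + hk)
    A_0 <- jacobian_at_modifier(model, tim, state, k0)
    (A_p - A_0) / hk
  } else {
    A_p <- jacobian_at_modifier(model, tim, state, k0 + hk)
    A_m <- jacobian_at_modifier(model, tim, state, k0 - hk)
    (A_p - A_m) / (2 * hk)
  }
}

jacobian_at_modifier <- function(model, tim, state, k) {
  if (tim$mode == "forced") {
    ti <- tim_index(model, tim$tim_id)
    model$tims[[ti]]$forced_density <- k
  } else {
    ix <- species_index(model, tim$modifier)
    state[ix] <- k
  }
  jacobian_fd_matrix(model, state)
}
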