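# shared fixtures and independent oracles, built in code

# mixed relative/absolute comparison: relative for O(1)+ values, absolute
# floor for near-zero entries
expect_close <- function(x, y, tol, floor = 1) {
  expect_lt(max(abs(x - y) / pmax(abs(y), floor)), tol)
}

# brute-force oracle for the net-sensitivity metric: central difference of
# the net-effects matrix across modifier density K +/- h (dynamic TIMs)
net_sensitivity_bruteforce <- function(model, tim_id, state) {
  tim <- timweb:::find_tim(model, tim_id)
  stopifnot(tim$mode == "dynamic")
  ik <- match(tim$modifier, model$species_order)
  k0 <- unname(state[[ik]])
  h <- .Machine$double.eps^(1/3) * max(abs(k0), 1)
  N_at <- function(k) {
    st <- state
    st[ik] <- k
    net_effects(jacobian(model, st, "symbolic"))$entries
  }
  dN <- (N_at(k0 + h) - N_at(k0 - h)) / (2 * h)
  i <- match(tim$resource, model$species_order)
  j <- match(tim$consumer, model$species_order)
  c(dNij_dK = dN[i, j], dNji_dK = dN[j, i])
}

# brute-force oracle for the Jacobian-sensitivity metric, same scheme
jacobian_sensitivity_bruteforce <- function(model, tim_id, state) {
  tim <- timweb:::find_tim(model, tim_id)
  stopifnot(tim$mode == "dynamic")
  ik <- match(tim$modifier, model$species_order)
  k0 <- unname(state[[ik]])
  h <- .Machine$double.eps^(1/3) * max(abs(k0), 1)
  A_at <- function(k) {
    st <- state
    st[ik] <- k
    jacobian(model, st, "symbolic")$entries
  }
  dA <- (A_at(k0 + h) - A_at(k0 - h)) / (2 * h)
  i <- match(tim$resource, model$species_order)
  j <- match(tim$consumer, model$species_order)
  c(dAij_dK = dA[i, j], dAji_dK = dA[j, i])
}

# synthetic sinusoidal "trajectory" whose first species carries the series
# k(t) = 1 + sin(t); with a linear_clipped TIM of strength 1 the
# modification term is 2 + sin(t), whose CV over whole periods is
# (1/sqrt(2))/2
sinusoid_trajectory <- function(n = 2001, periods = 2) {
  tt <- seq(0, 2 * pi * periods, length.out = n)
  structure(list(times = tt,
                 states = cbind(I = 1 + sin(tt), J = rep(1, length(tt))),
                 solver_info = list(synthetic = TRUE)),
            class = "trajectory")
}

sinusoid_cv_model <- function(strength = 1) {
  base <- lv_cue_model()
  community_model(base$species, base$links,
                  list(tim_spec("S", "I", "I", "J", form = "linear_clipped",
                                strength = strength)))
}
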