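test_that("trajectories respect fixed points and solver convergence", {
  m <- build_demo("chain_linear")
  eq <- find_equilibrium(m)
  tr <- simulate_model(m, eq$state, c(0, 100), n_steps = 200)
  expect_lt(max(abs(sweep(tr$states, 2, eq$state))), 1e-6)

  # zero-strength TIMs integrate identically to the stripped model
  m0 <- set_tim_strength(m, 0)
  tr1 <- simulate_model(m0, c(1, 0.5, 0.5), c(0, 100), n_steps = 200)
  tr2 <- simulate_model(strip_tims(m), c(1, 0.5, 0.5), c(0, 100),
                        n_steps = 200)
  expect_lt(max(abs(tr1$states - tr2$states)), 1e-8)

  # tolerance convergence on the demo chain
  trA <- simulate_model(m, c(1, 0.5, 0.5), c(0, 50))
  trB <- simulate_model(m, c(1, 0.5, 0.5), c(0, 50),
                        rtol = 1e-9, atol = 1e-11)
  expect_lt(max(abs(trA$states[nrow(trA$states), ] -
                    trB$states[nrow(trB$states), ])), 1e-5)
})

test_that("dynamics classification agrees with the eigenvalue scan", {
  # enriched consumer-resource pair: the TIM strength moves the system
  # across its Hopf point, located independently by the eigenvalue sign
  for (cc in c(0, -0.1, -0.3, -0.6)) {
    m <- build_stabilization_demo(cc)
    cl <- classify_dynamics(m, c(1, 0.5), t_span = c(0, 400))
    late <- cl$trajectory$states[cl$trajectory$times >= 200, , drop = FALSE]
    eq <- find_equilibrium(m, guess = pmax(colMeans(late), 1e-6))
    expect_true(eq$converged && eq$feasible)
    lead <- max(Re(eq$eigenvalues))
    expect_identical(cl$classification,
                     if (lead > 1e-7) "cycling" else "stable_point")
  }
  # classic neutral Lotka-Volterra: purely imaginary spectrum
  expect_identical(
    classify_dynamics(lv_cue_model(), c(1, 1),
                      t_span = c(0, 200))$classification,
    "marginal")
})

test_that("classification is invariant to doubling the integration span", {
  for (cc in c(0, -0.5)) {
    m <- build_stabilization_demo(cc)
    c1 <- classify_dynamics(m, c(1, 0.5), t_span = c(0, 400))$classification
    c2 <- classify_dynamics(m, c(1, 0.5), t_span = c(0, 800))$classification
    expect_identical(c1, c2)
  }
})

test_that("static replacement preserves the reference equilibrium", {
  for (nm in c("chain_linear", "chain_nonlinear", "aphid_parasitoid")) {
    m <- build_demo(nm)
    eq <- find_equilibrium(m)
    expect_true(eq$converged && eq$feasible)
    m2 <- static_replacement(m, "T1", eq$state)
    expect_length(m2$tims, 0L)
    expect_lt(max(abs(rhs(m2, eq$state))), 1e-8)
  }
  # c = 0 replacement is the stripped model, parameter for parameter
  m0 <- set_tim_strength(build_demo("chain_linear"), 0, "T1")
  eq0 <- find_equilibrium(m0)
  expect_identical(static_replacement(m0, "T1", eq0$state), strip_tims(m0))
})

test_that("static replacement changes the local stability structure", {
  m <- build_demo("chain_nonlinear")  # c = 0.5
  eq <- find_equilibrium(m)
  m2 <- static_replacement(m, "T1", eq$state)
  e1 <- sort(Re(eigen(jacobian(m, eq$state)$entries)$values))
  e2 <- sort(Re(eigen(jacobian(m2, eq$state)$entries)$values))
  expect_gt(max(abs(e1 - e2)), 1e-6)
})

test_that("the stabilisation scan finds a stable TIM range in a cycler", {
  tab <- stabilization_scan(build_stabilization_demo(0), "T1",
                            seq(0, -1, by = -0.2), c(1, 0.5),
                            t_span = c(0, 400))
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$classification[tab$c == 0], "cycling")
  expect_gt(sum(tab$classification == "stable_point"), 0)
  # the leading eigenvalue crosses zero where the classification flips
  cyc <- tab$leading_re[tab$classification == "cycling" & tab$eq_feasible]
  stab <- tab$leading_re[tab$classification == "stable_point" &
                           tab$eq_feasible]
  expect_true(all(cyc > 0))
  expect_true(all(stab < 0))
})

test_that("trajectories export to CSV with a time column per species", {
  m <- build_demo("chain_linear")
  tr <- simulate_model(m, c(1, 0.5, 0.5), c(0, 10), n_steps = 20)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- utils::read.csv(f, check.names = FALSE)
  expect_identical(names(df), c("time", "P", "H", "C"))
  expect_identical(nrow(df), 21L)
})
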