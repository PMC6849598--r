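test_that("flux change has the printed orientation and cancels densities", {
  # c = 0: identical fluxes
  m0 <- lv_cue_model(c = 0, K = 2)
  fc0 <- metric_flux_change(m0, "T1", c(1, 1))
  expect_identical(fc0$flux_ratio, 1)
  expect_identical(fc0$flux_difference, 0)

  # linear FR + exponential TIM on attack rate: ratio = exp(-cK), any state
  m <- lv_cue_model(c = 0.5, K = 2)
  for (st in list(c(1, 1), c(0.3, 2.7)))
    expect_equal(metric_flux_change(m, "T1", st)$flux_ratio, exp(-1),
                 tolerance = 1e-12)
  # strengthened interaction (term > 1) gives ratio < 1
  expect_lt(metric_flux_change(m, "T1", c(1, 1))$flux_ratio, 1)

  # holling2, a=h=1, R=C=1, term m=2: 0.5 - 2/3 = -1/6
  mh <- community_model(
    list(species_spec("I", 1, 0, "producer"),
         species_spec("J", 0.2, 0, "consumer")),
    list(trophic_link("I", "J", "holling2", 1, 1,
                      conversion_efficiency = 0.5)),
    list(tim_spec("T1", NA_character_, "I", "J", form = "exponential",
                  strength = log(2), mode = "forced", forced_density = 1)))
  expect_equal(metric_flux_change(mh, "T1", c(1, 1))$flux_difference,
               0.5 - 2 / 3, tolerance = 1e-12)
})

test_that("resource-equilibrium ratio follows the closed form exp(-cK)", {
  expect_equal(metric_bcr_change(lv_cue_model(c = 0, K = 2), "T1"), 1,
               tolerance = 1e-10)
  expect_equal(metric_bcr_change(lv_cue_model(c = 0.5, K = 2), "T1"),
               exp(-1), tolerance = 1e-6)
  for (cc in c(-1, -0.3, 0.4, 1)) for (K in c(0.5, 2))
    expect_equal(metric_bcr_change(lv_cue_model(c = cc, K = K), "T1"),
                 exp(-cc * K), tolerance = 1e-6)
})

test_that("bcr change equals the ratio of two independent equilibrium solves", {
  for (nm in c("chain_nonlinear", "aphid_parasitoid")) {
    m <- build_demo(nm)
    got <- metric_bcr_change(m, "T1")
    eq1 <- find_equilibrium(m)
    eq0 <- find_equilibrium(set_tim_strength(m, 0, "T1"))
    i <- match(m$tims[[1]]$resource, m$species_order)
    expect_equal(got, unname(eq1$state[[i]] / eq0$state[[i]]),
                 tolerance = 1e-8)
  }
})

test_that("TMII metric extracts the modifier column of the Jacobian", {
  m <- set_tim_strength(build_demo("chain_linear"), 0, "T1")
  eq <- find_equilibrium(m)
  tp <- metric_tmii(m, "T1", eq$state)
  # c = 0 and no direct C -> P link: modifier absent from the plant equation
  expect_equal(unname(tp[["dIdot_dK"]]), 0, tolerance = 1e-12)
  # C preys on H: dHdot/dC = -a2 * H at the state
  expect_equal(unname(tp[["dJdot_dK"]]),
               -0.4 * unname(eq$state[["H"]]), tolerance = 1e-8)
  A <- jacobian(m, eq$state)$entries
  expect_identical(unname(tp), unname(A[c("P", "H"), "C"]))

  expect_error(metric_tmii(lv_cue_model(c = 1, K = 1), "T1", c(1, 1)),
               "forced")
})

test_that("Jacobian sensitivity matches the closed form on the LV cue model", {
  # A_IJ = -a exp(cK) I, so dA_IJ/dK = -a c exp(cK) I = -0.25 at K=0, I=1
  m <- lv_cue_model(c = 0.5, K = 0)
  js <- metric_jacobian_sensitivity(m, "T1", c(1, 1))
  expect_equal(unname(js[["dAij_dK"]]), -0.25, tolerance = 1e-8)
  # zero-strength TIM with modifier otherwise absent: exactly no sensitivity
  m0 <- lv_cue_model(c = 0, K = 3)
  expect_equal(unname(metric_jacobian_sensitivity(m0, "T1", c(1, 1))),
               c(0, 0), tolerance = 1e-12)
})

test_that("derivative metrics agree between symbolic and nested differences", {
  for (s in 1:10) {
    m <- generate_random_chain(s)
    eq <- find_equilibrium(strip_tims(m), guess = rep(1, 3))
    j1 <- metric_jacobian_sensitivity(m, "T1", eq$state, "symbolic")
    j2 <- metric_jacobian_sensitivity(m, "T1", eq$state,
                                      "finite_difference")
    expect_close(j2, j1, 1e-4)
    n1 <- metric_net_sensitivity(m, "T1", eq$state, "symbolic")
    n2 <- metric_net_sensitivity(m, "T1", eq$state, "finite_difference")
    expect_close(n2, n1, 1e-4)
    # independent brute force: central difference of the net-effects matrix
    nb <- net_sensitivity_bruteforce(m, "T1", eq$state)
    expect_close(n1, nb, 1e-4)
    jb <- jacobian_sensitivity_bruteforce(m, "T1", eq$state)
    expect_close(j1, jb, 1e-4)
  }
})

test_that("direct sensitivity is blind to trophic coupling but net is not", {
  # modifier trophically connected, c = 0: direct (0,0), net nonzero
  m <- build_demo("chain_nonlinear",
                  overrides = list(pred_self_lim = 0.05, tim_strength = 0))
  eq <- find_equilibrium(m)
  js <- metric_jacobian_sensitivity(m, "T1", eq$state)
  ns <- metric_net_sensitivity(m, "T1", eq$state)
  expect_equal(unname(js), c(0, 0), tolerance = 1e-10)
  expect_gt(max(abs(ns)), 1e-6)
})

test_that("CV of the modification term honours its contracts", {
  # constant series at a stable fixed point: CV = 0
  m <- build_demo("chain_linear")
  eq <- find_equilibrium(m)
  tr <- simulate_model(m, eq$state, c(0, 50), n_steps = 400)
  expect_lt(abs(metric_cv(m, "T1", tr)), 1e-8)

  # sinusoid 2 + sin(t) over whole periods: CV = (1/sqrt(2))/2
  mS <- sinusoid_cv_model()
  cv1 <- metric_cv(mS, "S", sinusoid_trajectory(2001))
  expect_equal(cv1, (1 / sqrt(2)) / 2, tolerance = 1e-3)
  # quadrature convergence: halving the sampling step barely moves it
  cv2 <- metric_cv(mS, "S", sinusoid_trajectory(4001))
  expect_lt(abs(cv1 - cv2), 1e-3)

  # everywhere-clipped term (constant modifier, 1 + c*k = 0): CV undefined
  mC <- sinusoid_cv_model(strength = -0.5)
  trC <- sinusoid_trajectory(101)
  trC$states[, "I"] <- 2
  expect_error(metric_cv(mC, "S", trC), "CV undefined")
})

test_that("the full metric report satisfies the null-TIM row and composes", {
  m <- build_demo("chain_nonlinear", overrides = list(tim_strength = 0))
  rep0 <- compute_all_metrics(m, "T1", at = "equilibrium")
  expect_equal(rep0$modification_term, 1, tolerance = 1e-12)
  expect_equal(rep0$flux_ratio, 1, tolerance = 1e-12)
  expect_equal(rep0$flux_difference, 0, tolerance = 1e-12)
  expect_equal(rep0$bcr_change, 1, tolerance = 1e-8)
  expect_equal(unname(rep0$jacobian_sensitivity_pair), c(0, 0),
               tolerance = 1e-10)
  expect_null(rep0$cv_modification)  # equilibrium context has no trajectory

  m1 <- build_demo("chain_nonlinear")
  eq <- find_equilibrium(m1)
  rep1 <- compute_all_metrics(m1, "T1", at = "state", state = eq$state)
  expect_identical(rep1$flux_ratio,
                   metric_flux_change(m1, "T1", eq$state)$flux_ratio)
  expect_identical(rep1$jacobian_sensitivity_pair,
                   metric_jacobian_sensitivity(m1, "T1", eq$state))
  row <- metric_report_row(rep1)
  expect_identical(nrow(row), 1L)
  expect_true(is.na(row$cv_modification))
})
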