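test_that("modification terms follow the form catalogue and are 1 at c = 0", {
  sig_par <- list(midpoint = 1, steepness = 2)
  forms <- list(
    tim_spec("t", "x", "a", "b", form = "exponential", strength = 0),
    tim_spec("t", "x", "a", "b", form = "linear_clipped", strength = 0),
    tim_spec("t", "x", "a", "b", form = "hyperbolic", strength = 0),
    tim_spec("t", "x", "a", "b", form = "sigmoid", strength = 0,
             form_params = sig_par))
  for (tm in forms)
    for (k in c(0, 0.5, 5))
      expect_identical(modification_term(tm, k), 1)

  expect_equal(modification_term(
    tim_spec("t", "x", "a", "b", form = "exponential", strength = 0.5), 2),
    exp(1))
  expect_identical(modification_term(
    tim_spec("t", "x", "a", "b", form = "linear_clipped", strength = -0.4),
    5), 0)
  # hyperbolic: saturating increase for c > 0, strictly positive decay c < 0
  expect_equal(modification_term(
    tim_spec("t", "x", "a", "b", form = "hyperbolic", strength = 0.5), 3),
    2.5)
  expect_equal(modification_term(
    tim_spec("t", "x", "a", "b", form = "hyperbolic", strength = -0.5), 3),
    1 / 2.5)
  # sigmoid at the midpoint is halfway up
  expect_equal(modification_term(
    tim_spec("t", "x", "a", "b", form = "sigmoid", strength = 0.8,
             form_params = list(midpoint = 2, steepness = 3)), 2),
    1.4)
  expect_error(modification_term(
    tim_spec("t", "x", "a", "b", form = "exponential", strength = 1), -1),
    "modifier_density")
})

test_that("forced and dynamic TIMs give identical terms at equal density", {
  for (k in c(0, 0.7, 3)) {
    dyn <- tim_spec("d", "x", "a", "b", form = "exponential",
                    strength = -0.3)
    fr <- tim_spec("f", NA_character_, "a", "b", form = "exponential",
                   strength = -0.3, mode = "forced", forced_density = k)
    expect_identical(modification_term(dyn, k),
                     modification_term(fr, k))
  }
})

test_that("combined modification is a multiplicative, order-invariant product", {
  m <- build_demo("chain_linear")
  st <- state_vector(m, c(1, 1, 1))
  expect_identical(combined_modification(m, list(), st), 1)

  t1 <- tim_spec("a1", "C", "P", "H", form = "exponential", strength = 0.3)
  t2 <- tim_spec("a2", "C", "P", "H", form = "exponential", strength = -0.3)
  expect_equal(combined_modification(m, list(t1, t2), st), 1)

  t3 <- tim_spec("a3", "C", "P", "H", form = "exponential", strength = 0.5)
  t4 <- tim_spec("a4", "C", "P", "H", form = "exponential", strength = 0.5)
  expect_equal(combined_modification(m, list(t3, t4), st), exp(0.5)^2)
  expect_identical(combined_modification(m, list(t3, t4), st),
                   combined_modification(m, list(t4, t3), st))

  t5 <- tim_spec("a5", "C", "P", "H", affected_parameter = "handling_time",
                 form = "exponential", strength = 0.5)
  expect_error(combined_modification(m, list(t3, t5), st),
               "affected_parameter")
})

test_that("link fluxes match hand-computed functional responses", {
  m <- community_model(
    list(species_spec("R", 1, 0.1, "producer"),
         species_spec("C", 0.2, 0, "consumer")),
    list(trophic_link("R", "C", "linear", 0.5,
                      conversion_efficiency = 0.5)))
  expect_equal(link_flux(m, c("R", "C"), c(2, 3)), 3.0)   # 0.5*2*3
  expect_identical(link_flux(m, c("R", "C"), c(0, 3)), 0)

  m2 <- community_model(
    list(species_spec("R", 1, 0.1, "producer"),
         species_spec("C", 0.2, 0, "consumer")),
    list(trophic_link("R", "C", "holling2", 1, 1,
                      conversion_efficiency = 0.5)))
  expect_equal(link_flux(m2, c("R", "C"), c(1, 1)), 0.5)  # aR/(1+ahR)

  m3 <- community_model(
    list(species_spec("R", 1, 0.1, "producer"),
         species_spec("C", 0.2, 0, "consumer")),
    list(trophic_link("R", "C", "holling2_interference", 1, 1,
                      interference = 0.5, conversion_efficiency = 0.5)))
  expect_equal(link_flux(m3, c("R", "C"), c(1, 2)), 2 / 3)
})

test_that("rhs matches hand arithmetic and vanishes at fixed points", {
  m <- lv_cue_model(c = 0.7, K = 0)  # forced K = 0: c arbitrary
  expect_equal(unname(rhs(m, c(1, 1))), c(0.5, 0.05))
  expect_identical(unname(rhs(m, c(0, 0))), c(0, 0))
  eq <- find_equilibrium(m, c(1, 1))
  expect_lt(max(abs(rhs(m, eq$state))), 1e-8)
})

test_that("no flux flows from an absent species", {
  m <- build_demo("chain_linear")
  r <- rhs(m, c(2, 0, 1))
  expect_identical(unname(r[["H"]]), 0)     # no herbivores, no herbivory
  expect_equal(unname(r[["P"]]), 2 * (1 - 0.05 * 2))  # pure logistic growth
})

test_that("zero-strength TIMs reproduce the TIM-free vector field exactly", {
  for (s in 1:10) {
    m <- generate_random_chain(s)
    m0 <- set_tim_strength(m, 0)
    ms <- strip_tims(m)
    for (st in list(c(1, 1, 1), c(0.2, 3, 0.5), c(5, 0, 2)))
      expect_identical(rhs(m0, st), rhs(ms, st))
  }
})

test_that("model validation reports all violations together", {
  m <- build_demo("chain_linear")
  bad <- m
  bad$tims[[1]]$resource <- "X"
  bad$species[[2]]$id <- "P"  # duplicate id
  errs <- validate_model(bad)
  expect_true(any(grepl("duplicated species ids", errs)))
  expect_true(any(grepl("TIM 'T1' targets missing link", errs)))

  expect_error(trophic_link("a", "b", "linear", -1), "attack_rate")
  expect_error(trophic_link("a", "b", "linear", 1, handling_time = 0.5),
               "handling_time")
  expect_error(trophic_link("a", "a", "linear", 1), "differ")
})
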