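test_that("every demo admits a feasible stable interior equilibrium at c=0", {
  for (nm in c("chain_linear", "chain_nonlinear", "aphid_parasitoid")) {
    m <- set_tim_strength(build_demo(nm), 0, "T1")
    eq <- find_equilibrium(m)
    expect_true(eq$converged, info = nm)
    expect_true(eq$feasible, info = nm)
    expect_identical(eq$stability, "stable")
  }
  expect_error(build_demo("no_such_demo"), "chain_linear")
})

test_that("demo overrides change exactly the named parameters", {
  m1 <- build_demo("chain_linear")
  m2 <- build_demo("chain_linear", overrides = list(a1 = 0.7))
  expect_identical(m2$links[[1]]$attack_rate, 0.7)
  m2$links[[1]]$attack_rate <- m1$links[[1]]$attack_rate
  expect_identical(m1, m2)
  expect_error(build_demo("chain_linear", overrides = list(zeta = 1)),
               "unknown demo parameter")
})

test_that("demo models survive a serialisation round trip", {
  for (nm in c("chain_linear", "chain_nonlinear", "aphid_parasitoid")) {
    m <- build_demo(nm)
    f <- tempfile(fileext = ".json")
    write_model(m, f)
    expect_identical(read_model(f), m)
  }
})

test_that("the sweep walks the grid and satisfies null-TIM invariants", {
  m <- lv_cue_model(K = 2)
  grid <- seq(-1, 1, by = 0.25)
  tab <- sweep_tim_parameter(m, "T1", grid)
  expect_identical(nrow(tab), length(grid))
  expect_identical(tab$c, grid)
  expect_true(all(tab$converged & tab$feasible))
  r0 <- tab[tab$c == 0, ]
  expect_equal(r0$flux_ratio, 1, tolerance = 1e-10)
  expect_equal(r0$flux_difference, 0, tolerance = 1e-10)
  expect_equal(r0$bcr_change, 1, tolerance = 1e-8)
  # analytically solvable cue sub-model: bcr column is exp(-cK) pointwise
  expect_equal(tab$bcr_change, exp(-tab$c * 2), tolerance = 1e-6)
})

test_that("random chain generation is deterministic and verified", {
  m1 <- generate_random_chain(7)
  m2 <- generate_random_chain(7)
  attr(m1, "attempts") <- attr(m2, "attempts") <- NULL
  expect_identical(m1, m2)
  for (s in 1:10) {
    m <- generate_random_chain(s)
    eq <- find_equilibrium(strip_tims(m), guess = rep(1, 3))
    expect_true(eq$converged && eq$feasible)
    expect_identical(eq$stability, "stable")
  }
  # narrowed parameter ranges are respected
  m <- generate_random_chain(3, ranges = list(a = c(0.4, 0.45)))
  for (ln in m$links) {
    expect_gte(ln$attack_rate, 0.4)
    expect_lte(ln$attack_rate, 0.45)
  }
})

test_that("synthetic experiments reproduce the true surface and noise level", {
  true <- list(fr_form = "holling2", attack_rate = 1, handling_time = 0.5,
               strength = 0.5)
  design <- list(prey_levels = c(0.5, 1, 2, 4, 8),
                 modifier_levels = c(0, 0.5, 1, 2, 4), replicates = 10)
  d0 <- generate_fr_experiment(true, design, noise_cv = 0, seed = 1)
  expect_identical(nrow(d0), 250L)
  aeff <- 1 * exp(0.5 * d0$modifier_density)
  expect_equal(d0$consumption_rate,
               aeff * d0$prey_density / (1 + aeff * 0.5 * d0$prey_density),
               tolerance = 1e-12)

  d1 <- generate_fr_experiment(true, design, noise_cv = 0.05, seed = 9)
  d2 <- generate_fr_experiment(true, design, noise_cv = 0.05, seed = 9)
  expect_identical(d1, d2)

  # empirical CV at one design cell approaches the nominal CV
  cell <- list(prey_levels = 2, modifier_levels = c(0, 1), replicates = 200)
  dc <- generate_fr_experiment(true, cell, noise_cv = 0.05, seed = 11)
  one <- dc[dc$modifier_density == 1, "consumption_rate"]
  expect_lt(abs(stats::sd(one) / mean(one) - 0.05), 0.01)

  expect_error(generate_fr_experiment(
    true, list(prey_levels = 1, modifier_levels = 2, replicates = 3)),
    "modifier levels")
})

test_that("fitting recovers known parameters from noiseless data", {
  true <- list(fr_form = "holling2", attack_rate = 1, handling_time = 0.5,
               strength = 0.5)
  design <- list(prey_levels = c(0.5, 1, 2, 4, 8),
                 modifier_levels = c(0, 0.5, 1, 2, 4), replicates = 10)
  d0 <- generate_fr_experiment(true, design, noise_cv = 0, seed = 1)
  fit <- fit_tim_model(d0, list(fr_form = "holling2"), seed = 1)
  expect_equal(unname(fit$par), c(1, 0.5, 0.5), tolerance = 1e-6)

  lin <- list(fr_form = "linear", attack_rate = 0.8, strength = -0.4)
  dl <- generate_fr_experiment(lin, design, noise_cv = 0, seed = 2)
  fl <- fit_tim_model(dl, list(fr_form = "linear"), seed = 2)
  expect_equal(unname(fl$par[c("a", "c")]), c(0.8, -0.4), tolerance = 1e-6)

  expect_error(fit_tim_model(
    data.frame(prey_density = 1:5, modifier_density = 1,
               consumption_rate = 1),
    list(fr_form = "linear")), "modifier levels")
})

test_that("a null TIM is not detected as significant under noise", {
  null <- list(fr_form = "holling2", attack_rate = 1, handling_time = 0.5,
               strength = 0)
  design <- list(prey_levels = c(0.5, 1, 2, 4, 8),
                 modifier_levels = c(0, 0.5, 1, 2, 4), replicates = 10)
  d <- generate_fr_experiment(null, design, noise_cv = 0.05, seed = 21)
  fit <- fit_tim_model(d, list(fr_form = "holling2"), seed = 3)
  expect_lt(abs(fit$par[["c"]]), 2 * fit$se[["c"]])
})
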