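test_that("implied latent matrix follows the path algebra", {
  expect_equal(implied_latent_matrix(0, 0, 0),
               diag(3), ignore_attr = TRUE)
  # full mediation: r_SQ = a * b exactly
  L <- implied_latent_matrix(-0.5, -0.4, 0)
  expect_equal(L["social_support", "quality_of_life"], 0.2)
  # forward map inverts the closed-form paths
  L2 <- implied_latent_matrix(-0.408, -0.379, 0.400)
  expect_equal(unname(mediation_closed_form(L2)),
               c(-0.408, -0.379, 0.400), tolerance = 1e-12)
  # and matches the disattenuated fixture matrix to ~3 decimals
  expect_lt(max(abs(L2 - disattenuate(table5_matrix()))), 5e-4)
  expect_error(implied_latent_matrix(0.9, 0.9, 0.9), "positive definite")
})

test_that("the generator is deterministic under a seed", {
  cfg <- simulation_config(n_studies = 10)
  s1 <- simulate_studies(cfg, seed = 42)
  s2 <- simulate_studies(cfg, seed = 42)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$true_z, s2$true_z)
  s3 <- simulate_studies(cfg, seed = 43)
  expect_false(identical(s1$data, s3$data))
})

test_that("with no heterogeneity and huge n the sample r hits its target", {
  cfg <- simulation_config(tau_z = 0, n_studies = 3, n_per_study = 1e6,
                           cell_prob = 1)
  sim <- simulate_studies(cfg, seed = 8)
  # every reported r should sit within 0.005 of its attenuated population value
  lat <- cfg$latent
  for (i in seq_len(nrow(sim$data))) {
    rec <- sim$data[i, ]
    target <- tanh(sim$true_z[1, rec$relationship]) *
      sqrt(rec$rel_x * rec$rel_y)
    expect_lt(abs(rec$r - target), 0.005)
  }
  # and true_z equals the population z when tau = 0
  expect_equal(unname(sim$true_z[1, ]),
               unname(atanh(c(lat[2, 1], lat[1, 3], lat[2, 3]))))
})

test_that("explicit reporting patterns reproduce a target k profile", {
  # 11 + 9 + 3 studies giving k = 23 (SS-PS), 9 (PS-QoL), 12 (SS-QoL)
  pattern <- c(rep(list("SS-PS"), 11),
               rep(list(c("SS-PS", "SS-QoL", "PS-QoL")), 9),
               rep(list(c("SS-PS", "SS-QoL")), 3))
  cfg <- simulation_config(n_studies = 23, cell_prob = pattern,
                           n_per_study = c(50, 200))
  sim <- simulate_studies(cfg, seed = 3)
  v <- validate_studies(sim$data)
  expect_identical(unname(v$k), c(23L, 9L, 12L))
})

test_that("moderator effects injected on the z scale are recoverable", {
  # a large sociocultural shift powers the subgroup Q test
  cfg <- simulation_config(a = -0.3, b = -0.3, cp = 0.3, tau_z = 0.02,
                           n_studies = 24, n_per_study = 500, cell_prob = 1,
                           culture_effect = c(east = 0, west = -0.5))
  sim <- simulate_studies(cfg, seed = 21)
  sg <- subgroup_analysis(sim$data, "SS-PS", "culture")
  expect_lt(sg$p, 0.01)
  # an age slope shows up in meta-regression with the right sign
  cfg2 <- simulation_config(a = -0.3, b = -0.3, cp = 0.3, tau_z = 0.02,
                            n_studies = 40, n_per_study = 500, cell_prob = 1,
                            age_slope = 0.05)
  sim2 <- simulate_studies(cfg2, seed = 22)
  mr <- meta_regression(sim2$data, "SS-PS", "child_age")
  expect_gt(mr$slope, 0)
  expect_lt(mr$p, 0.05)
})

test_that("pooled-estimate precision improves with study size", {
  pooled_r <- function(n_per, seed) {
    cfg <- simulation_config(tau_z = 0, n_studies = 8, n_per_study = n_per,
                             cell_prob = 1)
    sim <- simulate_studies(cfg, seed = seed)
    pool_effects(sim$data, "SS-PS", model = "fixed")$r
  }
  small <- vapply(1:30, function(s) pooled_r(60, s), numeric(1))
  big <- vapply(1:30, function(s) pooled_r(2000, 1000 + s), numeric(1))
  expect_gt(stats::sd(small), stats::sd(big))
})

test_that("generator config is validated", {
  expect_error(simulation_config(a = 0.9, b = 0.9, cp = 0.9), "positive definite")
  expect_error(simulation_config(reliability = c(0.8, 0.9, 1.4)))
  expect_error(simulation_config(tau_z = -0.1))
  expect_error(simulate_studies(simulation_config()), "seed")
})
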