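test_that("the saturated model reproduces the observed matrix exactly", {
  fit <- fit_mediation(table5_matrix())
  expect_true(fit$converged)
  expect_identical(fit$df, 0L)
  expect_lt(fit$chi2, 1e-6)
  expect_lt(max(abs(fit$S - fit$implied)), 1e-8)
  set.seed(17)
  for (i in 1:10) {
    S <- rand_corr3()
    f <- suppressWarnings(fit_mediation(masem_matrix(S), n = 500))
    expect_lt(f$chi2, 1e-6)
    expect_lt(max(abs(S - f$implied)), 1e-7)
  }
})

test_that("the ML optimizer agrees with the closed-form oracle on random matrices", {
  set.seed(19)
  for (i in 1:200) {
    S <- rand_corr3()
    # suppression patterns legitimately push standardized paths past 1,
    # which fit_mediation flags; the oracle identity must hold regardless
    f <- suppressWarnings(fit_mediation(masem_matrix(S), n = 1000))
    expect_equal(unname(coef(f)), unname(mediation_closed_form(S)),
                 tolerance = 1e-6)
  }
  # and through a measurement layer: paths estimated on the observed matrix
  # with reliabilities equal those computed on the disattenuated matrix
  m <- table5_matrix()
  f <- fit_mediation(m)
  expect_equal(unname(coef(f)), unname(mediation_closed_form(disattenuate(m))),
               tolerance = 1e-6)
})

test_that("mediation_closed_form handles its boundary algebra", {
  expect_equal(unname(mediation_closed_form(diag(3))), c(0, 0, 0))
  # orthogonality: r_SQ = r_SP * r_PQ makes the direct path vanish
  L <- implied_latent_matrix(-0.5, -0.4, 0)
  expect_equal(unname(mediation_closed_form(L)["cp"]), 0, tolerance = 1e-12)
  sing <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  expect_error(mediation_closed_form(sing), "singular")
})

test_that("chi-square scales linearly in N - 1 and vanishes for a true model", {
  m <- table5_matrix()
  f1 <- fit_mediation(m, model = "full", n = 1000)
  f2 <- fit_mediation(m, model = "full", n = 1999)
  expect_equal(f2$chi2 / f1$chi2, 1998 / 999, tolerance = 1e-6)
  # an observed matrix exactly consistent with full mediation fits perfectly
  rel <- c(0.86, 0.84, 0.87)
  L <- implied_latent_matrix(-0.45, -0.35, 0)
  lam <- sqrt(rel)
  S <- L * tcrossprod(lam); diag(S) <- 1
  f0 <- fit_mediation(masem_matrix(S, reliability = rel), model = "full", n = 5000)
  expect_lt(f0$chi2, 1e-6)
  # RMSEA identity
  expect_equal(f1$rmsea, sqrt(max(0, f1$chi2 - 1) / (1 * 999)), tolerance = 1e-10)
})

test_that("fit accessors and the nested comparison behave", {
  m <- table5_matrix()
  sat <- fit_mediation(m)
  full <- fit_mediation(m, model = "full")
  expect_named(coef(sat), c("a", "b", "cp"))
  V <- vcov(sat)
  expect_true(isSymmetric(V, tol = 1e-10))
  expect_true(all(diag(V) > 0))
  cmp <- compare_nested(full, sat)
  expect_identical(cmp$delta_df, 1L)
  expect_gt(cmp$delta_chi2, 0)
  expect_lt(cmp$p, 0.001)
  # saturated against itself: the trivial comparison
  self <- compare_nested(sat, sat)
  expect_equal(self$delta_chi2, 0)
  expect_identical(self$p, 1)
  expect_error(compare_nested(sat, full), "not nested")
  other <- fit_mediation(m, n = 999)
  expect_error(compare_nested(full, other), "same data")
  tab <- anova(full, sat)
  expect_equal(tab$delta_chi2[2], cmp$delta_chi2)
})

test_that("Monte Carlo mediation effects are reproducible and coherent", {
  fit <- fit_mediation(table5_matrix())
  e1 <- mediation_effects(fit, draws = 5000, seed = 99)
  e2 <- mediation_effects(fit, draws = 5000, seed = 99)
  expect_identical(e1$ci, e2$ci)
  e3 <- mediation_effects(fit, draws = 5000, seed = 100)
  expect_false(identical(e1$ci, e3$ci))
  # total = direct + indirect identically
  expect_equal(unname(e1$estimates["total"]),
               unname(e1$estimates["direct"] + e1$estimates["indirect"]))
  expect_true(all(e1$ci[, "lower"] < e1$ci[, "upper"]))
  expect_error(mediation_effects(fit), "seed")
  expect_warning(mediation_effects(fit, draws = 100, seed = 1), "1000")
  # a path fixed at zero has a degenerate (point) interval
  full <- fit_mediation(table5_matrix(), model = "full")
  ef <- mediation_effects(full, draws = 2000, seed = 5)
  expect_identical(unname(ef$ci["direct", ]), c(0, 0))
  expect_identical(unname(ef$estimates["direct"]), 0)
})

test_that("mediation_effects leaves the caller's RNG stream untouched", {
  fit <- fit_mediation(table5_matrix())
  set.seed(123)
  x1 <- rnorm(1)
  set.seed(123)
  invisible(mediation_effects(fit, draws = 2000, seed = 77))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("multigroup comparison flags only truly differing paths", {
  r <- diag(3); r[1, 2] <- r[2, 1] <- -0.4; r[1, 3] <- r[3, 1] <- -0.45
  r[2, 3] <- r[3, 2] <- 0.5
  m <- masem_matrix(r)
  # identical groups: every CMIN is numerically zero
  g0 <- multigroup_compare(list(x = m, y = m), n = c(800, 800))
  expect_true(all(g0$tests$cmin < 1e-4))
  # one path grossly different: only that CMIN is large
  La <- implied_latent_matrix(-0.4, -0.35, 0.6)
  Lb <- implied_latent_matrix(-0.4, -0.35, 0.0)
  g1 <- multigroup_compare(list(x = masem_matrix(La), y = masem_matrix(Lb)),
                           n = c(1000, 1000))
  tests <- g1$tests
  expect_gt(tests$cmin[tests$path == "cp"], 3.84)
  expect_lt(tests$cmin[tests$path == "a"], 0.5)
  expect_error(multigroup_compare(list(m), n = 500), "two groups")
})
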