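test_that("fixed-effect subgroup analysis partitions Q exactly", {
  set.seed(13)
  for (i in 1:10) {
    k <- 12
    d <- make_studies(r = stats::runif(k, -0.5, 0.5), n = sample(30:300, k),
                      role = sample(c("mother", "father"), k, replace = TRUE))
    sg <- subgroup_analysis(d, "SS-PS", "role", pool_within = "fixed")
    expect_equal(sg$Q_total, sg$Q_between + sg$Q_within, tolerance = 1e-10)
  }
})

test_that("between-group Q has its two-level closed form and null behavior", {
  z <- list(atanh(c(0.1, 0.2, 0.15)), atanh(c(0.4, 0.5)))
  v <- list(1 / (c(50, 80, 60) - 3), 1 / (c(90, 120) - 3))
  pools <- Map(pool_fixed, z, v)
  bq <- between_group_q(pools)
  W <- vapply(pools, function(p) 1 / p$se_z^2, numeric(1))
  zj <- vapply(pools, function(p) p$z, numeric(1))
  expect_equal(bq$Q_between, prod(W) / sum(W) * diff(zj)^2, tolerance = 1e-12)
  # equal pooled means: Q_between = 0, p = 1
  same <- list(pool_fixed(rep(0.3, 2), rep(0.01, 2)),
               pool_fixed(rep(0.3, 3), rep(0.02, 3)))
  bq0 <- between_group_q(same)
  expect_equal(bq0$Q_between, 0, tolerance = 1e-14)
  expect_equal(bq0$p, 1)
  expect_error(between_group_q(same[1]), "two levels")
})

test_that("duplicated levels carry no between-group heterogeneity", {
  d <- make_studies(r = c(0.2, 0.4, 0.2, 0.4), n = c(100, 150, 100, 150),
                    role = c("mother", "mother", "father", "father"))
  sg <- subgroup_analysis(d, "SS-PS", "role", pool_within = "fixed")
  expect_lt(sg$Q_between, 1e-12)
})

test_that("subgroup analysis drops unreported moderators and needs two levels", {
  d <- make_studies(r = c(0.2, 0.3, 0.4), n = c(50, 60, 70),
                    role = c("mother", "not_reported", "mother"))
  expect_error(subgroup_analysis(d, "SS-PS", "role"), "fewer than two")
  d2 <- make_studies(r = c(0.2, 0.3, 0.4), n = c(50, 60, 70),
                     role = c("mother", "father", "mother"))
  expect_warning(sg <- subgroup_analysis(d2, "SS-PS", "role"), "single effect")
  expect_identical(sg$levels$father$k, 1L)
})

test_that("meta-regression matches metafor's mixed-effects fit on the fixture", {
  d <- asd_parenting_studies()
  mr <- meta_regression(d, "SS-PS", "child_age")
  s <- d[d$relationship == "SS-PS" & !is.na(d$child_age), ]
  f <- metafor::rma(yi = atanh(s$r), vi = 1 / (s$n - 3), mods = ~child_age,
                    data = s, method = "DL")
  expect_identical(mr$k, 18L)
  expect_equal(mr$slope, unname(coef(f)["child_age"]), tolerance = 1e-10)
  expect_equal(mr$se, f$se[2], tolerance = 1e-10)
  expect_equal(mr$tau2, f$tau2, tolerance = 1e-10)
  expect_equal(mr$p, f$pval[2], tolerance = 1e-10)
})

test_that("meta-regression is translation invariant and guards its inputs", {
  d <- asd_parenting_studies()
  mr <- meta_regression(d, "SS-PS", "child_age")
  d2 <- d; d2$child_age <- d2$child_age + 100
  mr2 <- meta_regression(d2, "SS-PS", "child_age")
  expect_equal(mr2$slope, mr$slope, tolerance = 1e-10)
  expect_equal(mr2$se, mr$se, tolerance = 1e-8)
  dc <- make_studies(r = c(0.1, 0.2, 0.3), n = c(50, 60, 70), child_age = 5)
  expect_error(meta_regression(dc, "SS-PS", "child_age"), "zero variance")
  expect_error(meta_regression(dc[1:2, ], "SS-PS", "child_age"), "k >= 3")
})

test_that("meta-regression is calibrated under a null slope", {
  # 200 seeded replicates of k = 50 studies with no true moderator effect:
  # the |slope| < 2 SE event should occur at about its nominal 95% rate
  # (binomial fluctuation allowed)
  set.seed(29)
  inside <- vapply(1:200, function(i) {
    n <- sample(50:400, 50, replace = TRUE)
    x <- stats::runif(50, 2, 12)
    z <- 0.3 + stats::rnorm(50, 0, sqrt(1 / (n - 3)))
    d <- make_studies(r = tanh(z), n = n, child_age = x)
    mr <- meta_regression(d, "SS-PS", "child_age")
    abs(mr$slope) < 2 * mr$se
  }, logical(1))
  expect_gte(mean(inside), 0.91)
  expect_lte(mean(inside), 1.00)
})
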