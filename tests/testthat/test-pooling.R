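test_that("fixed-effect pooling matches hand computation and scales precision", {
  # single study passes through with its own Wald CI
  p1 <- pool_fixed(atanh(0.3), 1 / 47, n = 50)
  expect_equal(p1$r, 0.3)
  expect_equal(p1$ci, tanh(atanh(0.3) + c(-1, 1) * qnorm(0.975) * sqrt(1 / 47)))
  # two identical studies: same estimate, CI narrower by sqrt(2) on z scale
  p2 <- pool_fixed(rep(atanh(0.3), 2), rep(1 / 47, 2))
  expect_equal(p2$r, 0.3)
  expect_equal(p1$se_z / p2$se_z, sqrt(2))
  expect_error(pool_fixed(numeric(0), numeric(0)), "no effects")
})

test_that("DerSimonian-Laird pooling agrees with a step-by-step oracle", {
  dl_oracle <- function(z, v) {
    w <- 1 / v
    zf <- sum(w * z) / sum(w)
    Q <- sum(w * (z - zf)^2)
    tau2 <- max(0, (Q - (length(z) - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (v + tau2)
    list(r = tanh(sum(ws * z) / sum(ws)), tau2 = tau2,
         se = sqrt(1 / sum(ws)))
  }
  z <- atanh(c(0.1, 0.3, 0.5)); v <- rep(1 / 47, 3)
  p <- pool_random(z, v)
  o <- dl_oracle(z, v)
  expect_equal(p$r, o$r, tolerance = 1e-12)
  expect_equal(p$het$tau2, o$tau2, tolerance = 1e-12)
  expect_equal(p$se_z, o$se, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:12, 1)
    z <- atanh(stats::runif(k, -0.6, 0.6))
    v <- 1 / (sample(20:500, k) - 3)
    p <- pool_random(z, v)
    o <- dl_oracle(z, v)
    expect_equal(p$r, o$r, tolerance = 1e-12)
    expect_equal(p$het$tau2, o$tau2, tolerance = 1e-12)
  }
  expect_error(pool_random(atanh(0.3), 1 / 47), "k >= 2")
})

test_that("DL pooling matches metafor on a fixed instance", {
  z <- atanh(c(-0.1, 0.25, 0.4, 0.55)); v <- 1 / (c(40, 80, 160, 320) - 3)
  p <- pool_random(z, v)
  f <- metafor::rma(yi = z, vi = v, method = "DL")
  expect_equal(p$z, as.numeric(f$beta), tolerance = 1e-10)
  expect_equal(p$het$tau2, f$tau2, tolerance = 1e-10)
  expect_equal(p$het$Q, f$QE, tolerance = 1e-10)
  expect_equal(p$het$I2, f$I2, tolerance = 1e-8)
})

test_that("heterogeneity statistics obey their defining identities", {
  # identical effects: no heterogeneity at all
  h0 <- heterogeneity(rep(0.4, 5), rep(0.01, 5))
  expect_equal(h0$Q, 0)
  expect_equal(h0$I2, 0)
  expect_equal(h0$tau2, 0)
  # k = 2 closed form Q = w1 w2/(w1+w2) (z1-z2)^2
  z <- c(0.2, 0.6); v <- c(1 / 97, 1 / 37)
  h <- heterogeneity(z, v)
  w <- 1 / v
  expect_equal(h$Q, prod(w) / sum(w) * diff(z)^2, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    h <- heterogeneity(rnorm(k, 0, 0.3), 1 / (sample(20:200, k) - 3))
    expect_gte(h$I2, 0); expect_lt(h$I2, 100)
    expect_gte(h$tau2, 0)
  }
  expect_error(heterogeneity(0.3, 0.01), "k >= 2")
})

test_that("pooled estimates respect convex-hull and ordering invariants", {
  set.seed(9)
  for (i in 1:25) {
    k <- sample(2:10, 1)
    r <- stats::runif(k, -0.7, 0.7)
    z <- atanh(r); v <- 1 / (sample(20:300, k) - 3)
    pf <- pool_fixed(z, v); pr <- pool_random(z, v)
    for (p in list(pf, pr)) {
      expect_gte(p$r, min(r) - 1e-12)
      expect_lte(p$r, max(r) + 1e-12)
      expect_true(p$ci[1] < p$r && p$r < p$ci[2])
      expect_true(all(abs(p$ci) < 1))
    }
    # random-effects CI never narrower than fixed
    expect_gte(pr$se_z, pf$se_z - 1e-15)
    # tau2 = 0 implies the two models coincide
    if (pr$het$tau2 == 0) expect_equal(pr$r, pf$r, tolerance = 1e-14)
    # duplicating every study leaves the fixed-effect estimate unchanged
    pf2 <- pool_fixed(rep(z, 2), rep(v, 2))
    expect_equal(pf2$r, pf$r, tolerance = 1e-14)
  }
})

test_that("model selection follows the Q-or-I2 disjunction", {
  expect_identical(select_model(list(p = 0.01, I2 = 50)), "random")
  expect_identical(select_model(list(p = 0.30, I2 = 10)), "fixed")
  expect_identical(select_model(list(p = 0.30, I2 = 80)), "random")
})

test_that("classic fail-safe N matches its algebra", {
  v <- rep(1 / 97, 4)
  expect_identical(fail_safe_n(rep(0, 4), v), 0L)
  # one study whose normal deviate is 3 z_crit: N_fs = ceil(9 - 1) = 8
  zc <- qnorm(0.975)
  expect_identical(fail_safe_n(3 * zc * sqrt(1 / 97), 1 / 97), 8L)
  # one-tailed variant agrees with metafor's Rosenthal fsn
  d <- asd_parenting_studies()
  s <- d[d$relationship == "PS-QoL", ]
  z <- atanh(s$r); vv <- 1 / (s$n - 3)
  f <- metafor::fsn(z, vi = vv, type = "Rosenthal")
  expect_identical(fail_safe_n(z, vv, tails = 1), as.integer(f$fsnum))
})

test_that("pool_effects filters, auto-selects and optionally disattenuates", {
  d <- asd_parenting_studies()
  p <- pool_effects(d, "SS-PS")
  expect_identical(p$model, "random")   # Q strongly significant
  expect_identical(p$k, 23L)
  pf <- pool_effects(d, "SS-PS", model = "fixed")
  expect_identical(pf$model, "fixed")
  # attenuation correction grows the pooled magnitude
  da <- make_studies(r = c(-0.3, -0.4), n = c(100, 120),
                     rel_x = 0.8, rel_y = 0.9)
  pa <- pool_effects(da, "SS-PS", model = "fixed", attenuate = TRUE)
  expect_gt(abs(pa$r), abs(pool_effects(da, "SS-PS", model = "fixed")$r))
  expect_error(pool_effects(d[d$relationship == "SS-PS", ], "PS-QoL"),
               "no effects")
})
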