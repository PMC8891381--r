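# Stage one moderator analysis: subgroup Q-between tests and
# mixed-effects meta-regression for continuous moderators.

#' Between-group heterogeneity Q
#'
#' Given per-level pooled estimates, computes
#' \eqn{Q_B = \sum_j W_j (\bar z_j - \bar z)^2} where \eqn{W_j} is the
#' inverse squared standard error of level j's pooled Fisher-z mean and
#' \eqn{\bar z} the W-weighted grand mean, with a chi-square p-value on
#' (number of levels - 1) df.
#'
#' @param pools a list of two or more [masem_pool][pool_fixed()] objects.
#' @return a list with `Q_between`, `df`, `p`.
#' @export
between_group_q <- function(pools) {
  if (length(pools) < 2L) stop("need at least two levels", call. = FALSE)
  zj <- vapply(pools, function(p) p$z, numeric(1))
  Wj <- vapply(pools, function(p) 1 / p$se_z^2, numeric(1))
  zall <- sum(Wj * zj) / sum(Wj)
  Q <- sum(Wj * (zj - zall)^2)
  df <- length(pools) - 1L
  list(Q_between = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Categorical subgroup analysis of one relationship
#'
#' Splits the effects of one relationship by a categorical moderator, pools
#' within each level, and tests for a between-level difference with
#' [between_group_q()] (the analog-to-ANOVA partition of heterogeneity).
#' Records whose moderator is `"not_reported"`/`"not_applicable"` are
#' excluded and counted in `n_dropped`; the analysis can also be restricted
#' to a subset of levels via `levels` (the published tables compare selected
#' pairs, e.g. FSS vs MSPSS, leaving "other" instruments aside).
#'
#' Within-level pooling defaults to DerSimonian-Laird random effects with
#' the between-group Q computed on the random-effects level means -- the
#' mixed-effects subgroup analysis that reproduces the published moderator
#' table. `pool_within = "fixed"` gives the fully fixed-effect partition,
#' for which \eqn{Q_{total} = Q_{between} + \sum_j Q_{within,j}} holds
#' exactly (returned as `Q_within` and `Q_total`).
#'
#' @inheritParams pool_effects
#' @param moderator one of `"role"`, `"ss_measure"`, `"qol_focus"`,
#'   `"culture"`.
#' @param levels optional character vector restricting the compared levels.
#' @param pool_within `"random"` (default) or `"fixed"`.
#' @return a `masem_subgroup` object: per-level `masem_pool`s in `levels`,
#'   `Q_between`, `df`, `p`, the moderator name, `n_dropped`, and (always
#'   computed with fixed-effect weights) `Q_within`, `Q_total`.
#' @examples
#' d <- asd_parenting_studies()
#' subgroup_analysis(d, "SS-PS", "role", levels = c("father", "mother"))
#' @export
subgroup_analysis <- function(data, relationship, moderator,
                              levels = NULL,
                              pool_within = c("random", "fixed"),
                              alpha = 0.05) {
  stopifnot(inherits(data, "masem_data"))
  pool_within <- match.arg(pool_within)
  relationship <- match.arg(relationship, .relationships)
  moderator <- match.arg(moderator, c("role", "ss_measure", "qol_focus", "culture"))
  s <- data[data$relationship == relationship, ]
  g <- s[[moderator]]
  keep <- !g %in% c("not_reported", "not_applicable")
  if (!is.null(levels)) keep <- keep & g %in% levels
  n_dropped <- sum(!keep)
  s <- s[keep, ]; g <- g[keep]
  lv <- if (is.null(levels)) sort(unique(g)) else intersect(levels, unique(g))
  if (length(lv) < 2L) stop("fewer than two non-empty moderator levels", call. = FALSE)
  z <- fisher_z(s$r); v <- 1 / (s$n - 3)
  pools <- lapply(lv, function(l) {
    i <- which(g == l)
    if (length(i) == 1L) {
      warning("level '", l, "' has a single effect size")
      pool_fixed(z[i], v[i], alpha, n = s$n[i])
    } else if (pool_within == "random") {
      pool_random(z[i], v[i], alpha, n = s$n[i])
    } else {
      pool_fixed(z[i], v[i], alpha, n = s$n[i])
    }
  })
  names(pools) <- lv
  bq <- between_group_q(pools)
  # fixed-effect partition (for the exact Q decomposition)
  w <- 1 / v
  Q_total <- sum(w * (z - sum(w * z) / sum(w))^2)
  Q_within <- sum(vapply(lv, function(l) {
    i <- which(g == l); wi <- w[i]
    sum(wi * (z[i] - sum(wi * z[i]) / sum(wi))^2)
  }, numeric(1)))
  out <- list(relationship = relationship, moderator = moderator,
              levels = pools, pool_within = pool_within,
              Q_between = bq$Q_between, df = bq$df, p = bq$p,
              Q_within = Q_within, Q_total = Q_total,
              n_dropped = n_dropped, alpha = alpha)
  class(out) <- "masem_subgroup"
  out
}

#' @export
print.masem_subgroup <- function(x, digits = 3, ...) {
  cat(sprintf("Subgroup analysis of %s by %s (%s within levels)\n",
              x$relationship, x$moderator, x$pool_within))
  for (l in names(x$levels)) {
    p <- x$levels[[l]]
    cat(sprintf("  %-12s k = %2d  r = %6.*f  [%6.*f, %6.*f]\n",
                l, p$k, digits, p$r, digits, p$ci[1], digits, p$ci[2]))
  }
  cat(sprintf("  Q_between = %.*f (df = %d, p = %.3g)", digits, x$Q_between, x$df, x$p))
  if (x$n_dropped > 0) cat(sprintf("  [%d record(s) excluded]", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Mixed-effects meta-regression on a continuous moderator
#'
#' Regresses the Fisher-z effect sizes of one relationship on a continuous
#' study-level covariate. A first weighted least-squares pass with
#' fixed-effect weights \eqn{w_i = 1/v_i} yields the residual heterogeneity
#' \eqn{Q_E}, from which the method-of-moments residual between-study
#' variance is
#' \eqn{\hat\tau^2 = \max\{0, (Q_E - (k - p)) / (\mathrm{tr}(W) -
#' \mathrm{tr}[(X'WX)^{-1} X'W^2X])\}}; the final pass uses
#' \eqn{w_i^* = 1/(v_i + \hat\tau^2)}. Effects are regressed as signed
#' values exactly as coded (a positive slope on negative correlations means
#' the correlation weakens in magnitude).
#'
#' @inheritParams pool_effects
#' @param moderator name of a numeric column, e.g. `"child_age"`; records
#'   with a missing value are dropped.
#' @return a `masem_metareg` object: `slope`, `se`, `zval`, `p`, `ci`,
#'   `intercept`, `k`, `tau2`.
#' @examples
#' d <- asd_parenting_studies()
#' meta_regression(d, "SS-PS", "child_age")   # slope 0.037, Z = 2.31
#' @export
meta_regression <- function(data, relationship, moderator = "child_age",
                            alpha = 0.05) {
  stopifnot(inherits(data, "masem_data"))
  relationship <- match.arg(relationship, .relationships)
  s <- data[data$relationship == relationship, ]
  x <- s[[moderator]]
  if (!is.numeric(x)) stop("moderator must be numeric", call. = FALSE)
  keep <- !is.na(x)
  s <- s[keep, ]; x <- x[keep]
  k <- nrow(s)
  if (k < 3L) stop("meta-regression needs k >= 3 records with the moderator present",
                   call. = FALSE)
  if (stats::var(x) == 0) stop("moderator has zero variance", call. = FALSE)
  z <- fisher_z(s$r); v <- 1 / (s$n - 3)
  X <- cbind(1, x)
  wls <- function(w) {
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% z)
    list(beta = drop(beta), XtWX_inv = solve(XtW %*% X))
  }
  f0 <- wls(1 / v)
  res <- z - X %*% f0$beta
  QE <- sum((res^2) / v)
  denom <- sum(1 / v) - sum(diag(f0$XtWX_inv %*% (t(X * (1 / v)^2) %*% X)))
  tau2 <- max(0, (QE - (k - 2)) / denom)
  w <- 1 / (v + tau2)
  f1 <- wls(w)
  V <- f1$XtWX_inv  # weights are inverse total variances, so this is acov
  se <- sqrt(diag(V))
  zval <- f1$beta / se
  mult <- stats::qnorm(1 - alpha / 2)
  out <- list(relationship = relationship, moderator = moderator,
              slope = unname(f1$beta[2]), se = unname(se[2]),
              zval = unname(zval[2]),
              p = unname(2 * stats::pnorm(-abs(zval[2]))),
              ci = unname(f1$beta[2] + c(-1, 1) * mult * se[2]),
              intercept = unname(f1$beta[1]), k = k, tau2 = tau2,
              QE = QE, alpha = alpha)
  class(out) <- "masem_metareg"
  out
}

#' @export
print.masem_metareg <- function(x, digits = 3, ...) {
  cat(sprintf("Meta-regression of %s on %s (k = %d)\n",
              x$relationship, x$moderator, x$k))
  cat(sprintf("  slope b = %.*f (SE %.*f), Z = %.2f, p = %.3g, %d%% CI [%.*f, %.*f]\n",
              digits, x$slope, digits, x$se, x$zval, x$p,
              round(100 * (1 - x$alpha)), digits, x$ci[1], digits, x$ci[2]))
  cat(sprintf("  residual tau2 = %.4g\n", x$tau2))
  invisible(x)
}
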