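# Stage one: inverse-variance pooling on the Fisher-z scale.

.zcrit <- 1.959964  # two-sided 95%

#' Heterogeneity statistics on the Fisher-z scale
#'
#' Cochran's \eqn{Q = \sum w_i (z_i - \bar z)^2} with fixed-effect weights
#' \eqn{w_i = 1/v_i}, its chi-square p-value on \eqn{k - 1} df,
#' \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}, and the DerSimonian-Laird
#' moment estimator
#' \eqn{\hat\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))}.
#'
#' @param z Fisher-z effect sizes (at least two).
#' @param v their sampling variances, \eqn{1/(n-3)} for correlations.
#' @return a list with `Q`, `df`, `p`, `I2` (percent), `tau2`.
#' @export
heterogeneity <- function(z, v) {
  k <- length(z)
  if (k < 2L) stop("heterogeneity requires k >= 2 effects", call. = FALSE)
  stopifnot(length(v) == k, all(v > 0))
  w <- 1 / v
  zbar <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar)^2)
  df <- k - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = I2, tau2 = tau2)
}

#' Choose between fixed- and random-effects pooling
#'
#' The random-effects model is selected when the heterogeneity Q test is
#' significant at `alpha` or \eqn{I^2} exceeds `i2_cut` percent; otherwise
#' the fixed-effects model.
#'
#' @param het a list as returned by [heterogeneity()].
#' @param alpha significance level for the Q test.
#' @param i2_cut \eqn{I^2} threshold in percent.
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(het, alpha = 0.05, i2_cut = 75) {
  if (het$p < alpha || het$I2 > i2_cut) "random" else "fixed"
}

#' Rosenthal's classic fail-safe N
#'
#' The number of unretrieved null studies that would be needed to bring the
#' combined significance of the observed effects down to `alpha`. With
#' per-study standard normal deviates \eqn{Z_i = z_i \sqrt{n_i - 3} =
#' z_i/\sqrt{v_i}}, the classic formula is
#' \eqn{N_{fs} = \lceil (\sum Z_i)^2 / z_{crit}^2 - k \rceil}, truncated at
#' zero.
#'
#' @inheritParams heterogeneity
#' @param alpha significance level defining \eqn{z_{crit}}.
#' @param tails 2 (default) or 1; the source software era differed in which
#'   it used, so both are available.
#' @return an integer count of hypothetical null studies.
#' @export
fail_safe_n <- function(z, v, alpha = 0.05, tails = 2) {
  stopifnot(length(z) >= 1L, length(v) == length(z), all(v > 0), tails %in% c(1, 2))
  zcrit <- stats::qnorm(1 - alpha / tails)
  n_fs <- (sum(z / sqrt(v)))^2 / zcrit^2 - length(z)
  max(0L, as.integer(ceiling(n_fs)))
}

# shared back-end: pooled z, its SE and CI on the r scale
.pool_z <- function(z, w, model, alpha) {
  zbar <- sum(w * z) / sum(w)
  se <- sqrt(1 / sum(w))
  mult <- stats::qnorm(1 - alpha / 2)
  list(model = model, z = zbar, se_z = se,
       r = tanh(zbar), ci = tanh(zbar + c(-1, 1) * mult * se),
       p = 2 * stats::pnorm(-abs(zbar / se)))
}

#' Pool Fisher-z effects under the fixed- or random-effects model
#'
#' `pool_fixed()` pools with inverse-variance weights \eqn{w_i = 1/v_i};
#' `pool_random()` uses DerSimonian-Laird weights
#' \eqn{w_i^* = 1/(v_i + \hat\tau^2)}. Both pool on the z scale and
#' back-transform the estimate and its 95 percent (or `1 - alpha`) Wald
#' interval to the correlation scale, so the bounds stay inside (-1, 1).
#'
#' @inheritParams heterogeneity
#' @param alpha two-sided confidence level is `1 - alpha`.
#' @param n optional per-study sample sizes (used for the reported total N
#'   and the fail-safe N; defaults to `1/v + 3`).
#' @return a `masem_pool` object: pooled `r`, `ci`, pooled `z` and `se_z`,
#'   `k`, `n_total`, heterogeneity statistics `het`, `fail_safe_n`, `model`.
#' @seealso [pool_effects()] for the data-frame interface.
#' @export
pool_fixed <- function(z, v, alpha = 0.05, n = NULL) {
  .pool_make(z, v, "fixed", alpha, n)
}

#' @rdname pool_fixed
#' @export
pool_random <- function(z, v, alpha = 0.05, n = NULL) {
  if (length(z) < 2L) {
    stop("random-effects pooling requires k >= 2; use pool_fixed() for a single effect",
         call. = FALSE)
  }
  .pool_make(z, v, "random", alpha, n)
}

.pool_make <- function(z, v, model, alpha, n = NULL) {
  k <- length(z)
  if (k < 1L) stop("no effects to pool", call. = FALSE)
  stopifnot(length(v) == k, all(v > 0))
  if (is.null(n)) n <- 1 / v + 3
  het <- if (k >= 2L) heterogeneity(z, v) else
    list(Q = 0, df = 0L, p = NA_real_, I2 = 0, tau2 = 0)
  w <- if (model == "random") 1 / (v + het$tau2) else 1 / v
  out <- .pool_z(z, w, model, alpha)
  out$k <- k
  out$n_total <- sum(n)
  out$het <- het
  out$fail_safe_n <- fail_safe_n(z, v, alpha = alpha)
  out$alpha <- alpha
  out$weights <- w
  class(out) <- "masem_pool"
  out
}

#' Pool the coded correlations of one relationship
#'
#' The data-frame front end to Stage-1 pooling: filters a [study_data()]
#' table to one relationship, transforms each correlation to Fisher's z
#' with variance \eqn{1/(n-3)}, and pools. With `model = "auto"` (default)
#' the fixed/random choice follows [select_model()]: random effects when the
#' Q test is significant at `alpha` or \eqn{I^2 > 75} percent.
#'
#' Pooling operates on the coded correlations as given. With
#' `attenuate = TRUE` each correlation is first disattenuated by its
#' study-reported reliabilities ([disattenuate_r()]; `default_rel`
#' substituted where a study reported none). The published Stage-1 tables
#' were produced without this correction, which instead enters Stage 2
#' through the latent measurement model, so the default is off.
#'
#' @param data a `masem_data` table.
#' @param relationship one of `"SS-PS"`, `"PS-QoL"`, `"SS-QoL"`.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param alpha significance level (CI coverage `1 - alpha`).
#' @param attenuate correct each r for unreliability before pooling.
#' @param default_rel reliability substituted when a study reports none.
#' @return a `masem_pool` object.
#' @examples
#' d <- asd_parenting_studies()
#' pool_effects(d, "SS-PS")          # random effects, r = -0.339
#' @export
pool_effects <- function(data, relationship, model = c("auto", "fixed", "random"),
                         alpha = 0.05, attenuate = FALSE, default_rel = 0.8) {
  stopifnot(inherits(data, "masem_data"))
  model <- match.arg(model)
  relationship <- match.arg(relationship, .relationships)
  s <- data[data$relationship == relationship, ]
  if (nrow(s) == 0L) stop("no effects for relationship ", relationship, call. = FALSE)
  r <- s$r
  if (attenuate) {
    rx <- ifelse(is.na(s$rel_x), default_rel, s$rel_x)
    ry <- ifelse(is.na(s$rel_y), default_rel, s$rel_y)
    r <- disattenuate_r(r, rx, ry)
    r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
  }
  z <- fisher_z(r)
  v <- 1 / (s$n - 3)
  if (model == "auto") {
    model <- if (nrow(s) >= 2L) select_model(heterogeneity(z, v), alpha) else "fixed"
  }
  out <- if (model == "random" && nrow(s) >= 2L) pool_random(z, v, alpha, n = s$n)
         else pool_fixed(z, v, alpha, n = s$n)
  out$relationship <- relationship
  out$attenuated <- attenuate
  out
}

#' @export
print.masem_pool <- function(x, digits = 3, ...) {
  cat(sprintf("%s-effects pooled correlation%s\n", x$model,
              if (!is.null(x$relationship)) paste0(" (", x$relationship, ")") else ""))
  cat(sprintf("  r = %.*f, %d%% CI [%.*f, %.*f], k = %d, N = %d\n",
              digits, x$r, round(100 * (1 - x$alpha)), digits, x$ci[1],
              digits, x$ci[2], x$k, as.integer(x$n_total)))
  if (x$k >= 2) {
    cat(sprintf("  Q = %.*f (df = %d, p = %.2g), I2 = %.*f%%, tau2 = %.4g\n",
                digits, x$het$Q, x$het$df, x$het$p, digits, x$het$I2, x$het$tau2))
  }
  cat("  classic fail-safe N =", x$fail_safe_n, "\n")
  invisible(x)
}
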