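# Monte Carlo (parametric bootstrap) intervals for the mediation effects.

# evaluate expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# draws from N(mu, V) via an eigendecomposition square root (V may be
# singular, e.g. a path fixed at zero)
.rmvnorm <- function(n, mu, V) {
  p <- length(mu)
  e <- eigen(V, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  matrix(stats::rnorm(n * p), n, p) %*% rt + rep(mu, each = n)
}

#' Monte Carlo test of the indirect, direct and total effects
#'
#' Samples the path coefficients from their joint asymptotic normal
#' distribution at the ML estimates (the Monte Carlo, or parametric
#' bootstrap, method -- it needs only the fitted matrix, not raw data) and
#' forms percentile 95 percent intervals for the indirect effect
#' \eqn{a \times b}, the direct effect \eqn{c'}, and the total effect
#' \eqn{c' + ab}. Point estimates and the reported standard errors use the
#' delta method; intervals are the 2.5/97.5 Monte Carlo percentiles.
#'
#' @param fit a converged [fit_mediation()] fit.
#' @param draws number of Monte Carlo draws (default 20000; fewer than 1000
#'   draws a warning, the percentiles are then unstable).
#' @param seed integer seed; required so the interval is reproducible. The
#'   caller's RNG state is left untouched.
#' @param alpha interval level is `1 - alpha`.
#' @return a `masem_mediation` object: `estimates`, `se`, `z`, `ci` (matrix
#'   with rows indirect/direct/total), `draws`, `seed`.
#' @examples
#' fit <- fit_mediation(asd_pooled_matrix())
#' mediation_effects(fit, seed = 1)
#' @export
mediation_effects <- function(fit, draws = 20000L, seed, alpha = 0.05) {
  stopifnot(inherits(fit, "masem_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (missing(seed)) stop("'seed' is required for a reproducible interval",
                          call. = FALSE)
  if (draws < 1000L) warning("fewer than 1000 draws: percentile interval is unstable")
  full <- fit$model == "full"
  est <- fit$estimates
  a <- est[["a"]]; b <- est[["b"]]; cp <- if (full) 0 else est[["cp"]]
  V3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "cp"), c("a", "b", "cp")))
  idx <- rownames(fit$vcov)
  V3[idx, idx] <- fit$vcov

  point <- c(indirect = a * b, direct = cp, total = cp + a * b)
  grad <- rbind(indirect = c(b, a, 0), direct = c(0, 0, 1), total = c(b, a, 1))
  se <- sqrt(pmax(0, diag(grad %*% V3 %*% t(grad))))

  sam <- .with_seed(seed, .rmvnorm(draws, c(a, b, cp), V3))
  eff <- cbind(indirect = sam[, 1] * sam[, 2],
               direct = sam[, 3],
               total = sam[, 3] + sam[, 1] * sam[, 2])
  ci <- t(apply(eff, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2)))
  colnames(ci) <- c("lower", "upper")

  out <- list(estimates = point, se = se, z = point / ifelse(se > 0, se, NA),
              ci = ci, draws = as.integer(draws), seed = seed,
              method = "monte_carlo", alpha = alpha, model = fit$model)
  class(out) <- "masem_mediation"
  out
}

#' @export
print.masem_mediation <- function(x, digits = 3, ...) {
  cat(sprintf("Mediation effects, Monte Carlo percentile %d%% CI (%d draws, seed %s)\n",
              round(100 * (1 - x$alpha)), x$draws, format(x$seed)))
  tab <- data.frame(estimate = x$estimates, se = x$se, z = x$z,
                    lower = x$ci[, "lower"], upper = x$ci[, "upper"])
  print(round(tab, digits))
  invisible(x)
}
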