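# Stage two: maximum-likelihood path analysis of the mediation triangle
# on a pooled correlation matrix, with a fixed single-indicator
# measurement layer (loading sqrt(reliability), error 1 - reliability).
#
# Construct order throughout: (parenting_stress, social_support,
# quality_of_life) = (P, S, Q). Structural model:
#   P = a*S + z1,  Q = cp*S + b*P + z2,  S exogenous with variance phi.
# Free parameters: a, b, (cp unless full mediation), and log-variances
# log(phi), log(psi1), log(psi2).

# latent covariance implied by the structural parameters
.latent_sigma <- function(a, b, cp, phi, psi1, psi2) {
  vS <- phi
  vP <- a^2 * phi + psi1
  cSP <- a * phi
  cSQ <- (cp + a * b) * phi
  cPQ <- a * (cp + a * b) * phi + b * psi1
  vQ <- (cp + a * b)^2 * phi + b^2 * psi1 + psi2
  matrix(c(vP, cSP, cPQ,
           cSP, vS, cSQ,
           cPQ, cSQ, vQ), 3, 3)
}

.par_unpack <- function(par, full) {
  par <- unname(par)
  if (full) list(a = par[1], b = par[2], cp = 0,
                 phi = exp(par[3]), psi1 = exp(par[4]), psi2 = exp(par[5]))
  else list(a = par[1], b = par[2], cp = par[3],
            phi = exp(par[4]), psi1 = exp(par[5]), psi2 = exp(par[6]))
}

.implied_sigma <- function(par, full, lam, theta) {
  p <- .par_unpack(par, full)
  L <- .latent_sigma(p$a, p$b, p$cp, p$phi, p$psi1, p$psi2)
  lam * rep(lam, each = 3) * L + diag(theta)
}

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - 3,
# guarded against indefinite Sigma during line searches
.fml_factory <- function(S, full, lam, theta) {
  ldS <- determinant(S, logarithm = TRUE)$modulus
  function(par) {
    Sig <- .implied_sigma(par, full, lam, theta)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < 1e-10)) return(1e10)
    2 * sum(log(diag(ch))) + sum(S * chol2inv(ch)) - as.numeric(ldS) - 3
  }
}

#' Closed-form saturated mediation paths from a latent correlation matrix
#'
#' For the three-construct mediation triangle the saturated model is just
#' two nested regressions, so the paths have closed forms: with the latent
#' correlations \eqn{r_{SP}, r_{PQ}, r_{SQ}},
#' \eqn{a = r_{SP}},
#' \eqn{b = (r_{PQ} - r_{SP} r_{SQ})/(1 - r_{SP}^2)},
#' \eqn{c' = (r_{SQ} - r_{SP} r_{PQ})/(1 - r_{SP}^2)}.
#' This is the independent algebraic oracle against which the ML optimizer
#' is checked.
#'
#' @param latent a 3x3 positive-definite latent correlation matrix in
#'   construct order (parenting stress, social support, quality of life).
#' @return named vector `c(a = , b = , cp = )`: support-to-stress,
#'   stress-to-QoL, and direct support-to-QoL paths.
#' @export
mediation_closed_form <- function(latent) {
  latent <- as.matrix(latent)
  r_SP <- latent[2, 1]; r_SQ <- latent[2, 3]; r_PQ <- latent[1, 3]
  if (abs(r_SP) >= 1) stop("singular design: |r_SP| = 1", call. = FALSE)
  den <- 1 - r_SP^2
  c(a = r_SP,
    b = (r_PQ - r_SP * r_SQ) / den,
    cp = (r_SQ - r_SP * r_PQ) / den)
}

#' Fit the latent mediation path model to a pooled correlation matrix
#'
#' Fits the three-construct mediation model (social support -> parenting
#' stress -> quality of life, with or without the direct support -> QoL
#' path) to a pooled correlation matrix by maximum likelihood. Each
#' construct is measured by a single indicator with fixed loading
#' \eqn{\sqrt{reliability}} and fixed error variance \eqn{1 - reliability},
#' so the structural coefficients refer to the disattenuated (latent)
#' constructs; with `reliability = NULL` the matrix is analyzed as is.
#'
#' The discrepancy \eqn{F = \log|\Sigma(\theta)| +
#' \mathrm{tr}(S\Sigma(\theta)^{-1}) - \log|S| - 3} is minimized by
#' quasi-Newton iterations from the closed-form start
#' ([mediation_closed_form()]); the correlation matrix is treated as a
#' covariance matrix of standardized variables, matching the conventional
#' software treatment. The test statistic is \eqn{\chi^2 = (N - 1)
#' F_{min}} at the fitting sample size N (default: the harmonic mean of
#' the per-cell total sample sizes), with
#' \eqn{df = 6 - \#\mathrm{parameters}} (0 for the saturated
#' partial-mediation model, 1 for full mediation) and
#' \eqn{RMSEA = \sqrt{\max(0, \chi^2 - df)/(df\,(N-1))}}.
#'
#' @param m a [masem_matrix()] (or plain 3x3 correlation matrix, taken to
#'   have perfectly reliable indicators and requiring an explicit `n`).
#' @param model `"partial"` (saturated: direct path included) or `"full"`
#'   (direct path fixed to zero).
#' @param n fitting sample size: `"harmonic"` (default) or a number.
#' @param reltol convergence tolerance on the discrepancy.
#' @return a `masem_fit` object with components `estimates` (standardized
#'   paths `a`, `b`, `cp`), `chi2`, `df`, `p`, `rmsea`, `n_fit`,
#'   `converged`, `vcov` (asymptotic covariance of the path estimates),
#'   `S`, `implied`, `model`, plus `coef()`, `vcov()`, `print()`,
#'   `summary()` and `anova()` methods.
#' @examples
#' fit <- fit_mediation(asd_pooled_matrix())
#' coef(fit)                       # -0.408, -0.379, 0.400
#' anova(fit_mediation(asd_pooled_matrix(), model = "full"), fit)
#' @export
fit_mediation <- function(m, model = c("partial", "full"), n = "harmonic",
                          reltol = 1e-12) {
  model <- match.arg(model)
  if (!inherits(m, "masem_matrix")) m <- masem_matrix(m)
  full <- model == "full"
  if (identical(n, "harmonic")) {
    if (is.null(m$cell_n)) stop("matrix carries no cell sample sizes; give 'n'",
                                call. = FALSE)
    n_fit <- harmonic_mean_n(m$cell_n)
  } else {
    n_fit <- as.numeric(n)
    stopifnot(is.finite(n_fit), n_fit > 6)
  }
  rel <- if (is.null(m$reliability)) rep(1, 3) else unname(m$reliability)
  lam <- sqrt(rel); theta <- 1 - rel
  S <- unname(m$r)

  # closed-form start on the disattenuated matrix
  latent <- disattenuate(m)
  st <- mediation_closed_form(latent)
  a0 <- st["a"]; b0 <- st["b"]; cp0 <- if (full) 0 else st["cp"]
  psi1 <- max(1e-4, 1 - a0^2)
  psi2 <- max(1e-4, 1 - ((cp0 + a0 * b0)^2 + b0^2 * psi1))
  par0 <- if (full) c(a0, b0, 0, log(psi1), log(psi2))
          else c(st, 0, log(psi1), log(psi2))
  obj <- .fml_factory(S, full, lam, theta)
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(reltol = reltol, maxit = 2000))
  if (opt$value > obj(par0)) { # defensive: never leave a good start
    opt$par <- par0; opt$value <- obj(par0); opt$convergence <- 0L
  }
  fmin <- max(0, opt$value)
  pars <- .par_unpack(opt$par, full)
  Lhat <- .latent_sigma(pars$a, pars$b, pars$cp, pars$phi, pars$psi1, pars$psi2)
  sd_S <- sqrt(Lhat[2, 2]); sd_P <- sqrt(Lhat[1, 1]); sd_Q <- sqrt(Lhat[3, 3])
  est <- c(a = pars$a * sd_S / sd_P,
           b = pars$b * sd_P / sd_Q,
           cp = if (full) 0 else pars$cp * sd_S / sd_Q)

  npar <- if (full) 5L else 6L
  df <- 6L - npar
  chi2 <- (n_fit - 1) * fmin
  rmsea <- if (df > 0) sqrt(max(0, chi2 - df) / (df * (n_fit - 1))) else 0

  # asymptotic covariance of the free parameters: 2/(N-1) * H^-1
  H <- tryCatch(stats::optimHess(opt$par, obj), error = function(e) NULL)
  vc <- NULL
  if (!is.null(H)) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi)) {
      vc_full <- 2 / (n_fit - 1) * Hi
      idx <- if (full) 1:2 else 1:3
      vc <- vc_full[idx, idx, drop = FALSE]
      dimnames(vc) <- list(names(est)[idx], names(est)[idx])
    }
  }
  converged <- opt$convergence == 0L && !is.null(vc)
  if (any(abs(est) > 1 + 1e-6)) {
    warning("inadmissible solution: a standardized path exceeds 1 in magnitude")
  }
  out <- list(estimates = est, chi2 = chi2, df = df,
              p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
              rmsea = rmsea, n_fit = n_fit, converged = converged,
              fmin = fmin, vcov = vc, par = opt$par, model = model,
              S = S, reliability = if (is.null(m$reliability)) NULL else m$reliability,
              implied = .implied_sigma(opt$par, full, lam, theta),
              call = match.call())
  class(out) <- "masem_fit"
  out
}

#' @export
coef.masem_fit <- function(object, ...) object$estimates

#' @export
vcov.masem_fit <- function(object, ...) object$vcov

#' @export
print.masem_fit <- function(x, digits = 3, ...) {
  lab <- c(a = "support -> stress   (a) ",
           b = "stress  -> QoL      (b) ",
           cp = "support -> QoL      (c')")
  cat(sprintf("Latent mediation path model (%s), ML on pooled correlations\n",
              if (x$model == "full") "full mediation" else "saturated partial mediation"))
  for (nm in names(x$estimates)) {
    if (x$model == "full" && nm == "cp") next
    se <- if (!is.null(x$vcov) && nm %in% rownames(x$vcov))
      sqrt(x$vcov[nm, nm]) else NA_real_
    cat(sprintf("  %s %7.*f  (SE %.*f)\n", lab[[nm]], digits,
                x$estimates[[nm]], digits, se))
  }
  cat(sprintf("  chi2 = %.*f, df = %d%s, N = %.1f%s\n", digits, x$chi2, x$df,
              if (x$df > 0) sprintf(", p = %.3g, RMSEA = %.*f", x$p, digits, x$rmsea)
              else "",
              x$n_fit, if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.masem_fit <- function(object, ...) {
  se <- if (is.null(object$vcov)) rep(NA_real_, length(object$estimates))
        else sqrt(diag(object$vcov))[names(object$estimates)]
  zv <- object$estimates / se
  tab <- data.frame(estimate = object$estimates, se = se, z = zv,
                    p = 2 * stats::pnorm(-abs(zv)))
  if (object$model == "full") tab <- tab[c("a", "b"), ]
  out <- list(paths = tab, chi2 = object$chi2, df = object$df, p = object$p,
              rmsea = object$rmsea, n_fit = object$n_fit, model = object$model,
              converged = object$converged)
  class(out) <- "summary.masem_fit"
  out
}

#' @export
print.summary.masem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Mediation path model (%s)\n", x$model))
  print(round(x$paths, digits))
  cat(sprintf("chi2 = %.*f, df = %d, RMSEA = %.*f, N = %.1f\n",
              digits, x$chi2, x$df, digits, x$rmsea, x$n_fit))
  invisible(x)
}

#' Chi-square difference test between nested mediation fits
#'
#' Compares the full-mediation model (direct path dropped) with the
#' saturated partial-mediation model fitted to the same matrix at the same
#' sample size: \eqn{\Delta\chi^2 = \chi^2_{full} - \chi^2_{saturated}} on
#' \eqn{\Delta df} degrees of freedom. Against the saturated baseline this
#' equals the full model's own chi-square. `anova()` on two `masem_fit`
#' objects is a synonym.
#'
#' @param fit_full the more constrained fit (larger df).
#' @param fit_saturated the baseline fit (smaller or equal df).
#' @return a list with `delta_chi2`, `delta_df`, `p`.
#' @export
compare_nested <- function(fit_full, fit_saturated) {
  stopifnot(inherits(fit_full, "masem_fit"), inherits(fit_saturated, "masem_fit"))
  if (max(abs(fit_full$S - fit_saturated$S)) > 1e-10 ||
      abs(fit_full$n_fit - fit_saturated$n_fit) > 1e-8) {
    stop("fits are not on the same data", call. = FALSE)
  }
  ddf <- fit_full$df - fit_saturated$df
  dchi <- fit_full$chi2 - fit_saturated$chi2
  if (ddf < 0L || (ddf == 0L && abs(dchi) > 1e-6)) {
    stop("models are not nested (df of the first must exceed that of the second)",
         call. = FALSE)
  }
  dchi <- max(0, dchi)
  list(delta_chi2 = dchi, delta_df = ddf,
       p = if (ddf > 0) stats::pchisq(dchi, ddf, lower.tail = FALSE) else 1)
}

#' @export
anova.masem_fit <- function(object, ...) {
  others <- list(...)
  if (length(others) != 1L || !inherits(others[[1]], "masem_fit")) {
    stop("anova() needs exactly two masem_fit objects", call. = FALSE)
  }
  cmp <- compare_nested(object, others[[1]])
  tab <- data.frame(df = c(object$df, others[[1]]$df),
                    chi2 = c(object$chi2, others[[1]]$chi2),
                    delta_chi2 = c(NA, cmp$delta_chi2),
                    delta_df = c(NA, cmp$delta_df),
                    p = c(NA, cmp$p))
  rownames(tab) <- c("model 1", "model 2")
  structure(tab, heading = "Chi-square difference test", class = c("anova", "data.frame"))
}
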