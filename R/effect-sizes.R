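#' Fisher's z transform of a correlation
#'
#' `fisher_z()` maps a Pearson correlation to the z scale,
#' \eqn{z = 0.5 \log((1+r)/(1-r)) = \mathrm{artanh}(r)}, on which effect
#' sizes are approximately normal with sampling variance \eqn{1/(n-3)}.
#' `fisher_z_inv()` is the inverse, \eqn{r = \tanh(z)}.
#'
#' @param r numeric vector of correlations, each strictly inside (-1, 1).
#' @param z numeric vector of Fisher-z values.
#' @return numeric vector of the same length.
#' @examples
#' fisher_z(0.62)            # 0.725
#' fisher_z_inv(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(abs(r) >= 1)) {
    stop("'r' must be numeric with |r| < 1", call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    stop("'z' must be finite numeric", call. = FALSE)
  }
  tanh(z)
}

#' Correct a correlation for measurement unreliability
#'
#' Divides an observed correlation by the square root of the product of the
#' two measures' reliabilities (the classical attenuation correction). A
#' corrected value outside \eqn{[-1, 1]} is clamped to the boundary with a
#' warning, since it signals inconsistent inputs rather than a valid latent
#' correlation.
#'
#' @param r observed correlation(s) in (-1, 1).
#' @param rel_x,rel_y reliabilities of the two measures, each in (0, 1].
#' @return the disattenuated correlation(s), clamped to \eqn{[-1, 1]}.
#' @examples
#' disattenuate_r(-0.346, 0.837, 0.860)   # -0.408
#' @export
disattenuate_r <- function(r, rel_x, rel_y) {
  if (any(rel_x <= 0) || any(rel_x > 1) || any(rel_y <= 0) || any(rel_y > 1)) {
    stop("reliabilities must lie in (0, 1]", call. = FALSE)
  }
  out <- r / sqrt(rel_x * rel_y)
  if (any(abs(out) > 1)) {
    warning("disattenuated correlation outside [-1, 1]; clamped to the boundary")
    out <- pmin(1, pmax(-1, out))
  }
  out
}

#' Composite-score correlation from subdimension correlations
#'
#' When a study reports only correlations between the subdimensions of two
#' constructs, the correlation between the (unit-weighted) composite scores
#' is
#' \deqn{r_{xy} = \frac{\sum_{i,j} r_{x_i y_j}}
#'   {\sqrt{p + p(p-1)\bar r_{x_i x_j}}\ \sqrt{q + q(q-1)\bar r_{y_i y_j}}},}
#' where \eqn{p} and \eqn{q} are the numbers of subdimensions and
#' \eqn{\bar r_{x_i x_j}}, \eqn{\bar r_{y_i y_j}} the mean intercorrelations
#' within each construct. With a single subdimension on a side the mean
#' intercorrelation is irrelevant and the formula reduces to the reported
#' correlation.
#'
#' @param r_cross p x q matrix (or vector, coerced to a one-column matrix)
#'   of cross-correlations between the subdimensions of X and of Y.
#' @param r_xx mean intercorrelation among the X subdimensions. Ignored when
#'   `p = 1`.
#' @param r_yy mean intercorrelation among the Y subdimensions. Ignored when
#'   `q = 1`.
#' @return the composite correlation, a single number in \eqn{[-1, 1]}.
#' @examples
#' composite_correlation(matrix(0.3, 2, 2), r_xx = 0.5, r_yy = 0.5)
#' composite_correlation(0.42)   # p = q = 1 passes through
#' @export
composite_correlation <- function(r_cross, r_xx = NA_real_, r_yy = NA_real_) {
  r_cross <- as.matrix(r_cross)
  p <- nrow(r_cross); q <- ncol(r_cross)
  if (any(abs(r_cross) >= 1)) stop("cross-correlations must lie in (-1, 1)", call. = FALSE)
  den_x <- if (p == 1L) 1 else {
    if (is.na(r_xx)) stop("'r_xx' required when p > 1", call. = FALSE)
    p + p * (p - 1) * r_xx
  }
  den_y <- if (q == 1L) 1 else {
    if (is.na(r_yy)) stop("'r_yy' required when q > 1", call. = FALSE)
    q + q * (q - 1) * r_yy
  }
  if (den_x <= 0 || den_y <= 0) {
    stop("degenerate subdimension block: composite variance is not positive",
         call. = FALSE)
  }
  out <- sum(r_cross) / (sqrt(den_x) * sqrt(den_y))
  if (abs(out) > 1) {
    warning("composite correlation outside [-1, 1]; clamped")
    out <- sign(out)
  }
  out
}

#' Inter-rater agreement percentage
#'
#' Simple percent agreement between two coders,
#' `100 * n_agree / (n_agree + n_disagree)`.
#'
#' @param n_agree,n_disagree nonnegative counts; their sum must be positive.
#' @return agreement in percent.
#' @examples
#' interrater_agreement(33, 4)   # 89.19
#' @export
interrater_agreement <- function(n_agree, n_disagree) {
  if (n_agree < 0 || n_disagree < 0 || n_agree + n_disagree <= 0) {
    stop("counts must be nonnegative with a positive total", call. = FALSE)
  }
  100 * n_agree / (n_agree + n_disagree)
}
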