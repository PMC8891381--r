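# Stage two inputs: the pooled 3x3 correlation matrix.

#' A pooled correlation matrix with construct reliabilities
#'
#' Container for the Stage-2 input: a symmetric 3x3 correlation matrix over
#' the constructs (parenting stress, social support, quality of life), the
#' mean measurement reliability of each construct, and the per-cell study
#' counts and total sample sizes inherited from Stage 1. The matrix must be
#' positive definite before any structural model is fitted; this is checked
#' at construction.
#'
#' @param r symmetric 3x3 numeric matrix with unit diagonal and
#'   off-diagonal entries strictly inside (-1, 1). Rows/columns are taken in
#'   construct order (parenting_stress, social_support, quality_of_life).
#' @param reliability named or positional numeric vector of three mean
#'   reliabilities in (0, 1], or `NULL` for perfectly reliable (no
#'   measurement adjustment).
#' @param cell_n per-relationship total sample sizes, named by
#'   `"SS-PS"`, `"PS-QoL"`, `"SS-QoL"` (or positional in that order).
#' @param cell_k per-relationship study counts (optional bookkeeping).
#' @return a `masem_matrix` object.
#' @seealso [pooled_matrix()] to assemble one from a study table,
#'   [fit_mediation()] to fit it.
#' @export
masem_matrix <- function(r, reliability = NULL, cell_n = NULL, cell_k = NULL) {
  r <- as.matrix(r)
  stopifnot(identical(dim(r), c(3L, 3L)))
  if (max(abs(r - t(r))) > 1e-10) stop("matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-10) stop("matrix must have unit diagonal", call. = FALSE)
  off <- r[lower.tri(r)]
  if (any(abs(off) >= 1)) stop("off-diagonal correlations must lie in (-1, 1)",
                               call. = FALSE)
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("pooled correlation matrix is not positive definite", call. = FALSE)
  }
  dimnames(r) <- list(.constructs, .constructs)
  if (!is.null(reliability)) {
    reliability <- .named3(reliability, .constructs, "reliability")
    if (any(reliability <= 0 | reliability > 1)) {
      stop("reliabilities must lie in (0, 1]", call. = FALSE)
    }
  }
  if (!is.null(cell_n)) {
    cell_n <- .named3(cell_n, .relationships, "cell_n")
    stopifnot(all(cell_n > 0))
  }
  if (!is.null(cell_k)) cell_k <- .named3(cell_k, .relationships, "cell_k")
  out <- list(r = r, reliability = reliability, cell_n = cell_n, cell_k = cell_k)
  class(out) <- "masem_matrix"
  out
}

.named3 <- function(x, nms, what) {
  x <- unlist(x)
  if (length(x) != 3L) stop("'", what, "' must have three entries", call. = FALSE)
  if (is.null(names(x))) names(x) <- nms else {
    if (!setequal(names(x), nms)) stop("'", what, "' must be named by ",
                                       paste(nms, collapse = ", "), call. = FALSE)
    x <- x[nms]
  }
  x
}

#' @export
print.masem_matrix <- function(x, digits = 3, ...) {
  cat("Pooled correlation matrix (3 constructs)\n")
  print(round(x$r, digits))
  if (!is.null(x$reliability)) {
    cat("mean reliabilities:",
        paste(sprintf("%s = %.3f", names(x$reliability), x$reliability),
              collapse = ", "), "\n")
  }
  if (!is.null(x$cell_n)) {
    cat("cell N:", paste(sprintf("%s = %d", names(x$cell_n),
                                 as.integer(x$cell_n)), collapse = ", "),
        " (harmonic mean", round(harmonic_mean_n(x$cell_n), 1), ")\n")
  }
  invisible(x)
}

#' Assemble the pooled matrix from a coded study table
#'
#' Runs Stage-1 pooling ([pool_effects()]) for each of the three
#' relationships and places the pooled correlations in the 3x3 matrix.
#' Construct reliabilities are the means of the study-reported scale
#' reliabilities for each construct, with `default_rel` (0.8, a
#' conservative convention) substituted for every study that reported none;
#' a `reliability` argument overrides this (the packaged study table does
#' not carry per-study reliabilities, so the published means are supplied
#' that way, see [asd_pooled_matrix()]).
#'
#' @inheritParams pool_effects
#' @param reliability optional per-construct reliabilities overriding the
#'   computed means; `NULL` and no reported reliabilities means every
#'   construct gets `default_rel`.
#' @return a [masem_matrix()] with per-cell k and N recorded.
#' @export
pooled_matrix <- function(data, model = c("auto", "fixed", "random"),
                          reliability = NULL, default_rel = 0.8,
                          alpha = 0.05) {
  stopifnot(inherits(data, "masem_data"))
  model <- match.arg(model)
  absent <- setdiff(.relationships, unique(data$relationship))
  if (length(absent)) stop("relationship(s) missing from the data: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  pools <- lapply(.relationships, function(rl) pool_effects(data, rl, model, alpha))
  names(pools) <- .relationships
  r <- diag(3)
  dimnames(r) <- list(.constructs, .constructs)
  for (rl in .relationships) {
    cc <- .cell_constructs[[rl]]
    r[cc[1], cc[2]] <- r[cc[2], cc[1]] <- pools[[rl]]$r
  }
  if (is.null(reliability)) {
    reliability <- vapply(.constructs, function(con) {
      vals <- c()
      for (rl in .relationships) {
        cc <- .cell_constructs[[rl]]
        s <- data[data$relationship == rl, ]
        if (con == cc[1]) vals <- c(vals, s$rel_x)
        if (con == cc[2]) vals <- c(vals, s$rel_y)
      }
      vals[is.na(vals)] <- default_rel
      mean(vals)
    }, numeric(1))
  }
  m <- masem_matrix(r, reliability = reliability,
                    cell_n = vapply(pools, function(p) p$n_total, numeric(1)),
                    cell_k = vapply(pools, function(p) as.numeric(p$k), numeric(1)))
  m$pools <- pools
  m
}

#' Harmonic mean of cell sample sizes
#'
#' The sample-size convention for fitting a structural model to a pooled
#' matrix whose cells rest on different numbers of participants:
#' \eqn{m / \sum_i 1/N_i} over the m cells.
#'
#' @param n positive sample sizes.
#' @return their harmonic mean.
#' @examples
#' harmonic_mean_n(c(6051, 3242, 4127))   # 4189.8
#' @export
harmonic_mean_n <- function(n) {
  stopifnot(length(n) >= 1L, all(n > 0))
  length(n) / sum(1 / n)
}

#' Disattenuate a pooled correlation matrix
#'
#' Returns the latent correlation matrix implied by the single-indicator
#' measurement model: each off-diagonal entry divided by the square root of
#' the product of the two constructs' reliabilities, unit diagonal. Errors
#' if any corrected entry reaches magnitude 1 (the measurement model is then
#' inadmissible).
#'
#' @param m a [masem_matrix()]; with `NULL` reliabilities the matrix is
#'   returned unchanged.
#' @return a plain 3x3 latent correlation matrix.
#' @export
disattenuate <- function(m) {
  stopifnot(inherits(m, "masem_matrix"))
  if (is.null(m$reliability)) return(m$r)
  lam <- sqrt(m$reliability)
  out <- m$r / tcrossprod(lam)
  diag(out) <- 1
  if (any(abs(out[lower.tri(out)]) >= 1)) {
    stop("disattenuated correlation reaches |r| >= 1: measurement model inadmissible",
         call. = FALSE)
  }
  out
}
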