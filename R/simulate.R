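# Synthetic study sets drawn from a known latent mediation truth, for
# ground-truth testing of the whole two-stage pipeline.

#' Correlation matrix implied by standardized mediation paths
#'
#' For the standardized mediation triangle with paths `a` (support ->
#' stress), `b` (stress -> QoL) and `cp` (direct support -> QoL), the
#' implied latent correlations are \eqn{r_{SP} = a},
#' \eqn{r_{PQ} = b + a c'}, \eqn{r_{SQ} = c' + a b}. The result is
#' returned in construct order (parenting stress, social support, quality
#' of life) and must be positive definite.
#'
#' @param a,b,cp standardized path coefficients.
#' @return a 3x3 latent correlation matrix.
#' @examples
#' implied_latent_matrix(-0.408, -0.379, 0.400)
#' @export
implied_latent_matrix <- function(a, b, cp) {
  r_SP <- a; r_PQ <- b + a * cp; r_SQ <- cp + a * b
  m <- matrix(c(1, r_SP, r_PQ,
                r_SP, 1, r_SQ,
                r_PQ, r_SQ, 1), 3, 3,
              dimnames = list(.constructs, .constructs))
  if (any(abs(m[lower.tri(m)]) >= 1) ||
      min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("paths imply a correlation matrix that is not positive definite",
         call. = FALSE)
  }
  m
}

#' Configuration of the synthetic study-set generator
#'
#' Collects and validates the ground truth and the study-level sampling
#' design for [simulate_studies()]. The defaults emulate the packaged ASD
#' parenting study table: 31 independent samples with sizes drawn uniformly
#' from the fixture's observed range, each sample reporting each
#' relationship with the fixture's empirical frequency, true paths and
#' reliabilities set to the fitted values of the motivating analysis, and
#' between-study heterogeneity of SD 0.12 on the Fisher-z scale (about the
#' middle of the three fixture estimates).
#'
#' @param a,b,cp true standardized paths (support->stress, stress->QoL,
#'   direct support->QoL); the implied matrix must be positive definite.
#' @param reliability per-construct reliabilities in (0, 1], order
#'   (parenting stress, social support, quality of life).
#' @param tau_z between-study SD on the z scale, one value or one per
#'   relationship (`SS-PS`, `PS-QoL`, `SS-QoL`); heterogeneity is drawn
#'   independently per cell.
#' @param n_studies number of independent samples.
#' @param n_per_study a single sample size or a range `c(min, max)` for
#'   uniform integer draws.
#' @param cell_prob probability that a study reports each relationship
#'   (recycled to length 3); studies that would report nothing are
#'   redrawn. Alternatively a list of explicit per-study relationship
#'   vectors.
#' @param culture_effect optional named numeric of z-scale shifts per
#'   sociocultural level, e.g. `c(east = 0, west = -0.1)`; levels are
#'   assigned to studies with equal probability.
#' @param age_slope optional z-scale slope of a child-age covariate, drawn
#'   uniformly on `age_range` per study.
#' @param age_range range of the simulated mean child age, in years.
#' @return a validated `masem_simconfig` list.
#' @export
simulation_config <- function(a = -0.408, b = -0.379, cp = 0.400,
                              reliability = c(0.860, 0.837, 0.874),
                              tau_z = 0.12,
                              n_studies = 31L,
                              n_per_study = c(25L, 1384L),
                              cell_prob = c(0.74, 0.29, 0.39),
                              culture_effect = NULL,
                              age_slope = NULL,
                              age_range = c(2, 12)) {
  latent <- implied_latent_matrix(a, b, cp)
  reliability <- .named3(reliability, .constructs, "reliability")
  stopifnot(all(reliability > 0), all(reliability <= 1))
  if (length(tau_z) == 1L) tau_z <- rep(tau_z, 3)
  tau_z <- .named3(tau_z, .relationships, "tau_z")
  stopifnot(all(tau_z >= 0), n_studies >= 1)
  if (is.numeric(n_per_study)) {
    stopifnot(length(n_per_study) %in% 1:2, all(n_per_study >= 4))
    if (length(n_per_study) == 1L) n_per_study <- rep(n_per_study, 2)
  } else stop("'n_per_study' must be a size or a range", call. = FALSE)
  if (is.numeric(cell_prob)) {
    cell_prob <- rep_len(cell_prob, 3)
    names(cell_prob) <- .relationships
    stopifnot(all(cell_prob >= 0), all(cell_prob <= 1), any(cell_prob > 0))
  } else if (is.list(cell_prob)) {
    stopifnot(length(cell_prob) == n_studies,
              all(vapply(cell_prob, function(p) length(p) >= 1 &&
                           all(p %in% .relationships), logical(1))))
  } else stop("'cell_prob' must be probabilities or an explicit pattern list",
              call. = FALSE)
  if (!is.null(culture_effect)) {
    stopifnot(is.numeric(culture_effect), !is.null(names(culture_effect)),
              length(culture_effect) >= 2)
  }
  out <- list(a = a, b = b, cp = cp, latent = latent,
              reliability = reliability, tau_z = tau_z,
              n_studies = as.integer(n_studies),
              n_per_study = as.integer(round(n_per_study)),
              cell_prob = cell_prob,
              culture_effect = culture_effect,
              age_slope = age_slope, age_range = age_range)
  class(out) <- "masem_simconfig"
  out
}

# reliability pair (x, y) for one relationship cell
.cell_rel <- function(reliability, rl) {
  cc <- .cell_constructs[[rl]]
  c(reliability[[cc[1]]], reliability[[cc[2]]])
}

#' Simulate a coded study set from a known mediation truth
#'
#' For each study: the three cell-level true Fisher-z values are the
#' population latent z's plus independent N(0, tau_z^2) deviations (plus
#' any moderator shift); the resulting latent correlations are attenuated
#' by \eqn{\sqrt{rel_x\, rel_y}}; `n` observations are drawn from the
#' trivariate normal with the study's attenuated correlation matrix; and
#' the sample Pearson correlations of the study's reported cells are
#' emitted as coded records. A study whose attenuated matrix is not
#' positive definite is redrawn (and counted) rather than clipped, which
#' would bias correlations toward zero.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; the run is fully reproducible and the
#'   caller's RNG state is untouched.
#' @return a `masem_simstudies` list: `data` (a [study_data()] table),
#'   `truth` (the config), `true_z` (per study x cell matrix of true
#'   latent z values), `redraws` (count of non-positive-definite
#'   redraws).
#' @examples
#' sim <- simulate_studies(simulation_config(n_studies = 8), seed = 42)
#' validate_studies(sim$data)
#' @export
simulate_studies <- function(cfg, seed) {
  stopifnot(inherits(cfg, "masem_simconfig"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  .with_seed(seed, .simulate_impl(cfg))
}

.simulate_impl <- function(cfg) {
  z_pop <- vapply(.relationships, function(rl) {
    cc <- .cell_constructs[[rl]]
    atanh(cfg$latent[cc[1], cc[2]])
  }, numeric(1))
  ns <- cfg$n_studies
  rows <- vector("list", ns)
  true_z <- matrix(NA_real_, ns, 3, dimnames = list(NULL, .relationships))
  redraws <- 0L

  cultures <- if (!is.null(cfg$culture_effect)) {
    sample(names(cfg$culture_effect), ns, replace = TRUE)
  } else rep("not_reported", ns)
  ages <- if (!is.null(cfg$age_slope)) {
    stats::runif(ns, cfg$age_range[1], cfg$age_range[2])
  } else rep(NA_real_, ns)

  for (i in seq_len(ns)) {
    cells <- if (is.list(cfg$cell_prob)) cfg$cell_prob[[i]] else {
      repeat {
        rep_cells <- .relationships[stats::runif(3) < cfg$cell_prob]
        if (length(rep_cells)) break
      }
      rep_cells
    }
    n_i <- if (cfg$n_per_study[1] == cfg$n_per_study[2]) cfg$n_per_study[1]
           else sample(cfg$n_per_study[1]:cfg$n_per_study[2], 1L)
    shift <- 0
    if (!is.null(cfg$culture_effect)) shift <- shift + cfg$culture_effect[[cultures[i]]]
    if (!is.null(cfg$age_slope)) shift <- shift + cfg$age_slope * ages[i]

    repeat {
      z_i <- z_pop + stats::rnorm(3, 0, cfg$tau_z) + shift
      r_lat <- tanh(z_i)
      r_att <- vapply(.relationships, function(rl) {
        rel <- .cell_rel(cfg$reliability, rl)
        r_lat[[rl]] * sqrt(rel[1] * rel[2])
      }, numeric(1))
      M <- diag(3); dimnames(M) <- list(.constructs, .constructs)
      for (rl in .relationships) {
        cc <- .cell_constructs[[rl]]
        M[cc[1], cc[2]] <- M[cc[2], cc[1]] <- r_att[[rl]]
      }
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 1e-8) break
      redraws <- redraws + 1L
    }
    true_z[i, ] <- z_i
    X <- matrix(stats::rnorm(n_i * 3), n_i, 3) %*% chol(M)
    R <- stats::cor(X)
    dimnames(R) <- list(.constructs, .constructs)
    rows[[i]] <- do.call(rbind, lapply(cells, function(rl) {
      cc <- .cell_constructs[[rl]]
      rel <- .cell_rel(cfg$reliability, rl)
      data.frame(study = sprintf("sim%03d", i), sample = sprintf("sim%03d-1", i),
                 relationship = rl, r = R[cc[1], cc[2]], n = n_i,
                 rel_x = rel[1], rel_y = rel[2],
                 role = "not_reported", ss_measure = "not_applicable",
                 qol_focus = "not_applicable", culture = cultures[i],
                 child_age = ages[i], pub_status = "published",
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(data = study_data(do.call(rbind, rows)), truth = cfg,
              true_z = true_z, redraws = redraws)
  class(out) <- "masem_simstudies"
  out
}

#' @export
print.masem_simstudies <- function(x, ...) {
  cat("Simulated study set:", x$truth$n_studies, "studies,",
      nrow(x$data), "coded correlations",
      if (x$redraws > 0) sprintf("(%d inadmissible redraws)", x$redraws) else "",
      "\n")
  invisible(x)
}
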