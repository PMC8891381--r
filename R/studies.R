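# Coded study table: validation, I/O and the built-in fixture.

.relationships <- c("SS-PS", "PS-QoL", "SS-QoL")
.constructs <- c("parenting_stress", "social_support", "quality_of_life")
# which two constructs each relationship connects (x, y), in construct order
.cell_constructs <- list(
  "SS-PS"  = c("social_support", "parenting_stress"),
  "PS-QoL" = c("parenting_stress", "quality_of_life"),
  "SS-QoL" = c("social_support", "quality_of_life")
)
.mod_levels <- list(
  role       = c("mother", "father", "both", "not_reported"),
  ss_measure = c("MSPSS", "FSS", "other", "not_applicable"),
  qol_focus  = c("FQoL", "HQoL", "OQoL", "not_applicable"),
  culture    = c("east", "west", "not_reported"),
  pub_status = c("published", "unpublished")
)
.study_cols <- c("study", "sample", "relationship", "r", "n", "rel_x", "rel_y",
                 "role", "ss_measure", "qol_focus", "culture", "child_age",
                 "pub_status")

#' Construct a coded study-effect table
#'
#' Validates and classes a data frame of study-level effect sizes: one row
#' per coded correlation, identified by `(study, sample, relationship)`.
#' Required columns are `study`, `sample`, `relationship` (one of `"SS-PS"`,
#' `"PS-QoL"`, `"SS-QoL"`), `r` (Pearson correlation, strictly inside
#' (-1, 1)) and `n` (sample size, at least 4 so the Fisher-z variance
#' \eqn{1/(n-3)} is finite). Optional columns `rel_x`/`rel_y` carry scale
#' reliabilities, `role`, `ss_measure`, `qol_focus`, `culture` the
#' categorical moderators (missing values are mapped to
#' `"not_reported"`/`"not_applicable"`), `child_age` the mean child age in
#' years (finite and below 18 when present), and `pub_status` the
#' publication status.
#'
#' @param x a data frame with at least `study`, `sample`, `relationship`,
#'   `r`, `n`.
#' @return the validated table, classed `"masem_data"`.
#' @seealso [read_studies()], [validate_studies()], [asd_parenting_studies()]
#' @export
study_data <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("study", "sample", "relationship", "r", "n")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(x) == 0L) {
    warning("empty study table")
    for (col in setdiff(.study_cols, names(x))) x[[col]] <- character(0)
    x <- x[, .study_cols]
    class(x) <- c("masem_data", "data.frame")
    return(x)
  }
  for (col in c("r", "n", "rel_x", "rel_y", "child_age")) {
    if (!col %in% names(x)) next
    v <- x[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(vn))
    if (length(bad)) stop(sprintf("column '%s' is not numeric in row(s) %s",
                                  col, paste(bad, collapse = ", ")), call. = FALSE)
    x[[col]] <- vn
  }
  if (!"rel_x" %in% names(x)) x$rel_x <- NA_real_
  if (!"rel_y" %in% names(x)) x$rel_y <- NA_real_
  if (!"child_age" %in% names(x)) x$child_age <- NA_real_
  if (!"pub_status" %in% names(x)) x$pub_status <- "published"

  bad <- which(is.na(x$r) | abs(x$r) >= 1)
  if (length(bad)) stop("invalid correlation (need |r| < 1) in row(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(is.na(x$n) | x$n < 4 | x$n != round(x$n))
  if (length(bad)) stop("invalid sample size (need integer n >= 4) in row(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!x$relationship %in% .relationships)
  if (length(bad)) stop("unknown relationship label in row(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  key <- paste(x$study, x$sample, x$relationship, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (study, sample, relationship) in row(s) ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  for (col in c("rel_x", "rel_y")) {
    bad <- which(!is.na(x[[col]]) & (x[[col]] <= 0 | x[[col]] > 1))
    if (length(bad)) stop(sprintf("column '%s' outside (0, 1] in row(s) %s",
                                  col, paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.na(x$child_age) & (!is.finite(x$child_age) |
                 x$child_age < 0 | x$child_age >= 18))
  if (length(bad)) stop("child_age must be finite, nonnegative and < 18 in row(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)

  # moderators: closed vocabularies, missing -> explicit "not reported" member
  for (mod in names(.mod_levels)) {
    fallback <- if (mod %in% c("ss_measure", "qol_focus")) "not_applicable"
                else if (mod == "pub_status") "published" else "not_reported"
    v <- if (mod %in% names(x)) as.character(x[[mod]]) else rep(NA_character_, nrow(x))
    v[is.na(v) | !nzchar(trimws(v))] <- fallback
    bad <- which(!v %in% .mod_levels[[mod]])
    if (length(bad)) stop(sprintf("column '%s' has values outside {%s} in row(s) %s",
                                  mod, paste(.mod_levels[[mod]], collapse = ", "),
                                  paste(bad, collapse = ", ")), call. = FALSE)
    x[[mod]] <- v
  }
  x <- x[, .study_cols]
  rownames(x) <- NULL
  class(x) <- c("masem_data", "data.frame")
  x
}

#' Read or write a coded study table
#'
#' CSV interchange for [study_data()] tables: UTF-8, decimal point, empty
#' string for missing values, header
#' `study,sample,relationship,r,n,rel_x,rel_y,role,ss_measure,qol_focus,culture,child_age,pub_status`.
#' `read_studies()` validates on load; `write_studies()` writes a file that
#' reads back to an identical table.
#'
#' @param path file path.
#' @param x a `masem_data` table.
#' @return `read_studies()` returns a `masem_data` table;
#'   `write_studies()` returns `path` invisibly.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                       fileEncoding = "UTF-8")
  study_data(x)
}

#' @rdname read_studies
#' @export
write_studies <- function(x, path) {
  stopifnot(inherits(x, "masem_data"))
  utils::write.csv(x, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize a coded study table
#'
#' Report-only validation: per-relationship study counts and total sample
#' sizes, the number of independent samples, and a flag for any relationship
#' coded from fewer than `min_k` samples (pooled correlations feeding a
#' structural model are conventionally required to rest on at least seven).
#'
#' @param x a `masem_data` table.
#' @param min_k minimum acceptable number of effect sizes per relationship.
#' @return a `masem_validation` list with components `k`, `n_total`
#'   (named by relationship), `n_samples`, `n_unique_participants`,
#'   `flagged` (character vector of relationships with `k < min_k`).
#' @export
validate_studies <- function(x, min_k = 7L) {
  stopifnot(inherits(x, "masem_data"))
  k <- vapply(.relationships, function(rl) sum(x$relationship == rl), integer(1))
  n_total <- vapply(.relationships, function(rl) sum(x$n[x$relationship == rl]),
                    numeric(1))
  skey <- paste(x$study, x$sample, sep = "\r")
  n_unique <- sum(x$n[!duplicated(skey)])
  out <- list(k = k, n_total = n_total,
              n_samples = length(unique(skey)),
              n_records = nrow(x),
              n_unique_participants = n_unique,
              min_k = min_k,
              flagged = .relationships[k > 0 & k < min_k],
              absent = .relationships[k == 0])
  class(out) <- "masem_validation"
  out
}

#' @export
print.masem_validation <- function(x, ...) {
  cat("Coded study table:", x$n_records, "effect sizes,",
      x$n_samples, "independent samples,",
      x$n_unique_participants, "participants\n")
  tab <- data.frame(k = x$k, N = x$n_total)
  print(tab)
  if (length(x$flagged)) {
    cat("Flagged (k <", x$min_k, "):", paste(x$flagged, collapse = ", "), "\n")
  }
  if (length(x$absent)) cat("Absent relationships:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' The coded study table of the motivating meta-analysis
#'
#' The 44 coded correlations (31 independent samples, 28 studies) between
#' social support, parenting stress and quality of life in parents of
#' autistic children under age 18, as packaged with this package. Rows are
#' stored exactly as coded in the source meta-analysis, including two
#' apparent instrument-name typos normalized to MSPSS.
#'
#' @return a `masem_data` table with 44 rows.
#' @examples
#' d <- asd_parenting_studies()
#' validate_studies(d)
#' @export
asd_parenting_studies <- function() {
  read_studies(system.file("extdata", "asd_parenting_studies.csv",
                           package = "masem3", mustWork = TRUE))
}

#' Pooled correlation matrix and reliabilities of the motivating analysis
#'
#' `asd_pooled_matrix()` returns the published pooled correlation matrix
#' (construct order parenting stress, social support, quality of life) with
#' mean construct reliabilities 0.860, 0.837, 0.874 and per-cell study
#' counts and total sample sizes, as a [masem_matrix()] object ready for
#' [fit_mediation()]. `asd_group_matrices()` returns the east/west pooled
#' matrices of the sociocultural group comparison, with per-group cell
#' sample sizes recomputed from the packaged study table.
#'
#' Note the published matrix carries -0.346 for the social-support /
#' parenting-stress cell while the overall random-effects pooling of the
#' study table gives -0.339; both values appear in the source and are kept
#' distinct here (the matrix is what the structural stage consumed).
#'
#' @return a `masem_matrix` (or, for `asd_group_matrices()`, a named list of
#'   two of them).
#' @export
asd_pooled_matrix <- function() {
  j <- .asd_sidecar()
  r <- matrix(unlist(j$r), 3, 3, dimnames = list(.constructs, .constructs))
  masem_matrix(r, reliability = unlist(j$reliability),
               cell_n = unlist(j$cell_n), cell_k = unlist(j$cell_k))
}

#' @rdname asd_pooled_matrix
#' @export
asd_group_matrices <- function() {
  j <- .asd_sidecar()
  d <- asd_parenting_studies()
  out <- lapply(c(east = "east", west = "west"), function(g) {
    r <- matrix(unlist(j$groups[[g]]), 3, 3,
                dimnames = list(.constructs, .constructs))
    sub <- d[d$culture == g, ]
    cell_n <- vapply(.relationships,
                     function(rl) sum(sub$n[sub$relationship == rl]), numeric(1))
    cell_k <- vapply(.relationships,
                     function(rl) sum(sub$relationship == rl), numeric(1))
    masem_matrix(r, reliability = NULL, cell_n = cell_n, cell_k = cell_k)
  })
  out
}

.asd_sidecar <- function() {
  jsonlite::read_json(system.file("extdata", "asd_pooled_matrix.json",
                                  package = "masem3", mustWork = TRUE))
}
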