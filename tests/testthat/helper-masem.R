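# Shared helpers: in-code fixtures and small random generators.

# minimal coded table from parallel vectors
make_studies <- function(r, n, relationship = "SS-PS", ...) {
  k <- length(r)
  args <- list(...)
  df <- data.frame(study = sprintf("st%02d", seq_len(k)),
                   sample = sprintf("st%02d-1", seq_len(k)),
                   relationship = rep_len(relationship, k),
                   r = r, n = n, stringsAsFactors = FALSE)
  for (nm in names(args)) df[[nm]] <- rep_len(args[[nm]], k)
  study_data(df)
}

# random admissible standardized paths, rejection-sampled
rand_paths <- function() {
  repeat {
    p <- stats::runif(3, -0.7, 0.7)
    ok <- tryCatch({ implied_latent_matrix(p[1], p[2], p[3]); TRUE },
                   error = function(e) FALSE)
    if (ok) return(c(a = p[1], b = p[2], cp = p[3]))
  }
}

# random positive-definite 3x3 correlation matrix
rand_corr3 <- function() {
  repeat {
    A <- matrix(stats::rnorm(12), 4, 3)
    S <- stats::cor(A)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0.05 &&
        max(abs(S[lower.tri(S)])) < 0.95) return(S)
  }
}

table5_matrix <- function() asd_pooled_matrix()
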