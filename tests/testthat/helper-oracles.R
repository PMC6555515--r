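# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Kappa and percent agreement evaluated directly from a (weighted)
# contingency table by looping over cells.
kappa_oracle <- function(tab) {
  total <- sum(tab)
  k <- nrow(tab)
  p_o <- 0
  for (i in seq_len(k)) p_o <- p_o + tab[i, i] / total
  p_e <- 0
  for (i in seq_len(k)) {
    ri <- sum(tab[i, ]) / total
    ci <- sum(tab[, i]) / total
    p_e <- p_e + ri * ci
  }
  list(p_o = p_o, p_e = p_e,
       percent_agreement = 100 * p_o,
       kappa = (p_o - p_e) / (1 - p_e))
}

# Expand a weighted contingency table (integer weights) into paired category
# vectors plus unit weights, for feeding the implementation.
table_to_vectors <- function(tab) {
  lev <- rownames(tab)
  a <- character(0); b <- character(0)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    a <- c(a, rep(lev[i], tab[i, j]))
    b <- c(b, rep(lev[j], tab[i, j]))
  }
  list(a = factor(a, levels = lev), b = factor(b, levels = lev))
}

# Weighted lower quantile by direct evaluation of the weighted empirical CDF
# at every observed value.
weighted_quantile_oracle <- function(x, w, p) {
  vals <- sort(unique(x))
  total <- sum(w)
  for (v in vals) {
    if (sum(w[x <= v]) / total >= p - 1e-10) return(v)
  }
  vals[length(vals)]
}

# PCA oracle through the SVD route (prcomp), independent of eigen().
pca_oracle <- function(x) {
  keep <- apply(x, 2, function(col) var(col) > 0)
  pr <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  list(eigenvalues = pr$sdev^2, loadings = pr$rotation)
}

# A tiny indicator matrix wrapper for unit tests that bypass construction:
# take a plain 0/1 matrix over the default catalog's item ids.
as_qoc_matrix <- function(x, catalog = fpqual::default_catalog(), weight = NULL) {
  stopifnot(ncol(x) == nrow(catalog))
  colnames(x) <- catalog$id
  out <- dplyr::bind_cols(
    tibble::tibble(facility_id = sprintf("F%03d", seq_len(nrow(x))),
                   weight = weight %||% rep(1, nrow(x))),
    tibble::as_tibble(x)
  )
  class(out) <- c("qoc_matrix", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
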