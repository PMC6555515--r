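#' Simple additive quality score
#'
#' The unweighted sum of all binary indicators: every item carries equal
#' weight, so with the 53-item catalog the score ranges 0-53.
#'
#' @param matrix A `qoc_matrix` from [build_indicator_matrix()].
#' @param catalog The indicator catalog.
#' @return Integer vector, one score per facility row.
#' @export
score_simple <- function(matrix, catalog = default_catalog()) {
  as.integer(rowSums(indicator_values(matrix, catalog)))
}

#' Domain-weighted additive quality score
#'
#' Each domain's proportion of positive indicators is scaled to 100 and the
#' eight domain scores averaged: score = sum_d (k_d / n_d) * 100 / D. Every
#' domain carries equal influence regardless of how many items it holds, and
#' the score ranges 0-100.
#'
#' @inheritParams score_simple
#' @return Numeric vector in `[0, 100]`, one score per facility row.
#' @export
score_weighted <- function(matrix, catalog = default_catalog()) {
  validate_catalog(catalog)
  sizes <- table(catalog$domain)
  if (any(sizes == 0)) abort("catalog has an empty domain.")
  x <- indicator_values(matrix, catalog)
  doms <- unique(catalog$domain)
  d_scores <- vapply(doms, function(d) {
    cols <- catalog$id[catalog$domain == d]
    rowSums(x[, cols, drop = FALSE]) / length(cols)
  }, numeric(nrow(x)))
  if (nrow(x) == 1) d_scores <- matrix(d_scores, nrow = 1)
  as.numeric(rowSums(d_scores) * 100 / length(doms))
}

#' Principal component analysis of the indicator matrix
#'
#' Unrotated, unweighted PCA by eigendecomposition of the item correlation
#' matrix (default) or covariance matrix. Items with zero variance across
#' facilities are dropped (standardization is undefined for them) and
#' recorded in the fit. The first component's sign is oriented so its
#' loadings sum to a nonnegative value, making a higher score mean more items
#' present on average.
#'
#' @inheritParams score_simple
#' @param standardize Analyze the correlation matrix (`TRUE`, default) or the
#'   covariance matrix.
#' @return A `qoc_pca` object: `loadings` (items x components, unit-norm
#'   columns), `eigenvalues` (descending), `pct_variance_first`,
#'   `kaiser_count` (components with eigenvalue >= 1), `center`, `scale`,
#'   `items` (analyzed), `dropped` (zero-variance items), `standardize`.
#' @export
#' @examples
#' sim <- simulate_spa(sim_config(n_facilities = 60), seed = 1)
#' m <- build_indicator_matrix(sim$tables)
#' fit <- qoc_pca(m)
#' glance(fit)
qoc_pca <- function(matrix, catalog = default_catalog(), standardize = TRUE) {
  x <- indicator_values(matrix, catalog)
  if (nrow(x) < 2) abort("PCA needs at least 2 facilities.")
  v <- apply(x, 2, var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped) > 0) {
    inform(sprintf("dropping %d zero-variance item(s) from PCA: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- colnames(x)[v > 0]
  if (length(keep) == 0) abort("all items are constant; PCA is degenerate.")
  xk <- x[, keep, drop = FALSE]
  s <- if (standardize) cor(xk) else stats::cov(xk)
  eig <- eigen(s, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  load <- eig$vectors
  # orient each component so its loadings sum >= 0 (first component especially)
  signs <- ifelse(colSums(load) < 0, -1, 1)
  load <- sweep(load, 2, signs, `*`)
  rownames(load) <- keep
  colnames(load) <- paste0("PC", seq_along(lam))
  structure(
    list(loadings = load,
         eigenvalues = lam,
         pct_variance_first = lam[1] / sum(lam),
         kaiser_count = sum(lam >= 1),
         center = colMeans(xk),
         scale = if (standardize) apply(xk, 2, sd) else rep(1, ncol(xk)),
         items = keep, dropped = dropped,
         standardize = standardize),
    class = "qoc_pca"
  )
}

#' First-component PCA quality score
#'
#' Applies the first-component loadings as item weights: score_f =
#' sum_j a_j z_fj, where z_fj is the standardized (default) or raw indicator
#' value, centered at the fitting sample's item means. Items dropped from the
#' fit contribute 0.
#'
#' @param fit A `qoc_pca` object.
#' @param matrix A `qoc_matrix` covering the fit's item set.
#' @param standardized Weight standardized values (default `TRUE`) or raw
#'   binaries.
#' @param catalog The indicator catalog.
#' @return Numeric vector of scores, one per facility row; with standardized
#'   values, the fitting sample's scores have mean 0 and variance equal to
#'   the first eigenvalue.
#' @export
pca_scores <- function(fit, matrix, standardized = TRUE,
                       catalog = default_catalog()) {
  x <- indicator_values(matrix, catalog)
  if (!all(fit$items %in% colnames(x))) {
    abort("indicator matrix does not cover the fitted item set.")
  }
  xk <- x[, fit$items, drop = FALSE]
  a1 <- fit$loadings[, 1]
  z <- if (standardized) {
    sweep(sweep(xk, 2, fit$center), 2, fit$scale, `/`)
  } else {
    xk
  }
  as.numeric(z %*% a1)
}

#' Scree table of PCA eigenvalues
#'
#' @param fit A `qoc_pca` object.
#' @return A tibble with `component` and `eigenvalue` (non-increasing).
#' @export
scree_table <- function(fit) {
  tibble(component = seq_along(fit$eigenvalues), eigenvalue = fit$eigenvalues)
}

#' Kaiser criterion count
#'
#' Number of components with eigenvalue at or above 1 — on the correlation
#' scale, the components that explain at least as much variance as a single
#' standardized item. A large count signals a highly dimensional construct.
#'
#' @param fit A `qoc_pca` object.
#' @return Integer count.
#' @export
kaiser_count <- function(fit) fit$kaiser_count

#' @export
print.qoc_pca <- function(x, ...) {
  cat(sprintf("PCA of %d items (%s matrix)%s\n", length(x$items),
              if (x$standardize) "correlation" else "covariance",
              if (length(x$dropped)) sprintf(", %d constant item(s) dropped", length(x$dropped)) else ""))
  cat(sprintf("  first eigenvalue %.3f (%.1f%% of total variance); %d components with eigenvalue >= 1\n",
              x$eigenvalues[1], 100 * x$pct_variance_first, x$kaiser_count))
  invisible(x)
}

#' Tidy the first-component loadings of a PCA fit
#'
#' @param x A `qoc_pca` object.
#' @param catalog Catalog used to annotate items with domain and label.
#' @param ... Unused.
#' @return A tibble with `item`, `domain`, `label`, `loading` (first
#'   component), mirroring a loadings table.
#' @method tidy qoc_pca
#' @export
tidy.qoc_pca <- function(x, catalog = default_catalog(), ...) {
  out <- tibble(item = x$items, loading = x$loadings[, 1])
  left_join(out, select(as_tibble(catalog), item = "id", "domain", "label"),
            by = "item") |>
    relocate("item", "domain", "label", "loading")
}

#' One-row summary of a PCA fit
#'
#' @param x A `qoc_pca` object.
#' @param ... Unused.
#' @return A tibble with `n_items`, `n_dropped`, `eigenvalue_first`,
#'   `pct_variance_first`, `kaiser_count`.
#' @method glance qoc_pca
#' @export
glance.qoc_pca <- function(x, ...) {
  tibble(n_items = length(x$items), n_dropped = length(x$dropped),
         eigenvalue_first = x$eigenvalues[1],
         pct_variance_first = x$pct_variance_first,
         kaiser_count = x$kaiser_count)
}

#' Compute all three summary scores for an indicator matrix
#'
#' Runs the simple additive, domain-weighted additive, and first-component
#' PCA scores in one pass.
#'
#' @inheritParams score_simple
#' @param config A `qoc_config`; controls PCA standardization flags.
#' @return A `qoc_scores` tibble: `facility_id`, `weight`, any stratifier
#'   columns, `simple_additive`, `weighted_additive`, `pca_score`; the
#'   `qoc_pca` fit is attached as attribute `"pca"`.
#' @export
score_facilities <- function(matrix, catalog = default_catalog(),
                             config = run_config()) {
  fit <- qoc_pca(matrix, catalog, standardize = config$pca_standardize)
  strat <- intersect(c("facility_type", "managing_authority", "locality"),
                     names(matrix))
  out <- bind_cols(
    tibble(facility_id = matrix$facility_id, weight = matrix$weight),
    matrix[, strat, drop = FALSE],
    tibble(
      simple_additive = score_simple(matrix, catalog),
      weighted_additive = score_weighted(matrix, catalog),
      pca_score = pca_scores(fit, matrix,
                             standardized = config$pca_score_standardized,
                             catalog = catalog)
    )
  )
  attr(out, "pca") <- fit
  class(out) <- c("qoc_scores", class(out))
  out
}
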