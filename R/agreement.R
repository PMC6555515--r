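qoc_tercile_levels <- c("low", "medium", "high")

#' Classify scores into weighted terciles
#'
#' Cut points are the weighted empirical quantiles at 1/3 and 2/3, defined as
#' the inverse of the left-continuous weighted CDF. Boundaries are
#' lower-inclusive: score <= q(1/3) is `low`, q(1/3) < score <= q(2/3) is
#' `medium`, above that `high`. Tied scores always share a category, so
#' heaped score distributions can produce unequal groups.
#'
#' @param scores Numeric vector of facility scores.
#' @param weights Facility weights; `NULL` for equal weights.
#' @param weighted Use the weights for the cut points (default `TRUE`).
#' @return An ordered factor with levels low < medium < high and the two cut
#'   points attached as attribute `"cuts"`. All-identical scores raise a
#'   degenerate-classification error.
#' @export
#' @examples
#' tercile_assign(1:9)                        # 3 low, 3 medium, 3 high
#' tercile_assign(c(1, 1, 1, 2, 3, 3))        # ties share the low category
tercile_assign <- function(scores, weights = NULL, weighted = TRUE) {
  if (length(scores) < 3) abort("tercile classification needs at least 3 facilities.")
  if (length(unique(scores)) == 1) {
    abort("all scores are identical; tercile classification is degenerate.")
  }
  w <- if (weighted) weights else NULL
  cuts <- weighted_quantile(scores, w, c(1 / 3, 2 / 3))
  cat <- ifelse(scores <= cuts[1], "low",
                ifelse(scores <= cuts[2], "medium", "high"))
  out <- factor(cat, levels = qoc_tercile_levels, ordered = TRUE)
  attr(out, "cuts") <- cuts
  out
}

#' Weighted percent agreement between two categorizations
#'
#' @param a,b Category vectors over the same facilities (same length/order).
#' @param weights Facility weights; `NULL` for equal weights.
#' @return Weighted share of facilities given the same category, times 100.
#' @export
percent_agreement <- function(a, b, weights = NULL) {
  if (length(a) != length(b)) abort("category vectors must cover the same facilities.")
  if (is.null(weights)) weights <- rep(1, length(a))
  100 * sum(weights[as.character(a) == as.character(b)]) / sum(weights)
}

#' Cohen's kappa between two categorizations
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the weighted observed agreement and p_e the expected agreement from the
#' weighted marginals. The null standard error uses the standard formula
#' se0 = sqrt((p_e + p_e^2 - sum_i r_i c_i (r_i + c_i)) / (n (1 - p_e)^2))
#' with marginal proportions r_i, c_i and effective n equal to the sum of
#' weights normalized to mean 1; z = kappa / se0 is tested against H0:
#' kappa = 0 (one-sided kappa > 0 by default).
#'
#' @param a,b Category vectors (factors share levels; characters are unioned).
#' @param weights Facility weights; `NULL` for equal weights.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `qoc_agreement` object: the weighted contingency `table`,
#'   `percent_agreement`, `p_o`, `p_e`, `kappa`, `se0`, `z`, `p_value`,
#'   `band` (Landis-Koch label), `n_eff`.
#' @export
#' @examples
#' a <- rep(c("low", "medium", "high"), times = c(30, 30, 30))
#' b <- c(rep(c("low","medium","high"), c(20,5,5)),
#'        rep(c("low","medium","high"), c(5,20,5)),
#'        rep(c("low","medium","high"), c(5,5,20)))
#' fit <- cohens_kappa(a, b)
#' fit$kappa  # 0.5
cohens_kappa <- function(a, b, weights = NULL,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) abort("category vectors must cover the same facilities.")
  if (is.null(weights)) weights <- rep(1, length(a))
  lev <- if (is.factor(a) && is.factor(b) && identical(levels(a), levels(b))) {
    levels(a)
  } else {
    sort(union(unique(as.character(a)), unique(as.character(b))))
  }
  a <- factor(as.character(a), levels = lev)
  b <- factor(as.character(b), levels = lev)
  tab <- matrix(0, length(lev), length(lev), dimnames = list(a = lev, b = lev))
  for (k in seq_along(a)) tab[a[k], b[k]] <- tab[a[k], b[k]] + weights[k]
  total <- sum(tab)
  p <- tab / total
  p_o <- sum(diag(p))
  r <- rowSums(p)
  cc <- colSums(p)
  p_e <- sum(r * cc)
  if (1 - p_e < .Machine$double.eps) {
    abort("both categorizations are constant; kappa is undefined (p_e = 1).")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  n_eff <- sum(weights / mean(weights))
  se0 <- sqrt((p_e + p_e^2 - sum(r * cc * (r + cc))) / (n_eff * (1 - p_e)^2))
  z <- kappa / se0
  p_value <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else 2 * pnorm(-abs(z))
  structure(
    list(table = tab, percent_agreement = 100 * p_o, p_o = p_o, p_e = p_e,
         kappa = kappa, se0 = se0, z = z, p_value = p_value,
         band = landis_koch(kappa), n_eff = n_eff,
         alternative = alternative),
    class = "qoc_agreement"
  )
}

#' @export
print.qoc_agreement <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s); percent agreement = %.1f%%\n",
              x$kappa, x$band, x$percent_agreement))
  cat(sprintf("  z = %.2f, p = %.3g (H1: kappa %s 0)\n", x$z, x$p_value,
              if (x$alternative == "greater") ">" else "!="))
  invisible(x)
}

#' @rdname cohens_kappa
#' @param x A `qoc_agreement` object.
#' @param ... Unused.
#' @method glance qoc_agreement
#' @export
glance.qoc_agreement <- function(x, ...) {
  tibble(percent_agreement = x$percent_agreement, kappa = x$kappa,
         se0 = x$se0, z = x$z, p_value = x$p_value, band = x$band,
         n_eff = x$n_eff)
}

#' Landis-Koch descriptive band for a kappa value
#'
#' Bands: 0.81-1.0 near perfect, 0.61-0.80 good, 0.41-0.60 moderate,
#' 0.21-0.40 fair, 0.0-0.20 poor, below 0 worse than chance.
#'
#' @param kappa Numeric values in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
landis_koch <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < -1 - 1e-12) || any(kappa > 1 + 1e-12)) {
    abort("kappa must lie in [-1, 1].")
  }
  vapply(kappa, function(k) {
    if (k < 0) "worse than chance"
    else if (k < 0.21) "poor"
    else if (k < 0.41) "fair"
    else if (k < 0.61) "moderate"
    else if (k < 0.81) "good"
    else "near perfect"
  }, character(1))
}

#' Pairwise agreement between the three scoring mechanisms
#'
#' Tercile-categorizes each score, then computes percent agreement and
#' Cohen's kappa for the three pairs (simple vs weighted, weighted vs PCA,
#' PCA vs simple).
#'
#' @param scores A `qoc_scores` tibble from [score_facilities()] (or any data
#'   frame with the three score columns and `weight`).
#' @param config A `qoc_config`; controls tercile weighting and test
#'   sidedness.
#' @return A tibble with one row per pair: `index_1`, `index_2`,
#'   `percent_agreement`, `kappa`, `se0`, `z`, `p_value`, `band`. The three
#'   `qoc_agreement` objects are attached as attribute `"agreements"` and the
#'   tercile assignments as attribute `"terciles"`.
#' @export
compare_scores <- function(scores, config = run_config()) {
  stopifnot_cols(scores, c("simple_additive", "weighted_additive", "pca_score"),
                 "score set")
  w <- scores$weight %||% rep(1, nrow(scores))
  cats <- list(
    simple_additive = tercile_assign(scores$simple_additive, w,
                                     weighted = config$weighted_terciles),
    weighted_additive = tercile_assign(scores$weighted_additive, w,
                                       weighted = config$weighted_terciles),
    pca_score = tercile_assign(scores$pca_score, w,
                               weighted = config$weighted_terciles)
  )
  pairs <- list(c("simple_additive", "weighted_additive"),
                c("weighted_additive", "pca_score"),
                c("pca_score", "simple_additive"))
  fits <- lapply(pairs, function(p) {
    cohens_kappa(cats[[p[1]]], cats[[p[2]]], w,
                 alternative = config$kappa_alternative)
  })
  out <- purrr::map2_dfr(pairs, fits, function(p, f) {
    bind_cols(tibble(index_1 = p[1], index_2 = p[2]), glance(f)[, c(
      "percent_agreement", "kappa", "se0", "z", "p_value", "band")])
  })
  attr(out, "agreements") <- setNames(fits, vapply(pairs, paste, "", collapse = "_vs_"))
  attr(out, "terciles") <- cats
  out
}

#' Share of high-quality facilities by background characteristic
#'
#' For each scoring mechanism and each stratum of the given facility
#' characteristics, the weighted percent of facilities the mechanism places
#' in the high tercile.
#'
#' @param scores A `qoc_scores` tibble carrying the stratifier columns.
#' @param characteristics Stratifier column names (default: facility type,
#'   managing authority, locality — whichever are present).
#' @param config A `qoc_config`.
#' @return A tibble with `characteristic`, `stratum`, `score`, `pct_high`,
#'   `n_facilities`.
#' @export
high_quality_profile <- function(scores,
                                 characteristics = NULL,
                                 config = run_config()) {
  characteristics <- characteristics %||%
    intersect(c("facility_type", "managing_authority", "locality"), names(scores))
  bad <- setdiff(characteristics, names(scores))
  if (length(bad) > 0) {
    abort(sprintf("unknown stratifier column(s): %s", paste(bad, collapse = ", ")))
  }
  w <- scores$weight %||% rep(1, nrow(scores))
  score_cols <- c("simple_additive", "weighted_additive", "pca_score")
  cats <- lapply(score_cols, function(s) {
    tercile_assign(scores[[s]], w, weighted = config$weighted_terciles)
  })
  names(cats) <- score_cols
  purrr::map_dfr(characteristics, function(ch) {
    purrr::map_dfr(score_cols, function(s) {
      df <- tibble(stratum = as.character(scores[[ch]]),
                   high = cats[[s]] == "high", w = w)
      df |>
        group_by(.data$stratum) |>
        summarise(pct_high = 100 * sum(.data$w[.data$high]) / sum(.data$w),
                  n_facilities = n(), .groups = "drop") |>
        mutate(characteristic = ch, score = s) |>
        relocate("characteristic", "stratum", "score")
    })
  })
}
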