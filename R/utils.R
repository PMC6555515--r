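# internal helpers shared across modules

# Weighted mean that treats NA values as 0 (the missing-data rule applied
# upstream makes NA impossible in normal operation, but be defensive).
weighted_mean0 <- function(x, w = NULL) {
  x[is.na(x)] <- 0
  if (is.null(w)) return(mean(x))
  if (length(w) != length(x)) abort("weights must match values in length.")
  sum(w * x) / sum(w)
}

# Inverse of the left-continuous weighted empirical CDF: the smallest
# observed value x_(i) whose cumulative weight share reaches p. With equal
# weights this is the "type 1" empirical quantile. A small relative
# tolerance keeps p = k/n comparisons exact in floating point.
weighted_quantile <- function(x, w = NULL, probs) {
  if (length(x) == 0L) abort("cannot take quantiles of zero values.")
  if (is.null(w)) w <- rep(1, length(x))
  if (any(w < 0) || all(w == 0)) abort("weights must be nonnegative and not all zero.")
  ord <- order(x)
  xs <- x[ord]
  cw <- cumsum(w[ord])
  total <- cw[length(cw)]
  vapply(probs, function(p) {
    xs[which(cw >= p * total - 1e-10 * total)[1L]]
  }, numeric(1))
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
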