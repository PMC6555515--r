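#' Run the full quality-of-care scoring pipeline
#'
#' Orchestrates catalog validation, (optionally simulated) survey input,
#' indicator-matrix construction, the three summary scores with PCA
#' diagnostics, pairwise tercile agreement, the high-quality profile, and a
#' run manifest. Deterministic given the seed and configuration.
#'
#' @param inputs Either a `qoc_tables` object, a named list of CSV paths
#'   (`facility`, `provider`, `client`), or a `sim_config` to simulate from.
#' @param catalog A `qoc_catalog` or the token `"default"`.
#' @param config A `qoc_config`.
#' @param out_dir Optional directory; when given, all tables plus
#'   `manifest.json` are written there as CSV/JSON.
#' @param seed Seed used when `inputs` is a `sim_config`.
#' @return A `qoc_bundle` list: `matrix`, `scores`, `pca`, `agreement`,
#'   `profile`, `manifest`, and `truth` when simulated.
#' @export
#' @examples
#' bundle <- run_pipeline(sim_config(n_facilities = 40), seed = 7)
#' bundle$agreement
run_pipeline <- function(inputs, catalog = "default", config = run_config(),
                         out_dir = NULL, seed = NULL) {
  if (identical(catalog, "default")) catalog <- default_catalog()
  validate_catalog(catalog)
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, w)

  truth <- NULL
  if (inherits(inputs, "sim_config")) {
    sim <- simulate_spa(inputs, seed = seed)
    tables <- sim$tables
    truth <- sim$truth
    seed_used <- seed %||% inputs$seed
  } else if (inherits(inputs, "qoc_tables")) {
    tables <- inputs
    seed_used <- config$seed
  } else if (is.list(inputs)) {
    stopifnot_cols(as_tibble(as.list(inputs)), c("facility", "provider", "client"),
                   "input path list")
    tables <- withCallingHandlers(
      read_survey_tables(inputs$facility, inputs$provider, inputs$client,
                         catalog = catalog),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    seed_used <- config$seed
  } else {
    abort("inputs must be survey tables, CSV paths, or a sim_config.")
  }

  matrix <- withCallingHandlers(
    build_indicator_matrix(tables, catalog, config),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  scores <- score_facilities(matrix, catalog, config)
  pca <- attr(scores, "pca")
  if (length(pca$dropped) > 0) {
    note(sprintf("zero-variance items dropped from PCA: %s",
                 paste(pca$dropped, collapse = ", ")))
  }
  agreement <- compare_scores(scores, config)
  profile <- high_quality_profile(scores, config = config)

  manifest <- list(
    config = unclass(config),
    seed = seed_used,
    catalog_checksum = catalog_checksum(catalog),
    counts = list(facilities = nrow(tables$facility),
                  providers = nrow(tables$provider),
                  clients = nrow(tables$client),
                  eligible_facilities = nrow(matrix)),
    pca = as.list(glance(pca)),
    warnings = as.list(warnings_log)
  )

  bundle <- structure(
    list(matrix = matrix, scores = scores, pca = pca, agreement = agreement,
         profile = profile, manifest = manifest, truth = truth),
    class = "qoc_bundle"
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

catalog_checksum <- function(catalog) {
  # order-insensitive content digest without extra dependencies
  rows <- apply(as.matrix(as_tibble(catalog)), 1, paste, collapse = "\x1f")
  s <- sum(vapply(sort(rows), function(r) sum(utf8ToInt(r) * seq_along(utf8ToInt(r))),
                  numeric(1)))
  sprintf("%.0f", s)
}

#' Write a pipeline bundle to a directory
#'
#' @param bundle A `qoc_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_qoc_csv(bundle$matrix, p("indicator_matrix.csv"))
  write_qoc_csv(as_tibble(bundle$scores), p("scores.csv"))
  write_qoc_csv(tidy(bundle$pca), p("pca_loadings.csv"))
  write_qoc_csv(scree_table(bundle$pca), p("pca_scree.csv"))
  write_qoc_csv(bundle$agreement, p("agreement.csv"))
  write_qoc_csv(bundle$profile, p("profile.csv"))
  if (!is.null(bundle$truth)) write_qoc_csv(bundle$truth, p("sim_truth.csv"))
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.qoc_bundle <- function(x, ...) {
  cat(sprintf("Quality-of-care pipeline bundle: %d facilities scored\n",
              nrow(x$scores)))
  print(x$agreement[, c("index_1", "index_2", "percent_agreement", "kappa", "band")])
  invisible(x)
}

fmt2 <- function(x) formatC(x, digits = 2, format = "f")

#' Render a text report for a pipeline bundle
#'
#' A human-readable markdown summary: PCA dimensionality diagnostics with the
#' leading eigenvalues, the first-component loadings by domain, pairwise
#' agreement with Landis-Koch bands, and the stratified high-quality profile.
#' Values are rounded to 2 decimals; empty strata render as "n/a".
#'
#' @param bundle A complete `qoc_bundle`.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(bundle) {
  need <- c("matrix", "scores", "pca", "agreement", "profile", "manifest")
  miss <- need[vapply(need, function(nm) is.null(bundle[[nm]]), logical(1))]
  if (length(miss) > 0) {
    abort(sprintf("bundle is incomplete; missing artifact(s): %s",
                  paste(miss, collapse = ", ")))
  }
  g <- glance(bundle$pca)
  lines <- c(
    "# Quality of care summary report",
    "",
    sprintf("Facilities scored: %d", nrow(bundle$scores)),
    "",
    "## PCA diagnostics",
    sprintf("- First eigenvalue: %s (%s%% of total variance)",
            fmt2(g$eigenvalue_first), fmt2(100 * g$pct_variance_first)),
    sprintf("- Components with eigenvalue >= 1 (Kaiser): %d of %d items",
            g$kaiser_count, g$n_items),
    sprintf("- Leading eigenvalues: %s",
            paste(fmt2(head(bundle$pca$eigenvalues, 8)), collapse = ", ")),
    "",
    "## First-component loadings (by domain)"
  )
  ld <- tidy(bundle$pca)
  for (d in unique(ld$domain)) {
    sub <- ld[ld$domain == d, ]
    lines <- c(lines, sprintf("- %s: %s", d,
                              paste(sprintf("%s=%s", sub$item, fmt2(sub$loading)),
                                    collapse = ", ")))
  }
  lines <- c(lines, "", "## Agreement between scoring mechanisms")
  ag <- bundle$agreement
  for (i in seq_len(nrow(ag))) {
    lines <- c(lines, sprintf(
      "- %s vs %s: %s%% agreement, kappa = %s (%s), p = %.3g",
      ag$index_1[i], ag$index_2[i], fmt2(ag$percent_agreement[i]),
      fmt2(ag$kappa[i]), ag$band[i], ag$p_value[i]))
  }
  lines <- c(lines, "", "## Percent of facilities ranked high, by characteristic")
  pr <- bundle$profile
  for (i in seq_len(nrow(pr))) {
    val <- if (pr$n_facilities[i] == 0 || is.na(pr$pct_high[i])) "n/a" else fmt2(pr$pct_high[i])
    lines <- c(lines, sprintf("- %s = %s [%s]: %s%%", pr$characteristic[i],
                              pr$stratum[i], pr$score[i], val))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
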