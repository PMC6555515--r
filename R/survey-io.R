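#' Link facility, provider, and client survey tables
#'
#' Bundles the three levels of an SPA-type survey into a validated object.
#' Orphan provider/client rows (with a `facility_id` absent from the facility
#' table) are dropped with a warning; missing weights default to 1. When a
#' catalog is supplied, raw fields it references that are absent from the
#' tables are reported (the construction stage will force the affected
#' indicators to 0 under the missing-data rule).
#'
#' @param facility,provider,client Data frames. All must carry `facility_id`;
#'   `facility` must carry a nonnegative `weight` (added as 1 if absent).
#' @param catalog Optional `qoc_catalog` used to report missing raw fields.
#' @return A `qoc_tables` list with elements `facility`, `provider`, `client`
#'   (tibbles) and `dropped` (orphan row counts).
#' @export
as_survey_tables <- function(facility, provider, client, catalog = NULL) {
  facility <- as_tibble(facility)
  provider <- as_tibble(provider)
  client <- as_tibble(client)
  stopifnot_cols(facility, "facility_id", "facility table")
  stopifnot_cols(provider, "facility_id", "provider table")
  stopifnot_cols(client, "facility_id", "client table")
  if (nrow(facility) == 0) abort("facility table has no rows.")
  if (anyDuplicated(facility$facility_id)) abort("facility_id must be unique in the facility table.")
  for (nm in c("facility", "provider", "client")) {
    tab <- get(nm)
    if (!"weight" %in% names(tab)) tab$weight <- 1
    if (any(is.na(tab$weight)) || any(tab$weight < 0)) {
      abort(sprintf("%s table has missing or negative weights.", nm))
    }
    assign(nm, tab)
  }
  dropped <- c(provider = 0L, client = 0L)
  for (nm in c("provider", "client")) {
    tab <- get(nm)
    orphan <- !tab$facility_id %in% facility$facility_id
    if (any(orphan)) {
      dropped[[nm]] <- sum(orphan)
      warn(sprintf("dropped %d %s row(s) with unknown facility_id.", sum(orphan), nm))
      assign(nm, tab[!orphan, ])
    }
  }
  out <- structure(
    list(facility = facility, provider = provider, client = client,
         dropped = dropped),
    class = "qoc_tables"
  )
  if (!is.null(catalog)) {
    miss <- missing_raw_fields(out, catalog)
    if (nrow(miss) > 0) {
      warn(sprintf(
        "survey tables lack %d raw field(s) referenced by the catalog (affected indicators will be coded 0): %s",
        nrow(miss), paste(unique(miss$field), collapse = ", ")))
    }
  }
  out
}

#' Read the three survey tables from CSV files
#'
#' @param facility_path,provider_path,client_path CSV paths with header rows;
#'   each must contain `facility_id`.
#' @inheritParams as_survey_tables
#' @return A `qoc_tables` object; see [as_survey_tables()].
#' @export
read_survey_tables <- function(facility_path, provider_path, client_path,
                               catalog = NULL) {
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  as_survey_tables(rd(facility_path), rd(provider_path), rd(client_path),
                   catalog = catalog)
}

#' @export
print.qoc_tables <- function(x, ...) {
  cat(sprintf("Linked survey tables: %d facilities, %d providers, %d clients\n",
              nrow(x$facility), nrow(x$provider), nrow(x$client)))
  if (any(x$dropped > 0)) {
    cat(sprintf("  (dropped orphan rows: %d provider, %d client)\n",
                x$dropped[["provider"]], x$dropped[["client"]]))
  }
  invisible(x)
}

#' Report catalog raw fields absent from a set of survey tables
#'
#' @param tables A `qoc_tables` object.
#' @param catalog A `qoc_catalog`.
#' @return A tibble with columns `field`, `source_level`, `indicator` listing
#'   each absent raw field and the indicator(s) it feeds.
#' @export
missing_raw_fields <- function(tables, catalog) {
  validate_catalog(catalog)
  fields <- catalog_fields(catalog)
  out <- purrr::map2_dfr(seq_len(nrow(catalog)), fields, function(i, fl) {
    lvl <- catalog$source_level[i]
    present <- names(tables[[lvl]])
    miss <- setdiff(fl, present)
    if (length(miss) == 0) return(tibble())
    tibble(field = miss, source_level = lvl, indicator = catalog$id[i])
  })
  out
}

#' Write a pipeline output table to CSV
#'
#' Writes any of the pipeline's tabular outputs (indicator matrix, score set,
#' agreement table, profile table) with a stable column order so that
#' write-read-write is byte-identical.
#'
#' @param x A data frame produced by the pipeline.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qoc_csv <- function(x, path) {
  x <- as_tibble(x)
  # print doubles at 15 significant digits: parsing and re-printing such a
  # value reproduces the same text, so write -> read -> write is stable
  dbl <- vapply(x, is.double, logical(1))
  x[dbl] <- lapply(x[dbl], function(col) sprintf("%.15g", col))
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline output table written by [write_qoc_csv()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_qoc_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config()`, a `qoc_config` list; see [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @param config A `qoc_config` list.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run configuration for the scoring pipeline
#'
#' @param weighted_dichotomize Use facility weights when computing the
#'   across-facility mean threshold that dichotomizes collapsed client and
#'   provider items (default `TRUE`).
#' @param weighted_terciles Use facility weights for the tercile cut points
#'   (default `TRUE`).
#' @param pca_standardize Run the PCA on the correlation matrix
#'   (standardized items, default `TRUE`) rather than the covariance matrix.
#' @param pca_score_standardized Apply first-component loadings to
#'   standardized indicator values (default `TRUE`) rather than raw binaries.
#' @param kappa_alternative Sidedness of the kappa null test: `"greater"`
#'   (default, H1: kappa > 0) or `"two.sided"`.
#' @param seed Optional integer seed recorded in the run manifest.
#' @return A `qoc_config` list.
#' @export
run_config <- function(weighted_dichotomize = TRUE,
                       weighted_terciles = TRUE,
                       pca_standardize = TRUE,
                       pca_score_standardized = TRUE,
                       kappa_alternative = c("greater", "two.sided"),
                       seed = NULL) {
  kappa_alternative <- match.arg(kappa_alternative)
  for (flag in list(weighted_dichotomize, weighted_terciles, pca_standardize,
                    pca_score_standardized)) {
    if (!is.logical(flag) || length(flag) != 1 || is.na(flag)) {
      abort("configuration flags must be single TRUE/FALSE values.")
    }
  }
  structure(
    list(weighted_dichotomize = weighted_dichotomize,
         weighted_terciles = weighted_terciles,
         pca_standardize = pca_standardize,
         pca_score_standardized = pca_score_standardized,
         kappa_alternative = kappa_alternative,
         seed = seed),
    class = "qoc_config"
  )
}
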