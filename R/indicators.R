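#' Facilities eligible for index construction
#'
#' A facility enters the indices only if at least one family planning client
#' was observed there on the day of the survey, i.e. it has at least one
#' linked client record.
#'
#' @param tables A `qoc_tables` object.
#' @return Character vector of eligible `facility_id`s, in facility-table
#'   order, or an error when none qualify.
#' @export
eligible_facilities <- function(tables) {
  ids <- tables$facility$facility_id
  keep <- ids %in% unique(tables$client$facility_id)
  if (!any(keep)) abort("no facility has an observed client; nothing to score.")
  ids[keep]
}

#' Concordance coding of paired observation / exit-interview items
#'
#' A process item assessed both by the visit observer and in the client exit
#' interview is coded positive only when both sources report it. Missing
#' values are treated as "did not occur" and coded 0.
#'
#' @param observed,exit Binary vectors (0/1/NA) of equal length, one element
#'   per client.
#' @return Integer 0/1 vector: 1 iff both inputs are 1.
#' @export
#' @examples
#' concordance_item(c(1, 1, 0, NA), c(1, 0, 1, 1))  # 1 0 0 0
concordance_item <- function(observed, exit) {
  if (length(observed) != length(exit)) abort("observed and exit must have equal length.")
  o <- ifelse(is.na(observed), 0L, as.integer(observed))
  e <- ifelse(is.na(exit), 0L, as.integer(exit))
  as.integer(o == 1L & e == 1L)
}

#' Collapse client- or provider-level binaries to facility means
#'
#' Missing values are coded 0 before averaging; a facility with no
#' contributing records gets mean 0 under the same missing-data rule.
#' Within-facility averaging is unweighted (a plain mean over the facility's
#' records).
#'
#' @param values Binary vector (0/1/NA), one element per record.
#' @param facility_id Facility key per record.
#' @param all_facilities Facility ids defining the output rows (defaults to
#'   the ids present in `facility_id`).
#' @return Named numeric vector of per-facility means in `[0, 1]`, one per
#'   element of `all_facilities`.
#' @export
collapse_to_facility_mean <- function(values, facility_id,
                                      all_facilities = unique(facility_id)) {
  v <- ifelse(is.na(values), 0, as.numeric(values))
  means <- tapply(v, factor(facility_id, levels = all_facilities), mean)
  means[is.na(means)] <- 0
  setNames(as.numeric(means), all_facilities)
}

#' Dichotomize facility means at the across-facility mean
#'
#' The threshold is the (optionally facility-weighted) mean of the facility
#' means; facilities at or above it are coded 1 ("at and above"), below it 0.
#'
#' @param facility_means Numeric vector of per-facility values in `[0, 1]`.
#' @param weights Facility weights (used only when `weighted = TRUE`).
#' @param weighted Use weighted threshold (default `TRUE`).
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' dichotomize_at_mean(c(0.2, 0.4, 0.6, 0.8))           # 0 0 1 1
#' dichotomize_at_mean(c(0, 1), weights = c(3, 1))      # 0 1 (threshold 0.25)
dichotomize_at_mean <- function(facility_means, weights = NULL, weighted = TRUE) {
  if (length(facility_means) == 0) abort("need at least one facility.")
  t <- if (weighted && !is.null(weights)) {
    weighted_mean0(facility_means, weights)
  } else {
    mean(facility_means)
  }
  as.integer(facility_means >= t)
}

#' Method-mix availability composite
#'
#' A facility offers an adequate method mix when it stocks (unexpired) at
#' least one short-acting method (pill or injectable), at least one
#' long-acting reversible or permanent method (implant, IUD, or
#' sterilization), and a barrier method (condom). Missing flags count as
#' unavailable.
#'
#' @param pill,injectable,implant,iud,sterilization,condom Binary vectors
#'   (0/1/NA) of a common length.
#' @return Integer 0/1 vector.
#' @export
method_mix_indicator <- function(pill, injectable, implant, iud,
                                 sterilization, condom) {
  z <- function(x) ifelse(is.na(x), 0L, as.integer(x))
  short <- z(pill) | z(injectable)
  larc <- z(implant) | z(iud) | z(sterilization)
  as.integer(short & larc & z(condom))
}

#' Quality-assurance composite
#'
#' Positive when the facility routinely conducts and documents at least one
#' quality-assurance activity: QA meeting minutes/report, a supervisory
#' checklist, a mortality review, or an audit of records or registers. Each
#' input flag must already encode "conducted AND documented"; missing counts
#' as absent.
#'
#' @param meeting_minutes,supervisory_checklist,mortality_review,record_audit
#'   Binary vectors (0/1/NA) of a common length.
#' @return Integer 0/1 vector.
#' @export
quality_assurance_indicator <- function(meeting_minutes, supervisory_checklist,
                                        mortality_review, record_audit) {
  z <- function(x) ifelse(is.na(x), 0L, as.integer(x))
  as.integer(z(meeting_minutes) | z(supervisory_checklist) |
               z(mortality_review) | z(record_audit))
}

fetch_field <- function(tab, field, n) {
  if (field %in% names(tab)) tab[[field]] else rep(NA_integer_, n)
}

#' Build the facility-by-indicator binary matrix
#'
#' Applies each catalog indicator's construction rule to the linked survey
#' tables, restricted to [eligible_facilities()]:
#' * `direct` — the facility field itself (missing coded 0);
#' * `method_mix`, `quality_assurance` — the facility-level composites;
#' * `mean_dichotomize` — client or provider binaries collapsed to facility
#'   means, then dichotomized at the across-facility (weighted) mean;
#' * `concordance` — per-client conjunction of the observation and exit
#'   report, then collapsed and dichotomized the same way.
#'
#' Raw fields referenced by the catalog but absent from the tables force the
#' affected indicator to 0 everywhere, with a warning.
#'
#' @param tables A `qoc_tables` object.
#' @param catalog A `qoc_catalog` (default: packaged catalog).
#' @param config A `qoc_config`; `weighted_dichotomize` controls the
#'   threshold weighting.
#' @return A `qoc_matrix` tibble: `facility_id`, `weight`, the stratifier
#'   columns present in the facility table, then one 0/1 column per catalog
#'   indicator, in catalog order.
#' @export
build_indicator_matrix <- function(tables, catalog = default_catalog(),
                                   config = run_config()) {
  validate_catalog(catalog)
  elig <- eligible_facilities(tables)
  fac <- tables$facility[match(elig, tables$facility$facility_id), ]
  n <- nrow(fac)
  weights <- fac$weight
  fields <- catalog_fields(catalog)

  prov <- tables$provider[tables$provider$facility_id %in% elig, ]
  cli <- tables$client[tables$client$facility_id %in% elig, ]

  absent <- missing_raw_fields(tables, catalog)
  if (nrow(absent) > 0) {
    warn(sprintf("indicator(s) forced to 0 for all facilities (missing raw fields): %s",
                 paste(unique(absent$indicator), collapse = ", ")))
  }

  one_indicator <- function(i) {
    fl <- fields[[i]]
    rule <- catalog$rule[i]
    lvl <- catalog$source_level[i]
    if (rule == "direct") {
      v <- fetch_field(fac, fl, n)
      return(as.integer(ifelse(is.na(v), 0L, as.integer(v)) == 1L))
    }
    if (rule == "method_mix") {
      args <- lapply(fl, fetch_field, tab = fac, n = n)
      return(do.call(method_mix_indicator, args))
    }
    if (rule == "quality_assurance") {
      args <- lapply(fl, fetch_field, tab = fac, n = n)
      return(do.call(quality_assurance_indicator, args))
    }
    tab <- if (lvl == "provider") prov else cli
    rec_vals <- if (rule == "concordance") {
      concordance_item(fetch_field(tab, fl[1], nrow(tab)),
                       fetch_field(tab, fl[2], nrow(tab)))
    } else {
      fetch_field(tab, fl[1], nrow(tab))
    }
    means <- collapse_to_facility_mean(rec_vals, tab$facility_id,
                                       all_facilities = elig)
    dichotomize_at_mean(means, weights, weighted = config$weighted_dichotomize)
  }

  cols <- lapply(seq_len(nrow(catalog)), one_indicator)
  names(cols) <- catalog$id
  strat <- intersect(c("facility_type", "managing_authority", "locality"),
                     names(fac))
  out <- bind_cols(
    tibble(facility_id = fac$facility_id, weight = weights),
    fac[, strat, drop = FALSE],
    as_tibble(cols)
  )
  class(out) <- c("qoc_matrix", class(out))
  out
}

#' Extract the indicator columns of a `qoc_matrix` as a numeric matrix
#'
#' @param matrix A `qoc_matrix` tibble from [build_indicator_matrix()].
#' @param catalog The catalog that built it.
#' @return Numeric matrix, facilities by indicators, in catalog order.
#' @export
indicator_values <- function(matrix, catalog = default_catalog()) {
  stopifnot_cols(matrix, catalog$id, "indicator matrix")
  m <- as.matrix(matrix[, catalog$id, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- matrix$facility_id
  m
}
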