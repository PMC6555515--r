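#' Default per-item simulation parameters
#'
#' One row per raw survey field consumed by the catalog, giving the logistic
#' intercept `alpha` (controls marginal prevalence) and loading `beta`
#' (slope on the facility's latent quality in the item's domain). Exit
#' interview fields are excluded: they are produced by the recall /
#' false-positive reporting channel, not directly from the latent scale.
#'
#' Defaults: `beta = 1` for every item, and `alpha` cycling over
#' (-1.5, -0.7, 0, 0.7, 1.5), which spreads marginal prevalences over roughly
#' 18-82% — the range facility surveys typically show across readiness and
#' process items.
#'
#' @param catalog A `qoc_catalog`; defaults to the packaged catalog.
#' @return A tibble with columns `field`, `source_level`, `domain`, `alpha`,
#'   `beta`.
#' @export
default_item_params <- function(catalog = default_catalog()) {
  validate_catalog(catalog)
  fields <- catalog_fields(catalog)
  per_field <- purrr::map2_dfr(seq_len(nrow(catalog)), fields, function(i, fl) {
    fl <- fl[!startsWith(fl, "exit_")]
    tibble(field = fl, source_level = catalog$source_level[i],
           domain = catalog$domain[i])
  })
  per_field <- distinct(per_field, .data$field, .keep_all = TRUE)
  alphas <- c(-1.5, -0.7, 0, 0.7, 1.5)
  per_field$alpha <- alphas[(seq_len(nrow(per_field)) - 1L) %% length(alphas) + 1L]
  per_field$beta <- 1
  per_field
}

#' Simulation configuration for SPA-like survey tables
#'
#' Describes a hierarchical generative model for facility, provider, and
#' client tables with a known latent quality structure. Each facility carries
#' a latent quality vector over the eight catalog domains, multivariate
#' normal with exchangeable inter-domain correlation `domain_correlation`.
#' Binary items are Bernoulli with a logistic link on the item's domain
#' latent; client-level items add a per-client heterogeneity term. The three
#' concordance items get paired exit-interview reports through a
#' recall / false-positive channel.
#'
#' @param n_facilities Number of facilities (default 400, the order of a
#'   national facility census arm).
#' @param domain_correlation Exchangeable correlation of the 8-domain latent,
#'   in `[-1/7, 1]` (positive-semidefiniteness bound for 8 dimensions).
#' @param item_params Per-item `alpha`/`beta` tibble; see
#'   [default_item_params()].
#' @param clients_mean,clients_max Clients observed per facility are
#'   `1 + Poisson(clients_mean - 1)` capped at `clients_max` (defaults 3.5
#'   and 15: a mean of 3-4 clients with range 1-15).
#' @param providers_mean Providers interviewed per facility,
#'   `1 + Poisson(providers_mean - 1)` (default 2.5).
#' @param exit_recall P(exit interview reports yes | observed yes).
#' @param exit_false_positive P(exit reports yes | observed no).
#' @param client_noise_sd SD of the per-client latent heterogeneity added to
#'   process-item logits.
#' @param strata_effects Named list of additive latent shifts by facility
#'   type, managing authority, and locality.
#' @param weight_sdlog SD of the log-normal survey weights (normalized to
#'   mean 1 per table).
#' @param catalog Catalog whose raw-field vocabulary the tables must cover.
#' @param seed Optional default seed used by [simulate_spa()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_facilities = 400,
                       domain_correlation = 0.5,
                       item_params = NULL,
                       clients_mean = 3.5,
                       clients_max = 15,
                       providers_mean = 2.5,
                       exit_recall = 0.9,
                       exit_false_positive = 0.1,
                       client_noise_sd = 0.5,
                       strata_effects = NULL,
                       weight_sdlog = 0.25,
                       catalog = default_catalog(),
                       seed = NULL) {
  validate_catalog(catalog)
  if (is.null(item_params)) item_params <- default_item_params(catalog)
  if (is.null(strata_effects)) {
    strata_effects <- list(
      facility_type = c(hospital = 0.6, health_center = 0, dispensary = -0.3),
      managing_authority = c(public = 0, private = 0.1),
      locality = c(urban = 0.25, rural = 0)
    )
  }
  n_dom <- nrow(qoc_domains())
  if (n_facilities < 1) abort("n_facilities must be positive.")
  if (domain_correlation < -1 / (n_dom - 1) || domain_correlation > 1) {
    abort(sprintf(
      "domain_correlation %.3f makes the latent covariance non-positive-semidefinite (allowed range [%.4f, 1]).",
      domain_correlation, -1 / (n_dom - 1)))
  }
  for (p in c(exit_recall, exit_false_positive)) {
    if (p < 0 || p > 1) abort("exit_recall and exit_false_positive must lie in [0, 1].")
  }
  if (clients_mean < 1 || clients_max < 1 || clients_mean > clients_max) {
    abort("clients_mean must lie in [1, clients_max].")
  }
  if (any(item_params$beta < 0)) abort("item loadings beta must be nonnegative.")
  needed <- c(catalog_raw_fields(catalog, "facility"),
              catalog_raw_fields(catalog, "provider"),
              grep("^exit_", catalog_raw_fields(catalog, "client"),
                   value = TRUE, invert = TRUE))
  miss <- setdiff(needed, item_params$field)
  if (length(miss) > 0) {
    abort(sprintf("item_params missing catalog field(s): %s",
                  paste(miss, collapse = ", ")))
  }
  structure(
    list(n_facilities = as.integer(n_facilities),
         domain_correlation = domain_correlation,
         item_params = item_params,
         clients_mean = clients_mean, clients_max = as.integer(clients_max),
         providers_mean = providers_mean,
         exit_recall = exit_recall, exit_false_positive = exit_false_positive,
         client_noise_sd = client_noise_sd,
         strata_effects = strata_effects,
         weight_sdlog = weight_sdlog,
         catalog = catalog, seed = seed),
    class = "sim_config"
  )
}

#' Preset: near-unidimensional latent quality
#'
#' High inter-domain correlation (0.95) with uniform loadings, so a single
#' latent dimension drives all items — the regime in which a first principal
#' component summarizes quality well and all three indices rank facilities
#' alike.
#'
#' @param strength `"strong"` (beta = 2) or `"weak"` (beta = 0.8) uniform
#'   item loadings.
#' @param n_facilities Number of facilities (default 1000).
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_unidimensional <- function(strength = c("strong", "weak"),
                               n_facilities = 1000, ...) {
  strength <- match.arg(strength)
  params <- default_item_params()
  params$beta <- if (strength == "strong") 2 else 0.8
  sim_config(n_facilities = n_facilities, domain_correlation = 0.95,
             item_params = params, ...)
}

#' Preset: multidimensional latent quality
#'
#' Uncorrelated domain latents with mixed item loadings, so variance spreads
#' across many components and the first principal component explains little
#' of the total — the low-variance regime facility-survey quality data tends
#' to occupy.
#'
#' @inheritParams sim_unidimensional
#' @return A `sim_config`.
#' @export
sim_multidimensional <- function(n_facilities = 1000, ...) {
  params <- default_item_params()
  params$beta <- rep(c(0.25, 0.75, 1.5), length.out = nrow(params))
  sim_config(n_facilities = n_facilities, domain_correlation = 0,
             item_params = params, ...)
}

draw_strata <- function(n) {
  tibble(
    facility_type = sample(c("hospital", "health_center", "dispensary"), n,
                           replace = TRUE, prob = c(0.12, 0.50, 0.38)),
    managing_authority = sample(c("public", "private"), n, replace = TRUE,
                                prob = c(0.65, 0.35)),
    locality = sample(c("urban", "rural"), n, replace = TRUE,
                      prob = c(0.30, 0.70))
  )
}

norm_weights <- function(n, sdlog) {
  w <- rlnorm(n, 0, sdlog)
  w / mean(w)
}

#' Generate synthetic SPA-like survey tables with known ground truth
#'
#' Draws facilities with stratifiers and an 8-domain latent quality vector,
#' then facility structural items, provider training flags, and per-client
#' observed process items with paired exit-interview reports, all per the
#' generative model documented in [sim_config()]. The same seed always
#' reproduces the same tables.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; overrides `config$seed`. Required through one of
#'   the two.
#' @return A list with `tables` (a `qoc_tables` object) and `truth` (a tibble
#'   with the latent domain qualities `q_<domain>`, their mean
#'   `true_quality`, and `true_tercile`).
#' @export
#' @examples
#' sim <- simulate_spa(sim_config(n_facilities = 30), seed = 7)
#' sim$tables
#' head(sim$truth)
simulate_spa <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config().")
  seed <- seed %||% config$seed
  if (is.null(seed)) abort("a seed is required (argument or config$seed).")
  set.seed(as.integer(seed))

  n <- config$n_facilities
  doms <- qoc_domains()$domain
  n_dom <- length(doms)
  rho <- config$domain_correlation
  sigma <- matrix(rho, n_dom, n_dom)
  diag(sigma) <- 1
  q <- MASS::mvrnorm(n, mu = rep(0, n_dom), Sigma = sigma)
  if (n == 1) q <- matrix(q, nrow = 1)
  colnames(q) <- doms

  strata <- draw_strata(n)
  shift <- config$strata_effects$facility_type[strata$facility_type] +
    config$strata_effects$managing_authority[strata$managing_authority] +
    config$strata_effects$locality[strata$locality]
  q <- q + shift  # recycled column-wise: same shift on every domain

  params <- config$item_params
  item_p <- function(fields, latent_rows, extra = 0) {
    # latent_rows: facility index per output row
    out <- lapply(fields, function(f) {
      pr <- params[params$field == f, ]
      eta <- pr$alpha + pr$beta * q[latent_rows, pr$domain] + extra
      rbinom(length(latent_rows), 1L, plogis(eta))
    })
    setNames(out, fields)
  }

  fac_fields <- intersect(params$field[params$source_level == "facility"],
                          catalog_raw_fields(config$catalog, "facility"))
  facility <- bind_cols(
    tibble(facility_id = sprintf("F%04d", seq_len(n)),
           weight = norm_weights(n, config$weight_sdlog)),
    strata,
    as_tibble(item_p(fac_fields, seq_len(n)))
  )

  ## providers
  n_prov <- 1L + rpois(n, config$providers_mean - 1)
  prov_fac <- rep(seq_len(n), n_prov)
  prov_fields <- params$field[params$source_level == "provider"]
  prov_noise <- rnorm(length(prov_fac), 0, config$client_noise_sd)
  provider <- bind_cols(
    tibble(facility_id = facility$facility_id[prov_fac],
           provider_id = sprintf("P%05d", seq_along(prov_fac)),
           weight = norm_weights(length(prov_fac), config$weight_sdlog)),
    as_tibble(item_p(prov_fields, prov_fac, extra = prov_noise))
  )

  ## clients: 1 + truncated Poisson, observed items + exit channel
  n_cli <- pmin(1L + rpois(n, config$clients_mean - 1), config$clients_max)
  cli_fac <- rep(seq_len(n), n_cli)
  cli_noise <- rnorm(length(cli_fac), 0, config$client_noise_sd)
  obs_fields <- params$field[params$source_level == "client"]
  obs <- item_p(obs_fields, cli_fac, extra = cli_noise)
  conc <- catalog_fields(config$catalog[config$catalog$rule == "concordance", ])
  exit_cols <- lapply(conc, function(pair) {
    observed <- obs[[pair[1]]]
    p_yes <- ifelse(observed == 1L, config$exit_recall, config$exit_false_positive)
    rbinom(length(observed), 1L, p_yes)
  })
  names(exit_cols) <- vapply(conc, `[`, character(1), 2L)
  client <- bind_cols(
    tibble(facility_id = facility$facility_id[cli_fac],
           client_id = sprintf("C%05d", seq_along(cli_fac)),
           weight = norm_weights(length(cli_fac), config$weight_sdlog)),
    as_tibble(obs), as_tibble(exit_cols)
  )

  true_quality <- rowMeans(q)
  truth <- bind_cols(
    tibble(facility_id = facility$facility_id),
    as_tibble(q) |> rlang::set_names(paste0("q_", doms)),
    tibble(true_quality = true_quality,
           true_tercile = tercile_assign(true_quality))
  )

  list(tables = as_survey_tables(facility, provider, client,
                                 catalog = config$catalog),
       truth = truth)
}

#' Preset: near-unidimensional latent quality with controlled loading spread
#'
#' Holds the latent structure of [sim_unidimensional()] (inter-domain
#' correlation 0.95) while varying how unevenly items load on it. With
#' `"uniform"` loadings every item is equally informative, so
#' first-component PCA weights barely vary and the PCA score behaves like
#' the simple additive sum; increasing dispersion concentrates the PCA
#' weights on a few items and pulls the two scores apart.
#'
#' @param dispersion `"uniform"` (all beta = 1.2), `"medium"` (beta cycles
#'   0.6/1.2/1.8), or `"high"` (beta cycles 0.1/0.4/3.1 — same mean).
#' @inheritParams sim_unidimensional
#' @return A `sim_config`.
#' @export
sim_loading_dispersion <- function(dispersion = c("uniform", "medium", "high"),
                                   n_facilities = 800, ...) {
  dispersion <- match.arg(dispersion)
  betas <- switch(dispersion,
                  uniform = c(1.2, 1.2, 1.2),
                  medium = c(0.6, 1.2, 1.8),
                  high = c(0.1, 0.4, 3.1))
  params <- default_item_params()
  params$beta <- rep(betas, length.out = nrow(params))
  sim_config(n_facilities = n_facilities, domain_correlation = 0.95,
             item_params = params, ...)
}
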