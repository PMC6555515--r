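test_that("simple additive is the plain indicator sum with range 0-53", {
  cat53 <- default_catalog()
  rows <- rbind(rep(1, 53), rep(0, 53), c(rep(1, 10), rep(0, 43)))
  m <- mini_matrix(rows, cat53)
  expect_equal(score_simple(m, cat53), c(53L, 0L, 10L))
})

test_that("weighted additive equalizes domains per the printed formula", {
  cat53 <- default_catalog()
  all_on <- mini_matrix(rbind(rep(1, 53)), cat53)
  expect_equal(score_weighted(all_on, cat53), 100)
  # two of the five constellation-of-services items, all else 0
  row <- rep(0, 53)
  row[match(c("svc_anc", "svc_pnc"), cat53$id)] <- 1
  expect_equal(score_weighted(mini_matrix(rbind(row), cat53), cat53),
               (2 / 5) * 100 / 8)
  # general case agrees with the domain-share formula evaluated by hand
  set.seed(42)
  x <- matrix(rbinom(5 * 53, 1, 0.5), nrow = 5)
  m <- mini_matrix(x, cat53)
  by_hand <- sapply(seq_len(5), function(f) {
    sum(tapply(x[f, ], cat53$domain, mean)) * 100 / 8
  })
  expect_equal(score_weighted(m, cat53), unname(by_hand))
})

test_that("flipping any indicator on never decreases the additive scores", {
  cat53 <- default_catalog()
  set.seed(7)
  base <- rbinom(53, 1, 0.4)
  m0 <- mini_matrix(rbind(base), cat53)
  s0 <- score_simple(m0, cat53)
  w0 <- score_weighted(m0, cat53)
  for (j in which(base == 0)) {
    flipped <- base
    flipped[j] <- 1
    m1 <- mini_matrix(rbind(flipped), cat53)
    expect_gte(score_simple(m1, cat53), s0)
    expect_gte(score_weighted(m1, cat53), w0)
  }
})

test_that("duplicating every item within its domain preserves the weighted score and doubles the simple score", {
  cat53 <- default_catalog()
  dup <- cat53
  dup$id <- paste0(dup$id, "_copy")
  both <- validate_catalog(dplyr::bind_rows(cat53, dup))
  set.seed(8)
  x <- matrix(rbinom(6 * 53, 1, 0.5), nrow = 6)
  m1 <- mini_matrix(x, cat53)
  m2 <- mini_matrix(cbind(x, x), both)
  expect_equal(score_weighted(m2, both), score_weighted(m1, cat53))
  expect_equal(score_simple(m2, both), 2L * score_simple(m1, cat53))
})

test_that("two-item PCA matches the closed form: eigenvalues 1 +/- r, equal loadings", {
  cases <- list(c(1, 1), c(13, 7), c(3, 1), c(19, 1))  # r = 0, 0.3, 0.5, 0.9
  for (ab in cases) {
    r <- (ab[1] - ab[2]) / (ab[1] + ab[2])
    cat2 <- make_mini_catalog(2)
    m <- mini_matrix(two_item_matrix(ab[1], ab[2]), cat2)
    fit <- qoc_pca(m, cat2)
    expect_equal(fit$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-10)
    if (r > 0) {
      # at r = 0 the spectrum is degenerate and the eigenbasis arbitrary
      expect_equal(unname(fit$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-10)
    }
    expect_equal(kaiser_count(fit), if (r > 0) 1L else 2L)
  }
})

test_that("PCA agrees with the SVD oracle on random binary matrices", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(10:50, 1)
    p <- sample(3:8, 1)
    x <- matrix(rbinom(n * p, 1, runif(1, 0.3, 0.7)), nrow = n)
    if (any(apply(x, 2, var) == 0)) next
    catp <- make_mini_catalog(p)
    m <- mini_matrix(x, catp)
    fit <- qoc_pca(m, catp)
    orc <- pca_oracle(x)
    expect_equal(fit$eigenvalues, unname(orc$eigenvalues), tolerance = 1e-8)
    expect_equal(abs(unname(fit$loadings)), abs(unname(orc$loadings)),
                 tolerance = 1e-8)
    expect_equal(sum(fit$eigenvalues), p, tolerance = 1e-8)
    # the scores carry the first component's variance
    sc <- pca_scores(fit, m, catalog = catp)
    expect_equal(var(sc), fit$eigenvalues[1], tolerance = 1e-8)
    expect_equal(mean(sc), 0, tolerance = 1e-10)
    # orientation: first-component loadings sum to a nonnegative value
    expect_gte(sum(fit$loadings[, 1]), 0)
    # scree is non-increasing and the share of the first component is in (0, 1]
    expect_true(all(diff(scree_table(fit)$eigenvalue) <= 1e-12))
    expect_gt(fit$pct_variance_first, 0)
    expect_lte(fit$pct_variance_first, 1)
  }
})

test_that("zero-variance items are dropped from PCA but kept in additive scores", {
  cat3 <- make_mini_catalog(3)
  x <- cbind(two_item_matrix(3, 1), rep(1, 8))
  m <- mini_matrix(x, cat3)
  expect_message(fit <- qoc_pca(m, cat3), "zero-variance")
  expect_equal(fit$items, c("item01", "item02"))
  expect_equal(fit$dropped, "item03")
  expect_equal(sum(fit$eigenvalues), 2, tolerance = 1e-10)
  expect_equal(score_simple(m, cat3), as.integer(rowSums(x)))
  # identical rows get identical scores; dropped items contribute nothing
  sc <- pca_scores(fit, m, catalog = cat3)
  expect_equal(sc[1], sc[2])
})

test_that("degenerate PCA inputs error clearly", {
  cat2 <- make_mini_catalog(2)
  expect_error(qoc_pca(mini_matrix(rbind(c(1, 0)), cat2), cat2), "at least 2")
  m <- mini_matrix(rbind(c(1, 1), c(1, 1)), cat2)
  expect_error(suppressMessages(qoc_pca(m, cat2)), "constant")
})

test_that("score_facilities returns all three mechanisms with the PCA fit attached", {
  sim <- simulate_spa(sim_config(n_facilities = 50), seed = 17)
  m <- build_indicator_matrix(sim$tables)
  sc <- score_facilities(m)
  expect_s3_class(sc, "qoc_scores")
  expect_true(all(c("simple_additive", "weighted_additive", "pca_score") %in% names(sc)))
  expect_true(all(sc$simple_additive >= 0 & sc$simple_additive <= 53))
  expect_true(all(sc$weighted_additive >= 0 & sc$weighted_additive <= 100))
  fit <- attr(sc, "pca")
  expect_s3_class(fit, "qoc_pca")
  expect_equal(nrow(tidy(fit)), length(fit$items))
  expect_equal(glance(fit)$n_items + glance(fit)$n_dropped, 53L)
})

test_that("rank recovery: strong unidimensional data yields Spearman > 0.8 for all indices", {
  sim <- simulate_spa(sim_unidimensional("strong", n_facilities = 1000), seed = 11)
  m <- build_indicator_matrix(sim$tables)
  sc <- score_facilities(m)
  truth <- sim$truth$true_quality[match(sc$facility_id, sim$truth$facility_id)]
  for (s in c("simple_additive", "weighted_additive", "pca_score")) {
    expect_gt(cor(sc[[s]], truth, method = "spearman"), 0.8)
  }
})
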