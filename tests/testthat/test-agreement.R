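test_that("equal-weight terciles split distinct scores into thirds", {
  cats <- tercile_assign(1:9)
  expect_equal(as.vector(table(cats)), c(3, 3, 3))
  expect_equal(unname(attr(cats, "cuts")), c(3, 6))
})

test_that("tied scores share a category under the inclusive cut rule", {
  cats <- tercile_assign(c(1, 1, 1, 2, 3, 3))
  expect_equal(as.character(cats), c("low", "low", "low", "medium", "high", "high"))
})

test_that("weighted tercile cuts match the weighted-CDF oracle, including concentrated weights", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:10, n, replace = TRUE)
    if (length(unique(x)) < 2) next
    w <- sample(1:10, n, replace = TRUE)
    if (rep %% 4 == 0) w[1] <- 100  # dominating facility
    cats <- tercile_assign(x, w)
    cuts <- attr(cats, "cuts")
    expect_equal(cuts[1], weighted_quantile_oracle(x, w, 1 / 3))
    expect_equal(cuts[2], weighted_quantile_oracle(x, w, 2 / 3))
    # monotone: a higher score never gets a lower category
    ord <- order(x)
    expect_true(all(diff(as.integer(cats[ord])) >= 0 | diff(x[ord]) == 0))
  }
})

test_that("degenerate and tiny inputs are classification errors", {
  expect_error(tercile_assign(rep(5, 10)), "degenerate")
  expect_error(tercile_assign(c(1, 2)), "at least 3")
})

test_that("percent agreement counts weighted matches", {
  a <- c("low", "low", "medium", "medium", "high", "high")
  b <- c("low", "low", "medium", "high", "low", "high")
  expect_equal(percent_agreement(a, a), 100)
  shifted <- c("medium", "medium", "high", "high", "low", "low")
  expect_equal(percent_agreement(a, shifted), 0)
  expect_equal(percent_agreement(a, b), 100 * 4 / 6)
  expect_equal(percent_agreement(a, b, weights = c(2, 2, 2, 1, 1, 2)), 80)
})

test_that("kappa reproduces the hand-computed symmetric 3x3 example", {
  tab <- matrix(c(20, 5, 5, 5, 20, 5, 5, 5, 20), 3, 3, byrow = TRUE,
                dimnames = list(c("low", "medium", "high"),
                                c("low", "medium", "high")))
  v <- table_to_vectors(tab)
  fit <- cohens_kappa(v$a, v$b)
  expect_equal(fit$p_o, 2 / 3)
  expect_equal(fit$p_e, 1 / 3)
  expect_equal(fit$kappa, 0.5)
  expect_equal(fit$band, "moderate")
})

test_that("kappa and percent agreement match the brute-force oracle on random weighted tables", {
  set.seed(123)
  for (rep in 1:200) {
    tab <- matrix(sample(0:8, 9, replace = TRUE), 3, 3,
                  dimnames = list(c("l", "m", "h"), c("l", "m", "h")))
    if (sum(tab) == 0 || sum(tab) > 50) next
    orc <- kappa_oracle(tab)
    if (orc$p_e >= 1 - 1e-12) next
    v <- table_to_vectors(tab)
    w <- runif(length(v$a), 0.5, 2)
    # integer-expanded vectors with unit weights reproduce the table exactly
    fit <- cohens_kappa(v$a, v$b)
    expect_equal(fit$kappa, orc$kappa, tolerance = 1e-10)
    expect_equal(fit$percent_agreement, orc$percent_agreement, tolerance = 1e-10)
    # and fractional weights agree with the oracle on the reweighted table
    fit_w <- cohens_kappa(v$a, v$b, weights = w)
    expect_equal(fit_w$kappa, kappa_oracle(fit_w$table)$kappa, tolerance = 1e-10)
  }
})

test_that("kappa agrees with an independent library on an unweighted table", {
  skip_if_not_installed("e1071")
  set.seed(5)
  tab <- matrix(sample(1:10, 9, replace = TRUE), 3, 3,
                dimnames = list(c("l", "m", "h"), c("l", "m", "h")))
  v <- table_to_vectors(tab)
  fit <- cohens_kappa(v$a, v$b)
  expect_equal(fit$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
})

test_that("kappa invariants: identity, label permutation, independence, constant raters", {
  a <- factor(rep(c("low", "medium", "high"), times = c(10, 12, 8)),
              levels = c("low", "medium", "high"))
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  expect_equal(percent_agreement(a, a), 100)
  # simultaneous relabeling of both assignments leaves kappa unchanged
  perm <- c(low = "high", medium = "low", high = "medium")
  set.seed(31)
  b <- sample(a)
  k1 <- cohens_kappa(a, b)$kappa
  k2 <- cohens_kappa(factor(perm[as.character(a)], levels = perm),
                     factor(perm[as.character(b)], levels = perm))$kappa
  expect_equal(k1, k2)
  expect_lte(k1, 1)
  # independent assignments at large n give kappa near 0
  set.seed(32)
  big_a <- sample(c("low", "medium", "high"), 6000, replace = TRUE)
  big_b <- sample(c("low", "medium", "high"), 6000, replace = TRUE)
  expect_lt(abs(cohens_kappa(big_a, big_b)$kappa), 0.05)
  expect_error(cohens_kappa(rep("low", 5), rep("low", 5)), "undefined")
})

test_that("Landis-Koch labels reproduce the published band edges", {
  expect_equal(landis_koch(c(0.90, 0.81, 0.80, 0.61, 0.60, 0.46, 0.41, 0.40,
                             0.21, 0.20, 0.0, -0.1)),
               c("near perfect", "near perfect", "good", "good", "moderate",
                 "moderate", "moderate", "fair", "fair", "poor", "poor",
                 "worse than chance"))
  expect_error(landis_koch(1.5), "\\[-1, 1\\]")
})

test_that("compare_scores yields kappa 1 for identical rankings and respects pair structure", {
  set.seed(55)
  x <- sample(0:53, 60, replace = TRUE)
  scores <- tibble::tibble(
    facility_id = sprintf("F%02d", 1:60), weight = 1,
    simple_additive = x, weighted_additive = x * 100 / 53, pca_score = as.numeric(x)
  )
  out <- compare_scores(scores)
  expect_equal(nrow(out), 3)
  expect_equal(out$kappa, rep(1, 3))
  expect_equal(out$percent_agreement, rep(100, 3))
  # PCA identical to simple but weighted different: only that pair is perfect
  scores$weighted_additive <- rev(seq_len(60)) + runif(60)
  out2 <- compare_scores(scores)
  expect_equal(out2$kappa[out2$index_1 == "pca_score"], 1)
  expect_lt(out2$kappa[out2$index_1 == "simple_additive"], 1)
})

test_that("high-quality profile matches hand-tabulated weighted shares", {
  scores <- tibble::tibble(
    facility_id = sprintf("F%d", 1:6),
    weight = c(1, 2, 1, 1, 2, 1),
    facility_type = c("hospital", "hospital", "clinic", "clinic", "clinic", "clinic"),
    simple_additive = c(9, 8, 7, 5, 3, 1),
    weighted_additive = c(90, 80, 70, 50, 30, 10),
    pca_score = c(9, 8, 7, 5, 3, 1) / 2
  )
  cfg <- run_config(weighted_terciles = FALSE)
  prof <- high_quality_profile(scores, config = cfg)
  # unweighted terciles of 9,8,7,5,3,1: cuts at 3 and 7 -> high = {9, 8}
  hosp <- prof[prof$stratum == "hospital" & prof$score == "simple_additive", ]
  expect_equal(hosp$pct_high, 100)  # both hospitals (weights 1+2) are high
  clin <- prof[prof$stratum == "clinic" & prof$score == "simple_additive", ]
  expect_equal(clin$pct_high, 0)
  expect_error(high_quality_profile(scores, characteristics = "region"),
               "unknown stratifier")
})

test_that("within a stratum the three tercile shares sum to 100", {
  sim <- simulate_spa(sim_config(n_facilities = 80), seed = 19)
  m <- build_indicator_matrix(sim$tables)
  sc <- score_facilities(m)
  cats <- tercile_assign(sc$simple_additive, sc$weight)
  for (st in unique(sc$facility_type)) {
    idx <- sc$facility_type == st
    shares <- vapply(c("low", "medium", "high"), function(lv) {
      100 * sum(sc$weight[idx & cats == lv]) / sum(sc$weight[idx])
    }, numeric(1))
    expect_equal(sum(shares), 100)
  }
})
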