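test_that("ICC matches an independent ANOVA decomposition", {
  # 4x2 toy matrix with mean squares recomputed through lm()'s ANOVA
  obs <- c(9, 6, 8, 7)
  est <- c(8, 5, 9, 6)
  res <- icc_agreement(obs, est)
  ms <- oracle_anova_ms(obs, est)
  expect_equal(res$ms_rows, ms$ms_rows, tolerance = 1e-12)
  expect_equal(res$ms_cols, ms$ms_cols, tolerance = 1e-12)
  expect_equal(res$ms_error, ms$ms_error, tolerance = 1e-12)
  n <- 4
  icc_hand <- (ms$ms_rows - ms$ms_error) /
    (ms$ms_rows + ms$ms_error + (2 / n) * (ms$ms_cols - ms$ms_error))
  expect_equal(res$icc, icc_hand, tolerance = 1e-12)

  # random matrices: same agreement along both routes
  set.seed(41)
  for (rep in 1:20) {
    o <- rnorm(12, 20, 4)
    e <- o + rnorm(12, 0.5, 2)
    res <- icc_agreement(o, e)
    ms <- oracle_anova_ms(o, e)
    icc_hand <- (ms$ms_rows - ms$ms_error) /
      (ms$ms_rows + ms$ms_error + (2 / 12) * (ms$ms_cols - ms$ms_error))
    expect_equal(res$icc, icc_hand, tolerance = 1e-12)
  }
})

test_that("ICC has the expected fixed points, signs and bands", {
  v <- c(10, 14, 18, 25, 30)
  perfect <- icc_agreement(v, v)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$band, "excellent")
  # reversed ranking disagrees more than chance
  expect_lt(icc_agreement(c(1, 2, 3), c(3, 2, 1))$icc, 0)
  # band boundaries
  expect_equal(icc_band(c(0.2, 0.6, 0.8, 0.95)),
               c("poor", "moderate", "good", "excellent"))
  # confidence interval brackets the estimate
  set.seed(43)
  o <- rnorm(40, 22, 5)
  e <- o + rnorm(40, 0, 2)
  res <- icc_agreement(o, e)
  expect_lt(res$conf_low, res$icc)
  expect_gt(res$conf_high, res$icc)
  expect_true(res$conf_high <= 1 + 1e-12)

  expect_error(icc_agreement(1:2, 1:2), class = "equicross_size_error")
  expect_error(icc_agreement(rep(5, 6), rep(5, 6)),
               class = "equicross_degeneracy_error")
})

test_that("agreement vs consistency ICC differ in shift invariance", {
  set.seed(47)
  o <- rnorm(30, 20, 4)
  e <- o + rnorm(30, 0, 1.5)

  base_a <- icc_agreement(o, e, type = "agreement")$icc
  base_c <- icc_agreement(o, e, type = "consistency")$icc
  # adding the same constant to both vectors changes neither form
  expect_equal(icc_agreement(o + 7, e + 7, type = "agreement")$icc, base_a,
               tolerance = 1e-12)
  expect_equal(icc_agreement(o + 7, e + 7, type = "consistency")$icc, base_c,
               tolerance = 1e-12)
  # a constant offset on one vector leaves consistency unchanged but
  # penalizes absolute agreement
  shift_c <- icc_agreement(o, e + 3, type = "consistency")$icc
  shift_a <- icc_agreement(o, e + 3, type = "agreement")$icc
  expect_equal(shift_c, base_c, tolerance = 1e-12)
  expect_lt(shift_a, base_a)
})

test_that("Pearson summary matches direct arithmetic and its bands", {
  # exact linearity
  lin <- pearson_with_band(1:10, 2 * (1:10) + 1)
  expect_equal(lin$r, 1)
  expect_equal(lin$band, "very high")
  # 5-point hand computation
  x <- c(2, 4, 5, 7, 9)
  y <- c(1, 3, 6, 6, 10)
  res <- pearson_with_band(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$r2_percent, 100 * r_hand^2, tolerance = 1e-12)
  # the band thresholds: a correlation of .841 is high, with r2 ~ 71%
  expect_equal(equicross:::pearson_band(0.841), "high")
  expect_equal(round(100 * 0.841^2), 71)
  expect_equal(equicross:::pearson_band(c(0.1, 0.4, 0.6, 0.95)),
               c("very low", "low", "moderate", "very high"))
  expect_error(pearson_with_band(rep(3, 5), 1:5),
               class = "equicross_degeneracy_error")
})

test_that("agreement_within counts by enumeration and is monotone in k", {
  obs <- c(20, 25, 30)
  est <- c(22, 25, 29)
  expect_equal(agreement_within(obs, est, 1), 100 * 2 / 3)
  expect_equal(agreement_within(obs, est, 2), 100)
  # k = 0 is the exact-match percentage
  expect_equal(agreement_within(obs, est, 0), 100 * 1 / 3)
  expect_equal(agreement_within(obs, obs, 0:3), rep(100, 4))
  # monotone nondecreasing in k on random data
  set.seed(53)
  o <- sample(0:30, 50, replace = TRUE)
  e <- pmin(pmax(o + sample(-4:4, 50, replace = TRUE), 0), 30)
  pct <- agreement_within(o, e, 0:6)
  expect_true(all(diff(pct) >= 0))
  expect_error(agreement_within(numeric(0), numeric(0), 1),
               class = "equicross_empty_error")
})

test_that("validate_crosswalk reproduces a full hand computation", {
  # identity cohort with identity table: perfect agreement
  ident <- make_cohort(c(10, 15, 20, 25, 28, 30), c(10, 15, 20, 25, 28, 30))
  id_tab <- crosswalk(0:30, 0:30, provenance = "identity")
  rep_id <- validate_crosswalk(ident, id_tab)
  expect_equal(rep_id$overall$icc, 1)
  expect_equal(rep_id$overall$pct_within_1, 100)

  # 6-record cohort against the published table, all statistics by hand
  coh <- make_cohort(
    rudas = c(10, 14, 18, 23, 26, 30),
    mmse  = c(13, 16, 22, 25, 28, 30),
    group = c("GDS4_5", "GDS3", "GDS3", "HC", "HC", "HC")
  )
  tab <- published_crosswalk()
  est <- apply_crosswalk(tab, coh$rudas)
  expect_equal(est, c(12, 17, 21, 26, 28, 30))
  rep6 <- validate_crosswalk(coh, tab)
  expect_equal(rep6$overall$n, 6)
  expect_equal(rep6$overall$pct_within_1,
               100 * mean(abs(coh$mmse - est) <= 1))
  expect_equal(rep6$overall$pct_within_2,
               100 * mean(abs(coh$mmse - est) <= 2))
  expect_equal(rep6$overall$icc, icc_agreement(coh$mmse, est)$icc)
  expect_equal(rep6$overall$pearson_r, pearson_with_band(coh$mmse, est)$r)
  # subgroup decomposition: HC and pwAD = GDS3 + GDS4_5
  expect_setequal(rep6$subgroups$subset, c("HC", "pwAD"))
  expect_equal(rep6$subgroups$n[rep6$subgroups$subset == "pwAD"], 3)
})

test_that("validation reports are well-formed on simulated cohorts", {
  coh <- simulate_cohort(default_configs()$minority, seed = 12)
  rep <- validate_crosswalk(coh, published_crosswalk())
  o <- rep$overall
  expect_true(all(is.finite(c(o$icc, o$icc_low, o$icc_high, o$pearson_r,
                              o$pct_within_1, o$pct_within_2))))
  expect_true(o$icc_band %in% c("poor", "moderate", "good", "excellent"))
  expect_lte(o$pct_within_1, o$pct_within_2)
  expect_lte(o$pct_within_2, 100)
  expect_equal(o$r2_percent, 100 * o$pearson_r^2, tolerance = 1e-12)
  td <- tidy(rep)
  expect_true(all(c("overall", "HC", "pwAD") %in% td$subset))
  json <- export_report_json(rep)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$overall$icc, o$icc, tolerance = 1e-9)
})

test_that("pooled ICC can exceed both subgroup ICCs on a clinical mixture", {
  # range restriction within groups depresses subgroup ICCs relative to the
  # pooled coefficient; observed on the default simulated mixture
  coh <- simulate_cohort(default_configs()$majority_validation, seed = 2)
  rep <- validate_crosswalk(coh, published_crosswalk())
  iccs <- rep$subgroups$icc
  expect_true(all(rep$overall$icc >= -1 & rep$overall$icc <= 1))
  expect_true(all(iccs >= -1 & iccs <= 1))
  expect_gt(rep$overall$icc, max(iccs))
})

test_that("undersized subgroups are omitted with a warning", {
  coh <- make_cohort(c(10, 15, 20, 25, 28), c(12, 17, 22, 26, 29),
                     group = c("HC", "HC", "HC", "HC", "GDS3"))
  expect_warning(
    rep <- validate_crosswalk(coh, published_crosswalk()),
    "fewer than 3"
  )
  expect_false("pwAD" %in% rep$subgroups$subset)
})
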