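test_that("percentile ranks follow the continuity-corrected definition", {
  # point mass: half the mass lies below the score's midpoint
  pt <- as_score_distribution(c(0, 0, 0, 0, 0, 1), max_score = 5)
  expect_equal(percentile_rank(pt, 5), 50)
  # uniform two-point case
  d2 <- as_score_distribution(c(0.5, 0.5), max_score = 1)
  expect_equal(percentile_rank(d2, 0:1), c(25, 75))
  # direct evaluation of the defining formula
  d4 <- as_score_distribution(c(0.1, 0.2, 0.3, 0.4), max_score = 3)
  expect_equal(percentile_rank(d4, 2), 45)
  expect_equal(percentile_rank(d4, 0:3), c(5, 20, 45, 80))
  expect_error(percentile_rank(d4, 4), class = "equicross_range_error")
})

test_that("inverse percentile inverts the rank and handles edge cases", {
  d <- as_score_distribution(c(0.5, 0.25, 0.25), max_score = 2)
  # hand evaluation: F(0) = .5 is not > .5, so x_U = 1
  expect_equal(inverse_percentile(d, 50), 0.5)
  # endpoints
  expect_equal(inverse_percentile(d, 0), -0.5)
  expect_equal(inverse_percentile(d, 100), 2.5)
  # point mass symmetry
  pt <- as_score_distribution(c(0, 0, 0, 0, 0, 1), max_score = 5)
  expect_equal(inverse_percentile(pt, 50), 5)
  # flat region (zero-frequency cell): midpoint of the bracketing interval
  flat <- as_score_distribution(c(0.5, 0, 0.5), max_score = 2)
  expect_equal(inverse_percentile(flat, 50), 1)
  expect_error(inverse_percentile(d, 101), class = "equicross_range_error")

  # round-trip on every observed score, raw and smoothed
  set.seed(5)
  for (rep in 1:20) {
    probs <- random_probs(10)
    dr <- as_score_distribution(probs, max_score = 10)
    x <- 0:10
    expect_equal(inverse_percentile(dr, percentile_rank(dr, x)), x,
                 tolerance = 1e-12)
  }
})

test_that("equating any distribution to itself is the identity", {
  set.seed(9)
  for (rep in 1:20) {
    probs <- random_probs(30, concentrated = rep %% 2 == 0)
    d <- as_score_distribution(probs, max_score = 30)
    eq <- equate_equipercentile(d, d)
    expect_equal(eq$concordance$equated, 0:30, tolerance = 1e-9)
    expect_equal(eq$crosswalk$mmse, 0:30)
  }
  # also through the smoothed path
  scores <- pmin(pmax(round(rnorm(300, 22, 5)), 0), 30)
  fit <- fit_loglinear(score_distribution(scores), 3)
  eq_s <- equate_equipercentile(fit, fit)
  expect_equal(eq_s$concordance$equated, 0:30, tolerance = 1e-9)
})

test_that("hand-computed small-support equating is reproduced", {
  dx <- as_score_distribution(c(0.25, 0.5, 0.25), max_score = 2)
  dy <- as_score_distribution(c(0.5, 0.25, 0.25), max_score = 2)
  eq <- equate_equipercentile(dx, dy, x_name = "x", y_name = "y")
  expect_equal(eq$concordance$equated[2], 0.5)
})

test_that("equating matches the brute-force CDF-matching oracle", {
  set.seed(17)
  for (K in 2:5) {
    for (rep in 1:25) {
      px <- random_probs(K)
      py <- random_probs(K)
      dx <- as_score_distribution(px, max_score = K)
      dy <- as_score_distribution(py, max_score = K)
      got <- equate_equipercentile(dx, dy, x_name = "x", y_name = "y")
      expect_equal(got$concordance$equated, oracle_equate(px, py),
                   tolerance = 1e-12)
    }
  }
})

test_that("equated functions are monotone and within range for random pairs", {
  set.seed(23)
  for (rep in 1:200) {
    dx <- as_score_distribution(random_probs(30, concentrated = TRUE),
                                max_score = 30)
    dy <- as_score_distribution(random_probs(30, concentrated = TRUE),
                                max_score = 30)
    eq <- equate_equipercentile(dx, dy)
    e <- eq$concordance$equated
    expect_true(all(diff(e) >= -1e-12))
    expect_true(all(e >= -0.5 & e <= 30.5))
    expect_false(is.unsorted(eq$crosswalk$mmse))
  }
})

test_that("symmetry: X->Y then Y->X round-trips on smoothed distributions", {
  set.seed(29)
  for (rep in 1:10) {
    sx <- pmin(pmax(round(rnorm(400, runif(1, 12, 22), 5)), 0), 30)
    sy <- pmin(pmax(round(rnorm(400, runif(1, 15, 25), 4)), 0), 30)
    fx <- fit_loglinear(score_distribution(sx), 3)
    fy <- fit_loglinear(score_distribution(sy), 3)
    e_xy <- equate_equipercentile(fx, fy)$concordance$equated
    # map the continuous equated values back through the reverse direction
    back <- vapply(e_xy, function(t) {
      oracle_quantile(fx$table$fitted_prob,
                      oracle_cdf(fy$table$fitted_prob, t), tol = 1e-15)
    }, numeric(1))
    expect_equal(back, 0:30, tolerance = 1e-9)
  }
})

test_that("stochastically smaller source implies equated values above identity", {
  set.seed(31)
  for (rep in 1:20) {
    py <- random_probs(30)
    # shift Y down by two scores, piling the bottom mass at 0, to build a
    # stochastically smaller X
    px <- c(sum(py[1:3]), py[4:31], 0, 0)
    dx <- as_score_distribution(px, max_score = 30)
    dy <- as_score_distribution(py, max_score = 30)
    e <- equate_equipercentile(dx, dy)$concordance$equated
    expect_true(all(e >= 0:30 - 1e-9))
  }
})

test_that("crosswalk construction rounds half up, clips, and validates", {
  dx <- as_score_distribution(random_probs(30), max_score = 30)
  eq <- equate_equipercentile(dx, dx)
  expect_equal(eq$crosswalk$mmse, 0:30)  # identity table

  # declared rule: 16.5 rounds to 17
  expect_equal(equicross:::round_clip(16.5), 17)
  expect_equal(equicross:::round_clip(c(-0.5, 30.5)), c(0, 30))

  expect_error(crosswalk(0:30, c(1, 0, rep(2, 29))),
               class = "equicross_integrity_error")   # not monotone
  expect_error(crosswalk(0:29, rep(1, 30)),
               class = "equicross_integrity_error")   # not total on 0..30
  expect_error(crosswalk(0:30, c(rep(1, 30), 31)),
               class = "equicross_integrity_error")   # out of range
})

test_that("crosswalk application, serialization and inversion behave", {
  tab <- crosswalk(0:30, pmin(0:30 + 2, 30), provenance = "shift-by-two")
  expect_equal(apply_crosswalk(tab, c(0, 5, 28, 30)), c(2, 7, 30, 30))
  expect_error(apply_crosswalk(tab, c(3, 31)), class = "equicross_range_error")

  path <- withr::local_tempfile(fileext = ".csv")
  write_crosswalk(tab, path)
  tab2 <- read_crosswalk(path)
  expect_equal(tab2$mmse, tab$mmse)

  json <- export_crosswalk_json(tab)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$map$mmse, tab$mmse)

  inv <- invert_crosswalk(tab)
  expect_false(is.unsorted(inv[[2]]))
  expect_match(attr(inv, "provenance"), "derived inverse")
})
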