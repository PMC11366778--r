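#' Intraclass correlation between observed and estimated scores
#'
#' Computes the single-measurement, two-way random-effects ICC from the
#' two-way ANOVA decomposition of the n-subjects-by-2-measurements matrix.
#' The default absolute-agreement form, ICC(2,1) / ICC(A,1),
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' penalizes systematic offsets between the two measurements -- the right
#' property for a score-prediction crosswalk, where a constant bias is a real
#' error. The consistency form (which ignores constant offsets) is available
#' via `type = "consistency"`. The 95% confidence interval uses the classical
#' F-distribution formulas (Satterthwaite degrees of freedom for the
#' agreement form). Reliability bands follow the Koo--Li conventions:
#' below .5 poor, .5--.75 moderate, .75--.90 good, above .90 excellent.
#'
#' @param observed,estimated Numeric vectors of equal length (n >= 3).
#' @param type `"agreement"` (default, ICC(2,1) absolute agreement) or
#'   `"consistency"` (ICC(C,1)).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `icc`, `conf_low`, `conf_high`, `band`, `type`,
#'   `n`, and the ANOVA mean squares `ms_rows`, `ms_cols`, `ms_error`.
#' @examples
#' obs <- c(25, 28, 22, 30, 19, 27)
#' est <- c(26, 28, 21, 30, 20, 26)
#' icc_agreement(obs, est)
#' @export
icc_agreement <- function(observed, estimated, type = c("agreement", "consistency"),
                          conf_level = 0.95) {
  type <- match.arg(type)
  if (length(observed) != length(estimated)) {
    abort("`observed` and `estimated` must have equal length",
          class = "equicross_config_error")
  }
  n <- length(observed)
  if (n < 3) {
    abort("ICC requires at least 3 paired measurements",
          class = "equicross_size_error")
  }
  if (any(!is.finite(observed)) || any(!is.finite(estimated))) {
    abort("ICC inputs must be finite", class = "equicross_config_error")
  }
  k <- 2
  Y <- cbind(observed, estimated)
  row_means <- rowMeans(Y)
  col_means <- colMeans(Y)
  grand <- mean(Y)

  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols

  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_error / ((n - 1) * (k - 1))

  # undefined only when there is no variance at all to attribute: a
  # reversed ranking (zero between-subject variance, positive error
  # variance) still yields a well-defined negative ICC
  if (ss_total <= .Machine$double.eps * sum(Y^2) || ms_r + ms_e == 0) {
    abort("ICC undefined: no variance in the measurements",
          class = "equicross_degeneracy_error")
  }

  alpha <- 1 - conf_level
  if (type == "agreement") {
    icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
    # McGraw & Wong F-based interval for ICC(A,1)
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * ms_c + b * ms_e)^2 /
      ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    denom_common <- k * ms_c + (k * n - k - n) * ms_e
    lower <- n * (ms_r - f_l * ms_e) / (f_l * denom_common + n * ms_r)
    upper <- n * (f_u * ms_r - ms_e) / (denom_common + n * f_u * ms_r)
  } else {
    icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
    fobs <- ms_r / ms_e
    df2 <- (n - 1) * (k - 1)
    f_l <- fobs / qf(1 - alpha / 2, n - 1, df2)
    f_u <- fobs * qf(1 - alpha / 2, df2, n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  }

  tibble(
    icc = icc, conf_low = lower, conf_high = upper,
    band = icc_band(icc), type = type, n = n,
    ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e
  )
}

#' Reliability band for an ICC value
#'
#' @param icc ICC value(s).
#' @return Character band(s): `"poor"` (< .5), `"moderate"` (.5--.75),
#'   `"good"` (.75--.90), `"excellent"` (> .90).
#' @export
icc_band <- function(icc) {
  dplyr::case_when(
    icc < 0.5 ~ "poor",
    icc < 0.75 ~ "moderate",
    icc <= 0.90 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Pearson correlation with interpretation band
#'
#' Product-moment correlation plus the coefficient of determination reported
#' as a percentage of shared variance, banded as: |r| <= .29 very low,
#' .3--.49 low, .5--.69 moderate, .7--.89 high, >= .90 very high.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return A one-row tibble: `r`, `r2_percent`, `band`, `p_value`, `n`.
#' @examples
#' pearson_with_band(1:10, 1:10 * 2 + 1)
#' @export
pearson_with_band <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3",
          class = "equicross_size_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          class = "equicross_degeneracy_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  tibble(
    r = r,
    r2_percent = 100 * r^2,
    band = pearson_band(r),
    p_value = ct$p.value,
    n = length(x)
  )
}

pearson_band <- function(r) {
  a <- abs(r)
  dplyr::case_when(
    a <= 0.29 ~ "very low",
    a <= 0.49 ~ "low",
    a <= 0.69 ~ "moderate",
    a <= 0.89 ~ "high",
    TRUE ~ "very high"
  )
}

#' Percentage of cases within k points
#'
#' Share of paired scores whose absolute difference is at most `k` points --
#' the clinically interpretable agreement summary for a score crosswalk.
#'
#' @param observed,estimated Numeric vectors of equal length (non-empty).
#' @param k Nonnegative integer tolerance(s) in score points; vectorized.
#' @return Percentage(s) in `[0, 100]`, one per element of `k`.
#' @examples
#' agreement_within(c(20, 25, 30), c(22, 25, 29), k = 1:2)
#' @export
agreement_within <- function(observed, estimated, k) {
  if (length(observed) == 0) {
    abort("empty input", class = "equicross_empty_error")
  }
  if (length(observed) != length(estimated)) {
    abort("`observed` and `estimated` must have equal length",
          class = "equicross_config_error")
  }
  if (any(k < 0) || any(k != round(k))) {
    abort("`k` must be nonnegative integer(s)", class = "equicross_config_error")
  }
  d <- abs(observed - estimated)
  vapply(k, function(ki) 100 * mean(d <= ki), numeric(1))
}

#' Validate a crosswalk against observed scores
#'
#' Applies the conversion table to each participant's source-test (RUDAS)
#' score and summarizes agreement between the estimated and observed
#' target-test (MMSE) scores: ICC with confidence interval and reliability
#' band, Pearson r with band and shared-variance percentage, and the
#' percentages of cases within 1 and 2 points. Statistics are computed
#' overall and for the healthy-control (HC) and Alzheimer's-disease (pwAD =
#' GDS3 + GDS4_5) subgroups, plus per population when the cohort mixes
#' populations. Subgroups with fewer than 3 records are omitted with a
#' warning.
#'
#' @param cohort A cohort tibble.
#' @param table A [crosswalk].
#' @param type ICC form passed to [icc_agreement()].
#' @param conf_level Confidence level for the ICC interval.
#' @return An object of class `validation_report`: tibbles `overall` (one
#'   row) and `subgroups`, the per-record `data`, and the crosswalk
#'   `provenance`. `tidy()` returns all rows long; `glance()` the overall
#'   row.
#' @examples
#' coh <- simulate_cohort(default_configs()$majority_validation, seed = 7)
#' validate_crosswalk(coh, published_crosswalk())
#' @export
validate_crosswalk <- function(cohort, table, type = "agreement",
                               conf_level = 0.95) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) {
    abort("cannot validate on an empty cohort", class = "equicross_empty_error")
  }
  stopifnot(inherits(table, "crosswalk"))
  data <- dplyr::mutate(
    cohort,
    estimated_mmse = apply_crosswalk(table, .data$rudas),
    clinical = ifelse(.data$group == "HC", "HC", "pwAD")
  )

  subsets <- list(overall = data)
  for (g in unique(data$clinical)) subsets[[g]] <- data[data$clinical == g, ]
  if (dplyr::n_distinct(data$population) > 1) {
    for (p in unique(as.character(data$population))) {
      subsets[[p]] <- data[data$population == p, ]
    }
  }

  rows <- purrr::imap(subsets, function(d, nm) {
    if (nrow(d) < 3) {
      warn(paste0("subgroup '", nm, "' has fewer than 3 records; omitted"))
      return(NULL)
    }
    icc_res <- tryCatch(
      icc_agreement(d$mmse, d$estimated_mmse, type = type,
                    conf_level = conf_level),
      error = function(e) {
        warn(paste0("subgroup '", nm, "': ", conditionMessage(e), "; omitted"))
        NULL
      }
    )
    if (is.null(icc_res)) return(NULL)
    pr_res <- pearson_with_band(d$mmse, d$estimated_mmse)
    tibble(
      subset = nm, n = nrow(d),
      icc = icc_res$icc, icc_low = icc_res$conf_low,
      icc_high = icc_res$conf_high, icc_band = icc_res$band,
      pearson_r = pr_res$r, r2_percent = pr_res$r2_percent,
      r_band = pr_res$band,
      pct_within_1 = agreement_within(d$mmse, d$estimated_mmse, 1),
      pct_within_2 = agreement_within(d$mmse, d$estimated_mmse, 2)
    )
  })
  stats <- dplyr::bind_rows(rows)

  structure(
    list(
      overall = stats[stats$subset == "overall", , drop = FALSE],
      subgroups = stats[stats$subset != "overall", , drop = FALSE],
      data = data,
      provenance = attr(table, "provenance"),
      type = type, conf_level = conf_level
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  o <- x$overall
  cat("Crosswalk validation (", x$provenance, ")\n", sep = "")
  cat(sprintf("  n = %d: ICC = %.2f (95%% CI %.2f-%.2f, %s); r = %.3f (%s, r2 = %.0f%%)\n",
              o$n, o$icc, o$icc_low, o$icc_high, o$icc_band,
              o$pearson_r, o$r_band, o$r2_percent))
  cat(sprintf("  within ±1 point: %.1f%%; within ±2 points: %.1f%%\n",
              o$pct_within_1, o$pct_within_2))
  if (nrow(x$subgroups) > 0) {
    for (i in seq_len(nrow(x$subgroups))) {
      s <- x$subgroups[i, ]
      cat(sprintf("  %-9s n = %3d: ICC = %.2f (%s), ±1 %.1f%%, ±2 %.1f%%\n",
                  s$subset, s$n, s$icc, s$icc_band, s$pct_within_1,
                  s$pct_within_2))
    }
  }
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) {
  dplyr::bind_rows(x$overall, x$subgroups)
}

#' @export
glance.validation_report <- function(x, ...) x$overall

#' Export a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
export_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  obj <- list(
    provenance = report$provenance,
    icc_type = report$type,
    conf_level = report$conf_level,
    overall = as.data.frame(report$overall),
    subgroups = as.data.frame(report$subgroups)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
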