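#' Validate a paired-score cohort
#'
#' A cohort is a tibble with one row per participant and columns
#' `participant_id`, `group`, `population`, `rudas`, `mmse`. Both test scores
#' are integers on 0--30. `group` is one of `"HC"` (healthy control),
#' `"GDS3"`, `"GDS4_5"` (early-stage Alzheimer's disease, Global Deterioration
#' Scale strata); common spelling variants such as `"GDS 3"` or `"GDS 4-5"`
#' are normalized. `population` is `"majority"` or `"minority"`.
#'
#' @param x A data frame with the columns above (case-insensitive names).
#' @param label Optional free-text label stored as an attribute.
#' @return A validated cohort tibble (row order preserved).
#' @examples
#' as_cohort(data.frame(
#'   participant_id = c("p1", "p2"), group = c("HC", "GDS 3"),
#'   population = "majority", rudas = c(28, 22), mmse = c(29, 24)
#' ))
#' @export
as_cohort <- function(x, label = NULL) {
  stopifnot(is.data.frame(x))
  names(x) <- tolower(names(x))
  required <- c("participant_id", "group", "population", "rudas", "mmse")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("cohort is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "equicross_format_error"
    )
  }
  out <- as_tibble(x)[required]
  out$participant_id <- as.character(out$participant_id)
  out$group <- normalize_group(out$group)
  out$population <- normalize_population(out$population)
  out$rudas <- check_score(out$rudas, "rudas")
  out$mmse <- check_score(out$mmse, "mmse")

  dup <- duplicated(out$participant_id)
  if (any(dup)) {
    abort(
      paste0("duplicate participant_id: ",
             paste(unique(out$participant_id[dup]), collapse = ", ")),
      class = "equicross_integrity_error"
    )
  }
  attr(out, "label") <- label
  out
}

normalize_group <- function(g) {
  raw <- as.character(g)
  norm <- toupper(trimws(raw))
  # unify spaces and dash variants (hyphen, en/em dash) into underscores
  norm <- gsub("[–— -]+", "_", norm, perl = TRUE)
  norm <- sub("^GDS_", "GDS", norm)        # "GDS 3" -> "GDS3", "GDS 4-5" -> "GDS4_5"
  bad <- !(norm %in% GROUP_LEVELS) & !is.na(norm)
  if (any(bad)) {
    abort(
      paste0("unrecognized group label(s): ",
             paste(unique(raw[bad]), collapse = ", "),
             " (expected HC, GDS3, GDS4_5)"),
      class = "equicross_format_error"
    )
  }
  factor(norm, levels = GROUP_LEVELS)
}

normalize_population <- function(p) {
  norm <- tolower(trimws(as.character(p)))
  bad <- !(norm %in% POPULATION_LEVELS) & !is.na(norm)
  if (any(bad)) {
    abort(
      paste0("unrecognized population label(s): ",
             paste(unique(norm[bad]), collapse = ", "),
             " (expected majority, minority)"),
      class = "equicross_format_error"
    )
  }
  factor(norm, levels = POPULATION_LEVELS)
}

check_score <- function(v, name) {
  v_num <- suppressWarnings(as.numeric(v))
  bad_type <- is.na(v_num) & !is.na(v)
  bad_int <- !bad_type & !is.na(v_num) & v_num != round(v_num)
  bad_range <- !bad_type & !bad_int & !is.na(v_num) & (v_num < 0 | v_num > MAX_SCORE)
  bad <- bad_type | bad_int | bad_range
  if (any(bad)) {
    abort(
      paste0("column '", name, "': score must be an integer in [0, ",
             MAX_SCORE, "] at row(s) ", paste(which(bad), collapse = ", ")),
      class = "equicross_range_error",
      rows = which(bad)
    )
  }
  as.integer(v_num)
}

#' Read a paired-score cohort from a delimited text file
#'
#' @param path Path to a delimited file with header columns
#'   `participant_id`, `group`, `population`, `rudas`, `mmse`
#'   (case-insensitive, any order).
#' @param delim Field delimiter (default comma).
#' @inheritParams as_cohort
#' @return A validated cohort tibble; row order follows the file.
#' @seealso [write_cohort()], [as_cohort()]
#' @export
read_cohort <- function(path, delim = ",", label = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "equicross_format_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  as_cohort(raw, label = label %||% basename(path))
}

#' Write a cohort to a delimited text file
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  cohort <- as_cohort(cohort)
  readr::write_delim(cohort, path, delim = delim)
  invisible(cohort)
}

#' Descriptive summary of a cohort
#'
#' Per-test mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum, plus per-group and per-population counts and percentages,
#' mirroring the usual "mean +/- SD (min-max) or frequency (%)" reporting of
#' clinical cohort tables. With a single record the SD is undefined and
#' reported as `NA`.
#'
#' @param cohort A cohort tibble (non-empty).
#' @return An object of class `cohort_summary`: a list with tibbles `scores`
#'   (test, n, mean, sd, min, max), `groups` and `populations` (level, n, pct).
#' @examples
#' coh <- simulate_cohort(default_configs()$majority_training, seed = 1)
#' describe(coh)
#' @export
describe <- function(cohort) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) {
    abort("cannot describe an empty cohort", class = "equicross_empty_error")
  }
  n <- nrow(cohort)
  scores <- purrr::map_dfr(c("rudas", "mmse"), function(test) {
    v <- cohort[[test]]
    tibble(
      test = test, n = n, mean = mean(v),
      sd = if (n > 1) sd(v) else NA_real_,
      min = min(v), max = max(v)
    )
  })
  count_pct <- function(f) {
    tab <- table(f)
    counts <- as.integer(tab)
    tibble(level = names(tab), n = counts, pct = 100 * counts / !!n)
  }
  structure(
    list(scores = scores,
         groups = count_pct(cohort$group),
         populations = count_pct(cohort$population),
         n = n, label = attr(cohort, "label")),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary", if (!is.null(x$label)) paste0("(", x$label, ")"),
      "- n =", x$n, "\n")
  fmt <- function(r) sprintf("  %-6s %.1f ± %.1f (%d–%d)\n",
                             r$test, r$mean, r$sd, r$min, r$max)
  for (i in seq_len(nrow(x$scores))) cat(fmt(x$scores[i, ]))
  g <- x$groups
  cat("  groups:", paste0(g$level, " ", g$n, " (", sprintf("%.1f", g$pct), "%)",
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$scores

#' Stratified train/validation split
#'
#' Partitions a cohort into a training and a validation set. The training
#' size within each stratum follows largest-remainder apportionment toward
#' `round(fraction * n_total)`: each stratum first receives
#' `floor(fraction * n_stratum)` training records, and the remaining seats go
#' to the strata with the largest fractional remainders. Assignment within a
#' stratum is simple random sampling, fully determined by `seed`.
#'
#' Stratifying (by clinical group, the default) keeps the healthy-control /
#' Alzheimer's-disease balance of the training and validation arms nearly
#' identical, which a simple random split does not guarantee.
#'
#' @param cohort A cohort tibble.
#' @param fraction Training proportion, strictly between 0 and 1 (default 0.7).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @param strata Name of the column to stratify on (default `"group"`).
#' @return A list with cohort tibbles `training` and `validation` that
#'   partition the input.
#' @examples
#' coh <- simulate_cohort(default_configs()$majority_training, seed = 1)
#' parts <- split_train_validation(coh, fraction = 0.7, seed = 42)
#' nrow(parts$training); nrow(parts$validation)
#' @export
split_train_validation <- function(cohort, fraction = 0.7, seed, strata = "group") {
  cohort <- as_cohort(cohort)
  if (!(is.numeric(fraction) && length(fraction) == 1 &&
        fraction > 0 && fraction < 1)) {
    abort("`fraction` must be a single number strictly between 0 and 1",
          class = "equicross_config_error")
  }
  if (!strata %in% names(cohort)) {
    abort(paste0("stratum column '", strata, "' not found"),
          class = "equicross_config_error")
  }
  lvl <- as.character(cohort[[strata]])
  strata_names <- sort(unique(lvl))
  n_s <- vapply(strata_names, function(s) sum(lvl == s), integer(1))

  small <- n_s < 2
  if (any(small)) {
    warn(paste0("stratum/strata with fewer than 2 records assigned wholly ",
                "to training: ", paste(strata_names[small], collapse = ", ")))
  }
  target_total <- round(fraction * nrow(cohort))
  quota <- fraction * n_s
  take <- floor(quota)
  take[small] <- n_s[small]
  free <- which(!small)
  extra <- target_total - sum(take)
  if (extra > 0 && length(free) > 0) {
    rem <- quota[free] - floor(quota[free])
    # largest remainder first; ties broken by stratum name order (stable)
    ord <- free[order(-rem, strata_names[free])]
    bump <- head(ord[take[ord] < n_s[ord]], extra)
    take[bump] <- take[bump] + 1L
  }

  train_idx <- integer(0)
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (i in seq_along(strata_names)) {
      idx <- which(lvl == strata_names[i])
      train_idx <- c(train_idx, sort(sample(idx, take[i])))
    }
  })
  train_idx <- sort(train_idx)
  training <- cohort[train_idx, , drop = FALSE]
  validation <- cohort[setdiff(seq_len(nrow(cohort)), train_idx), , drop = FALSE]
  attr(training, "label") <- "training"
  attr(validation, "label") <- "validation"
  list(training = training, validation = validation)
}

# Run code with the caller's RNG state untouched afterwards.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
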