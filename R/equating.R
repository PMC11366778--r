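#' Continuity-corrected percentile rank
#'
#' The percentile rank of integer score `x` treats the probability mass at
#' `x` as spread uniformly over the half-open interval `[x - 0.5, x + 0.5)`:
#' \deqn{P(x) = 100\,[F(x - 1) + f(x)/2]} with \eqn{F(-1) = 0}. This is the
#' standard continuization used in discrete equipercentile equating.
#'
#' @param dist A [score_distribution()] or [fit_loglinear()] result.
#' @param x Integer score(s) in `0..max_score`.
#' @return Percentile(s) in `[0, 100]`, nondecreasing in `x`.
#' @examples
#' d <- as_score_distribution(c(0.1, 0.2, 0.3, 0.4), max_score = 3)
#' percentile_rank(d, 2)  # 100 * (0.3 + 0.15) = 45
#' @export
percentile_rank <- function(dist, x) {
  p <- dist_probs(dist)
  K <- dist_max_score(dist)
  if (any(is.na(x)) || any(x != round(x)) || any(x < 0 | x > K)) {
    abort(paste0("score must be an integer in [0, ", K, "]"),
          class = "equicross_range_error")
  }
  Fcum <- cumsum(p)
  F_prev <- c(0, Fcum)[x + 1L]   # F(x - 1), with F(-1) = 0
  100 * (F_prev + p[x + 1L] / 2)
}

#' Inverse percentile (continuized quantile) of a discrete score distribution
#'
#' Inverts the continuity-corrected cumulative distribution: the returned
#' value is the continuous score `t` in `[-0.5, max_score + 0.5]` whose
#' continuized cumulative proportion equals `p / 100`. Writing
#' `p* = p / 100`, let `x_U` be the smallest integer with `F(x_U) > p*`
#' (`max_score` if none); when `p*` falls strictly inside that score's mass
#' the result is `x_U - 0.5 + (p* - F(x_U - 1)) / f(x_U)`. When `p*` lands
#' exactly on a flat stretch of the cumulative (possible only with
#' zero-frequency cells in raw, unsmoothed input), the midpoint of the
#' bracketing half-open score interval is returned. `p = 0` maps to `-0.5`
#' and `p = 100` to `max_score + 0.5`.
#'
#' @param dist A [score_distribution()] or [fit_loglinear()] result.
#' @param p Percentile(s) in `[0, 100]`.
#' @return Continuous score(s) in `[-0.5, max_score + 0.5]`.
#' @examples
#' d <- as_score_distribution(c(0.5, 0.25, 0.25), max_score = 2)
#' inverse_percentile(d, 50)  # 0.5
#' @export
inverse_percentile <- function(dist, p) {
  probs <- dist_probs(dist)
  K <- dist_max_score(dist)
  if (any(is.na(p)) || any(p < 0 | p > 100)) {
    abort("percentile must be in [0, 100]", class = "equicross_range_error")
  }
  Fcum <- cumsum(probs)
  vapply(p, function(pi) inverse_percentile_one(pi, probs, Fcum, K), numeric(1))
}

inverse_percentile_one <- function(p, probs, Fcum, K) {
  if (p <= 0) return(-0.5)
  if (p >= 100) return(K + 0.5)
  pstar <- p / 100
  above <- which(Fcum > pstar)
  if (length(above) == 0) return(K + 0.5)
  x_U <- above[1] - 1L                       # scores are 0-based
  F_prev <- if (x_U == 0) 0 else Fcum[x_U]   # F(x_U - 1)
  if (pstar > F_prev) {
    # strictly inside the mass of x_U (f(x_U) > 0 is then guaranteed)
    return(x_U - 0.5 + (pstar - F_prev) / probs[x_U + 1L])
  }
  # p* sits exactly on the cumulative at x_U - 1: the continuized CDF is flat
  # over [x_low + 0.5, x_U - 0.5]; return the midpoint of that interval.
  x_low <- which(Fcum >= pstar)[1] - 1L
  (x_low + x_U) / 2
}

#' Equipercentile equating of two score distributions
#'
#' Links two tests taken by the same examinees (single-group design) by
#' matching continuity-corrected percentile ranks: the equated value of
#' score `x` on test X is \deqn{e_Y(x) = Q_Y(P_X(x)),} the score on test Y's
#' scale whose percentile rank equals that of `x` on test X. `e_Y` is
#' nondecreasing and lies in `[-0.5, max_score + 0.5]`. With presmoothed
#' inputs ([fit_loglinear()]), all probabilities are strictly positive and
#' the equated function is defined and strictly increasing over the full
#' support, including scores outside the observed range.
#'
#' @param dist_x Distribution of the source test (e.g. RUDAS).
#' @param dist_y Distribution of the target test (e.g. MMSE).
#' @param rounding Rounding rule for the integer crosswalk; only
#'   `"half_up"` (round half away from zero, then clip to the score range)
#'   is currently implemented. Recorded in the result's metadata so tables
#'   are auditable.
#' @param x_name,y_name Column names for the two tests in the concordance
#'   table (defaults `"rudas"`, `"mmse"`).
#' @return An object of class `equating_result`: the `concordance` tibble
#'   (source score, continuous `equated` value, rounded integer `converted`),
#'   the derived [crosswalk] and metadata (n, smoothing degrees, rounding).
#' @examples
#' x <- score_distribution(pmin(30, rpois(300, 22)))
#' y <- score_distribution(pmin(30, rpois(300, 24)))
#' eq <- equate_equipercentile(fit_loglinear(x, 3), fit_loglinear(y, 3))
#' tidy(eq)
#' @export
equate_equipercentile <- function(dist_x, dist_y, rounding = "half_up",
                                  x_name = "rudas", y_name = "mmse") {
  K <- dist_max_score(dist_x)
  if (dist_max_score(dist_y) != K) {
    abort("both distributions must share the same support",
          class = "equicross_config_error")
  }
  if (sum(dist_probs(dist_y) > 0) < 2) {
    abort("degenerate target distribution: single support point",
          class = "equicross_degeneracy_error")
  }
  scores <- 0:K
  e <- inverse_percentile(dist_y, percentile_rank(dist_x, scores))
  concordance <- tibble(
    !!x_name := scores,
    equated = e,
    converted = round_clip(e, rounding, K)
  )
  meta <- list(
    n_x = if (!is.null(dist_x$n)) dist_x$n else NA,
    n_y = if (!is.null(dist_y$n)) dist_y$n else NA,
    degree_x = if (inherits(dist_x, "loglinear_fit")) dist_x$degree else NA_integer_,
    degree_y = if (inherits(dist_y, "loglinear_fit")) dist_y$degree else NA_integer_,
    smoothed = inherits(dist_x, "loglinear_fit") && inherits(dist_y, "loglinear_fit"),
    rounding = rounding,
    x_name = x_name, y_name = y_name, max_score = K
  )
  res <- structure(
    list(concordance = concordance, metadata = meta),
    class = "equating_result"
  )
  res$crosswalk <- build_crosswalk(res)
  res
}

round_clip <- function(e, rounding = "half_up", K = MAX_SCORE) {
  rounding <- match.arg(rounding, "half_up")
  pmin(pmax(floor(e + 0.5), 0L), K)
}

#' @export
print.equating_result <- function(x, ...) {
  m <- x$metadata
  cat("Equipercentile equating ", m$x_name, " -> ", m$y_name,
      if (isTRUE(m$smoothed)) paste0(" (log-linear presmoothing, degrees ",
                                     m$degree_x, "/", m$degree_y, ")")
      else " (unsmoothed)", "\n", sep = "")
  cat("  rounding: ", m$rounding, "; n = ", format(m$n_x), "\n", sep = "")
  print(x$concordance, n = 5)
  invisible(x)
}

#' @export
tidy.equating_result <- function(x, ...) x$concordance

#' @export
glance.equating_result <- function(x, ...) {
  m <- x$metadata
  tibble(n = m$n_x, smoothed = isTRUE(m$smoothed),
         degree_x = m$degree_x, degree_y = m$degree_y,
         rounding = m$rounding,
         monotone = !is.unsorted(x$concordance$equated))
}

#' Construct or extract an integer crosswalk table
#'
#' `build_crosswalk()` rounds the continuous equated function of an
#' [equate_equipercentile()] result into a total, monotone integer map
#' `0..30 -> 0..30` (`clip(round_half_up(e(x)), 0, 30)`); many-to-one entries
#' are expected where the equated function is flat. `crosswalk()` builds a
#' table directly from two integer vectors.
#'
#' @param result An `equating_result`.
#' @param rounding Rounding rule (see [equate_equipercentile()]).
#' @return A `crosswalk`: a tibble with integer columns named after the two
#'   tests (default `rudas`, `mmse`) and a `provenance` attribute.
#' @export
build_crosswalk <- function(result, rounding = NULL) {
  stopifnot(inherits(result, "equating_result"))
  m <- result$metadata
  rounding <- rounding %||% m$rounding
  converted <- round_clip(result$concordance$equated, rounding, m$max_score)
  prov <- paste0("equipercentile ", m$x_name, "->", m$y_name,
                 if (isTRUE(m$smoothed)) paste0(", presmoothed C=", m$degree_x,
                                                "/", m$degree_y),
                 ", n=", format(m$n_x), ", rounding=", rounding)
  crosswalk(result$concordance[[m$x_name]], converted,
            provenance = prov, x_name = m$x_name, y_name = m$y_name,
            max_score = m$max_score)
}

#' @rdname build_crosswalk
#' @param from,to Integer score vectors: `from` must be exactly
#'   `0..max_score` and `to` a nondecreasing vector of scores in
#'   `0..max_score`.
#' @param provenance Free-text provenance recorded with the table.
#' @param x_name,y_name Column names (defaults `"rudas"`, `"mmse"`).
#' @param max_score Maximum score of the support (default 30).
#' @export
crosswalk <- function(from, to, provenance = "unspecified",
                      x_name = "rudas", y_name = "mmse",
                      max_score = MAX_SCORE) {
  K <- as.integer(max_score)
  if (!identical(as.integer(from), 0:K)) {
    abort(paste0("crosswalk must cover every score 0..", K, " exactly once"),
          class = "equicross_integrity_error")
  }
  to <- as.integer(to)
  if (any(is.na(to)) || any(to < 0 | to > K)) {
    abort(paste0("crosswalk values must be integers in [0, ", K, "]"),
          class = "equicross_integrity_error")
  }
  if (is.unsorted(to)) {
    abort("crosswalk must be monotone nondecreasing",
          class = "equicross_integrity_error")
  }
  out <- tibble(!!x_name := 0:K, !!y_name := to)
  class(out) <- c("crosswalk", class(out))
  attr(out, "provenance") <- provenance
  attr(out, "max_score") <- K
  out
}

#' @export
print.crosswalk <- function(x, ...) {
  cat("Crosswalk (", attr(x, "provenance"), ")\n", sep = "")
  NextMethod()
}

#' Apply a crosswalk to scores
#'
#' Vectorized lookup: each source-test score is converted to its estimated
#' target-test score.
#'
#' @param table A [crosswalk].
#' @param scores Integer scores in `0..30`.
#' @return Integer vector of converted scores, same length as `scores`.
#' @examples
#' apply_crosswalk(published_crosswalk(), c(14, 23, 24))
#' @export
apply_crosswalk <- function(table, scores) {
  stopifnot(inherits(table, "crosswalk"))
  K <- attr(table, "max_score") %||% (nrow(table) - 1L)
  bad <- is.na(scores) | scores != round(scores) | scores < 0 | scores > K
  if (any(bad)) {
    abort(paste0("scores out of range [0, ", K, "] at index ",
                 paste(which(bad), collapse = ", ")),
          class = "equicross_range_error", index = which(bad))
  }
  table[[2]][as.integer(scores) + 1L]
}

#' Write / read a crosswalk as two-column CSV
#'
#' @param table A [crosswalk].
#' @param path File path.
#' @return `write_crosswalk()` returns the table invisibly;
#'   `read_crosswalk()` returns a `crosswalk`.
#' @export
write_crosswalk <- function(table, path) {
  stopifnot(inherits(table, "crosswalk"))
  df <- as.data.frame(table)
  readr::write_csv(df, path)
  invisible(table)
}

#' @rdname write_crosswalk
#' @param provenance Provenance to attach to the table read from disk; by
#'   default the file path.
#' @export
read_crosswalk <- function(path, provenance = path) {
  df <- readr::read_csv(path, col_types = "ii", progress = FALSE,
                        show_col_types = FALSE)
  if (ncol(df) != 2) {
    abort("crosswalk file must have exactly two columns",
          class = "equicross_format_error")
  }
  crosswalk(df[[1]], df[[2]], provenance = provenance,
            x_name = names(df)[1], y_name = names(df)[2],
            max_score = nrow(df) - 1L)
}

#' Export a crosswalk as JSON
#'
#' @param table A [crosswalk].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
export_crosswalk_json <- function(table, path = NULL) {
  stopifnot(inherits(table, "crosswalk"))
  obj <- list(provenance = attr(table, "provenance"),
              map = as.data.frame(table))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Invert a crosswalk (derived reverse lookup)
#'
#' Builds a reverse map by assigning to each target score the midpoint-rounded
#' source score among those mapping to it, with gaps filled monotonically.
#' This is a derived convenience, not a published table: equipercentile
#' conversions are direction-specific and the published resource covers only
#' the forward direction.
#'
#' @param table A [crosswalk].
#' @return A `crosswalk` in the reverse direction, provenance-tagged as
#'   derived.
#' @export
invert_crosswalk <- function(table) {
  stopifnot(inherits(table, "crosswalk"))
  from <- table[[1]]
  to <- table[[2]]
  K <- attr(table, "max_score") %||% (nrow(table) - 1L)
  rev_map <- integer(K + 1)
  for (y in 0:K) {
    hits <- from[to == y]
    rev_map[y + 1] <- if (length(hits) > 0) round(mean(hits)) else NA_integer_
  }
  # fill unhit target scores by carrying the nearest mapped value below/above
  for (y in seq_along(rev_map)) {
    if (is.na(rev_map[y])) {
      below <- rev_map[seq_len(y - 1)]
      rev_map[y] <- if (any(!is.na(below))) max(below, na.rm = TRUE) else 0L
    }
  }
  rev_map <- cummax(rev_map)
  crosswalk(0:K, rev_map,
            provenance = paste0("derived inverse of: ", attr(table, "provenance")),
            x_name = names(table)[2], y_name = names(table)[1],
            max_score = K)
}
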