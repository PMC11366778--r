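#' Discrete score frequency distribution
#'
#' Tabulates integer scores over the full support `0..max_score`, including
#' cells with zero observed frequency. Keeping the full support matters for
#' equating: the conversion must be defined at every possible score, not only
#' the observed ones.
#'
#' @param scores Integer scores in `0..max_score`.
#' @param max_score Maximum attainable score (default 30).
#' @return An object of class `score_distribution`: a list with the support
#'   tibble `table` (`score`, `freq`, `prop`, `cum_prop`), the total count `n`
#'   and `max_score`.
#' @examples
#' d <- score_distribution(c(28, 29, 30, 30, 27))
#' tidy(d)
#' @export
score_distribution <- function(scores, max_score = 30) {
  if (length(scores) == 0) {
    abort("cannot build a distribution from zero scores",
          class = "equicross_empty_error")
  }
  if (any(is.na(scores)) || any(scores != round(scores)) ||
      any(scores < 0 | scores > max_score)) {
    abort(paste0("scores must be integers in [0, ", max_score, "]"),
          class = "equicross_range_error")
  }
  freq <- tabulate(scores + 1L, nbins = max_score + 1L)
  new_score_distribution(freq, max_score)
}

#' Build a score distribution from a frequency (or probability) vector
#'
#' @param freq Nonnegative vector of length `max_score + 1` giving the
#'   frequency (or probability mass) of each score `0..max_score`.
#' @param max_score Maximum attainable score.
#' @return A `score_distribution`.
#' @export
as_score_distribution <- function(freq, max_score = length(freq) - 1L) {
  if (length(freq) != max_score + 1L || any(freq < 0) || sum(freq) <= 0) {
    abort("`freq` must be a nonnegative vector of length max_score + 1 with positive sum",
          class = "equicross_config_error")
  }
  new_score_distribution(as.numeric(freq), max_score)
}

new_score_distribution <- function(freq, max_score) {
  n <- sum(freq)
  prop <- freq / n
  structure(
    list(
      table = tibble(score = 0:max_score, freq = freq, prop = prop,
                     cum_prop = cumsum(prop)),
      n = n,
      max_score = as.integer(max_score)
    ),
    class = "score_distribution"
  )
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("Score distribution on 0..", x$max_score, " (n = ", format(x$n), ")\n",
      sep = "")
  obs <- x$table$score[x$table$freq > 0]
  cat("  observed range: ", min(obs), "-", max(obs), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.score_distribution <- function(x, ...) x$table

# Accessors shared by raw and smoothed distributions.
dist_probs <- function(dist) {
  if (inherits(dist, "score_distribution")) return(dist$table$prop)
  if (inherits(dist, "loglinear_fit")) return(dist$table$fitted_prob)
  abort("expected a score_distribution or loglinear_fit",
        class = "equicross_config_error")
}

dist_max_score <- function(dist) dist$max_score

#' Log-linear presmoothing of a discrete score distribution
#'
#' Fits the polynomial log-probability model
#' \deqn{\log p(x) = \beta_0 + \sum_{k=1}^{C} \beta_k (x / K)^k, \quad x = 0, \dots, K}
#' to the score frequencies by maximum likelihood. The powers of the scaled
#' score \eqn{x/K} span the same polynomial space as raw powers but keep the
#' design well conditioned at \eqn{K = 30} and degree 6. The fit has two
#' properties that equating relies on: the fitted distribution preserves the
#' first `degree` raw sample moments, and every fitted probability is strictly
#' positive -- so percentile matching is defined over the whole 0--30 support,
#' including scores never observed (which is what licenses extrapolating the
#' conversion below the observed minimum).
#'
#' The maximum-likelihood fit is computed through the Poisson log-linear
#' surrogate ([stats::glm()] with a log link), whose likelihood equations for
#' this design coincide with the multinomial ones.
#'
#' @param dist A [score_distribution()].
#' @param degree Polynomial degree `C` (1--10). The distribution must have at
#'   least `degree + 1` distinct observed scores.
#' @return An object of class `loglinear_fit`: the support tibble `table`
#'   (`score`, `freq`, `prop`, `fitted_prob`), `degree`, `coefficients`,
#'   multinomial `loglik` and `aic`, and `moment_residuals` (relative error of
#'   the first `degree` fitted raw moments against the sample moments).
#' @examples
#' d <- score_distribution(pmin(30, rpois(200, 24)))
#' fit <- fit_loglinear(d, degree = 3)
#' glance(fit)
#' @export
fit_loglinear <- function(dist, degree) {
  stopifnot(inherits(dist, "score_distribution"))
  if (!(length(degree) == 1 && degree == round(degree) &&
        degree >= 1 && degree <= 10)) {
    abort("`degree` must be a single integer in 1..10",
          class = "equicross_config_error")
  }
  degree <- as.integer(degree)
  freq <- dist$table$freq
  K <- dist$max_score
  n_distinct <- sum(freq > 0)
  if (n_distinct == 1) {
    abort("degenerate distribution: all mass on a single score",
          class = "equicross_degeneracy_error")
  }
  if (n_distinct < degree + 1) {
    abort(paste0("need at least degree + 1 = ", degree + 1,
                 " distinct observed scores (got ", n_distinct, ")"),
          class = "equicross_config_error")
  }

  x <- 0:K
  X <- outer(x / K, seq_len(degree), `^`)
  colnames(X) <- paste0("b", seq_len(degree))
  fit <- suppressWarnings(
    glm(freq ~ X, family = poisson(),
        control = list(epsilon = 1e-12, maxit = 200))
  )
  p_hat <- as.numeric(fitted(fit)) / sum(fitted(fit))

  sample_moments <- vapply(seq_len(degree),
                           function(k) sum(x^k * freq) / sum(freq), numeric(1))
  fitted_moments <- vapply(seq_len(degree),
                           function(k) sum(x^k * p_hat), numeric(1))
  moment_residuals <- abs(fitted_moments - sample_moments) /
    pmax(1, abs(sample_moments))

  if (!fit$converged || any(!is.finite(p_hat)) ||
      any(moment_residuals > 1e-6)) {
    abort(
      "log-linear fit did not converge to a moment-preserving solution",
      class = "equicross_convergence_error",
      degree = degree, moment_residuals = moment_residuals,
      glm_converged = fit$converged
    )
  }

  prop <- freq / sum(freq)
  ll <- sum(freq[freq > 0] * log(p_hat[freq > 0]))  # multinomial log-likelihood
  structure(
    list(
      table = tibble(score = x, freq = freq, prop = prop, fitted_prob = p_hat),
      degree = degree,
      coefficients = setNames(coef(fit), c("b0", colnames(X))),
      loglik = ll,
      aic = -2 * ll + 2 * degree,
      deviance = 2 * sum(ifelse(freq > 0, freq * log(prop / p_hat), 0)),
      moment_residuals = moment_residuals,
      n = dist$n,
      max_score = K,
      converged = TRUE
    ),
    class = "loglinear_fit"
  )
}

#' Select the presmoothing degree by AIC
#'
#' Fits [fit_loglinear()] at each candidate degree and returns the converged
#' fit with the smallest AIC (multinomial log-likelihood penalized by
#' 2 x degree); ties go to the smaller degree. AIC selection balances the
#' moment-matching flexibility of higher degrees against overfitting the
#' 31-cell frequency vector.
#'
#' @param dist A [score_distribution()].
#' @param candidates Candidate degrees (default `2:6`).
#' @return The selected `loglinear_fit`.
#' @export
select_degree <- function(dist, candidates = 2:6) {
  if (length(candidates) == 0) {
    abort("`candidates` must be non-empty", class = "equicross_config_error")
  }
  candidates <- sort(unique(as.integer(candidates)))
  fits <- purrr::map(candidates, function(C) {
    tryCatch(fit_loglinear(dist, C), error = function(e) NULL)
  })
  ok <- !purrr::map_lgl(fits, is.null)
  if (!any(ok)) {
    abort("no candidate degree converged", class = "equicross_convergence_error",
          candidates = candidates)
  }
  fits <- fits[ok]
  aics <- purrr::map_dbl(fits, "aic")
  # which.min returns the first minimum; candidates are sorted ascending,
  # so ties already resolve toward the smaller degree
  fits[[which.min(aics)]]
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat("Log-linear presmoothing fit (degree ", x$degree, ") on 0..",
      x$max_score, "\n", sep = "")
  cat("  n = ", format(x$n), ", logLik = ", format(x$loglik, digits = 6),
      ", AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  cat("  max relative moment residual: ",
      format(max(x$moment_residuals), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.loglinear_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = as.numeric(x$coefficients))
}

#' @export
glance.loglinear_fit <- function(x, ...) {
  tibble(degree = x$degree, logLik = x$loglik, AIC = x$aic,
         deviance = x$deviance,
         max_moment_residual = max(x$moment_residuals),
         min_fitted_prob = min(x$table$fitted_prob), n = x$n)
}

#' Export a presmoothing fit summary as JSON
#'
#' @param fit A `loglinear_fit`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
export_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "loglinear_fit"))
  obj <- list(
    degree = fit$degree,
    coefficients = as.list(fit$coefficients),
    loglik = fit$loglik,
    aic = fit$aic,
    moment_residuals = fit$moment_residuals,
    n = fit$n,
    max_score = fit$max_score
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
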