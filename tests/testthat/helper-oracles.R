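# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the continuized CDF is evaluated directly and
# inverted by bisection, the log-linear likelihood is maximized by coordinate
# descent on the raw parameter vector, and the ICC mean squares come from a
# stats::lm ANOVA decomposition.

# Continuized CDF of a discrete distribution on 0..K: piecewise linear with
# F*(x + 0.5) = F(x), evaluated at arbitrary continuous t.
oracle_cdf <- function(probs, t) {
  K <- length(probs) - 1
  Fcum <- cumsum(probs)
  knots_t <- seq(-0.5, K + 0.5, by = 1)
  knots_F <- c(0, Fcum)
  stats::approx(knots_t, knots_F, xout = t, rule = 2)$y
}

# Inverse of the continuized CDF by bisection (requires strictly positive
# probs so the CDF is strictly increasing).
oracle_quantile <- function(probs, p, tol = 1e-14) {
  K <- length(probs) - 1
  lo <- -0.5
  hi <- K + 0.5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (oracle_cdf(probs, mid) < p) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Equipercentile equating by direct CDF matching.
oracle_equate <- function(probs_x, probs_y) {
  K <- length(probs_x) - 1
  vapply(0:K, function(x) oracle_quantile(probs_y, oracle_cdf(probs_x, x)),
         numeric(1))
}

# Multinomial log-likelihood of the log-linear model at beta over a given
# polynomial basis (the intercept is the normalizing constant).
oracle_loglinear_loglik <- function(beta, freq, basis) {
  eta <- as.numeric(basis %*% beta)
  logp <- eta - log(sum(exp(eta - max(eta)))) - max(eta)
  sum(freq * logp)
}

# Brute-force maximizer: coarse per-coordinate grid refined by coordinate
# descent with shrinking step sizes. Runs on an orthogonal polynomial basis
# of the same degree (identical model space, far better conditioned for
# one-coordinate-at-a-time search); the maximizing distribution is the same.
oracle_loglinear_fit <- function(freq, degree, sweeps = 2000) {
  K <- length(freq) - 1
  basis <- unclass(stats::poly(0:K, degree = degree))
  beta <- rep(0, degree)
  step <- rep(32, degree)
  best <- oracle_loglinear_loglik(beta, freq, basis)
  for (s in seq_len(sweeps)) {
    improved <- FALSE
    for (k in seq_len(degree)) {
      for (cand in c(beta[k] - step[k], beta[k] + step[k])) {
        b2 <- beta
        b2[k] <- cand
        ll <- oracle_loglinear_loglik(b2, freq, basis)
        if (ll > best + 1e-15) {
          beta <- b2
          best <- ll
          improved <- TRUE
        }
      }
    }
    if (!improved) {
      step <- step / 2
      if (all(step < 1e-12)) break
    }
  }
  eta <- as.numeric(basis %*% beta)
  p <- exp(eta - max(eta))
  list(beta = beta, p = p / sum(p), loglik = best)
}

# Two-way ANOVA mean squares via lm(), an independent route to the ICC
# ingredients.
oracle_anova_ms <- function(observed, estimated) {
  n <- length(observed)
  df <- data.frame(
    y = c(observed, estimated),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("obs", "est"), each = n))
  )
  tab <- stats::anova(stats::lm(y ~ subject + rater, data = df))
  list(ms_rows = tab["subject", "Mean Sq"],
       ms_cols = tab["rater", "Mean Sq"],
       ms_error = tab["Residuals", "Mean Sq"])
}

# Random strictly positive probability vector on 0..K (Dirichlet-ish).
random_probs <- function(K, concentrated = FALSE) {
  w <- stats::rgamma(K + 1, shape = if (concentrated) 0.5 else 2)
  w <- pmax(w, 1e-6)
  w / sum(w)
}

# Small cohort builder for hand-checked tests.
make_cohort <- function(rudas, mmse, group = "HC", population = "majority") {
  as_cohort(data.frame(
    participant_id = paste0("p", seq_along(rudas)),
    group = rep_len(group, length(rudas)),
    population = rep_len(population, length(rudas)),
    rudas = rudas, mmse = mmse
  ))
}
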