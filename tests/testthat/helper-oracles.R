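# Independent oracles used to cross-check the closed-form implementations.
# They deliberately share no code with the package internals.

# generic numerical minimizer of the penalized least-squares cost
# J(theta) = ||y - X theta||^2 + lambda ||theta||^2: quasi-Newton search
# followed by Newton polishing steps whose Hessian comes from finite
# differences of the gradient (no use of the closed-form solution)
oracle_ridge_minimize <- function(X, y, lambda) {
  fn <- function(b) sum((y - X %*% b)^2) + lambda * sum(b^2)
  gr <- function(b) drop(-2 * t(X) %*% (y - X %*% b) + 2 * lambda * b)
  p <- ncol(X)
  fit <- stats::optim(rep(0, p), fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  par <- fit$par
  h <- 1e-4
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- rep(0, p)
    e[j] <- h
    H[, j] <- (gr(par + e) - gr(par - e)) / (2 * h)
  }
  for (it in 1:5) {
    step <- solve(H, gr(par))
    if (!all(is.finite(step))) break
    par <- par - step
    if (max(abs(step)) < 1e-14) break
  }
  par
}

# explicit-inverse OLS coefficient covariance (the brute-force analytic
# route, as opposed to the package's QR path)
oracle_ols_se <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  unname(sqrt(diag(s2 * xtx_inv)))
}

# count-based mid-ranks: rank of v = (#smaller) + (#equal + 1)/2
oracle_midranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Kruskal-Wallis H from first principles via the rank-sum form
oracle_kruskal_h <- function(x, g) {
  r <- oracle_midranks(x)
  n_total <- length(x)
  rank_sums <- tapply(r, g, sum)
  sizes <- tapply(r, g, length)
  h_raw <- 12 / (n_total * (n_total + 1)) * sum(rank_sums^2 / sizes) -
    3 * (n_total + 1)
  ties <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    ties <- ties + t^3 - t
  }
  h_raw / (1 - ties / (n_total^3 - n_total))
}

# Dunn z for one pair of groups, from the same first-principles ranks
oracle_dunn_z <- function(x, g, g1, g2) {
  r <- oracle_midranks(x)
  n_total <- length(x)
  ties <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    ties <- ties + t^3 - t
  }
  var_term <- n_total * (n_total + 1) / 12 - ties / (12 * (n_total - 1))
  m1 <- mean(r[g == g1])
  m2 <- mean(r[g == g2])
  (m1 - m2) / sqrt(var_term * (1 / sum(g == g1) + 1 / sum(g == g2)))
}

# single-parameter cohort spec with no condition effects, for tests that
# care only about the noise model
single_param_spec <- function(parameter, n_records = NULL, seed = 1,
                              target_r2 = NULL, noise_sd = NULL, ...) {
  defs <- fetal_curve_defaults()
  defs <- defs[defs$parameter == parameter, ]
  if (!is.null(n_records)) defs$n_records <- as.integer(n_records)
  if (!is.null(target_r2)) defs$target_r2 <- target_r2
  if (!is.null(noise_sd)) {
    defs$target_r2 <- NA_real_
    defs$noise_sd <- noise_sd
  }
  cohort_spec(parameters = defs, gdm_prevalence = 0, pe_prevalence = 0,
              gdm_effect = 0, pe_effect = 0, seed = seed, ...)
}

# evaluate an ascending coefficient vector (independent of the package's
# Horner routine)
oracle_poly <- function(coefs, x) {
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1)
  out
}

table2_totals <- c(AC = 4594L, CRL = 985L, EFW = 5639L,
                   HC = 4495L, BPD = 4573L, FL = 4531L)
table2_train <- c(AC = 3215L, CRL = 689L, EFW = 3947L,
                  HC = 3146L, BPD = 3201L, FL = 3171L)
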