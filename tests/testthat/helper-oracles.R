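# Independent oracles used across the suite. These deliberately avoid the
# package's grouped profile-likelihood shortcut: the likelihood oracle forms
# the dense n x n marginal covariance and evaluates the Gaussian log-density
# directly, so agreement with the fitter is a genuine cross-check.

dense_loglik <- function(X, y, farm, beta, theta_U, theta_eps) {
  n <- length(y)
  Z <- stats::model.matrix(~ 0 + factor(farm))
  V <- theta_eps * diag(n) + theta_U * tcrossprod(Z)
  r <- y - drop(X %*% beta)
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       crossprod(r, solve(V, r)) + n * log(2 * pi)))
}

# a small random mixed-model instance with known structure
random_lmm_instance <- function(seed, n_max = 60) {
  set.seed(seed)
  J <- sample(3:8, 1)
  nj <- sample(2:7, J, replace = TRUE)
  while (sum(nj) > n_max) nj <- pmax(2, nj - 1)
  farm <- rep(sprintf("f%02d", seq_len(J)), nj)
  n <- length(farm)
  x1 <- rnorm(n)
  x2 <- factor(sample(c("a", "b", "c"), n, replace = TRUE),
               levels = c("a", "b", "c"))
  u <- rnorm(J, 0, sqrt(runif(1, 0, 2)))
  y <- 1 + 0.8 * x1 + 0.5 * (x2 == "b") - 0.7 * (x2 == "c") +
    u[as.integer(factor(farm))] + rnorm(n, 0, sqrt(runif(1, 0.3, 2)))
  data.frame(farm_id = farm, x1 = x1, x2 = x2, y = y,
             stringsAsFactors = FALSE)
}

# verify that every committed deletion of a stepwise path was AIC-minimal
# at its step, by slow independent refits of all one-term deletions
check_greedy_path <- function(data, outcome, terms, group = "farm_id") {
  st <- backward_aic(data, outcome, terms, group)
  refit_aic <- function(keep) {
    f <- if (length(keep)) stats::reformulate(keep, response = outcome)
    else stats::as.formula(paste(outcome, "~ 1"))
    lmm_ml(f, data, group = group, drop_aliased = TRUE)$aic
  }
  # the usable candidate set the stepwise loop actually started from
  current <- intersect(st$candidates, union(st$final_terms, st$path$dropped))
  ok <- TRUE
  for (i in seq_len(nrow(st$path))) {
    aics <- vapply(current,
                   function(t) refit_aic(setdiff(current, t)), numeric(1))
    committed <- st$path$dropped[i]
    best <- min(aics)
    if (!isTRUE(all.equal(aics[[committed]], best, tolerance = 1e-6)) ||
        st$path$aic_after[i] > st$path$aic_before[i]) ok <- FALSE
    current <- setdiff(current, committed)
  }
  # stopping rule: no remaining deletion may lower the AIC further
  if (length(current)) {
    aics <- vapply(current,
                   function(t) refit_aic(setdiff(current, t)), numeric(1))
    if (any(aics < st$fit$aic - 1e-9)) ok <- FALSE
  }
  list(ok = ok, step = st)
}

# sample quantile oracle: sort-and-linear-interpolate at prob p (type 7)
interp_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
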