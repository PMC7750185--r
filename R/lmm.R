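# Maximum-likelihood random-intercept linear mixed model
#
#   y_ij = x_ij' beta + U_j + eps_ij,  U_j ~ N(0, theta_U), eps ~ N(0, theta_eps)
#
# fitted by profiling: write lambda = theta_U / theta_eps. Conditional on
# lambda the marginal covariance is theta_eps * (I + lambda * Z Z'), block
# diagonal by farm, so beta and theta_eps have closed forms and the
# log-likelihood reduces to a smooth one-dimensional function of lambda that
# is maximised numerically on the log scale. The per-block Woodbury identity
#   (I + lambda J)^{-1} = I - lambda/(1 + lambda n_j) J
# lets every likelihood evaluation use only per-farm column sums, which is
# what makes thousands of bootstrap refits cheap.

.lmm_profile_fit <- function(X, y, g, lambda = NULL, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  gi <- as.integer(g)
  J <- nlevels(g)
  nj <- tabulate(gi, nbins = J)
  if (any(nj == 0)) stop("internal: empty farm level reached the fitter")
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y * y)
  S <- rowsum(X, gi)                      # J x p per-farm column sums
  t_ <- drop(rowsum(y, gi))

  profile <- function(lam) {
    c_j <- lam / (1 + lam * nj)
    M <- XtX - crossprod(S, S * c_j)
    v <- Xty - drop(crossprod(S, t_ * c_j))
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), v))
    yWy <- yty - sum(c_j * t_^2)
    rss <- max(yWy - sum(beta * v), .Machine$double.xmin)
    sig2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sig2) + sum(log1p(lam * nj)) + n)
    list(ll = ll, beta = drop(beta), sig2 = sig2, ch = ch, c_j = c_j)
  }

  if (is.null(lambda)) {
    f <- function(u) profile(exp(u))$ll
    grid <- seq(-18, 12, length.out = 25)
    vals <- vapply(grid, f, numeric(1))
    if (all(!is.finite(vals))) {
      return(list(converged = FALSE, loglik = -Inf))
    }
    k <- which.max(vals)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-7)
    lam_hat <- exp(opt$maximum)
    best <- profile(lam_hat)
    # the variance of the farm intercept may sit on its boundary at zero
    at0 <- profile(0)
    boundary <- FALSE
    if (is.finite(at0$ll) && at0$ll >= best$ll - tol) {
      lam_hat <- 0
      best <- at0
      boundary <- TRUE
    }
  } else {
    lam_hat <- lambda
    best <- profile(lambda)
    boundary <- lambda == 0
  }
  if (!is.finite(best$ll)) return(list(converged = FALSE, loglik = -Inf))

  beta <- stats::setNames(best$beta, colnames(X))
  sig2 <- best$sig2
  # conditional modes (BLUPs) of the farm intercepts
  resid_sums <- t_ - drop(S %*% best$beta)
  u <- (lam_hat / (1 + lam_hat * nj)) * resid_sums
  vcov_beta <- sig2 * chol2inv(best$ch)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  fitted_fixed <- drop(X %*% best$beta)
  list(beta = beta, vcov = vcov_beta,
       theta_U = lam_hat * sig2, theta_eps = sig2, lambda = lam_hat,
       loglik = best$ll, n = n, p = p, k_params = p + 2L,
       aic = -2 * best$ll + 2 * (p + 2),
       u = stats::setNames(u, levels(g)),
       fitted_fixed = fitted_fixed,
       fitted = fitted_fixed + u[gi],
       converged = TRUE, boundary = boundary)
}

# Build the (full-dummy) design for a set of candidate terms. Terms without
# variation in `data` (single observed factor level, constant continuous
# variable) cannot enter any model and are reported in `unusable`.
.make_design <- function(data, outcome, terms, group) {
  data <- droplevels(data)
  if (!outcome %in% names(data)) stop("outcome `", outcome, "` not found")
  if (!group %in% names(data)) stop("grouping variable `", group, "` not found")
  y <- data[[outcome]]
  if (any(is.na(y))) stop("outcome contains missing values; filter first")
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("at least 2 distinct farms are required")
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  usable_var <- function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("model term `", v, "` not found in data")
    if (any(is.na(x))) stop("model term `", v, "` contains missing values")
    if (is.factor(x) || is.character(x)) nlevels(factor(x)) >= 2 else
      stats::var(as.numeric(x)) > 0
  }
  var_ok <- vapply(base_vars, usable_var, logical(1))
  keep <- vapply(strsplit(terms, ":", fixed = TRUE),
                 function(vs) all(var_ok[vs]), logical(1))
  usable <- terms[keep]
  if (length(usable)) {
    f <- stats::reformulate(usable)
    X <- stats::model.matrix(f, data)
    term_labels <- attr(stats::terms(f), "term.labels")
    assign <- attr(X, "assign")
  } else {
    X <- matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))
    term_labels <- character()
    assign <- 0L
  }
  xlevels <- lapply(data[intersect(base_vars[var_ok[base_vars]], names(data))],
                    function(x) if (is.factor(x)) levels(x) else NULL)
  xlevels <- xlevels[!vapply(xlevels, is.null, logical(1))]
  list(X = X, assign = assign, terms = term_labels, y = y, g = g,
       unusable = terms[!keep], xlevels = xlevels, n = nrow(data))
}

# Fit the model containing `terms_keep` (plus intercept and farm intercept).
# Columns made collinear by the structural design are dropped by pivoted QR
# when `drop_aliased`, and reported; otherwise the fit errors naming them.
.fit_design <- function(design, terms_keep = design$terms, lambda = NULL,
                        drop_aliased = TRUE) {
  sel <- design$assign == 0L |
    (design$assign > 0L & design$terms[pmax(design$assign, 1L)] %in% terms_keep)
  Xs <- design$X[, sel, drop = FALSE]
  dropped <- character()
  q <- qr(Xs)
  if (q$rank < ncol(Xs)) {
    kept_idx <- sort(q$pivot[seq_len(q$rank)])
    dropped <- colnames(Xs)[setdiff(seq_len(ncol(Xs)), kept_idx)]
    if (!drop_aliased) {
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
    Xs <- Xs[, kept_idx, drop = FALSE]
  }
  if (design$n <= ncol(Xs) + 2L) {
    stop("too few records (", design$n, ") for ", ncol(Xs),
         " fixed coefficients plus two variance parameters")
  }
  fit <- .lmm_profile_fit(Xs, design$y, design$g, lambda = lambda)
  fit$dropped_columns <- dropped
  fit$terms <- terms_keep
  fit$X <- Xs
  fit
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits `outcome ~ fixed terms + (1 | group)` with a Gaussian random farm
#' intercept, by full maximum likelihood (not REML) so that AIC values are
#' comparable across models with different fixed effects. The variance ratio
#' is profiled out and maximised on a bounded log scale; a zero farm
#' variance is an admissible boundary solution and is flagged.
#'
#' @param formula Fixed-effects formula, e.g.
#'   `log_tbc ~ milking_system + feeding_hot_water`.
#' @param data Per-sample data frame with no missing values in the model
#'   columns.
#' @param group Name of the clustering column (default `"farm_id"`).
#' @param lambda Optional fixed variance ratio `theta_U / theta_eps`; `0`
#'   forces the ordinary-least-squares limit. `NULL` (default) estimates it.
#' @param drop_aliased Drop collinear design columns by pivoted QR instead
#'   of erroring? Default `FALSE`: a rank-deficient design is an error
#'   naming the collinear columns. The bootstrap/stepwise pipeline enables
#'   dropping because the structural "Not applicable" coding makes whole
#'   column blocks collinear whenever the collection point is in the model.
#' @return An object of class `lmm_ml` with `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `AIC`, `predict`, `fitted`, `residuals`, `nobs` and
#'   `simulate` methods. `theta_U` and `theta_eps` are the farm-intercept
#'   and residual variances; `k_params` counts fixed coefficients plus the
#'   two variance parameters, and `aic = -2 loglik + 2 k_params`.
#' @export
#' @examples
#' d <- simulate_colostrum(n_farms = 10, seed = 1)
#' fit <- lmm_ml(log_tbc ~ feeding_hot_water, d)
#' fit
lmm_ml <- function(formula, data, group = "farm_id", lambda = NULL,
                   drop_aliased = FALSE) {
  cl <- match.call()
  outcome <- deparse(formula[[2]])
  term_labels <- attr(stats::terms(formula), "term.labels")
  design <- .make_design(data, outcome, term_labels, group)
  if (length(design$unusable)) {
    stop("term(s) without variation in `data`: ",
         paste(design$unusable, collapse = ", "))
  }
  fit <- .fit_design(design, lambda = lambda, drop_aliased = drop_aliased)
  if (!isTRUE(fit$converged)) stop("mixed-model fit did not converge")
  structure(
    list(coefficients = fit$beta, vcov = fit$vcov,
         theta_U = fit$theta_U, theta_eps = fit$theta_eps,
         lambda = fit$lambda, loglik = fit$loglik, aic = fit$aic,
         n = fit$n, k_params = fit$k_params,
         converged = fit$converged, boundary = fit$boundary,
         u = fit$u, fitted_fixed = fit$fitted_fixed, fitted = fit$fitted,
         residuals = design$y - fit$fitted, y = design$y,
         g = design$g, X = fit$X,
         dropped_columns = fit$dropped_columns,
         term_labels = design$terms, xlevels = design$xlevels,
         outcome = outcome, group = group, call = cl),
    class = "lmm_ml")
}

#' AIC of a converged mixed-model fit
#'
#' `-2 * loglik + 2 * k_params`, where `k_params` counts the fixed
#' coefficients (including the intercept) plus the two variance parameters.
#'
#' @param fit An [lmm_ml()] fit (or an internal fit record).
#' @return Numeric AIC.
#' @export
aic_of <- function(fit) {
  if (!isTRUE(fit$converged)) stop("AIC undefined: fit did not converge")
  fit$aic
}

#' @export
logLik.lmm_ml <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.lmm_ml <- function(object, ...) object$n

#' @export
coef.lmm_ml <- function(object, ...) object$coefficients

#' @export
vcov.lmm_ml <- function(object, ...) object$vcov

#' @export
fitted.lmm_ml <- function(object, ...) object$fitted

#' @export
residuals.lmm_ml <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  if (type == "conditional") object$residuals
  else object$y - object$fitted_fixed
}

#' @export
print.lmm_ml <- function(x, digits = 3, ...) {
  cat("Random-intercept linear mixed model (ML)\n")
  cat("  outcome:", x$outcome, " groups:", nlevels(x$g),
      " n:", x$n, "\n")
  cat("  theta_U:", format(x$theta_U, digits = digits),
      " theta_eps:", format(x$theta_eps, digits = digits),
      if (x$boundary) " (farm variance at boundary 0)" else "", "\n")
  cat("  logLik:", format(x$loglik, digits = 7),
      " AIC:", format(x$aic, digits = 7), "\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  if (length(x$dropped_columns)) {
    cat("Dropped (aliased):", paste(x$dropped_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.lmm_ml <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, theta_U = object$theta_U,
                 theta_eps = object$theta_eps, loglik = object$loglik,
                 aic = object$aic, n = object$n,
                 n_groups = nlevels(object$g), boundary = object$boundary,
                 dropped_columns = object$dropped_columns,
                 outcome = object$outcome),
            class = "summary.lmm_ml")
}

#' @export
print.summary.lmm_ml <- function(x, digits = 3, ...) {
  cat("Random-intercept linear mixed model (ML), outcome", x$outcome, "\n")
  cat("n =", x$n, "samples over", x$n_groups, "farms\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nVariance components: farm", format(x$theta_U, digits = digits),
      "| residual", format(x$theta_eps, digits = digits),
      if (x$boundary) "(boundary)" else "", "\n")
  cat("logLik", format(x$loglik, digits = 7), "  AIC",
      format(x$aic, digits = 7), "\n")
  if (length(x$dropped_columns)) {
    cat("Aliased columns dropped:",
        paste(x$dropped_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

.model_matrix_newdata <- function(object, newdata) {
  for (v in names(object$xlevels)) {
    if (!v %in% names(newdata)) stop("`newdata` lacks model variable `", v, "`")
    vals <- as.character(newdata[[v]])
    bad <- setdiff(unique(vals[!is.na(vals)]), object$xlevels[[v]])
    if (length(bad)) {
      stop("unseen level(s) for `", v, "`: ", paste(shQuote(bad), collapse = ", "))
    }
    newdata[[v]] <- factor(vals, levels = object$xlevels[[v]])
  }
  if (length(object$term_labels)) {
    X <- stats::model.matrix(stats::reformulate(object$term_labels), newdata)
  } else {
    X <- matrix(1, nrow(newdata), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  X[, names(object$coefficients), drop = FALSE]
}

#' Predict from a random-intercept model
#'
#' @param object An [lmm_ml()] fit.
#' @param newdata Data frame of records to predict (default: training data).
#' @param mode `"with_farm_effect"` adds the conditional mode (BLUP) of the
#'   farm intercept for farms seen in training and zero for unseen farms;
#'   `"fixed_only"` returns the population-level prediction `X beta`.
#' @param ... Unused.
#' @return Numeric predictions on the log cfu/ml scale.
#' @export
predict.lmm_ml <- function(object, newdata = NULL,
                           mode = c("with_farm_effect", "fixed_only"), ...) {
  mode <- match.arg(mode)
  if (is.null(newdata)) {
    fixed <- object$fitted_fixed
    farms <- as.character(object$g)
  } else {
    X <- .model_matrix_newdata(object, newdata)
    fixed <- drop(X %*% object$coefficients)
    farms <- as.character(newdata[[object$group]])
  }
  if (mode == "fixed_only") return(fixed)
  u <- object$u[farms]
  u[is.na(u)] <- 0
  fixed + unname(u)
}

#' @export
simulate.lmm_ml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  J <- nlevels(object$g)
  gi <- as.integer(object$g)
  out <- replicate(nsim, {
    u <- stats::rnorm(J, 0, sqrt(object$theta_U))
    object$fitted_fixed + u[gi] +
      stats::rnorm(object$n, 0, sqrt(object$theta_eps))
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Residual normality diagnostics
#'
#' Descriptive normality summary of the conditional residuals: skewness,
#' excess kurtosis and normal quantile-quantile data. Advisory only — it
#' never gates the pipeline; the summary is flagged unreliable below eight
#' residuals.
#'
#' @param fit An [lmm_ml()] fit.
#' @return List of class `residual_normality` with `skewness`, `kurtosis`
#'   (excess), `n`, `unreliable` and `qq` (theoretical and sample
#'   quantiles).
#' @export
residual_normality <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  r <- residuals(fit)
  n <- length(r)
  m <- mean(r)
  s2 <- mean((r - m)^2)
  skew <- mean((r - m)^3) / s2^1.5
  kurt <- mean((r - m)^4) / s2^2 - 3
  qq <- stats::qqnorm(r, plot.it = FALSE)
  structure(list(skewness = skew, kurtosis = kurt, n = n,
                 unreliable = n < 8,
                 qq = list(theoretical = qq$x, sample = qq$y)),
            class = "residual_normality")
}

#' @export
print.residual_normality <- function(x, ...) {
  cat("Residual normality summary (n = ", x$n, ")\n", sep = "")
  cat("  skewness:", format(x$skewness, digits = 3),
      " excess kurtosis:", format(x$kurtosis, digits = 3), "\n")
  if (x$unreliable) cat("  note: fewer than 8 residuals; summary unreliable\n")
  invisible(x)
}
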