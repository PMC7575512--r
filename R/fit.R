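# Observed vs common-rate model fits, likelihood-ratio test and AIC.
#
# Observed model: unconstrained rate matrix, closed-form ML (k = 2p free
# parameters counted: p rates + p means; evolutionary covariances appear in
# both models and are not counted). Common model: all traits share one rate
# sigma^2, with the evolutionary covariances re-estimated jointly under the
# equal-diagonal constraint (default), or pinned at their observed-model MLE
# correlations with only the rate optimised in 1-D. Either way k = p + 1, so
# the LRT has p - 1 degrees of freedom. The GLS mean is the exact ML mean
# under both models (it does not depend on the rate matrix), so profiling it
# out is exact.

new_bm_fit <- function(model, R, mu, logL, k, n, sigma2 = NULL) {
  stopifnot(model %in% c("observed", "common"))
  fit <- list(model = model, R = R, rates = setNames(diag(R), colnames(R)),
              mu = mu, logL = logL, k = as.integer(k),
              AIC = -2 * logL + 2 * k, n = as.integer(n), p = ncol(R),
              sigma2_common = sigma2)
  class(fit) <- "bm_fit"
  fit
}

#' @export
print.bm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Brownian-motion %s-rate model fit (n = %d species, p = %d traits)\n",
              x$model, x$n, x$p))
  if (!is.null(x$sigma2_common))
    cat(sprintf("common rate sigma^2 = %s\n", fmt_num(x$sigma2_common, digits)))
  cat("rate matrix (diagonal = per-trait sigma^2):\n")
  print(round(x$R, digits))
  cat(sprintf("logL = %s   k = %d   AIC = %s\n",
              fmt_num(x$logL, digits), x$k, fmt_num(x$AIC, digits)))
  invisible(x)
}

#' Fit the observed (unconstrained-rate) Brownian model
#'
#' Closed-form maximum likelihood: GLS mean, then \eqn{\hat R = D'C^{-1}D/n}.
#' `k = 2p` parameters are counted for AIC (p rates + p phylogenetic means).
#'
#' @inheritParams phylo_mean
#' @return A `bm_fit` object with elements `R`, `rates`, `mu`, `logL`, `k`,
#'   `AIC`, `n`, `p`.
#' @export
fit_observed <- function(X, C) {
  st <- bm_suffstats(X, C)
  R <- st$S / st$n
  dimnames(R) <- list(colnames(X), colnames(X))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (st$p >= 2 && min(ev) <= max(ev) * 1e-10)
    stop_numeric("traits are collinear after phylogenetic transformation (singular rate matrix)")
  logL <- ll_from_stats(st$S, st$logdetC, st$n, st$p, R)
  new_bm_fit("observed", R, st$mu, logL, k = 2 * st$p, n = st$n)
}

# 1-D profile fit with correlations pinned at P: returns sigma2 and logL.
# Deterministic bounded scalar maximisation, relative tolerance 1e-10,
# bracket spanning 1e-4 to 1e4 times the observed rate range.
common_fixed_profile <- function(st, P, R_obs) {
  lo <- log(min(diag(R_obs)) * 1e-4)
  hi <- log(max(diag(R_obs)) * 1e4)
  f <- function(t) ll_from_stats(st$S, st$logdetC, st$n, st$p, exp(t) * P)
  opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (!is.finite(opt$objective))
    stop_numeric("common-rate optimisation failed on bracket [%g, %g], last iterate %g",
                 exp(lo), exp(hi), exp(opt$maximum))
  list(sigma2 = exp(opt$maximum), logL = opt$objective)
}

# Full constrained ML: R = sigma^2 I + free off-diagonal covariances,
# BFGS on (log sigma^2, covariances) with the analytic gradient
# dl/dR = -(n R^-1 - R^-1 S R^-1)/2, started at the 1-D profile optimum.
common_joint_ml <- function(st, R_start) {
  p <- st$p
  n <- st$n
  S <- st$S
  const <- n * p * log(2 * pi) + p * st$logdetC
  unpack <- function(th) {
    R <- diag(exp(th[1]), p)
    R[lower.tri(R)] <- th[-1]
    R + t(R) - diag(diag(R))
  }
  fn <- function(th) {
    ch <- tryCatch(chol(unpack(th)), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    0.5 * (const + 2 * n * sum(log(diag(ch))) + sum(chol2inv(ch) * S))
  }
  gr <- function(th) {
    ch <- tryCatch(chol(unpack(th)), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(th)))
    iR <- chol2inv(ch)
    G <- 0.5 * (n * iR - iR %*% S %*% iR)
    c(exp(th[1]) * sum(diag(G)), 2 * G[lower.tri(G)])
  }
  th0 <- c(log(mean(diag(R_start))), R_start[lower.tri(R_start)])
  opt <- optim(th0, fn, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  R_c <- unpack(opt$par)
  if (!is.finite(opt$value) || opt$value >= 1e9)
    stop_numeric("joint common-rate optimisation failed (non-PD optimum); last iterate sigma^2 = %g",
                 exp(opt$par[1]))
  list(sigma2 = exp(opt$par[1]), logL = -opt$value, R = R_c)
}

#' Fit the constrained common-rate Brownian model
#'
#' All traits are forced to share a single Brownian rate \eqn{\sigma^2}.
#' With `common_model = "joint"` (default) the evolutionary covariances are
#' re-estimated jointly with \eqn{\sigma^2} under the equal-diagonal
#' constraint — the full constrained maximum likelihood — by BFGS with the
#' analytic gradient, started from the 1-D profile optimum. With
#' `common_model = "fixed_correlations"` the constrained rate matrix is
#' \eqn{R_c(\sigma^2) = \sigma^2 P} with `P` the observed-model MLE
#' correlation matrix and only \eqn{\sigma^2} optimised (deterministic
#' bounded scalar maximisation, relative tolerance 1e-10). The joint fit
#' always attains at least the fixed-correlation likelihood, which keeps the
#' LRT against [fit_observed()] from being inflated by an under-maximised
#' null. Either way `k = p + 1` parameters are counted (one rate + p means),
#' so the LRT has `p - 1` degrees of freedom.
#'
#' @inheritParams phylo_mean
#' @param common_model `"joint"` or `"fixed_correlations"`.
#' @return A `bm_fit` object; `sigma2_common` holds the fitted common rate.
#' @export
fit_common <- function(X, C, common_model = c("joint", "fixed_correlations")) {
  common_model <- match.arg(common_model)
  st <- bm_suffstats(X, C)
  if (st$p < 2) stop_input("the common-rate model needs at least 2 traits")
  R_obs <- st$S / st$n
  dimnames(R_obs) <- list(colnames(X), colnames(X))
  ev <- eigen(R_obs, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10)
    stop_numeric("traits are collinear after phylogenetic transformation (singular rate matrix)")

  P <- cov2cor(R_obs)
  prof <- common_fixed_profile(st, P, R_obs)
  if (common_model == "fixed_correlations") {
    sigma2 <- prof$sigma2
    R_c <- sigma2 * P
    logL <- prof$logL
  } else {
    fit <- common_joint_ml(st, prof$sigma2 * P)
    sigma2 <- fit$sigma2
    R_c <- fit$R
    logL <- fit$logL
  }
  dimnames(R_c) <- dimnames(R_obs)
  new_bm_fit("common", R_c, st$mu, logL, k = st$p + 1, n = st$n, sigma2 = sigma2)
}

#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, used to refer the LRT
#' statistic of nested Brownian rate models to its asymptotic null.
#'
#' @param stat Non-negative test statistic.
#' @param df Positive integer degrees of freedom.
#' @return Probability in \[0, 1\].
#' @examples
#' chisq_upper_tail(8.50, 2)
#' @export
chisq_upper_tail <- function(stat, df) {
  if (!is.numeric(stat) || any(stat < 0)) stop_input("test statistic must be >= 0")
  if (!is.numeric(df) || any(df != round(df)) || any(df < 1))
    stop_input("df must be a positive integer")
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Compare observed and common-rate Brownian models
#'
#' Fits both models and assembles the likelihood-ratio test
#' \eqn{LRT = 2(\log L_{obs} - \log L_{common})}, referred to a chi-square
#' distribution with `p - 1` degrees of freedom, together with AICs and the
#' matrix of pairwise rate ratios \eqn{\sigma^2_i / \sigma^2_j} from the
#' observed diagonal.
#'
#' @inheritParams fit_common
#' @return A `rate_comparison` object with elements `observed`, `common`,
#'   `LRT`, `df`, `p_value`, `rate_ratios`, `n`, `p`.
#' @export
compare_rates <- function(X, C, common_model = c("joint", "fixed_correlations")) {
  common_model <- match.arg(common_model)
  obs <- fit_observed(X, C)
  com <- fit_common(X, C, common_model)
  lrt <- 2 * (obs$logL - com$logL)
  if (lrt < -1e-6)
    stop_numeric("nested-model violation: logL_common exceeds logL_observed by %g", -lrt / 2)
  lrt <- max(lrt, 0)
  df <- obs$p - 1L
  ratios <- outer(obs$rates, obs$rates, "/")
  dimnames(ratios) <- dimnames(obs$R)
  out <- list(observed = obs, common = com, LRT = lrt, df = df,
              p_value = chisq_upper_tail(lrt, df), rate_ratios = ratios,
              n = obs$n, p = obs$p, common_model = common_model)
  class(out) <- "rate_comparison"
  out
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Ratio of two observed evolutionary rates
#'
#' \eqn{\sigma^2_i / \sigma^2_j} taken from the observed-model diagonal, the
#' quantity behind statements such as "trait i evolved 3.4 times faster than
#' trait j".
#'
#' @param fit A `bm_fit` or `rate_comparison` object.
#' @param trait_i,trait_j Trait names or indices.
#' @return A single numeric ratio.
#' @export
rate_ratio <- function(fit, trait_i, trait_j) {
  if (inherits(fit, "rate_comparison")) fit <- fit$observed
  if (!inherits(fit, "bm_fit")) stop_input("'fit' must be a bm_fit or rate_comparison")
  rates <- fit$rates
  get1 <- function(tr) {
    if (is.character(tr) && !tr %in% names(rates))
      stop_input("trait '%s' not in fit (traits: %s)", tr,
                 paste(names(rates), collapse = ", "))
    rates[[tr]]
  }
  num <- get1(trait_i)
  den <- get1(trait_j)
  if (den == 0) stop_input("rate of trait '%s' is zero; ratio undefined", as.character(trait_j))
  num / den
}
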