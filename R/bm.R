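# Matrix-normal likelihood of p traits evolving by correlated Brownian motion
# on a phylogeny.
#
# Model: the n x p trait matrix X is matrix-normal with mean 1 mu', row
# covariance C (phylogenetic covariance) and column covariance R (the
# evolutionary rate matrix). Equivalently vec(X) ~ N(vec(1 mu'), R %x% C).
# Everything below works from one Cholesky factorisation of C per dataset;
# log-determinants come from factor diagonals and no matrix is inverted
# explicitly.

check_alignment <- function(X, C) {
  if (!is.matrix(X)) stop_input("trait table must be a numeric matrix")
  if (!is.numeric(X) || anyNA(X))
    stop_input("trait table must be numeric with no missing values")
  if (!is_square_symmetric(C))
    stop_input("phylogenetic covariance must be a symmetric square matrix")
  if (nrow(X) != nrow(C))
    stop_input("trait table has %d species but covariance has %d", nrow(X), nrow(C))
  if (nrow(X) < 2) stop_input("at least 2 species are required")
  if (!is.null(rownames(X)) && !is.null(rownames(C)) &&
      !identical(rownames(X), rownames(C)))
    stop_input("species order of trait table and covariance matrix differ")
  invisible(TRUE)
}

# Sufficient statistics shared by all fits: GLS mean, cross-product
# S = D' C^-1 D with D = X - 1 mu', and log|C|.
bm_suffstats <- function(X, C) {
  check_alignment(X, C)
  L <- chol_lower(C)
  n <- nrow(X)
  ones <- rep(1, n)
  A1 <- forwardsolve(L, ones)            # L^-1 1
  AX <- forwardsolve(L, X)               # L^-1 X
  mu <- drop(crossprod(A1, AX)) / drop(crossprod(A1))
  D <- X - tcrossprod(ones, mu)
  AD <- AX - tcrossprod(A1, mu)          # L^-1 D
  S <- crossprod(AD)
  list(mu = setNames(mu, colnames(X)), S = S, logdetC = 2 * sum(log(diag(L))),
       n = n, p = ncol(X), L = L)
}

#' Phylogenetic (GLS) mean of each trait
#'
#' The maximum-likelihood estimate of the Brownian-motion root state, i.e. the
#' generalised-least-squares mean \eqn{\hat\mu_j = (1'C^{-1}1)^{-1} 1'C^{-1}
#' x_j} for each trait column. On a star tree with equal branch lengths this
#' reduces to the ordinary column mean. Does not depend on the rate matrix.
#'
#' @param X Numeric species x trait matrix (rows aligned with `C`).
#' @param C Phylogenetic covariance matrix from [phylo_covariance()].
#' @return Named numeric vector of length p.
#' @export
phylo_mean <- function(X, C) {
  bm_suffstats(X, C)$mu
}

#' Maximum-likelihood evolutionary rate matrix
#'
#' The ML estimate \eqn{\hat R = D'C^{-1}D / n} with \eqn{D = X - 1\mu'},
#' using the ML divisor n. The diagonal holds the per-trait Brownian rates
#' \eqn{\sigma^2_i} (squared trait units per unit branch length); off-diagonal
#' entries are evolutionary covariances. A rank-deficient estimate (e.g. from
#' duplicated trait columns) is returned with attribute `singular = TRUE`.
#'
#' @inheritParams phylo_mean
#' @param mu Optional mean vector; defaults to [phylo_mean()].
#' @return p x p symmetric matrix with trait dimnames.
#' @export
ml_rate_matrix <- function(X, C, mu = NULL) {
  st <- bm_suffstats(X, C)
  if (!is.null(mu)) {
    if (length(mu) != st$p) stop_input("mu has length %d, expected %d", length(mu), st$p)
    D <- X - tcrossprod(rep(1, st$n), as.numeric(mu))
    AD <- forwardsolve(st$L, D)
    R <- crossprod(AD) / st$n
  } else {
    R <- st$S / st$n
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  attr(R, "singular") <- min(ev) <= max(ev) * 1e-10
  R
}

#' Matrix-normal Brownian-motion log-likelihood
#'
#' Evaluates \deqn{-\tfrac12\left[np\log(2\pi) + p\log|C| + n\log|R| +
#' \mathrm{tr}(R^{-1} D' C^{-1} D)\right]} with \eqn{D = X - 1\mu'}: the
#' log-density of the matrix-normal distribution with row covariance `C` and
#' column covariance `R`. Identical (to numerical precision) to the dense
#' np-variate normal log-density with covariance `kronecker(R, C)`. Both `C`
#' and `R` must be positive definite; non-PD inputs raise an error rather
#' than being silently regularised, since any jitter would corrupt the LRT
#' arithmetic downstream.
#'
#' @inheritParams phylo_mean
#' @param R p x p positive-definite rate matrix.
#' @param mu Numeric vector of length p.
#' @return A single numeric log-likelihood.
#' @export
bm_log_likelihood <- function(X, C, R, mu) {
  st <- bm_suffstats(X, C)
  if (length(mu) != st$p) stop_input("mu has length %d, expected %d", length(mu), st$p)
  if (!is_square_symmetric(as.matrix(R)) || nrow(as.matrix(R)) != st$p)
    stop_input("R must be a symmetric %d x %d matrix", st$p, st$p)
  D <- X - tcrossprod(rep(1, st$n), as.numeric(mu))
  AD <- forwardsolve(st$L, D)
  ll_from_stats(crossprod(AD), st$logdetC, st$n, st$p, as.matrix(R))
}

# Core evaluation given S = D' C^-1 D.
ll_from_stats <- function(S, logdetC, n, p, R) {
  LR <- chol_lower(R, what = "rate matrix")
  logdetR <- 2 * sum(log(diag(LR)))
  B <- forwardsolve(LR, S)          # LR^-1 S
  tr <- sum(diag(forwardsolve(LR, t(B))))  # tr(R^-1 S)
  -0.5 * (n * p * log(2 * pi) + p * logdetC + n * logdetR + tr)
}
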