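# Shared fixtures and independent oracles for the likelihood machinery.

# Brute-force matrix-normal log-density through the dense np x np Kronecker
# covariance: independent of the factorised likelihood it checks.
logL_kron <- function(X, C, R, mu) {
  n <- nrow(X)
  p <- ncol(X)
  Sig <- kronecker(R, C)
  v <- as.vector(X - tcrossprod(rep(1, n), mu))
  -0.5 * (n * p * log(2 * pi) +
            as.numeric(determinant(Sig, logarithm = TRUE)$modulus) +
            drop(t(v) %*% solve(Sig) %*% v))
}

rand_spd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p)
  (crossprod(A) / p + diag(p) * 0.2) * scale
}

# Random rooted non-ultrametric tree with strictly positive branch lengths.
rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

sim_dataset <- function(tree, R, mu = rep(0, ncol(as.matrix(R))), seed = 1) {
  X <- simulate_traits(tree, R, mu, seed = seed)
  C <- phylo_covariance(tree)
  list(X = X, C = C[rownames(X), rownames(X)])
}

# Equal-rate matrix with common positive correlation, the null-model
# generator used in calibration simulations.
equicorr_R <- function(p, rate = 0.5, rho = 0.3) {
  P <- matrix(rho, p, p)
  diag(P) <- 1
  rate * P
}
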