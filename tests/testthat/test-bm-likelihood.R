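test_that("phylo_mean is the GLS mean: star, weighted two-taxon, constant cases", {
  star <- read_newick(text = "(A:1,B:1,C:1,D:1);")
  Cs <- phylo_covariance(star)
  X <- matrix(rnorm(8), 4, 2, dimnames = list(rownames(Cs), c("u", "v")))
  expect_equal(unname(phylo_mean(X, Cs)), unname(colMeans(X)))

  # hand-derived: C = diag(1, 3), values (0, 4) -> (0/1 + 4/3)/(1 + 1/3) = 1
  tr2 <- read_newick(text = "(A:1,B:3);")
  C2 <- phylo_covariance(tr2, order = c("A", "B"))
  X2 <- matrix(c(0, 4), 2, 1, dimnames = list(c("A", "B"), "t"))
  expect_equal(unname(phylo_mean(X2, C2)), 1)

  # constant trait has mean v on any tree
  set.seed(3)
  tr <- rand_tree(7)
  Cm <- phylo_covariance(tr)
  Xc <- matrix(2.5, 7, 1, dimnames = list(rownames(Cm), "t"))
  expect_equal(unname(phylo_mean(Xc, Cm)), 2.5)
})

test_that("ml_rate_matrix uses divisor n, scales inversely with branch lengths, flags rank deficiency", {
  star <- simulate_tree(6, "star")
  Cs <- phylo_covariance(star)
  set.seed(4)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(rownames(Cs), c("u", "v")))
  R <- ml_rate_matrix(X, Cs)
  D <- sweep(X, 2, colMeans(X))
  expect_equal(unname(R), unname(crossprod(D) / 6), ignore_attr = TRUE)

  # branch lengths x10 -> rates / 10 exactly
  expect_equal(unname(ml_rate_matrix(X, 10 * Cs)), unname(R) / 10,
               ignore_attr = TRUE)

  Xdup <- cbind(X, w = X[, 1])
  expect_true(attr(ml_rate_matrix(Xdup, Cs), "singular"))
})

test_that("log-likelihood matches hand derivation and the dense Kronecker oracle", {
  star <- read_newick(text = "(A:1,B:1,C:1);")
  Cs <- phylo_covariance(star, order = c("A", "B", "C"))
  X <- matrix(c(0, 0, 3), 3, 1, dimnames = list(c("A", "B", "C"), "t"))
  expect_equal(bm_log_likelihood(X, Cs, matrix(2), mu = 1),
               -0.5 * (3 * log(2 * pi) + 3 * log(2) + 3), tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    p <- sample(1:5, 1)
    tr <- rand_tree(n)
    Cm <- phylo_covariance(tr)
    R <- rand_spd(p)
    mu <- rnorm(p)
    X <- simulate_traits(tr, R, mu, seed = rep)
    X <- X[rownames(Cm), , drop = FALSE]
    expect_equal(bm_log_likelihood(X, Cm, R, mu), logL_kron(X, Cm, R, mu),
                 tolerance = 1e-8)
  }
})

test_that("the closed-form (mu, R) maximise the likelihood and independent traits factorise", {
  set.seed(31)
  tr <- rand_tree(8)
  Cm <- phylo_covariance(tr)
  ds <- sim_dataset(tr, rand_spd(2), seed = 9)
  mu <- phylo_mean(ds$X, ds$C)
  R <- ml_rate_matrix(ds$X, ds$C)
  attr(R, "singular") <- NULL
  base <- bm_log_likelihood(ds$X, ds$C, R, mu)
  for (k in 1:10) {
    mu2 <- mu + rnorm(2) * 0.2
    R2 <- R + rand_spd(2, 0.1)
    expect_lt(bm_log_likelihood(ds$X, ds$C, R2, mu2), base)
  }

  # block-diagonal R: bivariate logL = sum of univariate logLs
  R0 <- diag(c(0.7, 1.8))
  mu0 <- c(0.3, -0.1)
  ll2 <- bm_log_likelihood(ds$X, ds$C, R0, mu0)
  ll_sep <- sum(vapply(1:2, function(j)
    bm_log_likelihood(ds$X[, j, drop = FALSE], ds$C,
                      R0[j, j, drop = FALSE] |> matrix(1, 1), mu0[j]),
    numeric(1)))
  expect_equal(ll2, ll_sep, tolerance = 1e-10)
})

test_that("simultaneous species reordering leaves the likelihood unchanged", {
  set.seed(41)
  tr <- rand_tree(9)
  Cm <- phylo_covariance(tr)
  ds <- sim_dataset(tr, rand_spd(3), seed = 2)
  mu <- phylo_mean(ds$X, ds$C)
  R <- ml_rate_matrix(ds$X, ds$C)
  attr(R, "singular") <- NULL
  ll <- bm_log_likelihood(ds$X, ds$C, R, mu)
  for (k in 1:5) {
    perm <- sample(nrow(ds$X))
    llp <- bm_log_likelihood(ds$X[perm, , drop = FALSE],
                             ds$C[perm, perm], R, mu)
    expect_equal(llp, ll, tolerance = 1e-10 * abs(ll))
  }
})

test_that("non-positive-definite C or R raise errors instead of silent repair", {
  zero_tr <- read_newick(text = "((A:0,B:0):1,C:1);")
  Cz <- phylo_covariance(zero_tr, order = c("A", "B", "C"))
  X <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("u", "v")))
  err <- expect_error(phylo_mean(X, Cz), class = "traitrates_numeric_error")
  expect_match(conditionMessage(err), "A/B")

  star <- read_newick(text = "(A:1,B:1,C:1);")
  Cs <- phylo_covariance(star, order = c("A", "B", "C"))
  Rbad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(bm_log_likelihood(X, Cs, Rbad, c(0, 0)),
               "rate matrix", class = "traitrates_numeric_error")
})

test_that("the rate-matrix estimator is consistent on a large star tree", {
  star <- simulate_tree(200, "star")
  Cs <- phylo_covariance(star)
  R_true <- matrix(c(1, 0.4, 0.4, 0.8), 2,
                   dimnames = list(c("u", "v"), c("u", "v")))
  X <- simulate_traits(star, R_true, c(0, 0), seed = 77)
  R_hat <- ml_rate_matrix(X[rownames(Cs), ], Cs)
  rel <- abs(R_hat - R_true) / abs(R_true)
  expect_lt(median(rel), 0.10)
})
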