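test_that("model fits carry the AIC identity and parameter-count convention", {
  fx <- make_fixture("drosophila", seed = 3)
  C <- phylo_covariance(fx$tree)
  obs <- fit_observed(fx$X_log10, C)
  com <- fit_common(fx$X_log10, C)
  expect_identical(obs$k, 8L)          # 2p
  expect_identical(com$k, 5L)          # p + 1
  expect_equal(obs$AIC, -2 * obs$logL + 2 * obs$k)
  expect_equal(com$AIC, -2 * com$logL + 2 * com$k)

  cmp <- compare_rates(fx$X_log10, C)
  expect_identical(cmp$df, 3L)         # p - 1 = k_obs - k_common
  expect_equal(cmp$LRT, 2 * (obs$logL - com$logL), tolerance = 1e-8)
  expect_equal(cmp$p_value, chisq_upper_tail(cmp$LRT, cmp$df))
  expect_equal(diag(cmp$rate_ratios), rep(1, 4), ignore_attr = TRUE)
})

test_that("the common model is nested: logL_common <= logL_obs and joint >= fixed", {
  set.seed(55)
  for (rep in 1:6) {
    tr <- if (rep %% 2) simulate_tree(10, "yule", seed = rep) else rand_tree(10)
    p <- sample(2:4, 1)
    ds <- sim_dataset(tr, rand_spd(p), seed = rep + 100)
    obs <- fit_observed(ds$X, ds$C)
    fixed <- fit_common(ds$X, ds$C, "fixed_correlations")
    joint <- fit_common(ds$X, ds$C, "joint")
    expect_gte(joint$logL, fixed$logL - 1e-8)
    expect_gte(obs$logL, joint$logL - 1e-6)
    expect_gte(compare_rates(ds$X, ds$C)$LRT, 0)
  }
})

test_that("chisq_upper_tail reproduces reference tail probabilities", {
  expect_equal(chisq_upper_tail(8.50, 2), 0.0143, tolerance = 1e-2)
  expect_equal(chisq_upper_tail(3.59, 1), 0.0581, tolerance = 1e-2)
  expect_identical(chisq_upper_tail(0, 5), 1)
  expect_error(chisq_upper_tail(-1, 2), class = "traitrates_input_error")
  expect_error(chisq_upper_tail(3, 0.5), class = "traitrates_input_error")
})

test_that("rate_ratio reads the observed diagonal and guards division by zero", {
  fx <- make_fixture("lepidoptera", seed = 4)
  C <- phylo_covariance(fx$tree)
  cmp <- compare_rates(fx$X_log10, C)
  r <- rate_ratio(cmp, "fertile_total", "nonfertile_total")
  expect_equal(r, cmp$observed$rates[["fertile_total"]] /
                 cmp$observed$rates[["nonfertile_total"]])
  expect_equal(rate_ratio(cmp, "forewing", "forewing"), 1)
  expect_error(rate_ratio(cmp, "fertile_total", "nope"), "not in fit",
               class = "traitrates_input_error")

  fake <- traitrates:::new_bm_fit(
    "observed", matrix(c(1, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b"))),
    c(a = 0, b = 0), logL = 0, k = 4, n = 5)
  expect_error(rate_ratio(fake, "a", "b"), "zero",
               class = "traitrates_input_error")
})

test_that("branch-length rescaling changes rates by 1/c but not LRT, df or p", {
  fx <- make_fixture("drosophila", seed = 8)
  C <- phylo_covariance(fx$tree)
  cmp1 <- compare_rates(fx$X_log10, C)
  for (c_scale in c(10, 0.25)) {
    cmp2 <- compare_rates(fx$X_log10, c_scale * C)
    expect_equal(cmp2$observed$rates, cmp1$observed$rates / c_scale,
                 tolerance = 1e-8)
    expect_equal(cmp2$common$sigma2_common, cmp1$common$sigma2_common / c_scale,
                 tolerance = 1e-6)
    expect_equal(cmp2$LRT, cmp1$LRT, tolerance = 1e-8 * max(1, cmp1$LRT))
    expect_identical(cmp2$df, cmp1$df)
    expect_equal(cmp2$p_value, cmp1$p_value, tolerance = 1e-8)
  }
})

test_that("the 1-D common-rate optimum matches an exhaustive grid search", {
  for (seed in c(2, 13)) {
    fx <- make_fixture("drosophila", seed = seed)
    C <- phylo_covariance(fx$tree)
    st <- traitrates:::bm_suffstats(fx$X_log10, C)
    P <- cov2cor(st$S / st$n)
    ll <- function(s2) traitrates:::ll_from_stats(st$S, st$logdetC, st$n, st$p, s2 * P)
    s_bar <- mean(diag(st$S / st$n))
    grid <- exp(seq(log(1e-4 * s_bar), log(1e4 * s_bar), length.out = 1000))
    best <- grid[which.max(vapply(grid, ll, numeric(1)))]
    refined <- exp(seq(log(best) - 0.02, log(best) + 0.02, length.out = 2000))
    best <- refined[which.max(vapply(refined, ll, numeric(1)))]
    fit <- fit_common(fx$X_log10, C, "fixed_correlations")
    expect_lt(abs(fit$sigma2_common - best) / best, 0.001)
    # and both agree with the analytic profile optimum tr(P^-1 S) / (n p)
    expect_equal(fit$sigma2_common, sum(solve(P) * st$S) / (st$n * st$p),
                 tolerance = 1e-6)
  }
})

test_that("equal-rate uncorrelated traits give a common rate near both observed rates", {
  star <- simulate_tree(400, "star")
  C <- phylo_covariance(star)
  X <- simulate_traits(star, diag(2), c(0, 0), seed = 19)
  cmp <- compare_rates(X[rownames(C), ], C)
  expect_equal(cmp$common$sigma2_common, 1, tolerance = 0.15)
  expect_equal(unname(cmp$observed$rates), rep(1, 2), tolerance = 0.15)
  expect_gt(cmp$p_value, 0.01)
})

test_that("single-trait fits are allowed but cannot be compared", {
  tr <- simulate_tree(8, "yule", seed = 2)
  C <- phylo_covariance(tr)
  X <- simulate_traits(tr, matrix(0.5), 0, seed = 3)
  fit <- fit_observed(X[rownames(C), , drop = FALSE], C)
  expect_identical(fit$k, 2L)
  expect_error(fit_common(X[rownames(C), , drop = FALSE], C),
               "at least 2 traits", class = "traitrates_input_error")
})
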