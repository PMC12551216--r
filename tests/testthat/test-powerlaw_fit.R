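# Brute-force likelihood-grid oracle for the discrete power law at
# xmin = 1, normalized with the Riemann zeta from pracma (independent of
# the package's Hurwitz-zeta code path).
oracle_grid_alpha <- function(x, grid, log_zeta_grid) {
  S <- sum(log(x))
  ll <- -length(x) * log_zeta_grid - grid * S
  grid[which.max(ll)]
}

test_that("discrete MLE matches the brute-force likelihood grid", {
  grid <- seq(1.0001, 8, by = 1e-4)
  log_zeta_grid <- log(pracma::zeta(grid))

  # the tiny worked sample
  x0 <- c(1, 1, 1, 2, 3)
  f0 <- suppressWarnings(fit_powerlaw_discrete(x0, xmin = 1, alpha_max = 8))
  expect_equal(f0$alpha, oracle_grid_alpha(x0, grid, log_zeta_grid),
               tolerance = 1e-3)

  # 100 seeded small samples
  for (i in 1:100) {
    x <- rpowerlaw_discrete(50, 1.5 + (i %% 10) / 4, xmin = 1, seed = 500 + i)
    if (length(unique(x)) < 2) next
    f <- suppressWarnings(fit_powerlaw_discrete(x, xmin = 1, alpha_max = 8))
    expect_equal(f$alpha, oracle_grid_alpha(x, grid, log_zeta_grid),
                 tolerance = 1e-3)
  }
})

test_that("alpha and xmin are recovered from large samples", {
  x <- rpowerlaw_discrete(10000, 2.5, xmin = 1, seed = 42)
  f <- fit_powerlaw_discrete(x)
  expect_gt(f$alpha, 2.4)
  expect_lt(f$alpha, 2.6)

  # hard lower cutoff at 5 with sub-cutoff noise, 40 seeded runs
  hits <- vapply(1:40, function(i) {
    tail_x <- rpowerlaw_discrete(5000, 2.5, xmin = 5, seed = 900 + i)
    noise <- genolex:::with_seed(300 + i,
      sample(1:4, 3000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)))
    xm <- fit_powerlaw_discrete(c(tail_x, noise))$xmin
    xm >= 3 && xm <= 8
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  expect_error(fit_powerlaw_discrete(rep(3L, 10)), "degenerate")
})

test_that("KS distance is a proper sup-norm in [0, 1]", {
  x <- rpowerlaw_discrete(10000, 2.2, xmin = 1, seed = 7)
  f <- fit_powerlaw_discrete(x, xmin = 1)
  ks_pl <- ks_statistic(x, f)
  expect_gte(ks_pl, 0)
  expect_lte(ks_pl, 1)
  expect_lt(ks_pl, 0.02)   # its own generating family fits tightly

  # same sample against a fitted discrete exponential: worse KS
  lam <- log(1 + 1 / (mean(x) - 1))
  exp_cdf <- function(v) 1 - exp(-lam * (v + 1 - 1))  # P(X <= v), support >= 1
  xs <- sort(unique(x))
  emp <- vapply(xs, function(v) mean(x <= v), numeric(1))
  ks_exp <- max(abs(emp - exp_cdf(xs)))
  expect_lt(ks_pl, ks_exp)
})

test_that("model comparison picks the generating family", {
  x <- rpowerlaw_discrete(10000, 2.0, xmin = 1, seed = 11)
  cmp <- compare_models(x, xmin = 1)
  expect_equal(cmp$best_by_aic, "powerlaw")

  g <- genolex:::with_seed(13, rgeom(10000, 0.25) + 1L)
  cmp_g <- compare_models(g, xmin = 1)
  expect_equal(cmp_g$best_by_aic, "exponential")

  # AIC/BIC algebraic identity on every candidate
  for (m in cmp$models)
    expect_equal(m$aic - m$bic, 2 * m$n_params - m$n_params * log(cmp$n_tail))
  expect_error(compare_models(1:5, xmin = 1), ">= 10")
})

test_that("bootstrap CIs are seeded, bounded and cover exact-Zipf truth", {
  tab <- exact_zipf_table(1)
  tab$count <- as.integer(round(1e6 * tab$rel_freq))

  b1 <- bootstrap_exponent(tab, "ols_zeta", n_boot = 50, seed = 99)
  b2 <- bootstrap_exponent(tab, "ols_zeta", n_boot = 50, seed = 99)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] <= 1 && 1 <= b1$ci[2])

  b3 <- bootstrap_exponent(tab, "ols_zeta", n_boot = 1, seed = 5)
  expect_equal(b3$ci[1], b3$ci[2])

  expect_error(bootstrap_exponent(tab, "ols_zeta", n_boot = 10001), "10000")

  x <- rpowerlaw_discrete(2000, 2.5, xmin = 1, seed = 3)
  bm <- bootstrap_exponent(x, "mle_alpha", n_boot = 50, seed = 4)
  expect_true(bm$ci[1] <= bm$estimate && bm$estimate <= bm$ci[2])
})
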