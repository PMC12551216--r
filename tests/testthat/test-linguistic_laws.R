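test_that("Heaps curves are monotone, bounded and fit a growth exponent", {
  s <- gen_iid(length = 1e5, seed = 20)
  hc <- heaps_curve(s, k = 8, n_points = 25, seed = 1)
  expect_true(all(diff(hc$sample_points$distinct_types) >= 0))
  expect_true(all(hc$sample_points$distinct_types <=
                  pmin(hc$sample_points$tokens_seen, 4^8)))
  expect_gt(hc$beta, 0)
  expect_lt(hc$beta, 1)

  # k = 3: alphabet bound holds at every checkpoint
  hc3 <- heaps_curve(gen_iid(length = 5e4, seed = 21), k = 3, seed = 1)
  expect_true(all(hc3$sample_points$distinct_types <= 64))

  # saturated everywhere (k = 1, periodic): fit refused, curve returned
  expect_warning(hc1 <- heaps_curve(strrep("ACGT", 5000), k = 1, seed = 1),
                 "saturated")
  expect_true(is.na(hc1$beta))
  expect_true(all(hc1$sample_points$distinct_types == 4))

  # checkpoint-density invariance: same cumulative counts underneath
  hc_a <- heaps_curve(s, k = 8, n_points = 10, seed = 1)
  hc_b <- heaps_curve(s, k = 8, n_points = 40, seed = 1)
  common <- intersect(hc_a$sample_points$tokens_seen,
                      hc_b$sample_points$tokens_seen)
  expect_identical(
    hc_a$sample_points$distinct_types[match(common, hc_a$sample_points$tokens_seen)],
    hc_b$sample_points$distinct_types[match(common, hc_b$sample_points$tokens_seen)])
})

test_that("abbreviation correlation has the designed sign", {
  # spectra over the full 4^k vocabulary whose 10 designated top tokens
  # carry exactly specified log2 enrichments e_i over the uniform
  # expectation; the remaining mass is spread uniformly
  mk_spec <- function(k, e_values, seed) {
    vocab <- do.call(paste0, expand.grid(rep(list(c("A","C","G","T")), k)))
    V <- length(vocab)
    N <- 1e6
    top_counts <- round(N * 4^(-k) * 2^e_values)
    idx <- genolex:::with_seed(seed, sample(V, length(e_values)))
    counts <- rep(max(1L, round((N - sum(top_counts)) / (V - length(idx)))), V)
    counts[idx] <- top_counts
    names(counts) <- vocab
    genolex:::new_kmer_spectrum(counts, k, 1L, sum(counts), 0L, 1L)
  }
  # k in 4..8 keeps the designated mass 10 * 2^e / 4^k well below 1
  # abbreviation effect: enrichment falls with token length
  specs_abbr <- lapply(4:8, function(k)
    mk_spec(k, genolex:::with_seed(100 + k, 3.5 - 0.35 * k + runif(10, 0, 0.2)),
            seed = 200 + k))
  expect_lt(abbreviation_correlation(specs_abbr, m = 10)$rho, 0)

  # enrichment independent of length by construction: |rho| small
  rhos <- vapply(1:20, function(r) {
    specs <- lapply(4:8, function(k)
      mk_spec(k, genolex:::with_seed(r * 31 + k, runif(10, 1, 2)),
              seed = r * 131 + k))
    abbreviation_correlation(specs, m = 10)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.2)

  expect_error(abbreviation_correlation(list(count_kmers("ACGTAC", 3))),
               "2 distinct k")
})

test_that("Menzerath fits recover exact and noisy power-law pairs", {
  d_exact <- data.frame(n_parts = 1:20,
                        mean_part_size = 100 * (1:20)^(-0.5))
  fit <- menzerath_fit(d_exact)
  expect_equal(fit$b, -0.5, tolerance = 1e-9)
  expect_equal(fit$a, 100, tolerance = 1e-6)

  for (b in c(-2, -1, 0.5, 2)) {
    d <- data.frame(n_parts = 2:12, mean_part_size = 7 * (2:12)^b)
    expect_equal(menzerath_fit(d)$b, b, tolerance = 1e-9)
  }

  d_const <- data.frame(n_parts = 1:10, mean_part_size = rep(50, 10))
  expect_equal(menzerath_fit(d_const)$b, 0, tolerance = 1e-12)

  # noisy generator: b = -0.3 with lognormal noise, 200 constructs
  d_noisy <- genolex:::with_seed(42, {
    x <- sample(1:15, 200, replace = TRUE)
    data.frame(n_parts = x,
               mean_part_size = 100 * x^(-0.3) * exp(rnorm(200, 0, 0.2)))
  })
  b_hat <- menzerath_fit(d_noisy)$b
  expect_gt(b_hat, -0.45)
  expect_lt(b_hat, -0.15)

  expect_error(menzerath_fit(data.frame(n_parts = c(1, 1, 2, 2),
                                        mean_part_size = c(4, 5, 3, 2))),
               "5 distinct")

  # feature-list interface: intervals act as parts
  feats <- lapply(1:8, function(i) {
    size <- round(100 * i^(-0.5))
    starts <- seq(0, by = size + 10, length.out = i)
    genolex:::new_feature("CDS", "+", cbind(starts, starts + size))
  })
  fit_f <- menzerath_fit(feats)
  expect_lt(fit_f$b, 0)
  expect_lt(fit_f$spearman_rho, 0)
})
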