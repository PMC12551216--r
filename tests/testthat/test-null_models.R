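test_that("permutation conserves composition and is seeded", {
  s <- gen_iid(length = 2000, seed = 1)
  p1 <- permute_sequence(s, seed = 10)
  p2 <- permute_sequence(s, seed = 10)
  expect_identical(p1, p2)
  expect_false(identical(p1, permute_sequence(s, seed = 11)))
  expect_equal(sort(strsplit(p1, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_identical(permute_sequence("AAAA", 3), "AAAA")
})

test_that("Markov fitting recovers transition structure", {
  m1 <- fit_markov("AAAA", 1)
  expect_equal(m1$transition["A", "A"], 1)
  expect_true("C" %in% m1$unseen_contexts)

  m2 <- fit_markov("ACACAC", 1)
  expect_equal(m2$transition["A", "C"], 1)
  expect_equal(m2$transition["C", "A"], 1)

  expect_error(fit_markov("ACGT", 3), "order")
  expect_error(fit_markov("A", 1), "shorter")

  # long sample from a known order-1 matrix: rows recovered within 0.01
  trans <- matrix(c(0.5, 0.2, 0.2, 0.1,
                    0.1, 0.6, 0.2, 0.1,
                    0.3, 0.3, 0.2, 0.2,
                    0.25, 0.25, 0.25, 0.25), 4, 4, byrow = TRUE,
                  dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  model <- structure(list(order = 1L, transition = trans,
                          initial = setNames(rep(0.25, 4), rownames(trans)),
                          unseen_contexts = character(0)),
                     class = "markov_model")
  s <- sample_markov(model, 2e5, seed = 77)
  fitted <- fit_markov(s, 1)
  expect_lt(max(abs(fitted$transition - trans)), 0.01)
})

test_that("Markov sampling is seeded and preserves k-mer structure", {
  m <- fit_markov(gen_zipf_motifs(16, 4, 1.5, 50000, seed = 4), 2)
  s1 <- sample_markov(m, 5000, seed = 5)
  expect_identical(s1, sample_markov(m, 5000, seed = 5))
  expect_equal(nchar(s1), 5000L)

  # deterministic chain
  det <- structure(list(order = 1L,
                        transition = matrix(c(1, 0, 0, 0), 4, 4,
                                            dimnames = list(c("A","C","G","T"),
                                                            c("A","C","G","T"))),
                        initial = c(A = 1, C = 0, G = 0, T = 0),
                        unseen_contexts = character(0)),
                   class = "markov_model")
  expect_identical(sample_markov(det, 8, seed = 1), "AAAAAAAA")

  # fit -> sample round trip preserves 2-mer frequencies
  src <- gen_iid(c(A = 0.4, C = 0.3, G = 0.2, T = 0.1), 2e5, seed = 6)
  m1 <- fit_markov(src, 1)
  out <- sample_markov(m1, 2e5, seed = 7)
  f_src <- count_kmers(src, 2)$counts / (2e5 - 1)
  f_out <- count_kmers(out, 2)$counts / (2e5 - 1)
  all_tok <- union(names(f_src), names(f_out))
  expect_lt(max(abs(setNames(f_src[all_tok], all_tok) -
                    setNames(f_out[all_tok], all_tok)), na.rm = TRUE), 0.01)
})

test_that("null comparison yields add-one empirical p-values", {
  # 4-bp motifs with moderately skewed usage: 3-mer structure beyond
  # first-order dependencies, but the fitted chain is not degenerate
  s <- gen_zipf_motifs(32, 4, 1.2, 10000, seed = 8)
  res <- null_compare(s, "zeta_ols", null = "markov1", n = 99, seed = 9)
  expect_lte(res$p_empirical, 0.05)   # structured sequence beats its Markov null
  expect_gt(res$p_empirical, 0)
  expect_length(res$null_values, 99)

  # determinism under seed
  res2 <- null_compare(s, "zeta_ols", null = "markov1", n = 99, seed = 9)
  expect_identical(res$null_values, res2$null_values)

  # minimal n with the add-one rule: p can never be 0, smallest is 1/(n+1)
  iid <- gen_iid(length = 2000, seed = 10)
  res3 <- null_compare(iid, "entropy_k", null = "permute", n = 19, seed = 11)
  expect_gte(res3$p_empirical, 1 / 20)
  expect_lte(res3$p_empirical, 1)

  expect_error(null_compare(iid, "nope", n = 19), "unknown statistic")
  expect_error(null_compare(iid, "entropy_k", n = 5), "19")
})

test_that("markov1 sampling conserves base composition in expectation", {
  src <- gen_iid(c(A = 0.4, C = 0.2, G = 0.2, T = 0.2), 5e4, seed = 12)
  m <- fit_markov(src, 1)
  out <- sample_markov(m, 5e4, seed = 13)
  p_src <- table(factor(strsplit(src, "")[[1]], levels = c("A","C","G","T"))) / 5e4
  p_out <- table(factor(strsplit(out, "")[[1]], levels = c("A","C","G","T"))) / 5e4
  se <- sqrt(p_src * (1 - p_src) / 5e4)
  expect_true(all(abs(p_out - p_src) < 3 * se + 1e-3))
})
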