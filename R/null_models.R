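# Permutation and Markov-chain null models with empirical p-values.

BASES <- c("A", "C", "G", "T")

#' Randomly permute a sequence
#'
#' Uniform random permutation of the symbols; composition is conserved
#' exactly.
#'
#' @param sequence Character scalar.
#' @param seed Integer seed.
#' @return Permuted character scalar.
#' @export
permute_sequence <- function(sequence, seed) {
  sym <- strsplit(sequence, "")[[1]]
  if (length(sym) == 0) stop("empty sequence")
  paste(with_seed(seed, sample(sym)), collapse = "")
}

#' Fit a first- or second-order Markov chain to a sequence
#'
#' Maximum-likelihood transition frequencies over contexts of length
#' \code{order}. Contexts never observed get a uniform row and are
#' flagged. Symbols outside \{A,C,G,T\} break the context chain (no
#' transition is counted across them).
#'
#' @param sequence Character scalar (length > order).
#' @param order 1 or 2.
#' @return A \code{markov_model} with \code{order}, \code{transition}
#'   (contexts x 4 row-stochastic matrix), \code{initial} (distribution
#'   over contexts), \code{unseen_contexts}.
#' @export
fit_markov <- function(sequence, order) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  seq <- toupper(sequence)
  if (nchar(seq) <= order) stop("sequence shorter than order + 1")
  sym <- strsplit(seq, "")[[1]]
  ok <- sym %in% BASES
  contexts <- do.call(paste0, expand.grid(rep(list(BASES), order),
                                          stringsAsFactors = FALSE)[, order:1, drop = FALSE])
  contexts <- sort(contexts)
  n <- length(sym)
  # context string ending at position i, next symbol at i+1
  ctx <- substring(seq, seq_len(n - order), seq_len(n - order) + order - 1L)
  nxt <- sym[(order + 1L):n]
  valid <- nxt %in% BASES & ctx %in% contexts
  tab <- table(factor(ctx[valid], levels = contexts),
               factor(nxt[valid], levels = BASES))
  counts <- matrix(as.numeric(tab), nrow = length(contexts),
                   dimnames = list(contexts, BASES))
  rs <- rowSums(counts)
  unseen <- rownames(counts)[rs == 0]
  trans <- counts / ifelse(rs == 0, 1, rs)
  trans[rs == 0, ] <- 1 / 4
  ctx_valid <- ctx[ctx %in% contexts]
  init <- table(factor(ctx_valid, levels = contexts))
  init <- as.numeric(init) / sum(init)
  names(init) <- contexts
  structure(list(order = as.integer(order), transition = trans,
                 initial = init, unseen_contexts = unseen),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> order", x$order, "-", nrow(x$transition), "contexts",
      if (length(x$unseen_contexts))
        paste0("(", length(x$unseen_contexts), " unseen, uniform rows)"),
      "\n")
  invisible(x)
}

#' Sample a sequence from a Markov model
#'
#' Seeded generation; the initial context is drawn from the model's
#' initial (observed-context) distribution.
#'
#' @param model A \code{markov_model}.
#' @param length Output length in symbols (> order).
#' @param seed Integer seed.
#' @return Character scalar of the requested length.
#' @export
sample_markov <- function(model, length, seed) {
  ord <- model$order
  stopifnot(length > ord)
  trans <- model$transition
  contexts <- rownames(trans)
  with_seed(seed, {
    ctx <- sample(contexts, 1, prob = model$initial)
    out <- character(length)
    out[seq_len(ord)] <- strsplit(ctx, "")[[1]]
    # pre-draw uniforms and walk the chain via cumulative rows
    cum <- t(apply(trans, 1, cumsum))
    u <- runif(length - ord)
    ci <- match(ctx, contexts)
    for (i in (ord + 1L):length) {
      s <- BASES[findInterval(u[i - ord], cum[ci, ], left.open = TRUE) + 1L]
      out[i] <- s
      nctx <- if (ord == 1) s else paste0(substring(ctx, 2), s)
      ctx <- nctx
      ci <- match(ctx, contexts)
    }
    paste(out, collapse = "")
  })
}

# Named statistics usable in null comparisons. Each entry: the function
# of a sequence, and the one-sided direction in which the observed value
# is deemed "more structured than null".
null_statistics <- function(k = 3L) {
  list(
    zeta_ols = list(
      fun = function(s) fit_zipf_ols(rank_frequency(count_kmers(s, k)))$zeta,
      direction = "greater"),
    hurst_dfa = list(
      fun = function(s) dfa(build_walk(s))$H,
      direction = "greater"),
    entropy_k = list(
      fun = function(s) block_entropy(s, k)$H_bits,
      direction = "less")
  )
}

#' Compare a statistic against a null ensemble
#'
#' Computes a named statistic on the observed sequence and on \code{n}
#' seeded null replicates (random permutation, or sequences sampled from
#' a first- or second-order Markov chain fitted to the observation), and
#' returns the add-one empirical p-value
#' \eqn{p = (\#\{null \ge obs\} + 1)/(n + 1)} (direction per statistic:
#' \code{zeta_ols} and \code{hurst_dfa} test for larger-than-null,
#' \code{entropy_k} for smaller-than-null).
#'
#' @param sequence Character scalar.
#' @param statistic One of \code{"zeta_ols"}, \code{"hurst_dfa"},
#'   \code{"entropy_k"}.
#' @param null One of \code{"permute"}, \code{"markov1"},
#'   \code{"markov2"}.
#' @param n Number of null replicates (>= 19).
#' @param seed Integer seed.
#' @param k Token length for the k-mer based statistics.
#' @return A \code{null_ensemble_result} with \code{observed},
#'   \code{null_values}, \code{p_empirical}, \code{direction}, \code{n},
#'   \code{seed}.
#' @export
null_compare <- function(sequence, statistic, null = c("permute", "markov1", "markov2"),
                         n = 99, seed = 1L, k = 3L) {
  null <- match.arg(null)
  stats_reg <- null_statistics(k)
  if (!statistic %in% names(stats_reg))
    stop("unknown statistic '", statistic, "'; available: ",
         paste(names(stats_reg), collapse = ", "))
  if (n < 19) stop("need at least 19 null replicates")
  st <- stats_reg[[statistic]]
  observed <- st$fun(sequence)
  model <- switch(null, permute = NULL,
                  markov1 = fit_markov(sequence, 1L),
                  markov2 = fit_markov(sequence, 2L))
  len <- nchar(sequence)
  null_values <- vapply(seq_len(n), function(i) {
    si <- child_seed(seed, i)
    rep_seq <- if (null == "permute") permute_sequence(sequence, si)
               else sample_markov(model, len, si)
    st$fun(rep_seq)
  }, numeric(1))
  p <- if (st$direction == "greater") (sum(null_values >= observed) + 1) / (n + 1)
       else (sum(null_values <= observed) + 1) / (n + 1)
  structure(list(statistic = statistic, observed = observed,
                 null_values = null_values, p_empirical = p,
                 direction = st$direction, null_type = null,
                 n = n, seed = seed),
            class = "null_ensemble_result")
}

#' @export
print.null_ensemble_result <- function(x, ...) {
  cat(sprintf("<null_ensemble_result> %s = %.4f vs %s null (n = %d): p = %.4f (%s)\n",
              x$statistic, x$observed, x$null_type, x$n, x$p_empirical,
              x$direction))
  invisible(x)
}
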