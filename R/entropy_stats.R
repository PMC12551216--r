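# Shannon entropy, block entropy and redundancy of nucleotide sequences.

new_entropy_report <- function(H_bits, k, n_tokens, estimator,
                               alphabet_size = 4) {
  H_per_symbol <- H_bits / k
  structure(list(order_k = as.integer(k),
                 H_bits = H_bits,
                 H_per_symbol = H_per_symbol,
                 redundancy = 1 - H_per_symbol / log2(alphabet_size),
                 n_tokens = n_tokens,
                 estimator = estimator,
                 alphabet_size = alphabet_size),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("<entropy_report> k = %d: H = %.4f bits (%.4f bits/symbol), redundancy = %.4f (%s, n = %d)\n",
              x$order_k, x$H_bits, x$H_per_symbol, x$redundancy,
              x$estimator, x$n_tokens))
  invisible(x)
}

#' Shannon entropy of a count table
#'
#' Plug-in estimator \eqn{H = -\sum_i p_i \log_2 p_i} over observed
#' tokens; zero-count tokens contribute nothing. The Miller-Madow
#' correction adds \eqn{(V - 1) / (2 n \ln 2)} for the downward bias of
#' the plug-in estimator at small samples.
#'
#' @param counts Named (or plain) non-negative numeric vector of token
#'   counts, or a \code{kmer_spectrum}.
#' @param k Block length represented by each token (default: inferred
#'   from a spectrum, else 1).
#' @param estimator \code{"plugin"} (default) or \code{"miller_madow"}.
#' @return An \code{entropy_report} with \code{H_bits},
#'   \code{H_per_symbol}, \code{redundancy} (relative to the 2-bit
#'   4-letter alphabet maximum), \code{n_tokens}.
#' @examples
#' shannon_entropy(c(A = 1, C = 1, G = 1, T = 1))  # 2 bits
#' @export
shannon_entropy <- function(counts, k = NULL,
                            estimator = c("plugin", "miller_madow")) {
  estimator <- match.arg(estimator)
  if (inherits(counts, "kmer_spectrum")) {
    k <- k %||% counts$k
    counts <- counts$counts
  }
  k <- k %||% 1L
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  p <- counts[counts > 0] / total
  H <- -sum(p * log2(p))
  if (estimator == "miller_madow")
    H <- H + (length(p) - 1) / (2 * total * log(2))
  new_entropy_report(H, k, as.integer(total), estimator)
}

#' Block entropy of sequence segments
#'
#' Entropy of the k-mer spectrum counted with \code{\link{count_kmers}};
#' \code{H_per_symbol = H_bits / k} and redundancy is taken against the
#' 2 bits/symbol maximum of the 4-letter alphabet.
#'
#' @param segments Character vector of sequence segments.
#' @param k Block length.
#' @param step Window step (see \code{\link{count_kmers}}).
#' @param estimator Passed to \code{\link{shannon_entropy}}.
#' @return An \code{entropy_report}.
#' @export
block_entropy <- function(segments, k, step = 1L,
                          estimator = c("plugin", "miller_madow")) {
  sp <- count_kmers(segments, k, step)
  if (sp$total_tokens == 0) stop("empty spectrum at k = ", k)
  shannon_entropy(sp, estimator = match.arg(estimator))
}

#' Block-entropy ladder and conditional entropy rate
#'
#' Computes block entropies \eqn{H_k} for \eqn{k = 1..k_{max}} and the
#' differenced rate \eqn{h_k = H_k - H_{k-1}} (bits per symbol of new
#' information given a context of \eqn{k-1} symbols), with \eqn{h_1 =
#' H_1}. Plug-in \eqn{h_k} is non-increasing in expectation; observed
#' increases are flagged as undersampling.
#'
#' @param segments Character vector of segments.
#' @param k_max Largest block length (>= 2).
#' @param step Window step for counting.
#' @return A list with \code{reports} (one \code{entropy_report} per k),
#'   \code{h_k} (numeric vector), and \code{undersampled} (logical:
#'   any \eqn{h_k} increase).
#' @export
entropy_rate_estimate <- function(segments, k_max, step = 1L) {
  stopifnot(k_max >= 2)
  reports <- lapply(seq_len(k_max), function(k) block_entropy(segments, k, step))
  Hk <- vapply(reports, `[[`, numeric(1), "H_bits")
  hk <- c(Hk[1], diff(Hk))
  undersampled <- any(diff(hk) > 1e-9)
  if (undersampled)
    warning("conditional entropy rate not monotone non-increasing; ",
            "larger blocks are undersampled")
  list(reports = reports, h_k = hk, undersampled = undersampled)
}
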