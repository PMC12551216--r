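# Heaps' law vocabulary growth, Zipf's law of abbreviation and
# Menzerath's law on sequences and annotations.

#' Heaps' law vocabulary-growth curve
#'
#' Streams the k-mer tokens of the segments (overlapping windows, each
#' segment independently; windows with ambiguity codes skipped), counts
#' the cumulative number of distinct types at log-spaced checkpoints,
#' and fits \eqn{V = K n^\beta} by OLS on logs over the pre-saturation
#' range (checkpoints where fewer than \eqn{4^k} types are seen).
#'
#' @param segments Character vector of segments.
#' @param k Token length.
#' @param n_points Number of log-spaced checkpoints.
#' @param seed Integer seed; segments are streamed in a seeded random
#'   order so the curve does not depend on an arbitrary input ordering.
#' @return A \code{heaps_curve} with \code{sample_points} (data frame:
#'   tokens_seen, distinct_types), \code{K}, \code{beta} (NA when the
#'   vocabulary is saturated at every checkpoint), \code{k}.
#' @export
heaps_curve <- function(segments, k, n_points = 25L, seed = 1L) {
  segments <- segments[nchar(segments) >= k]
  if (length(segments) == 0) stop("no segment of length >= k")
  ord <- with_seed(seed, sample(length(segments)))
  tokens <- unlist(lapply(segments[ord], function(s) {
    n <- nchar(s)
    tok <- substring(s, 1:(n - k + 1), k:n)
    tok[!grepl("[^ACGT]", tok)]
  }), use.names = FALSE)
  n_tok <- length(tokens)
  if (n_tok < n_points) stop("fewer tokens than checkpoints")
  v_cum <- cumsum(!duplicated(tokens))
  checkpoints <- unique(round(exp(seq(log(10), log(n_tok),
                                      length.out = n_points))))
  checkpoints <- checkpoints[checkpoints >= 1 & checkpoints <= n_tok]
  pts <- data.frame(tokens_seen = checkpoints,
                    distinct_types = v_cum[checkpoints])
  unsat <- pts$distinct_types < 4^k
  K <- beta <- NA_real_
  if (sum(unsat) >= 3) {
    fit <- lm(log(distinct_types) ~ log(tokens_seen), data = pts[unsat, ])
    K <- exp(unname(coef(fit)[1]))
    beta <- unname(coef(fit)[2])
  } else {
    warning("vocabulary saturated at nearly all checkpoints; no Heaps fit")
  }
  structure(list(sample_points = pts, K = K, beta = beta, k = as.integer(k)),
            class = "heaps_curve")
}

#' @export
print.heaps_curve <- function(x, ...) {
  cat(sprintf("<heaps_curve> k = %d, %d checkpoints; V = %.3g * n^%.3f\n",
              x$k, nrow(x$sample_points), x$K, x$beta))
  invisible(x)
}

#' Zipf's law of abbreviation across token lengths
#'
#' For each k-mer spectrum, the top-\code{m} tokens are scored by their
#' enrichment over the uniform expectation for their length,
#' \eqn{\log_2(4^k \cdot relfreq)}, which makes frequencies of different
#' token lengths commensurate. The report is the Spearman correlation
#' between token length and enrichment over the pooled top tokens; a
#' negative correlation (long tokens relatively less used) is the
#' abbreviation effect.
#'
#' @param spectra List of \code{kmer_spectrum} objects over at least two
#'   distinct k.
#' @param m Number of top-ranked tokens used per spectrum.
#' @return An \code{abbreviation_report} with \code{rho}, \code{p_value}
#'   and the pooled \code{points} (k, token, enrichment_log2).
#' @export
abbreviation_correlation <- function(spectra, m = 20L) {
  ks <- vapply(spectra, `[[`, integer(1), "k")
  if (length(unique(ks)) < 2) stop("need spectra at >= 2 distinct k")
  pts <- do.call(rbind, lapply(spectra, function(sp) {
    tab <- rank_frequency(sp)
    mm <- min(m, nrow(tab))
    if (mm < m) warning("only ", mm, " tokens available at k = ", sp$k)
    top <- tab[seq_len(mm), ]
    data.frame(k = sp$k, token = top$token,
               enrichment_log2 = log2(4^sp$k * top$rel_freq))
  }))
  if (nrow(pts) < 3) stop("insufficient data for a correlation")
  ct <- suppressWarnings(stats::cor.test(pts$k, pts$enrichment_log2,
                                         method = "spearman"))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 points = pts, m = m),
            class = "abbreviation_report")
}

#' @export
print.abbreviation_report <- function(x, ...) {
  cat(sprintf("<abbreviation_report> Spearman rho = %.3f (p = %.3g) over %d points\n",
              x$rho, x$p_value, nrow(x$points)))
  invisible(x)
}

#' Menzerath's law fit over multi-part constructs
#'
#' For each construct (e.g. a joined multi-interval CDS feature, whose
#' intervals act as exon-like parts), takes \eqn{x =} number of parts
#' and \eqn{y =} mean part length in bp, and fits \eqn{y = a x^b} by OLS
#' on logs. Menzerath's law predicts \eqn{b < 0}: constructs with more
#' parts have shorter parts.
#'
#' @param constructs Either a list of features (parts = their intervals)
#'   or a data frame with columns \code{n_parts} and
#'   \code{mean_part_size}.
#' @return A \code{menzerath_fit} with \code{a}, \code{b},
#'   \code{spearman_rho}, \code{pairs}.
#' @export
menzerath_fit <- function(constructs) {
  d <- if (is.data.frame(constructs)) constructs
  else do.call(rbind, lapply(constructs, function(f) {
    widths <- f$intervals[, 2] - f$intervals[, 1]
    data.frame(n_parts = nrow(f$intervals), mean_part_size = mean(widths))
  }))
  stopifnot(all(c("n_parts", "mean_part_size") %in% names(d)))
  if (length(unique(d$n_parts)) < 5)
    stop("need constructs with >= 5 distinct part counts")
  fit <- lm(log(mean_part_size) ~ log(n_parts), data = d)
  rho <- suppressWarnings(cor(d$n_parts, d$mean_part_size,
                              method = "spearman"))
  structure(list(a = exp(unname(coef(fit)[1])), b = unname(coef(fit)[2]),
                 spearman_rho = rho, pairs = d),
            class = "menzerath_fit")
}

#' @export
print.menzerath_fit <- function(x, ...) {
  cat(sprintf("<menzerath_fit> y = %.3g * x^%.3f (Spearman rho = %.3f, %d constructs)\n",
              x$a, x$b, x$spearman_rho, nrow(x$pairs)))
  invisible(x)
}
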