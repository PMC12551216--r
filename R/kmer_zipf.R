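# k-mer spectra, rank-frequency tables and Zipf-exponent OLS fits.

#' Count k-mers over sequence segments
#'
#' Slides a window of width \code{k} within each segment independently
#' (no tokens span segment junctions). Windows containing any symbol
#' outside \{A,C,G,T\} are skipped and tallied in \code{skipped_windows}.
#'
#' @param segments Character vector of sequence segments.
#' @param k Token length (>= 1).
#' @param step Window step; 1 (default) counts overlapping windows,
#'   \code{step = k} counts non-overlapping blocks.
#' @return A \code{kmer_spectrum}: named integer vector \code{counts}
#'   (only tokens with count > 0), plus \code{k}, \code{step},
#'   \code{total_tokens}, \code{skipped_windows}, \code{n_segments}.
#' @examples
#' count_kmers("ACGTACGT", k = 3)
#' @export
count_kmers <- function(segments, k, step = 1L) {
  stopifnot(k >= 1, step >= 1)
  segments <- toupper(segments[nchar(segments) > 0])
  if (length(segments) == 0 || max(nchar(segments)) < k) {
    warning("no segment of length >= k = ", k, "; empty spectrum")
    return(new_kmer_spectrum(integer(0), k, step, 0L, 0L, length(segments)))
  }
  segs <- Biostrings::DNAStringSet(segments)
  counts <- Biostrings::oligonucleotideFrequency(segs, width = k, step = step)
  total_counts <- colSums(counts)
  n_windows <- sum(pmax(0L, (nchar(segments) - k) %/% step + 1L))
  total <- sum(total_counts)
  new_kmer_spectrum(total_counts[total_counts > 0], k, as.integer(step),
                    as.integer(total), as.integer(n_windows - total),
                    length(segments))
}

new_kmer_spectrum <- function(counts, k, step, total, skipped, n_segments) {
  structure(list(counts = counts, k = as.integer(k), step = as.integer(step),
                 total_tokens = total, skipped_windows = skipped,
                 n_segments = n_segments),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("<kmer_spectrum> k =", x$k, "step =", x$step, ":",
      length(x$counts), "distinct tokens,",
      x$total_tokens, "total,", x$skipped_windows, "skipped\n")
  invisible(x)
}

#' Build a rank-frequency table from a k-mer spectrum
#'
#' Sorts tokens by count descending, ties broken by lexicographic token
#' order, and assigns consecutive ranks from 1.
#'
#' @param spectrum A \code{kmer_spectrum} with \code{total_tokens > 0},
#'   or a named count vector.
#' @return A data frame of class \code{rank_frequency_table} with columns
#'   \code{rank}, \code{token}, \code{count}, \code{rel_freq}.
#' @export
rank_frequency <- function(spectrum) {
  counts <- if (inherits(spectrum, "kmer_spectrum")) spectrum$counts else spectrum
  if (length(counts) == 0 || sum(counts) == 0) stop("empty spectrum")
  o <- order(-counts, names(counts))
  counts <- counts[o]
  d <- data.frame(rank = seq_along(counts), token = names(counts),
                  count = as.integer(counts),
                  rel_freq = as.numeric(counts) / sum(counts),
                  stringsAsFactors = FALSE, row.names = NULL)
  class(d) <- c("rank_frequency_table", "data.frame")
  d
}

#' Fit the Zipf exponent by OLS on log-log axes
#'
#' Ordinary least squares of log10 relative frequency on log10 rank;
#' the Zipf exponent is reported as the positive magnitude
#' \eqn{\zeta = -slope}. The slope is identical whether raw counts or
#' relative frequencies are used.
#'
#' @param table A \code{rank_frequency_table}.
#' @param rank_range Optional \code{c(lo, hi)} restricting the ranks
#'   used; default all ranks with count > 0.
#' @return A \code{zipf_ols_fit} with \code{zeta}, \code{intercept},
#'   \code{r_squared}, \code{rank_range}, \code{n_points}.
#' @export
fit_zipf_ols <- function(table, rank_range = NULL) {
  d <- table[table$count > 0, ]
  if (!is.null(rank_range))
    d <- d[d$rank >= rank_range[1] & d$rank <= rank_range[2], ]
  if (nrow(d) < 3) stop("need at least 3 ranks with positive counts")
  x <- log10(d$rank)
  y <- log10(d$rel_freq)
  fit <- lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 1e-28) NA_real_ else 1 - sum(fit$residuals^2) / tss
  structure(list(zeta = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 rank_range = c(min(d$rank), max(d$rank)),
                 n_points = nrow(d)),
            class = "zipf_ols_fit")
}

#' @export
print.zipf_ols_fit <- function(x, ...) {
  cat(sprintf("<zipf_ols_fit> zeta = %.4f  r^2 = %.4f  ranks [%d, %d]\n",
              x$zeta, x$r_squared, x$rank_range[1], x$rank_range[2]))
  invisible(x)
}

#' Paired Zipf report for coding vs non-coding tables
#'
#' The machine-readable surface of a two-class log-log Zipf plot: the
#' (log10 rank, log10 frequency) point sets for each region class
#' together with their OLS fits.
#'
#' @param coding_table,noncoding_table Rank-frequency tables; either may
#'   be NULL for a partial (single-class) report.
#' @return A \code{zipf_report} list with per-class \code{points}
#'   (data frame: rank, count, rel_freq, log10_rank, log10_rel_freq,
#'   log10_count) and \code{fit}.
#' @export
zipf_report <- function(coding_table = NULL, noncoding_table = NULL) {
  if (is.null(coding_table) && is.null(noncoding_table))
    stop("at least one table required")
  one <- function(tab) {
    if (is.null(tab)) return(NULL)
    pts <- data.frame(rank = tab$rank, count = tab$count,
                      rel_freq = tab$rel_freq,
                      log10_rank = log10(tab$rank),
                      log10_rel_freq = log10(tab$rel_freq),
                      log10_count = log10(tab$count))
    list(points = pts, fit = fit_zipf_ols(tab))
  }
  structure(list(coding = one(coding_table), noncoding = one(noncoding_table)),
            class = "zipf_report")
}

#' Write a rank-frequency table as TSV
#'
#' @param table A \code{rank_frequency_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_rank_frequency_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
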