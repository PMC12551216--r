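# Seeded generators: iid and Markov sequences, Zipf-distributed motif
# concatenations, long-range-correlated symbolic sequences, and fully
# annotated toy genomes with ground-truth sidecars.

#' Generate an iid nucleotide sequence
#'
#' @param composition Probabilities for A, C, G, T (must sum to 1).
#' @param length Sequence length in bp.
#' @param seed Integer seed.
#' @return Character scalar.
#' @export
gen_iid <- function(composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    length, seed) {
  composition <- composition[BASES]
  if (any(is.na(composition)) || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9)
    stop("composition must be non-negative probabilities for A,C,G,T summing to 1")
  with_seed(seed, paste(sample(BASES, length, replace = TRUE,
                               prob = composition), collapse = ""))
}

#' Generate a motif-concatenation sequence with Zipf-distributed usage
#'
#' Builds a fixed random vocabulary of \code{V} motifs of length
#' \code{L} (derived deterministically from the seed) and concatenates
#' motifs drawn with probability proportional to \eqn{rank^{-s}}. With
#' \eqn{s > 0} the output has a power-law k-mer spectrum and low block
#' entropy, emulating the statistics attributed to non-coding DNA.
#'
#' @param V Vocabulary size.
#' @param L Motif length in bp.
#' @param s Zipf exponent of motif usage (>= 0; 0 = uniform usage).
#' @param length Output length in bp (last motif truncated as needed).
#' @param seed Integer seed.
#' @return Character scalar of exactly \code{length} bp.
#' @export
gen_zipf_motifs <- function(V, L, s, length, seed) {
  stopifnot(V >= 1, L >= 1, s >= 0, length >= 1)
  with_seed(seed, {
    vocab <- vapply(seq_len(V), function(i)
      paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
    prob <- seq_len(V)^(-s)
    n_mot <- ceiling(length / L)
    draws <- sample(V, n_mot, replace = TRUE, prob = prob)
    substr(paste(vocab[draws], collapse = ""), 1, length)
  })
}

# Fractional Gaussian noise of Hurst index H via circulant embedding
# (Davies-Harte). The fGn autocovariance embeds in a non-negative
# definite circulant for all H in (0,1).
fgn_davies_harte <- function(H, n, seed) {
  m <- n
  gamma_k <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                                abs(k - 1)^(2 * H))
  g <- gamma_k(0:m)
  circ <- c(g, g[m:2])                 # length 2m
  lambda <- Re(fft(circ))
  lambda[lambda < 0] <- 0              # clip tiny negative rounding error
  with_seed(seed, {
    z <- complex(real = rnorm(2 * m), imaginary = rnorm(2 * m))
    w <- sqrt(lambda / (4 * m)) * z
    Re(fft(w))[seq_len(n)] * sqrt(2)
  })
}

#' Generate a long-range-correlated nucleotide sequence
#'
#' Synthesizes fractional Gaussian noise with the target Hurst index,
#' thresholds it at its median into +1/-1 steps, and maps +1 to a purine
#' (A or G, equiprobable) and -1 to a pyrimidine (C or T). The
#' dichotomization attenuates the measured scaling exponent slightly
#' below the Gaussian target for large H.
#'
#' @param H_target Hurst index in (0, 1).
#' @param length Sequence length in bp.
#' @param seed Integer seed.
#' @return Character scalar.
#' @export
gen_correlated <- function(H_target, length, seed) {
  if (H_target <= 0 || H_target >= 1) stop("H_target must be in (0, 1)")
  x <- fgn_davies_harte(H_target, length, seed)
  up <- x > median(x)
  letters_up <- with_seed(child_seed(seed, 1),
                          sample(c("A", "G"), length, replace = TRUE))
  letters_dn <- with_seed(child_seed(seed, 2),
                          sample(c("C", "T"), length, replace = TRUE))
  paste(ifelse(up, letters_up, letters_dn), collapse = "")
}

#' Specification of a synthetic annotated toy genome
#'
#' Describes an alternating layout of coding-like blocks (iid uniform,
#' high entropy, uncorrelated) and non-coding-like blocks (Zipf motif
#' concatenations and/or long-range-correlated sequence: low entropy,
#' power-law k-mer spectrum).
#'
#' @param n_blocks Number of alternating blocks (coding first).
#' @param block_length Length of each block in bp.
#' @param noncoding_kind \code{"zipf_motifs"}, \code{"correlated"} or
#'   \code{"mixed"} (motif blocks and correlated blocks alternate).
#' @param V,L,s Motif vocabulary size, motif length and usage exponent
#'   for motif blocks.
#' @param H_target Hurst index for correlated blocks.
#' @param seed Integer seed.
#' @return A \code{toy_genome_spec} list (serializable to JSON).
#' @export
toy_genome_spec <- function(n_blocks = 10L, block_length = 5000L,
                            noncoding_kind = "zipf_motifs",
                            V = 64L, L = 3L, s = 1.2, H_target = 0.8,
                            seed = 1L) {
  stopifnot(n_blocks >= 2, block_length >= 100,
            noncoding_kind %in% c("zipf_motifs", "correlated", "mixed"))
  structure(list(kind = "toy_genome", n_blocks = as.integer(n_blocks),
                 block_length = as.integer(block_length),
                 noncoding_kind = noncoding_kind,
                 V = as.integer(V), L = as.integer(L), s = s,
                 H_target = H_target, seed = as.integer(seed)),
            class = "toy_genome_spec")
}

#' Generate an annotated toy genome
#'
#' Emits a FASTA sequence and GFF3 features marking the coding-like
#' blocks as CDS, plus a ground-truth JSON sidecar holding the generator
#' spec and the exact block layout. Every output is a pure function of
#' the spec (which includes the seed).
#'
#' @param spec A \code{toy_genome_spec}.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return List with \code{fasta}, \code{gff3}, \code{sidecar} paths,
#'   the \code{record}, \code{features}, and \code{truth} (block table).
#' @export
gen_toy_genome <- function(spec, dir = tempfile("toygenome"),
                           prefix = "toy") {
  stopifnot(inherits(spec, "toy_genome_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bl <- spec$block_length
  blocks <- lapply(seq_len(spec$n_blocks), function(i) {
    si <- child_seed(spec$seed, i)
    coding <- i %% 2L == 1L
    kind <- if (coding) "iid" else switch(spec$noncoding_kind,
      zipf_motifs = "zipf_motifs", correlated = "correlated",
      mixed = if ((i %/% 2L) %% 2L == 0L) "zipf_motifs" else "correlated")
    seq <- switch(kind,
      iid = gen_iid(length = bl, seed = si),
      zipf_motifs = gen_zipf_motifs(spec$V, spec$L, spec$s, bl, si),
      correlated = gen_correlated(spec$H_target, bl, si))
    list(coding = coding, kind = kind, seq = seq)
  })
  starts <- cumsum(c(0L, rep(bl, spec$n_blocks - 1L)))
  truth <- data.frame(block = seq_len(spec$n_blocks),
                      start = starts, end = starts + bl,
                      coding = vapply(blocks, `[[`, logical(1), "coding"),
                      kind = vapply(blocks, `[[`, character(1), "kind"))
  sequence <- paste(vapply(blocks, `[[`, character(1), "seq"), collapse = "")
  record <- genome_record(paste0(prefix, "_genome"), sequence)

  cds <- which(truth$coding)
  features <- lapply(seq_along(cds), function(j) {
    i <- cds[j]
    new_feature("CDS", "+", cbind(truth$start[i], truth$end[i]),
                list(ID = sprintf("cds%03d", j)))
  })

  fasta <- file.path(dir, paste0(prefix, ".fa"))
  ss <- Biostrings::DNAStringSet(sequence)
  names(ss) <- record$id
  Biostrings::writeXStringSet(ss, fasta)
  gff3 <- file.path(dir, paste0(prefix, ".gff3"))
  write_features_gff3(features, record$id, gff3)
  sidecar <- file.path(dir, paste0(prefix, ".truth.json"))
  jsonlite::write_json(list(spec = unclass(spec), blocks = truth),
                       sidecar, auto_unbox = TRUE, digits = NA)
  list(fasta = fasta, gff3 = gff3, sidecar = sidecar,
       record = record, features = features, truth = truth, spec = spec)
}

#' Read a toy-genome ground-truth sidecar
#'
#' @param path Path to the JSON sidecar written by
#'   \code{\link{gen_toy_genome}}.
#' @return List with the reconstructed \code{spec}
#'   (\code{toy_genome_spec}) and \code{blocks} data frame.
#' @export
read_toy_genome_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- x$spec
  spec <- toy_genome_spec(n_blocks = sp$n_blocks,
                          block_length = sp$block_length,
                          noncoding_kind = sp$noncoding_kind,
                          V = sp$V, L = sp$L, s = sp$s,
                          H_target = sp$H_target, seed = sp$seed)
  list(spec = spec, blocks = x$blocks)
}
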