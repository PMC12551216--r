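# Fixtures built in code: tiny FASTA/GenBank files and exact tables.

write_tmp_fasta <- function(lines, ext = ".fa") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Minimal GenBank flat file with a given locus length and feature lines.
# feature_lines: character vector already formatted as the FEATURES table
# body (key at column 6, location at column 22).
write_tmp_genbank <- function(length_bp, feature_lines,
                              sequence = strrep("a", length_bp)) {
  f <- tempfile(fileext = ".gb")
  origin <- paste0("        1 ", substr(sequence, 1, min(60, nchar(sequence))))
  writeLines(c(
    sprintf("LOCUS       TESTSEQ    %d bp    DNA     linear   UNA 01-JAN-2000",
            length_bp),
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    feature_lines,
    "ORIGIN",
    origin,
    "//"), f)
  f
}

gb_feature <- function(key, location, qualifiers = character(0)) {
  c(sprintf("     %-16s%s", key, location),
    if (length(qualifiers)) sprintf("                     %s", qualifiers))
}

# Rank-frequency table with relative frequencies exactly proportional to
# rank^(-s) (counts are placeholders; the OLS fit uses rel_freq).
exact_zipf_table <- function(s, V = 64) {
  w <- (1:V)^(-s)
  d <- data.frame(rank = 1:V, token = sprintf("tok%03d", 1:V),
                  count = rep(1L, V), rel_freq = w / sum(w))
  class(d) <- c("rank_frequency_table", "data.frame")
  d
}

# Brute-force k-mer dictionary counter (independent oracle).
oracle_count_kmers <- function(segments, k) {
  toks <- unlist(lapply(segments, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  toks <- toks[!grepl("[^ACGT]", toks)]
  table(toks)
}
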