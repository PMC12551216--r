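# Reading sequences and annotations; coding/non-coding partition.
#
# All internal coordinates are 0-based half-open [start, end); GenBank
# and GFF3 1-based inclusive coordinates are converted on ingest.

IUPAC_CODES <- c("A","C","G","T","U","R","Y","S","W","K","M","B","D","H","V","N")

#' Read a genome record from a FASTA file
#'
#' Reads a nucleotide FASTA file and returns one record as a
#' \code{genome_record}: the sequence is upper-cased and checked against
#' the IUPAC nucleotide alphabet.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param id Optional record identifier; by default the first record is
#'   returned. The id is matched against the first whitespace-delimited
#'   word of each FASTA header.
#' @return A \code{genome_record} list with fields \code{id},
#'   \code{sequence} (character scalar, upper case) and \code{length} (bp).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  i <- if (is.null(id)) 1L else match(id, ids)
  if (is.na(i)) stop("record '", id, "' not found in ", path)
  seq <- toupper(as.character(set[[i]]))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), IUPAC_CODES)
  if (length(bad) > 0)
    stop("non-IUPAC symbols in record '", ids[i], "': ",
         paste(bad, collapse = ","))
  genome_record(ids[i], seq)
}

genome_record <- function(id, sequence) {
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$id, "-", format(x$length, big.mark = ","), "bp\n")
  invisible(x)
}

new_feature <- function(ftype, strand, intervals, attributes = list()) {
  # intervals: 2-column matrix of 0-based half-open [start, end)
  intervals <- matrix(as.integer(intervals), ncol = 2)
  stopifnot(all(intervals[, 1] < intervals[, 2]))
  o <- order(intervals[, 1])
  structure(list(ftype = ftype, strand = strand,
                 intervals = intervals[o, , drop = FALSE],
                 attributes = attributes),
            class = "genolex_feature")
}

#' Read features from a GenBank flat file or GFF3
#'
#' Parses feature annotations and converts their 1-based inclusive source
#' coordinates to 0-based half-open intervals. Compound (joined)
#' locations are preserved as multiple intervals of a single feature;
#' strand is recorded. GFF3 rows sharing an \code{ID} (or, for CDS rows,
#' a \code{Parent}) are grouped into one multi-interval feature.
#'
#' @param path Path to the annotation file.
#' @param format Either \code{"genbank"} or \code{"gff3"}.
#' @param seq_length Optional sequence length in bp; when given, any
#'   feature interval reaching past it is an error.
#' @return A list of features, each with fields \code{ftype},
#'   \code{strand} (\code{"+"} or \code{"-"}), \code{intervals}
#'   (two-column integer matrix of 0-based half-open pairs) and
#'   \code{attributes}.
#' @export
read_features <- function(path, format = c("genbank", "gff3"),
                          seq_length = NULL) {
  format <- match.arg(format)
  feats <- switch(format,
                  genbank = read_genbank_features(path),
                  gff3 = read_gff3_features(path))
  if (!is.null(seq_length)) {
    for (f in feats) {
      if (any(f$intervals[, 2] > seq_length))
        stop("feature '", f$ftype, " ",
             f$attributes$locus_tag %||% f$attributes$ID %||% "?",
             "' exceeds sequence length ", seq_length)
    }
  }
  feats
}

# GenBank flat-file FEATURES table parser. Handles the location grammar
# used by NCBI nucleotide records: n..m, n, join(...), complement(...),
# order(...), and fuzzy ends (<n..m, n..>m). Qualifiers are collected as
# attributes.
read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) stop("no FEATURES table in GenBank file: ", path)
  i <- fstart[1] + 1L
  # table ends at the next non-indented section (ORIGIN, CONTIG, //, ...)
  fend <- i
  while (fend <= length(lines) && grepl("^ ", lines[fend])) fend <- fend + 1L
  block <- lines[i:(fend - 1L)]

  # feature headers have the key in columns 6-20; continuations start at 22
  is_key <- grepl("^ {5}\\S", block)
  if (!any(is_key)) return(list())
  idx <- which(is_key)
  ends <- c(idx[-1] - 1L, length(block))

  feats <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    chunk <- block[idx[j]:ends[j]]
    key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
    rest <- trimws(substring(chunk[1], 21))
    body <- trimws(chunk[-1])
    # location may continue over lines until the first qualifier (/...)
    qual_at <- which(grepl("^/", body))
    loc_extra <- if (length(qual_at)) body[seq_len(min(qual_at) - 1L)] else body
    loc <- gsub("\\s+", "", paste(c(rest, loc_extra), collapse = ""))
    parsed <- parse_genbank_location(loc)
    quals <- if (length(qual_at)) body[min(qual_at):length(body)] else character(0)
    attrs <- parse_genbank_qualifiers(quals)
    feats[[j]] <- new_feature(key, parsed$strand, parsed$intervals, attrs)
  }
  feats
}

parse_genbank_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  # tolerate complement() nested around individual spans
  if (grepl("complement\\(", loc)) {
    strand <- "-"
    loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ivs <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (any(is.na(nums))) stop("cannot parse GenBank location part: ", p)
    if (length(nums) == 1L) nums <- c(nums, nums)
    c(nums[1] - 1L, nums[2])            # 1-based inclusive -> 0-based half-open
  }, integer(2)))
  list(strand = strand, intervals = ivs)
}

parse_genbank_qualifiers <- function(quals) {
  if (length(quals) == 0) return(list())
  # re-join continuation lines (those not starting with /) to the previous one
  joined <- character(0)
  for (q in quals) {
    if (grepl("^/", q) || length(joined) == 0) joined <- c(joined, q)
    else joined[length(joined)] <- paste(joined[length(joined)], q)
  }
  out <- list()
  for (q in joined) {
    m <- regmatches(q, regexec('^/([^=]+)(?:=\"?([^\"]*)\"?)?$', q))[[1]]
    if (length(m) >= 2 && nzchar(m[2]))
      out[[m[2]]] <- if (length(m) >= 3 && nzchar(m[3])) m[3] else TRUE
  }
  out
}

read_gff3_features <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0) return(list())
  type <- as.character(gr$type)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  st <- BiocGenerics::start(gr) - 1L      # to 0-based half-open
  en <- BiocGenerics::end(gr)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent))
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))
  # group multi-row features: same type + same ID, or same type + Parent
  key <- ifelse(!is.na(id), paste(type, id),
                ifelse(!is.na(parent), paste(type, parent),
                       paste(type, seq_along(gr))))
  lapply(split(seq_along(gr), key)[unique(key)], function(ix) {
    attrs <- list()
    if (!is.na(id[ix[1]])) attrs$ID <- id[ix[1]]
    if (!is.na(parent[ix[1]])) attrs$Parent <- parent[ix[1]]
    new_feature(type[ix[1]], strand[ix[1]], cbind(st[ix], en[ix]), attrs)
  })
}

#' Partition a genome into coding and non-coding regions
#'
#' Merges the intervals of all features whose type is in
#' \code{coding_types} into a disjoint sorted coding set and takes the
#' complement within \code{[0, length)} as the non-coding set. Base-pair
#' totals are reported under two conventions: the merged union
#' (\code{coding_bp_union}) and the sum of raw feature interval lengths
#' with overlaps double-counted (\code{coding_bp_summed}); published
#' totals sometimes follow the second convention.
#'
#' @param record A \code{genome_record}.
#' @param features List of features from \code{\link{read_features}}.
#' @param coding_types Character vector of feature types treated as
#'   coding (default \code{"CDS"}).
#' @return A \code{region_partition} with \code{coding_intervals} and
#'   \code{noncoding_intervals} (two-column 0-based half-open matrices),
#'   and the bp accounting fields.
#' @export
partition_regions <- function(record, features, coding_types = "CDS") {
  sel <- Filter(function(f) f$ftype %in% coding_types, features)
  if (length(sel) == 0)
    warning("no features of type ", paste(coding_types, collapse = "/"),
            "; partition has zero coding bp")
  ivs <- do.call(rbind, c(lapply(sel, `[[`, "intervals"),
                          list(matrix(integer(0), ncol = 2))))
  if (nrow(ivs) > 0 && any(ivs[, 2] > record$length))
    stop("coding feature interval exceeds record length")
  # IRanges is 1-based inclusive; shift on the way in and out
  ir <- IRanges::IRanges(start = ivs[, 1] + 1L, end = ivs[, 2])
  merged <- IRanges::reduce(ir)
  gaps <- IRanges::gaps(merged, start = 1L, end = record$length)
  coding <- cbind(BiocGenerics::start(merged) - 1L, BiocGenerics::end(merged))
  noncoding <- cbind(BiocGenerics::start(gaps) - 1L, BiocGenerics::end(gaps))
  structure(list(
    length = record$length,
    coding_intervals = coding,
    noncoding_intervals = noncoding,
    coding_bp_union = sum(coding[, 2] - coding[, 1]),
    coding_bp_summed = sum(ivs[, 2] - ivs[, 1]),
    noncoding_bp = sum(noncoding[, 2] - noncoding[, 1])
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>", format(x$length, big.mark = ","), "bp:",
      format(x$coding_bp_union, big.mark = ","), "coding (union),",
      format(x$coding_bp_summed, big.mark = ","), "coding (summed),",
      format(x$noncoding_bp, big.mark = ","), "non-coding\n")
  invisible(x)
}

#' Extract coding or non-coding sequence segments
#'
#' Returns one string per partition interval, on the forward strand as
#' stored. Segments are deliberately not concatenated so that downstream
#' k-mer counting cannot create tokens spanning region junctions.
#'
#' @param record A \code{genome_record}.
#' @param partition A \code{region_partition} derived from it.
#' @param which \code{"coding"} or \code{"noncoding"}.
#' @return Character vector of sequence segments (possibly empty).
#' @export
extract_region_sequences <- function(record, partition,
                                     which = c("coding", "noncoding")) {
  which <- match.arg(which)
  ivs <- if (which == "coding") partition$coding_intervals
         else partition$noncoding_intervals
  if (nrow(ivs) == 0) return(character(0))
  substring(record$sequence, ivs[, 1] + 1L, ivs[, 2])
}

#' Write a region partition to BED and GFF3
#'
#' @param partition A \code{region_partition}.
#' @param seqname Sequence name for output records.
#' @param bed_path,gff3_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_partition <- function(partition, seqname, bed_path = NULL,
                            gff3_path = NULL) {
  mk_gr <- function(ivs, label) {
    GenomicRanges::GRanges(seqnames = seqname,
                           ranges = IRanges::IRanges(start = ivs[, 1] + 1L,
                                                     end = ivs[, 2]),
                           type = label)
  }
  gr <- c(mk_gr(partition$coding_intervals, "coding_region"),
          mk_gr(partition$noncoding_intervals, "noncoding_region"))
  if (!is.null(bed_path)) {
    gr_bed <- gr
    names(gr_bed) <- gr_bed$type
    rtracklayer::export(gr_bed, bed_path, format = "BED")
  }
  if (!is.null(gff3_path)) rtracklayer::export(gr, gff3_path, format = "GFF3")
  invisible(c(bed = bed_path, gff3 = gff3_path))
}

#' Write features to GFF3
#'
#' Emits one GFF3 row per feature interval; multi-interval features share
#' an \code{ID} so that \code{\link{read_features}} regroups them.
#'
#' @param features List of features.
#' @param seqname Sequence name.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_features_gff3 <- function(features, seqname, path) {
  rows <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    id <- f$attributes$ID %||% sprintf("feat%04d", i)
    data.frame(start = f$intervals[, 1] + 1L, end = f$intervals[, 2],
               type = f$ftype, strand = f$strand, id = id,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(seqnames = seqname,
                               ranges = IRanges::IRanges(d$start, d$end),
                               strand = d$strand)
  gr$type <- d$type
  gr$ID <- d$id
  gr$phase <- ifelse(d$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
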