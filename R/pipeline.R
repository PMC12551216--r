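# One-command replication: partition -> Zipf -> power-law MLE -> DNA
# walk -> entropy -> null models, with a two-class comparison report.

#' Run the full coding vs non-coding replication analysis
#'
#' Executes the whole pipeline on a genome FASTA and its annotations:
#' region partition, k-mer rank-frequency tables and OLS Zipf exponents
#' (with a sensitivity block covering non-overlapping windows and the
#' MLE tail exponent), discrete power-law fits of the k-mer count
#' distribution with lognormal/exponential comparison, DNA-walk scaling
#' exponents by R/S and DFA-1, block entropy and redundancy at k = 1 and
#' the analysis k, bootstrap confidence intervals for the Zipf exponent,
#' and (optionally) null-model p-values.
#'
#' @param fasta Path to the genome FASTA.
#' @param features Path to the annotation file.
#' @param format Annotation format: \code{"gff3"} or \code{"genbank"}.
#' @param k Token length for the Zipf analysis (default 3).
#' @param step Window step for k-mer counting (1 = overlapping).
#' @param coding_types Feature types treated as coding.
#' @param n_boot Bootstrap replicates for the Zipf exponent CI.
#' @param null_type Null model for p-values (\code{"none"} to skip;
#'   otherwise \code{"permute"}, \code{"markov1"} or \code{"markov2"}).
#' @param n_null Null replicates per statistic.
#' @param seed Integer seed covering every stochastic step.
#' @param out_dir Optional output directory; when given, writes
#'   \code{report.json}, \code{zipf_coding.tsv}, \code{zipf_noncoding.tsv},
#'   \code{loglog_points.tsv} and \code{partition.bed}.
#' @return A \code{replication_report} list; see Details in the package
#'   vignette.
#' @export
run_replication <- function(fasta, features, format = c("gff3", "genbank"),
                            k = 3L, step = 1L, coding_types = "CDS",
                            n_boot = 200L, null_type = "none", n_null = 19L,
                            seed = 1L, out_dir = NULL) {
  format <- match.arg(format)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[genolex] %-12s %6.1fs", name, proc.time()[3] - t0))
    out
  }

  record <- stage("genome_io", read_fasta(fasta))
  feats <- stage("features",
                 read_features(features, format, seq_length = record$length))
  part <- stage("partition", partition_regions(record, feats, coding_types))

  analyse_class <- function(segments, class_seed) {
    if (length(segments) == 0 || max(nchar(segments)) < k) return(NULL)
    sp <- count_kmers(segments, k, step)
    tab <- rank_frequency(sp)
    ols <- fit_zipf_ols(tab)
    sp_block <- count_kmers(segments, k, step = k)
    sens <- list(
      nonoverlap_zeta = tryCatch(fit_zipf_ols(rank_frequency(sp_block))$zeta,
                                 error = function(e) NA_real_),
      tail_trimmed_zeta = tryCatch(
        fit_zipf_ols(tab, rank_range = c(1, max(3, nrow(tab) %/% 2)))$zeta,
        error = function(e) NA_real_))
    pl <- tryCatch(fit_powerlaw_discrete(tab$count),
                   error = function(e) NULL)
    cmp <- if (!is.null(pl))
      tryCatch(compare_models(tab$count, xmin = pl$xmin),
               error = function(e) NULL)
    walk <- build_walk(segments)
    hs <- list(rs = tryCatch(hurst_rs(walk), error = function(e) NULL),
               dfa1 = tryCatch(dfa(walk), error = function(e) NULL))
    ent <- lapply(setNames(unique(c(1L, k)), paste0("k", unique(c(1L, k)))),
                  function(kk) block_entropy(segments, kk, step))
    boot <- if (n_boot > 0)
      bootstrap_exponent(tab, "ols_zeta", n_boot = n_boot, seed = class_seed)
    nulls <- NULL
    if (null_type != "none") {
      concat <- paste(segments, collapse = "")
      nulls <- lapply(setNames(nm = c("zeta_ols", "hurst_dfa", "entropy_k")),
                      function(st) null_compare(concat, st, null_type,
                                                n = n_null,
                                                seed = child_seed(class_seed, 7),
                                                k = k))
    }
    list(n_segments = length(segments),
         bp = sum(nchar(segments)),
         spectrum = sp, table = tab, zipf_ols = ols, sensitivity = sens,
         powerlaw = pl, model_comparison = cmp, hurst = hs, entropy = ent,
         bootstrap = boot, nulls = nulls)
  }

  coding_segs <- extract_region_sequences(record, part, "coding")
  noncod_segs <- extract_region_sequences(record, part, "noncoding")
  coding <- stage("coding", analyse_class(coding_segs, child_seed(seed, 1)))
  noncoding <- stage("noncoding", analyse_class(noncod_segs, child_seed(seed, 2)))

  report <- structure(list(
    provenance = list(fasta = basename(fasta), features = basename(features),
                      format = format, record_id = record$id,
                      record_length = record$length,
                      n_features = length(feats),
                      k = k, step = step, coding_types = coding_types,
                      n_boot = n_boot, null_type = null_type, n_null = n_null,
                      seed = seed,
                      version = as.character(utils::packageVersion("genolex"))),
    partition = list(coding_bp_union = part$coding_bp_union,
                     coding_bp_summed = part$coding_bp_summed,
                     noncoding_bp = part$noncoding_bp),
    coding = coding, noncoding = noncoding
  ), class = "replication_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(out_dir,
      c("report.json", "zipf_coding.tsv", "zipf_noncoding.tsv",
        "loglog_points.tsv", "partition.bed"))), add = TRUE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(coding))
      write_rank_frequency_tsv(coding$table, file.path(out_dir, "zipf_coding.tsv"))
    if (!is.null(noncoding))
      write_rank_frequency_tsv(noncoding$table,
                               file.path(out_dir, "zipf_noncoding.tsv"))
    zr <- zipf_report(coding$table, noncoding$table)
    pts <- rbind(
      if (!is.null(zr$coding)) cbind(class = "coding", zr$coding$points),
      if (!is.null(zr$noncoding)) cbind(class = "noncoding", zr$noncoding$points))
    utils::write.table(pts, file.path(out_dir, "loglog_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_partition(part, record$id,
                    bed_path = file.path(out_dir, "partition.bed"))
    ok <- TRUE
  }
  report
}

# Flatten a replication report into plain lists for stable JSON output.
report_to_json <- function(report) {
  class_json <- function(cl) {
    if (is.null(cl)) return(NULL)
    list(
      n_segments = cl$n_segments, bp = cl$bp,
      total_tokens = cl$spectrum$total_tokens,
      skipped_windows = cl$spectrum$skipped_windows,
      zipf = list(zeta = cl$zipf_ols$zeta,
                  intercept = cl$zipf_ols$intercept,
                  r_squared = cl$zipf_ols$r_squared,
                  rank_range = cl$zipf_ols$rank_range),
      sensitivity = cl$sensitivity,
      powerlaw = if (!is.null(cl$powerlaw))
        list(alpha = cl$powerlaw$alpha, xmin = cl$powerlaw$xmin,
             ks = cl$powerlaw$ks_stat, n_tail = cl$powerlaw$n_tail),
      model_comparison = if (!is.null(cl$model_comparison)) list(
        aic = lapply(cl$model_comparison$models, `[[`, "aic"),
        bic = lapply(cl$model_comparison$models, `[[`, "bic"),
        best_by_aic = cl$model_comparison$best_by_aic,
        best_by_bic = cl$model_comparison$best_by_bic),
      hurst = list(
        rs = if (!is.null(cl$hurst$rs)) cl$hurst$rs$H,
        dfa1 = if (!is.null(cl$hurst$dfa1)) cl$hurst$dfa1$H),
      entropy = lapply(cl$entropy, function(e)
        list(H_bits = e$H_bits, H_per_symbol = e$H_per_symbol,
             redundancy = e$redundancy)),
      bootstrap = if (!is.null(cl$bootstrap))
        list(zeta = cl$bootstrap$estimate,
             ci = cl$bootstrap$ci, n_boot = cl$bootstrap$n_boot),
      nulls = if (!is.null(cl$nulls)) lapply(cl$nulls, function(nr)
        list(observed = nr$observed, p = nr$p_empirical,
             direction = nr$direction, n = nr$n))
    )
  }
  list(provenance = report$provenance, partition = report$partition,
       coding = class_json(report$coding),
       noncoding = class_json(report$noncoding))
}

#' @export
print.replication_report <- function(x, ...) {
  cat("<replication_report>", x$provenance$record_id, "-",
      format(x$provenance$record_length, big.mark = ","), "bp,",
      x$provenance$n_features, "features\n")
  cat("  coding:", format(x$partition$coding_bp_union, big.mark = ","),
      "bp (union) /", format(x$partition$coding_bp_summed, big.mark = ","),
      "bp (summed); non-coding:",
      format(x$partition$noncoding_bp, big.mark = ","), "bp\n")
  for (cl in c("coding", "noncoding")) {
    y <- x[[cl]]
    if (is.null(y)) next
    cat(sprintf("  %-10s zeta = %.4f (r2 = %.3f)  H_dfa = %s  H1 = %.3f bits/sym  red_k = %.4f\n",
                cl, y$zipf_ols$zeta, y$zipf_ols$r_squared,
                if (!is.null(y$hurst$dfa1)) sprintf("%.4f", y$hurst$dfa1$H) else "NA",
                y$entropy$k1$H_per_symbol,
                y$entropy[[length(y$entropy)]]$redundancy))
  }
  invisible(x)
}

#' Coding vs non-coding contrast table
#'
#' Reduces a two-class replication report to the four-row linguistic
#' contrast: DNA-walk correlation exponent (DFA-1), Zipf decay (OLS
#' exponent and its log-log r-squared as a power-law-likeness score),
#' entropy per symbol, and redundancy, each with the observed direction
#' of the inequality between region classes.
#'
#' @param report A \code{replication_report} with both classes present.
#' @return A data frame with columns \code{feature}, \code{coding},
#'   \code{noncoding}, \code{direction} (\code{">"}, \code{"<"} or
#'   \code{"tie"}).
#' @export
compare_regions <- function(report) {
  if (is.null(report$coding) || is.null(report$noncoding))
    stop("both region classes required for a contrast")
  kmax <- length(report$coding$entropy)
  rows <- list(
    correlation_exponent_alpha = c(
      if (!is.null(report$coding$hurst$dfa1)) report$coding$hurst$dfa1$H else NA,
      if (!is.null(report$noncoding$hurst$dfa1)) report$noncoding$hurst$dfa1$H else NA),
    zipf_exponent_zeta = c(report$coding$zipf_ols$zeta,
                           report$noncoding$zipf_ols$zeta),
    zipf_loglog_r_squared = c(report$coding$zipf_ols$r_squared,
                              report$noncoding$zipf_ols$r_squared),
    entropy_bits_per_symbol = c(report$coding$entropy[[kmax]]$H_per_symbol,
                                report$noncoding$entropy[[kmax]]$H_per_symbol),
    redundancy = c(report$coding$entropy[[kmax]]$redundancy,
                   report$noncoding$entropy[[kmax]]$redundancy)
  )
  keep <- !vapply(rows, function(r) any(is.na(r)), logical(1))
  if (!all(keep)) warning("contrast omits rows with missing estimates: ",
                          paste(names(rows)[!keep], collapse = ", "))
  rows <- rows[keep]
  data.frame(
    feature = names(rows),
    coding = vapply(rows, `[`, numeric(1), 1),
    noncoding = vapply(rows, `[`, numeric(1), 2),
    direction = vapply(rows, function(r) {
      if (isTRUE(all.equal(r[1], r[2]))) "tie"
      else if (r[2] > r[1]) "noncoding>coding" else "coding>noncoding"
    }, character(1)),
    row.names = NULL)
}
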