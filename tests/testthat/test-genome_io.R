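test_that("FASTA records are parsed, upper-cased and alphabet-checked", {
  f <- write_tmp_fasta(c(">x", "acgt"))
  rec <- read_fasta(f)
  expect_equal(rec$id, "x")
  expect_equal(rec$sequence, "ACGT")
  expect_equal(rec$length, 4L)

  f2 <- write_tmp_fasta(c(">amb desc", strrep("N", 100)))
  rec2 <- read_fasta(f2)
  expect_equal(rec2$length, 100L)
  expect_equal(rec2$id, "amb")

  f3 <- write_tmp_fasta(c(">a", "ACGT", ">b", "GGCC"))
  expect_equal(read_fasta(f3, id = "b")$sequence, "GGCC")

  expect_error(read_fasta(write_tmp_fasta(character(0))), "empty|read")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("GenBank locations convert to 0-based half-open intervals", {
  gb <- write_tmp_genbank(100, gb_feature("CDS", "11..40",
                                          '/locus_tag="t1"'))
  feats <- read_features(gb, "genbank")
  expect_length(feats, 1)
  expect_equal(feats[[1]]$ftype, "CDS")
  expect_equal(feats[[1]]$intervals, matrix(c(10L, 40L), ncol = 2))
  expect_equal(feats[[1]]$attributes$locus_tag, "t1")

  gb2 <- write_tmp_genbank(100,
    gb_feature("CDS", "complement(join(5..10,21..30))"))
  f2 <- read_features(gb2, "genbank")[[1]]
  expect_equal(f2$strand, "-")
  expect_equal(f2$intervals, matrix(c(4L, 20L, 10L, 30L), ncol = 2))

  gb3 <- write_tmp_genbank(50, c(gb_feature("gene", "<1..>50"),
                                 gb_feature("tRNA", "7")))
  f3 <- read_features(gb3, "genbank")
  expect_equal(f3[[1]]$intervals, matrix(c(0L, 50L), ncol = 2))
  expect_equal(f3[[2]]$intervals, matrix(c(6L, 7L), ncol = 2))

  gb4 <- write_tmp_genbank(20, gb_feature("CDS", "11..40"))
  expect_error(read_features(gb4, "genbank", seq_length = 20), "exceeds")
})

test_that("partition merges coding intervals and complements exactly", {
  rec <- genolex:::genome_record("r", strrep("A", 100))
  f1 <- genolex:::new_feature("CDS", "+", cbind(10L, 40L))
  p1 <- partition_regions(rec, list(f1))
  expect_equal(p1$coding_bp_union, 30L)
  expect_equal(p1$noncoding_bp, 70L)

  f2 <- genolex:::new_feature("CDS", "+", cbind(30L, 60L))
  p2 <- partition_regions(rec, list(f1, f2))
  expect_equal(p2$coding_bp_union, 50L)
  expect_equal(p2$coding_bp_summed, 60L)
  expect_gte(p2$coding_bp_summed, p2$coding_bp_union)

  expect_warning(p0 <- partition_regions(rec, list()), "zero coding")
  expect_equal(p0$coding_bp_union, 0L)
  expect_equal(p0$noncoding_bp, 100L)
})

test_that("partition identities hold for random feature sets", {
  for (i in 1:25) {
    len <- 200L
    rec <- genolex:::genome_record("r", gen_iid(length = len, seed = 100 + i))
    nf <- 1L + (i %% 6L)
    feats <- lapply(seq_len(nf), function(j) {
      st <- ((i * 37L + j * 53L) %% (len - 10L))
      en <- min(len, st + 5L + (j * 13L) %% 60L)
      genolex:::new_feature("CDS", "+", cbind(st, en))
    })
    p <- partition_regions(rec, feats)
    expect_identical(p$coding_bp_union + p$noncoding_bp, len)
    segs <- extract_region_sequences(rec, p, "noncoding")
    expect_equal(sum(nchar(segs)), p$noncoding_bp)
    # idempotence: re-partition the merged union
    feats2 <- list(genolex:::new_feature("CDS", "+", p$coding_intervals))
    p2 <- partition_regions(rec, feats2)
    expect_identical(p2$coding_intervals, p$coding_intervals)
    expect_identical(p2$noncoding_intervals, p$noncoding_intervals)
  }
})

test_that("region sequences are extracted per interval, not concatenated", {
  rec <- genolex:::genome_record("r", "AAACCCGGG")
  p <- partition_regions(rec, list(genolex:::new_feature("CDS", "+",
                                                         cbind(3L, 6L))))
  expect_equal(extract_region_sequences(rec, p, "noncoding"),
               c("AAA", "GGG"))
  expect_equal(extract_region_sequences(rec, p, "coding"), "CCC")

  p_full <- partition_regions(rec, list(genolex:::new_feature("CDS", "+",
                                                              cbind(0L, 9L))))
  expect_identical(extract_region_sequences(rec, p_full, "noncoding"),
                   character(0))
})

test_that("features round-trip through GFF3", {
  feats <- list(
    genolex:::new_feature("CDS", "+", cbind(c(4L, 20L), c(10L, 30L)),
                          list(ID = "cds1")),
    genolex:::new_feature("gene", "-", cbind(50L, 80L), list(ID = "g1")))
  path <- tempfile(fileext = ".gff3")
  write_features_gff3(feats, "chr", path)
  back <- read_features(path, "gff3")
  types <- vapply(back, `[[`, character(1), "ftype")
  cds <- back[[which(types == "CDS")]]
  gene <- back[[which(types == "gene")]]
  expect_identical(cds$intervals, feats[[1]]$intervals)
  expect_identical(gene$intervals, feats[[2]]$intervals)
  expect_equal(gene$strand, "-")
})
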