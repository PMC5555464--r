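test_that("interval_length reproduces printed 1-based inclusive arithmetic", {
  expect_equal(interval_length(genomic_interval("chr5", 16669728, 16670275)), 548L)
  iv <- genomic_interval("contig_000055998", 9394, 10516)
  expect_equal(interval_length(iv), 1123L)
  expect_equal(interval_length(iv) - 273L, 850L)  # 5'-UTR once the CDS is removed
  expect_equal(interval_length(genomic_interval("c", 7, 7)), 1L)
})

test_that("exons listed out of order are sorted into transcription order", {
  shuffled <- data.frame(start = c(481L, 101L, 261L), end = c(600L, 160L, 380L))
  t <- transcript_model("t", shuffled)
  expect_equal(t$exons$start, c(101L, 261L, 481L))
  expect_equal(t$exons$end, c(160L, 380L, 600L))
})

test_that("invalid transcript geometry is rejected", {
  expect_error(transcript_model("t", data.frame(start = c(1, 50), end = c(60, 90))),
               "non-overlapping")
  expect_error(transcript_model("t", data.frame(start = 10, end = 5)), "exceed")
  expect_error(transcript_model("t", data.frame(start = 1, end = 30),
                                cds = c(10, 50)), "inside exons")
})

test_that("coordinate maps are mutually inverse bijections on exonic positions", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 8L
    starts <- 100L + cumsum(sample(200:400, n))
    ends <- starts + sample(30:120, n)
    strand <- sample(c("+", "-"), 1L)
    t <- transcript_model("t", data.frame(start = starts, end = ends),
                          strand = strand)
    exonic <- unlist(Map(seq, t$exons$start, t$exons$end))
    g <- sample(exonic, min(1000L, length(exonic)))
    p <- genomic_to_spliced(t, g)
    expect_false(anyNA(p))
    expect_equal(spliced_to_genomic(t, p), g)
    # spliced positions cover 1..L exactly once
    expect_setequal(genomic_to_spliced(t, exonic), seq_len(spliced_length(t)))
    # intronic and flanking positions map to NA
    ints <- introns(t)
    if (nrow(ints)) expect_true(all(is.na(genomic_to_spliced(t, ints$start))))
    expect_true(is.na(genomic_to_spliced(t, min(starts) - 1L)))
  }
})

test_that("spliced_sequence matches a per-base brute-force oracle", {
  set.seed(7)
  seqc <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  starts <- cumsum(sample(80:200, 5)) ; ends <- starts + sample(30:100, 5)
  t <- transcript_model("t", data.frame(start = starts, end = ends))
  exonic <- unlist(Map(seq, t$exons$start, t$exons$end))
  oracle <- paste(vapply(exonic, function(p) substr(seqc, p, p), character(1L)),
                  collapse = "")
  expect_equal(spliced_sequence(seqc, t), oracle)
  expect_equal(nchar(spliced_sequence(seqc, t)), spliced_length(t))
  expect_equal(spliced_length(t),
               sum(interval_length(list(start = t$exons$start, end = t$exons$end))))
})

test_that("minus-strand single-exon transcript is reverse-complemented", {
  t_plus <- transcript_model("p", data.frame(start = 1, end = 4))
  t_minus <- transcript_model("m", data.frame(start = 1, end = 4), strand = "-")
  expect_equal(spliced_sequence("ATGC", t_plus), "ATGC")
  expect_equal(spliced_sequence("ATGC", t_minus), "GCAT")
})

test_that("GFF3 write/read round-trips the feature set exactly", {
  gen <- generate_locus(locus_spec(seed = 11, n_exons = 8,
                                   features = list(feat_me_first(2),
                                                   feat_nagnag(5))))
  d <- withr::local_tempdir()
  write_locus_files(gen$locus, d, gen$truth)
  loc2 <- read_gene_models(file.path(d, "models.gff3"), file.path(d, "locus.fa"),
                           file.path(d, "evidence.bed"))
  expect_equal(loc2$seq, gen$locus$seq)
  m1 <- all_models_for_test(gen$locus); m2 <- all_models_for_test(loc2)
  expect_equal(names(m2), names(m1))
  for (id in names(m1)) {
    expect_equal(m2[[id]]$exons[c("start", "end")], m1[[id]]$exons[c("start", "end")])
    expect_equal(m2[[id]]$cds, m1[[id]]$cds)
    expect_equal(m2[[id]]$source, m1[[id]]$source)
  }
  expect_equal(loc2$evidence$position, gen$locus$evidence$position)
  expect_equal(loc2$evidence$source, gen$locus$evidence$source)
  # re-emitting the re-read locus reproduces the file byte-identically
  write_gene_models(loc2, file.path(d, "models2.gff3"))
  expect_identical(readLines(file.path(d, "models2.gff3")),
                   readLines(file.path(d, "models.gff3")))
})

test_that("minus-strand input is normalised to an equivalent plus-strand working copy", {
  toy <- toy_locus()
  plus <- toy$locus
  L <- nchar(plus$seq)
  minus_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus$seq)))
  ex <- plus$reference$exons
  m_start <- L - ex$end + 1L; m_end <- L - ex$start + 1L
  d <- withr::local_tempdir()
  fa <- file.path(d, "m.fa"); gff <- file.path(d, "m.gff3")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(structure(minus_seq, names = "locus")), fa)
  attrs <- function(id, parent = NULL)
    paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
  lines <- c("##gff-version 3",
             sprintf("locus\tRefSeq\tgene\t%d\t%d\t.\t-\t.\t%s",
                     min(m_start), max(m_end), attrs("g1")),
             sprintf("locus\tRefSeq\tmRNA\t%d\t%d\t.\t-\t.\t%s",
                     min(m_start), max(m_end), attrs("ref", "g1")),
             sprintf("locus\tRefSeq\texon\t%d\t%d\t.\t-\t.\t%s",
                     rev(m_start), rev(m_end),
                     attrs(paste0("e", 1:3), "ref")),
             sprintf("locus\tRefSeq\tCDS\t%d\t%d\t.\t-\t0\t%s",
                     L - plus$reference$cds[2] + 1L, L - plus$reference$cds[1] + 1L,
                     attrs("c1", "ref")))
  writeLines(lines, gff)
  loc <- read_gene_models(gff, fa)
  expect_equal(loc$seq, plus$seq)
  expect_equal(loc$reference$exons[c("start", "end")], ex[c("start", "end")])
  expect_equal(loc$reference$cds, plus$reference$cds)
  expect_equal(attr(loc, "input_strand"), "-")
  # report positions translate back to the input frame
  expect_equal(original_coords(loc, 101L), L - 101L + 1L)
})
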