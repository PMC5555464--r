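se_ref <- function() {
  starts <- 1001L + (0:7) * 500L
  transcript_model("ref", data.frame(start = starts, end = starts + 99L),
                   cds = c(1031L, 4570L))
}

test_that("identical structures yield no events", {
  ref <- se_ref()
  ev <- diff_transcripts(ref, ref)
  expect_equal(nrow(ev), 0L)
  expect_true(attr(ev, "conserved"))
})

test_that("a lone missing reference exon is one skipped_exon event", {
  ref <- se_ref()
  alt <- transcript_model("alt", ref$exons[-6L, ], cds = ref$cds)
  ev <- diff_transcripts(alt, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "skipped_exon")
  expect_equal(ev$ref_exons, "6")
  expect_equal(ev$delta_nt, -100L)
  expect_true(attr(ev, "conserved"))
})

test_that("a contiguous multi-exon skip is reported as one event with all ordinals", {
  ref <- se_ref()
  alt <- transcript_model("alt", ref$exons[-c(4L, 5L), ], cds = ref$cds)
  ev <- diff_transcripts(alt, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ref_exons, "4,5")
  expect_equal(ev$delta_nt, -200L)
  # two separate runs give two events
  alt2 <- transcript_model("alt2", ref$exons[-c(3L, 6L), ], cds = ref$cds)
  ev2 <- diff_transcripts(alt2, ref)
  expect_equal(ev2$ref_exons, c("3", "6"))
})

test_that("donor and acceptor shifts carry signed deltas and correct kinds", {
  ref <- se_ref()
  ex <- ref$exons
  # donor of exon 3 moved 21 nt upstream: 21 nt excluded
  d <- ex; d$end[3] <- d$end[3] - 21L
  ev <- diff_transcripts(transcript_model("d", d, cds = ref$cds), ref)
  expect_equal(ev$kind, "alt_donor")
  expect_equal(ev$delta_nt, -21L)
  expect_equal(ev$ref_exons, "3")
  # acceptor of exon 5 moved 15 nt into the exon
  a <- ex; a$start[5] <- a$start[5] + 15L
  ev <- diff_transcripts(transcript_model("a", a, cds = ref$cds), ref)
  expect_equal(ev$kind, "alt_acceptor")
  expect_equal(ev$delta_nt, -15L)
  # donor of a coding exon moved 40 nt into the intron: partial retention
  r <- ex; r$end[4] <- r$end[4] + 40L
  ev <- diff_transcripts(transcript_model("r", r), ref)
  expect_equal(ev$kind, "intron_retention")
  expect_equal(ev$delta_nt, 40L)
})

test_that("a UTR-confined downstream donor shift is typed cryptic_donor_utr", {
  # noncoding exon 1 (CDS starts in exon 2); donor slides 132 nt into intron 1
  ref <- transcript_model("ref", data.frame(start = c(101L, 1001L, 2001L),
                                            end = c(300L, 1400L, 2300L)),
                          cds = c(1031L, 2200L))
  alt <- transcript_model("alt", data.frame(start = c(101L, 1001L, 2001L),
                                            end = c(432L, 1400L, 2300L)))
  ev <- diff_transcripts(alt, ref)
  expect_equal(ev$kind, "cryptic_donor_utr")
  expect_equal(ev$delta_nt, 132L)
})

test_that("full intron retention spanning two introns is one event recording the subsumed exon", {
  ref <- se_ref()
  ex <- ref$exons
  merged <- rbind(data.frame(start = ex$start[2], end = ex$end[4]),
                  ex[-(2:4), c("start", "end")])
  ev <- diff_transcripts(transcript_model("m", merged), ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "intron_retention")
  expect_equal(ev$delta_nt, 800L)       # two 400-nt introns
  expect_equal(ev$ref_exons, "3")       # exon 3 subsumed
  expect_true(attr(ev, "conserved"))
})

test_that("NAGNAG detection matches the motif definition", {
  # intron ending ...TTCAGCAG with the exon starting right after
  seqc <- paste0(strrep("C", 94), "TTCAGCAG", strrep("G", 50))
  site <- detect_nagnag(seqc, 102L)   # last intronic base
  expect_false(is.null(site))
  expect_equal(site$distal_AG - site$proximal_AG, 3L)
  expect_equal(site$motif, "CAGCAG")
  expect_null(detect_nagnag(paste0(strrep("C", 95), "TTTTCAG"), 102L))
  expect_null(detect_nagnag("ACGTACGT", 3L))  # too close to the contig edge
})

test_that("NAGNAG acceptance agrees with a brute-force matcher on all 4096 hexamers", {
  b <- c("A", "C", "G", "T")
  hex <- do.call(paste0, do.call(expand.grid, rep(list(b), 6)))
  accept <- vapply(hex, function(h) {
    s <- paste0(strrep("C", 60), h, strrep("G", 10))
    !is.null(detect_nagnag(s, 66L))
  }, logical(1L), USE.NAMES = FALSE)
  oracle <- vapply(hex, function(h) {
    ch <- strsplit(h, "")[[1]]
    ch[2] == "A" && ch[3] == "G" && ch[5] == "A" && ch[6] == "G"
  }, logical(1L), USE.NAMES = FALSE)
  expect_equal(accept, oracle)
  expect_equal(sum(oracle), 16L)
})

test_that("a 3-nt acceptor shift at a planted NAGNAG site is flagged", {
  gen <- generate_locus(locus_spec(seed = 21, n_exons = 8,
                                   features = list(feat_nagnag(4))))
  alt <- gen$locus$alternatives[[1]]
  ev <- diff_transcripts(alt, gen$locus$reference, gen$locus)
  expect_equal(ev$kind, "alt_acceptor")
  expect_equal(ev$delta_nt, -3L)
  expect_true(ev$nagnag)
  expect_equal(count_nagnag_sites(gen$locus), 1L)
})

test_that("mutually exclusive exon pairs are recovered and shared exons are not paired", {
  gen <- generate_locus(locus_spec(seed = 13, n_exons = 10,
                                   features = list(feat_me_pair(4),
                                                   feat_me_pair(7))))
  pairs <- pair_mutually_exclusive(gen$locus$alternatives, gen$locus$reference)
  expect_equal(nrow(pairs), 2L)
  expect_equal(sort(pairs$ref_ordinal), c(4L, 7L))
  expect_equal(pairs$label_a[pairs$ref_ordinal == 4L], "4a")
  # pairwise diff calls the swap as one mutually_exclusive_pair event
  alt <- gen$locus$alternatives[[1]]
  ev <- diff_transcripts(alt, gen$locus$reference, gen$locus)
  expect_equal(ev$kind, "mutually_exclusive_pair")
  expect_true(attr(ev, "conserved"))
  # transcripts sharing all internal exons pair nothing
  ref <- se_ref()
  same <- transcript_model("same", ref$exons, cds = ref$cds)
  expect_equal(nrow(pair_mutually_exclusive(list(same), ref)), 0L)
})

test_that("event deltas always sum to the spliced-length difference", {
  for (seed in 11:18) {
    gen <- generate_locus(random_block_spec(seed))
    for (alt in gen$locus$alternatives) {
      ev <- diff_transcripts(alt, gen$locus$reference, gen$locus)
      expect_true(attr(ev, "conserved"),
                  info = sprintf("seed %d, %s", seed, alt$id))
    }
  }
})

test_that("event calls are invariant under a constant genomic offset", {
  gen <- generate_locus(locus_spec(seed = 31, n_exons = 8,
                                   features = list(feat_alt_donor(3, -21),
                                                   feat_retention(5, 38, "donor"))))
  locus <- gen$locus
  pad <- 777L
  shift_tx <- function(t) transcript_model(
    t$id, data.frame(start = t$exons$start + pad, end = t$exons$end + pad),
    cds = if (is.null(t$cds)) NULL else t$cds + pad, source = t$source)
  seq2 <- paste0(strrep("A", pad), locus$seq)
  ref2 <- shift_tx(locus$reference)
  for (i in seq_along(locus$alternatives)) {
    ev1 <- diff_transcripts(locus$alternatives[[i]], locus$reference, locus)
    ev2 <- diff_transcripts(shift_tx(locus$alternatives[[i]]), ref2, seq2)
    expect_equal(ev2$kind, ev1$kind)
    expect_equal(ev2$delta_nt, ev1$delta_nt)
    expect_equal(ev2$start, ev1$start + pad)
  }
})

test_that("non-overlapping transcripts produce a warning and no events", {
  ref <- se_ref()
  far <- transcript_model("far", data.frame(start = 9000L, end = 9100L))
  expect_warning(ev <- diff_transcripts(far, ref), "do not overlap")
  expect_equal(nrow(ev), 0L)
})
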