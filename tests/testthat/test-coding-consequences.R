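test_that("ORF finding and translation handle annotated and scanned ORFs", {
  # minimal scanned ORF
  t1 <- transcript_model("t1", data.frame(start = 1L, end = 6L))
  p <- find_orf_and_translate("ATGTAA", t1)
  expect_true(p$coding)
  expect_equal(p$sequence, "M")
  expect_equal(p$length, 1L)
  expect_equal(p$orf_span, c(1L, 6L))
  # no AUG and no in-frame stop are non-coding calls, not errors
  t2 <- transcript_model("t2", data.frame(start = 1L, end = 9L))
  expect_false(find_orf_and_translate("CCCCCCCCC", t2)$coding)
  expect_false(find_orf_and_translate("ATGCCCCCC", t2)$coding)
})

test_that("a complete 2529-nt ORF translates to 842 residues", {
  set.seed(8)
  body <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                               c("TAA", "TAG", "TGA")), 841, replace = TRUE),
                collapse = "")
  orf <- paste0("ATG", body, "TAA")
  expect_equal(nchar(orf), 2529L)
  t <- transcript_model("fbrsl1_like", data.frame(start = 1L, end = 2529L),
                        cds = c(1L, 2529L))
  p <- find_orf_and_translate(orf, t)
  expect_equal(p$length, 842L)
  expect_equal(p$length, nchar(orf) / 3 - 1)
})

test_that("translation agrees with an independent codon-table oracle", {
  set.seed(17)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (i in 1:50) {
    n <- sample(5:80, 1L)
    orf <- paste0("ATG", paste(sample(sense, n, replace = TRUE), collapse = ""), "TGA")
    t <- transcript_model("t", data.frame(start = 1L, end = nchar(orf)),
                          cds = c(1L, nchar(orf)))
    p <- find_orf_and_translate(orf, t)
    expect_equal(paste0(p$sequence, "*"), oracle_translate(orf))
  }
})

test_that("splice-consequence arithmetic matches the tandem-acceptor and donor cases", {
  run_one <- function(feat, seed = 101) {
    gen <- generate_locus(locus_spec(seed = seed, n_exons = 9,
                                     features = list(feat)))
    alt <- gen$locus$alternatives[[1]]
    ev <- diff_transcripts(alt, gen$locus$reference, gen$locus)
    expect_equal(nrow(ev), 1L)
    list(ev = ev, cq = consequence_of_event(gen$locus, gen$locus$reference, alt, ev[1L, ]),
         gen = gen, alt = alt)
  }
  # NAGNAG: 3 nt excluded, one residue deleted
  r <- run_one(feat_nagnag(4))
  expect_equal(abs(r$ev$delta_nt), 3L)
  expect_equal(r$cq$category, "inframe_deletion")
  expect_equal(r$cq$deleted_residues, 1L)
  # -21 nt donor: seven residues deleted
  r <- run_one(feat_alt_donor(5, -21))
  expect_equal(r$cq$category, "inframe_deletion")
  expect_equal(r$cq$deleted_residues, 7L)
  # -15 nt acceptor: five residues deleted
  r <- run_one(feat_alt_acceptor(5, -15))
  expect_equal(r$cq$category, "inframe_deletion")
  expect_equal(r$cq$deleted_residues, 5L)
  # -6 nt junction construct: two deleted (G, K) plus a Y->D substitution
  r <- run_one(feat_alt_donor(5, -6, codon_aligned = FALSE))
  expect_equal(r$cq$category, "inframe_deletion_with_substitution")
  expect_equal(r$cq$deleted_residues, 2L)
  expect_equal(r$cq$substitutions$ref_aa, "Y")
  expect_equal(r$cq$substitutions$alt_aa, "D")
})

test_that("event-level consequences agree with a full-translation oracle", {
  for (seed in 41:46) {
    gen <- generate_locus(random_block_spec(seed))
    ref <- gen$locus$reference
    refp <- find_orf_and_translate(gen$locus, ref)
    for (alt in gen$locus$alternatives) {
      ev <- diff_transcripts(alt, ref, gen$locus)
      if (nrow(ev) != 1L) next
      cq <- consequence_of_event(gen$locus, ref, alt, ev[1L, ])
      altp <- find_orf_and_translate(gen$locus, alt)
      if (cq$category %in% c("inframe_deletion", "inframe_deletion_with_substitution")) {
        st <- oracle_suffix_stats(refp$sequence, altp$sequence)
        expect_equal(refp$length - altp$length, cq$deleted_residues)
        # deleted + substituted residues account for the non-shared interior
        expect_lte(st$missing_n - st$unique_n, cq$deleted_residues + nrow(cq$substitutions))
      } else if (cq$category == "frameshift_ptc") {
        expect_lt(altp$length, refp$length)
      } else if (cq$category == "silent_utr") {
        expect_identical(altp$sequence, refp$sequence)
      }
    }
  }
})

test_that("a 106-nt intron retention causes a frameshift with a premature stop", {
  gen <- generate_locus(locus_spec(seed = 55, n_exons = 7,
                                   features = list(feat_retention(3, 106, "full"))))
  alt <- gen$locus$alternatives[[1]]
  ev <- diff_transcripts(alt, gen$locus$reference, gen$locus)
  expect_equal(ev$delta_nt, 106L)
  expect_equal(106L %% 3L, 1L)
  cq <- consequence_of_event(gen$locus, gen$locus$reference, alt, ev[1L, ])
  expect_equal(cq$category, "frameshift_ptc")
  expect_false(is.na(cq$ptc_spliced_position))
  expect_true(cq$nmd_candidate)  # stop sits several introns upstream of the last junction
  # the PTC really is a stop codon in the retained frame
  s <- spliced_sequence(gen$locus, alt)
  expect_true(substr(s, cq$ptc_spliced_position, cq$ptc_spliced_position + 2L)
              %in% c("TAA", "TAG", "TGA"))
})

test_that("events confined to the UTR leave the protein bit-identical", {
  # exon 1 noncoding; CDS = 124 codons in exon 2 + 66 in exon 3 (all Ala + stop)
  ref <- transcript_model("ref", data.frame(start = c(101L, 1001L, 2001L),
                                            end = c(300L, 1402L, 2300L)),
                          cds = c(1031L, 2198L))
  alt <- transcript_model("alt", data.frame(start = c(101L, 1001L, 2001L),
                                            end = c(432L, 1402L, 2300L)))
  seqc <- strrep("C", 2500)
  substr(seqc, 1031, 1402) <- paste0("ATG", strrep("GCT", 123))
  substr(seqc, 2001, 2198) <- paste0(strrep("GCT", 65), "TAA")
  locus <- gene_locus(seqc, ref, alternatives = list(alt))
  ev <- diff_transcripts(alt, ref, locus)
  cq <- consequence_of_event(locus, ref, alt, ev[1L, ])
  expect_equal(cq$category, "silent_utr")
  alt$cds <- ref$cds
  expect_identical(find_orf_and_translate(locus, alt)$sequence,
                   find_orf_and_translate(locus, ref)$sequence)
})

test_that("N-terminal truncation bookkeeping reproduces the printed isoform arithmetic", {
  set.seed(4)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref_p <- paste(sample(aa, 1278, replace = TRUE), collapse = "")
  make_alt <- function(unique_n, shared) {
    boundary <- substr(ref_p, 1278 - shared, 1278 - shared)  # residue just 5' of the suffix
    novel <- paste(sample(setdiff(aa, boundary), unique_n, replace = TRUE),
                   collapse = "")
    paste0(novel, substring(ref_p, 1278 - shared + 1))
  }
  alt1 <- make_alt(16, 1112)
  st <- nterm_truncation_stats(ref_p, alt1)
  expect_equal(st, list(unique_n = 16L, missing_n = 166L, shared_suffix = 1112L,
                        unrelated = FALSE))
  expect_equal(nchar(alt1), 1128L)
  alt2 <- make_alt(32, 1051)
  st2 <- nterm_truncation_stats(ref_p, alt2)
  expect_equal(st2$missing_n, 227L)
  expect_equal(nchar(alt2), 1083L)
  # identical proteins
  st3 <- nterm_truncation_stats(ref_p, ref_p)
  expect_equal(st3[c("unique_n", "missing_n", "shared_suffix")],
               list(unique_n = 0L, missing_n = 0L, shared_suffix = 1278L))
  # completely unrelated C-termini still return stats, flagged
  expect_true(nterm_truncation_stats("AAAA", "CCCC")$unrelated)
})

test_that("truncation stats agree with a brute-force suffix scan on random pairs", {
  set.seed(23)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:40) {
    a <- paste(sample(aa, sample(5:60, 1L), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:60, 1L), replace = TRUE), collapse = "")
    if (runif(1) < 0.5) b <- paste0(substr(b, 1, 3), substring(a, sample(nchar(a), 1L)))
    st <- nterm_truncation_stats(a, b)
    orc <- oracle_suffix_stats(a, b)
    expect_equal(st[c("unique_n", "missing_n", "shared_suffix")], orc)
    # the truncation identity holds for all inputs
    expect_equal(nchar(b), nchar(a) - st$missing_n + st$unique_n)
  }
})

test_that("predicted isoform lengths follow the truncation identity", {
  expect_equal(predicted_isoform_length(1278, 166, 16), 1128L)
  expect_equal(predicted_isoform_length(1278, 227, 32), 1083L)
  expect_equal(predicted_isoform_length(842, 0, 0), 842L)
  expect_error(predicted_isoform_length(100, 200, 5))
})

test_that("alternative first exons yield truncation consequences consistent with translation", {
  gen <- generate_locus(locus_spec(seed = 61, n_exons = 9,
                                   features = list(feat_me_first(3),
                                                   feat_extension(6, 80))))
  ref <- gen$locus$reference
  for (alt in gen$locus$alternatives) {
    cq <- consequence_of_first_exon(gen$locus, ref, alt)
    expect_equal(cq$category, "n_terminal_truncation")
    refp <- find_orf_and_translate(gen$locus, ref)
    altp <- find_orf_and_translate(gen$locus, alt)
    expect_equal(altp$length,
                 refp$length - cq$truncation$missing_n + cq$truncation$unique_n)
  }
})
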