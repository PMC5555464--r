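# Hand-assembled toy locus with fully known layout, used by unit tests.
# Plus strand; coding exon 2 carries one exonic ATG at a known position.
toy_locus <- function() {
  flank <- strrep("C", 100)                                  # 1..100
  utr5 <- strrep("C", 30)
  cds1 <- paste0("ATG", strrep("GCT", 9))                    # 30 nt
  exon1 <- paste0(utr5, cds1)                                # 101..160
  intron1 <- paste0("GT", strrep("C", 94), "CCAG")           # 161..260
  cds2 <- paste0(strrep("GCT", 4), "ATG", strrep("GCT", 35)) # 120 nt, ATG at offset 13
  exon2 <- cds2                                              # 261..380
  intron2 <- paste0("GT", strrep("C", 94), "CCAG")           # 381..480
  cds3 <- paste0(strrep("GCT", 29), "TAA")                   # 90 nt
  exon3 <- paste0(cds3, strrep("C", 30))                     # 481..600
  seq <- paste0(flank, exon1, intron1, exon2, intron2, exon3, strrep("C", 100))
  ref <- transcript_model("ref",
                          data.frame(start = c(101L, 261L, 481L),
                                     end = c(160L, 380L, 600L)),
                          cds = c(131L, 570L), source = "RefSeq")
  list(locus = gene_locus(seq, ref),
       pos = list(ref_start = 101L, cds_start = 131L, cds_end = 570L,
                  exon2_atg = 273L, exon_starts = c(101L, 261L, 481L),
                  exon_ends = c(160L, 380L, 600L)))
}

all_models_for_test <- function(locus) {
  m <- c(list(locus$reference), locus$alternatives)
  stats::setNames(m, vapply(m, `[[`, character(1L), "id"))
}

# independent codon-table oracle (per-codon lookup, no Biostrings translate)
oracle_translate <- function(nt) {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  cods <- substring(nt, seq(1, nchar(nt) - 2, by = 3), seq(3, nchar(nt), by = 3))
  paste(gc[cods], collapse = "")
}

# brute-force longest-common-suffix scan
oracle_suffix_stats <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  k <- 0L
  while (k < min(length(av), length(bv)) &&
         av[length(av) - k] == bv[length(bv) - k]) k <- k + 1L
  list(unique_n = length(bv) - k, missing_n = length(av) - k, shared_suffix = k)
}

# exhaustive pairwise-gap oracle for 1-D single-linkage cluster count
oracle_cluster_count <- function(pos, thr) {
  p <- sort(pos)
  if (length(p) == 0L) return(0L)
  1L + sum(diff(p) > thr)
}

# brute-force TATAWAWR matcher for one 8-mer
oracle_is_tata <- function(s8) {
  ch <- strsplit(s8, "")[[1]]
  all(ch[1:4] == c("T", "A", "T", "A")) && ch[5] %in% c("A", "T") &&
    ch[6] == "A" && ch[7] %in% c("A", "T") && ch[8] %in% c("A", "G")
}

# one structural feature per disjoint two-exon block, so any random draw is a
# valid spec; returns the spec (block base exons are 2, 4, 6, ... <= n - 3)
random_block_spec <- function(seed, n_exons = 14L) {
  set.seed(seed)
  bases <- seq(2L, n_exons - 3L, by = 2L)
  kinds <- sample(c("nagnag", "donor21", "donor6", "acceptor15", "skip1",
                    "skip2", "ret_donor", "ret_acceptor", "ret_full",
                    "me_first", "me_pair", "extension"),
                  length(bases), replace = TRUE)
  feats <- mapply(function(e, kind) switch(kind,
    nagnag = feat_nagnag(e + 1L),
    donor21 = feat_alt_donor(e, -21L),
    donor6 = feat_alt_donor(e, -6L, codon_aligned = FALSE),
    acceptor15 = feat_alt_acceptor(e + 1L, -15L),
    skip1 = feat_skip(e),
    skip2 = feat_skip(c(e, e + 1L)),
    ret_donor = feat_retention(e, 38L + 3L * sample(0:20, 1L) + sample(1:2, 1L), "donor"),
    ret_acceptor = feat_retention(e, 40L + sample(1:50, 1L), "acceptor"),
    ret_full = feat_retention(e, 106L, "full"),
    me_first = feat_me_first(e),
    me_pair = feat_me_pair(e, lengths = 3L * sample(20:50, 2L)),
    extension = feat_extension(e + 1L, 70L + sample(0:40, 1L))),
    bases, kinds, SIMPLIFY = FALSE)
  locus_spec(seed = seed, n_exons = n_exons, features = feats)
}

# check one generated locus against its declared truth; returns a character
# vector of mismatch descriptions (empty = perfect recovery)
check_truth_recovery <- function(gen) {
  locus <- gen$locus; truth <- gen$truth
  bad <- character(0)
  fe <- classify_first_exons(locus)
  for (i in seq_len(nrow(truth$first_exons))) {
    tr <- truth$first_exons[i, ]
    ob <- fe[fe$transcript_id == tr$transcript_id, ]
    if (nrow(ob) != 1L || ob$class != tr$class ||
        (!is.na(tr$anchor_exon) && ob$anchor_exon != tr$anchor_exon))
      bad <- c(bad, sprintf("first exon of %s", tr$transcript_id))
  }
  alts <- stats::setNames(locus$alternatives,
                          vapply(locus$alternatives, `[[`, character(1L), "id"))
  if (!is.null(truth$events)) for (i in seq_len(nrow(truth$events))) {
    tr <- truth$events[i, ]
    ev <- diff_transcripts(alts[[tr$transcript_id]], locus$reference, locus)
    hit <- ev$kind == tr$kind & ev$delta_nt == tr$delta_nt &
      ev$ref_exons == tr$ref_exons
    if (sum(hit) != 1L || nrow(ev) != sum(truth$events$transcript_id == tr$transcript_id) ||
        (tr$nagnag && !ev$nagnag[hit]))
      bad <- c(bad, sprintf("event %s/%s", tr$transcript_id, tr$kind))
  }
  if (!is.null(truth$consequences)) for (i in seq_len(nrow(truth$consequences))) {
    tr <- truth$consequences[i, ]
    alt <- alts[[tr$transcript_id]]
    if (tr$category == "n_terminal_truncation") {
      cq <- consequence_of_first_exon(locus, locus$reference, alt)
      ok <- cq$category == tr$category &&
        (is.na(tr$missing_n) || cq$truncation$missing_n == tr$missing_n)
    } else {
      ev <- diff_transcripts(alt, locus$reference, locus)
      cq <- consequence_of_event(locus, locus$reference, alt, ev[1L, ])
      ok <- cq$category == tr$category &&
        (is.na(tr$deleted_residues) || cq$deleted_residues == tr$deleted_residues) &&
        nrow(cq$substitutions) == tr$n_substitutions
    }
    if (!ok) bad <- c(bad, sprintf("consequence %s/%s", tr$transcript_id, tr$category))
  }
  bad
}
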