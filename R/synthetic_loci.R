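SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# remove every ATG trinucleotide (T -> C); replacement cannot create a new ATG
scrub_atg <- function(s) gsub("ATG", "ACG", s, fixed = TRUE)

plant <- function(s, pos, what) {
  substr(s, pos, pos + nchar(what) - 1L) <- what
  s
}

#' Feature descriptors for the locus simulator
#'
#' Each `feat_*` helper returns one planted-feature descriptor for
#' [locus_spec()]. Structural features add one alternative transcript each;
#' `feat_tss_cluster`/`feat_tata` plant 5'-end evidence and promoter motifs.
#'
#' @param exon,intron 1-based ordinal in the reference backbone.
#' @param offset signed donor/acceptor shift in nt (negative = excludes
#'   sequence from the mRNA). Codon-aligned shifts must be multiples of 3;
#'   the only supported non-aligned donor shift is -6, generated as the
#'   junction-substitution construct (two residues deleted, one substituted).
#' @param codon_aligned whether the excision respects codon boundaries.
#' @param lengths for `feat_me_pair`: lengths (multiples of 3) of the two
#'   mutually exclusive exons; the first becomes reference exon `intron`,
#'   the second is planted in the intron downstream of it.
#' @param exons for `feat_skip`: contiguous run of internal exon ordinals
#'   skipped together.
#' @param retained retained intronic nt for `feat_retention`.
#' @param edge `"donor"`, `"acceptor"`, `"full"` (whole intron) or `"span2"`
#'   (two consecutive introns retained, subsuming the exon between them;
#'   `retained` is split across the two introns).
#' @param exon_length length of a planted mutually exclusive first exon.
#' @param extension nt of intronic sequence by which a 5'-extension first
#'   exon extends reference exon `exon`.
#' @param offsets planted TSS positions relative to the cluster anchor.
#' @param anchor `"ref_start"`, `"tx"` (start of transcript `tx`) or
#'   `"genomic"` (absolute position `at`).
#' @param tx,at anchor details, see `anchor`.
#' @param source evidence source tag for planted tags.
#' @param cluster 1-based index of the planted `feat_tss_cluster` whose
#'   promoter receives a TATA-box (motif `TATAAAAG` at -30 nt).
#' @return A list descriptor with a `type` field.
#' @name simulator-features
NULL

#' @rdname simulator-features
#' @export
feat_nagnag <- function(exon) list(type = "nagnag", exon = as.integer(exon))

#' @rdname simulator-features
#' @export
feat_alt_donor <- function(exon, offset, codon_aligned = offset %% 3 == 0)
  list(type = "alt_donor", exon = as.integer(exon), offset = as.integer(offset),
       codon_aligned = codon_aligned)

#' @rdname simulator-features
#' @export
feat_alt_acceptor <- function(exon, offset)
  list(type = "alt_acceptor", exon = as.integer(exon), offset = as.integer(offset))

#' @rdname simulator-features
#' @export
feat_me_pair <- function(intron, lengths = c(102L, 135L))
  list(type = "me_pair", intron = as.integer(intron), lengths = as.integer(lengths))

#' @rdname simulator-features
#' @export
feat_skip <- function(exons) list(type = "skip", exons = as.integer(exons))

#' @rdname simulator-features
#' @export
feat_retention <- function(intron, retained, edge = c("donor", "acceptor", "full", "span2"))
  list(type = "retention", intron = as.integer(intron),
       retained = as.integer(retained), edge = match.arg(edge))

#' @rdname simulator-features
#' @export
feat_me_first <- function(intron, exon_length = 120L)
  list(type = "me_first", intron = as.integer(intron),
       exon_length = as.integer(exon_length))

#' @rdname simulator-features
#' @export
feat_extension <- function(exon, extension = 90L)
  list(type = "extension", exon = as.integer(exon),
       extension = as.integer(extension))

#' @rdname simulator-features
#' @export
feat_tss_cluster <- function(offsets, anchor = "ref_start", tx = NULL, at = NULL,
                             source = "RACE")
  list(type = "tss_cluster", offsets = as.integer(offsets), anchor = anchor,
       tx = tx, at = at, source = source)

#' @rdname simulator-features
#' @export
feat_tata <- function(cluster = 1L) list(type = "tata", cluster = as.integer(cluster))

#' Specification of a synthetic gene locus
#'
#' Declares the backbone of a toy gene locus (exon count, exon/intron length
#' ranges, UTR lengths) and the list of planted features (see
#' [simulator-features]) whose detection the pipeline is tested against.
#' Validation checks that planted features are mutually compatible before any
#' sequence is generated; each exon boundary or intron slot may be used by at
#' most one structural feature (a NAGNAG acceptor and a translation-anchor
#' ATG may share an exon).
#'
#' @param seed integer RNG seed; the same spec and seed reproduce the locus
#'   and truth set bit-identically.
#' @param n_exons exons in the reference backbone (>= 6).
#' @param exon_length,intron_length length ranges in nt.
#' @param utr5,utr3 UTR lengths within the first/last exon.
#' @param flank nt of intergenic sequence on each side.
#' @param features list of feature descriptors.
#' @param auto_evidence plant one 5'-end tag at every transcript start
#'   (RefSeq for the reference, RNASeq for alternatives).
#' @param tss_jitter half-width of uniform jitter added to planted cluster
#'   tag positions (0 = exact placement, the default, so cluster widths are
#'   deterministic).
#' @return An object of class `"locus_spec"`.
#' @export
locus_spec <- function(seed = 1L, n_exons = 10L, exon_length = c(90L, 180L),
                       intron_length = c(550L, 900L), utr5 = 150L, utr3 = 120L,
                       flank = 400L, features = list(), auto_evidence = TRUE,
                       tss_jitter = 0L) {
  spec <- structure(list(seed = as.integer(seed), n_exons = as.integer(n_exons),
                         exon_length = as.integer(exon_length),
                         intron_length = as.integer(intron_length),
                         utr5 = as.integer(utr5), utr3 = as.integer(utr3),
                         flank = as.integer(flank), features = features,
                         auto_evidence = auto_evidence,
                         tss_jitter = as.integer(tss_jitter)),
                    class = "locus_spec")
  validate_locus_spec(spec)
  spec
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> seed %d: %d exons, %d planted feature(s)\n",
              x$seed, x$n_exons, length(x$features)))
  invisible(x)
}

validate_locus_spec <- function(spec) {
  n <- spec$n_exons
  if (n < 6L) stop("locus_spec: n_exons must be >= 6")
  if (spec$intron_length[1L] < 80L)
    stop("locus_spec: minimum intron length must be >= 80 nt")
  if (spec$flank < 60L) stop("locus_spec: flank must be >= 60 nt")
  claims <- character()
  claim <- function(ids, f) {
    dup <- intersect(ids, claims)
    if (length(dup))
      stop(sprintf("locus_spec: incompatible features, slot '%s' claimed twice (%s)",
                   dup[1L], f$type))
    claims <<- c(claims, ids)
  }
  for (f in spec$features) switch(f$type,
    nagnag = {
      if (f$exon < 2L || f$exon > n - 1L) stop("nagnag exon must be internal")
      claim(sprintf("acc_%d", f$exon), f)
    },
    alt_donor = {
      if (f$exon < 2L || f$exon > n - 2L) stop("alt_donor exon out of range")
      if (f$offset >= 0L) stop("alt_donor offset must be negative (exclusion)")
      if (f$codon_aligned && f$offset %% 3L != 0L)
        stop("codon-aligned donor offset must be a multiple of 3")
      if (!f$codon_aligned && f$offset != -6L)
        stop("non-aligned donor shifts are generated only as the -6 nt junction-substitution construct")
      claim(sprintf("don_%d", f$exon), f)
      if (!f$codon_aligned) claim(c(sprintf("acc_%d", f$exon + 1L),
                                    sprintf("phase_%d", f$exon)), f)
    },
    alt_acceptor = {
      if (f$exon < 2L || f$exon > n - 1L) stop("alt_acceptor exon out of range")
      if (f$offset >= 0L || f$offset %% 3L != 0L || f$offset > -6L)
        stop("alt_acceptor offset must be a negative multiple of 3, at most -6")
      claim(sprintf("acc_%d", f$exon), f)
    },
    me_pair = {
      if (f$intron < 2L || f$intron > n - 2L) stop("me_pair intron out of range")
      if (any(f$lengths %% 3L != 0L)) stop("me_pair exon lengths must be multiples of 3")
      claim(c(sprintf("payload_%d", f$intron), sprintf("exon_%d", f$intron)), f)
    },
    skip = {
      if (any(f$exons < 2L) || any(f$exons > n - 1L) ||
          !all(diff(f$exons) == 1L)) stop("skip exons must be a contiguous internal run")
      claim(sprintf("exon_%d", f$exons), f)
    },
    retention = {
      k <- f$intron
      if (f$edge == "span2") {
        if (k < 2L || k > n - 3L) stop("span2 retention intron out of range")
        if (f$retained < 20L) stop("span2 retained nt too small")
        claim(c(sprintf("don_%d", k), sprintf("acc_%d", k + 1L),
                sprintf("don_%d", k + 1L), sprintf("acc_%d", k + 2L),
                sprintf("exon_%d", k + 1L)), f)
      } else {
        if (k < 2L || k > n - 2L) stop("retention intron out of range")
        if (f$retained < 12L) stop("retention must keep >= 12 nt")
        claim(switch(f$edge,
                     donor = c(sprintf("don_%d", k), sprintf("payload_%d", k)),
                     acceptor = c(sprintf("acc_%d", k + 1L), sprintf("payload_%d", k),
                                  sprintf("tail_%d", k)),
                     full = c(sprintf("don_%d", k), sprintf("acc_%d", k + 1L),
                              sprintf("payload_%d", k), sprintf("tail_%d", k))), f)
      }
    },
    me_first = {
      if (f$intron < 1L || f$intron > n - 2L) stop("me_first intron out of range")
      if (f$exon_length < 30L) stop("me_first exon_length too small")
      claim(sprintf("payload_%d", f$intron), f)
    },
    extension = {
      if (f$exon < 2L || f$exon > n - 1L) stop("extension exon out of range")
      claim(sprintf("tail_%d", f$exon - 1L), f)
    },
    tss_cluster = {
      if (!f$anchor %in% c("ref_start", "tx", "genomic"))
        stop("tss_cluster anchor must be ref_start, tx or genomic")
    },
    tata = NULL,
    stop(sprintf("unknown feature type '%s'", f$type))
  )
  # an extension consumes its host intron's tail; a planted exon may not
  # share that intron
  pay <- vapply(Filter(function(f) f$type %in% c("me_first", "me_pair"),
                       spec$features), `[[`, integer(1L), "intron")
  tails <- vapply(Filter(function(f) f$type == "extension", spec$features),
                  function(f) f$exon - 1L, integer(1L))
  both <- intersect(pay, tails)
  if (length(both))
    stop(sprintf("locus_spec: intron %d cannot host both a planted exon and an extension tail",
                 both[1L]))
  invisible(TRUE)
}

feature_id <- function(f) switch(f$type,
  nagnag = sprintf("nagnag_e%d", f$exon),
  alt_donor = sprintf("altdonor_e%d", f$exon),
  alt_acceptor = sprintf("altacc_e%d", f$exon),
  me_pair = sprintf("me_pair_i%d", f$intron),
  skip = sprintf("skip_e%s", paste(f$exons, collapse = "_")),
  retention = sprintf("ret_i%d", f$intron),
  me_first = sprintf("me_first_i%d", f$intron),
  extension = sprintf("ext_e%d", f$exon),
  NA_character_)

#' Generate a synthetic gene locus with its ground-truth annotation
#'
#' Builds a random gene locus realising a [locus_spec()]: a reference
#' transcript whose CDS is stop-free sense codons, introns beginning `GT` and
#' ending `AG`, one alternative transcript per planted structural feature
#' (with splice-site dinucleotides preserved at every alternative junction),
#' planted 5'-end evidence, and a truth set naming the first-exon class,
#' splice events and coding-consequence category the pipeline must recover.
#' Planted coding constructs are back-checked by translation before the
#' locus is returned. NAGNAG-lookalike hexamers and upstream AUGs are
#' scrubbed from positions where they would create unplanted features.
#'
#' @param spec a [locus_spec()].
#' @return list with elements `locus` (a [gene_locus()]) and `truth` (lists
#'   `first_exons`, `events`, `consequences`, `clusters` as data.frames, plus
#'   `n_nagnag_sites`).
#' @export
generate_locus <- function(spec) {
  validate_locus_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_exons
  feats <- spec$features
  of_type <- function(ty) Filter(function(f) f$type == ty, feats)

  # ---- per-exon CDS lengths (nt); internal exons are pure CDS
  cod_min <- max(8L, ceiling(spec$exon_length[1L] / 3))
  cod_max <- max(cod_min + 1L, floor(spec$exon_length[2L] / 3))
  cds_len <- 3L * sample(cod_min:cod_max, n, replace = TRUE)
  for (f in of_type("alt_donor"))
    cds_len[f$exon] <- max(cds_len[f$exon], abs(f$offset) + 9L -
                             (abs(f$offset) + 9L) %% 3L + 3L)
  for (f in of_type("alt_acceptor"))
    cds_len[f$exon] <- max(cds_len[f$exon], abs(f$offset) + 9L)
  for (f in of_type("me_pair")) cds_len[f$intron] <- f$lengths[1L]
  fsub <- integer(0)
  for (f in of_type("alt_donor")) if (!f$codon_aligned) {
    cds_len[f$exon] <- cds_len[f$exon] + 1L
    cds_len[f$exon + 1L] <- cds_len[f$exon + 1L] - 1L
    fsub <- c(fsub, f$exon)
  }
  cum <- cumsum(cds_len)
  ncodons <- cum[n] %/% 3L

  # ---- reference CDS as codons
  cod <- sample(SENSE_CODONS, ncodons, replace = TRUE)
  cod[1L] <- "ATG"; cod[ncodons] <- "TAA"
  first_codon_idx <- function(k) cum[k - 1L] %/% 3L + 1L  # valid off the phase-shifted exon
  # scrub accidental exon-initial NAG codons (would mimic a NAGNAG acceptor)
  nag_exons <- vapply(of_type("nagnag"), `[[`, integer(1L), "exon")
  for (k in 2L:n) {
    if (k %in% (fsub + 1L)) next
    i <- first_codon_idx(k)
    if (!k %in% nag_exons && grepl("^[ACGT]AG$", cod[i])) cod[i] <- "CTT"
  }
  for (k in nag_exons) cod[first_codon_idx(k)] <- "CAG"
  # translation anchors: exon-initial AUG (codon 2) for transcripts that lose
  # the annotated start (mutually exclusive / extension first exons)
  anchors <- sort(unique(c(
    vapply(of_type("me_first"), function(f) f$intron + 1L, integer(1L)),
    vapply(of_type("extension"), `[[`, integer(1L), "exon"))))
  if (any((fsub + 1L) %in% anchors))
    stop("locus_spec: a translation anchor cannot sit on the phase-shifted exon of a non-aligned donor construct")
  missing_codons <- integer(0)
  for (k in anchors) {
    i <- first_codon_idx(k)
    if (!k %in% nag_exons) cod[i] <- "CAA"
    cod[i + 1L] <- "ATG"
    missing_codons[as.character(k)] <- i   # residues of ref absent N-terminal of the anchor Met
  }
  # codon-aligned donor/acceptor shifts: the excluded block must carry the
  # alternative splice-site dinucleotide
  for (f in of_type("alt_donor")) if (f$codon_aligned) {
    o <- cum[f$exon] + f$offset                 # 0-based CDS offset of first excluded base
    cod[o %/% 3L + 1L] <- "GTG"                 # excluded block starts GT
  }
  for (f in of_type("alt_acceptor")) {
    o <- cum[f$exon - 1L] - f$offset            # excluded block = first |offset| nt of exon
    cod[o %/% 3L] <- "AAG"                      # excluded block ends AG
  }
  for (fk in fsub) {
    o <- cum[fk] - 7L                           # 9-mer GGT AAA TAT straddles the junction
    cod[o %/% 3L + 1L:3L] <- c("GGT", "AAA", "TAT")
  }
  cds_seq <- paste(cod, collapse = "")

  # ---- exon sequences
  utr5_seq <- scrub_atg(rand_dna(spec$utr5))
  utr3_seq <- rand_dna(spec$utr3)
  cds_piece <- function(k) substr(cds_seq, c(0L, cum)[k] + 1L, cum[k])
  exon_seq <- vapply(seq_len(n), cds_piece, character(1L))
  exon_seq[1L] <- paste0(utr5_seq, exon_seq[1L])
  exon_seq[n] <- paste0(exon_seq[n], utr3_seq)

  # ---- intron construction
  intron_len <- sample(spec$intron_length[1L]:spec$intron_length[2L], n - 1L,
                       replace = TRUE)
  payload_len <- integer(n - 1L); payload_off <- integer(n - 1L)
  payload_seq <- character(n - 1L)
  for (f in c(of_type("me_first"), of_type("me_pair"))) {
    k <- f$intron
    plen <- if (f$type == "me_first") f$exon_length else f$lengths[2L]
    pre <- 260L + sample(0:30, 1L); post <- 260L + sample(0:30, 1L)
    payload_len[k] <- plen; payload_off[k] <- pre + 1L
    payload_seq[k] <- if (f$type == "me_pair")
      paste(sample(SENSE_CODONS, plen %/% 3L, replace = TRUE), collapse = "")
    else scrub_atg(rand_dna(plen))
    intron_len[k] <- pre + plen + post
  }
  for (f in of_type("retention")) {
    if (f$edge == "full") intron_len[f$intron] <- f$retained
    else if (f$edge == "span2") {
      intron_len[f$intron] <- f$retained %/% 2L
      intron_len[f$intron + 1L] <- f$retained - f$retained %/% 2L
    } else intron_len[f$intron] <- max(intron_len[f$intron], f$retained + 80L)
  }
  for (f in of_type("extension"))
    intron_len[f$exon - 1L] <- max(intron_len[f$exon - 1L], f$extension + 120L)

  ext_introns <- vapply(of_type("extension"), function(f) f$exon - 1L, integer(1L))
  ret_by_intron <- list()
  for (f in of_type("retention")) ret_by_intron[[as.character(f$intron)]] <- f

  intron_seq <- character(n - 1L)
  for (k in seq_len(n - 1L)) {
    len <- intron_len[k]
    s <- rand_dna(len)
    if (k %in% ext_introns) s <- scrub_atg(s)  # becomes 5'-UTR of the extension isoform
    s <- plant(s, 1L, "GT")
    s <- plant(s, len - 1L, "AG")
    s <- plant(s, len - 4L, "CC")              # scrub upstream-AG NAGNAG lookalike
    if ((k + 1L) %in% nag_exons) s <- plant(s, len - 2L, "TAG")
    if (payload_len[k] > 0L) {
      s <- plant(s, payload_off[k], payload_seq[k])
      s <- plant(s, payload_off[k] - 2L, "AG")           # payload acceptor
      s <- plant(s, payload_off[k] + payload_len[k], "GT")  # payload donor
    }
    rf <- ret_by_intron[[as.character(k)]]
    if (!is.null(rf)) {
      if (rf$edge == "donor") {
        s <- plant(s, 4L, "TAA")               # in-frame stop in the retained head
        s <- plant(s, rf$retained + 1L, "GT")  # alternative donor site
      } else if (rf$edge == "acceptor") {
        s <- plant(s, len - rf$retained + 4L, "TAA")  # codon 2 of the retained tail
        s <- plant(s, len - rf$retained - 1L, "AG")   # alternative acceptor site
      } else s <- plant(s, 4L, "TAA")          # full / span2 (first intron)
    }
    intron_seq[k] <- s
  }

  # ---- assemble the genome
  pieces <- character(0); names_p <- character(0)
  add <- function(nm, s) { pieces <<- c(pieces, s); names_p <<- c(names_p, nm) }
  add("flank5", rand_dna(spec$flank))
  for (i in seq_len(n)) {
    add(sprintf("exon%d", i), exon_seq[i])
    if (i < n) add(sprintf("intron%d", i), intron_seq[i])
  }
  add("flank3", rand_dna(spec$flank))
  plen <- nchar(pieces)
  pstart <- cumsum(c(1L, plen))[seq_along(pieces)]
  pos_of <- function(nm) pstart[match(nm, names_p)]
  genome <- paste(pieces, collapse = "")

  ex_start <- vapply(seq_len(n), function(i) pos_of(sprintf("exon%d", i)), integer(1L))
  ex_end <- ex_start + nchar(exon_seq) - 1L
  in_start <- ex_end[-n] + 1L
  cds_g <- c(ex_start[1L] + spec$utr5, ex_start[n] + cds_len[n] - 1L)

  ref <- transcript_model("ref", data.frame(start = ex_start, end = ex_end),
                          cds = cds_g, source = "RefSeq")

  # ---- alternative transcripts + truth records
  alts <- list(); tfe <- list(); tev <- list(); tcq <- list()
  ref_len_aa <- ncodons - 1L
  add_truth <- function(id, fe_class, fe_anchor, fe_ret, ev_kind, ev_exons,
                        ev_delta, ev_nagnag, cq_cat, cq_del, cq_sub,
                        cq_missing = NA_integer_) {
    tfe[[length(tfe) + 1L]] <<- data.frame(
      transcript_id = id, class = fe_class, anchor_exon = fe_anchor,
      retained_nt = fe_ret, stringsAsFactors = FALSE)
    if (!is.na(ev_kind))
      tev[[length(tev) + 1L]] <<- data.frame(
        transcript_id = id, kind = ev_kind,
        ref_exons = paste(ev_exons, collapse = ","),
        delta_nt = ev_delta, nagnag = ev_nagnag, stringsAsFactors = FALSE)
    tcq[[length(tcq) + 1L]] <<- data.frame(
      transcript_id = id, category = cq_cat, deleted_residues = cq_del,
      n_substitutions = cq_sub, missing_n = cq_missing, stringsAsFactors = FALSE)
  }

  for (f in feats) {
    id <- feature_id(f)
    if (is.na(id)) next
    ex <- data.frame(start = ex_start, end = ex_end)
    switch(f$type,
      nagnag = {
        ex$start[f$exon] <- ex$start[f$exon] + 3L
        alts[[id]] <- transcript_model(id, ex, cds = cds_g, source = "cloned")
        add_truth(id, "canonical", 1L, 0L, "alt_acceptor", f$exon, -3L, TRUE,
                  "inframe_deletion", 1L, 0L)
      },
      alt_donor = {
        ex$end[f$exon] <- ex$end[f$exon] + f$offset
        alts[[id]] <- transcript_model(id, ex, cds = cds_g, source = "cloned")
        if (f$codon_aligned)
          add_truth(id, "canonical", 1L, 0L, "alt_donor", f$exon, f$offset, FALSE,
                    "inframe_deletion", abs(f$offset) %/% 3L, 0L)
        else
          add_truth(id, "canonical", 1L, 0L, "alt_donor", f$exon, f$offset, FALSE,
                    "inframe_deletion_with_substitution", 2L, 1L)
      },
      alt_acceptor = {
        ex$start[f$exon] <- ex$start[f$exon] - f$offset
        alts[[id]] <- transcript_model(id, ex, cds = cds_g, source = "cloned")
        add_truth(id, "canonical", 1L, 0L, "alt_acceptor", f$exon, f$offset, FALSE,
                  "inframe_deletion", abs(f$offset) %/% 3L, 0L)
      },
      skip = {
        ex <- ex[-f$exons, , drop = FALSE]
        alts[[id]] <- transcript_model(id, ex, cds = cds_g, source = "RNASeq")
        d <- -sum(cds_len[f$exons])
        add_truth(id, "canonical", 1L, 0L, "skipped_exon", f$exons, d, FALSE,
                  "inframe_deletion", abs(d) %/% 3L, 0L)
      },
      me_pair = {
        k <- f$intron
        bst <- in_start[k] + payload_off[k] - 1L
        ex$start[k] <- bst; ex$end[k] <- bst + payload_len[k] - 1L
        alts[[id]] <- transcript_model(id, ex, cds = cds_g, source = "cloned")
        add_truth(id, "canonical", 1L, 0L, "mutually_exclusive_pair", k,
                  f$lengths[2L] - f$lengths[1L], FALSE, "exon_substitution",
                  NA_integer_, 0L)
      },
      retention = {
        k <- f$intron
        if (f$edge == "donor") {
          ex$end[k] <- ex$end[k] + f$retained
        } else if (f$edge == "acceptor") {
          ex$start[k + 1L] <- ex$start[k + 1L] - f$retained
        } else if (f$edge == "full") {
          ex$end[k] <- ex$end[k + 1L]; ex <- ex[-(k + 1L), , drop = FALSE]
        } else {  # span2
          ex$end[k] <- ex$end[k + 2L]; ex <- ex[-c(k + 1L, k + 2L), , drop = FALSE]
        }
        alts[[id]] <- transcript_model(id, ex, source = "cloned")
        add_truth(id, "canonical", 1L, 0L, "intron_retention",
                  switch(f$edge, donor = k, acceptor = k + 1L,
                         full = integer(0), span2 = k + 1L),
                  f$retained, FALSE, "frameshift_ptc", 0L, 0L)
      },
      me_first = {
        k <- f$intron
        pst <- in_start[k] + payload_off[k] - 1L
        ex <- rbind(data.frame(start = pst, end = pst + payload_len[k] - 1L),
                    ex[(k + 1L):n, ])
        alts[[id]] <- transcript_model(id, ex, source = "RNASeq")
        miss <- missing_codons[[as.character(k + 1L)]]
        add_truth(id, "mutually_exclusive_first", k + 1L, 0L,
                  NA_character_, NA, NA, NA, "n_terminal_truncation", 0L, 0L,
                  cq_missing = miss)
      },
      extension = {
        k <- f$exon
        ex <- rbind(data.frame(start = ex_start[k] - f$extension, end = ex_end[k]),
                    if (k < n) ex[(k + 1L):n, ] else NULL)
        alts[[id]] <- transcript_model(id, ex, source = "RNASeq")
        miss <- missing_codons[[as.character(k)]]
        add_truth(id, "five_prime_extension", k, 0L,
                  NA_character_, NA, NA, NA, "n_terminal_truncation", 0L, 0L,
                  cq_missing = miss)
      },
      NULL)
  }

  # ---- evidence and promoter motifs
  evidence <- data.frame(position = integer(), strand = character(),
                         source = character(), transcript_id = character(),
                         stringsAsFactors = FALSE)
  if (spec$auto_evidence) {
    models <- c(list(ref), unname(alts))
    evidence <- data.frame(
      position = vapply(models, tx_start, integer(1L)), strand = "+",
      source = c("RefSeq", rep("RNASeq", length(alts))),
      transcript_id = vapply(models, `[[`, character(1L), "id"),
      stringsAsFactors = FALSE)
  }
  anchor_pos <- function(f) switch(f$anchor,
    ref_start = ex_start[1L],
    tx = {
      if (is.null(alts[[f$tx]])) stop(sprintf("tss_cluster anchor tx '%s' not found", f$tx))
      tx_start(alts[[f$tx]])
    },
    genomic = as.integer(f$at))
  clusters <- of_type("tss_cluster")
  cl_rep <- integer(0)
  for (f in clusters) {
    base <- anchor_pos(f)
    posns <- base + f$offsets
    if (spec$tss_jitter > 0L)
      posns <- posns + sample(-spec$tss_jitter:spec$tss_jitter,
                              length(posns), replace = TRUE)
    evidence <- rbind(evidence, data.frame(
      position = posns, strand = "+", source = f$source,
      transcript_id = NA_character_, stringsAsFactors = FALSE))
    cl_rep <- c(cl_rep, min(posns))
  }
  tata_cl <- vapply(of_type("tata"), `[[`, integer(1L), "cluster")
  for (ci in tata_cl) {
    if (ci > length(cl_rep)) stop("tata feature refers to a missing tss_cluster")
    genome <- plant(genome, cl_rep[ci] - 30L, "TATAAAAG")
  }
  # scrub accidental TATA motifs from windows of clusters not meant to have one
  exonic_any <- function(lo, hi) any(ex_start <= hi & ex_end >= lo)
  for (ci in seq_along(cl_rep)) {
    if (ci %in% tata_cl) next
    lo <- max(1L, cl_rep[ci] - 40L); hi <- cl_rep[ci] - 13L
    if (hi < lo || exonic_any(lo, hi)) next
    repeat {
      m <- regexpr("TATA[AT]A[AT][AG]", substr(genome, lo, hi))
      if (m < 0L) break
      genome <- plant(genome, lo + as.integer(m) - 1L, "C")
    }
  }

  locus <- gene_locus(genome, ref, unname(alts), evidence)

  # ---- back-check: splice sites and planted coding consequences
  for (t in all_models(locus)) {
    ii <- introns(t)
    if (nrow(ii) &&
        (!all(substring(genome, ii$start, ii$start + 1L) == "GT") ||
         !all(substring(genome, ii$end - 1L, ii$end) == "AG")))
      stop(sprintf("generator back-check failed: non-GT/AG intron in %s", t$id))
  }
  refp <- find_orf_and_translate(locus, ref)
  if (refp$length != ref_len_aa)
    stop("generator back-check failed: reference protein length")
  for (f in of_type("retention")) {
    p <- find_orf_and_translate(locus, alts[[feature_id(f)]])
    if (!p$coding || p$length >= refp$length)
      stop("generator back-check failed: retention isoform lacks a premature stop")
  }

  truth <- list(
    first_exons = if (length(tfe)) do.call(rbind, tfe) else NULL,
    events = if (length(tev)) do.call(rbind, tev) else NULL,
    consequences = if (length(tcq)) do.call(rbind, tcq) else NULL,
    clusters = if (length(clusters)) data.frame(
      representative = cl_rep,
      width = vapply(clusters, function(f) max(f$offsets) - min(f$offsets), integer(1L)),
      tata = seq_along(clusters) %in% tata_cl) else NULL,
    n_nagnag_sites = length(nag_exons),
    ref_protein_length = ref_len_aa)
  list(locus = locus, truth = truth)
}

#' A preset locus spec emulating a large auts2-like gene architecture
#'
#' A 19-exon locus carrying the feature inventory of a complex vertebrate
#' gene of the auts2 family: five mutually exclusive novel first exons, six
#' 5'-extension first exons, NAGNAG tandem acceptors at exons 3, 8 and 15, a
#' -21 nt alternative donor at exon 9 (7-residue in-frame deletion), a 38-nt
#' partial intron retention and a 745-nt retention spanning two introns and
#' subsuming the exon between them (both creating premature termination
#' codons), plus a sharp TATA-box promoter cluster (five tags within 58 nt)
#' at the reference start and a broad promoter cluster (tags over 300 nt) at
#' a downstream first exon.
#'
#' @param seed RNG seed.
#' @return A [locus_spec()].
#' @export
preset_auts2a_like <- function(seed = 1L) {
  locus_spec(
    seed = seed, n_exons = 19L, exon_length = c(90L, 180L),
    intron_length = c(550L, 900L), utr5 = 150L, utr3 = 120L, flank = 400L,
    features = list(
      feat_me_first(2L), feat_me_first(3L), feat_me_first(4L),
      feat_me_first(10L), feat_me_first(11L),
      feat_extension(2L, 90L), feat_extension(6L, 90L), feat_extension(7L, 90L),
      feat_extension(8L, 90L), feat_extension(16L, 90L), feat_extension(17L, 90L),
      feat_nagnag(3L), feat_nagnag(8L), feat_nagnag(15L),
      feat_alt_donor(9L, -21L),
      feat_retention(15L, 38L, "donor"),
      feat_retention(12L, 745L, "span2"),
      feat_tss_cluster(c(0L, 12L, 25L, 40L, 58L), anchor = "ref_start"),
      feat_tss_cluster(c(0L, 100L, 200L, 300L), anchor = "tx", tx = "me_first_i11"),
      feat_tata(1L)))
}
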