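STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_nt <- function(nt) {
  if (nchar(nt) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(nt), no.init.codon = TRUE))
}

codons_of <- function(s, from = 1L) {
  n <- floor((nchar(s) - from + 1L) / 3L)
  if (n <= 0L) return(character())
  substring(s, from + 3L * (seq_len(n) - 1L), from + 3L * seq_len(n) - 1L)
}

#' Find the ORF of a transcript and translate it
#'
#' When the transcript carries a CDS annotation that span is translated;
#' otherwise the ORF runs from the first AUG to the first in-frame stop
#' (no Kozak-context scoring), the way ORFs are read off cloned cDNAs.
#' Standard nuclear genetic code. A transcript with no AUG or no in-frame
#' stop is recorded as non-coding, not an error.
#'
#' @param locus a [gene_locus()] (or contig sequence).
#' @param t a [transcript_model()].
#' @return An object of class `"protein_isoform"`: `transcript_id`,
#'   `coding` (logical), `sequence` (amino acids, no stop symbol), `length`
#'   (residues), `orf_span` (1-based spliced coordinates, start codon through
#'   stop codon inclusive).
#' @export
find_orf_and_translate <- function(locus, t) {
  s <- spliced_sequence(locus, t)
  noncoding <- function(note) structure(
    list(transcript_id = t$id, coding = FALSE, sequence = NA_character_,
         length = NA_integer_, orf_span = c(NA_integer_, NA_integer_),
         note = note), class = "protein_isoform")
  if (nchar(s) < 6L) return(noncoding("spliced sequence shorter than 6 nt"))
  if (!is.null(t$cds)) {
    b <- sort(genomic_to_spliced(t, t$cds))
    orf <- substr(s, b[1L], b[2L])
    if (nchar(orf) %% 3L != 0L) stop("annotated CDS length not divisible by 3")
    from <- b[1L]
  } else {
    i <- regexpr("ATG", s, fixed = TRUE)
    if (i < 0L) return(noncoding("no AUG"))
    cods <- codons_of(s, as.integer(i))
    stop_i <- which(cods %in% STOP_CODONS)
    if (length(stop_i) == 0L) return(noncoding("no in-frame stop"))
    orf <- substr(s, i, i + 3L * stop_i[1L] - 1L)
    from <- as.integer(i)
  }
  aa <- translate_nt(orf)
  if (substr(aa, nchar(aa), nchar(aa)) != "*")
    stop(sprintf("ORF of %s does not end in a stop codon", t$id))
  prot <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", prot, fixed = TRUE))
    stop(sprintf("internal stop codon in annotated CDS of %s", t$id))
  structure(list(transcript_id = t$id, coding = TRUE, sequence = prot,
                 length = nchar(prot),
                 orf_span = c(from, from + nchar(orf) - 1L), note = ""),
            class = "protein_isoform")
}

#' @export
print.protein_isoform <- function(x, ...) {
  if (x$coding)
    cat(sprintf("<protein_isoform> %s: %d aa (ORF %d-%d)\n", x$transcript_id,
                x$length, x$orf_span[1], x$orf_span[2]))
  else cat(sprintf("<protein_isoform> %s: non-coding (%s)\n", x$transcript_id, x$note))
  invisible(x)
}

new_consequence <- function(category, deleted = 0L, substitutions = NULL,
                            ptc = NA_integer_, nmd = FALSE, truncation = NULL,
                            note = "") {
  if (is.null(substitutions))
    substitutions <- data.frame(position = integer(), ref_aa = character(),
                                alt_aa = character(), stringsAsFactors = FALSE)
  structure(list(category = category, deleted_residues = as.integer(deleted),
                 substitutions = substitutions,
                 ptc_spliced_position = as.integer(ptc),
                 nmd_candidate = nmd, truncation = truncation, note = note),
            class = "coding_consequence")
}

#' @export
print.coding_consequence <- function(x, ...) {
  cat(sprintf("<coding_consequence> %s", x$category))
  if (x$deleted_residues > 0L) cat(sprintf(", %d residue(s) deleted", x$deleted_residues))
  if (nrow(x$substitutions) > 0L)
    cat(sprintf(", substitution %s",
                paste(sprintf("%s%d%s", x$substitutions$ref_aa,
                              x$substitutions$position, x$substitutions$alt_aa),
                      collapse = ",")))
  if (!is.na(x$ptc_spliced_position))
    cat(sprintf(", PTC at spliced position %d (NMD candidate: %s)",
                x$ptc_spliced_position, x$nmd_candidate))
  if (!is.null(x$truncation))
    cat(sprintf(", truncation (unique_n=%d, missing_n=%d, shared=%d)",
                x$truncation$unique_n, x$truncation$missing_n,
                x$truncation$shared_suffix))
  cat("\n")
  invisible(x)
}

# first downstream in-frame stop in `s` translating from spliced position
# `from`; returns the spliced position of the stop codon's first base, or NA
first_inframe_stop <- function(s, from) {
  cods <- codons_of(s, from)
  i <- which(cods %in% STOP_CODONS)
  if (length(i) == 0L) return(NA_integer_)
  from + 3L * (i[1L] - 1L)
}

last_junction_spliced <- function(t) {
  n <- n_exons(t)
  if (n < 2L) return(NA_integer_)
  spliced_length(t) - exon_lengths(t)[if (t$strand == "+") n else 1L]
}

#' Protein-level consequence of one splice event
#'
#' Classifies an event from [diff_transcripts()]:
#' \describe{
#'   \item{silent_utr}{the event lies entirely outside the reference CDS;
#'     the protein is untouched.}
#'   \item{inframe_deletion(_with_substitution)}{an exclusion divisible by 3
#'     removes `|delta|/3` residues; when the excision is not codon-aligned
#'     the chimeric junction codon is translated and a substitution is
#'     reported only if the residue actually changes.}
#'   \item{inframe_insertion(_with_substitution)}{the symmetric case for
#'     in-frame retained sequence without a stop codon.}
#'   \item{frameshift_ptc}{`delta` not divisible by 3 (or retained in-frame
#'     sequence carrying a stop): the first downstream in-frame stop becomes
#'     the premature termination codon; `nmd_candidate` is `TRUE` when the
#'     PTC lies more than `nmd_distance` nt upstream of the transcript's last
#'     exon-exon junction (the standard 50-nt rule; advisory only).}
#' }
#'
#' @param locus a [gene_locus()].
#' @param ref reference [transcript_model()] (must carry a CDS).
#' @param alt alternative [transcript_model()].
#' @param event one row of the data.frame from `diff_transcripts(alt, ref)`.
#' @param nmd_distance nt upstream of the last junction beyond which a PTC is
#'   flagged as an NMD candidate (default 50).
#' @return A `"coding_consequence"` object.
#' @export
consequence_of_event <- function(locus, ref, alt, event, nmd_distance = 50L) {
  if (is.null(ref$cds)) stop("reference transcript has no CDS")
  ev_lo <- event$start; ev_hi <- event$end
  if (ev_hi < ref$exons$start[1L] || ev_lo > ref$exons$end[n_exons(ref)])
    stop("event outside transcript bounds")
  delta <- event$delta_nt

  if (ev_hi < ref$cds[1L] || ev_lo > ref$cds[2L])
    return(new_consequence("silent_utr"))

  refseq <- spliced_sequence(locus, ref)
  if (identical(event$kind, "mutually_exclusive_pair")) {
    # an internal exon swap: summarise by whole-protein alignment
    cb0 <- sort(genomic_to_spliced(ref, ref$cds))
    rp <- substr(translate_nt(substr(refseq, cb0[1L], cb0[2L])), 1L,
                 (cb0[2L] - cb0[1L] + 1L) / 3L - 1L)
    altp <- find_orf_and_translate(locus, alt)
    if (!altp$coding)
      return(new_consequence("frameshift_ptc", note = "alternative transcript non-coding"))
    pre <- common_prefix_len(rp, altp$sequence)
    suf <- common_suffix_len(rp, altp$sequence)
    over <- pre + suf - min(nchar(rp), nchar(altp$sequence))
    if (over > 0L) pre <- pre - over
    return(new_consequence("exon_substitution", deleted = nchar(rp) - pre - suf,
                           note = sprintf("%d reference residue(s) replaced by %d novel residue(s)",
                                          nchar(rp) - pre - suf,
                                          nchar(altp$sequence) - pre - suf)))
  }
  cb <- sort(genomic_to_spliced(ref, ref$cds))
  ref_cds <- substr(refseq, cb[1L], cb[2L])
  ref_prot <- substr(translate_nt(ref_cds), 1L, nchar(ref_cds) / 3L - 1L)

  altseq <- spliced_sequence(locus, alt)
  ast <- genomic_to_spliced(alt, ref$cds[1L])
  if (is.na(ast))
    stop("reference start codon is not exonic in the alternative transcript")

  if (delta %% 3L != 0L) {
    ptc <- first_inframe_stop(altseq, ast)
    if (is.na(ptc)) return(new_consequence("frameshift_ptc",
                                           note = "no in-frame stop found"))
    jp <- last_junction_spliced(alt)
    nmd <- !is.na(jp) && (jp - ptc) > nmd_distance
    return(new_consequence("frameshift_ptc", ptc = ptc, nmd = nmd))
  }

  if (delta < 0L) {
    # exclusion of |delta| nt that are exonic in the reference
    p1 <- genomic_to_spliced(ref, ev_lo)
    p0 <- p1 - cb[1L]                      # 0-based offset within the CDS
    if (is.na(p1) || p0 < 0L || p1 - delta - 1L > cb[2L]) {
      # straddles the CDS boundary: fall back to whole-protein comparison
      return(protein_diff_consequence(locus, ref, alt, ref_prot))
    }
    deleted <- (-delta) %/% 3L
    alt_cds <- paste0(substr(ref_cds, 1L, p0), substring(ref_cds, p0 - delta + 1L))
    if (p0 %% 3L == 0L)
      return(new_consequence("inframe_deletion", deleted))
    ci <- p0 %/% 3L                         # 0-based index of the chimeric codon
    chim <- substr(alt_cds, ci * 3L + 1L, ci * 3L + 3L)
    aa_new <- translate_nt(chim)
    # compare against the reference codon contributing the majority of the
    # chimeric codon (one prefix base -> the downstream codon, two -> upstream)
    cmp_idx <- if (p0 %% 3L == 1L) (p0 - delta) %/% 3L + 1L else ci + 1L
    aa_ref <- substr(ref_prot, cmp_idx, cmp_idx)
    if (aa_new %in% c("*", "")) {
      ptc <- ast + ci * 3L
      jp <- last_junction_spliced(alt)
      return(new_consequence("frameshift_ptc", ptc = ptc,
                             nmd = !is.na(jp) && (jp - ptc) > nmd_distance,
                             note = "stop created at deletion junction"))
    }
    if (aa_new != aa_ref)
      return(new_consequence("inframe_deletion_with_substitution", deleted,
                             substitutions = data.frame(position = cmp_idx,
                                                        ref_aa = aa_ref,
                                                        alt_aa = aa_new,
                                                        stringsAsFactors = FALSE)))
    return(new_consequence("inframe_deletion", deleted))
  }

  # delta > 0, in frame: retained sequence inserted into the CDS
  aend <- genomic_to_spliced(alt, ref$cds[2L])
  if (is.na(aend))
    return(protein_diff_consequence(locus, ref, alt, ref_prot))
  alt_cds <- substr(altseq, ast, aend)
  aa <- translate_nt(alt_cds)
  body <- substr(aa, 1L, nchar(aa) - 1L)
  star <- regexpr("*", body, fixed = TRUE)
  if (star > 0L) {
    ptc <- ast + 3L * (as.integer(star) - 1L)
    jp <- last_junction_spliced(alt)
    return(new_consequence("frameshift_ptc", ptc = ptc,
                           nmd = !is.na(jp) && (jp - ptc) > nmd_distance,
                           note = "stop codon within in-frame retained sequence"))
  }
  ins <- delta %/% 3L
  # substitution check at the insertion junctions via prefix/suffix alignment
  sub_df <- chimeric_substitutions(ref_prot, body)
  cat_name <- if (nrow(sub_df)) "inframe_insertion_with_substitution" else "inframe_insertion"
  new_consequence(cat_name, deleted = 0L, substitutions = sub_df,
                  note = sprintf("%d residue(s) inserted", ins))
}

# longest common prefix/suffix alignment of two proteins; any single
# mismatched residue bordering the indel is reported as a substitution
chimeric_substitutions <- function(ref_p, alt_p) {
  la <- nchar(ref_p); lb <- nchar(alt_p)
  pre <- common_prefix_len(ref_p, alt_p)
  suf <- common_suffix_len(ref_p, alt_p)
  over <- pre + suf - min(la, lb)
  if (over > 0L) { pre <- pre - over }
  empty <- data.frame(position = integer(), ref_aa = character(),
                      alt_aa = character(), stringsAsFactors = FALSE)
  # mismatch window on the reference: residues pre+1 .. la-suf
  if (la - suf - pre == 1L && lb - suf - pre >= 1L) {
    pos <- pre + 1L
    ra <- substr(ref_p, pos, pos)
    aa <- substr(alt_p, lb - suf, lb - suf)
    if (ra != aa) return(data.frame(position = pos, ref_aa = ra, alt_aa = aa,
                                    stringsAsFactors = FALSE))
  }
  empty
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

common_suffix_len <- function(a, b) {
  la <- nchar(a); lb <- nchar(b); n <- min(la, lb)
  av <- rev(utf8ToInt(a)); bv <- rev(utf8ToInt(b))
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

# fallback: classify an event by translating both transcripts in full
protein_diff_consequence <- function(locus, ref, alt, ref_prot) {
  altp <- find_orf_and_translate(locus, alt)
  if (!altp$coding) return(new_consequence("frameshift_ptc",
                                           note = "alternative transcript non-coding"))
  if (identical(altp$sequence, ref_prot)) return(new_consequence("silent_utr"))
  st <- nterm_truncation_stats(ref_prot, altp$sequence)
  new_consequence("n_terminal_truncation", truncation = st,
                  note = "classified by whole-protein comparison")
}

#' N-terminal truncation bookkeeping for a protein isoform pair
#'
#' Compares two proteins by their longest common suffix: `shared_suffix` is
#' its length, `unique_n` the novel N-terminal residues of the alternative
#' isoform, `missing_n` the reference N-terminal residues it lacks. The
#' identity `length(alt) = length(ref) - missing_n + unique_n` holds by
#' construction. A pair with no common suffix is still summarised but flagged
#' `unrelated`.
#'
#' @param ref_protein,alt_protein amino-acid strings (or
#'   `"protein_isoform"` objects).
#' @return list with `unique_n`, `missing_n`, `shared_suffix`, `unrelated`.
#' @export
nterm_truncation_stats <- function(ref_protein, alt_protein) {
  a <- if (inherits(ref_protein, "protein_isoform")) ref_protein$sequence else ref_protein
  b <- if (inherits(alt_protein, "protein_isoform")) alt_protein$sequence else alt_protein
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  k <- common_suffix_len(a, b)
  list(unique_n = nchar(b) - k, missing_n = nchar(a) - k,
       shared_suffix = k, unrelated = k == 0L)
}

#' Predicted isoform length from the truncation identity
#'
#' @param ref_len reference protein length (residues).
#' @param missing_n reference N-terminal residues the isoform lacks.
#' @param unique_n novel N-terminal residues of the isoform.
#' @return `ref_len - missing_n + unique_n`.
#' @examples
#' predicted_isoform_length(1278, 166, 16)  # 1128
#' predicted_isoform_length(1278, 227, 32)  # 1083
#' @export
predicted_isoform_length <- function(ref_len, missing_n, unique_n) {
  stopifnot(missing_n <= ref_len)
  as.integer(ref_len - missing_n + unique_n)
}

#' Protein-level consequence of an alternative first exon
#'
#' Translates both transcripts and reports `silent_utr` when the proteins are
#' identical, `noncoding` when the alternative transcript yields no ORF, and
#' otherwise `n_terminal_truncation` with the [nterm_truncation_stats()]
#' triple.
#'
#' @param locus a [gene_locus()].
#' @param ref,alt [transcript_model()]s.
#' @return A `"coding_consequence"` object.
#' @export
consequence_of_first_exon <- function(locus, ref, alt) {
  refp <- find_orf_and_translate(locus, ref)
  altp <- find_orf_and_translate(locus, alt)
  if (!altp$coding) return(new_consequence("noncoding", note = altp$note))
  if (identical(refp$sequence, altp$sequence)) return(new_consequence("silent_utr"))
  st <- nterm_truncation_stats(refp$sequence, altp$sequence)
  new_consequence("n_terminal_truncation", truncation = st,
                  note = if (st$unrelated) "unrelated C-termini" else "")
}
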