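#' Genomic interval
#'
#' A simple container for a 1-based, fully-closed genomic interval, the
#' convention used by GFF3 and by printed coordinates in the genomics
#' literature. All coordinates in this package follow this convention.
#'
#' @param contig contig/chromosome identifier.
#' @param start,end 1-based inclusive boundaries, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `"genomic_interval"`.
#' @examples
#' iv <- genomic_interval("chr5", 16669728, 16670275)
#' interval_length(iv)  # 548
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start > end) stop("interval start must not exceed end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(contig = as.character(contig), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' Number of bases covered by an interval
#'
#' Under the 1-based inclusive convention a degenerate interval with
#' `start == end` covers one base, and the interval 9394--10516 covers
#' 1123 bases.
#'
#' @param iv a [genomic_interval()], or anything with `$start`/`$end`.
#' @return Integer base count.
#' @export
interval_length <- function(iv) {
  as.integer(iv$end - iv$start + 1L)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%d-%d(%s) [%d nt]\n",
              x$contig, x$start, x$end, x$strand, interval_length(x)))
  invisible(x)
}

#' Transcript model
#'
#' An ordered set of exon intervals on one contig, with an optional CDS span.
#' Exons are stored 1-based inclusive, sorted by genomic start, non-overlapping
#' and separated by at least one intronic nucleotide; an intron-retention
#' isoform simply has the retained region merged into a single exon row.
#'
#' @param id transcript identifier.
#' @param exons data.frame with integer columns `start`, `end` (1-based
#'   inclusive) and optionally `label`; rows may arrive in any order.
#' @param cds optional length-2 integer vector: genomic span of the coding
#'   sequence (leftmost, rightmost base, including the stop codon). Both
#'   boundaries must be exonic.
#' @param strand `"+"` or `"-"`. Transcription order is ascending starts on
#'   `"+"` and descending on `"-"`.
#' @param source provenance tag: one of `"RACE"`, `"RNASeq"`, `"RefSeq"`,
#'   `"cloned"`, `"synthetic"`.
#' @param contig contig identifier.
#' @return An object of class `"transcript_model"`.
#' @export
transcript_model <- function(id, exons, cds = NULL, strand = "+",
                             source = "synthetic", contig = "locus") {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1L)
  ex <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  ex$label <- if ("label" %in% names(exons)) as.character(exons$label) else NA_character_
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  if (any(ex$start > ex$end)) stop("exon start must not exceed end")
  n <- nrow(ex)
  if (n > 1L && any(ex$start[-1L] <= ex$end[-n] + 1L))
    stop("exons must be non-overlapping and separated by >= 1 intronic nt")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  source <- match.arg(source, c("RACE", "RNASeq", "RefSeq", "cloned", "synthetic"))
  t <- structure(list(id = as.character(id), exons = ex, cds = NULL,
                      strand = strand, source = source,
                      contig = as.character(contig)),
                 class = "transcript_model")
  if (!is.null(cds)) {
    cds <- sort(as.integer(cds))
    stopifnot(length(cds) == 2L)
    if (is.na(genomic_to_spliced(t, cds[1])) || is.na(genomic_to_spliced(t, cds[2])))
      stop("CDS boundaries must fall inside exons")
    t$cds <- cds
  }
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s [%s, %s]: %d exon(s), %d nt spliced%s\n",
              x$id, x$source, x$strand, nrow(x$exons), spliced_length(x),
              if (is.null(x$cds)) "" else sprintf(", CDS %d-%d", x$cds[1], x$cds[2])))
  invisible(x)
}

n_exons <- function(t) nrow(t$exons)

exon_lengths <- function(t) t$exons$end - t$exons$start + 1L

#' Total spliced (mature mRNA) length of a transcript
#' @param t a [transcript_model()].
#' @return Integer nucleotide count.
#' @export
spliced_length <- function(t) sum(exon_lengths(t))

#' Intron spans of a transcript
#'
#' @param t a [transcript_model()].
#' @return data.frame with columns `start`, `end` (1-based inclusive intronic
#'   span, genomic order) and `length`; zero rows for single-exon transcripts.
#' @export
introns <- function(t) {
  n <- n_exons(t)
  if (n < 2L) return(data.frame(start = integer(), end = integer(), length = integer()))
  s <- t$exons$end[-n] + 1L
  e <- t$exons$start[-1L] - 1L
  data.frame(start = s, end = e, length = e - s + 1L)
}

#' Transcription start position of a transcript
#'
#' The genomic position of the transcript's first (5'-most in transcription
#' order) nucleotide.
#' @param t a [transcript_model()].
#' @return Integer genomic position.
#' @export
tx_start <- function(t) {
  if (t$strand == "+") t$exons$start[1L] else t$exons$end[n_exons(t)]
}

#' Map a genomic position to spliced transcript coordinates
#'
#' Returns the 1-based position of genomic base `g` within the spliced
#' transcript (counting in transcription order), or `NA` when `g` is intronic
#' or outside the transcript. Vectorised over `g`. Inverse of
#' [spliced_to_genomic()] on exonic positions.
#'
#' @param t a [transcript_model()].
#' @param g integer vector of genomic positions.
#' @return Integer vector, `NA` where `g` is not exonic.
#' @export
genomic_to_spliced <- function(t, g) {
  g <- as.integer(g)
  ex <- t$exons
  lens <- ex$end - ex$start + 1L
  if (t$strand == "+") {
    before <- c(0L, cumsum(lens))[-(nrow(ex) + 1L)]
    out <- rep(NA_integer_, length(g))
    for (i in seq_len(nrow(ex))) {
      hit <- !is.na(g) & g >= ex$start[i] & g <= ex$end[i]
      out[hit] <- before[i] + (g[hit] - ex$start[i] + 1L)
    }
  } else {
    ord <- rev(seq_len(nrow(ex)))
    before <- c(0L, cumsum(lens[ord]))[-(nrow(ex) + 1L)]
    out <- rep(NA_integer_, length(g))
    for (k in seq_along(ord)) {
      i <- ord[k]
      hit <- !is.na(g) & g >= ex$start[i] & g <= ex$end[i]
      out[hit] <- before[k] + (ex$end[i] - g[hit] + 1L)
    }
  }
  out
}

#' Map a spliced transcript position back to the genome
#'
#' @param t a [transcript_model()].
#' @param p integer vector of 1-based spliced positions.
#' @return Integer vector of genomic positions; `NA` outside `1..spliced_length`.
#' @export
spliced_to_genomic <- function(t, p) {
  p <- as.integer(p)
  ex <- t$exons
  lens <- ex$end - ex$start + 1L
  ord <- if (t$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  bounds <- c(0L, cumsum(lens[ord]))
  out <- rep(NA_integer_, length(p))
  for (k in seq_along(ord)) {
    i <- ord[k]
    hit <- !is.na(p) & p > bounds[k] & p <= bounds[k + 1L]
    off <- p[hit] - bounds[k]
    out[hit] <- if (t$strand == "+") ex$start[i] + off - 1L else ex$end[i] - off + 1L
  }
  out
}

#' Spliced (mature mRNA) sequence of a transcript
#'
#' Concatenates exon sequences in transcription order; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param locus a [gene_locus()] (or any list with a `$seq` character contig).
#' @param t a [transcript_model()].
#' @return Character scalar of length [spliced_length()].
#' @export
spliced_sequence <- function(locus, t) {
  seqc <- locus_seq(locus)
  parts <- substring(seqc, t$exons$start, t$exons$end)
  s <- paste(parts, collapse = "")
  if (t$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

locus_seq <- function(locus) {
  if (is.character(locus)) return(locus)
  as.character(locus$seq)
}

#' Gene locus container
#'
#' Bundles a contig sequence, the reference transcript model, any number of
#' alternative transcript models, and mapped transcript 5'-end evidence.
#' Minus-strand loci are normalised to a plus-strand working copy at load time
#' by [read_gene_models()]; constructed loci are expected on the plus strand.
#'
#' @param seq contig sequence (character or `DNAString`).
#' @param reference reference [transcript_model()]; must carry a CDS.
#' @param alternatives list of alternative [transcript_model()]s.
#' @param evidence data.frame of 5'-end evidence with columns `position`,
#'   `strand`, `source` (`RACE`/`RNASeq`/`RefSeq`) and `transcript_id`
#'   (may be `NA`), or `NULL`.
#' @param contig contig identifier.
#' @return An object of class `"gene_locus"`.
#' @export
gene_locus <- function(seq, reference, alternatives = list(), evidence = NULL,
                       contig = "locus") {
  seq <- as.character(seq)
  stopifnot(inherits(reference, "transcript_model"))
  if (is.null(reference$cds)) stop("reference transcript must carry a CDS")
  L <- nchar(seq)
  for (t in c(list(reference), alternatives)) {
    if (t$exons$start[1L] < 1L || t$exons$end[n_exons(t)] > L)
      stop(sprintf("transcript %s falls outside the contig", t$id))
  }
  if (is.null(evidence)) {
    evidence <- data.frame(position = integer(), strand = character(),
                           source = character(), transcript_id = character(),
                           stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("position", "source") %in% names(evidence)))
    if (is.null(evidence$strand)) evidence$strand <- "+"
    if (is.null(evidence$transcript_id)) evidence$transcript_id <- NA_character_
    evidence$position <- as.integer(evidence$position)
    if (any(evidence$position < 1L | evidence$position > L))
      stop("evidence position outside contig bounds")
    bad <- !evidence$source %in% c("RACE", "RNASeq", "RefSeq")
    if (any(bad)) stop("evidence source must be RACE, RNASeq or RefSeq")
  }
  structure(list(seq = seq, contig = as.character(contig),
                 reference = reference, alternatives = alternatives,
                 evidence = evidence),
            class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s: %d nt contig, reference %s (%d exons), %d alternative(s), %d 5'-end tag(s)\n",
              x$contig, nchar(x$seq), x$reference$id, n_exons(x$reference),
              length(x$alternatives), nrow(x$evidence)))
  invisible(x)
}

all_models <- function(locus) c(list(locus$reference), locus$alternatives)
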