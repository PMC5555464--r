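empty_events <- function() {
  data.frame(kind = character(), ref_exons = character(), delta_nt = integer(),
             start = integer(), end = integer(), nagnag = logical(),
             note = character(), stringsAsFactors = FALSE)
}

event_row <- function(kind, ref_exons, delta, start, end, nagnag = FALSE, note = "") {
  data.frame(kind = kind, ref_exons = paste(ref_exons, collapse = ","),
             delta_nt = as.integer(delta), start = as.integer(start),
             end = as.integer(end), nagnag = nagnag, note = note,
             stringsAsFactors = FALSE)
}

clipped_spliced_length <- function(ex, lo, hi) {
  sum(pmax(0L, pmin(ex$end, hi) - pmax(ex$start, lo) + 1L))
}

#' Enumerate splice events between an alternative transcript and the reference
#'
#' Diffs the intron chains of the two transcripts over their shared region and
#' assigns every boundary difference to exactly one event:
#' \describe{
#'   \item{skipped_exon}{a contiguous run of reference exons bridged by one
#'     alternative intron (one event per run, all ordinals recorded);
#'     `delta_nt` = minus the skipped exonic length.}
#'   \item{alt_donor / alt_acceptor}{a 5' donor or 3' acceptor shifted into
#'     the exon (excluding sequence from the mRNA, `delta_nt < 0`). A 3-nt
#'     acceptor shift at a NAGNAG tandem acceptor is flagged `nagnag`.}
#'   \item{cryptic_donor_utr}{a donor shifted downstream into the intron
#'     entirely within the 5'-UTR, lengthening the UTR without touching the
#'     coding region.}
#'   \item{intron_retention}{intronic sequence kept in the mature transcript,
#'     either a whole intron (or several, with any subsumed reference exons
#'     recorded) or a partial run at the donor or acceptor edge;
#'     `delta_nt` = +retained intronic nt.}
#'   \item{mutually_exclusive_pair}{a reference internal exon replaced by a
#'     disjoint novel exon between the same flanking junctions.}
#' }
#' First-exon differences are factored out (see [classify_first_exon()]): for
#' non-canonical first exons the comparison starts at the acceptor the
#' alternative transcript first splices into. The sum of `delta_nt` over all
#' events equals the spliced-length difference over the compared region
#' (checked; violation raises a warning and is recorded in the
#' `"conserved"` attribute).
#'
#' @param alt,ref [transcript_model()]s on the same contig and strand.
#' @param locus optional [gene_locus()] (or contig character); enables NAGNAG
#'   classification of 3-nt acceptor shifts.
#' @param first_exon_tolerance nt of start scatter treated as the same
#'   (canonical) first exon; default 62.
#' @return data.frame of events sorted 5' to 3' with columns `kind`,
#'   `ref_exons`, `delta_nt`, `start`, `end`, `nagnag`, `note`.
#' @export
diff_transcripts <- function(alt, ref, locus = NULL, first_exon_tolerance = 62L) {
  stopifnot(inherits(alt, "transcript_model"), inherits(ref, "transcript_model"))
  if (!identical(alt$contig, ref$contig) || !identical(alt$strand, ref$strand))
    stop("transcripts must share contig and strand")
  seqc <- if (is.null(locus)) NULL else locus_seq(locus)
  aex <- alt$exons; rex <- ref$exons
  out <- empty_events()

  if (aex$end[nrow(aex)] < rex$start[1L] || rex$end[nrow(rex)] < aex$start[1L]) {
    warning("transcripts do not overlap; no events called")
    return(out)
  }
  canonical_first <- abs(aex$start[1L] - rex$start[1L]) <= first_exon_tolerance
  if (canonical_first) {
    cmp_start <- max(aex$start[1L], rex$start[1L])
  } else {
    if (nrow(aex) < 2L) return(structure(out, conserved = TRUE))
    cmp_start <- aex$start[2L]
  }
  cmp_end <- min(aex$end[nrow(aex)], rex$end[nrow(rex)])
  if (cmp_end <= cmp_start) return(structure(out, conserved = TRUE))

  rin <- introns(ref); rin$ord <- seq_len(nrow(rin))
  ain <- introns(alt); ain$ord <- seq_len(nrow(ain))
  rin <- rin[rin$start >= cmp_start & rin$end <= cmp_end, , drop = FALSE]
  ain <- ain[ain$start >= cmp_start & ain$end <= cmp_end, , drop = FALSE]

  key <- function(x) paste(x$start, x$end)
  shared <- intersect(key(rin), key(ain))
  rin <- rin[!key(rin) %in% shared, , drop = FALSE]
  ain <- ain[!key(ain) %in% shared, , drop = FALSE]

  nagnag_at <- function(acc) {
    if (is.null(seqc) || acc < 6L) return(FALSE)
    grepl("^[ACGT]AG[ACGT]AG$", substr(seqc, acc - 5L, acc))
  }
  in_utr5 <- function(lo, hi) !is.null(ref$cds) && hi < ref$cds[1L]

  # --- full retentions: unmatched ref introns with no alt-intron overlap,
  #     grouped by the alternative exon that contains them
  if (nrow(rin)) {
    overlaps_alt_intron <- vapply(seq_len(nrow(rin)), function(i) {
      nrow(ain) > 0L && any(ain$start <= rin$end[i] & ain$end >= rin$start[i])
    }, logical(1L))
    retained <- rin[!overlaps_alt_intron, , drop = FALSE]
    rin <- rin[overlaps_alt_intron, , drop = FALSE]
    if (nrow(retained)) {
      host <- vapply(seq_len(nrow(retained)), function(i) {
        h <- which(aex$start <= retained$start[i] & aex$end >= retained$end[i])
        if (length(h)) h[1L] else NA_integer_
      }, integer(1L))
      bad <- is.na(host)
      if (any(bad)) {
        warning("reference intron neither spliced nor fully retained; unresolved")
        retained <- retained[!bad, , drop = FALSE]; host <- host[!bad]
      }
      if (nrow(retained)) {
        grp <- cumsum(c(1L, as.integer(diff(retained$ord) != 1L |
                                         diff(host) != 0L)))
        for (g in split(seq_len(nrow(retained)), grp)) {
          ri <- retained[g, , drop = FALSE]
          subsumed <- if (nrow(ri) > 1L) (min(ri$ord) + 1L):max(ri$ord) else integer()
          out <- rbind(out, event_row(
            "intron_retention", subsumed, sum(ri$length),
            min(ri$start), max(ri$end),
            note = if (length(subsumed))
              sprintf("full retention subsuming exon(s) %s",
                      paste(subsumed, collapse = ",")) else "full retention"))
        }
      }
    }
  }

  # --- overlap components of the remaining unmatched introns
  if (nrow(rin) + nrow(ain) > 0L) {
    iv <- rbind(data.frame(s = rin$start, e = rin$end, who = "ref", ord = rin$ord),
                data.frame(s = ain$start, e = ain$end, who = "alt", ord = ain$ord))
    iv <- iv[order(iv$s, iv$e), , drop = FALSE]
    comp <- integer(nrow(iv)); cur <- 0L; maxe <- -1L
    for (i in seq_len(nrow(iv))) {
      if (iv$s[i] > maxe) { cur <- cur + 1L; maxe <- iv$e[i] }
      else maxe <- max(maxe, iv$e[i])
      comp[i] <- cur
    }
    for (ci in unique(comp)) {
      R <- iv[comp == ci & iv$who == "ref", , drop = FALSE]
      A <- iv[comp == ci & iv$who == "alt", , drop = FALSE]
      if (nrow(R) == 1L && nrow(A) == 1L) {
        r <- R[1L, ]; a <- A[1L, ]
        if (r$s != a$s) {            # donor shift (5' boundary of the intron)
          delta <- a$s - r$s
          lo <- min(a$s, r$s); hi <- max(a$s, r$s) - 1L
          kind <- if (delta < 0L) "alt_donor"
                  else if (in_utr5(lo, hi)) "cryptic_donor_utr"
                  else "intron_retention"
          out <- rbind(out, event_row(kind, r$ord, delta, lo, hi,
                                      note = if (kind == "intron_retention")
                                        "partial retention, donor edge" else ""))
        }
        if (r$e != a$e) {            # acceptor shift (3' boundary)
          delta <- r$e - a$e
          lo <- min(a$e, r$e) + 1L; hi <- max(a$e, r$e)
          if (delta < 0L) {
            out <- rbind(out, event_row("alt_acceptor", r$ord + 1L, delta, lo, hi,
                                        nagnag = delta == -3L && nagnag_at(a$e)))
          } else if (delta == 3L && nagnag_at(r$e)) {
            out <- rbind(out, event_row("alt_acceptor", r$ord + 1L, delta, lo, hi,
                                        nagnag = TRUE))
          } else {
            out <- rbind(out, event_row("intron_retention", r$ord + 1L, delta, lo, hi,
                                        note = "partial retention, acceptor edge"))
          }
        }
      } else if (nrow(A) >= 1L && nrow(R) >= 1L) {
        span_lo <- min(c(R$s, A$s)); span_hi <- max(c(R$e, A$e))
        novel <- which(aex$start >= span_lo & aex$end <= span_hi &
                         !vapply(seq_len(nrow(aex)), function(i)
                           any(rex$start <= aex$end[i] & rex$end >= aex$start[i]),
                           logical(1L)))
        if (nrow(A) == 1L && length(novel) == 0L) {
          skipped <- which(rex$start >= A$s[1L] & rex$end <= A$e[1L])
          if (length(skipped) && A$s[1L] == min(R$s) && A$e[1L] == max(R$e)) {
            lens <- rex$end[skipped] - rex$start[skipped] + 1L
            out <- rbind(out, event_row("skipped_exon", skipped, -sum(lens),
                                        min(rex$start[skipped]),
                                        max(rex$end[skipped])))
          } else {
            warning("unresolved multi-intron difference; skipped-exon flanks do not match")
          }
        } else if (length(novel) >= 1L) {
          skipped <- which(vapply(seq_len(nrow(rex)), function(i) {
            rex$start[i] >= span_lo && rex$end[i] <= span_hi &&
              !any(aex$start <= rex$end[i] & aex$end >= rex$start[i])
          }, logical(1L)))
          if (length(skipped)) {
            nlen <- sum(aex$end[novel] - aex$start[novel] + 1L)
            slen <- sum(rex$end[skipped] - rex$start[skipped] + 1L)
            out <- rbind(out, event_row(
              "mutually_exclusive_pair", skipped, nlen - slen, span_lo, span_hi,
              note = sprintf("novel exon %s",
                             paste(sprintf("%d-%d", aex$start[novel], aex$end[novel]),
                                   collapse = ";"))))
          } else {
            warning("novel alternative exon without a displaced reference exon; unresolved")
          }
        } else {
          warning("unresolved splice difference component")
        }
      } else {
        warning("novel intron inside a reference exon; unresolved")
      }
    }
  }

  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  alt_len <- clipped_spliced_length(aex, cmp_start, cmp_end)
  ref_len <- clipped_spliced_length(rex, cmp_start, cmp_end)
  conserved <- sum(out$delta_nt) == alt_len - ref_len
  if (!conserved)
    warning("event deltas do not account for the full spliced-length difference")
  structure(out, conserved = conserved,
            compare_region = c(cmp_start, cmp_end))
}

#' Detect a NAGNAG tandem splice acceptor
#'
#' Tests whether the six intron-terminal nucleotides ending at
#' `acceptor_position` (the last intronic base, i.e. the exon's first base
#' minus one) match NAGNAG (N = any base), the motif offering two 3' splice
#' AGs three nucleotides apart. Under this package's nomenclature the
#' *proximal* AG is the acceptor producing the longer mRNA (the upstream AG
#' of the hexamer) and the *distal* AG the shorter one.
#'
#' @param locus a [gene_locus()] or contig sequence.
#' @param acceptor_position genomic position of the last intronic base.
#' @return `NULL` if no site (or within 6 nt of the contig start), else a
#'   list with `acceptor`, `proximal_AG`, `distal_AG` (positions of each AG's
#'   G) and `motif` (the hexamer).
#' @export
detect_nagnag <- function(locus, acceptor_position) {
  seqc <- locus_seq(locus)
  a <- as.integer(acceptor_position)
  if (a < 6L || a > nchar(seqc)) return(NULL)
  hex <- substr(seqc, a - 5L, a)
  if (!grepl("^[ACGT]AG[ACGT]AG$", hex)) return(NULL)
  list(acceptor = a, proximal_AG = a - 3L, distal_AG = a, motif = hex)
}

#' Report mutually exclusive internal exon pairs across a transcript set
#'
#' Two internal exons form a mutually exclusive pair when they occupy
#' disjoint genomic intervals between the same flanking splice junctions
#' (identical upstream donor and downstream acceptor partners), no transcript
#' contains both, and each appears in at least one transcript.
#'
#' @param alt_set list of [transcript_model()]s.
#' @param ref optional reference [transcript_model()] to include in the set
#'   and to take exon ordinals ("9a"/"9b"-style labels) from.
#' @return data.frame, one row per pair: coordinates of both exons, the
#'   reference ordinal (NA if neither exon is a reference exon), labels, and
#'   the transcripts carrying each.
#' @export
pair_mutually_exclusive <- function(alt_set, ref = NULL) {
  txs <- alt_set
  if (!is.null(ref)) txs <- c(txs, list(ref))
  if (length(txs) < 2L) stop("need at least two transcripts")
  recs <- list()
  for (t in txs) {
    n <- n_exons(t)
    if (n < 3L) next
    for (i in 2L:(n - 1L)) {
      recs[[length(recs) + 1L]] <- data.frame(
        s = t$exons$start[i], e = t$exons$end[i], tx = t$id,
        prev_e = t$exons$end[i - 1L], next_s = t$exons$start[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      ref_ordinal = integer(), label_a = character(),
                      label_b = character(), tx_a = character(),
                      tx_b = character(), stringsAsFactors = FALSE)
  if (length(recs) == 0L) return(empty)
  rd <- do.call(rbind, recs)
  rd$key <- paste(rd$s, rd$e)
  uex <- unique(rd[c("s", "e", "key")])
  uex <- uex[order(uex$s), , drop = FALSE]
  ref_ord_of <- function(s, e) {
    if (is.null(ref)) return(NA_integer_)
    hit <- which(ref$exons$start == s & ref$exons$end == e)
    if (length(hit)) hit else NA_integer_
  }
  out <- empty
  if (nrow(uex) >= 2L) {
    for (i in seq_len(nrow(uex) - 1L)) for (j in (i + 1L):nrow(uex)) {
      if (uex$e[i] >= uex$s[j] && uex$e[j] >= uex$s[i]) next  # not disjoint
      ri <- rd[rd$key == uex$key[i], , drop = FALSE]
      rj <- rd[rd$key == uex$key[j], , drop = FALSE]
      if (length(intersect(ri$tx, rj$tx))) next
      ctx_i <- paste(ri$prev_e, ri$next_s)
      ctx_j <- paste(rj$prev_e, rj$next_s)
      if (!length(intersect(ctx_i, ctx_j))) next
      k <- ref_ord_of(uex$s[i], uex$e[i])
      if (is.na(k)) k <- ref_ord_of(uex$s[j], uex$e[j])
      lab <- if (is.na(k)) c("a", "b") else paste0(k, c("a", "b"))
      out <- rbind(out, data.frame(
        a_start = uex$s[i], a_end = uex$e[i],
        b_start = uex$s[j], b_end = uex$e[j],
        ref_ordinal = k, label_a = lab[1L], label_b = lab[2L],
        tx_a = paste(sort(unique(ri$tx)), collapse = ","),
        tx_b = paste(sort(unique(rj$tx)), collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
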