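#' Call candidate TSSs from 5'-end evidence
#'
#' Classifies each mapped transcript 5'-end against the locus's annotated
#' exon/intron structure. A 5'-end falling in an intron (or outside every
#' annotated exon) is accepted as a putative TSS; one coinciding with an
#' annotated transcript start, or falling within any first exon, is accepted
#' as `annotated_start`; one inside an internal exon is accepted unless it
#' sits exactly on an ATG trinucleotide, in which case it is rejected as a
#' truncated-cDNA suspect (such 5'-ends would begin the transcript at a
#' translation start, the classic signature of incomplete cDNA synthesis).
#'
#' @param locus a [gene_locus()] with evidence.
#' @return data.frame with columns `position`, `source`, `transcript_id`,
#'   `context` (`annotated_start` / `intronic` / `internal_exonic` /
#'   `internal_exonic_at_ATG`) and `status` (`accepted` / `canonical` /
#'   `rejected_truncation_suspect`).
#' @export
call_candidate_tss <- function(locus) {
  ev <- locus$evidence
  models <- all_models(locus)
  starts <- vapply(models, tx_start, integer(1L))
  firsts <- do.call(rbind, lapply(models, function(t) t$exons[1L, c("start", "end")]))
  n <- nrow(ev)
  context <- character(n); status <- character(n)
  for (i in seq_len(n)) {
    p <- ev$position[i]
    in_first <- any(p >= firsts$start & p <= firsts$end)
    in_internal <- FALSE
    for (t in models) {
      nn <- n_exons(t)
      if (nn >= 2L) {
        ex <- t$exons[-1L, , drop = FALSE]
        if (any(p >= ex$start & p <= ex$end)) { in_internal <- TRUE; break }
      }
    }
    if (p %in% starts || in_first) {
      context[i] <- "annotated_start"
      status[i] <- if (p %in% starts) "canonical" else "accepted"
    } else if (in_internal) {
      at_atg <- substr(locus$seq, p, p + 2L) == "ATG"
      context[i] <- if (at_atg) "internal_exonic_at_ATG" else "internal_exonic"
      status[i] <- if (at_atg) "rejected_truncation_suspect" else "accepted"
    } else {
      context[i] <- "intronic"
      status[i] <- "accepted"
    }
  }
  data.frame(position = ev$position, source = ev$source,
             transcript_id = ev$transcript_id, context = context,
             status = status, stringsAsFactors = FALSE)
}

#' Cluster accepted TSSs into putative alternative promoters
#'
#' Single-linkage clustering along the chromosome: consecutive sorted
#' positions separated by a gap strictly greater than `separation_threshold`
#' start a new cluster, following the convention that TSS clusters driven by
#' distinct promoters are separated by more than 500 bp. Ties at exactly the
#' threshold merge. The partition is independent of input order, and lowering
#' the threshold can only increase the number of clusters.
#'
#' @param candidates data.frame from [call_candidate_tss()] (rejected rows are
#'   dropped), or a bare numeric vector of positions.
#' @param separation_threshold maximum intra-cluster gap in nt (default 500).
#' @return List of `"tss_cluster"` objects, 5' to 3'; each has `members`
#'   (data.frame), `representative` (5'-most position), `width`, `n`.
#' @export
cluster_tss <- function(candidates, separation_threshold = 500L) {
  if (is.numeric(candidates))
    candidates <- data.frame(position = as.integer(candidates),
                             source = rep("RNASeq", length(candidates)),
                             transcript_id = rep(NA_character_, length(candidates)),
                             context = rep("intronic", length(candidates)),
                             status = rep("accepted", length(candidates)))
  keep <- candidates$status %in% c("accepted", "canonical")
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(list())
  cand <- cand[order(cand$position), , drop = FALSE]
  gaps <- diff(cand$position)
  grp <- cumsum(c(1L, as.integer(gaps > separation_threshold)))
  unname(lapply(split(seq_len(nrow(cand)), grp), function(ix) {
    m <- cand[ix, , drop = FALSE]
    rownames(m) <- NULL
    structure(list(members = m,
                   representative = min(m$position),
                   width = max(m$position) - min(m$position),
                   n = nrow(m)),
              class = "tss_cluster")
  }))
}

#' @export
print.tss_cluster <- function(x, ...) {
  cat(sprintf("<tss_cluster> rep %d, %d member(s), width %d nt\n",
              x$representative, x$n, x$width))
  invisible(x)
}

#' Classify promoter shape from TSS scatter
#'
#' Sharp promoters (typically TATA-box associated) concentrate initiation
#' within a few tens of nucleotides; broad (CpG-type) promoters scatter it
#' over 100 nt or more. The default cutoff of 62 nt is the reported average
#' range of TSS scatter.
#'
#' @param cluster a `"tss_cluster"` (or anything with `$width`).
#' @param sharp_width_max widths up to this are `sharp` (default 62).
#' @return `"sharp"` or `"broad"`.
#' @export
classify_shape <- function(cluster, sharp_width_max = 62L) {
  if (cluster$width <= sharp_width_max) "sharp" else "broad"
}

#' Scan a promoter window for a TATA-box
#'
#' Searches the sense strand for the TATAWAWR consensus (W = A/T, R = A/G)
#' with the motif start inside `window` relative to the cluster
#' representative. Windows truncated by the contig edge are scanned as far as
#' they reach.
#'
#' @param locus a [gene_locus()].
#' @param cluster a `"tss_cluster"` (or a bare integer TSS position).
#' @param window integer length-2 offsets relative to the representative
#'   (default `c(-40, -20)`).
#' @return list with `tata` (logical) and `position` (genomic start of the
#'   leftmost hit, or `NA`).
#' @export
scan_tata <- function(locus, cluster, window = c(-40L, -20L)) {
  rep_pos <- if (is.numeric(cluster)) as.integer(cluster) else cluster$representative
  L <- nchar(locus_seq(locus))
  lo <- max(1L, rep_pos + as.integer(window[1L]))
  hi <- min(L, rep_pos + as.integer(window[2L]))
  if (hi < lo) return(list(tata = FALSE, position = NA_integer_))
  seg <- substr(locus_seq(locus), lo, min(L, hi + 7L))
  m <- regexpr("TATA[AT]A[AT][AG]", seg)
  if (m > 0L && (lo + m - 1L) <= hi)
    list(tata = TRUE, position = lo + as.integer(m) - 1L)
  else list(tata = FALSE, position = NA_integer_)
}

#' Flag a TSS cluster as internal/exonic
#'
#' A cluster is flagged when its representative lies strictly inside an
#' internal or coding exon of an annotated transcript AND is more than
#' `separation_threshold` nt away from every annotated transcript start
#' (the same threshold that separates promoters); closer clusters are taken
#' to belong to that start's promoter.
#'
#' @param cluster a `"tss_cluster"`.
#' @param locus a [gene_locus()].
#' @param separation_threshold nt (default 500).
#' @return Logical.
#' @export
flag_exonic_tss <- function(cluster, locus, separation_threshold = 500L) {
  p <- cluster$representative
  models <- all_models(locus)
  starts <- vapply(models, tx_start, integer(1L))
  if (min(abs(p - starts)) <= separation_threshold) return(FALSE)
  for (t in models) {
    ex <- t$exons
    inside <- p > ex$start & p < ex$end
    internal <- seq_len(nrow(ex)) > 1L
    coding <- if (is.null(t$cds)) rep(FALSE, nrow(ex)) else
      ex$end >= t$cds[1] & ex$start <= t$cds[2]
    if (any(inside & (internal | coding))) return(TRUE)
  }
  FALSE
}

#' Summarise TSS clusters as a table
#'
#' @param clusters list from [cluster_tss()].
#' @param locus a [gene_locus()] (for TATA scan and exonic flag).
#' @param sharp_width_max,separation_threshold,tata_window thresholds, see
#'   [classify_shape()], [flag_exonic_tss()], [scan_tata()].
#' @return data.frame, one row per cluster.
#' @export
tss_cluster_table <- function(clusters, locus, sharp_width_max = 62L,
                              separation_threshold = 500L,
                              tata_window = c(-40L, -20L)) {
  if (length(clusters) == 0L)
    return(data.frame(representative = integer(), n_members = integer(),
                      width = integer(), shape = character(), tata = logical(),
                      exonic = logical(), sources = character()))
  rows <- lapply(clusters, function(cl) {
    data.frame(representative = cl$representative, n_members = cl$n,
               width = cl$width,
               shape = classify_shape(cl, sharp_width_max),
               tata = scan_tata(locus, cl, tata_window)$tata,
               exonic = flag_exonic_tss(cl, locus, separation_threshold),
               sources = paste(sort(unique(cl$members$source)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
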