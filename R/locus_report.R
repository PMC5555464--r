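#' Count NAGNAG tandem acceptor sites at reference acceptors
#'
#' Scans every internal exon of the reference model for a tandem acceptor:
#' a NAGNAG hexamer positioned so that the annotated acceptor uses one AG and
#' a second AG lies 3 nt away (the hexamer ending two bases inside the exon,
#' i.e. the distal AG supplied by the exon's first codon).
#'
#' @param locus a [gene_locus()].
#' @return Integer count of exons with a tandem acceptor.
#' @export
count_nagnag_sites <- function(locus) {
  ex <- locus$reference$exons
  if (nrow(ex) < 2L) return(0L)
  sum(vapply(2L:nrow(ex), function(k)
    !is.null(detect_nagnag(locus, ex$start[k] + 2L)), logical(1L)))
}

#' Annotate a gene locus: promoters, first exons, splice events, consequences
#'
#' The package's main entry point. Runs the full pipeline:
#' TSS calling ([call_candidate_tss()]) and clustering ([cluster_tss()]) with
#' shape/TATA/exonic classification; first-exon taxonomy
#' ([classify_first_exons()]); per-isoform splice-event diffing
#' ([diff_transcripts()]); NAGNAG site census ([count_nagnag_sites()]); and
#' protein-level consequences ([consequence_of_event()],
#' [consequence_of_first_exon()]).
#'
#' @param locus a [gene_locus()].
#' @param separation_threshold nt gap separating TSS clusters of distinct
#'   promoters (default 500).
#' @param sharp_width_max sharp/broad cluster-shape cutoff in nt (default 62).
#' @param first_exon_tolerance TSS scatter counted as the canonical first
#'   exon, nt (default 62).
#' @param nmd_distance PTC-to-last-junction distance for the NMD flag,
#'   nt (default 50).
#' @param tata_window promoter window scanned for a TATA-box, relative to the
#'   cluster representative (default `c(-40, -20)`).
#' @return An object of class `"locus_report"` with data.frame components
#'   `tss_clusters`, `first_exons`, `events`, `consequences`, a `summary`
#'   list of counts, and the `params` used.
#' @export
annotate_locus <- function(locus, separation_threshold = 500L,
                           sharp_width_max = 62L, first_exon_tolerance = 62L,
                           nmd_distance = 50L, tata_window = c(-40L, -20L)) {
  stopifnot(inherits(locus, "gene_locus"))
  params <- list(separation_threshold = separation_threshold,
                 sharp_width_max = sharp_width_max,
                 first_exon_tolerance = first_exon_tolerance,
                 nmd_distance = nmd_distance,
                 tata_window = as.integer(tata_window))

  candidates <- call_candidate_tss(locus)
  clusters <- cluster_tss(candidates, separation_threshold)
  tss_tab <- tss_cluster_table(clusters, locus, sharp_width_max,
                               separation_threshold, tata_window)

  fe_tab <- classify_first_exons(locus, first_exon_tolerance)

  ev_rows <- list(); cq_rows <- list()
  for (alt in locus$alternatives) {
    evs <- diff_transcripts(alt, locus$reference, locus, first_exon_tolerance)
    if (nrow(evs)) {
      evs <- cbind(transcript_id = alt$id,
                   event_id = sprintf("%s.ev%d", alt$id, seq_len(nrow(evs))),
                   evs, stringsAsFactors = FALSE)
      ev_rows[[length(ev_rows) + 1L]] <- evs
      for (i in seq_len(nrow(evs))) {
        cq <- consequence_of_event(locus, locus$reference, alt, evs[i, ],
                                   nmd_distance)
        cq_rows[[length(cq_rows) + 1L]] <- data.frame(
          transcript_id = alt$id, event_id = evs$event_id[i],
          category = cq$category, deleted_residues = cq$deleted_residues,
          substitutions = paste(sprintf("%s%d%s", cq$substitutions$ref_aa,
                                        cq$substitutions$position,
                                        cq$substitutions$alt_aa), collapse = ","),
          ptc_spliced_position = cq$ptc_spliced_position,
          nmd_candidate = cq$nmd_candidate,
          unique_n = NA_integer_, missing_n = NA_integer_,
          shared_suffix = NA_integer_, stringsAsFactors = FALSE)
      }
    }
    fe_class <- fe_tab$class[fe_tab$transcript_id == alt$id]
    if (length(fe_class) == 1L && fe_class != "canonical") {
      cq <- consequence_of_first_exon(locus, locus$reference, alt)
      cq_rows[[length(cq_rows) + 1L]] <- data.frame(
        transcript_id = alt$id, event_id = sprintf("%s.first_exon", alt$id),
        category = cq$category, deleted_residues = cq$deleted_residues,
        substitutions = "", ptc_spliced_position = NA_integer_,
        nmd_candidate = FALSE,
        unique_n = if (is.null(cq$truncation)) NA_integer_ else cq$truncation$unique_n,
        missing_n = if (is.null(cq$truncation)) NA_integer_ else cq$truncation$missing_n,
        shared_suffix = if (is.null(cq$truncation)) NA_integer_ else cq$truncation$shared_suffix,
        stringsAsFactors = FALSE)
    }
  }
  ev_tab <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    cbind(transcript_id = character(), event_id = character(), empty_events())
  cq_tab <- if (length(cq_rows)) do.call(rbind, cq_rows) else
    data.frame(transcript_id = character(), event_id = character(),
               category = character(), deleted_residues = integer(),
               substitutions = character(), ptc_spliced_position = integer(),
               nmd_candidate = logical(), unique_n = integer(),
               missing_n = integer(), shared_suffix = integer(),
               stringsAsFactors = FALSE)
  rownames(ev_tab) <- NULL; rownames(cq_tab) <- NULL

  smry <- list(
    locus = locus$contig,
    n_isoforms = 1L + length(locus$alternatives),
    n_PAPs = nrow(tss_tab),
    n_ME_first_exons = sum(fe_tab$class == "mutually_exclusive_first"),
    n_extensions = sum(fe_tab$class == "five_prime_extension"),
    n_NAGNAG = count_nagnag_sites(locus),
    n_retentions = sum(ev_tab$kind == "intron_retention") +
      sum(fe_tab$class == "intron_retaining_first"),
    n_events = nrow(ev_tab))

  structure(list(tss_clusters = tss_tab, first_exons = fe_tab,
                 events = ev_tab, consequences = cq_tab,
                 summary = smry, params = params),
            class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<locus_report> %s\n", s$locus))
  cat(sprintf("  isoforms: %d   putative alternative promoters: %d\n",
              s$n_isoforms, s$n_PAPs))
  cat(sprintf("  first exons: %d mutually exclusive, %d 5'-extension\n",
              s$n_ME_first_exons, s$n_extensions))
  cat(sprintf("  NAGNAG tandem acceptors: %d   splice events: %d (%d retention)\n",
              s$n_NAGNAG, s$n_events, s$n_retentions))
  invisible(x)
}

#' @export
summary.locus_report <- function(object, ...) object$summary

#' Write a locus report as TSV tables + JSON
#'
#' Emits `tss_clusters.tsv`, `first_exons.tsv`, `events.tsv`,
#' `consequences.tsv` and a `report.json` combining all tables, the summary
#' counts and every threshold used (full provenance). Output is
#' deterministic: identical inputs yield byte-identical files.
#'
#' @param report a `"locus_report"`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "locus_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) utils::write.table(
    df, file.path(dir, nm), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(report$tss_clusters, "tss_clusters.tsv")
  wr(report$first_exons, "first_exons.tsv")
  wr(report$events, "events.tsv")
  wr(report$consequences, "consequences.tsv")
  jsonlite::write_json(
    list(params = report$params, summary = report$summary,
         tss_clusters = report$tss_clusters, first_exons = report$first_exons,
         events = report$events, consequences = report$consequences),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  invisible(dir)
}

#' Write splice events as GFF3
#'
#' One feature per event: the event kind in the type column, `delta_nt` and
#' the affected reference exon ordinals as attributes.
#'
#' @param events event table from [annotate_locus()] (or
#'   [diff_transcripts()] output with a `transcript_id` column).
#' @param path output path.
#' @param contig contig name.
#' @return `path`, invisibly.
#' @export
write_events_gff3 <- function(events, path, contig = "locus") {
  if (nrow(events) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(events$start, events$end),
                               strand = "+")
  gr$source <- rep("spliceform", nrow(events))
  gr$type <- events$kind
  gr$ID <- if ("event_id" %in% names(events)) events$event_id else
    sprintf("ev%d", seq_len(nrow(events)))
  gr$delta_nt <- as.character(events$delta_nt)
  gr$ref_exons <- events$ref_exons
  if ("transcript_id" %in% names(events)) gr$transcript <- events$transcript_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
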