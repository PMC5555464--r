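#' Read a gene locus from GFF3 + FASTA (optionally BED6 5'-end evidence)
#'
#' Expects a `gene`/`mRNA`/`exon`/`CDS` feature hierarchy in the GFF3 and the
#' referenced contig in the FASTA. The reference transcript is the mRNA whose
#' `reference` attribute is `"true"` when present, otherwise the mRNA with the
#' longest CDS (ties: most exons). mRNAs without exons are skipped with a
#' warning. Minus-strand loci are normalised to a plus-strand working copy:
#' coordinates are mirrored, the contig is reverse-complemented, and the
#' original frame is recorded in attributes `input_strand` and `contig_length`
#' (see [original_coords()]).
#'
#' @param gff3_path path to a GFF3 file.
#' @param fasta_path path to a FASTA file containing the contig.
#' @param evidence_path optional path to a BED6 file of 5'-end tags; the name
#'   field carries the source tag (`RACE`/`RNASeq`/`RefSeq`), optionally as
#'   `source:transcript_id`.
#' @return A [gene_locus()].
#' @export
read_gene_models <- function(gff3_path, fasta_path, evidence_path = NULL) {
  gr <- rtracklayer::import(gff3_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  type <- as.character(gr$type)
  mrna <- gr[type %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) stop("no mRNA/transcript features in GFF3")
  contig <- as.character(GenomicRanges::seqnames(mrna))[1L]
  if (!contig %in% names(seqs))
    stop(sprintf("contig '%s' missing from FASTA", contig))
  contig_seq <- as.character(seqs[[contig]])
  L <- nchar(contig_seq)

  exons <- gr[type == "exon"]
  cdss <- gr[type == "CDS"]
  parent_of <- function(g) vapply(g$Parent, function(p)
    if (length(p)) as.character(p[1L]) else NA_character_, character(1L))
  ex_parent <- parent_of(exons)
  cds_parent <- parent_of(cdss)

  models <- list()
  refflag <- logical(0)
  for (i in seq_along(mrna)) {
    id <- as.character(mrna$ID[i])
    sel <- which(ex_parent == id)
    if (length(sel) == 0L) {
      warning(sprintf("mRNA %s has no exons; skipped", id))
      next
    }
    exdf <- data.frame(start = GenomicRanges::start(exons)[sel],
                       end = GenomicRanges::end(exons)[sel])
    if (!is.null(exons$Name)) exdf$label <- as.character(exons$Name[sel])
    if (any(exdf$start < 1L | exdf$end > L))
      stop(sprintf("exon of %s outside contig bounds", id))
    csel <- which(cds_parent == id)
    cds <- if (length(csel))
      c(min(GenomicRanges::start(cdss)[csel]), max(GenomicRanges::end(cdss)[csel]))
    else NULL
    src <- as.character(mrna$source[i])
    if (!src %in% c("RACE", "RNASeq", "RefSeq", "cloned", "synthetic"))
      src <- "synthetic"
    strand <- as.character(GenomicRanges::strand(mrna))[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    models[[length(models) + 1L]] <-
      transcript_model(id, exdf, cds = cds, strand = strand, source = src,
                       contig = contig)
    rf <- if (!is.null(mrna$reference)) identical(as.character(mrna$reference[i]), "true") else FALSE
    refflag <- c(refflag, rf)
  }
  if (length(models) == 0L) stop("no usable transcripts in GFF3")

  evidence <- if (!is.null(evidence_path)) read_tss_evidence(evidence_path) else NULL

  # normalise minus-strand loci to a plus-strand working copy
  input_strand <- models[[1L]]$strand
  if (input_strand == "-") {
    contig_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig_seq)))
    models <- lapply(models, function(t) {
      ex <- data.frame(start = L - t$exons$end + 1L, end = L - t$exons$start + 1L,
                       label = t$exons$label)
      transcript_model(t$id, ex,
                       cds = if (is.null(t$cds)) NULL else
                         c(L - t$cds[2] + 1L, L - t$cds[1] + 1L),
                       strand = "+", source = t$source, contig = t$contig)
    })
    if (!is.null(evidence)) evidence$position <- L - evidence$position + 1L
  }

  if (!any(refflag)) {
    cdslen <- vapply(models, function(t)
      if (is.null(t$cds)) -1L else t$cds[2] - t$cds[1] + 1L, integer(1L))
    nex <- vapply(models, n_exons, integer(1L))
    refflag <- seq_along(models) == order(-cdslen, -nex)[1L]
  }
  ref <- models[[which(refflag)[1L]]]
  alts <- models[!seq_along(models) %in% which(refflag)[1L]]

  loc <- gene_locus(contig_seq, ref, alts, evidence, contig = contig)
  attr(loc, "input_strand") <- input_strand
  attr(loc, "contig_length") <- L
  loc
}

#' Translate working-copy coordinates back to the input frame
#'
#' Loci read from minus-strand annotation are mirrored to a plus-strand
#' working copy; this maps positions in the working copy back to the original
#' coordinate frame.
#'
#' @param locus a [gene_locus()].
#' @param pos integer vector of working-copy positions.
#' @return Integer vector in the input frame.
#' @export
original_coords <- function(locus, pos) {
  if (identical(attr(locus, "input_strand"), "-")) {
    L <- attr(locus, "contig_length")
    L - as.integer(pos) + 1L
  } else as.integer(pos)
}

#' Write a gene locus as GFF3
#'
#' Emits a `gene`/`mRNA`/`exon`/`CDS` hierarchy that [read_gene_models()]
#' reads back feature-identically. The reference transcript carries a
#' `reference=true` attribute; each mRNA's provenance tag goes in the GFF3
#' source column.
#'
#' @param locus a [gene_locus()].
#' @param gff3_path output path.
#' @return `gff3_path`, invisibly.
#' @export
write_gene_models <- function(locus, gff3_path) {
  models <- all_models(locus)
  isref <- c(TRUE, rep(FALSE, length(locus$alternatives)))
  rows <- list()
  gmin <- min(vapply(models, function(t) t$exons$start[1L], integer(1L)))
  gmax <- max(vapply(models, function(t) t$exons$end[n_exons(t)], integer(1L)))
  rows[[1L]] <- data.frame(start = gmin, end = gmax, type = "gene",
                           source = "spliceform", ID = "gene1", Parent = NA,
                           reference = NA, phase = NA_integer_)
  for (i in seq_along(models)) {
    t <- models[[i]]
    rows[[length(rows) + 1L]] <-
      data.frame(start = t$exons$start[1L], end = t$exons$end[n_exons(t)],
                 type = "mRNA", source = t$source, ID = t$id, Parent = "gene1",
                 reference = if (isref[i]) "true" else "false",
                 phase = NA_integer_)
    rows[[length(rows) + 1L]] <-
      data.frame(start = t$exons$start, end = t$exons$end, type = "exon",
                 source = t$source, ID = paste0(t$id, ":exon", seq_len(n_exons(t))),
                 Parent = t$id, reference = NA, phase = NA_integer_)
    if (!is.null(t$cds)) {
      cs <- pmax(t$exons$start, t$cds[1]); ce <- pmin(t$exons$end, t$cds[2])
      keep <- cs <= ce
      cdf <- data.frame(start = cs[keep], end = ce[keep])
      # GFF3 phase: bases to remove before the first complete codon
      if (t$strand == "+") {
        lens <- cdf$end - cdf$start + 1L
        before <- c(0L, cumsum(lens))[seq_len(nrow(cdf))]
        ph <- (3L - before %% 3L) %% 3L
      } else ph <- rep(0L, nrow(cdf))
      rows[[length(rows) + 1L]] <-
        data.frame(start = cdf$start, end = cdf$end, type = "CDS",
                   source = t$source, ID = paste0(t$id, ":cds", seq_len(nrow(cdf))),
                   Parent = t$id, reference = NA, phase = ph)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(locus$contig,
                               IRanges::IRanges(df$start, df$end), strand = "+")
  gr$source <- df$source
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr$reference <- df$reference
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(gff3_path)
}

#' Read 5'-end evidence from BED6
#'
#' The 5'-end position of each record is its strand-aware first base
#' (BED start for `+`, BED end for `-`). The BED name field carries the
#' evidence source, optionally suffixed `source:transcript_id`.
#'
#' @param bed_path path to a BED file.
#' @return data.frame with columns `position` (1-based), `strand`, `source`,
#'   `transcript_id`.
#' @export
read_tss_evidence <- function(bed_path) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  pos <- ifelse(strand == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep("RNASeq", length(gr))
  src <- sub(":.*$", "", nm)
  txid <- ifelse(grepl(":", nm), sub("^[^:]*:", "", nm), NA_character_)
  data.frame(position = as.integer(pos), strand = strand, source = src,
             transcript_id = txid, stringsAsFactors = FALSE)
}

#' Write 5'-end evidence as BED6
#'
#' @param evidence evidence data.frame (see [read_tss_evidence()]).
#' @param bed_path output path.
#' @param contig contig name for the BED records.
#' @return `bed_path`, invisibly.
#' @export
write_tss_evidence <- function(evidence, bed_path, contig = "locus") {
  nm <- ifelse(is.na(evidence$transcript_id), evidence$source,
               paste0(evidence$source, ":", evidence$transcript_id))
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(evidence$position, evidence$position),
                               strand = evidence$strand)
  gr$name <- nm
  gr$score <- rep(0L, nrow(evidence))
  rtracklayer::export(gr, bed_path, format = "bed")
  invisible(bed_path)
}

#' Read transcript models from BED12
#'
#' BED12 blocks become exons; `thickStart`/`thickEnd` define the CDS.
#'
#' @param bed_path path to a BED12 file.
#' @param source provenance tag to assign.
#' @return List of [transcript_model()]s.
#' @export
read_transcripts_bed12 <- function(bed_path, source = "RNASeq") {
  gr <- rtracklayer::import(bed_path, format = "bed")
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    blocks <- gr$blocks[[i]]
    offs <- GenomicRanges::start(gr)[i] - 1L
    exdf <- data.frame(start = offs + IRanges::start(blocks),
                       end = offs + IRanges::end(blocks))
    thick <- gr$thick[i]
    cds <- if (IRanges::width(thick) > 1L)
      c(IRanges::start(thick), IRanges::end(thick)) else NULL
    strand <- as.character(GenomicRanges::strand(gr))[i]
    if (!strand %in% c("+", "-")) strand <- "+"
    out[[i]] <- transcript_model(
      if (!is.null(gr$name)) as.character(gr$name[i]) else paste0("bed_tx", i),
      exdf, cds = cds, strand = strand, source = source,
      contig = as.character(GenomicRanges::seqnames(gr))[i])
  }
  out
}

#' Write a locus and its truth set to a directory
#'
#' Emits `locus.fa`, `models.gff3`, `evidence.bed` and (when a truth set is
#' supplied) `truth.json`, the layout the simulator documents.
#'
#' @param locus a [gene_locus()].
#' @param dir output directory (created if missing).
#' @param truth optional truth-set list from [generate_locus()].
#' @return `dir`, invisibly.
#' @export
write_locus_files <- function(locus, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(structure(locus$seq, names = locus$contig))
  Biostrings::writeXStringSet(ss, file.path(dir, "locus.fa"), width = 80L)
  write_gene_models(locus, file.path(dir, "models.gff3"))
  if (nrow(locus$evidence) > 0L)
    write_tss_evidence(locus$evidence, file.path(dir, "evidence.bed"),
                       contig = locus$contig)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
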