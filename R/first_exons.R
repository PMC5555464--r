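#' Classify an alternative transcript's first exon against the reference
#'
#' Places each alternative first exon in a four-class taxonomy:
#' \describe{
#'   \item{canonical}{starts within `tolerance` nt of the reference start
#'     (TSS scatter around one promoter is treated as one first exon).}
#'   \item{mutually_exclusive_first}{lies entirely within a reference intron
#'     (no overlap with any reference exon, not even 1 nt) and its donor
#'     splices to a downstream reference acceptor.}
#'   \item{five_prime_extension}{starts in a reference intron and shares its
#'     3' boundary with reference exon N (an "NL" exon).}
#'   \item{intron_retaining_first}{runs uninterrupted from one reference
#'     exon/intron unit through at least one complete reference intron into
#'     the next exon; `retained_nt` counts the intronic nucleotides included.}
#' }
#' A first exon that overlaps no reference feature and splices nowhere is
#' reported as `unresolvable` with a warning.
#'
#' @param alt,ref [transcript_model()]s on the same (plus-strand working)
#'   contig; `ref` must carry a CDS.
#' @param tolerance nt of start scatter counted as canonical (default 62).
#' @return list of class `"first_exon_call"`: `transcript_id`, `class`,
#'   `anchor_exon`, `retained_nt`.
#' @export
classify_first_exon <- function(alt, ref, tolerance = 62L) {
  stopifnot(inherits(alt, "transcript_model"), inherits(ref, "transcript_model"))
  fe <- alt$exons[1L, ]
  rex <- ref$exons
  call <- function(class, anchor = NA_integer_, retained = 0L)
    structure(list(transcript_id = alt$id, class = class,
                   anchor_exon = as.integer(anchor),
                   retained_nt = as.integer(retained)),
              class = "first_exon_call")

  if (abs(fe$start - rex$start[1L]) <= tolerance)
    return(call("canonical", 1L))

  ov <- which(rex$end >= fe$start & rex$start <= fe$end)
  if (length(ov) == 0L) {
    # candidate mutually exclusive first exon: must splice to a ref acceptor
    if (n_exons(alt) >= 2L) {
      anchor <- which(rex$start == alt$exons$start[2L])
      if (length(anchor) == 1L) return(call("mutually_exclusive_first", anchor))
    }
    warning(sprintf("first exon of %s overlaps no reference feature and splices to no reference acceptor",
                    alt$id))
    return(call("unresolvable"))
  }
  if (length(ov) >= 2L) {
    ri <- introns(ref)
    retained <- sum(pmax(0L, pmin(ri$end, fe$end) - pmax(ri$start, fe$start) + 1L))
    return(call("intron_retaining_first", max(ov), retained))
  }
  N <- ov
  if (fe$start < rex$start[N] && fe$end == rex$end[N])
    return(call("five_prime_extension", N))
  warning(sprintf("first exon of %s has an unrecognised relationship to reference exon %d",
                  alt$id, N))
  call("unresolvable", N)
}

#' @export
print.first_exon_call <- function(x, ...) {
  cat(sprintf("<first_exon_call> %s: %s (anchor exon %s, retained %d nt)\n",
              x$transcript_id, x$class,
              ifelse(is.na(x$anchor_exon), "-", x$anchor_exon), x$retained_nt))
  invisible(x)
}

#' Classify all alternative first exons of a locus
#'
#' Runs [classify_first_exon()] over every alternative transcript and
#' auto-generates display labels: mutually exclusive first exons get
#' "1B"-style letters in genomic order (the canonical first exon being "1A"),
#' 5'-extensions get "NL"-style labels from their anchor exon.
#'
#' @param locus a [gene_locus()].
#' @param tolerance see [classify_first_exon()].
#' @return data.frame with columns `transcript_id`, `class`, `anchor_exon`,
#'   `retained_nt`, `label`, `first_exon_start`.
#' @export
classify_first_exons <- function(locus, tolerance = 62L) {
  alts <- locus$alternatives
  if (length(alts) == 0L)
    return(data.frame(transcript_id = character(), class = character(),
                      anchor_exon = integer(), retained_nt = integer(),
                      label = character(), first_exon_start = integer()))
  calls <- lapply(alts, classify_first_exon, ref = locus$reference,
                  tolerance = tolerance)
  out <- data.frame(
    transcript_id = vapply(calls, `[[`, character(1L), "transcript_id"),
    class = vapply(calls, `[[`, character(1L), "class"),
    anchor_exon = vapply(calls, `[[`, integer(1L), "anchor_exon"),
    retained_nt = vapply(calls, `[[`, integer(1L), "retained_nt"),
    stringsAsFactors = FALSE)
  out$first_exon_start <- vapply(alts, function(t) t$exons$start[1L], integer(1L))
  out$label <- NA_character_
  out$label[out$class == "canonical"] <- "1A"
  me <- which(out$class == "mutually_exclusive_first")
  if (length(me)) {
    ord <- me[order(out$first_exon_start[me])]
    out$label[ord] <- paste0("1", LETTERS[1L + seq_along(ord)])
  }
  ext <- out$class == "five_prime_extension"
  out$label[ext] <- paste0(out$anchor_exon[ext], "L")
  ret <- out$class == "intron_retaining_first"
  out$label[ret] <- paste0("1R", out$anchor_exon[ret])
  out
}
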