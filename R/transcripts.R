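#' Transcript record table
#'
#' The central annotation container of the package: one row per linear or
#' circular transcript. Exon coordinates are 1-based inclusive genomic
#' intervals on the annotation contig, stored as list columns so that a
#' single tibble holds multi-exon structures. Circular transcripts
#' (back-spliced isoforms) carry the identifier of the linear parent whose
#' exons they reuse; their span start/end are the back-splice coordinates.
#'
#' @param transcript_id Character, stable unique IDs (Ensembl-style
#'   `ENST...` for linear, circBase-style `hsa_circ_...` for circular
#'   transcripts).
#' @param name Display name, e.g. `"CXCL8-201"`.
#' @param gene_id Locus identifier shared by all isoforms of a gene.
#' @param biotype Annotation biotype string, e.g. `"protein_coding"`,
#'   `"lincRNA"`, `"retained_intron"`, `"circRNA"`.
#' @param tsl Ensembl transcript support level, integer 1 (best) to 5, or
#'   `NA` when not assigned.
#' @param topology `"linear"` or `"circular"`.
#' @param contig Name of the contig the exons live on.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Lists of integer vectors, one vector per
#'   transcript, same lengths, 1-based inclusive.
#' @param circ_parent For circular records, the `transcript_id` of the
#'   linear parent; `NA` otherwise.
#' @param seq Optional spliced sequence (uppercase ACGT), `NA` if unknown.
#'
#' @return A tibble of class `transcript_records`, with a derived
#'   `length_nt` column equal to the summed exon widths and `length_kb` in
#'   kilobases.
#' @export
transcript_records <- function(transcript_id, name = transcript_id,
                               gene_id, biotype, tsl = NA_integer_,
                               topology = "linear", contig = "chrS",
                               strand = "+", exon_start, exon_end,
                               circ_parent = NA_character_, seq = NA_character_) {
  n <- length(transcript_id)
  stopifnot(n >= 1, !anyDuplicated(transcript_id))
  exon_start <- lapply(exon_start, as.integer)
  exon_end <- lapply(exon_end, as.integer)
  if (length(exon_start) != n || length(exon_end) != n)
    stop("one exon coordinate vector required per transcript")
  widths <- mapply(function(s, e) {
    if (length(s) != length(e)) stop("exon_start/exon_end length mismatch")
    if (any(e < s)) stop("exon end before start")
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1)
      stop("exons must be in ascending genomic order")
    sum(e - s + 1L)
  }, exon_start, exon_end)
  bad <- widths <= 0
  if (any(bad)) stop("zero-length transcript: ", transcript_id[bad][1])
  tsl <- suppressWarnings(as.integer(tsl))
  if (any(!is.na(tsl) & (tsl < 1L | tsl > 5L)))
    stop("tsl must be 1..5 or NA")
  if (!all(topology %in% c("linear", "circular")))
    stop("topology must be 'linear' or 'circular'")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- tibble::tibble(
    transcript_id = as.character(transcript_id),
    name = rep_len(as.character(name), n),
    gene_id = rep_len(as.character(gene_id), n),
    length_nt = as.integer(widths),
    length_kb = as.numeric(widths) / 1000,
    biotype = rep_len(as.character(biotype), n),
    tsl = rep_len(tsl, n),
    topology = rep_len(topology, n),
    contig = rep_len(as.character(contig), n),
    strand = rep_len(strand, n),
    exon_start = exon_start,
    exon_end = exon_end,
    circ_parent = rep_len(as.character(circ_parent), n),
    seq = rep_len(as.character(seq), n)
  )
  circ <- out$topology == "circular"
  if (any(circ & is.na(out$circ_parent)))
    stop("circular transcripts must name a linear parent")
  class(out) <- c("transcript_records", class(out))
  out
}

#' Combine transcript record tables
#'
#' @param ... `transcript_records` tibbles.
#' @return A single `transcript_records` tibble.
#' @export
bind_records <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  out <- tibble::as_tibble(out)
  if (anyDuplicated(out$transcript_id)) stop("duplicate transcript_id")
  class(out) <- c("transcript_records", class(out))
  out
}

record_row <- function(records, id) {
  i <- match(id, records$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", id)
  records[i, , drop = FALSE]
}

transcript_lengths_kb <- function(records) {
  stats::setNames(records$length_kb, records$transcript_id)
}
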