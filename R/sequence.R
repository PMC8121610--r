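#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around Biostrings.
#'
#' @param x Character vector of DNA sequences (ACGT).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Spliced sequence of a transcript
#'
#' Concatenates the exon sequences in transcript order. Exons are stored in
#' ascending genomic order; for a minus-strand transcript the ascending
#' concatenation is reverse-complemented, which equals the 5'-to-3' spliced
#' product. For circular transcripts the returned string is the circle
#' linearized at the back-splice acceptor, i.e. the junction sits between
#' its last and first base.
#'
#' @param record One row of a `transcript_records` table.
#' @param genome Named `DNAStringSet` (or named character vector) holding
#'   the contig sequences.
#' @return A single uppercase character string whose length equals the
#'   record's `length_nt`.
#' @export
spliced_sequence <- function(record, genome) {
  stopifnot(nrow(record) == 1)
  contig_seq <- genome_contig(genome, record$contig)
  s <- record$exon_start[[1]]
  e <- record$exon_end[[1]]
  if (any(s < 1) || any(e > nchar(contig_seq)))
    stop("exon outside contig bounds for ", record$transcript_id)
  parts <- substring(contig_seq, s, e)
  out <- paste(parts, collapse = "")
  if (record$strand == "-") out <- revcomp(out)
  out
}

genome_contig <- function(genome, contig) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome)) && length(genome) == 1) return(genome[[1]])
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  genome[[contig]]
}

#' Attach spliced sequences to transcript records
#'
#' Fills the `seq` column from a genome, leaving already-populated entries
#' untouched.
#'
#' @param records A `transcript_records` table.
#' @param genome Named contig sequences.
#' @return The records with `seq` populated.
#' @export
add_sequences <- function(records, genome) {
  for (i in seq_len(nrow(records))) {
    if (is.na(records$seq[i]))
      records$seq[i] <- spliced_sequence(records[i, ], genome)
  }
  records
}

#' Back-splice junction context of a circular transcript
#'
#' A circular RNA has no free ends; the only sequence unique to it (relative
#' to its linear parent) is the back-splice junction where the circle's
#' 3' end rejoins its 5' end. The junction context is the last `w` nt of the
#' circle followed by its first `w` nt — a 2w-mer present in the circular
#' isoform and absent from linear isoforms (for sufficiently large `w`).
#'
#' @param circ One circular row of a `transcript_records` table, or a plain
#'   character string holding the circle's spliced sequence.
#' @param w Window half-width in nt (default 30).
#' @param genome Needed when `circ` is a record without a stored sequence.
#' @return A list of class `circ_junction`: `circ_id`, `w`, `junction`
#'   (the 2w-mer).
#' @export
build_backsplice_junction <- function(circ, w = 30, genome = NULL) {
  if (is.character(circ)) {
    seq <- circ
    id <- NA_character_
  } else {
    stopifnot(nrow(circ) == 1)
    if (circ$topology != "circular")
      stop(circ$transcript_id, " is not circular")
    seq <- if (!is.na(circ$seq)) circ$seq else spliced_sequence(circ, genome)
    id <- circ$transcript_id
  }
  n <- nchar(seq)
  if (n < 2 * w)
    stop("circle (", n, " nt) shorter than 2w = ", 2 * w, " nt")
  junction <- paste0(substr(seq, n - w + 1, n), substr(seq, 1, w))
  structure(list(circ_id = id, w = w, junction = junction),
            class = "circ_junction")
}
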