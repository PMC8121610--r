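#' Write an annotation bundle to disk
#'
#' Produces the standard plain-text trio the pipeline consumes: a contig
#' FASTA (`genome.fa`), a transcript FASTA of spliced sequences
#' (`transcripts.fa`), a GTF with `transcript` and `exon` features for the
#' linear isoforms (1-based inclusive, `gene_id`/`transcript_id`/
#' `transcript_biotype`/`transcript_support_level` attributes), and a
#' BED-like circRNA table (`circ.tsv`: contig, 0-based half-open span,
#' circBase-style name, parent transcript, strand).
#'
#' @param bundle An `annotation_bundle` from [make_annotation()] (or a list
#'   with `records` and `genome`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_annotation <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- bundle$records
  genome <- bundle$genome
  paths <- c(genome = file.path(dir, "genome.fa"),
             transcripts = file.path(dir, "transcripts.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             circ = file.path(dir, "circ.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                              paths["genome"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(records$seq,
                                             records$transcript_id)),
    paths["transcripts"])

  lin <- records[records$topology == "linear", , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(lin))) {
    tsl <- if (is.na(lin$tsl[i])) "NA" else as.character(lin$tsl[i])
    attrs <- sprintf(
      paste0('gene_id "%s"; transcript_id "%s"; transcript_name "%s"; ',
             'transcript_biotype "%s"; transcript_support_level "%s";'),
      lin$gene_id[i], lin$transcript_id[i], lin$name[i], lin$biotype[i], tsl)
    s <- lin$exon_start[[i]]; e <- lin$exon_end[[i]]
    lines <- c(lines,
               paste(lin$contig[i], "uromarker", "transcript", min(s), max(e),
                     ".", lin$strand[i], ".", attrs, sep = "\t"),
               paste(lin$contig[i], "uromarker", "exon", s, e, ".",
                     lin$strand[i], ".", attrs, sep = "\t"))
  }
  writeLines(lines, paths["gtf"])

  circ <- records[records$topology == "circular", , drop = FALSE]
  circ_df <- data.frame(
    contig = circ$contig,
    start = vapply(circ$exon_start, min, integer(1)) - 1L,  # 0-based
    end = vapply(circ$exon_end, max, integer(1)),           # half-open
    name = circ$transcript_id,
    parent = circ$circ_parent,
    strand = circ$strand)
  utils::write.table(circ_df, paths["circ"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read an annotation bundle from disk
#'
#' Counterpart of [write_annotation()]: parses the GTF (via rtracklayer)
#' into linear transcript records, reconstructs each circular isoform's exon
#' chain as the parent exons lying inside its back-splice span, and attaches
#' spliced sequences from the contig FASTA.
#'
#' @param dir Directory holding `genome.fa`, `annotation.gtf`, `circ.tsv`.
#' @return An `annotation_bundle`.
#' @export
read_annotation <- function(dir) {
  genome_set <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- stats::setNames(as.character(genome_set),
                            sub("\\s.*$", "", names(genome_set)))
  gr <- rtracklayer::import(file.path(dir, "annotation.gtf"), format = "gtf")
  ex <- gr[gr$type == "exon"]
  ids <- unique(ex$transcript_id)
  meta_idx <- match(ids, ex$transcript_id)
  tsl_raw <- ex$transcript_support_level[meta_idx]
  lin <- transcript_records(
    transcript_id = ids,
    name = ex$transcript_name[meta_idx],
    gene_id = ex$gene_id[meta_idx],
    biotype = ex$transcript_biotype[meta_idx],
    tsl = suppressWarnings(as.integer(tsl_raw)),
    topology = "linear",
    contig = as.character(GenomicRanges::seqnames(ex))[meta_idx],
    strand = as.character(GenomicRanges::strand(ex))[meta_idx],
    exon_start = lapply(ids, function(id)
      sort(GenomicRanges::start(ex)[ex$transcript_id == id])),
    exon_end = lapply(ids, function(id)
      sort(GenomicRanges::end(ex)[ex$transcript_id == id])))

  circ_path <- file.path(dir, "circ.tsv")
  records <- lin
  if (file.exists(circ_path)) {
    cd <- utils::read.delim(circ_path)
    if (nrow(cd) > 0) {
      circ <- transcript_records(
        transcript_id = cd$name,
        name = cd$name,
        gene_id = vapply(cd$parent, function(p)
          lin$gene_id[match(p, lin$transcript_id)], character(1)),
        biotype = "circRNA",
        tsl = NA_integer_,
        topology = "circular",
        contig = cd$contig,
        strand = cd$strand,
        exon_start = lapply(seq_len(nrow(cd)), function(i) {
          par <- record_row(lin, cd$parent[i])
          s <- par$exon_start[[1]]
          s[s >= cd$start[i] + 1L & par$exon_end[[1]] <= cd$end[i]]
        }),
        exon_end = lapply(seq_len(nrow(cd)), function(i) {
          par <- record_row(lin, cd$parent[i])
          e <- par$exon_end[[1]]
          e[par$exon_start[[1]] >= cd$start[i] + 1L & e <= cd$end[i]]
        }),
        circ_parent = cd$parent)
      records <- bind_records(lin, circ)
    }
  }
  records <- add_sequences(records, genome)
  structure(list(records = records, genome = genome, spec = NULL),
            class = "annotation_bundle")
}
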