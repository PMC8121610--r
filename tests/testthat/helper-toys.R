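# Shared hand-built fixtures, constructed in code at test time.

# A three-exon locus with three linear isoforms and one single-exon circle:
#   exon1 = 1..100, exon2 = 151..250, exon3 = 301..400 on a 400-nt contig.
#   T1 = e1+e2+e3, T2 = e1+e3 (skips exon 2), T3 = e2+e3, C1 = circle(e2).
toy_locus <- function(seed = 101) {
  contig <- with_seed_chr(seed, 400)
  records <- transcript_records(
    transcript_id = c("T1", "T2", "T3", "C1"),
    gene_id = "TOY1",
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "circRNA"),
    tsl = c(1L, 2L, 3L, NA),
    topology = c("linear", "linear", "linear", "circular"),
    contig = "chrT",
    strand = "+",
    exon_start = list(c(1L, 151L, 301L), c(1L, 301L), c(151L, 301L), 151L),
    exon_end = list(c(100L, 250L, 400L), c(100L, 400L), c(250L, 400L), 250L),
    circ_parent = c(NA, NA, NA, "T1"))
  genome <- c(chrT = contig)
  list(records = add_sequences(records, genome), genome = genome)
}

with_seed_chr <- function(seed, n, gc = 0.5) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Independent brute-force coverage oracle: exhaustive substring positions,
# no shared code with amplicon_coverage().
oracle_coverage <- function(fwd, rev, records, orientation = "convergent",
                            prod_range = c(70, 150)) {
  rrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  all_starts <- function(pat, subj) {
    lp <- nchar(pat)
    ns <- nchar(subj)
    if (lp > ns) return(integer(0))
    which(vapply(seq_len(ns - lp + 1),
                 function(i) substr(subj, i, i + lp - 1) == pat, logical(1)))
  }
  covered <- character(0)
  for (k in seq_len(nrow(records))) {
    circ <- records$topology[k] == "circular"
    if (orientation == "divergent" && !circ) next
    seq <- records$seq[k]
    L <- nchar(seq)
    subj <- if (circ) paste0(seq, seq) else seq
    ok <- FALSE
    for (i in all_starts(fwd, subj)) {
      if (circ && i > L) next
      for (j in all_starts(rrc, subj)) {
        if (j < i) next
        prod <- j + nchar(rrc) - i
        if (prod < max(prod_range[1], nchar(fwd), nchar(rrc)) ||
            prod > prod_range[2]) next
        if (circ) {
          if (prod > L) next
          spans <- (j + nchar(rrc) - 1) > L
          if (orientation == "divergent" && !spans) next
        }
        ok <- TRUE
      }
    }
    if (ok) covered <- c(covered, records$transcript_id[k])
  }
  covered
}

# Brute-force re-statement of the selection predicate for one transcript.
oracle_passes <- function(lgfc, tpm_a, tpm_b, len, tsl, cls, cr) {
  if (is.na(lgfc)) return(FALSE)
  (lgfc > cr$lgfc_up || lgfc < cr$lgfc_down) &&
    max(tpm_a, tpm_b) >= cr$min_tpm &&
    len >= cr$min_length_nt &&
    (cr$tsl_policy != "hard" ||
       (if (is.na(tsl)) 6 else tsl) <= cr$tsl_cutoff) &&
    cls %in% cr$classes
}

random_tpm_table <- function(n, conditions = c("A", "B"), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- tibble::tibble(transcript_id = sprintf("tx%02d", seq_len(n)))
  for (cc in conditions) x[[cc]] <- stats::rlnorm(n, log(20), 1)
  abundance_table(x, unit = "TPM")
}
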