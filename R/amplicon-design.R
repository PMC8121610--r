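#' Design constraints for RT-qPCR amplicons
#'
#' The physical window every returned design must satisfy: primer melting
#' temperatures inside \[57, 63\] degrees C with an optimum of 60 and a pair
#' difference of at most 3, primer lengths of 18-27 nt, and a PCR product of
#' 70-150 nt. Dimer screens reject pairs with a contiguous inter- or
#' intra-primer complementary run of at least `max_complement` bp, or
#' complementarity of at least `max_3p_complement` bp at a 3' terminus
#' (3'-anchored duplexes are extensible by the polymerase and the dominant
#' source of primer-dimer artifacts).
#'
#' @param tm_min,tm_max,tm_opt Melting-temperature window and optimum (C).
#' @param tm_diff_max Maximal |Tm_forward - Tm_reverse| (C).
#' @param primer_len Length-2 integer, min and max primer length (nt).
#' @param product_len Length-2 integer, min and max product length (nt).
#' @param primer_nM,na_mM Tm evaluation conditions.
#' @param max_complement Rejection threshold for contiguous complementary
#'   runs (bp).
#' @param max_3p_complement Rejection threshold for 3'-terminal
#'   complementarity (bp).
#' @return An `amplicon_constraints` object.
#' @export
amplicon_constraints <- function(tm_min = 57, tm_max = 63, tm_opt = 60,
                                 tm_diff_max = 3,
                                 primer_len = c(18L, 27L),
                                 product_len = c(70L, 150L),
                                 primer_nM = 200, na_mM = 50,
                                 max_complement = 8L,
                                 max_3p_complement = 4L) {
  stopifnot(tm_min < tm_max, length(primer_len) == 2,
            length(product_len) == 2, primer_len[1] <= primer_len[2],
            product_len[1] <= product_len[2])
  structure(list(tm_min = tm_min, tm_max = tm_max, tm_opt = tm_opt,
                 tm_diff_max = tm_diff_max,
                 primer_len = as.integer(primer_len),
                 product_len = as.integer(product_len),
                 primer_nM = primer_nM, na_mM = na_mM,
                 max_complement = as.integer(max_complement),
                 max_3p_complement = as.integer(max_3p_complement)),
            class = "amplicon_constraints")
}

#' A primer pair
#'
#' Both sequences are written 5' to 3' as synthesized. `orientation`
#' distinguishes convergent pairs (inward-facing, amplifying linear
#' templates) from divergent pairs (outward-facing on the genome, yielding
#' product only on a circular template where the back-splice junction closes
#' the path between them).
#'
#' @param forward,reverse Primer sequences, 5'->3', ACGT.
#' @param orientation `"convergent"` or `"divergent"`.
#' @param constraints Optional [amplicon_constraints()]; when supplied the
#'   pair is validated against the Tm window, Tm difference and primer
#'   lengths and an error is raised on violation.
#' @return A `primer_pair` object with `tm_forward`/`tm_reverse` fields.
#' @export
primer_pair <- function(forward, reverse,
                        orientation = c("convergent", "divergent"),
                        constraints = NULL) {
  orientation <- match.arg(orientation)
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse))
    if (!grepl("^[ACGT]+$", p)) stop("primers must be ACGT only")
  cn <- constraints %||% amplicon_constraints()
  tmf <- primer_tm(forward, cn$primer_nM, cn$na_mM)
  tmr <- primer_tm(reverse, cn$primer_nM, cn$na_mM)
  pp <- structure(list(forward = forward, reverse = reverse,
                       orientation = orientation,
                       tm_forward = tmf, tm_reverse = tmr),
                  class = "primer_pair")
  if (!is.null(constraints)) {
    viol <- check_primer_pair(pp, constraints)
    if (length(viol)) stop("primer pair violates: ",
                           paste(viol, collapse = ", "))
  }
  pp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a primer pair against constraints
#'
#' @param pair A `primer_pair`.
#' @param constraints An [amplicon_constraints()].
#' @return Character vector of violated constraint names (empty if valid).
#' @export
check_primer_pair <- function(pair, constraints) {
  cn <- constraints
  viol <- character(0)
  lens <- nchar(c(pair$forward, pair$reverse))
  if (any(lens < cn$primer_len[1] | lens > cn$primer_len[2]))
    viol <- c(viol, "primer_length")
  tms <- c(pair$tm_forward, pair$tm_reverse)
  if (any(tms < cn$tm_min | tms > cn$tm_max)) viol <- c(viol, "tm_window")
  if (abs(diff(tms)) > cn$tm_diff_max) viol <- c(viol, "tm_difference")
  viol
}

# Longest contiguous run shared by a and b (plain longest common substring,
# used with b = revcomp(other primer) to measure complementary runs).
longest_common_run <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    hit <- av[i] == bv
    cur[hit] <- 1L
    if (nb > 1) {
      idx <- which(hit & seq_len(nb) > 1)
      cur[idx] <- prev[idx - 1L] + 1L
    }
    best <- max(best, cur)
    prev <- cur
  }
  best
}

#' Self- and cross-complementarity screen
#'
#' Heuristic secondary-structure filter: a pair fails when any primer has a
#' contiguous complementary run of `max_complement` bp or more against
#' itself or its partner, or when the 3'-terminal `max_3p_complement` bases
#' of either primer find a complementary site anywhere in either primer.
#'
#' @param pair A `primer_pair`.
#' @param constraints An [amplicon_constraints()].
#' @return `TRUE` if the pair passes the screen.
#' @export
dimer_screen <- function(pair, constraints = amplicon_constraints()) {
  cn <- constraints
  f <- pair$forward; r <- pair$reverse
  runs <- c(longest_common_run(f, revcomp(r)),
            longest_common_run(f, revcomp(f)),
            longest_common_run(r, revcomp(r)))
  if (any(runs >= cn$max_complement)) return(FALSE)
  k <- cn$max_3p_complement
  for (p in c(f, r)) {
    tail3 <- substr(p, nchar(p) - k + 1, nchar(p))
    probe <- revcomp(tail3)
    if (grepl(probe, f, fixed = TRUE) || grepl(probe, r, fixed = TRUE))
      return(FALSE)
  }
  TRUE
}

match_starts <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Transcripts covered by a primer pair
#'
#' A linear transcript is covered iff the forward primer matches its spliced
#' sense strand exactly, the reverse complement of the reverse primer
#' matches downstream, and the implied product length falls inside the
#' product window. Circular transcripts are searched on their doubled
#' sequence so products running through the back-splice junction are found;
#' product lengths are measured along the circle and may not exceed the
#' circle length. Divergent pairs cover only circular transcripts, and only
#' through products that span the back-splice junction.
#'
#' @param pair A `primer_pair`.
#' @param records `transcript_records` with sequences populated.
#' @param product_len Length-2 product window in nt (default `c(70, 150)`).
#' @return Tibble with `transcript_id`, `topology` and `product_length`
#'   (shortest valid product per transcript); zero rows when nothing is
#'   covered.
#' @export
amplicon_coverage <- function(pair, records, product_len = c(70L, 150L)) {
  stopifnot(inherits(pair, "primer_pair"))
  if (any(is.na(records$seq))) stop("records must carry sequences")
  f <- pair$forward
  rrc <- revcomp(pair$reverse)
  lf <- nchar(f); lr <- nchar(rrc)
  rows <- lapply(seq_len(nrow(records)), function(k) {
    circ <- records$topology[k] == "circular"
    if (pair$orientation == "divergent" && !circ) return(NULL)
    seq <- records$seq[k]
    L <- nchar(seq)
    subject <- if (circ) paste0(seq, seq) else seq
    fi <- match_starts(f, subject)
    if (circ) fi <- fi[fi <= L]
    if (!length(fi)) return(NULL)
    ri <- match_starts(rrc, subject)
    if (!length(ri)) return(NULL)
    best <- Inf
    for (i in fi) for (j in ri) {
      if (j < i) next
      prod <- j + lr - i
      if (prod < max(product_len[1], lf, lr)) next
      if (prod > product_len[2]) next
      if (circ) {
        if (prod > L) next
        spans <- (j + lr - 1) > L && i <= L
        if (pair$orientation == "divergent" && !spans) next
      }
      best <- min(best, prod)
    }
    if (!is.finite(best)) return(NULL)
    data.frame(transcript_id = records$transcript_id[k],
               topology = records$topology[k],
               product_length = as.integer(best))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(tibble::tibble(transcript_id = character(0),
                          topology = character(0),
                          product_length = integer(0)))
  tibble::as_tibble(do.call(rbind, rows))
}

# Map spliced-coordinate positions to exon index in transcript order.
# Returns, for a primer occupying [start, start+len-1] on the spliced
# sequence, the exon of its first base and whether it crosses a boundary.
primer_placement <- function(record, start, len) {
  widths <- record$exon_end[[1]] - record$exon_start[[1]] + 1L
  if (record$strand == "-") widths <- rev(widths)
  bounds <- cumsum(widths)
  first_exon <- findInterval(start - 1L, c(0L, bounds), rightmost.closed = FALSE)
  last_exon <- findInterval(start + len - 2L, c(0L, bounds))
  list(exon = first_exon, spans_junction = last_exon != first_exon)
}

classify_pair_placement <- function(record, f_start, f_len, r_start, r_len) {
  pf <- primer_placement(record, f_start, f_len)
  pr <- primer_placement(record, r_start, r_len)
  if (pf$spans_junction || pr$spans_junction) "junction-spanning"
  else if (pf$exon != pr$exon) "intron-separated"
  else "same-exon"
}

enumerate_primers <- function(seq, constraints, step = 1L) {
  cn <- constraints
  out <- list()
  for (len in seq(cn$primer_len[1], cn$primer_len[2])) {
    starts <- seq(1L, nchar(seq) - len + 1L, by = step)
    for (s in starts) {
      p <- substr(seq, s, s + len - 1L)
      if (!grepl("^[ACGT]+$", p)) next
      tm <- primer_tm(p, cn$primer_nM, cn$na_mM)
      if (tm < cn$tm_min || tm > cn$tm_max) next
      out[[length(out) + 1L]] <- list(seq = p, start = s, len = len, tm = tm)
    }
  }
  out
}

amplicon_specs_tibble <- function(rows) {
  if (!length(rows))
    return(tibble::tibble(forward = character(0), reverse = character(0),
                          orientation = character(0),
                          placement = character(0),
                          tm_forward = numeric(0), tm_reverse = numeric(0),
                          covered = list(), product_lengths = list(),
                          aggregate_lgfc = numeric(0)))
  tibble::tibble(
    forward = vapply(rows, `[[`, character(1), "forward"),
    reverse = vapply(rows, `[[`, character(1), "reverse"),
    orientation = vapply(rows, `[[`, character(1), "orientation"),
    placement = vapply(rows, `[[`, character(1), "placement"),
    tm_forward = vapply(rows, `[[`, numeric(1), "tm_forward"),
    tm_reverse = vapply(rows, `[[`, numeric(1), "tm_reverse"),
    covered = lapply(rows, `[[`, "covered"),
    product_lengths = lapply(rows, `[[`, "product_lengths"),
    aggregate_lgfc = vapply(rows, `[[`, numeric(1), "aggregate_lgfc")
  )
}

design_aggregate_lgfc <- function(covered, table, pair) {
  if (is.null(table) || is.null(pair)) return(NA_real_)
  present <- intersect(covered, table$transcript_id)
  if (!length(present)) return(NA_real_)
  aggregate_lgfc(table, present, pair)
}

#' Design convergent primer pairs covering a requested isoform subset
#'
#' Enumerates candidate primers on a representative target transcript,
#' pairs them under the physical constraints, classifies placement
#' (same-exon, intron-separated, junction-spanning), screens dimers, and
#' keeps only pairs whose coverage over the whole annotation equals exactly
#' the requested transcript subset — this one predicate enforces both
#' isoform specificity within the locus and absence of off-locus
#' amplification. When nothing survives, an empty design table is returned
#' whose `"infeasibility"` attribute records how many candidates each
#' constraint pruned and which pruned last.
#'
#' @param records Full `transcript_records` annotation with sequences.
#' @param target_ids Transcript IDs the amplicon must detect, all of them
#'   and nothing else.
#' @param constraints An [amplicon_constraints()].
#' @param table,pair Optional abundance table and [group_pair()]; when given
#'   each design carries the aggregate lg(fc) over its covered set.
#' @param max_designs Stop after this many accepted designs.
#' @param step Primer start-position stride during enumeration.
#' @return Tibble of designs (class `amplicon_designs`): primer sequences,
#'   Tm values, placement class, covered IDs and per-transcript product
#'   lengths (list columns), aggregate lg(fc).
#' @export
design_convergent <- function(records, target_ids, constraints = amplicon_constraints(),
                              table = NULL, pair = NULL,
                              max_designs = 10L, step = 1L) {
  if (!length(target_ids)) stop("empty target subset")
  if (any(is.na(records$seq))) stop("records must carry sequences")
  missing <- setdiff(target_ids, records$transcript_id)
  if (length(missing)) stop("unknown target transcript: ", missing[1])
  rep_rec <- record_row(records, target_ids[1])
  seq <- rep_rec$seq
  cn <- constraints
  cand <- enumerate_primers(seq, cn, step = step)
  pruned <- c(tm_difference = 0L, product_length = 0L, dimer = 0L,
              coverage = 0L)
  designs <- list()
  for (a in cand) {
    if (length(designs) >= max_designs) break
    for (b in cand) {
      if (length(designs) >= max_designs) break
      # b is the reverse primer's binding site on the sense strand
      prod <- b$start + b$len - a$start
      if (b$start < a$start ||
          prod < max(cn$product_len[1], a$len, b$len) ||
          prod > cn$product_len[2]) {
        pruned["product_length"] <- pruned["product_length"] + 1L
        next
      }
      if (abs(a$tm - b$tm) > cn$tm_diff_max) {
        pruned["tm_difference"] <- pruned["tm_difference"] + 1L
        next
      }
      pp <- primer_pair(a$seq, revcomp(b$seq), "convergent")
      if (!dimer_screen(pp, cn)) {
        pruned["dimer"] <- pruned["dimer"] + 1L
        next
      }
      cov <- amplicon_coverage(pp, records, cn$product_len)
      if (!setequal(cov$transcript_id, target_ids)) {
        pruned["coverage"] <- pruned["coverage"] + 1L
        next
      }
      designs[[length(designs) + 1L]] <- list(
        forward = pp$forward, reverse = pp$reverse,
        orientation = "convergent",
        placement = classify_pair_placement(rep_rec, a$start, a$len,
                                            b$start, b$len),
        tm_forward = pp$tm_forward, tm_reverse = pp$tm_reverse,
        covered = cov$transcript_id,
        product_lengths = stats::setNames(cov$product_length,
                                          cov$transcript_id),
        aggregate_lgfc = design_aggregate_lgfc(cov$transcript_id, table, pair)
      )
    }
  }
  out <- amplicon_specs_tibble(designs)
  if (nrow(out) == 0) {
    nz <- pruned[pruned > 0]
    attr(out, "infeasibility") <- list(
      n_candidate_primers = length(cand),
      pruned = as.list(pruned),
      last_pruning_constraint = if (length(nz)) names(nz)[length(nz)] else
        "no_candidate_primers")
  }
  class(out) <- c("amplicon_designs", class(out))
  out
}

#' Design divergent primer pairs over back-splice junctions
#'
#' Divergent pairs face outward on the genome and therefore produce no
#' product from a linear template; on a circular template the back-splice
#' junction closes the path between them. Candidates are enumerated on the
#' doubled circle sequence in the window around the junction and only
#' products that read through the junction are accepted, so every returned
#' design is structurally blind to linear isoforms. When a single pair
#' covering all circular isoforms of the locus exists, only all-covering
#' designs are returned; otherwise the best-covering designs per circle are
#' returned and the `"all_covered"` attribute is `FALSE` (the situation
#' where no shared junction context exists across the circles).
#'
#' @param records `transcript_records` containing at least one circular
#'   record (with sequences); linear records participate in the coverage
#'   check.
#' @inheritParams design_convergent
#' @return Tibble of designs as in [design_convergent()], placement
#'   `"backsplice-divergent"`, with attribute `all_covered`.
#' @export
design_divergent <- function(records, constraints = amplicon_constraints(),
                             table = NULL, pair = NULL,
                             max_designs = 10L, step = 1L) {
  circs <- records[records$topology == "circular", , drop = FALSE]
  if (nrow(circs) == 0) stop("no circular records in the annotation")
  if (any(is.na(records$seq))) stop("records must carry sequences")
  cn <- constraints
  designs <- list()
  for (k in seq_len(nrow(circs))) {
    n_before <- length(designs)
    seq <- circs$seq[k]
    L <- nchar(seq)
    if (L < cn$product_len[1]) next  # circle too short for any product
    doubled <- paste0(seq, seq)
    win_lo <- max(1L, L - cn$product_len[2] + 1L)
    win_hi <- min(2L * L, L + cn$product_len[2])
    window <- substr(doubled, win_lo, win_hi)
    cand <- enumerate_primers(window, cn, step = step)
    for (a in cand) {
      a_start <- a$start + win_lo - 1L
      if (a_start > L) next                    # forward must start before the junction
      for (b in cand) {
        b_start <- b$start + win_lo - 1L
        if (b_start < a_start) next
        if (b_start + b$len - 1L <= L) next    # product must read through the junction
        prod <- b_start + b$len - a_start
        if (prod < max(cn$product_len[1], a$len, b$len) ||
            prod > min(cn$product_len[2], L)) next
        if (abs(a$tm - b$tm) > cn$tm_diff_max) next
        pp <- primer_pair(a$seq, revcomp(b$seq), "divergent")
        if (!dimer_screen(pp, cn)) next
        cov <- amplicon_coverage(pp, records, cn$product_len)
        if (!circs$transcript_id[k] %in% cov$transcript_id) next
        designs[[length(designs) + 1L]] <- list(
          target_circ = circs$transcript_id[k],
          forward = pp$forward, reverse = pp$reverse,
          orientation = "divergent", placement = "backsplice-divergent",
          tm_forward = pp$tm_forward, tm_reverse = pp$tm_reverse,
          covered = cov$transcript_id,
          product_lengths = stats::setNames(cov$product_length,
                                            cov$transcript_id),
          aggregate_lgfc = design_aggregate_lgfc(cov$transcript_id, table,
                                                 pair)
        )
        if (length(designs) - n_before >= max_designs) break
      }
      if (length(designs) - n_before >= max_designs) break
    }
  }
  all_ids <- circs$transcript_id
  covers_all <- vapply(designs, function(d) setequal(d$covered, all_ids),
                       logical(1))
  if (any(covers_all)) {
    designs <- designs[covers_all]
    all_covered <- TRUE
  } else if (length(designs)) {
    # keep, per circle, the widest-covering designs
    keep <- logical(length(designs))
    for (id in all_ids) {
      hits <- which(vapply(designs, function(d) id %in% d$covered,
                           logical(1)))
      if (!length(hits)) next
      sizes <- vapply(designs[hits], function(d) length(d$covered),
                      integer(1))
      keep[hits[sizes == max(sizes)]] <- TRUE
    }
    designs <- designs[keep]
    all_covered <- FALSE
  } else {
    all_covered <- FALSE
  }
  if (length(designs) > max_designs) {
    # keep designs for every target circle: truncate round-robin over circles
    tgt <- vapply(designs, `[[`, character(1), "target_circ")
    ord <- order(stats::ave(seq_along(tgt), tgt, FUN = seq_along),
                 match(tgt, all_ids))
    designs <- designs[ord][seq_len(max_designs)]
  }
  out <- amplicon_specs_tibble(designs)
  attr(out, "all_covered") <- all_covered
  class(out) <- c("amplicon_designs", class(out))
  out
}

#' Export amplicon designs
#'
#' `write_amplicons_tsv` flattens the design table (covered sets and product
#' lengths comma-joined); `write_primers_fasta` writes each design's two
#' primers as FASTA records.
#'
#' @param designs An `amplicon_designs` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_amplicons_tsv <- function(designs, path) {
  flat <- as.data.frame(designs[, c("forward", "reverse", "orientation",
                                    "placement", "tm_forward", "tm_reverse",
                                    "aggregate_lgfc")])
  flat$covered <- vapply(designs$covered, paste, character(1), collapse = ",")
  flat$product_lengths <- vapply(designs$product_lengths,
                                 function(x) paste(x, collapse = ","),
                                 character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_amplicons_tsv
#' @export
write_primers_fasta <- function(designs, path) {
  if (nrow(designs) == 0) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), path)
    return(invisible(path))
  }
  seqs <- character(0)
  for (i in seq_len(nrow(designs))) {
    seqs[sprintf("amplicon%02d_F", i)] <- designs$forward[i]
    seqs[sprintf("amplicon%02d_R", i)] <- designs$reverse[i]
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
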