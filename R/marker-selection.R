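#' Selection criteria for marker candidates
#'
#' The screening thresholds applied to every transcript: a base-10 log
#' fold-change window (strict inequalities — a candidate must exceed the up
#' threshold or fall below the down threshold), a minimum abundance of 10
#' TPM in at least one of the two conditions, a minimum transcript length of
#' 150 nt (the shortest template on which a 70–150 nt amplicon can be
#' placed), and a transcript support level (TSL) policy.
#'
#' TSL policies: `"rank-weight"` (default) keeps all TSLs but uses TSL as a
#' ranking tie-break, so poorly supported transcripts survive filtering yet
#' sink in the list; `"hard"` excludes transcripts with TSL worse than
#' `tsl_cutoff`; `"ignore"` drops TSL from consideration entirely. Missing
#' TSL is treated as worse than level 5 for ranking and hard cutoffs.
#'
#' @param lgfc_up Upper lg(fc) threshold, default 0.5 (strict).
#' @param lgfc_down Lower threshold, default -0.5 (strict).
#' @param min_tpm Minimum TPM in at least one condition, default 10
#'   (non-strict).
#' @param min_length_nt Minimum transcript length, default 150 nt
#'   (non-strict).
#' @param tsl_policy One of `"rank-weight"`, `"hard"`, `"ignore"`.
#' @param tsl_cutoff Worst acceptable TSL under the hard policy (default 3).
#' @param classes Biotype classes admitted, subset of
#'   `c("coding", "ncRNA", "circRNA")`.
#' @return A `filter_criteria` object.
#' @export
filter_criteria <- function(lgfc_up = 0.5, lgfc_down = -0.5, min_tpm = 10,
                            min_length_nt = 150,
                            tsl_policy = c("rank-weight", "hard", "ignore"),
                            tsl_cutoff = 3,
                            classes = c("coding", "ncRNA", "circRNA")) {
  tsl_policy <- match.arg(tsl_policy)
  if (!(lgfc_up > 0 && lgfc_down < 0))
    stop("need lgfc_up > 0 > lgfc_down")
  if (min_tpm < 0) stop("min_tpm must be >= 0")
  if (min_length_nt < 1) stop("min_length_nt must be >= 1")
  classes <- match.arg(classes, several.ok = TRUE)
  structure(list(lgfc_up = lgfc_up, lgfc_down = lgfc_down,
                 min_tpm = min_tpm, min_length_nt = min_length_nt,
                 tsl_policy = tsl_policy, tsl_cutoff = tsl_cutoff,
                 classes = classes),
            class = "filter_criteria")
}

.coding_biotypes <- c("protein_coding", "retained_intron",
                      "protein_coding_CDS_not_defined",
                      "nonsense_mediated_decay")
.ncRNA_biotypes <- c("ncRNA", "lincRNA", "lncRNA", "antisense", "miRNA",
                     "snoRNA", "snRNA", "misc_RNA", "rRNA",
                     "processed_transcript", "sense_intronic",
                     "sense_overlapping", "TEC", "scaRNA", "vault_RNA")

#' Classify a transcript into coding / ncRNA / circRNA
#'
#' Circular topology wins regardless of the parent's biotype (a back-spliced
#' product of a protein-coding locus is a circRNA); among linear
#' transcripts, protein-coding variants (including retained-intron isoforms
#' of coding loci) are `coding` and recognized non-coding biotypes are
#' `ncRNA`.
#'
#' @param records A `transcript_records` table (or one row of it).
#' @return Character vector of classes, one per record.
#' @export
classify_biotype <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    if (records$topology[i] == "circular") return("circRNA")
    bt <- records$biotype[i]
    if (bt %in% c("circRNA")) return("circRNA")
    if (bt %in% .coding_biotypes) return("coding")
    if (bt %in% .ncRNA_biotypes) return("ncRNA")
    stop("unknown biotype '", bt, "'; accepted: ",
         paste(c(.coding_biotypes, .ncRNA_biotypes, "circRNA"),
               collapse = ", "))
  }, character(1))
}

# TSL with NA mapped to a worst rank of 6 (no experimental support recorded)
tsl_rank <- function(tsl) ifelse(is.na(tsl), 6L, as.integer(tsl))

#' Apply the multi-criteria marker filter
#'
#' Scores every transcript with its lg(fc) for the given condition pair and
#' partitions the input into passing candidates and excluded transcripts.
#' A transcript passes iff its lg(fc) clears the up or down threshold
#' (strictly), its larger per-condition TPM is at least `min_tpm`, it is at
#' least `min_length_nt` long, its TSL satisfies the policy, and its class
#' is admitted. Every exclusion carries the full set of named reasons so the
#' filter is auditable.
#'
#' @param table An `abundance_table` with unit TPM covering both conditions.
#' @param records `transcript_records` for all rows of `table`.
#' @param criteria A [filter_criteria()].
#' @param pair A [group_pair()].
#' @return List with `candidates` (tibble: transcript metadata, class,
#'   per-condition TPM, `lgfc`, `direction`) and `excluded` (same columns
#'   plus `reasons`, a comma-joined string drawn from `lgfc_threshold`,
#'   `min_tpm`, `min_length`, `tsl`, `class`, `undefined_lgfc`).
#' @export
apply_filters <- function(table, records, criteria, pair) {
  stopifnot(inherits(criteria, "filter_criteria"),
            inherits(pair, "group_pair"))
  ids <- records$transcript_id
  lgfc <- lg_fold_change(table, pair, ids)
  tpm_num <- abundance_values(table, ids, pair$numerator)
  tpm_den <- abundance_values(table, ids, pair$denominator)
  cls <- classify_biotype(records)

  scored <- tibble::tibble(
    transcript_id = ids,
    name = records$name,
    gene_id = records$gene_id,
    length_nt = records$length_nt,
    length_kb = records$length_kb,
    tsl = records$tsl,
    biotype = records$biotype,
    class = cls,
    tpm_num = tpm_num,
    tpm_den = tpm_den,
    lgfc = unname(lgfc),
    direction = ifelse(is.na(lgfc), NA_character_,
                       ifelse(lgfc > 0, "up", "down"))
  )
  names(scored)[names(scored) == "tpm_num"] <- paste0("tpm_", pair$numerator)
  names(scored)[names(scored) == "tpm_den"] <- paste0("tpm_", pair$denominator)

  reasons <- lapply(seq_along(ids), function(i) {
    r <- character(0)
    if (is.na(lgfc[i])) r <- c(r, "undefined_lgfc")
    else if (!(lgfc[i] > criteria$lgfc_up || lgfc[i] < criteria$lgfc_down))
      r <- c(r, "lgfc_threshold")
    if (max(tpm_num[i], tpm_den[i]) < criteria$min_tpm) r <- c(r, "min_tpm")
    if (records$length_nt[i] < criteria$min_length_nt) r <- c(r, "min_length")
    if (criteria$tsl_policy == "hard" &&
        tsl_rank(records$tsl[i]) > criteria$tsl_cutoff)
      r <- c(r, "tsl")
    if (!cls[i] %in% criteria$classes) r <- c(r, "class")
    r
  })
  pass <- lengths(reasons) == 0
  excluded <- scored[!pass, , drop = FALSE]
  excluded$reasons <- vapply(reasons[!pass], paste, character(1),
                             collapse = ",")
  list(candidates = scored[pass, , drop = FALSE], excluded = excluded)
}

#' Rank marker candidates within direction and class
#'
#' Orders candidates by descending absolute lg(fc); ties are broken by
#' higher maximal per-condition TPM, then better (lower) TSL with missing
#' TSL last, then lexicographic transcript ID, giving a total and stable
#' order independent of input order.
#'
#' @param candidates The `candidates` tibble from [apply_filters()].
#' @return The same tibble ordered, with a `rank` column unique within each
#'   `(direction, class)` stratum.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  tpm_cols <- grep("^tpm_", names(candidates), value = TRUE)
  max_tpm <- do.call(pmax, candidates[tpm_cols])
  ord <- order(candidates$direction, candidates$class,
               -abs(candidates$lgfc), -max_tpm,
               tsl_rank(candidates$tsl), candidates$transcript_id,
               method = "radix")
  out <- candidates[ord, , drop = FALSE]
  key <- paste(out$direction, out$class)
  out$rank <- stats::ave(seq_len(nrow(out)), key,
                         FUN = seq_along)
  out
}

#' Write candidate lists as TSV
#'
#' One file mirroring the marker-table layout (transcript ID, name, length,
#' per-condition TPM, lg(fc), TSL, biotype, class, direction, rank), with an
#' exclusion-reason column when present.
#'
#' @param candidates Tibble from [apply_filters()] or [rank_candidates()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
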