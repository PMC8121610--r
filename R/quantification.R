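#' Convert read counts to TPM (transcripts per million)
#'
#' TPM removes the two systematic biases of count data: longer transcripts
#' collect more reads, and deeper libraries collect more reads overall. For
#' each condition column the count of transcript i is divided by its length
#' in kilobases to give a read rate, and rates are rescaled to sum to one
#' million over the normalization set:
#' \deqn{TPM_i = 10^6 \, (c_i/l_i) / \sum_j (c_j/l_j).}
#'
#' Normalization can be computed over all transcripts jointly or restricted
#' to a class (e.g. the coding, non-coding and circular reference sets
#' separately) by passing `normalization_set`; transcripts outside the set
#' are scaled by the set's denominator so their values remain comparable,
#' but only the set itself is guaranteed to sum to one million.
#'
#' @param counts An `abundance_table` with unit `"counts"`.
#' @param lengths_kb Named numeric vector, transcript length in kb for every
#'   transcript in `counts` (a `transcript_records` table is also accepted).
#' @param normalization_set Optional character vector of transcript IDs over
#'   which the per-million denominator is computed; default all.
#' @return An `abundance_table` with unit `"TPM"`.
#' @export
counts_to_tpm <- function(counts, lengths_kb, normalization_set = NULL) {
  if (!inherits(counts, "abundance_table") || abundance_unit(counts) != "counts")
    stop("counts must be an abundance_table with unit 'counts'")
  if (inherits(lengths_kb, "transcript_records"))
    lengths_kb <- transcript_lengths_kb(lengths_kb)
  ids <- counts$transcript_id
  missing_len <- setdiff(ids, names(lengths_kb))
  if (length(missing_len))
    stop("no length for transcript: ", missing_len[1])
  l <- lengths_kb[ids]
  if (any(l <= 0)) stop("non-positive transcript length")
  if (is.null(normalization_set)) normalization_set <- ids
  norm_idx <- match(normalization_set, ids)
  if (anyNA(norm_idx))
    stop("normalization_set transcript not in table: ",
         normalization_set[is.na(norm_idx)][1])
  out <- counts
  for (cc in conditions(counts)) {
    rate <- counts[[cc]] / l
    denom <- sum(rate[norm_idx])
    if (denom <= 0) stop("all-zero counts in condition ", cc,
                         " over the normalization set")
    out[[cc]] <- 1e6 * rate / denom
  }
  abundance_table(tibble::as_tibble(as.data.frame(out)), unit = "TPM",
                  normalization_set = normalization_set)
}

#' Base-10 log fold change between two conditions
#'
#' `lg(fc) = log10((x_num + eps)/(x_den + eps))` for one or more
#' transcripts, where eps is the pair's pseudocount. With the default
#' `eps = 0`, a zero denominator yields `NA` (an undefined value that is
#' excluded from ranking) rather than an error, and a zero numerator over a
#' positive denominator yields `-Inf`.
#'
#' @param table An `abundance_table` (typically TPM).
#' @param pair A [group_pair()].
#' @param transcript_id One or more IDs present in the table.
#' @return Numeric vector of lg(fc) values, named by transcript.
#' @export
lg_fold_change <- function(table, pair, transcript_id) {
  stopifnot(inherits(pair, "group_pair"))
  num <- abundance_values(table, transcript_id, pair$numerator)
  den <- abundance_values(table, transcript_id, pair$denominator)
  if (any(num < 0) || any(den < 0)) stop("negative abundance")
  lg_ratio(num, den, pair$pseudocount) |> stats::setNames(transcript_id)
}

lg_ratio <- function(num, den, eps = 0) {
  num <- num + eps
  den <- den + eps
  out <- ifelse(den == 0, NA_real_, log10(num / den))
  # 0/0 with eps = 0 is undefined, not -Inf
  out[den == 0] <- NA_real_
  out
}

#' Aggregate abundance of a transcript set
#'
#' The per-locus abundance of a marker amplicon that detects several splice
#' variants is summarized as the arithmetic mean of the member transcripts'
#' TPM values in the given condition.
#'
#' @param table An `abundance_table`.
#' @param transcript_ids Non-empty character vector of member IDs.
#' @param condition Condition label.
#' @return A single numeric value.
#' @export
aggregate_abundance <- function(table, transcript_ids, condition) {
  if (length(transcript_ids) < 1) stop("empty transcript set")
  mean(abundance_values(table, transcript_ids, condition))
}

#' Aggregate lg(fc) of a transcript set
#'
#' The log fold change of the aggregate: lg_fold_change applied to the two
#' per-condition aggregate means. Note this is not the mean of the
#' per-transcript lg(fc) values.
#'
#' @inheritParams aggregate_abundance
#' @param pair A [group_pair()].
#' @return A single numeric lg(fc).
#' @export
aggregate_lgfc <- function(table, transcript_ids, pair) {
  stopifnot(inherits(pair, "group_pair"))
  num <- aggregate_abundance(table, transcript_ids, pair$numerator)
  den <- aggregate_abundance(table, transcript_ids, pair$denominator)
  lg_ratio(num, den, pair$pseudocount)
}
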