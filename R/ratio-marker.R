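#' Two-marker ratio statistic
#'
#' Urine RNA concentrations vary between donors over orders of magnitude,
#' so any single marker's absolute abundance is an unreliable classifier.
#' The quotient of an up-regulated and a down-regulated marker cancels the
#' per-sample scale: within each condition the ratio of the two markers'
#' aggregate abundances is formed, and the base-10 log of the
#' between-condition ratio of ratios (the lg discrimination) measures how
#' far the two conditions separate. Algebraically the lg discrimination
#' equals `aggregate_lgfc(numerator) - aggregate_lgfc(denominator)`.
#'
#' @param table An `abundance_table` (TPM).
#' @param num_ids Transcript set of the numerator marker (e.g. the S100A6
#'   transcripts).
#' @param den_ids Transcript set of the denominator marker (e.g. TRAM1).
#' @param pair A [group_pair()] naming the two conditions.
#' @param num_label,den_label Display labels.
#' @return A `ratio_marker` object: per-condition ratios, `lg_discrimination`
#'   and the marker labels. Ratios are `NA` with a named condition when a
#'   denominator aggregate is zero.
#' @export
ratio_score <- function(table, num_ids, den_ids, pair,
                        num_label = "numerator", den_label = "denominator") {
  stopifnot(inherits(pair, "group_pair"))
  conds <- c(pair$numerator, pair$denominator)
  ratios <- vapply(conds, function(cc) {
    num <- aggregate_abundance(table, num_ids, cc)
    den <- aggregate_abundance(table, den_ids, cc)
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  undefined <- conds[is.na(ratios)]
  lg <- if (length(undefined)) NA_real_ else log10(ratios[1] / ratios[2])
  structure(list(num_label = num_label, den_label = den_label,
                 num_ids = num_ids, den_ids = den_ids,
                 conditions = conds, ratios = ratios,
                 lg_discrimination = unname(lg),
                 undefined_in = undefined),
            class = "ratio_marker")
}

#' Fold separation between conditions of a ratio marker
#'
#' `10^lg_discrimination`: the multiplicative factor by which the
#' marker-ratio differs between the two conditions.
#'
#' @param marker A `ratio_marker` from [ratio_score()].
#' @return A single positive number, or `NA` when the ratio is undefined.
#' @export
discrimination_factor <- function(marker) {
  stopifnot(inherits(marker, "ratio_marker"))
  10^marker$lg_discrimination
}

#' @export
print.ratio_marker <- function(x, ...) {
  cat(sprintf("ratio marker %s / %s\n", x$num_label, x$den_label))
  for (i in seq_along(x$conditions))
    cat(sprintf("  %-10s ratio = %s\n", x$conditions[i],
                format(round(x$ratios[i], 2))))
  cat(sprintf("  lg discrimination = %s (factor %s)\n",
              format(round(x$lg_discrimination, 2)),
              format(round(discrimination_factor(x), 1))))
  invisible(x)
}

#' Export a ratio-marker report
#'
#' @param marker A `ratio_marker`.
#' @param path Output path; `.json` gets a JSON document, anything else a
#'   one-row TSV.
#' @return `path`, invisibly.
#' @export
write_ratio_report <- function(marker, path) {
  row <- list(numerator = marker$num_label, denominator = marker$den_label,
              condition_1 = marker$conditions[1],
              ratio_1 = marker$ratios[[1]],
              condition_2 = marker$conditions[2],
              ratio_2 = marker$ratios[[2]],
              lg_discrimination = marker$lg_discrimination,
              factor = discrimination_factor(marker))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(row, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(row), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
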