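#' Abundance table
#'
#' A per-transcript abundance matrix for a set of named conditions, carried
#' as a tibble with a `transcript_id` column plus one numeric column per
#' condition. The unit (`"counts"` or `"TPM"`) and, for TPM tables, the set
#' of transcripts over which the per-million normalization was computed are
#' kept as attributes so downstream operations can check what they receive.
#'
#' @param x Data frame with a `transcript_id` column and one or more numeric
#'   condition columns.
#' @param unit `"counts"` or `"TPM"`.
#' @param normalization_set For TPM tables, the character vector of
#'   transcript IDs the column sums of one million refer to. Defaults to all
#'   rows.
#' @return A tibble of class `abundance_table`.
#' @export
abundance_table <- function(x, unit = c("counts", "TPM"),
                            normalization_set = NULL) {
  unit <- match.arg(unit)
  x <- tibble::as_tibble(x)
  if (!"transcript_id" %in% names(x)) stop("need a transcript_id column")
  cond <- setdiff(names(x), "transcript_id")
  if (length(cond) < 1) stop("need at least one condition column")
  for (cc in cond) {
    v <- x[[cc]]
    if (!is.numeric(v)) stop("condition column not numeric: ", cc)
    if (any(v < 0, na.rm = TRUE)) stop("negative abundance in column ", cc)
  }
  if (anyDuplicated(x$transcript_id)) stop("duplicate transcript_id rows")
  if (is.null(normalization_set) && unit == "TPM")
    normalization_set <- x$transcript_id
  structure(x,
            unit = unit,
            normalization_set = normalization_set,
            class = c("abundance_table", class(x)))
}

#' @rdname abundance_table
#' @export
abundance_unit <- function(x) attr(x, "unit", exact = TRUE)

#' Conditions (column labels) of an abundance table
#' @param x An `abundance_table`.
#' @return Character vector of condition labels.
#' @export
conditions <- function(x) setdiff(names(x), "transcript_id")

abundance_values <- function(x, ids, condition) {
  if (!condition %in% names(x)) stop("unknown condition: ", condition)
  i <- match(ids, x$transcript_id)
  if (anyNA(i)) stop("transcript not in table: ", ids[is.na(i)][1])
  x[[condition]][i]
}

#' Numerator/denominator condition pair for fold-change computation
#'
#' @param numerator,denominator Distinct condition labels; fold change is
#'   numerator over denominator (e.g. HR over C).
#' @param pseudocount Non-negative TPM offset added to both terms before
#'   taking the ratio; the default 0 keeps ratios exact and maps a zero
#'   denominator to an undefined (`NA`) log fold change.
#' @return A `group_pair` object.
#' @export
group_pair <- function(numerator, denominator, pseudocount = 0) {
  if (identical(numerator, denominator)) stop("condition labels must differ")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  structure(list(numerator = numerator, denominator = denominator,
                 pseudocount = pseudocount),
            class = "group_pair")
}

#' Read/write abundance tables as TSV
#'
#' Plain tab-separated text with a `transcript_id` column followed by the
#' condition columns; the unit travels in the file name or the `unit`
#' argument, not in the file.
#'
#' @param x An `abundance_table`.
#' @param path File path.
#' @param unit Unit to stamp on the table read back.
#' @return `write_abundance_tsv` returns `path` invisibly;
#'   `read_abundance_tsv` returns an `abundance_table`.
#' @export
write_abundance_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path, unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  abundance_table(utils::read.delim(path, check.names = FALSE), unit = unit)
}
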