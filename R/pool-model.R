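#' Mass proportions of donors in an equal-mass RNA pool
#'
#' Each donor contributes a measured RNA mass to the pooled library; the
#' proportion column of a pool composition table is simply each mass as a
#' percentage of the pool total, reported at two decimals.
#'
#' @param masses_ng Positive numeric vector of per-donor masses (ng).
#' @param digits Decimal places of the reported percentages (default 2, as
#'   printed in pool composition tables); use `NULL` for full precision.
#' @return Numeric vector of percentages, same order and names as input.
#' @export
pool_proportions <- function(masses_ng, digits = 2) {
  if (length(masses_ng) == 0) stop("no masses given")
  if (any(!is.finite(masses_ng)) || any(masses_ng <= 0))
    stop("all masses must be positive")
  p <- 100 * masses_ng / sum(masses_ng)
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Read/write a donor marker panel
#'
#' The panel is a per-donor table in the style of a pool composition table:
#' columns `group` (C or HR), `donor`, one column per marker holding copy
#' numbers (including the 18S rRNA reference), and `mass_ng`, the RNA mass
#' the donor contributes to the pool.
#'
#' @param path TSV file path.
#' @param panel Panel data frame.
#' @return `read_panel_tsv` returns a tibble; `write_panel_tsv` returns
#'   `path` invisibly.
#' @export
read_panel_tsv <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  validate_panel(x)
  x
}

#' @rdname read_panel_tsv
#' @export
write_panel_tsv <- function(panel, path) {
  validate_panel(panel)
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_panel <- function(panel) {
  need <- c("group", "donor", "mass_ng")
  if (!all(need %in% names(panel)))
    stop("panel needs columns: ", paste(need, collapse = ", "))
  markers <- panel_markers(panel)
  if (length(markers) < 1) stop("panel has no marker columns")
  for (m in markers)
    if (any(panel[[m]] < 0, na.rm = TRUE)) stop("negative copies for ", m)
  if (any(panel$mass_ng <= 0)) stop("masses must be positive")
  invisible(panel)
}

panel_markers <- function(panel) {
  setdiff(names(panel), c("group", "donor", "mass_ng"))
}

#' Group-level lg(fc) of a marker from a donor panel
#'
#' Per donor, the marker copy number is normalized to the donor's 18S rRNA
#' copies (correcting for input amount); donors within a group are then
#' summarized, by default with the geometric mean over donors with a
#' positive normalized value (log-domain averaging; zero values are dropped
#' with a warning since a zero has no logarithm). The returned statistic is
#' `log10(summary_HR / summary_C)` for the requested groups.
#'
#' @param panel A donor panel (see [read_panel_tsv()]).
#' @param marker Marker column name.
#' @param normalizer Reference column, default `"rRNA_18S"`.
#' @param groups Length-2 character: numerator group, denominator group.
#' @param summary `"geometric"` (default) or `"arithmetic"` mean of the
#'   normalized per-donor values.
#' @return A single lg(fc); `NA` if the marker is all-zero in a group.
#' @export
panel_group_lgfc <- function(panel, marker, normalizer = "rRNA_18S",
                             groups = c("HR", "C"),
                             summary = c("geometric", "arithmetic")) {
  summary <- match.arg(summary)
  validate_panel(panel)
  if (!marker %in% names(panel)) stop("unknown marker: ", marker)
  if (!normalizer %in% names(panel)) stop("unknown normalizer: ", normalizer)
  stopifnot(length(groups) == 2)
  summarize_group <- function(g) {
    rows <- panel$group == g
    if (!any(rows)) stop("no donors in group ", g)
    norm <- panel[[normalizer]][rows]
    if (any(norm <= 0)) stop("non-positive ", normalizer, " copies in group ", g)
    v <- panel[[marker]][rows] / norm
    pos <- v > 0
    if (!any(pos)) return(NA_real_)
    if (any(!pos))
      warning(sum(!pos), " zero-copy donor(s) dropped for ", marker,
              " in group ", g, call. = FALSE)
    if (summary == "geometric") exp(mean(log(v[pos]))) else mean(v[pos])
  }
  num <- summarize_group(groups[1])
  den <- summarize_group(groups[2])
  if (is.na(num) || is.na(den)) return(NA_real_)
  log10(num / den)
}

#' Concordance between panel-derived and pool-derived marker lg(fc)
#'
#' Pairs each marker's single-sample (RT-qPCR panel) lg(fc) with its pooled
#' RNA-seq lg(fc) and flags discordant markers: opposite signs, or absolute
#' difference above a threshold.
#'
#' @param panel_lgfc,pool_lgfc Named numeric vectors of lg(fc) per marker;
#'   names must share at least one marker.
#' @param threshold Absolute-difference flag threshold (default 0.5).
#' @return Tibble with columns `marker`, `panel_lgfc`, `pool_lgfc`, `delta`
#'   (absolute difference), `sign_flip`, `discordant`.
#' @export
concordance_table <- function(panel_lgfc, pool_lgfc, threshold = 0.5) {
  shared <- intersect(names(panel_lgfc), names(pool_lgfc))
  if (length(shared) == 0) stop("no shared markers")
  a <- panel_lgfc[shared]
  b <- pool_lgfc[shared]
  delta <- abs(a - b)
  flip <- sign(a) * sign(b) < 0
  tibble::tibble(
    marker = shared,
    panel_lgfc = unname(a),
    pool_lgfc = unname(b),
    delta = unname(delta),
    sign_flip = unname(flip),
    discordant = unname(flip | delta > threshold)
  )
}
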