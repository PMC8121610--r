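#' Bundled marker reference tables
#'
#' Small plain-text tables shipped with the package, taken from the pooled
#' urine-RNA bladder-cancer marker study the pipeline implements:
#'
#' * `"pool_composition"` — per-donor marker copy numbers (KRT20, LASP1,
#'   OP18, UPK1A, BIRC5, 18S rRNA) and contributed RNA mass for the control
#'   (C) and high-risk (HR) pools.
#' * `"cxcl8_transcripts"` — the three CXCL8 splice variants with their HR
#'   and C TPM values, TSL and biotype.
#' * `"tram1_circ_transcripts"` — the four circular TRAM1 isoforms with HR
#'   and C TPM values.
#' * `"marker_aggregates"` — locus-level aggregate TPM of the five
#'   validated markers in the urine pools (HR, C) and in the ECV-304 /
#'   RT-4 bladder-carcinoma cell-line model.
#'
#' @param name One of the table names above.
#' @return A tibble.
#' @export
marker_fixture <- function(name = c("pool_composition", "cxcl8_transcripts",
                                    "tram1_circ_transcripts",
                                    "marker_aggregates")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "uromarker", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Marker-table abundance fixtures as abundance tables
#'
#' Convenience wrappers returning the bundled TPM tables as
#' `abundance_table` objects ready for [aggregate_lgfc()] and
#' [ratio_score()].
#'
#' @return An `abundance_table` with unit TPM.
#' @export
urine_pool_tpm <- function() {
  cx <- marker_fixture("cxcl8_transcripts")
  tr <- marker_fixture("tram1_circ_transcripts")
  x <- rbind(cx[, c("transcript_id", "HR", "C")],
             tr[, c("transcript_id", "HR", "C")])
  abundance_table(x, unit = "TPM")
}

#' @rdname urine_pool_tpm
#' @export
marker_aggregate_tpm <- function() {
  abundance_table(marker_fixture("marker_aggregates"), unit = "TPM")
}
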