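#' Run the marker-discovery pipeline end to end
#'
#' Orchestrates the stages in the order of the analysis: read the
#' annotation and counts, normalize to TPM, score lg(fc) and apply the
#' multi-criteria filter, rank candidates per direction and class, design
#' amplicons for selected loci, and compute the configured two-marker ratio.
#' Everything is deterministic given the inputs and the seed; the report
#' carries a provenance block (config hash, package version, seed) and no
#' timestamps, so identical configurations reproduce byte-identical output.
#'
#' @param config A named list or the path of a YAML file with fields:
#'   `annotation_dir`, `counts_tsv` (+ optional `counts_unit`, default
#'   `"counts"`), `out_dir`, optional `panel_tsv`, `pair` (list
#'   `numerator`/`denominator`/`pseudocount`, default HR over C), `criteria`
#'   (arguments of [filter_criteria()]), `convergent_targets` (list of
#'   transcript-ID vectors), `divergent_loci` (gene IDs), `ratio` (list
#'   `num_ids`, `den_ids`, `num_label`, `den_label`), `seed`.
#' @return The report list, invisibly; files are written under `out_dir`
#'   (`candidates.tsv`, `excluded.tsv`, `amplicons.tsv`, `primers.fa`,
#'   `ratio.json` when configured, `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- validation ----------------------------------------------------------
  for (f in c("annotation_dir", "counts_tsv", "out_dir"))
    if (is.null(config[[f]])) stop("config field missing: ", f)
  if (!dir.exists(config$annotation_dir))
    stop("annotation_dir does not exist: ", config$annotation_dir)
  if (!file.exists(config$counts_tsv))
    stop("counts_tsv does not exist: ", config$counts_tsv)
  criteria <- do.call(filter_criteria, config$criteria %||% list())
  pair_cfg <- config$pair %||% list(numerator = "HR", denominator = "C")
  pair <- group_pair(pair_cfg$numerator, pair_cfg$denominator,
                     pair_cfg$pseudocount %||% 0)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- inputs --------------------------------------------------------------
  bundle <- stage("read_annotation", read_annotation(config$annotation_dir))
  if (nrow(bundle$records) == 0) stop("annotation is empty")
  unit <- config$counts_unit %||% "counts"
  counts <- stage("read_counts",
                  read_abundance_tsv(config$counts_tsv, unit = unit))

  # -- quantify ------------------------------------------------------------
  tpm <- stage("quantify", {
    if (abundance_unit(counts) == "counts")
      counts_to_tpm(counts, bundle$records) else counts
  })

  # -- select & rank -------------------------------------------------------
  selection <- stage("select",
                     apply_filters(tpm, bundle$records, criteria, pair))
  ranked <- stage("rank", rank_candidates(selection$candidates))
  write_candidates_tsv(ranked, file.path(config$out_dir, "candidates.tsv"))
  write_candidates_tsv(selection$excluded,
                       file.path(config$out_dir, "excluded.tsv"))

  # -- amplicons -----------------------------------------------------------
  constraints <- do.call(amplicon_constraints,
                         config$amplicon_constraints %||% list())
  designs <- stage("amplicons", {
    all_designs <- list()
    for (tgt in config$convergent_targets %||% list()) {
      d <- design_convergent(bundle$records, unlist(tgt), constraints,
                             table = tpm, pair = pair, max_designs = 3L,
                             step = 2L)
      all_designs[[length(all_designs) + 1L]] <- d
    }
    for (locus in config$divergent_loci %||% character(0)) {
      sub <- bundle$records[bundle$records$gene_id == locus, , drop = FALSE]
      d <- design_divergent(sub, constraints, table = tpm, pair = pair,
                            max_designs = 3L, step = 2L)
      all_designs[[length(all_designs) + 1L]] <- d
    }
    if (length(all_designs)) do.call(rbind, all_designs) else
      amplicon_specs_tibble(list())
  })
  write_amplicons_tsv(designs, file.path(config$out_dir, "amplicons.tsv"))
  write_primers_fasta(designs, file.path(config$out_dir, "primers.fa"))

  # -- ratio marker --------------------------------------------------------
  ratio <- NULL
  if (!is.null(config$ratio)) {
    rc <- config$ratio
    ratio <- stage("ratio",
                   ratio_score(tpm, unlist(rc$num_ids), unlist(rc$den_ids),
                               pair,
                               num_label = rc$num_label %||% "numerator",
                               den_label = rc$den_label %||% "denominator"))
    write_ratio_report(ratio, file.path(config$out_dir, "ratio.json"))
  }

  # -- provenance & report -------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config[order(names(config))], cfg_path)
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("uromarker")),
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = config$seed %||% NA),
    n_transcripts = nrow(bundle$records),
    n_candidates = nrow(ranked),
    n_excluded = nrow(selection$excluded),
    n_amplicon_designs = nrow(designs),
    top_candidates = utils::head(
      ranked[, c("transcript_id", "name", "class", "direction", "lgfc")], 10),
    ratio = if (!is.null(ratio))
      list(numerator = ratio$num_label, denominator = ratio$den_label,
           ratios = as.list(ratio$ratios),
           lg_discrimination = ratio$lg_discrimination,
           factor = discrimination_factor(ratio))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}

#' Write a complete demo input set
#'
#' Generates a small synthetic study — annotation with circular isoforms,
#' two-condition counts with four injected markers (two up, two down, one of
#' them circular), and a donor panel — and writes it under `dir` so a full
#' [run_pipeline()] can be exercised in seconds.
#'
#' @param dir Output directory.
#' @param seed Integer seed controlling every random draw.
#' @return Named list: `manifest` (file paths), `config` (a ready-to-run
#'   pipeline configuration writing to `file.path(dir, "out")`), and
#'   `markers` (the injected effects).
#' @export
make_demo_fixture <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- transcriptome_spec(n_loci = 8, variants_per_locus = c(1, 3),
                             exon_count_range = c(2, 5),
                             exon_length_range = c(90, 250),
                             circ_fraction = 0.5, seed = seed)
  bundle <- make_annotation(spec)
  records <- bundle$records
  lin <- records$transcript_id[records$topology == "linear"]
  circ <- records$transcript_id[records$topology == "circular"]
  markers <- data.frame(
    transcript_id = c(lin[1], lin[2], lin[3],
                      if (length(circ)) circ[1] else lin[4]),
    lgfc = c(0.8, 1.0, -0.8, -1.2))
  effects <- effect_spec(markers, depth = 5e5, seed = seed + 1L)
  counts <- simulate_counts(bundle, effects)
  panel <- simulate_patient_panel(patient_panel_spec(
    group_means = data.frame(marker = c("KRT20", "LASP1", "rRNA_18S"),
                             C = c(50, 900, 9e5), HR = c(1500, 2800, 2.4e6)),
    n_donors = 7, span = 2, seed = seed + 2L))

  ann_dir <- file.path(dir, "annotation")
  paths <- write_annotation(bundle, ann_dir)
  counts_path <- file.path(dir, "counts.tsv")
  write_abundance_tsv(counts, counts_path)
  panel_path <- file.path(dir, "panel.tsv")
  write_panel_tsv(panel, panel_path)

  config <- list(
    annotation_dir = ann_dir,
    counts_tsv = counts_path,
    counts_unit = "counts",
    panel_tsv = panel_path,
    out_dir = file.path(dir, "out"),
    pair = list(numerator = "HR", denominator = "C"),
    ratio = list(num_ids = markers$transcript_id[1],
                 den_ids = markers$transcript_id[4],
                 num_label = "up_marker", den_label = "down_marker"),
    seed = seed)
  list(manifest = c(paths, counts = counts_path, panel = panel_path),
       config = config, markers = markers)
}
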