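# Run code under a seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_range <- function(r, what, min_allowed = 1L) {
  if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
      r[1] < min_allowed)
    stop("degenerate ", what, " range: need min <= max and min >= ",
         min_allowed)
  as.integer(r)
}

#' Specification of a simulated two-class transcriptome
#'
#' Describes the synthetic annotation emulating the union of a cDNA
#' (coding), ncRNA and circRNA reference set: a single contig carrying
#' `n_loci` gene loci, each with a random number of splice variants built
#' from subsets of the locus exon chain, a fraction of loci additionally
#' emitting a circular isoform from a contiguous exon run of their first
#' (full-length) variant, transcript support levels drawn from a weight
#' vector, and exon sequence drawn uniformly over ACGT at a configurable GC
#' content.
#'
#' @param n_loci Number of gene loci.
#' @param variants_per_locus Integer range, linear splice variants per locus.
#' @param exon_count_range Integer range of exons per locus.
#' @param exon_length_range Integer range of exon lengths (nt).
#' @param intron_length_range Integer range of intron lengths (nt).
#' @param circ_fraction Fraction of loci that also emit a circular isoform.
#' @param coding_fraction Fraction of loci with protein-coding biotype; the
#'   rest are lincRNA.
#' @param minus_fraction Fraction of loci on the minus strand (default 0: a
#'   plus-strand-only fixture; strand handling is exercised separately).
#' @param tsl_weights Named weights over TSL levels `"1"`..`"5"` and `"NA"`.
#' @param gc GC content of the contig sequence.
#' @param seed Integer RNG seed; identical seeds give byte-identical output.
#' @return A `transcriptome_spec` object.
#' @export
transcriptome_spec <- function(n_loci,
                               variants_per_locus = c(1L, 4L),
                               exon_count_range = c(2L, 6L),
                               exon_length_range = c(80L, 300L),
                               intron_length_range = c(50L, 200L),
                               circ_fraction = 0.3,
                               coding_fraction = 0.7,
                               minus_fraction = 0,
                               tsl_weights = c("1" = 0.3, "2" = 0.2,
                                               "3" = 0.15, "4" = 0.1,
                                               "5" = 0.1, "NA" = 0.15),
                               gc = 0.5, seed = 1L) {
  if (n_loci < 1) stop("n_loci must be positive")
  if (circ_fraction < 0 || circ_fraction > 1)
    stop("circ_fraction must be in [0,1]")
  if (!setequal(names(tsl_weights), c(as.character(1:5), "NA")))
    stop("tsl_weights needs names 1..5 and NA")
  structure(list(
    n_loci = as.integer(n_loci),
    variants_per_locus = check_range(variants_per_locus, "variants_per_locus"),
    exon_count_range = check_range(exon_count_range, "exon_count"),
    exon_length_range = check_range(exon_length_range, "exon_length"),
    intron_length_range = check_range(intron_length_range, "intron_length"),
    circ_fraction = circ_fraction, coding_fraction = coding_fraction,
    minus_fraction = minus_fraction,
    tsl_weights = tsl_weights / sum(tsl_weights),
    gc = gc, seed = as.integer(seed)),
    class = "transcriptome_spec")
}

sample_tsl <- function(n, weights) {
  lev <- sample(names(weights), n, replace = TRUE, prob = weights)
  suppressWarnings(as.integer(lev))  # "NA" becomes NA by design
}

#' Generate a synthetic annotation bundle
#'
#' Lays the loci of a [transcriptome_spec()] end to end on one synthetic
#' contig (100 nt spacers), draws the contig sequence, and builds the
#' transcript records: per locus a full-length variant over all exons,
#' additional variants over random exon subsets (first and last exon always
#' retained so variants differ in internal splicing), and, for circular
#' loci, a back-spliced isoform over a contiguous exon run of the
#' full-length parent.
#'
#' @param spec A [transcriptome_spec()].
#' @return An `annotation_bundle`: list with `records`
#'   (`transcript_records`, sequences populated), `genome` (named character
#'   vector with the contig) and `spec`.
#' @export
make_annotation <- function(spec) {
  stopifnot(inherits(spec, "transcriptome_spec"))
  with_local_seed(spec$seed, {
    rows <- list()
    pos <- 1L
    circ_counter <- 0L
    tx_counter <- 0L
    for (g in seq_len(spec$n_loci)) {
      gene_id <- sprintf("GENE%04d", g)
      n_ex <- sample_int_range(spec$exon_count_range)
      ex_len <- sample_int_range(spec$exon_length_range, n_ex)
      in_len <- if (n_ex > 1) sample_int_range(spec$intron_length_range,
                                               n_ex - 1L) else integer(0)
      starts <- integer(n_ex)
      ends <- integer(n_ex)
      p <- pos
      for (i in seq_len(n_ex)) {
        starts[i] <- p
        ends[i] <- p + ex_len[i] - 1L
        p <- ends[i] + (if (i < n_ex) in_len[i] else 0L) + 1L
      }
      pos <- p + 100L
      strand <- if (stats::runif(1) < spec$minus_fraction) "-" else "+"
      coding <- stats::runif(1) < spec$coding_fraction
      biotype <- if (coding) "protein_coding" else "lincRNA"

      n_var <- sample_int_range(spec$variants_per_locus)
      subsets <- list(seq_len(n_ex))
      if (n_var > 1 && n_ex > 2) {
        for (v in seq_len(n_var - 1L)) {
          internal <- 2:(n_ex - 1L)
          keep <- internal[stats::runif(length(internal)) < 0.5]
          subsets[[length(subsets) + 1L]] <- c(1L, keep, n_ex)
        }
        subsets <- unique(subsets)
      }
      for (v in seq_along(subsets)) {
        tx_counter <- tx_counter + 1L
        idx <- subsets[[v]]
        rows[[length(rows) + 1L]] <- list(
          transcript_id = sprintf("ENSTS%08d", tx_counter),
          name = sprintf("%s-%03d", gene_id, 200L + v),
          gene_id = gene_id, biotype = biotype,
          tsl = sample_tsl(1, spec$tsl_weights),
          topology = "linear", strand = strand,
          exon_start = starts[idx], exon_end = ends[idx],
          circ_parent = NA_character_)
      }
      if (stats::runif(1) < spec$circ_fraction) {
        circ_counter <- circ_counter + 1L
        lo <- sample_int_range(c(1L, n_ex))
        hi <- sample_int_range(c(lo, n_ex))
        rows[[length(rows) + 1L]] <- list(
          transcript_id = sprintf("hsa_circ_%07d", circ_counter),
          name = sprintf("%s_circ", gene_id),
          gene_id = gene_id, biotype = "circRNA",
          tsl = NA_integer_, topology = "circular", strand = strand,
          exon_start = starts[lo:hi], exon_end = ends[lo:hi],
          circ_parent = rows[[which(vapply(rows, function(r)
            r$gene_id == gene_id && r$topology == "linear",
            logical(1)))[1]]]$transcript_id)
      }
    }
    contig_len <- pos + 100L
    contig <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE,
                           prob = c((1 - spec$gc) / 2, spec$gc / 2,
                                    spec$gc / 2, (1 - spec$gc) / 2)),
                    collapse = "")
    records <- transcript_records(
      transcript_id = vapply(rows, `[[`, character(1), "transcript_id"),
      name = vapply(rows, `[[`, character(1), "name"),
      gene_id = vapply(rows, `[[`, character(1), "gene_id"),
      biotype = vapply(rows, `[[`, character(1), "biotype"),
      tsl = vapply(rows, `[[`, integer(1), "tsl"),
      topology = vapply(rows, `[[`, character(1), "topology"),
      contig = "chrS",
      strand = vapply(rows, `[[`, character(1), "strand"),
      exon_start = lapply(rows, `[[`, "exon_start"),
      exon_end = lapply(rows, `[[`, "exon_end"),
      circ_parent = vapply(rows, `[[`, character(1), "circ_parent"))
    genome <- c(chrS = contig)
    records <- add_sequences(records, genome)
    structure(list(records = records, genome = genome, spec = spec),
              class = "annotation_bundle")
  })
}

sample_int_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep(r[1], n) else
    r[1] + sample.int(r[2] - r[1] + 1L, n, replace = TRUE) - 1L
}

#' Expression effects for the two-condition count simulation
#'
#' Assigns every transcript a baseline expression drawn log-normally and a
#' target lg(fc) (0 for all non-markers); the treated condition's expected
#' TPM is `baseline * 10^lgfc`.
#'
#' @param markers Data frame with columns `transcript_id` and `lgfc` (base-10
#'   target log fold change, positive for up-regulated markers); may have
#'   zero rows.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline TPM distribution.
#' @param depth Total reads per condition (multinomial size), >= 0.
#' @param seed Integer RNG seed.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(markers = data.frame(transcript_id = character(0),
                                             lgfc = numeric(0)),
                        baseline_meanlog = log(50), baseline_sdlog = 1,
                        depth = 1e6, seed = 1L) {
  stopifnot(all(c("transcript_id", "lgfc") %in% names(markers)))
  if (depth < 0) stop("depth must be >= 0")
  if (anyDuplicated(markers$transcript_id)) stop("duplicate marker IDs")
  structure(list(markers = markers, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, depth = depth,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

#' Simulate two-condition read counts
#'
#' Draws a baseline TPM profile, applies the marker effects to the second
#' (treated) condition, and samples reads per condition from a multinomial
#' whose category probabilities are proportional to `TPM_i * length_i` —
#' the inverse of the TPM transform, so that `counts_to_tpm()` on the
#' simulated counts is an unbiased estimator of the injected abundances.
#' Counts in each condition sum exactly to `depth`.
#'
#' @param annotation An `annotation_bundle` or `transcript_records` table.
#' @param effects An [effect_spec()].
#' @param conditions Two labels; the first is the baseline (control), the
#'   second carries the marker effects.
#' @return An `abundance_table` with unit `"counts"` and an attribute
#'   `true_tpm` holding the expected TPM matrix the counts were drawn from.
#' @export
simulate_counts <- function(annotation, effects, conditions = c("C", "HR")) {
  stopifnot(inherits(effects, "effect_spec"), length(conditions) == 2)
  records <- if (inherits(annotation, "annotation_bundle"))
    annotation$records else annotation
  ids <- records$transcript_id
  unknown <- setdiff(effects$markers$transcript_id, ids)
  if (length(unknown))
    stop("marker assignment names unknown transcript: ", unknown[1])
  with_local_seed(effects$seed, {
    n <- length(ids)
    baseline <- stats::rlnorm(n, effects$baseline_meanlog,
                              effects$baseline_sdlog)
    lgfc <- stats::setNames(rep(0, n), ids)
    lgfc[effects$markers$transcript_id] <- effects$markers$lgfc
    tpm <- cbind(baseline, baseline * 10^lgfc)
    colnames(tpm) <- conditions
    # renormalize each column to TPM scale (sums to 1e6)
    tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
    out <- tibble::tibble(transcript_id = ids)
    for (j in 1:2) {
      prob <- tpm[, j] * records$length_kb
      counts <- if (effects$depth == 0) rep(0L, n) else
        as.integer(stats::rmultinom(1, effects$depth, prob))
      out[[conditions[j]]] <- counts
    }
    tab <- abundance_table(out, unit = "counts")
    attr(tab, "true_tpm") <- tpm
    tab
  })
}

#' Specification of a donor marker panel
#'
#' Emulates a per-donor copy-number panel for a small marker set measured by
#' RT-qPCR in a control (C) and a high-risk (HR) donor group, with
#' inter-donor variability spanning up to a configured number of orders of
#' magnitude around the group geometric mean.
#'
#' @param group_means Data frame with a `marker` column plus one numeric
#'   column per group (e.g. `C`, `HR`) giving the group geometric-mean copy
#'   numbers; all means must be positive.
#' @param n_donors Donors per group (single integer or named per group).
#' @param span Inter-donor variability span in orders of magnitude: donor
#'   copies are the group mean times `10^u` with `u` truncated to
#'   `[-span/2, span/2]` (so the max/min ratio never exceeds `10^span`).
#' @param mass_ng_range Range the per-donor contributed RNA mass (ng) is
#'   drawn from uniformly (rounded to integer ng).
#' @param seed Integer RNG seed.
#' @return A `panel_spec` object.
#' @export
patient_panel_spec <- function(group_means, n_donors = 7L, span = 4,
                               mass_ng_range = c(11, 19), seed = 1L) {
  if (!"marker" %in% names(group_means)) stop("group_means needs 'marker'")
  groups <- setdiff(names(group_means), "marker")
  if (length(groups) < 2) stop("need at least two group columns")
  for (g in groups)
    if (any(group_means[[g]] <= 0)) stop("non-positive group mean in ", g)
  if (span < 0) stop("span must be >= 0")
  if (length(n_donors) == 1) n_donors <- stats::setNames(
    rep(as.integer(n_donors), length(groups)), groups)
  if (any(n_donors < 1)) stop("need at least one donor per group")
  structure(list(group_means = group_means, groups = groups,
                 n_donors = n_donors, span = span,
                 mass_ng_range = mass_ng_range, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Simulate a donor marker panel
#'
#' Per donor and marker, copies are drawn log-normally around the group
#' geometric mean: `copies = mean * 10^u` with `u ~ Normal(0, span/4)`
#' truncated (by inverse-CDF sampling) to `[-span/2, span/2]`. The symmetric
#' truncation keeps the group geometric mean unbiased and hard-caps the
#' max/min copy ratio at `10^span`. With `span = 0` every donor equals the
#' group geometric mean exactly.
#'
#' @param spec A [patient_panel_spec()].
#' @return A panel tibble (`group`, `donor`, marker columns, `mass_ng`)
#'   as consumed by [panel_group_lgfc()].
#' @export
simulate_patient_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_local_seed(spec$seed, {
    sd <- spec$span / 4
    half <- spec$span / 2
    draw_u <- function(n) {
      if (spec$span == 0) return(rep(0, n))
      plo <- stats::pnorm(-half, sd = sd)
      phi <- stats::pnorm(half, sd = sd)
      stats::qnorm(stats::runif(n, plo, phi), sd = sd)
    }
    out <- list()
    for (g in spec$groups) {
      nd <- spec$n_donors[[g]]
      block <- tibble::tibble(
        group = g,
        donor = sprintf("%s%02d", g, seq_len(nd)))
      for (i in seq_len(nrow(spec$group_means))) {
        m <- spec$group_means$marker[i]
        block[[m]] <- spec$group_means[[g]][i] * 10^draw_u(nd)
      }
      block$mass_ng <- round(stats::runif(nd, spec$mass_ng_range[1],
                                          spec$mass_ng_range[2]))
      out[[g]] <- block
    }
    panel <- do.call(rbind, out)
    rownames(panel) <- NULL
    validate_panel(panel)
  })
}
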