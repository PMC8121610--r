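make_selection_records <- function() {
  # ten transcripts spanning all failure modes of the filter
  transcript_records(
    transcript_id = sprintf("s%02d", 1:10),
    gene_id = sprintf("G%d", rep(1:5, each = 2)),
    biotype = c("protein_coding", "retained_intron", "lincRNA", "snoRNA",
                "circRNA", "protein_coding", "protein_coding", "lincRNA",
                "circRNA", "protein_coding"),
    tsl = c(1L, 2L, 3L, NA, NA, 5L, 1L, 2L, NA, 4L),
    topology = c(rep("linear", 4), "circular", rep("linear", 3),
                 "circular", "linear"),
    exon_start = as.list(rep(1L, 10)),
    exon_end = list(500L, 300L, 149L, 1000L, 200L, 400L, 2000L, 180L,
                    90L, 150L),
    circ_parent = c(NA, NA, NA, NA, "s01", NA, NA, NA, "s01", NA))
}

make_selection_table <- function() {
  abundance_table(tibble::tibble(
    transcript_id = sprintf("s%02d", 1:10),
    HR = c(100, 8, 60, 40, 30, 5, 11, 90, 12, 35),
    C = c(20, 2, 10, 39, 300, 0.4, 2, 9, 1, 4)), "TPM")
}

test_that("biotype classification partitions coding / ncRNA / circRNA", {
  rec <- make_selection_records()
  cls <- classify_biotype(rec)
  expect_identical(cls[rec$transcript_id == "s05"], "circRNA")  # topology wins
  expect_identical(cls[1:2], c("coding", "coding"))             # incl. retained intron
  expect_identical(cls[3], "ncRNA")
  bad <- rec[1, ]
  bad$biotype <- "weird_biotype"
  expect_error(classify_biotype(bad), "accepted")
})

test_that("filter survivors match a brute-force evaluation of the predicate", {
  rec <- make_selection_records()
  tab <- make_selection_table()
  pr <- group_pair("HR", "C")
  for (cr in list(filter_criteria(),
                  filter_criteria(tsl_policy = "hard", tsl_cutoff = 2),
                  filter_criteria(min_tpm = 50),
                  filter_criteria(classes = c("coding", "circRNA")),
                  filter_criteria(lgfc_up = 1.2, lgfc_down = -1.2))) {
    res <- apply_filters(tab, rec, cr, pr)
    lgfc <- lg_fold_change(tab, pr, rec$transcript_id)
    expected <- rec$transcript_id[vapply(seq_len(10), function(i)
      oracle_passes(lgfc[i], tab$HR[i], tab$C[i], rec$length_nt[i],
                    rec$tsl[i], classify_biotype(rec[i, ]), cr),
      logical(1))]
    expect_setequal(res$candidates$transcript_id, expected)
    # partition: everything lands on exactly one side
    expect_setequal(c(res$candidates$transcript_id,
                      res$excluded$transcript_id), rec$transcript_id)
    expect_length(intersect(res$candidates$transcript_id,
                            res$excluded$transcript_id), 0)
  }
})

test_that("each named exclusion reason fails when re-tested individually", {
  rec <- make_selection_records()
  tab <- make_selection_table()
  pr <- group_pair("HR", "C")
  cr <- filter_criteria(tsl_policy = "hard", tsl_cutoff = 3)
  res <- apply_filters(tab, rec, cr, pr)
  expect_true(nrow(res$excluded) > 0)
  for (i in seq_len(nrow(res$excluded))) {
    id <- res$excluded$transcript_id[i]
    reasons <- strsplit(res$excluded$reasons[i], ",")[[1]]
    expect_gte(length(reasons), 1)
    k <- match(id, rec$transcript_id)
    lgfc <- unname(lg_fold_change(tab, pr, id))
    for (r in reasons) {
      holds <- switch(
        r,
        lgfc_threshold = !(lgfc > cr$lgfc_up || lgfc < cr$lgfc_down),
        min_tpm = max(tab$HR[k], tab$C[k]) < cr$min_tpm,
        min_length = rec$length_nt[k] < cr$min_length_nt,
        tsl = (if (is.na(rec$tsl[k])) 6 else rec$tsl[k]) > cr$tsl_cutoff,
        class = !classify_biotype(rec[k, ]) %in% cr$classes,
        undefined_lgfc = is.na(lgfc))
      expect_true(holds, label = paste(id, r))
    }
  }
})

test_that("relaxing any single criterion never shrinks the passing set", {
  rec <- make_selection_records()
  tab <- make_selection_table()
  pr <- group_pair("HR", "C")
  strict <- filter_criteria(lgfc_up = 0.7, lgfc_down = -0.7, min_tpm = 20,
                            min_length_nt = 200, tsl_policy = "hard",
                            tsl_cutoff = 2)
  base <- apply_filters(tab, rec, strict, pr)$candidates$transcript_id
  relaxed <- list(
    filter_criteria(lgfc_up = 0.3, lgfc_down = -0.7, min_tpm = 20,
                    min_length_nt = 200, tsl_policy = "hard", tsl_cutoff = 2),
    filter_criteria(lgfc_up = 0.7, lgfc_down = -0.7, min_tpm = 5,
                    min_length_nt = 200, tsl_policy = "hard", tsl_cutoff = 2),
    filter_criteria(lgfc_up = 0.7, lgfc_down = -0.7, min_tpm = 20,
                    min_length_nt = 50, tsl_policy = "hard", tsl_cutoff = 2),
    filter_criteria(lgfc_up = 0.7, lgfc_down = -0.7, min_tpm = 20,
                    min_length_nt = 200, tsl_policy = "rank-weight"))
  for (cr in relaxed) {
    wider <- apply_filters(tab, rec, cr, pr)$candidates$transcript_id
    expect_true(all(base %in% wider))
  }
})

test_that("a high-abundance well-supported transcript passes the default filter", {
  # the CXCL8-201-style row: strong lg(fc), high TPM, long, TSL 1
  rec <- transcript_records("tx1", gene_id = "CXCL8like",
                            biotype = "retained_intron", tsl = 1L,
                            exon_start = list(1L), exon_end = list(1705L))
  tab <- abundance_table(tibble::tibble(transcript_id = "tx1",
                                        HR = 618.357, C = 148.984), "TPM")
  res <- apply_filters(tab, rec, filter_criteria(), group_pair("HR", "C"))
  expect_identical(res$candidates$transcript_id, "tx1")
  expect_identical(res$candidates$direction, "up")

  weak <- abundance_table(tibble::tibble(transcript_id = "tx1",
                                         HR = 20, C = 10.02), "TPM")
  res2 <- apply_filters(weak, rec, filter_criteria(), group_pair("HR", "C"))
  expect_identical(res2$excluded$reasons, "lgfc_threshold")
})

test_that("ranking is total, stable, and permutation-invariant", {
  rec <- make_selection_records()
  tab <- make_selection_table()
  pr <- group_pair("HR", "C")
  cand <- apply_filters(tab, rec, filter_criteria(), pr)$candidates
  ranked <- rank_candidates(cand)
  # rank unique within each direction/class stratum
  expect_false(any(duplicated(
    paste(ranked$direction, ranked$class, ranked$rank))))
  # |lg(fc)| non-increasing within stratum
  for (key in unique(paste(ranked$direction, ranked$class))) {
    sub <- ranked[paste(ranked$direction, ranked$class) == key, ]
    expect_true(all(diff(abs(sub$lgfc)) <= 1e-12))
  }
  for (seed in 1:3) {
    set.seed(seed)
    shuffled <- cand[sample(nrow(cand)), ]
    expect_identical(rank_candidates(shuffled)$transcript_id,
                     ranked$transcript_id)
  }
})

test_that("exact ties are broken by transcript ID", {
  twins <- tibble::tibble(
    transcript_id = c("zzz", "aaa"),
    name = c("z", "a"), gene_id = "G", length_nt = 500L, length_kb = 0.5,
    tsl = 1L, biotype = "protein_coding", class = "coding",
    tpm_HR = 100, tpm_C = 10, lgfc = 1, direction = "up")
  expect_identical(rank_candidates(twins)$transcript_id, c("aaa", "zzz"))
})
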