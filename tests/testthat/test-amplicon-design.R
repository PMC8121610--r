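test_that("spliced sequence concatenates exons and honors strand", {
  genome <- c(chr1 = "ACGTTTAACC")
  one <- transcript_records("t1", gene_id = "g", biotype = "protein_coding",
                            contig = "chr1", exon_start = list(1L),
                            exon_end = list(10L))
  expect_identical(spliced_sequence(one[1, ], genome), "ACGTTTAACC")

  two <- transcript_records("t2", gene_id = "g", biotype = "protein_coding",
                            contig = "chr1", exon_start = list(c(1L, 5L)),
                            exon_end = list(c(4L, 8L)))
  expect_identical(spliced_sequence(two[1, ], genome), "ACGTTTAA")

  # minus strand: hand-derived reverse complement of the concatenation
  minus <- transcript_records("t3", gene_id = "g", biotype = "protein_coding",
                              contig = "chr1", strand = "-",
                              exon_start = list(c(1L, 5L)),
                              exon_end = list(c(4L, 8L)))
  expect_identical(spliced_sequence(minus[1, ], genome), "TTAAACGT")

  oob <- transcript_records("t4", gene_id = "g", biotype = "protein_coding",
                            contig = "chr1", exon_start = list(5L),
                            exon_end = list(99L))
  expect_error(spliced_sequence(oob[1, ], genome), "bounds")
})

test_that("back-splice junction is tail-then-head of the circle", {
  j <- build_backsplice_junction("ACGTACGT", w = 4)
  expect_identical(j$junction, "ACGTACGT")

  # two 6-nt exons: junction = last 3 of exon2 + first 3 of exon1
  circ_seq <- paste0("AAATTT", "GGGCCC")
  j2 <- build_backsplice_junction(circ_seq, w = 3)
  expect_identical(j2$junction, paste0("CCC", "AAA"))

  # rotation oracle: the junction 2w-mer occurs in the doubled circle at
  # the rotation that places the back-splice in the middle
  circ <- with_seed_chr(7, 60)
  j3 <- build_backsplice_junction(circ, w = 20)
  doubled <- paste0(circ, circ)
  rotations <- vapply(0:59, function(r)
    substr(doubled, r + 1, r + 60), character(1))
  hits <- vapply(rotations, function(rot)
    grepl(j3$junction, rot, fixed = TRUE), logical(1))
  expect_true(any(hits))
  expect_true(hits[[41]])  # rotation starting 20 nt before the circle end

  expect_error(build_backsplice_junction("ACGT", w = 4), "shorter")
})

test_that("nearest-neighbor Tm matches an independent evaluation and is monotone in GC", {
  # frozen values from an external nearest-neighbor calculation with the
  # same unified parameter set, 200 nM primer / 4, 50 mM Na+
  expect_equal(primer_tm("AGCGTACGCTAGCTAGGCTA"), 56.351, tolerance = 1e-3)
  expect_equal(primer_tm("GCGCGGCCGCGGGCCGCGCC"), 77.488, tolerance = 1e-3)
  expect_equal(primer_tm("AAAAAAAAAAAAAAAAAAAA"), 37.781, tolerance = 1e-3)

  expect_gt(primer_tm(strrep("GC", 10)), primer_tm(strrep("AT", 10)))
  expect_identical(primer_tm("ACGTACGTACGTACGTACGT"),
                   primer_tm("ACGTACGTACGTACGTACGT"))
  expect_error(primer_tm("ACGTNACGTACGT"), "ambiguity|ACGT")
  expect_error(primer_tm("ACGT"), "shorter")
})

test_that("amplicon coverage equals the brute-force substring oracle", {
  toy <- toy_locus()
  rec <- toy$records
  seqs <- stats::setNames(rec$seq, rec$transcript_id)

  probes <- list(
    # same-exon pair inside exon 3 (shared by all isoforms)
    list(f = substr(seqs[["T1"]], 210, 229),
         r = revcomp(substr(seqs[["T1"]], 290, 309)), o = "convergent"),
    # forward spanning the exon1|exon3 junction, unique to T2
    list(f = substr(seqs[["T2"]], 91, 110),
         r = revcomp(substr(seqs[["T2"]], 160, 179)), o = "convergent"),
    # divergent pair across the back-splice junction of C1
    list(f = substr(paste0(seqs[["C1"]], seqs[["C1"]]), 85, 104),
         r = revcomp(substr(paste0(seqs[["C1"]], seqs[["C1"]]), 140, 159)),
         o = "divergent"),
    # random pair with no binding site at all
    list(f = strrep("ACGT", 5), r = strrep("TGCA", 5), o = "convergent"))

  for (p in probes) {
    pp <- primer_pair(p$f, p$r, p$o)
    got <- amplicon_coverage(pp, rec)
    expect_setequal(got$transcript_id,
                    oracle_coverage(p$f, p$r, rec, p$o))
  }
})

test_that("junction-spanning primers restrict coverage to isoforms with that junction", {
  toy <- toy_locus()
  rec <- toy$records
  t2 <- rec$seq[rec$transcript_id == "T2"]
  # forward overlapping the e1|e3 boundary (position 100|101 on T2)
  pp <- primer_pair(substr(t2, 92, 111), revcomp(substr(t2, 170, 189)),
                    "convergent")
  cov <- amplicon_coverage(pp, rec)
  expect_identical(cov$transcript_id, "T2")
})

test_that("divergent pairs cover circular transcripts only", {
  toy <- toy_locus()
  rec <- toy$records
  c1 <- rec$seq[rec$transcript_id == "C1"]
  doubled <- paste0(c1, c1)
  pp <- primer_pair(substr(doubled, 85, 104),
                    revcomp(substr(doubled, 140, 159)), "divergent")
  cov <- amplicon_coverage(pp, rec)
  expect_true(all(cov$topology == "circular"))
  expect_identical(cov$transcript_id, "C1")
  # exon 2 is shared with T1 and T3, so as a *convergent* pair the same
  # sequences would also see the linear isoforms through the doubled circle
  # context only if a 70-150 nt product exists; the divergent rule is what
  # blinds the pair to linear templates
  pp_conv <- primer_pair(pp$forward, pp$reverse, "convergent")
  cov_conv <- amplicon_coverage(pp_conv, rec)
  expect_true(all(cov_conv$topology == "circular"))
})

test_that("convergent designs satisfy every constraint and hit the requested subset", {
  toy <- toy_locus()
  rec <- toy$records
  cn <- amplicon_constraints()
  designs <- design_convergent(rec, "T2", cn, max_designs = 5, step = 2)
  expect_gt(nrow(designs), 0)
  for (i in seq_len(nrow(designs))) {
    f <- designs$forward[i]; r <- designs$reverse[i]
    expect_true(nchar(f) >= 18 && nchar(f) <= 27)
    expect_true(nchar(r) >= 18 && nchar(r) <= 27)
    tf <- primer_tm(f); tr <- primer_tm(r)
    expect_true(tf >= 57 && tf <= 63)
    expect_true(tr >= 57 && tr <= 63)
    expect_lte(abs(tf - tr), 3)
    expect_true(all(designs$product_lengths[[i]] >= 70 &
                      designs$product_lengths[[i]] <= 150))
    expect_setequal(designs$covered[[i]], "T2")
    # T2 is told apart either by its private e1|e3 junction or by the
    # product-length difference its skipped exon causes
    expect_true(designs$placement[i] %in% c("junction-spanning",
                                            "intron-separated"))
    expect_setequal(oracle_coverage(f, r, rec, "convergent"), "T2")
  }
})

test_that("infeasible convergent requests return an empty table with a report", {
  toy <- toy_locus()
  rec <- toy$records
  # impossible: T1 and T2 share no junction excluding T3's content upstream
  # of a 70 nt product against an absurd Tm window
  cn <- amplicon_constraints(tm_min = 75, tm_max = 76)
  designs <- design_convergent(rec, "T2", cn, max_designs = 2, step = 4)
  expect_identical(nrow(designs), 0L)
  expect_true(!is.null(attr(designs, "infeasibility")))
})

test_that("divergent designs exist for a circle, span its junction, and fail on linear-only input", {
  toy <- toy_locus()
  rec <- toy$records
  designs <- design_divergent(rec, max_designs = 5, step = 2)
  expect_gt(nrow(designs), 0)
  expect_true(attr(designs, "all_covered"))
  for (i in seq_len(nrow(designs))) {
    expect_identical(designs$placement[i], "backsplice-divergent")
    expect_setequal(designs$covered[[i]], "C1")
    expect_true(all(designs$product_lengths[[i]] <= 100))  # circle length
    expect_setequal(
      oracle_coverage(designs$forward[i], designs$reverse[i], rec,
                      "divergent"), "C1")
  }
  lin_only <- rec[rec$topology == "linear", ]
  expect_error(design_divergent(lin_only), "circular")
})

test_that("circles without shared junction context get per-circle designs", {
  # two circles from unrelated loci: no single divergent pair can cover both
  contig <- with_seed_chr(77, 700)
  rec <- transcript_records(
    transcript_id = c("L1", "L2", "CA", "CB"),
    gene_id = c("GA", "GB", "GA", "GB"),
    biotype = c("protein_coding", "protein_coding", "circRNA", "circRNA"),
    topology = c("linear", "linear", "circular", "circular"),
    contig = "chrX",
    exon_start = list(1L, 351L, 1L, 351L),
    exon_end = list(300L, 650L, 120L, 470L),
    circ_parent = c(NA, NA, "L1", "L2"))
  rec <- add_sequences(rec, c(chrX = contig))
  designs <- design_divergent(rec, max_designs = 6, step = 2)
  expect_false(attr(designs, "all_covered"))
  expect_gt(nrow(designs), 0)
  hit <- unique(unlist(designs$covered))
  expect_setequal(hit, c("CA", "CB"))
  for (i in seq_len(nrow(designs)))
    expect_length(designs$covered[[i]], 1)
})

test_that("dimer screen rejects complementary and 3'-anchored primer pairs", {
  # perfectly complementary 20-mers: maximal cross-dimer
  f <- "ACGTACGTACGTACGTACGT"
  expect_false(dimer_screen(primer_pair(f, f, "convergent")))
  # two primers with no complementarity above threshold
  ok <- primer_pair("AGGAGGAGGAGGAGGAGGAG", "TGGTGGTGGTGGTGGTGGTG",
                    "convergent")
  expect_true(dimer_screen(ok))
})
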