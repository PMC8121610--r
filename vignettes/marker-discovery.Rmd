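---
title: "Urine RNA marker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urine RNA marker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uromarker)
```

## The analysis this package implements

Urinary cell-free RNA is an attractive, non-invasive source of bladder-cancer
markers, but its concentration is minute (nanograms per 10 ml of urine) and
inter-donor copy numbers vary over up to four orders of magnitude. The
analysis supported here works around both problems in the same way the
underlying study design does: equal masses of RNA from several donors per
group are pooled into one control (C) and one high-risk (HR) library, the two
pooled transcriptomes are quantified, and candidate markers are selected by
their pool-level contrast rather than by per-donor statistics.

The pipeline stages are:

1. **Quantification.** Read counts are converted to TPM,
   $\mathrm{TPM}_i = 10^6 \,(c_i/l_i) / \sum_j (c_j/l_j)$ with $l_i$ in kb,
   which removes length and depth bias. Differential expression between the
   pools is the base-10 log fold change,
   $\mathrm{lg(fc)} = \log_{10}(\mathrm{TPM}_{HR}/\mathrm{TPM}_C)$.
2. **Selection.** Candidates must satisfy lg(fc) > 0.5 (up) or < −0.5
   (down), at least 10 TPM in one condition, at least 150 nt of length (the
   shortest template for a 70–150 nt amplicon), and a transcript-support
   policy; survivors are ranked by |lg(fc)| within direction × class
   (coding / ncRNA / circRNA).
3. **Amplicon design.** RT-qPCR primer pairs are placed on spliced
   transcript models: convergent pairs (same exon, separated by an intron,
   or junction-spanning) for linear isoforms, divergent pairs across the
   back-splice junction for circular isoforms. An amplicon's abundance
   readout is the arithmetic mean TPM over the transcripts it detects, and
   its contrast is the lg(fc) of those aggregate means.
4. **Ratio marker.** For robust discrimination independent of absolute copy
   number, an up-regulated and a down-regulated marker are combined into a
   per-condition ratio of aggregate abundances; the log of the
   between-condition ratio of ratios (the "lg discrimination") equals the
   difference of the two markers' aggregate lg(fc) values.

## Aggregation is a mean, taken before the log

Locus-level summary rows of multi-isoform markers are computed as the
arithmetic **mean** of the member transcripts' TPM values per condition, and
the locus lg(fc) is the log of the ratio of those means — not the mean of
per-transcript lg(fc) values. The two differ whenever isoform contrasts
differ; the mean-then-log form is the one consistent with what a single
amplicon detecting all the isoforms would measure, and it is the form that
reproduces the published locus summaries (CXCL8 0.61 from per-isoform values
0.618/0.625/0.550; circular TRAM1 −1.26 from −1.80/−1.43/−1.28/−0.81).

## Zero handling

With the default pseudocount of 0, a zero denominator makes lg(fc) undefined
(`NA`, excluded from ranking) rather than an error — donor panels genuinely
contain zero copy counts — and a zero numerator over a positive denominator
is `-Inf`. A configurable pseudocount is available for ranking robustness
when tables contain many zeros. In donor-panel summaries the geometric mean
is taken over donors with positive normalized values, dropping zeros with a
warning: a zero has no logarithm, and imputing one would require a limit of
detection the data do not state. The arithmetic-mean summary mode is exposed
for sensitivity analysis, since how the published single-sample values were
summarized into one per-marker value is not specified.

## TPM normalization sets

The reference material mixes three databases (cDNA, ncRNA, circRNA). Whether
the study normalized TPM within each reference class or jointly over the
union is not stated, so `counts_to_tpm()` takes an explicit
`normalization_set`: the default is the whole table (joint), and passing a
class's IDs normalizes within that class while keeping other transcripts on
the same denominator. The bundled tables are TPM excerpts, so this choice
does not affect the reproduced numbers; for full-transcriptome inputs it
changes absolute TPM but not within-set lg(fc) values.

## Filter and ranking policies

Thresholds follow their wording: strict inequalities for lg(fc), non-strict
for the 10 TPM and 150 nt minima. Transcript support level (TSL) is handled
by policy: the default `rank-weight` keeps poorly supported transcripts but
sinks them via the ranking tie-break (the study retained TSL-5 candidates
while flagging their existence as uncertain); a `hard` cutoff is available.
Missing TSL ranks as a notional level 6, i.e. worse than any assigned level
— conservative, since no experimental support is recorded. Ranking is total
and stable: descending |lg(fc)|, then higher maximal TPM, then better TSL,
then transcript ID. Qualitative "biological information" about a candidate
is deliberately not algorithmized; it would disguise curation as
computation.

## Amplicon design choices

* **Melting temperature.** Unified nearest-neighbor thermodynamics
  (stacking ΔH/ΔS, terminal initiation, entropy salt correction
  $0.368\,(N-1)\ln[\mathrm{Na^+}]$, $T_m = 1000\,\Delta H / (\Delta S + R
  \ln(C_T/4)) - 273.15$), evaluated at 200 nM primer and 50 mM monovalent
  salt — the assay's primer concentration, with excess primer over template.
  The accepted window is 57–63 °C, optimum 60, pair difference ≤ 3 °C;
  primer length 18–27 nt; product 70–150 nt.
* **Coverage.** A transcript is detected iff both primers match its spliced
  sequence exactly in amplifying orientation with a product inside the
  window. Matching is exact (0 mismatches) and restricted to the supplied
  transcript set; no genome-wide off-target search is attempted, so the
  specificity screen is deterministic and desk-scale. Circular transcripts
  are searched on their doubled sequence with product length measured along
  the circle; divergent pairs additionally require the product to read
  through the back-splice junction, which is what makes them structurally
  blind to linear templates. A circle shorter than the minimal product is
  undesignable by rule.
* **Back-splice junction context.** The junction 2w-mer is the circle's last
  w nt followed by its first w nt, with w = 30 by default (configurable);
  the window used by the original junction-retrieval service is not stated.
* **Dimer screens.** Pairs are rejected on a contiguous complementary run of
  ≥ 8 bp (inter- or intra-primer) or ≥ 4 complementary bp anchored at a 3'
  end. These are invented, configurable defaults standing in for the
  secondary-structure screens of interactive design tools.
* **Specificity as set equality.** A convergent design is accepted only if
  its coverage equals exactly the requested isoform subset, which folds
  isoform specificity and off-locus rejection into one predicate. When no
  design survives, the returned empty table carries a structured
  infeasibility report naming the constraint that pruned last. Divergent
  design returns all-covering pairs when a shared junction context exists,
  and per-circle best-covering pairs otherwise — the situation observed at
  loci whose circles share no junction.

## The synthetic data module

No sequencing data were deposited for this study, so the package ships a
generator that emulates the statistical structure the analysis assumes, and
the test suite runs entirely on it plus the bundled printed tables.

* **Annotation.** Loci are laid end to end on one synthetic contig; each has
  2–6 exons of 80–300 nt separated by 50–200 nt introns, 1–4 splice
  variants built from exon subsets (terminal exons retained so variants
  differ in internal splicing), and, at a configurable fraction, one
  circular isoform over a contiguous exon run of the full-length parent.
  Exon sequence is uniform ACGT at configurable GC (default 0.5) so primer
  Tm values spread realistically. The contig is plus-strand by default;
  minus-strand generation exists and strand handling is tested separately.
* **Counts.** Baseline TPM is log-normal; markers multiply the treated
  condition by $10^{\mathrm{lg(fc)}}$; reads are multinomial at the stated
  depth with category probabilities ∝ TPM × length, i.e. the exact inverse
  of the TPM transform, so quantification is an unbiased estimator of the
  injected abundances and per-condition counts sum exactly to the depth.
* **Donor panels.** Copies per donor and marker are the group geometric mean
  times $10^u$, with $u$ normal (sd = span/4), truncated by inverse-CDF
  sampling to ±span/2. The published information is only the *span* of
  inter-donor variability (up to four orders of magnitude), not a
  distribution family; the truncated log-normal is a stand-in, flagged
  here, chosen because it is symmetric in log space (keeping the group
  geometric mean unbiased) and hard-caps the max/min ratio at $10^{span}$.

What the generator does **not** emulate: read-level errors, adapters, rRNA
depletion, positional coverage bias, and any correlation structure between
markers within a donor. Passing tests therefore demonstrate that the
*algorithms* are correct and self-consistent at realistic scales, not that
the biological findings would replicate on new cohorts.

## Problem sizes and tolerances used in the checks

The bundled printed tables (14 donors, 3 + 4 + 5 marker rows) reproduce all
published numbers at two decimals in well under a second. Property checks
use 10–15 transcript random tables over ten seeds (identities to 1e−9 or
1e−12); parameter recovery uses 200 transcripts at a depth of 2 × 10⁶ reads
over 20 seeds, recovering an injected lg(fc) of 0.8 to within ±0.05 in the
Monte-Carlo mean; donor-panel recovery uses 7 + 7 donors at a two-order
span, where single-panel noise is large by design and the Monte-Carlo mean
over ten seeds is required to land within ±0.25. Amplicon-design checks run
on hand-built toy loci (≤ 400 nt, ≤ 5 isoforms) against an independent
brute-force substring oracle.

## Known limitations

* One pooled library per condition means no replication: the lg(fc) ranking
  is descriptive, and no significance testing is attempted (deliberately out
  of scope).
* Primer specificity is checked only against the supplied transcript set;
  genomic DNA and external transcriptomes are not searched.
* Exact-match coverage ignores mismatch-tolerant mispriming.
* The circRNA records model back-splice spans of annotated exon runs;
  intron-retaining circles and novel cryptic back-splices are not
  represented.
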