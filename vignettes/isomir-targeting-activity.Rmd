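---
title: "Background-adjusted isomiR targeting activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-adjusted isomiR targeting activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A standard way to prioritize miRNA–mRNA (or isomiR–mRNA) interactions is
to predict targets from sequence and then keep the pairs whose expression
levels are significantly negatively correlated across a sample series.
The weakness of that recipe is that negative correlation also arises
without any direct targeting — most obviously when a transcription factor
drives a transcript down while driving the small RNA up. This package
implements a joint isomiR–mRNA analysis that quantifies how much
anti-correlation among an isomiR's *predicted targets* exceeds the
anti-correlation observed among transcripts that *cannot* be its targets,
and tests that excess for significance.

A 5′-isomiR is an equivalence class of miRNA isoforms sharing a 5′ end,
written `name|shift` (`hsa-miR-192-5p|+1` lacks the canonical first 5′
nucleotide). Because the seed — nucleotides 2–7, extended 2–8, of the
molecule's own 5′ end — determines target recognition, 5′ variation
rewires the targetome while 3′ variation does not; 3′ variants are
therefore summed into their 5′-isomiR before analysis
(`aggregate_5prime_isomirs()`).

## The statistic

For one isomiR in one sample group, let

* `n_tar` — predicted targets, `m_tar` of which are significantly
  anti-correlated with the isomiR (Spearman `rho < -0.3` and BH
  `FDR < 0.05`, both strict);
* `n_nontar` — non-target transcripts (negative controls), `m_nontar`
  anti-correlated under the same thresholds.

Then

* **ITA** (isomiR targeting activity) `= m_tar`,
* **background ITA** `= n_tar * m_nontar / n_nontar`,
* **adjusted ITA** `= m_tar - n_tar * m_nontar / n_nontar`.

Adjusted ITA is the observed number of anti-correlated targets minus the
number expected if targets anti-correlated only at the background rate.
It is linear in both `m` counts, equals `m_tar` when the background is
empty, and is exactly zero when the two anti-correlation fractions agree.
A negative value does not prove absence of targeting: if the one
functional target among several predicted is a hub transcription factor,
the isomiR anti-correlates with the factor's downstream genes by
transitivity, the background fraction exceeds `m_tar / n_tar`, and the
score goes negative.

Significance is a one-sided Fisher exact test on
`[[m_tar, n_tar - m_tar], [m_nontar, n_nontar - m_nontar]]`. The test is
one-sided in the *greater* direction for the target row — enrichment of
anti-correlation among targets — which is the only direction that detects
activity; the implementation is the closed-form hypergeometric upper tail
(`stats::phyper`), and the test suite checks it against an explicit
probability-mass summation on every table with margins up to 30. Fisher
p-values are BH-adjusted across isomiRs within each (group, stratum)
family; an isomiR is *active* where `fisher_fdr < 0.05`. For display on a
symmetric log scale the records also carry
`signed_log(y) = sgn(y) * log2(|y| + 1)`.

## Non-target composition

Non-targets are transcripts containing no 6-mer seed-binding site
anywhere in their sequence, allowing an unlimited number of G:U wobbles.
`seed_site_kmers(seed, allow_wobble = TRUE)` enumerates every mRNA 6-mer
that pairs the seed antiparallel position-by-position (miRNA A admits
mRNA U; C admits G; G admits C or U; U admits A or G — the set has size
`2^(#G + #U)`), and `compose_nontarget_set()` returns the transcripts
with zero occurrences, looked up in a 6-mer hash index
(`build_kmer_index()`) rather than by rescanning.

Three choices here were genuinely open and are fixed as follows:

* wobbles are admitted in both orientations (G:U and U:G), as in standard
  RNA duplex chemistry;
* the excluding 6-mer is the seed of the *specific 5′-isomiR* (positions
  2–7 of its own 5′ end), not of the canonical miRNA;
* the scan covers the full transcript — 5′-UTR, CDS and 3′-UTR — since a
  site anywhere disqualifies a negative control.

## Site classification

`classify_site()` labels an 8-nt mRNA window (read 5′→3′; its 3′-most
nucleotide opposes isomiR position 1) with the classical seed-site types,
checked in precedence order: **8mer** (Watson–Crick 2–8 plus A opposite
position 1), **7mer-m8** (WC 2–8, non-A), **7mer-A1** (WC 2–7, position 8
unpaired, A), **6mer** (WC 2–7 only). Windows that are not classical but
whose positions 2–7 pair completely under a relaxed rule — unlimited G:U
wobbles plus at most one mismatch *or* one unpaired nucleotide — are
labelled **other**, the non-classical category a pattern-based predictor
reports; everything else is `none`.

The relaxed rule needs a geometry, which no site-type taxonomy pins down
fully; the package fixes it minimally and documents it as its own
convention: a mismatch is evaluated within the 8-nt window; a miRNA-side
bulge loops out one seed position against the 5-nt mRNA core (window
positions 3–7); an mRNA-side bulge is evaluated on a 9-nt window variant
with one of the seven central nucleotides looped out. Wobbles and the
single mismatch may co-occur (the rule is "plus at most one", not
"either/or"). The test suite pins the whole classifier against an
independent direct-definition oracle on all 65,536 possible 8-nt windows.

Coordinates are 0-based and half-open throughout; a site is keyed by its
window's 5′-most position, and a boundary-spanning site takes the region
of its start position (deterministic by construction). Transcript regions
partition the sequence as `[0, utr5_end)`, `[utr5_end, cds_end)`,
`[cds_end, length)`. DNA-alphabet input is transcribed to RNA at parse
time; any non-ACGU character after canonicalization is an error.

## Prediction-table dialects

`read_rna22_table()` and `read_targetscan_table()` read the two TSV
dialects (column maps are arguments, since such files have no fixed
schema; defaults ship with example files under `inst/extdata/`). The
TargetScan dialect is restricted to classical types in 3′-UTRs with
1-based coordinates converted on read; the RNA22 dialect carries all five
types and all regions, 0-based. When transcript and isomiR sequences are
supplied, every site is re-classified with `classify_site()` and rows
referring to unknown transcripts are dropped with a logged count. The
analysis uses the *union* of the tables at site level; pair-level views
(`interaction_pairs()`) label each pair with its maximum-precedence seed
type. When a pair carries several site types or regions, it participates
in every matching stratum.

## The correlation family

Within one sample group, Spearman correlations are computed for every
(isomiR, transcript) pair where the transcript is either a predicted
target or a non-target of that isomiR, and the BH adjustment is applied
to this *joint* family. Adjusting targets and non-targets together keeps
the significance threshold identical on both sides, which the contrast
`m_tar/n_tar` vs `m_nontar/n_nontar` requires; adjusting them separately
would build a different detection threshold into numerator and
denominator. Correlations are computed on `log2(x + 1)`-transformed
normalized expression. Rho is the Pearson correlation of mid-ranks
(average ranks on ties), with two-sided p-values from the large-sample t
approximation — adequate at the intended group sizes (hundreds of
samples; the package warns away groups below `min_group_size`). Constant
expression vectors have no defined rank correlation and are excluded
from numerator *and* denominator counts, with a logged tally.

## Normalization choices

Size factors are median-of-ratios (`estimateSizeFactors`-style, medians
taken in log space); there is deliberately no pseudo-reference fallback —
a matrix with no feature positive in all samples fails loudly rather than
silently switching estimator. FPM rescales size-factor-normalized counts
to per-million of the mean normalized library size; FPKM additionally
divides by length/1000 (isomiR matrices use FPM, transcript matrices
FPKM). Fractional expected counts are accepted as-is. Normalization is
computed once over all samples jointly before group splitting, mirroring
a single cohort-wide normalization; running the pipeline per group is
available by restricting `groups` in the configuration. IsomiR selection
keeps the shortest median-sorted prefix covering 99% of total median
expression (ties broken lexicographically — some rule is needed for
determinism and none is canonical); transcripts with zeros in strictly
more than half the samples are discarded ("more than half" read
strictly, so exactly half is retained).

## What the generator emulates — and what it does not

`simulation_config()` defaults are the package's reference study
conditions: 450 transcripts (150–400 nt), 20 isomiRs, 10 of them active
with 30 planted 8mer 3′-UTR targets each, two groups of 200 samples,
log-normal expression with repression slope `beta = -1`, residual sd
`sigma = 0.5`, isomiR sd `tau = 1`. With these values a true target's
log-expression shares ~80% of its variance with its isomiR (Spearman rho
near −0.85), a strong but realistic planted effect; group sizes match the
"at least 100 samples per group" regime the correlation t-approximation
assumes. Baselines for background transcripts reach low enough that zero
counts occur and the transcript filter has real work.

Mechanically: sequences are uniform-random; target transcripts get a site
constructed by inverting the classifier (so planting is idempotent by
construction); background transcripts are scrubbed of *every* admissible
6-mer of *every* isomiR by local rejection sampling (offending windows
are redrawn until none remain), which guarantees them as non-targets of
all isomiRs. Planted-pool transcripts are not scrubbed, so other isomiRs
acquire chance predicted targets there — deliberate, since it gives null
isomiRs a non-empty `n_tar` with genuinely independent expression. With
`gamma > 0`, a `gamma` fraction of transcripts (drawn from all of them,
so chance predicted targets are included — otherwise the confounder could
never inflate raw ITA) follows a latent per-sample confounder with slope
`confounder_slope`, and `n_confounded_isomirs` null isomiRs follow the
same confounder positively: those isomiRs anti-correlate with many
transcripts they do not target, raw ITA ranks them above the pure nulls,
and the background adjustment is what keeps them unflagged.

Counts are `round(exp(log-values))`. The generator is a pure function of
the configuration (seed included). It does not emulate read-level noise,
3′-isomiR sequence heterogeneity (3′ variants are synthesized only as
count splits to exercise aggregation), library-composition artefacts, or
any real tumor-subtype biology — so passing tests demonstrate that the
statistics behave as designed under monotone log-scale regulation, not
that any particular biological claim holds in real cohorts.

The internal sequence predictor used to fabricate the prediction tables
scans only windows anchored at admissible 6-mers, so it reports classical
sites and wobble-bearing "other" sites but not mismatch- or bulge-only
sites; for synthetic data this is sufficient because planted sites are
classical by construction.

## Numerical and degenerate-input conventions

* Strict inequalities at both anti-correlation thresholds.
* `fisher_one_sided(0, ...)` is exactly 1; Fisher p is monotone
  non-increasing in `m_tar` at fixed margins.
* `adjusted_ita()` refuses `n_nontar = 0` (no background estimable) and
  `n_tar = 0` records are dropped, with the stratum absent rather than
  padded.
* Jaccard of two empty sets is defined as 0 with a warning.
* An empty k-mer index yields an empty non-target set with a warning.
* Coverage selection guards the cumulative-sum comparison with a 1e-12
  relative tolerance so floating summation cannot drop the last isomiR.
* All pipeline outputs are written with fixed ordering; re-running on
  identical inputs is byte-identical.

## Problem sizes used in the checks

The test suite runs the reference conditions once for parameter recovery,
20 replicate seeds at `beta = 0` for null calibration (the flagged
fraction at `fisher_fdr < 0.05` stays at or below 0.1), and a
`gamma = 0.3` run for the confounder scenario; oracle equivalences use
20 isomiRs × 200 transcripts plus 50 smaller replicate draws (non-target
composition), all 65,536 windows × 3 isomiRs (classification), all 2×2
tables with margins ≤ 30 (Fisher), and 100 random vectors up to length
500 (BH). These sizes were chosen to exercise every code path at desk
scale while keeping the whole suite in the order of a minute.

## Known limitations

* The relaxed "other" geometry is one defensible reading of non-classical
  seed pairing; a full pattern-discovery/folding-energy engine is out of
  scope, and predictions from such tools are consumed as input tables
  instead.
* Spearman p-values rely on the t approximation; with very small groups
  (near the `min_group_size` floor of 3) exact permutation would differ.
* Active/inactive is a thresholded call; near-threshold isomiRs flip
  between neighbouring datasets, which is why the reports carry the full
  record tables and not just the calls.
* Non-target sets are defined purely by seed 6-mer absence; 3′-supplementary
  pairing or non-seed interactions could in principle make a "non-target"
  a real target, which would bias the background upward (conservative for
  activity detection).
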