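---
title: "Methods: differential RNA editing and drug resistance with editscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential RNA editing and drug resistance with editscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscape)
```

## The problem

A-to-I RNA editing — deamination of adenosine to inosine by ADAR enzymes,
with inosine read as guanosine — re-writes transcripts post-transcriptionally.
In tumors, shifts in editing at individual sites can track with whether a
patient's disease responds to a drug. `editscape` implements a complete
analysis chain for asking that question from an editing-level matrix
(sites × samples, fractions in [0, 1], missingness allowed) plus
drug-response labels:

1. derive **conditions** — one (cancer, drug) pair with labeled resistant
   and sensitive samples;
2. call **differential editing sites (DESs)** between the groups;
3. characterize editing **patterns** (over- vs under-editing) and how much
   ADAR expression explains them;
4. test **enrichment** of DESs in transcribed regions and within genes;
5. relate sites to **prognosis** (Cox regression, log-rank), scoring
   consistency with the resistance direction;
6. screen 3'-UTR DESs for **miRNA-regulation rewiring** — seed sites gained
   or lost through editing, filtered by three expression-level criteria
   into (DES, miRNA, gene) triplets.

Because the real inputs for such studies are controlled-access,
cohort-scale downloads, the package ships a first-class synthetic-data
generator that emulates their statistical structure with known ground
truth. Every stage is validated against that truth and against
independent oracles in the test suite.

## Conditions and labels

Tumor samples annotated "Progressive Disease" are treated as resistant and
"Complete Response" as sensitive; all other labels are excluded. A
condition is retained only with at least three samples in each group
(`min_per_group = 3`). For cell lines, ln(IC50) values are z-scored within
each compound; z > 0.8 is resistant, z < −0.8 sensitive, and everything
between is intermediate and unused. The inequalities are strict, and the
z-score uses the sample standard deviation (denominator n−1, the
convention of standard scaling functions); whether population or sample sd
is intended is genuinely ambiguous in the field's descriptions, so the
choice is documented here and fixed.

## DES calling

A site is **informative** for a condition when it has no missing values in
at least three resistant and three sensitive samples. For each informative
site a two-sided Wilcoxon rank-sum test compares the groups, and
`Diff = mean(resistant) − mean(sensitive)`. A DES requires `p < 0.05` and
`|Diff| ≥ 0.05` (five percentage points of editing). The direction is
*over* (higher in resistant) when Diff > 0, otherwise *under* — the signed
convention behind the absolute-value definition. Raw p-values gate the
calls, mirroring standard practice for this analysis; a Benjamini–Hochberg
column is emitted for transparency but never used for filtering.

The Wilcoxon implementation uses the exact distribution when both groups
have ≤ 25 observations and the pooled values are tie-free, and the normal
approximation with continuity and tie correction otherwise — the default
behavior of the standard statistical environment. The mode is exposed
(`exact =`) because p-values near 0.05 can flip between modes. A
consequence worth knowing: with exactly 3 + 3 observations the smallest
achievable exact two-sided p is 2/20 = 0.1, so no DES can be called from
minimal groups in exact mode; analyses that report DESs at 3 + 3 have
necessarily used the asymptotic mode or larger effective samples. Both
modes are provided; neither is asserted as the "right" one.

## OEL and ADAR regression

The overall editing level (OEL) of a sample is the mean of its non-missing
editing levels; samples with no observed values are omitted rather than
reported as zero (whether an "average over all informative sites" should
impute missing entries is unstated anywhere we know of; the non-missing
mean is the natural reading). Per-region OELs use the same rule within
each annotated region. OELs are regressed on ADAR-like expression by
ordinary least squares, reporting R² and the F-test p-value; expression is
used as provided (FPKM-like), with a `log_transform` flag rather than a
silent default.

## Patterns and the Meet/Min index

Per condition, the proportion of over-editing DESs summarizes the editing
pattern; the ADAR log2 fold change is `log2(mean resistant / mean
sensitive)`. Across ≥ 3 conditions the proportion is regressed on the fold
change to quantify how much of the pattern ADAR shifts explain. DES sets
(or gene sets, or term sets) of two conditions are compared with the
Meet/Min (Simpson) index `|A∩B| / min(|A|, |B|)` — 1 when one set contains
the other, 0 when disjoint.

## Enrichment

Region and gene enrichment both use the one-sided upper hypergeometric
tail P(X ≥ k): N informative sites, K in the unit (region or gene), n
DESs, k of them in the unit. For genes this is a *changing background*:
each gene's expectation scales with its own informative-site load, so
long, editing-dense genes are not flagged merely for being long. Only
enrichment is tested (the underlying question is over-representation);
depletion is not. When a site maps to several overlapping transcripts the
region precedence is 3'-UTR > 5'-UTR > exonic > ncRNA > intronic >
intergenic, a disjoint-category convention the generator also follows.
Integrative (cross-condition) tests pool DESs and informative sites as
*unique* sites; pooling with multiplicity is the other defensible reading,
and the choice is flagged here.

## Prognosis

Each site's editing levels are binarized at the median over all samples
with survival data (not only the condition's samples). Ties at the median
go to the under-editing group, so the over-editing group strictly exceeds
the median; the tie rule is arbitrary but deterministic and documented. A
univariate Cox model (Efron ties) of the over- vs under-editing indicator
gives the hazard ratio; the log-rank test (p < 0.05) gates which sites
count as prognosis-related. A site is *consistent* when its risk direction
matches its resistance direction — over-edited in resistant samples and
HR > 1, or under-edited and HR < 1. HR exactly 1 is indeterminate and
excluded from the consistency proportion.

## The miRNA rewiring screen

Canonical seed sites are matched exactly (no wobble pairs) in the three
TargetScan types: 8mer (reverse complement of miRNA positions 2–8
followed by A), 7mer-m8 (positions 2–8), and 7mer-A1 (positions 2–7 plus
A); where a longer site subsumes a shorter one at a locus only the
strongest type is reported. 6mer and 3'-supplementary sites are omitted:
the canonical types are the primary calls of seed-based target
prediction, and weaker classes would only add noise to a gain/loss
dichotomy. In-silico editing replaces A with G at the stated transcript
coordinates and refuses to touch any position not holding an A, which
catches strand and off-by-one bugs at the boundary where they are
cheapest.

A **gain** is a seed site present only in the edited form, a **loss** one
present only in the unedited form. The comparison is restricted to site
windows overlapping an edited position, encoding the stricter reading that
the editing site must fall inside the (potential) binding region — distal
sites elsewhere on the UTR cannot masquerade as events.

The triplet screen then applies three expression criteria per event, for a
DES over-edited in resistant samples: (1) significantly negative
miRNA–gene Pearson correlation (r < 0, two-sided p < 0.05) in the
designated group *and not* in the other — resistant for gains, sensitive
for losses ("significantly negative" is interpreted as the conjunction of
sign and two-sided significance, and "in X rather than Y" as significance
in X together with non-significance in Y); (2) gene fold-change direction
only (log2FC < 0 for gains, > 0 for losses) with no magnitude threshold;
(3) the miRNA itself not differentially expressed (rank-test p ≥ 0.05), so
the correlation is not an abundance artifact. For under-edited DESs the
edited form dominates the *sensitive* group, so the group roles in (1)–(2)
swap; this symmetric extension is behind a flag (default on) and such
triplets are labeled `extended_rule`.

Note that criterion (3) is a *retention* gate on a null hypothesis: a
truly non-DE miRNA will still be rejected about 5% of the time by chance,
so the screen's recall on perfect ground truth is expected to be slightly
below 1 in any single dataset. This is a property of the screen itself,
not of the implementation.

±20 bp windows around DESs are exported as FASTA for external motif tools
(MEME-style); windows are truncated with a warning at contig ends.

## The synthetic-data generator

The generator's role is to produce inputs whose ground truth the pipeline
must recover. What it emulates, and what it does not:

* **Editing levels** follow a per-site beta law parameterized by mean
  (default 0.25) and concentration (default 20, i.e. per-site sd ≈ 0.09).
  No published variance model exists for the editing profiles this
  emulates, so these are calibration choices: they give realistic
  intermediate editing levels with enough spread that a 15-point shift is
  detectable but not trivial at 20 + 20 samples. Planted DESs
  (`des_fraction = 0.05`, `effect_size = 0.15`) shift the beta *mean* by
  ± effect/2 per group, with baselines re-drawn at construction time until
  both group means stay inside (0.01, 0.99) — so the planted Diff is exact
  in expectation and never distorted by post-hoc clipping. Missingness is
  completely at random (default 10%), which is all the informative-site
  filter needs to be exercised.
* **ADAR coupling**: expression = a + b·OEL + noise, with the noise
  variance solved analytically from the OEL variance so the population R²
  equals the target (default 0.11, the magnitude reported for ADAR1 in
  bulk tumor cohorts). The regression stage recovers it to ±0.05 at
  n = 500.
* **Survival**: exponential event times with the planted hazard ratio
  (default 2) between editing groups and independent exponential censoring
  solved to hit the marginal censoring rate (default 30%).
* **UTR rewiring**: planted gains place a seed-match core broken by a
  single A (editing completes an 8mer); planted losses place an intact
  8mer whose core A the edit destroys. The editable base sits in the seed
  core in both constructions, because editing the flanking t1-A position
  merely toggles between site types (8mer ↔ 7mer-m8, or 7mer-A1 present in
  both forms) and is therefore not a true gain or loss under the canonical
  vocabulary. Backgrounds are re-drawn until no miRNA of the set has any
  confounding site overlapping the planted locus, so fixtures are
  collision-free by construction (bounded retries, then error).
* **Triplet expression**: correlations are induced on a latent Gaussian
  scale (exponentiated to an FPKM-like scale); miRNA group means are
  equal, truth genes shift by ~1.4 log2 units in the planted direction,
  decoys are independent everywhere.

What the generator does **not** model: sequencing-depth-dependent missing
data (missingness is MCAR, not coverage-driven), correlated sites (Alu
clusters edit together in real data), batch effects, multiple cancers'
shared biology, and count-level expression noise. Passing tests therefore
demonstrate correctness of the statistical machinery and recoverability
of planted structure, not robustness to every pathology of real cohorts.

One condition is simulated per dataset; multi-condition studies are
produced by repeated calls with distinct seeds.

## Numerical and design choices

* Missing editing values are written as empty TSV cells and read back as
  `NA` ("NA" is also accepted), matching commonly exported matrices.
* Coordinates are 1-based throughout; BED export converts to 0-based
  half-open explicitly.
* `log2` fold changes use a pseudocount of 0 by default and *error* on a
  zero denominator unless a pseudocount is given — a silent pseudocount
  can flip the sign of a fold change near zero, which matters because the
  triplet screen uses sign only.
* Constant features get p = 1 by convention in `rank_de()`; constant
  editing vectors are an error in `binarize_by_median()` (no split
  exists).
* All randomness flows from explicit seeds; `run_pipeline()` writes a
  manifest with no volatile fields, so identical configs give
  byte-identical output trees.

## Problem sizes used in validation

The test suite validates at sizes chosen to make the statistical claims
sharp while staying quick: Wilcoxon oracle equivalence on 200 random
matrices with groups ≤ 8 (full enumeration is exact there); type-I error
pooled over 20 null simulations of 2000 sites at 20 + 20; hypergeometric
exactness over the full (N ≤ 30, K, n, k) grid; survival recovery over
200 replicates at 150 + 150 with 30% censoring and a 500-replicate null
for log-rank uniformity; ADAR R² recovery over 200 replicates at n = 500.
The null calibration check for gene enrichment uses 100 genes, where the
99% binomial band around 0.05 has a lower limit of zero — appropriate,
because the discrete hypergeometric null is conservative and its
rejection rate sits below the nominal level.

## Known limitations

* The Wilcoxon mode question (exact vs asymptotic at small n) has no
  single right answer; results at minimal group sizes depend on it.
* The consistency proportion is computed over prognosis-related DESs of
  whatever cohort is supplied; it is a rule, not a reproduction of any
  published cohort-specific percentage.
* The rewiring screen treats each editing site independently;
  combinatorial multi-site edits of one UTR are not modeled.
* Expression filters use Pearson correlation on FPKM-like values as
  provided; heavy-tailed real data may warrant log-scale correlation,
  which the caller can apply upstream.
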