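---
title: "Methods: pathological response and multi-omics dynamics under neoadjuvant immunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathological response and multi-omics dynamics under neoadjuvant immunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoresponse)
```

## Scope and model

`neoresponse` implements the downstream statistics that connect paired
pre/post-treatment tumor multi-omics to pathological response in
neoadjuvant immunotherapy cohorts (the motivating setting is locally
advanced gastric cancer treated with PD-1 blockade plus chemotherapy and
anti-angiogenic therapy). Upstream tool outputs — somatic call tables,
tumor purity estimates, clonotype tables, a TPM matrix — are taken as
tabular inputs; alignment, variant calling, HLA typing, neoantigen
prediction, subclone inference and cell-type deconvolution are out of
scope. Because real cohorts of this kind are controlled-access, the
package ships a synthetic cohort generator that reproduces the
statistical structure the analysis assumes, so the full pipeline runs,
and is tested, on data generated in code.

## Pathological response

Pathologists score the percentage of residual viable tumor cells in the
resected tumor bed. The nested response categories use inclusive
("no more than") thresholds: CPR at 0%, MPR at 10%, PPR+ at 30%, PPR at
50%. The Becker tumor regression grades are TRG1a (0%), TRG1b (<10%),
TRG2 (10 to <50%), TRG3 (>=50%). The two systems disagree at exactly
10% viable tumor: such a case is MPR (inclusive) but TRG2 (TRG1b is
strictly below 10%). We follow the letter of both definitions rather
than forcing agreement, and read the TRG2 interval as [10, 50) so the
four grades partition the scale.

Cohort rates carry exact Clopper–Pearson intervals, computed from beta
quantiles: lower bound `qbeta(alpha/2, k, n-k+1)` (0 at k = 0), upper
`qbeta(1-alpha/2, k+1, n-k)` (1 at k = n). The exact interval is
conservative — coverage at least nominal — which the test suite checks
by simulation. Patients without resection are simply excluded from the
calls passed to `response_rate_table()`; the denominator is whatever
cohort the caller supplies.

```{r}
calls <- classify_response(c(0, 0, 0, 5, 8, 15, 20, 25, 40, rep(60, 10)))
response_rate_table(calls)
```

## Purity-corrected mutation dynamics

Observed VAF confounds clone dynamics with tumor purity, which drops
substantially after effective therapy. We adjust as
`adj = min(1, vaf / purity)` — the simplest monotone correction; a
cancer-cell-fraction variant `min(1, 2 vaf / purity)` (copy-neutral
heterozygous diploid) is available as `mode = "ccf"`. Fate
classification only uses the *sign* of the pre-to-post change, which is
invariant to the constant factor, so the choice does not affect fate
classes.

Mutations are keyed by `chrom:pos:ref:alt` (1-based), never by gene, so
several mutations per gene stay distinct. Calls are filtered with the
standard stack (VAF >= 0.02 inclusive, depth and alt-read minima)
before classification by default. Each mutation in the union of a
patient's pre and post call sets receives one of five fates: `lost`
(pre only), `gain` (post only), and `increase` / `decrease` / `stable`
for shared mutations by the sign of the adjusted-VAF change; `stable`
absorbs changes within `tie_tol` (default 0 — exact ties have measure
zero in real data, but integer counts in simulation can tie, so the
tolerance is exposed). The five classes partition the union by
construction, and the test suite cross-checks every classification
against a per-mutation brute-force oracle.

The lost-mutation fraction is `lost / (lost + shared)` — the
denominator is the pre-treatment mutation count, so emergent mutations
cannot deflate it. Its Spearman correlation with percent pathological
regression is the pipeline's tumor-genomic response readout.

TMB is nonsynonymous mutations per megabase, TNB neoantigen-flagged
mutations per megabase; the default 35 Mb footprint is a conventional
whole-exome capture size and is configurable wherever it is used.

### Purity-balancing dilution

When one sample of a pair has much higher purity (the ratio rule of
thumb is 1.5-fold), its burden is inflated. `purity_balance_dilution()`
abstracts read-level blending of the high-purity sample with its
matched normal: with mixing fraction `m = 1 - target/purity`, each alt
count is redrawn `Binomial(depth, vaf (1 - m))` with depth preserved,
filters are re-applied, and burden recomputed — so mutations diluted
below the detection thresholds drop out as they would in re-called
data. `m = 0` is an exact identity by construction. Expected filtered
TMB is non-increasing in `m`; the suite verifies this over 200 seeds,
along with the large-depth limit `vaf' -> vaf (1 - m)`.

### Subclone consistency

Given externally inferred subclone clusters with cellular prevalences,
a mutation is *consistent* with its cluster when the sign of its
adjusted-VAF change matches the sign of the cluster's prevalence
change; host genes of consistent mutations are the tumor's clonal
genes. Absence at a timepoint is coded as VAF 0, so a lost mutation
agrees with an eradicated cluster — a documented sign convention rather
than a claim about the unobservable truth.

## TCR repertoire

Clonotypes are keyed by (CDR3 amino-acid sequence, V segment,
J segment). Tables are renormalized on load (`count / total`), zero
counts dropped, and ordered by descending frequency with a
lexicographic tie-break so output is deterministic.

The clone-expansion (CE) score is the summed pre-to-post frequency
change of the top-20 clones. Two readings of "top 20" exist; the
default `"pooled"` mode fixes one clone set (the 20 largest by mean of
pre and post frequency) and sums `f_post - f_pre` over it, which makes
the score antisymmetric under swapping timepoints and bounded in
[-1, 1]; `"per-sample"` mode (post's own top-20 mass minus pre's own)
is provided for sensitivity analysis. A positive CE indicates
expansion of dominant clones after therapy and tracks response.

Size classes follow the four canonical frequency bins — small
(<= 1e-4), medium (1e-4, 1e-3], large (1e-3, 1e-2], hyperexpanded
(> 1e-2]. The upper bound of "large" is taken as 0.01 so the four
classes partition the unit interval. Diversity metrics are richness,
Shannon entropy in nats, Pielou evenness `H / ln(richness)` (defined 0
for a single clone), and D50 (top clonotypes needed to reach half the
repertoire, reported both as a count and as percent of richness — both
conventions exist in the literature). V/J usage sums clonotype
frequency per segment; overlap counts shared keys between samples.

## Expression signatures

Signature scores are unweighted means of `log2(TPM + 1)` over set genes
present in the matrix — a transparent stand-in for weighted published
scores, with a `weights` hook for users who have them. The default
sets (cytolytic, IFN-gamma, T-cell exhaustion, CD8 effector) are small
curated conveniences, clearly not an extracted published panel; real
analyses should supply their own YAML. Group contrasts use the
two-sided Wilcoxon rank-sum (independent groups) or signed-rank
(paired) test. No multiplicity adjustment is applied anywhere in the
package — the motivating analyses report raw two-sided p values at the
0.05 level — and every contrast output carries an `adjusted = FALSE`
flag so downstream users cannot miss it.

## The synthetic cohort generator

The generator's defaults are the study conditions the package is
tested under, chosen once:

* **Cohort**: 19 evaluable patients, responder fraction 8/19 (the
  PPR+ rate of the motivating cohort). Responder status is the truth
  label; "responder" emulates PPR+.
* **Regression**: Beta(8, 2) for responders (mean 80% regression),
  Beta(2, 6) for non-responders (mean 25%), on the 0–100% scale;
  viable% = 100 − regression%.
* **Tumor genomics**: 4 subclones, 80 mutations per tumor, mean depth
  200x (Poisson per site), purity Uniform(0.3, 0.8) pre and
  Uniform(0.15, 0.6) post, exome 35 Mb. True VAF is
  `prevalence x purity / 2` (copy-neutral heterozygous diploid — the
  simplest model consistent with a purity ratio correction); alt
  counts are Binomial(depth, true VAF) and zero-alt sites are absent
  from the table. Subclone eradication is Bernoulli per subclone
  (0.6 responders, 0.15 non-responders); emergent subclones arise with
  probability 0.05 / 0.3, mirroring the qualitative observation that
  new dominant subclones rise mainly in poor responders. Only outcomes,
  not a generative law, are observable in real cohorts, so these
  probabilities are calibrated qualitatively.
* **TCR**: 2000 clonotypes per repertoire with Zipf(1) frequencies;
  responders' top-20 counts are doubled post-treatment
  (`expansion_factor_responder = 2`); everyone's post repertoire
  additionally turns over 5% of its read mass to novel clonotypes,
  spread flat over many small clones so turnover dilutes existing
  clones without creating spurious dominant ones; both samples are
  resampled Multinomial(1e5 reads). Turnover plus resampling are what
  make non-responder CE scores systematically slightly negative (top
  clones are diluted), as observed in real repertoires; in the
  standalone `generate_repertoire_pair()` both layers default off so
  `expansion_factor = 1` yields exactly identical pre/post tables.
  CDR3s are random 13-mers on a CASS...F scaffold with ~10% drawn from
  a fixed public-clone catalogue, so patients share a little but not
  much of their repertoires.
* **Expression**: 200 genes, log2-normal baseline (signature genes at
  high baseline, log2 mean 5–8, sd 0.5), +1 log2 shift of signature
  genes in responder post-treatment samples.

Per-patient RNG substreams are derived by stable (FNV-1a) hashing of
the patient id added to the cohort seed, so any subset of patients is
reproducible independent of cohort order, and identical config + seed
give byte-identical written tables.

What the generator does **not** emulate: copy-number variation and
ploidy (so the diploid VAF model is exact in simulation, approximate in
life), sequencing artifacts and caller disagreement (calls are clean
binomial draws), clonal structure in the TCR compartment beyond a
single power law, batch effects and library-size variation in
expression, and any coupling between the three omics layers beyond the
shared responder label. Passing tests therefore demonstrate the
correctness and statistical behavior of the downstream computations
under the stated model, not robustness to real-world artifacts.

## Numerical and testing choices

Problem sizes in the test suite were chosen to give stable Monte-Carlo
verdicts at interactive runtimes: 100 generator seeds for the CE-sign
and lost-fraction-recovery properties (the latter at 100 patients per
cohort), 1000 random table pairs against the fate brute-force oracle,
200 seeds for the dilution monotonicity curve, and full enumeration
oracles (hypergeometric tables to n = 20, signed-rank sign assignments
to n = 10 pairs, Spearman rank permutations to n = 8) for the exact
tests, which the package otherwise delegates to `stats::fisher.test`,
`stats::wilcox.test` and `stats::cor.test`.

One printed-value subtlety: the exact Clopper–Pearson lower bound for
8/19 is 0.20252, i.e. 20.3% at one decimal; reports that show 20.0%
for this quantity have rounded the proportion to two decimals before
formatting as a percentage. The package always computes and stores the
full-precision exact value and rounds only in printing.

## Limitations

* Purity correction assumes copy-neutral heterozygous mutations; amplified
  or LOH loci violate the factor-of-two relation between VAF and CCF.
* The CE score depends on the top-k convention; both implemented modes are
  reported honestly, but scores from different conventions are not
  comparable across studies.
* Signature scoring is an unweighted mean; it is not the published
  weighted GEP and should not be labelled as such.
* No multiple-testing correction is applied by design; biomarker screens
  over many genes need their own error control.
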