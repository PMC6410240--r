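---
title: "Methods and design of the mtnadel pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mtnadel pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each stage of the
package, the parameters that matter and their defaults, the synthetic-data
generator's scope, and the numerical and design decisions taken where a
published description leaves the choice open.

## 1. Read-based allele calling

**Model.** The *MtnA* 3' UTR indel is genotyped from short reads against a
dual reference: the deletion allele (90 bp: a 49-bp upstream and a 41-bp
downstream flank joined at the deletion site) and the non-deletion allele
(the same flanks with the 49 inserted bases between them). Because the
references are two short known sequences, general-purpose read mapping is
unnecessary: `align_read()` scores *every* ungapped placement of a read
and of its reverse complement against each reference — including
overhanging placements — as `matches − mismatches` over the overlapping
span, and keeps the maximum. The scan is exact, so the allele call depends
only on the classification rules, not on mapper heuristics.

**Classification rules.** A read is *informative* for the higher-scoring
allele when (i) its aligned span covers at least `min_overlap` bases on
each side of the junction (deletion allele) or of the inserted interval
(non-deletion allele); (ii) its mismatch rate over the span is at most
`max_mismatch_rate`; and (iii) the two allele scores differ — a read lying
wholly within the shared flanks scores identically on both references and
carries no information. A line is called for an allele when the allele's
share of informative reads reaches `majority_threshold`; below that it is
`ambiguous`, with zero informative reads `no_data`.

**Parameters.**

| parameter | default | units | rationale |
|---|---|---|---|
| `min_overlap` | 15 bp (reads ≥ 100 bp), 8 bp otherwise | bases per junction side | the two settings used for the haploid-embryo (150-bp) and mixed-length (45–126-bp) cohorts |
| `majority_threshold` | 0.95 | fraction | the 95% rule that excludes lines with > 5% minor-allele reads (residual polymorphism in pooled inbred lines) |
| `max_mismatch_rate` | 0.10 | mismatches / aligned base | not specified in the published procedure; chosen to accept reads at ~1% sequencing error with margin while rejecting spurious cross-allele placements, which require ≥ 35% mismatches |
| `mismatch_penalty` | 1 | score units | symmetric match/mismatch weighting; any positive penalty gives the same classification on junction reads, so the simplest is used |

**Determinism.** Ties are broken by fixed rules: forward strand before
reverse, smaller offset first, and equal allele scores are always
uninformative rather than randomly assigned. Repeated runs are therefore
byte-identical.

**Degenerate inputs.** Empty reads are rejected; unreadable FASTQ files
are recorded per line (`call = "error"`) without stopping the cohort.
Paired-end mates are classified independently — there is no pair-aware
rescue, matching the per-read definition of the overlap rule.

## 2. Population-genetic statistics

Allele frequency from genotype counts is
$\hat p = (2 n_{DD} + n_{DN}) / 2n$, with the confidence interval computed
on the chromosome scale (x deletion chromosomes of 2n). Haploid data (one
allele per line) enter directly as x of n chromosomes.

*CI method.* The default is Clopper–Pearson (exact beta-quantile bounds):
it reproduces the published 95% CI of the Zambian haploid estimate
(5/192 → 0.009–0.060 at three decimals). The Wilson score interval is
available as a switch because the CI quoted from the earlier isofemale
survey (1/20 → 0.01–0.24) matches Wilson rather than Clopper–Pearson.

*Hardy–Weinberg.* Two tests are always reported. The chi-squared test
compares observed counts with $(n\hat p^2, 2n\hat p\hat q, n\hat q^2)$ on
1 degree of freedom (three categories minus one minus one estimated
parameter); Yates continuity correction is off by default and available
as a flag. The exact test uses the Levene–Haldane distribution of the
heterozygote count conditional on n and the minor-allele count, summing
the probabilities of all outcomes no more likely than the observed one
(relative tie tolerance 1e-7). The printed HWE p-values in the original
genotype table are not reproducible from its printed counts under a plain
chi-squared computation (e.g. the June 2016 row gives chi² ≈ 1.06,
p ≈ 0.30), which is why both tests are exposed and neither is asserted
against those printed values. Monomorphic samples are rejected as
undefined rather than reported as p = 1.

*Between-sample comparisons.* `fisher_2x2()` is the standard two-sided
conditional exact test (sum of hypergeometric point probabilities ≤ the
observed one); the odds ratio reported is the unconditioned sample OR,
not the conditional MLE. No multiple-testing correction is applied
anywhere, matching the original analysis.

## 3. ΔΔCt expression analysis

Technical replicates are averaged per biological replicate and gene
(arithmetic mean of Ct). Per replicate,
$\Delta Ct = Ct_{MtnA} - Ct_{RpL32}$; the calibrator is the non-deletion
group *within the same genetic background*, which is what makes the
per-background fold changes comparable. Amplification efficiency is fixed
at 2 (classic ΔΔCt); efficiency-corrected variants are out of scope. The
group-level fold change is $2^{\overline{\Delta Ct}_{non} -
\overline{\Delta Ct}_{del}}$.

The two-factor ANOVA (background × genotype) runs on the per-replicate
fold change by default, matching how relative expression is usually
displayed; a log2 option is provided because the scale actually analysed
in the original work is not stated. Sums of squares are Type II via
`car::Anova` — the published design is mildly unbalanced (25–28
biological replicates per cell) and Type II reduces to the classical
decomposition when balanced, which the tests assert numerically. η² is
the term's share of the total sum of squares. An empty cell drops the
interaction term with a warning. One-way variance explained
(`variance_explained`) is SS_between/SS_total, equal to the squared
point-biserial correlation.

## 4. Association with expression and survival

Expression is log2 signal intensity; fold changes are
$2^{\bar e_{del} - \bar e_{non}}$. The t test is pooled-variance
(Student) by default with a Welch flag, applied per sex. Spearman's
correlation uses mid-ranks with the t approximation on n − 2 df.

Survival associations use `survival::coxph` — the implementation cited by
the original analysis — behind the `cox_ph()` surface, with Efron tie
handling by default and Breslow as an option. A note on "line as a
factor": in an inbred-line panel the indel genotype is constant within
line, so genotype and a full set of line indicators are collinear; with
`line_effect = "factor"` the fitter's singularity handling silently drops
aliased line terms and the genotype coefficient absorbs a reparametrised
contrast. The default is therefore `line_effect = "none"` (sex +
genotype), with `"strata"` offered for within-line baseline
heterogeneity; this is a documented deviation from the published model
formula, made because the published formula is not identifiable as
written for line-constant covariates. `agent_contrast()` tabulates the
per-agent Spearman and Cox results without computing any new statistic.

## 5. Neighbor joining and admixture

Distances are p-distances over columns where both sequences carry an
unambiguous nucleotide (pairwise deletion — "indels excluded"); complete
deletion and a Jukes–Cantor correction are available because tree-builder
defaults differ and the distance model behind the original figure is not
stated. The Jukes–Cantor transform rejects p ≥ 0.75.

`neighbor_joining()` is the Saitou–Nei agglomeration with the
Studier–Keppler criterion
$Q(i,j) = (m-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$,
lexicographically smallest pair on ties, and the standard split branch
lengths $v_i = d(i,j)/2 + (r_i - r_j)/(2(m-2))$. Negative branch lengths
are clamped to zero with the deficit transferred to the sister branch (a
convention choice; the path-length sum across the joined pair is
preserved). On additive matrices the generating topology and metric are
recovered exactly, which the tests verify on 100 random 8-taxon trees.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and counts internal bipartitions,
keyed by orientation-free leaf sets so that support mapping is
independent of any later rooting. Supports are percentages of
`n_reps = 1000` replicates and attached to internal nodes; the root of
the unrooted representation carries no bipartition and gets none.
Replicates are driven by a single seed and are reproducible.

`is_admixed(tree, focal, source)` asks whether some internal edge places
the focal haplotypes (e.g. deletion-bearing African lines) together with
members of the source population and nothing else — no other member of
the focal population, no outgroup. Among qualifying edges the
best-supported one is reported. Two boundary decisions: the side must
contain at least one source taxon (a clade of the focal taxa alone is
population substructure, not admixture), and the focal set should be a
proper subset of its population — for the full population the question
degenerates into the plain population split. Keeping the outgroups in the
tree anchors the orientation of bipartitions, as rooting does in the
original figure; `root_with_outgroup()` roots on the outgroup edge and
falls back, with a warning, to the edge best separating outgroup from
ingroup when the outgroup is not monophyletic.

## 6. The synthetic-data generator

Every analysis input can be generated from a single seeded `sim_config()`;
identical configurations give byte-identical output.

* **Reads** are drawn from the chosen allele embedded mid-way in a 2-kb
  random context (the locus is the only thing that matters for a
  junction classifier; a genome-scale context would only add runtime).
  The number of reads is set so that the *expected* number overlapping
  the junction equals `coverage`. Errors are substitution-only at
  `error_rate` per base, qualities constant — the published procedure
  uses neither quality scores nor indel-error handling, and a
  substitution-only model keeps the aligner's ungapped contract exact.
  `mixed` templates draw each read's allele independently (residual
  polymorphism in pooled lines). The context stream is decoupled from
  the read stream so that a reference pair and a read set built from the
  same integer seed cannot leak the reference sequence into the context.
* **Genotype counts** are multinomial with probabilities
  $(p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq)$ — Hardy–Weinberg deformed by
  Wright's F; infeasible (negative) probabilities are rejected.
* **qPCR** follows an additive cycle model: per biological replicate,
  reference Ct ~ Normal(18, 0.3) and target Ct ~ Normal(22 − effect,
  0.3), technical replicates adding Normal(0, 0.1) per gene. The
  genotype effect is in cycles (= log2 fold), with per-background
  defaults log2 1.20 (M9) and log2 1.85 (M12) — the two published point
  estimates — and 26 biological × 2 technical replicates (mid-range of
  the published 25–28).
* **Survival panels** use an exponential baseline (mean 60 h) with
  multiplicative hazard ratios; the baseline form is irrelevant for Cox
  recovery, which is baseline-free. Defaults: deletion hazard ratio 0.6
  on MSB and 1.0 on paraquat, male hazard ratio 0.7, administrative
  censoring at 500 h, one observation per line × sex × agent, and log2
  expression with a log2 1.4 deletion effect and log2 1.67 male shift —
  directions and magnitudes of the published associations. Censoring and
  replicate structure are parameters because the original description
  does not state how vials entered the model.
* **Alignments** use a star-like substitution process: population
  founders derive from a random ancestor at per-site rate divergence/2
  each, haplotypes from their founder at diversity/2, migrants are
  haplotypes of the B founder labelled population A, outgroups sit at
  `outgroup_divergence` from the ancestor. Defaults (15 kb, 20 + 20
  taxa, 5% divergence, 0.5% diversity, 5 migrants, 2 outgroups at 15%)
  mirror the published tree's design. Expected pairwise p-distances have
  a closed form (products of per-branch substitution matrices) that the
  tests check against.

**What the generator does not emulate:** realistic error profiles, PCR
duplicates and coverage biases; coalescent genealogies with recombination
(the alignment process is star-like within populations, so it slightly
understates within-population structure); linkage between the indel and
nearby SNPs; array-normalization artefacts in expression values. Passing
tests therefore demonstrate correctness of the *computations* under the
stated statistical structure, not robustness to every pathology of real
sequencing or phenotyping data.

## 7. Problem sizes used in the tests

The suite exercises the pipeline at sizes chosen to make the stochastic
checks sharp while keeping the default run comfortably fast: classifier
accuracy over 20 seeds × 50 haploid lines at coverage 10 and 1% error;
exact-test equivalence by exhaustive enumeration for all genotype tables
up to n = 50; NJ consistency on 100 random additive 8-taxon matrices;
Clopper–Pearson coverage by full binomial enumeration at n = 388,
p = 0.9; Cox recovery over 50 seeds of 150-line panels; and the full
15-kb, 42-taxon, 1000-replicate bootstrap for the admixture verdict.

## 8. Known limitations

* The aligner is ungapped by design; reads containing true indel
  sequencing errors near the junction would lose score rather than be
  realigned. At the published read lengths and error rates this costs
  sensitivity, not specificity.
* Cohort-scale numbers from the original sequenced panels (e.g. how many
  of 210 lines classify) depend on the raw SRA data and on mapper
  soft-clipping behaviour; they are not reproducible offline and are not
  asserted.
* `hwe_exact` enumerates the heterozygote distribution in log-factorial
  space; for extremely large samples (n in the millions) a saddlepoint or
  normal approximation would be preferable.
* The NJ implementation is quadratic per join (cubic overall) in plain R
  with the distance bootstrap vectorised as matrix products; it is sized
  for tens of taxa × thousands of replicates, not thousands of taxa.
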