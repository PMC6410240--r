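# mtnadel

Analysis toolkit for the 49-bp insertion/deletion polymorphism in the 3'
untranslated region (UTR) of the *Drosophila melanogaster* *Metallothionein
A* (*MtnA*) gene. The deletion allele is at high frequency in temperate
populations, rare in sub-Saharan Africa, and associated with higher *MtnA*
expression and greater tolerance to oxidative stress. The package is for
population geneticists who want to re-run — or stress-test on synthetic
data — every computational stage of that analysis:

1. **Read-based allele calling** (`make_references`, `classify_reads`,
   `call_line`, `genotype_cohort`). Reads are aligned by an exhaustive
   ungapped scan against a dual reference: a 90-bp deletion allele (49 bp
   upstream + 41 bp downstream of the deletion site) and a 139-bp
   non-deletion allele. A read is *informative* only if its aligned span
   extends at least `min_overlap` bases (15 bp for long reads, 8 bp for
   short ones) on **each** side of the junction or of the inserted
   interval. A line is called for an allele when at least 95% of its
   informative reads support it; otherwise it is `ambiguous` (or `no_data`).
2. **Population genetics** (`allele_frequency`, `hwe_chisq`, `hwe_exact`,
   `fisher_2x2`, `seasonal_report`). Allele frequency
   p&#770; = (2·n_DelDel + n_DelNon)/2n with Clopper–Pearson (exact) or
   Wilson intervals; Hardy–Weinberg chi-squared (df = 1) and Levene–Haldane
   exact tests; pairwise Fisher exact tests between collections and sexes.
3. **qPCR relative expression** (`collapse_technical`,
   `relative_expression`, `ddct_fold`, `two_factor_anova`). Classic
   ΔΔCt: ΔCt = Ct_target − Ct_reference per biological replicate,
   fold = 2^(mean ΔCt_non − mean ΔCt_del) per genetic background, plus a
   background × genotype ANOVA (Type II SS) and η² variance decomposition.
4. **Genotype–phenotype association** (`expression_ttest`, `spearman_cor`,
   `cox_ph`, `agent_contrast`). t tests and fold changes on log2
   expression, Spearman correlation of expression with survival, and Cox
   proportional-hazards models (Efron ties) of survival in hours on
   oxidative-stress agents (MSB, paraquat).
5. **Admixture detection** (`p_distance`, `neighbor_joining`,
   `bootstrap_support`, `root_with_outgroup`, `is_admixed`). p-distance
   with pairwise deletion of indels, Saitou–Nei neighbor joining
   (Studier–Keppler criterion Q(i,j) = (n−2)d(i,j) − Σ_k d(i,k) − Σ_k
   d(j,k)), 1000-replicate column bootstrap, outgroup rooting, and a
   bipartition test for whether focal haplotypes cluster inside a source
   population.
6. **Synthetic data** (`sim_config`, `simulate_line_reads`,
   `simulate_population`, `simulate_qpcr`, `simulate_stress_panel`,
   `simulate_admixed_alignment`). Deterministic generators for every input
   above, so the whole pipeline runs and is testable offline.

The Munich seasonal survey's genotype-count tables ship as plain-text
fixtures (`munich_counts_path()`), so the population-genetic report is
reproducible without any download.

## Worked example

```r
library(mtnadel)

## population genetics on the packaged survey counts
rep <- seasonal_report(read_tsv(munich_counts_path("genotype")))
rep$frequencies
#>     stratum   n n_deldel n_delnon n_nonnon n_chromosomes p_hat ci_low ci_high
#> 1 June 2016 194      160       31        3           388 0.905  0.871   0.932
#> 2 Sept 2016 143      120       22        1           286 0.916  0.878   0.945
#> 3 June 2017 159      131       25        3           318 0.903  0.864   0.933
#> 4 Sept 2017 118       99       18        1           236 0.915  0.872   0.947
#> 5       All 614      510       96        8          1228 0.909  0.891   0.924
```

The pooled deletion frequency is 0.91 (95% CI 0.89–0.92) and is stable
across collections; no stratum departs from Hardy–Weinberg equilibrium
(`rep$hwe`, all p > 0.15), and all pairwise collection comparisons are
non-significant (`rep$pairwise_strata`).

```r
## genotype three simulated fly lines from reads
refs <- make_references(seed = 1)   # 90-bp and 139-bp allele references
lines <- list(
  zi_01 = simulate_line_reads("deletion",     refs, sim_config(seed = 101, coverage = 20)),
  zi_02 = simulate_line_reads("non_deletion", refs, sim_config(seed = 102, coverage = 20)),
  zi_03 = simulate_line_reads("mixed",        refs, sim_config(seed = 103, coverage = 40),
                              mixed_fraction = 0.25))
genotype_cohort(lines, refs, min_overlap = 15)$calls
#>   line_id n_del_reads n_non_reads major_fraction         call
#> 1   zi_01          19           0          1.000     deletion
#> 2   zi_02           0           2          1.000 non_deletion
#> 3   zi_03           9          18          0.667    ambiguous
```

Haploid-style lines are called cleanly; the line with residual polymorphism
(25% minor allele) fails the 95% majority rule and is excluded, exactly the
behaviour used to drop ambiguous pooled lines.

```r
## ddCt fold changes on synthetic qPCR data (true folds 1.85 / 1.20)
ddct_fold(collapse_technical(simulate_qpcr(sim_config(seed = 1))))
#>   background fold n_del n_non
#> 1        M12 1.64    26    26
#> 2         M9 1.19    26    26
```

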