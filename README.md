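# pneumotyper

Quantifying how upper-respiratory microbial input shapes the lung
microbiota, and calling **pneumotypes** — lung community classes defined by
the intensity of oral input.

## The problem

Lung (bronchoalveolar lavage, BAL) communities are continuously seeded from
the upper respiratory tract: saliva, the oropharynx, and the nasal cavity.
For clinicians and microbial ecologists working with paired multi-site 16S
or shotgun count tables, two questions recur:

1. How much of lung community structure is explained by **neutral
   immigration** from the source sites, and which taxa deviate?
2. Do subjects split into a **high-oral-input type (HOIT)** and a
   **low-oral-input type (LOIT)**, and how do the types differ in assembly
   stochasticity, niche structure, and co-occurrence networks?

`pneumotyper` implements the full analysis chain:

- **Sloan neutral model** — occurrence frequency predicted as
  `F̂ = 1 − BetaCDF(d; N_T·m·p, N_T·m·(1−p))`, migration rate `m` fitted by
  bounded least squares, `R²`, 95% Wilson score neutrality bands, and a
  multiple-source extension with per-site taxon attribution
  (`fit_neutral()`, `fit_multi_source()`).
- **Gibbs-sampling source tracking** — posterior mixing proportions of each
  BAL sample over named sources plus an unknown component; the saliva
  share is the **ST value** (`apportion()`, `cohort_st()`).
- **Pneumotype calling** — kernel-density trough cutoff on the bimodal ST
  distribution, cross-checked by Dirichlet multinomial mixture community
  typing with Laplace-evidence model selection, and Fisher-exact
  concordance (`density_trough()`, `fit_dmm()`, `call_pneumotypes()`).
- **Community ecology** — Shannon diversity, Bray-Curtis, PCoA, PERMANOVA,
  Levins niche breadth, and a normalized stochasticity ratio (NST) with a
  richness- and occupancy-preserving null model (`nst()`).
- **Interaction networks** — SparCC compositional correlations, permutation
  significance, `|ρ| ≥ 0.4 & p < 0.05` edge retention, targeted-attack
  robustness curves with AUC, neighbor-shift (NESH) driver scores, and
  saliva-lung cross-site networks (`sparcc()`, `attack_robustness()`,
  `neighbor_shift()`, `cross_site_network()`).
- **A synthetic multi-site cohort generator** with known ground truth
  (source profiles, per-subject mixing weights, group migration rates,
  latent HOIT/LOIT labels), so every stage is testable without sequencing
  data (`simulate_cohort()`).

See `vignettes/pneumotyper-methods.Rmd` for the models, parameter
conventions, and limitations.

## Worked example

```r
library(pneumotyper)

co   <- simulate_cohort(n_subjects = 60, n_taxa = 150, seed = 1)
meta <- co$counts$metadata
bal  <- subset_count_table(co$counts, samples = meta$sample_id[meta$site == "BAL"])
src  <- subset_count_table(co$counts, samples = meta$sample_id[meta$site != "BAL"])

# multiple-source neutral fit with per-site attribution
sites <- c("saliva", "oropharynx", "nasal")
fit <- fit_multi_source(setNames(lapply(sites, function(s)
  subset_count_table(src, samples = meta$sample_id[meta$site == s])), sites), bal)
fit
#> <neutral_fit> m = 0.02018, R2 = 0.7826, N_T = 10000, 150 taxa, 60 sinks
#>   partition: above=54, below=38, neutral=58
#>             group
#> site         lower-quartile interquartile upper-quartile
#>   nasal                  23            18              4
#>   oropharynx              3            11              8
#>   saliva                 13            38             32

# per-subject saliva contribution (ST) and pneumotype calling
st  <- cohort_st(bal, src, seed = 1)
dmm <- fit_dmm(bal, k_range = 2, seed = 1)
call_pneumotypes(st, dmm = dmm)
#> <pneumotype_result> cutoff = 0.317; 44 HOIT / 16 LOIT
#>   DMM concordance: 96.7% agreement, Fisher p = 1.02e-12

# assembly stochasticity per pneumotype
grp <- setNames(co$truth$subjects$group, co$truth$subjects$subject_id)
nst_res <- nst(bal, grp[bal$metadata$subject_id], R = 100, seed = 1)
sprintf("NST  HI: %.3f   LO: %.3f", nst_res$HI$NST, nst_res$LO$NST)
#> "NST  HI: 0.890   LO: 0.715"
```

Reading the output: the pooled-source neutral fit explains most occurrence
variation (`R² = 0.78`) at a migration rate of `m ≈ 0.02`; saliva-attributed
taxa dominate the upper occurrence quartile of the lungs while
nasal-attributed taxa concentrate in the lower quartile. The ST
distribution's density trough at 0.317 splits 44 HOIT from 16 LOIT
subjects, agreeing with the independent DMM typing for 58 of 60 subjects;
the high-input group assembles more stochastically (NST 0.89 vs 0.71),
consistent with freer immigration.

A thin command-line front end covering the same steps ships in
`inst/cli/pneumotyper.R`
(`Rscript inst/cli/pneumotyper.R simulate --seed 1 --out run1`, then
`neutral-fit-multi`, `sourcetrack`, `pneumotype`, `dmm`, `ecology`,
`network`, `robustness`, `netshift`).

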