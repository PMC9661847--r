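---
title: "Methods: source-driven assembly analysis and pneumotyping of the lung microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-driven assembly analysis and pneumotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumotyper)
```

## The scientific question

The lower airways are not sterile: lung (bronchoalveolar lavage, BAL)
communities are continuously seeded by microbial immigration from the upper
respiratory tract — saliva, the oropharynx, and the nasal cavity. Two
questions drive this package:

1. **How much of lung community structure is explained by neutral
   immigration from those source sites**, and which taxa deviate from the
   neutral expectation (candidates for selection by the host environment)?
2. **Do subjects fall into discrete "pneumotypes"** — a high-oral-input
   type (HOIT) whose lung community is dominated by salivary immigration,
   and a low-oral-input type (LOIT) where that input is restricted — and
   how do the two types differ in assembly stochasticity, niche structure,
   and co-occurrence network architecture?

Everything downstream operates on one exchange object, the `count_table`:
a samples x taxa matrix of integer read counts plus per-sample metadata
(subject, body site, optional group). Relative abundances are always
derived on demand and never stored, which removes a whole class of
double-normalization bugs.

## The neutral community model

For a source community where taxon $i$ has mean relative abundance $p_i$,
the Sloan neutral model predicts the probability of observing the taxon in
a local (lung) community of $N_T$ individuals exchanging migrants at rate
$m$:

$$\hat F_i \;=\; 1 - \mathrm{BetaCDF}\!\left(d;\; N_T m\, p_i,\; N_T m\,(1-p_i)\right),$$

the tail mass of the stationary beta abundance distribution above the
detection limit $d$. `fit_neutral()` estimates $m$ by bounded nonlinear
least squares on observed versus predicted occurrence frequencies (five
log-spaced starts over $m \in [10^{-6}, 10]$; the SSE surface is unimodal
in practice but flat for tiny $m$), reports $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$,
and wraps each prediction in a 95% Wilson score band (with $n$ = number of
sink samples) to partition taxa into `neutral`, `above` (over-represented
relative to immigration) and `below`.

**Detection-limit convention.** $N_T$ is taken as the mean sink read
depth. Occurrence is scored as a *nonzero read count*, and the detection
event "at least one read among $N_T$" has probability one half at
abundance $x = \log 2 / N_T$ (from $(1-x)^{N_T} = \tfrac12$), not at
$1/N_T$. Evaluating the beta CDF at this median detection threshold
(`detection = "median"`, the default) is a continuity correction we
derived from a closed-form refit oracle: with the classic $d = 1/N_T$ the
fitted $m$ is inflated by a structural +13% to +27% over
$m \in [0.01, 0.1]$, while the median threshold is unbiased to ~2%. The
classic convention remains available as `detection = "classic"` for
comparability with other implementations; `predict_occurrence()` itself
takes $d$ explicitly.

**Multiple sources.** `fit_multi_source()` pools the source sites into one
regional community — the mean relative abundance over the *concatenated*
source samples, so sites are implicitly weighted by their sample counts —
refits the neutral model against the pool, attributes each sink taxon to
the site where its mean relative abundance is maximal (ties broken by
higher prevalence, then lexicographic site name, so results are
deterministic), and cross-tabulates attributed taxa by site and by lung
occurrence-frequency quartile. Quartiles are inclusive; boundary taxa go
to the more extreme group.

## Gibbs-sampling source apportionment

`apportion()` estimates, per sink, the posterior mixing proportions over
the named sources plus an *unknown* source by collapsed Gibbs sampling
over per-read source assignments. The conditional for read $r$ of taxon
$t$ is

$$P(z_r = s) \;\propto\; \frac{m_{s,t} + \alpha}{\sum_t m_{s,t} + \alpha T}
 \cdot \left(n_s^{-r} + \beta\right),$$

where named sources contribute their fixed count profiles (pseudocount
$\alpha_1 = 0.001$), the unknown source's taxon counts are the sink reads
currently assigned to it (pseudocount $\alpha_2 = 0.1$), and $\beta = 10$
is a symmetric Dirichlet prior on the mixing proportions. Defaults (100
burn-in sweeps, 10 restarts, 1 retained draw per restart, rarefaction to
1000 reads without replacement) mirror the reference implementation's
documented defaults; all are configurable and logged. The sweep kernel is
compiled (Rcpp) because per-read sampling across sweeps, restarts and a
cohort of sinks is the pipeline's hot loop. Correctness is checked against
exhaustive enumeration of all assignment vectors on a small toy — the
sampler's posterior means agree with the exact posterior within
Monte-Carlo error.

`cohort_st()` collects, per subject, the posterior saliva contribution —
the **ST value**. Sources are subject-paired when pairs exist (falling
back to cohort-pooled site profiles for missing pairs) and cohort-pooled
otherwise; the mode is recorded in the run summary.

## Pneumotype calling

Across a cohort, ST values follow a bimodal distribution. `density_trough()`
fits a Gaussian KDE (Silverman's bandwidth, 512-point grid on $[0,1]$),
keeps modes whose height reaches at least 5% of the global maximum (a
ripple guard), requires at least two qualifying modes, and takes the
density minimum strictly between the two highest modes as the cutoff.
Subjects with ST at or above the cutoff are HOIT (the boundary is closed
on the high side, a documented convention); below, LOIT. Unimodal inputs
raise an error rather than fabricating a cutoff; a manual cutoff can then
be forced.

As an independent typing route, `fit_dmm()` fits a Dirichlet multinomial
mixture by EM (Dirichlet parameters updated by fixed-point iteration,
k-means initialization, three random restarts) and selects the number of
components by a Laplace-approximated negative log model evidence. The
per-component Hessian of the weighted Dirichlet-multinomial likelihood has
diagonal-plus-rank-one structure, so its log-determinant is closed-form;
the evidence includes the mass of a weak exponential(0.1) prior on every
Dirichlet parameter, as reference implementations of the method
regularize — without it the approximation under-penalizes near-duplicate
components, whose flat likelihood directions carry almost no curvature,
and the single-community null case overfits. BIC is available as an
alternative criterion. `concordance()` quantifies agreement between the
trough labels and the two-component DMM assignment with a 2x2 table and a
two-sided Fisher exact test.

## Community ecology statistics

- **Shannon diversity** $H = -\sum p \ln p$ (natural log) per sample.
- **Bray-Curtis dissimilarity** on relative abundances (not rarefied
  counts; rarefaction is available upstream as a preprocessing choice).
- **PCoA** by classical scaling of the double-centered squared-distance
  matrix; negative eigenvalues are dropped with their absolute mass
  fraction reported.
- **PERMANOVA** (Anderson's pseudo-F) with free permutation of sample
  labels — no restricted designs — and
  $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm}+1)$; pairwise mode
  applies Bonferroni across group pairs. The implementation is backed by
  `vegan::adonis2` and is cross-checked in the tests against a
  brute-force direct-sum oracle to $10^{-12}$.
- **Levins niche breadth** $B_j = 1/\sum_i P_{ij}^2$, with $P_{ij}$ the
  share of taxon $j$'s cohort-wide relative abundance found in sample $i$:
  $B$ runs from 1 (confined to one sample) to $N$ (spread evenly).
- **Normalized stochasticity ratio (NST).** Null communities preserve each
  sample's richness, draw taxa with probability proportional to cohort
  occupancy, and assign abundances proportional to the cohort mean
  relative abundance. For each sample pair the observed Bray-Curtis
  similarity $C$ is compared with the null expectation $E$ over $R = 100$
  randomizations and scored $1 - |C - E| / \max(E, 1-E)$: 1 when the pair
  looks exactly as the null predicts, 0 at the maximal possible deviation.
  NST is the group mean, clamped to $[0,1]$. **This normalization is this
  package's own** — it follows the spirit of the published NST framework
  but is not numerically interchangeable with the reference NST package;
  only ordering and threshold properties (stochastic assembly above 0.5,
  selection-dominated below) should be compared across implementations.

## Co-occurrence networks

`core_taxa_filter()` keeps taxa with cohort-total reads strictly above
1000 before network inference. `sparcc()` estimates basis correlations
from compositional data: pseudocount-1 fractions, log-ratio variation
matrix $T_{ij} = \mathrm{Var}\log(x_i/x_j)$, basis variances from the
sparse-approximation linear system solved in closed form, and
$\rho_{ij} = (\omega_i + \omega_j - T_{ij})/(2\sqrt{\omega_i\omega_j})$,
with up to 10 rounds of excluding the single strongest pair above
$|\rho| = 0.1$. Fraction estimation is deterministic (pseudocount rather
than Dirichlet draws) so that results are reproducible; uncertainty comes
from `edge_significance()`, which permutes each taxon's counts
independently across samples (1000 iterations by default) and reports
two-sided pseudo p-values; a resampling-with-replacement mode is provided
for comparison. `build_network()` retains edges with $|\rho| \ge 0.4$ and
$p < 0.05$. The retention rule reads an ambiguous convention strictly:
only *strong* correlations are kept, since a network of weak edges is
ecologically meaningless.

`attack_robustness()` removes nodes in descending initial-degree order
(ties: higher mean abundance, then name; the order is static, matching
degree-targeted attack methodology and keeping the curve deterministic —
an explicit `order` argument supports adaptive or comparative schemes) and
reports the largest-connected-component fraction after each removal plus
the trapezoidal AUC. `neighbor_shift()` scores each node shared by two
networks with the Jaccard dissimilarity of its neighborhoods — a
simplified re-implementation of the neighbor-shift (NESH) idea for driver
screening; drivers are top-quartile shifters whose degree increased.
`cross_site_network()` concatenates site-tagged per-subject vectors from
two body sites and reports per-node total and cross-site edge counts.

## The synthetic cohort generator

`simulate_cohort()` builds the study conditions every stage is tested
under:

- **Sources.** Saliva and oropharynx share a log-normal abundance
  spectrum over an oral taxon block (70% of oral taxa identical in the
  underlying profile by default), the nasal profile occupies a disjoint
  block (30% of taxa) — emulating the observed similarity of the two oral
  sites and the specificity of nasal communities. One sample per subject
  per site, multinomial at 10,000 reads.
- **Subjects.** Each subject draws a latent group — HI with probability
  0.7, echoing the roughly 70/30 split of high- and low-oral-input
  subjects in cohorts of this kind — and a saliva mixing weight from
  Beta(8,2) (HI) or Beta(2,8) (LO), bimodal across the cohort; the
  remaining weight is split between oropharynx and nasal input by a
  Beta(4,4) draw. Group migration rates default to $m_{HI} = 0.04$ and
  $m_{LO} = 0.012$, magnitudes on the order of fitted lung-community
  values.
- **Lungs.** Per subject, the regional pool is
  $q = \sum_s w_s p^{(s)}$ and the lung composition is drawn
  $\mathrm{Dirichlet}(N_T\, m_g\, q)$ — the stationary abundance
  distribution consistent with the beta-CDF occurrence prediction, which
  makes migration-rate recovery a true inverse problem — then reads
  multinomially at depth (default 10,000 = $N_T$).

One global integer seed drives everything; per-operation generators are
derived by hashing the operation name, so re-running one stage never
perturbs another, and identical configuration gives bit-identical cohorts.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: sequencing error, contamination and batch
effects; taxonomic mis-assignment; within-subject temporal dynamics;
non-neutral selection in the lung (beyond the two-group migration-rate
contrast); and realistic phylogenetic correlation among taxa. Recovery
results certify the estimators against their own generative assumptions,
not against the messiness of clinical sequencing.

## Numerical choices and degenerate inputs

- Neutral fit refuses fewer than 20 usable taxa or 10 sink samples; taxa
  with source abundance 0 or 1 are excluded; optimizer failures at all
  starts raise an error with diagnostics rather than returning garbage.
- The Wilson band is clamped to $[0,1]$ and, at float precision, nudged to
  contain its own prediction.
- KDE trough: all-equal ST values (zero bandwidth) and unimodal densities
  raise errors; the mode floor ignores <5%-height ripple.
- DMM: empty components are pruned with a warning; EM stops on a relative
  log-likelihood change below $10^{-6}$ or 100 iterations (best-so-far
  flagged if unconverged); $\alpha$ is floored at $10^{-10}$.
- SparCC: taxa with non-positive basis variance are dropped to `NA` with a
  warning; correlations are clamped to $[-1, 1]$.
- NST: groups smaller than 4 samples are skipped with a warning; the
  group value is clamped to $[0,1]$.
- Rarefaction below a sample's total leaves the sample as-is with a
  warning.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in about a minute on one core while keeping every
recovery property well-powered: 200 sinks x 300 taxa for migration-rate
recovery; a 60-subject, 150-taxon cohort for source tracking and
pneumotyping; 500 samples x 50 taxa with 1000 permutations for SparCC
calibration; 100 NST randomizations (the convention for this statistic);
exhaustive enumeration over $3^6$ assignments for the Gibbs oracle.

## Known limitations

- The NST normalization and the NESH score are simplified,
  package-defined statistics; compare only their qualitative behavior
  with other tools.
- SourceTracker-style apportionment systematically grants the unknown
  source a few percent of mass that belongs to named sources (it can fit
  sink-specific sampling noise); treat small unknown fractions as an
  upper bound.
- The DMM evidence is a Laplace approximation; for small cohorts the
  selected k can be sensitive to restarts (three by default).
- Genus- versus ASV-level input is not enforced; operations accept either
  and results are only comparable within one level.
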