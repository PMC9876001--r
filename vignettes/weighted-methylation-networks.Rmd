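---
title: "Weighted methylation networks via canonical correlation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted methylation networks via canonical correlation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methccanet)
```

# The model

`methccanet` analyzes a CpG-site-by-sample matrix of methylation fractions
(beta values, in $[0,1]$) together with a per-sample clinical table and a
*prior* gene regulatory network given as a gene-symbol edge list. The
analysis rests on three modelling ideas.

**Genes, not sites, are the network nodes.** A gene $g$ with CpG sites
$s_1, \dots, s_k$ is represented by the leading principal components of the
centered sample-by-site matrix of its betas: the smallest number of
components reaching 90% cumulative variance (`var_retained`, at least one,
at most $n-1$). This keeps the number of features per gene well below the
sample count, which is where canonical correlation estimates are reliable.

**Edges are weighted by the first canonical correlation.** For two genes
with score blocks $X \in \mathbb{R}^{n \times p}$ and
$Y \in \mathbb{R}^{n \times q}$, the edge weight is

$$ w = \max_{u, v} \; \mathrm{corr}(Xu, Yv) \;=\; \sigma_1\!\left(
   \Sigma_{XX}^{-1/2} \Sigma_{XY} \Sigma_{YY}^{-1/2} \right), $$

the largest singular value of the whitened cross-covariance
(`canonical_weight()`). Unlike a Pearson correlation of two summary
vectors, this compares feature *blocks* of different dimensions, so genes
with one site and genes with thirty are treated uniformly. The weight is
clipped to $[0,1]$; a ridge of $10^{-8}\,\mathrm{tr}(\Sigma)/p$ is added
to a singular within-block covariance before whitening (numerical guard
only). Canonical correlations of a block with itself are 1, and the weight
is invariant under invertible linear transforms of either block — both
properties are asserted in the tests against `stats::cancor` as an
independent route. The package also offers the mean of all canonical
correlations (`method = "mean"`); the leading correlation is the default
scalar summary because it is the quantity `cancor` reports first and the
only one with the max-correlation interpretation above.

**Modules are communities of the weighted network.** Only edges of the
prior network whose *both* endpoints are differentially methylated genes
are weighted (an "either endpoint" policy is available;
`restrict_prior_network()`), the largest connected component is kept, and
weighted multilevel (Louvain) modularity maximization partitions it.
Modularity is

$$ Q = \frac{1}{2m} \sum_{ij} \left[ w_{ij} - \frac{k_i k_j}{2m} \right]
     \delta(c_i, c_j), $$

implemented independently of the optimizer (`modularity_q()`), so any
partition can be audited; the optimizer's reported $Q$ is always this
recomputation. Modules below `min_module_size` (default 100 genes, the
published filter) are dropped.

# Downstream statistics

*Differential methylation* (`test_sites()`) is a per-site Welch $t$-test,
on the beta scale by default (M-values optional with an $\epsilon=10^{-6}$
logit guard). The moderated-variance machinery of array pipelines is
deliberately not reproduced: at cohort sizes of tens of samples per arm the
plain Welch test is asymptotically equivalent, self-contained and easy to
audit. A site is a DMP when $|\log_2 \mathrm{FC}| > |\log_2 0.235|$ and
$p < 0.05$ (raw $p$ by default; BH-adjusted optional, and BH itself wraps
`stats::p.adjust`). Whether the published fold-change gate means a
beta-ratio or a beta-difference is not decidable from its source; both are
implemented (`fc_measure = "ratio"` is the default, `"delta"` reads the
threshold as $|\Delta\beta| > 0.235$, the convention of limma-style logFC
computed on a beta matrix).

*Module eigengenes* (`compute_me()`) are the first principal component of a
module's site submatrix, computed on the background of sites whose
case/control test gives $p<0.05$ (`significant_sites()`; set
`me_alpha = 1` to use all sites). Restricting to significant sites keeps
trait association from being diluted by sites that carry no disease
signal. The eigengene sign is fixed so that it correlates non-negatively
with the module's mean beta — "higher eigengene = more methylated".
Associations with clinical traits use Spearman's rho (traits are ordinal:
event, age, and T/N/M stage codes T1..T4 $\to$ 1..4, N0..N2 $\to$ 0..2,
M0/M1 $\to$ 0/1, sub-stages truncated to their integer part) on pairwise
complete observations, without cross-cell multiplicity correction by
default (a BH flag exists).

*Key-site screening* (`screen_key_sites()`) uses module membership
MM = Pearson correlation of a site with its module eigengene (the
co-expression-network convention) and trait significance GS = Spearman
correlation with the trait (ordinal). Both gates are strict inequalities;
the defaults 0.85/0.17 are the published thresholds for the
metastasis-linked module (0.75/0.15 were used there for a second module and
can be set per call). Constant sites fail the screen with `NA`.

*Survival* (`km_estimate()`, `logrank_test()`, `key_site_survival()`)
follows the product-limit estimator and the two-sample log-rank test with
hypergeometric variance and no continuity correction. These are authored
in-package because the test suite uses `survival::survfit`/`survdiff` as
the *independent* reference (agreement to $10^{-9}$ on random censored
datasets); wrapping the reference would make that check circular. The
high/low grouping rule for a site is a median split with ties to "low"
(quantile configurable) — the most common convention for methylation KM
plots; the source analysis leaves this rule unstated, so it is a documented
package choice, as is the $p<0.05$ prognostic flag.

*Sample cleaning*: sites containing any zero or missing beta are dropped
(`"any-zero"`; zeros on beta arrays indicate failed probes; an
`"all-zero"` policy exists). Outlier samples are those outside the largest
cluster when the average-linkage Euclidean tree of samples is cut at the
0.95 quantile of merge heights. The order of operations in `run_all()` is
intersect $\to$ outlier removal $\to$ zero-site cleaning; the outlier scan
runs on case samples only, mirroring tumor-cohort QC.

# The synthetic cohort generator

`generate_dataset()` emulates the structure the analysis assumes, with
ground truth for every stage:

* Each module $m$ has a latent factor $z_{ms} \sim N(0,1)$ per sample;
  every site of a gene in $m$ has latent value
  $b + s\,(a\,z_{ms} + e)$, with loading $a = 0.8$, noise
  $e \sim N(0, 0.3^2)$ and overall signal scale $s = 0.5$. Betas are the
  logistic transform clipped to $[0.01, 0.99]$ (logistic rather than
  truncated-normal so betas stay strictly inside $(0,1)$ and M-values are
  defined). With these values the within-group per-site beta dispersion
  stays under $\approx 0.1$, the range typical of 450K-style arrays.
* One designated site per gene is a true DMP: control mean beta 0.05
  gaining $\Delta\beta = 0.3$ in cases — the CpG-island hypermethylation
  pattern, and a fold change (7x) that clears the published ratio gate.
  $\Delta\beta$ is defined on the *mean-beta* scale: the latent group means
  are solved numerically (fixed-grid Gaussian quadrature + `uniroot`) so
  the realized mean difference hits the target despite the logistic
  smearing.
* Prior-network edges appear within modules with probability 0.3 and
  between with 0.02.
* The ordinal trait `stage_N` (3 levels, 0.5/0.3/0.2) is a discretized
  monotone function of module 1's factor, tuned to Spearman
  $\rho \approx 0.5$; the latent correlation is inflated by the empirically
  measured attenuation factor 0.868 of rank correlation under 3-level
  binning. Age, T and M are generated independently.
* Survival times are exponential (baseline rate $10^{-3}$/day) with hazard
  ratio 2 for samples above the prognostic site's median beta, censored by
  an independent exponential ($1.25\times10^{-4}$/day, roughly 10%
  censoring); the prognostic site is the first DMP of the trait module.
* Expression per gene is negatively correlated with its first site's
  methylation (Spearman $\approx -0.5$).

Cohort defaults are 100 cases and 100 controls with 4 modules of 30 genes,
4 sites per gene. The real tumor cohort the method was designed around had
a heavily imbalanced 6-control arm; that imbalance is reachable through
`synth_config(n_control = 6)` but is not the default, because a balanced
cohort of this size matches the operating range at which the downstream
tests (two-arm Welch, log-rank with $\sim$180 events) have well-defined
power and makes the recovery benchmarks interpretable. One master seed
derives independent sub-streams per component (factors, noise, network,
trait, covariates, survival, censoring, expression), so regeneration is
bit-identical and changing one component's draw does not perturb the
others.

What the generator does **not** emulate: 450K probe-type chemistry,
CpG-island/shore spatial structure, co-methylation distance decay,
batch effects, cell-type mixture, or realistic survival shapes beyond the
exponential. Passing recovery tests therefore demonstrates correctness of
the algorithms under the assumed model, not performance on real arrays.

# Benchmark configurations and problem sizes

The test suite and `scripts/acceptance.R` run each check at a scale chosen
to finish in seconds while leaving comfortable statistical margins:
oracle comparisons on 100–200 random instances; module recovery on 4x30
planted networks over 20 seeds; calibration/power at 20 samples per arm
over 10–20 replicates; end-to-end runs at the full default cohort over
10–20 seeds. Two configuration points deviate deliberately from the
pipeline's real-data defaults when the input is synthetic:

* `min_module_size = 15` — planted modules hold 30 genes; the published
  100-gene filter is calibrated to a 4,719-gene network and would empty a
  120-gene benchmark.
* `cut_quantile = NA` (outlier stage disabled) — the generator plants no
  outlier samples, and on data with strong planted co-methylation the
  quantile-cut tree slice mistakes module structure for a fringe (it can
  discard a large fraction of one arm). This is a real limitation of
  quantile-height outlier cuts on strongly clustered data: on real cohorts
  the cut height deserves inspection of the sample tree rather than blind
  use of the default.
* The null-calibration dataset sets `loading = 0`: binomially banded
  false-positive fractions presume exchangeable sites, while planted module
  factors leave the per-site test valid only marginally (per-replicate
  fractions become correlated across a module's sites).

# Numerical choices and degenerate inputs

* Welch sites with zero variance in both groups report $t=0$, $p=1$ with a
  warning; `log_fc` is finite whenever both group means are positive
  (guaranteed after cleaning).
* PCA retention is capped at $n-1$ components; rank-1 genes yield the
  centered site vector itself (up to sign).
* CCA blocks with more total components than samples trigger a saturation
  warning; zero-variance blocks are errors.
* Louvain sweep order is randomized under the caller's seed; identical
  seed and input give identical partitions (asserted over repeat runs).
  Module labels are deterministic: 1, 2, ... by decreasing size, ties by
  first label.
* Tree cutting at `cut_height_quantile = 1` never cuts (no outliers); an
  all-identical sample set yields a single cluster.
* Median splits send ties to "low"; constant sites cannot be split and
  propagate as `NA` rows in the survival table.
* Log-rank with zero events returns $\chi^2 = 0$, $p = 1$ with a warning;
  variance terms with a single subject at risk are skipped.

# Known limitations

Beyond the generator's simplifications listed above: the prior network is
treated as undirected (the CCA weight is symmetric); multi-gene probes are
resolved to their first annotated symbol; no DMR-level calling, covariate
adjustment, cell-type deconvolution, GO enrichment or external-cohort
validation is provided; and the published cohort-specific headline numbers
(site counts, the 20-module/Q = 0.59 partition, specific prognostic CpGs)
depend on the original tumor matrix and are not reproducible from this
package alone — the tests instead verify the properties each stage must
satisfy on data with known truth.
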