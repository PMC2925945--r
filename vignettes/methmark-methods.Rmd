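---
title: "Statistical methods behind methmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind methmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmark)
```

## The problem

Bladder tumors split clinically into non-invasive (papillary, superficial)
and invasive disease, and the two differ broadly in DNA methylation:
invasive tumors show a general upward shift in promoter CpG methylation.
`methmark` implements a two-stage marker-discovery design on top of
GoldenGate-style methylation arrays. Stage one screens a samples x loci
matrix of *average beta* values (a proportion in $[0,1]$, methylated signal
over total signal) with three parallel selection procedures in each of two
independent patient series, and intersects the survivors. Stage two
evaluates the surviving candidate genes in a third series measured by
bisulfite pyrosequencing (percent methylation, 0-100), with nonparametric
grade/stage comparisons and confounder-adjusted logistic models.

Because no raw cohort accompanies the package, a synthetic-data module
generates cohorts with the statistical structure that the analysis assumes;
every stage of the pipeline is exercised and tested against those cohorts
and against closed-form or enumeration oracles.

## Array QC

Two filters, in the order samples -> loci, then an autosomal restriction:

* a sample is dropped when strictly more than 75% of its loci have
  detection p-value $> 10^{-5}$;
* a locus is dropped when its median detection p-value across the retained
  samples is strictly greater than 0.05 (even counts use the mean of the
  central pair);
* loci annotated on X or Y are removed, since sex-linked methylation
  differences would confound mixed-sex cohorts.

Running the sample filter first makes the locus median well defined on the
retained samples. On a 1505-locus panel with 8 constructed locus failures
and 84 sex-chromosome loci the filters retain 1413 autosomal loci, the
panel size the downstream defaults assume. The filters only ever subset the
matrix; values are never altered.

## Locus-wise quasi-binomial GLM

Average beta values behave like overdispersed proportions, so each locus
$j$ is tested with a generalized linear model with logit link, binomial
variance function and a free scale parameter:

$$\mathrm{logit}\, E[\beta_{ij}] = \alpha_j + \gamma_j \cdot
\mathrm{invasive}_i .$$

With a single binary covariate the fit is saturated, so $\hat\gamma_j$
equals the difference of group-mean logits; the scale parameter is the
Pearson chi-square over $n-2$, and the two-sided p-value uses a $t_{n-2}$
reference — the standard quasi-likelihood convention. Values are clamped to
$[10^{-6}, 1-10^{-6}]$ before the logit because boundary observations break
the link; loci with all values identical are reported with slope 0 and
$p = 1$ (conservative, keeps the result table complete), and the rare
perfectly separated locus (two distinct constant groups, zero Pearson
dispersion) is flagged and reported with $p = 0$.

Multiplicity is handled with Storey q-values: $\hat\pi_0$ is estimated on
the grid $\lambda = 0.05, 0.10, \ldots, 0.95$ and extrapolated with a
cubic smoothing spline (df = 3), clipped to $(0, 1]$; fewer than 30
p-values fall back to $\pi_0 = 1$, in which mode the procedure reduces
exactly to Benjamini-Hochberg (verified against `p.adjust` in the tests).
Loci with $q < 0.05$ are called, split by slope sign. Exploratory
clustering of samples uses Manhattan distance with average linkage.

## Random-forest screen

Invasive status is classified from the beta matrix by a random forest
(bagged trees with a random subspace of size $m$ per split; the
`randomForest` package supplies the ensemble). The screen's own content is:

* **mtry tuning**: candidate $m$ from $\lceil \sqrt{M}/2 \rceil$ to
  $\lfloor 2\sqrt{M} \rfloor$ ($M$ = locus count), choosing the $m$ with the
  lowest out-of-bag (OOB) error, ties toward the smaller $m$ (500 trees per
  forest by default — unstated upstream, chosen for stability at desk
  scale);
* **OOB permutation test**: the observed OOB error is compared with OOB
  errors from forests grown on label-permuted data;
  $p = (1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$,
  with $n_{\mathrm{perm}} = 100$ by default, so the attainable floor is
  $1/101$;
* **importance**: the phenotype is re-coded 0/1 and a regression forest's
  unscaled permutation importance is expressed as percent increase over the
  forest's OOB MSE. The selection threshold is strict (`> 6%` by default;
  the companion screening value 5% is config). Reporting an MSE-based
  importance for a classification task keeps the importance scale
  continuous and mirrors how this screen is conventionally run;
* **external validation**: a fitted forest's misclassification rate on a
  held-out second series.

Null forests reuse the tuned $m$ rather than re-tuning per permutation;
re-tuning inside the null would only make the null conservative and costs
a grid factor of compute.

## Recursively partitioned beta-mixture models

The inference engine is a recursively partitioned mixture model over beta
distributions. At a node holding fractional sample weights $w_i$, a
two-class mixture gives locus $j$ in class $k$ the density
$\mathrm{Beta}(a_{jk}, b_{jk})$, loci independent given class. EM details:

* **E-step**: responsibilities from the current class weights and beta
  parameters (log-sum-exp stabilized).
* **M-step**: weighted beta maximum likelihood per locus and class by
  damped Newton iteration on the digamma score equations, initialized at
  weighted method-of-moments; parameters floored at $10^{-3}$ and capped at
  $10^7$; a step is only accepted when it does not lower the weighted
  likelihood, so the M-step — and therefore the EM log-likelihood — is
  monotone by construction (asserted on every fitted trace in the tests).
* **initialization**: deterministic — samples are split at the *weighted*
  median of their scores on the first principal direction of the
  logit-beta matrix, with responsibilities 0.95/0.05. The weighting
  matters: at a child node most of the cohort carries near-zero weight and
  must not influence the split point.
* **convergence**: relative log-likelihood change below $10^{-6}$, up to
  1000 iterations; non-convergence warns with the trace available.

A split is retained when the 2-class BIC beats the 1-class BIC, both
computed with the node's effective sample size $n_{\mathrm{eff}} = \sum_i
w_i$ (the simplest faithful BIC-variant reading; parameters: $4J + 1$
versus $2J$). Children inherit soft weights $w_i r_{ik}$ rather than hard
assignments, matching the empirical-Bayes spirit of the method and
avoiding premature decisions. Nodes with fewer than 8 effective samples
(an unstated boundary; prevents degenerate fits) are not split. Final class
membership is the product of branch responsibilities along each root-leaf
path — rows sum to one, and hard classes take the argmax.

Class-phenotype association uses a Pearson chi-square statistic whose null
distribution comes from permuting the phenotype (10,000 permutations by
default; the attainable floor is $1/10001 < 10^{-4}$).

### Class-versus-rest AUC

For ranking loci, leaf $k$'s beta distribution $F_{jk}$ at locus $j$ is
compared against a normal approximation $G_{jk}$ of the prevalence-weighted
mixture of the other leaves' distributions (moment-matched, truncated to
$[0,1]$ and renormalized). The AUC is

$$\mathrm{AUC}_{jk} = P(X_k > X_{\mathrm{rest}})
= \int_0^1 \bar F_{jk}(g)\, dG_{jk}(g),$$

computed by trapezoidal integration on a 10,001-point grid and folded to
$\max(\mathrm{AUC}, 1-\mathrm{AUC})$, since whichever ROC branch dominates
is the informative one. The integral agrees with a $10^6$-draw Monte-Carlo
oracle to well under 0.005. Two thresholds circulate for this statistic —
0.90 as a within-model ranking cut and 0.75 as the intersection cut — and
both are exposed as configuration; the intersection default is 0.75.

## The intersection rule

A locus becomes a candidate when, in each series independently, it passes
all three filters — $q < 0.05$, importance $> 6\%$, and
$\mathrm{AUC} > 0.75$ for the *class of interest* — and then survives the
intersection of the two series' survivor sets. The class of interest is
resolved per series as the leaf with the highest (posterior-weighted)
prevalence of invasive tumors; whether it should instead be fixed a priori
is not determinable from the design, and the invasive-enriched-leaf rule is
the package's resolution. Pass/fail is evaluated per series before
intersecting, never on pooled data. The rule is monotone (tightening any
threshold never adds candidates) and symmetric in series order.

## Pyrosequencing validation statistics

Per-gene percent-methylation readouts over adjacent CpG sites are
summarized and tested with deliberately conventional tools: Spearman
correlations between sites; per-sample means across observed sites (with
the contributing-site count reported — the handling of sporadically failed
sites is unstated upstream and averaging over observed sites is the
package's choice); tie-corrected Kruskal-Wallis across the three tissue
groups; Wilcoxon rank-sum comparisons protected by the Kruskal-Wallis gate
(exact enumeration when the smaller group has at most 8 untied
observations, otherwise the tie-corrected normal approximation);
dichotomization at the median with "at or below" coded negative; Woolf
(log-scale) confidence intervals around cross-product odds ratios, with
Haldane 0.5 correction only when a cell is empty; and multivariable
logistic regression (IRLS to $10^{-8}$, Wald intervals — the printed
intervals are symmetric on the log scale, which Wald reproduces and profile
likelihood would not). A single-binary-exposure logistic fit equals the
2x2 cross-product OR to numerical precision, which the tests assert, and
perfect separation raises an error rather than returning a diverged fit.

The grade contrast is low (1-2) versus high (3) throughout — the coding
that all reported analyses use — although a variant coding (1 vs 2-4)
appears once in the source narrative; the package exposes the grouping as
an argument to the relevant functions via the sample sheet. The three-gene
panel is summarized by the indicator of all three promoters above their
medians, and the tumor-cell-fraction check refits the model with a
percent-tumor covariate and reports coefficient deltas (collinear
covariates are flagged, not refit). Relative expression after demethylating
treatment uses the Pfaffl efficiency-corrected ratio
$E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$.

Percentages for reproducing printed contingency tables round half to even
(the R `round()` convention, which matches the printed cells; strict
half-up does not).

## The synthetic-data generator

`generate_cohort()` draws, per sample and locus,
$\beta_{ij} \sim \mathrm{Beta}(m_{ij} s, (1-m_{ij}) s)$ with precision
$s = 10$ and baseline mean 0.2 by default (i.e. Beta(2, 8), giving an
across-sample SD of about 0.12 — typical biological spread for an
unmethylated promoter locus). Structure is layered on top:

* latent methylation classes with configurable per-class means (for
  mixture-model testing), drawn from simplex weights;
* a configurable fraction of loci differentially methylated by invasive
  status, shifted upward to mean 0.6 in invasive samples — emulating the
  observed invasive hypermethylation;
* detection p-values: passing measurements $\sim U(0, 10^{-6})$, failures
  $\sim U(10^{-5}, 1)$, straddling the two QC operating points;
* covariates: age $\sim N(62, 9.3^2)$, 73% male, invasive fraction 0.42
  (Series-1-like), high grade with probability 0.17 given non-invasive and
  0.85 given invasive, and TP53 IHC high staining linked to invasiveness
  through a configurable odds ratio (default 12, the crude association in
  the validation tables; baseline 10% in non-invasive samples).

`generate_pyro_table()` draws, per gene, an equicorrelated latent Gaussian
vector across the gene's CpG sites (a Gaussian copula) mapped onto
group-mean $+$ noise with truncation to $[0,100]$ — preserving the percent
support while giving a tunable between-site Spearman structure (latent
$\rho = 0.8$ yields Spearman $\approx 0.79$, within the tested 0.05). With
zero noise every site equals its group mean exactly, which pins the
noiseless tests.

Two-series studies share one array panel: `generate_series_pair()` reuses
series 1's annotation and differential locus set for series 2. Array loci
default to mutual independence given class; real arrays show inter-locus
correlation (co-methylation), which the generator exposes only through the
latent-class mechanism. Passing tests therefore demonstrate correctness of
the *procedures* under the stated generative assumptions, not performance
on correlated real-array noise, batch structure, or raw-intensity
artifacts, none of which are simulated.

## Problem sizes and what the checks can show

The package's own simulation studies (also recomputed by
`scripts/acceptance.R`) run at desk scale, chosen once:

* **Null calibration**: 20 cohorts of n = 150 x 500 loci with no
  differential loci; the GLM stage flags at most one locus at $q < 0.05$ in
  at least 18 of 20 runs, and both permutation tests give approximately
  uniform p-values over replicates (RF: 20 replicates of n = 60 x 50 loci,
  49 permutations of 100-tree forests; chi-square: 100 replicates,
  B = 999).
* **Recovery**: two series (n = 100 and 150) over 40 loci with 5 spiked
  loci shifted from mean 0.2 to 0.6 in invasive samples. The locus count
  matters for the mixture stage: a 2-class split is accepted only when the
  aggregate log-likelihood gain from the informative loci exceeds the BIC
  penalty $\tfrac12 (2J+1)\log n$ — roughly 186 nats at $J = 40$,
  $n = 100$, against a gain of about 2.7 nats per sample from the five
  spiked loci ($\approx 270$). At full panel size (1413 loci) with only
  five informative loci no model-based split is mathematically possible;
  the real-data situation, where hundreds of loci differ, is the opposite
  regime. Ten seeds; success = all five spiked loci recovered with at most
  two false candidates.
* **Mixture recovery**: four classes at means 0.15/0.35/0.60/0.85, 240
  samples x 100 loci — the recursion finds exactly 4 leaves with fitted
  class means within 0.05 of truth.
* **Coverage**: 200 replicates of n = 245 with a TP53-like confounder and a
  true adjusted OR of 7.7; Wald intervals cover at approximately the
  nominal 95%.

Array-scale headline counts from real cohorts (hundreds of significant
loci, a tuned mtry of 38, a specific 5-locus candidate set) depend on data
that is not distributable and are deliberately **not** asserted; the
property-based checks above are the package's claims.

## Known limitations

* The beta-mixture recursion treats loci as independent given class;
  strong co-methylation violates this and can fragment or merge classes.
* The BIC split criterion with soft weights is one reasonable reading of a
  "variant of BIC"; alternatives (hard-assignment BIC, weighted-ICL) could
  split differently near the decision boundary. The implementation keeps
  the criterion in one place (`recursive_partition`) so sensitivity checks
  are easy.
* Storey's smoother estimate of $\pi_0$ is unstable below a few dozen
  p-values; the implementation falls back to $\pi_0 = 1$ (BH) there.
* The normal approximation of the pooled complement in the AUC statistic
  is exactly that — an approximation; for identical but skewed class
  distributions it reports values slightly off 0.5 (the tests bound this
  by 0.05).
* Wald intervals undercover when counts are sparse; the separation guard
  errs on the side of refusing to report a diverged fit.
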