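---
title: "Assessing local adaptation from population allele frequencies: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing local adaptation from population allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrona)
```

## The problem

Small, fragmented plant populations under a changing climate may carry
allele frequencies that no longer match their local environment. When a
species-wide survey shows consistent clines between allele frequencies and
environmental gradients, a population that deviates from those clines is a
candidate for being locally maladapted, and a candidate recipient for
assisted gene flow (AGF): moving propagules from a population whose
genotypes better match the recipient's environment.

`adaptrona` implements this assessment end to end for population-labelled
biallelic SNP data: locus filtering, a drift-aware genotype–environment
association (GEA) scan, multi-locus estimation of each population's
*risk of nonadaptedness* under current (c-RONA) and projected (f-RONA)
climates, Shapley-index conservation prioritization, and donor–recipient
matching for AGF.

## Models

### Drift null and the GEA scan

Population structure is summarized by the covariance matrix $\Omega$ of
scaled allele frequencies: for each locus $l$,
$u_l = (f_l - \bar f_l \mathbf 1)/\sqrt{\bar f_l(1-\bar f_l)}$ and
$\Omega = \tfrac1L \sum_l u_l u_l^\top + \varepsilon I$ with
$\varepsilon = 10^{-6}\,\mathrm{tr}(\Omega)/P$ guaranteeing a Cholesky
factorization. Under a Balding–Nichols model with drift parameter $F$ and
independent populations, the diagonal of $\Omega$ estimates $F(P-1)/P$ (the
$(P-1)/P$ factor comes from centring on the across-population sample mean).

Before $\Omega$ is trusted as a *null*, strongly differentiated loci are
removed by an FLK-style screen: $T_l = (f_l - \hat f_l\mathbf 1)^\top
\Omega^{-1}(f_l - \hat f_l\mathbf 1)/(\hat f_l(1-\hat f_l)) \sim \chi^2_{P-1}$,
with $\hat f_l$ the GLS mean and Benjamini–Hochberg control at FDR 0.2.
$\Omega$ is estimated once from all loci, the screen applied, and $\Omega$
re-estimated excluding the flagged loci; all loci (including flagged ones)
are still tested in the GEA.

The per-locus, per-variable association statistic is a closed-form Bayes
factor in $\Omega$-whitened space. With $\Omega = LL^\top$, regress
$L^{-1}f_l$ on $[L^{-1}\mathbf 1, L^{-1}E_v]$; with whitened $R^2$ and a
Zellner $g$-prior on the environmental coefficient ($g = P$,
unit-information),
$$\mathrm{BF}_{10} = (1+g)^{(P-2)/2}\,\bigl(1+g(1-R^2)\bigr)^{-(P-1)/2}.$$
A locus is a candidate for a variable iff $\log_{10}\mathrm{BF} > 1$
(strong support) *and* its $|\rho|$ (Spearman, average ranks for ties)
reaches the top decile of $|\rho|$ across all loci for that variable —
the decile is computed over all tested loci, not only BF-passing ones.
Each candidate locus is then assigned to the single variable with the
largest BF (ties broken by environment-table order) so no locus is counted
twice downstream.

This deterministic BF replaces an MCMC importance-sampling estimate of the
same model family (multivariate normal around $\Omega$ with an
environmental mean shift); averaging over MCMC runs is therefore
unnecessary. Frequencies enter untransformed, matching the moment scaling
of $\Omega$; an arcsine or logit transform is a known sensitivity point.

### Ridge BLUP and RONA

For each variable with at least `min_loci` (default 6) assigned loci, the
standardized environment is regressed on the allele-frequency matrix of its
assigned loci:
$$E = \mu\mathbf 1 + F\beta + e,\qquad \beta \sim N(0, \sigma_\beta^2 I),\
e \sim N(0, \sigma_e^2 I).$$
The ratio $\delta = \sigma_e^2/\sigma_\beta^2$ is estimated by REML,
profiled on $\log_{10}\delta \in [-5, 5]$ (tolerance $10^{-6}$) using the
eigendecomposition of $FF^\top$; $\hat\mu$ is the GLS intercept and
$\hat\beta = F^\top (FF^\top + \delta I)^{-1}(E - \hat\mu\mathbf 1)$, which
equals the loci-space ridge solution $(F^\top F + \delta I)^{-1}F^\top
(E - \hat\mu\mathbf 1)$ exactly (an identity the tests verify to $10^{-8}$).
A boundary flag records when the REML optimum sits at a search bound (e.g.
noiseless signals drive $\delta$ to the lower bound).

$\hat E_p = \hat\mu + f_p\hat\beta$ is the environment population $p$'s
genotype is best matched to. The residual $r_p = E_p - \hat E_p$ is the
deviation from that optimum in standardized environment units; c-RONA
rescales it to allele-frequency units as
$$\text{c-RONA}_p = |r_p| \big/ \textstyle\sum_l |\hat\beta_l|,$$
the uniform per-locus frequency shift $\delta\!f$ that would close the gap
($\delta\!f \sum_l|\hat\beta_l| = |r_p|$). The method only states that the
risk is *proportional* to the required frequency change; equal per-locus
displacement is the one scale that makes the constant explicit, and the raw
residuals are always co-reported so the unscaled quantity remains
available. f-RONA is the same quantity against a projected environment
$E'$, standardized with the *current-period* mean and SD, so that a
scenario equal to the current table gives f-RONA $\equiv$ c-RONA exactly.
Across variables both the mean absolute residual (environment units) and
the mean c-RONA (frequency units) are reported, since the two aggregations
answer slightly different questions.

### Prioritization and AGF

Pairwise $F_{ST}$ uses the Weir–Cockerham ratio-of-sums estimator in its
allele-copy (haploid-sample) form — the within-individual component is not
identifiable from population counts. Permutation p-values reshuffle allele
copies between the pair at each locus (hypergeometric resampling of pooled
counts) with the add-one rule $(x+1)/(n_\text{perm}+1)$.

The Shapley index distributes total genetic diversity over populations.  On
an unrooted tree (neighbour joining on the $F_{ST}$ matrix, negative
distances floored at 0, negative branch lengths clamped to 0), each edge of
weight $w$ splitting the $n$ leaves into sides $A$ and $B$ contributes
$w|B|/(n|A|)$ to every leaf in $A$; scores sum to total tree length
(efficiency). The original method used NeighborNet split networks; the
Shapley split formula is identical given a split system, and the NJ tree is
the split-system restriction used here — the `shapley()` input is any
weighted tree, so a network backend can be swapped in. Distances are raw
$F_{ST}$ (not $F_{ST}/(1-F_{ST})$), the simplest reading; linearization is
a one-line change at the call site. The consensus ranking averages the rank
of ascending c-RONA with the rank of descending adaptive-set Shapley value
(ties averaged) — the aggregation itself is this package's choice, since no
standard one exists.

For AGF, population $q$ is an eligible donor for recipient $p$ and variable
$v$ iff $|\hat E_q - E_{p,v}| \le z\,\hat\sigma$ with $\hat\sigma$ the fit's
residual SD and $z = 1.96$ by default — the "confidence band of the
regression" operationalized as a residual-SD band; a prediction-interval
variant is available through $z$. If $p$ is its own eligible donor the plan
records `none_needed`; otherwise the geographically closest eligible donor
(haversine, Earth radius 6371 km; ties by lexicographic id) is selected, or
`no_donor_available`.

## The synthetic-data generator

`simulate_dataset()` emulates the end product of a RADseq survey of a
fragmented montane shrub: 26 populations on a Highlands-like landscape,
2000 neutral loci, 4 correlated climatic variables (pairwise correlation
0.3, induced by linear mixing of independent spatial gradient fields — the
collinearity the variable filter must handle), and 20 adaptive loci per
variable. Neutral loci follow Balding–Nichols:
$f_{p,l} \sim \mathrm{Beta}(\pi_l(1-F_p)/F_p,\ (1-\pi_l)(1-F_p)/F_p)$ with
$\pi_l \sim U(0.05, 0.95)$, $F_p = 0.05$ for ordinary populations and
$F_p = 0.3$ for five "relict" populations genotyped at only 2 allele copies
(1 diploid plant) — mirroring surveys in which a handful of range-edge
relicts are both tiny and drift-dominated. Adaptive loci follow
$\mathrm{logit}^{-1}(a_l + b_l E_{p,v})$ with $|b_l| \sim U(0.75, 1.5)$,
random sign, logit-scale noise SD 0.2, the same beta drift, clamped to
$[0.01, 0.99]$; observed counts are binomial in the genotyped copies
(12 per ordinary population — 6 diploids). The coupling strength was set
so that the frequency–environment correlation of a typical adaptive locus
is ~0.5–0.7, the regime in which a GEA is expected to work at 26
populations; everything is reproducible byte-for-byte from the seed.

`inject_maladaptation()` regenerates the adaptive loci of chosen
populations from $E + \delta$, creating genotypes adapted to an environment
offset by $\delta$ SD; `simulate_phenotypes()` ties fitness proxies to the
injected truth (catkin counts negative-binomial with log-mean
$\alpha - \gamma m_p$; germination binomial with a logit-linear decline;
baseline germination 7.6%).

What the generator does **not** emulate: isolation-by-distance covariance
between populations (off-diagonal $\Omega$ structure is exercised only
through unequal $F_p$), linkage between loci, nonlinear or interacting
environmental responses, and phenotypic plasticity. Passing tests therefore
show that the estimators recover the model they assume, under realistic
sample sizes and drift — not that the assumptions hold in any particular
field system.

## Numerical choices and degenerate inputs

* Locus filter: presence in $\ge 8$ populations means $\ge 1$ genotyped
  allele copy; the minor-allele frequency is computed on counts pooled
  across populations (robust to unequal sample sizes). Filtering is
  idempotent, and filtering everything is an error, not an empty result.
* Scenario tables are standardized with the current-period transform —
  never re-centred — so projected shifts remain visible.
* $\Omega$: loci with across-population mean frequency 0 or 1 carry no
  information and are excluded with a warning; masked cells use
  pairwise-complete averaging; the trace-scaled ridge is dimensionless.
* BF with masked cells: populations lacking the locus are dropped and the
  $\Omega$ submatrix used; fewer than 4 populations is an error.
* BLUP: populations with any missing assigned-locus frequency are dropped
  from that variable's fit (no imputation) and recorded; constant locus
  columns are dropped with a warning; if every effect shrinks to zero,
  c-RONA is refused rather than returned as 0/0.
* Exact BF ties in assignment fall back to environment-table order, with a
  message; AGF distance ties fall back to lexicographic population id, so
  plans are invariant to row order.
* Display percentages round half-up to integers; unrounded values are
  always retained.

## Known limitations

* **Leverage of tiny populations.** BLUP residuals are in-sample: a
  population genotyped at 2 allele copies has an extreme frequency vector,
  high leverage, and therefore an artificially *small* residual when the
  REML fit is close to interpolation. Exchangeable drift noise in such
  populations is largely absorbed by the fit and will not surface as
  c-RONA; a *systematic* offset (genotypes matching $E+\delta$) does
  surface. Leave-one-out prediction would remove this at the cost of
  departing from the standard in-sample definition; it is left to future
  work and matters most when assigned loci are few relative to populations.
* The false-positive fraction among GEA candidate calls is governed by the
  null tail of the BF at the fixed threshold ($\log_{10}\mathrm{BF} > 1$
  gives roughly a 0.5% per-locus null rate at 26 populations); with
  thousands of neutral loci, a non-trivial minority of calls will always be
  nulls. The top-decile Spearman conjunction reduces but does not remove
  them.
* Permutation p-values for $F_{ST}$ reshuffle allele copies, not
  individuals; with strong inbreeding the two differ.
* The AGF plan optimizes one variable at a time; a donor good for
  temperature may be poor for precipitation. Joint multi-variable donor
  choice is out of scope.

## Study sizes used in the automated checks

The test-suite experiments run at the generator defaults (26 populations,
2000 neutral + 80 adaptive loci) with 50 seeds for effect-size recovery and
maladaptation ranking, 20 seeds for GEA recovery and null calibration, and
200 replicates for the fitness-regression null; oracle-equivalence checks
(quadrature BF, WC84, ridge identity, NJ metrics, Shapley efficiency on
1000 random trees) are deterministic.
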