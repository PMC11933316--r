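---
title: "Temporally resolved CRISPR screen analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporally resolved CRISPR screen analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenpulse)
```

# The problem

In a pooled CRISPR knockout screen each cell carries one sgRNA; under
selection, the relative abundance of a guide reports the fitness effect of
losing its target gene. A *temporally resolved* drug screen samples the
population repeatedly (here: a shared Day-0 baseline, then vehicle and drug
arms at days 2–10 in two replicates) so that drug-specific selection can be
separated from baseline essentiality and followed over time. A *tiling*
screen instead walks 58 guides along one gene's coding sequence: in-frame
repair products delete small local regions, so guides in dispensable
domains behave like controls while guides in required domains deplete.

`screenpulse` implements the full count-level analysis for both designs,
plus a generative simulator that produces screens with known ground truth.

# The count model

Counts are negative binomial with the mean/overdispersion convention
$\mathrm{Var} = \mu + \alpha\mu^2$ throughout — simulator, likelihood and
moment estimators all share it, which keeps dispersion estimates and fits
consistent. $\alpha \to 0$ is the Poisson limit.

For guide $i$ of gene $g$ in sample $r$:

$$\log \mu_{ir} = \log s_r + \log b_i + \textstyle\sum_c D_{rc}\,\beta_{gc}$$

* $s_r$ — per-sample size factor (dimensionless). Computed DESeq-style as
  the median across non-targeting control guides of
  $K_{ir}/(\prod_v K_{iv})^{1/m}$. Non-targeting guides are the natural
  reference in a selection screen because their abundance has no
  fitness component. Controls with any zero count are dropped from the
  median (the geometric mean would be degenerate); if that empties the set,
  all all-positive guides are used, with a warning. Even-length medians are
  the midpoint of the central pair, fixed for determinism.
* $b_i$ — guide baseline abundance (counts at unit size factor), a free
  parameter per guide, so library representation skew never biases $\beta$.
* $D$ — 0/1 design: one column per (condition, day) contrast, e.g.
  `DAC_D6`; Day-0 samples have all-zero rows. Fitting every contrast
  jointly against the shared baseline mirrors a design in which each
  treatment-day is its own condition.
* $\beta_{gc}$ — the gene's log-scale selection coefficient for contrast
  $c$, shared across the gene's guides; positive = enrichment since Day 0.

Guide-level dispersions $\alpha_i$ are method-of-moments estimates
$(s^2 - \bar m)/\bar m^2$ on size-factor-normalized counts within replicate
groups (same condition and day), pooled across groups by count-weighted
average and clipped to $[0.01, 10]$. The floor also catches the negative
estimates that Poisson-level data produce. With only two replicates per
group the per-guide estimate is noisy but pooling over the eleven groups of
the genome-wide design stabilizes it; the test suite checks that
Poisson-simulated counts land at the floor and that the worked moment
example $(50,150) \mapsto \hat\alpha = 0.49$ is reproduced exactly.

## Fitting

Each gene is maximized jointly over $(\log b, \beta)$ by damped Newton
iteration on the observed information, with step-halving whenever a step
would decrease the likelihood, convergence when the largest parameter
update falls below $10^{-6}$, and a 100-iteration cap (the last iterate is
returned, flagged). Blockwise coordinate updates (baselines, then betas)
were evaluated first but converge only linearly — the shared Day-0 sample
couples the two blocks strongly, with observed rates near 0.9 per sweep —
so the joint step, whose per-gene information matrix is at most
(guides + contrasts) squared, is both faster and more robust.

Two numerical guards matter in practice: $\log b$ is clamped to $\pm 30$,
and $|\beta|$ to 15. The latter handles contrasts whose counts are all
zero — the MLE there is $-\infty$; a bound of 15 (an $e^{15}$-fold change,
far beyond what any screen depth resolves) keeps such genes finite,
directionally correct and convergent. Standard errors are the
observed-information diagonal after inversion; $z = \beta/\mathrm{se}$ is
reported but plays no role in hit calling, which is threshold-based.

The test suite pins the fitter to an *independent* oracle: an exhaustive
grid search over $\beta \in [-10, 10]$ at step $10^{-3}$, with the guide
baselines profiled out by bisection on the (monotone) score function.
Closed Poisson-limit forms — $\hat\beta = \ln(800/100)$ for one guide,
$\ln(500/200)$ for two pooled guides — are checked to $10^{-3}$.

## Cross-condition rescaling

Treatment arms can differ in overall proliferation, which stretches the
$\beta$ scale of one condition relative to another. The published analyses
this package follows correct for that with a "cell-cycle" normalization
whose algorithm is not public; `cellcycle_normalize()` therefore implements
a declared stand-in: per condition column (and replicate), $\beta$ and its
standard error are divided by $\kappa_c$, the median $|\beta|$ over a
reference gene set (default: all targeting genes; an essential-gene list
can be supplied). The transform is monotone per column, so within-day
orderings — and hence the mean$\pm k\sigma$ calls, which are location- and
scale-equivariant — are unaffected; what it changes is the comparability of
trajectories across days, which matters for clustering. The applied
$\kappa_c$ are recorded in the result's `"kappa"` attribute.

# Differential scores and hit calling

$\Delta\beta_{g,t} = \beta_{g,\mathrm{DAC},t} - \beta_{g,\mathrm{DMSO},t}$.
Replicates are fitted independently (each against its own Day-0 sample) and
their $\Delta\beta$ averaged before calling — matching the averaged
presentation of the source analyses; a joint fit across replicates is
available via `per_replicate = FALSE`. Because both arms of a replicate
share the Day-0 baseline, baseline noise enters both $\beta$ columns
equally and cancels in $\Delta\beta$.

Per day, hits are genes with $\Delta\beta$ strictly above
$\mathrm{mean} + k\sigma$ or strictly below $\mathrm{mean} - k\sigma$
($k = 2$ by default), with mean and $\sigma$ computed over all genes.
Choices fixed here: $\sigma$ uses the population denominator $n$
(immaterial at genome scale, fixed for determinism); inequalities are
strict ("higher/lower than" a threshold); a zero-$\sigma$ day yields no
calls. The rule is location-equivariant and antisymmetric under negation,
both property-tested.

The **high-fidelity filter** requires the same direction on at least two of
days 6, 8 and 10. With three eligible days the two directions can never
both reach two calls; with four or more they can, and such conflicts are
flagged `ambiguous` rather than resolved by majority — recurrence is meant
to certify consistency, so a conflicted gene should be surfaced, not
silently assigned. The 27 possible call triples are enumerated in the tests
against the rule's definition.

Trajectories of high-fidelity genes are clustered by `hclust` with Ward
linkage (`ward.D2`) on Euclidean distances of replicate-averaged
$\Delta\beta$ trajectories, cut at $k = 6$ clusters by default, and
relabelled by descending final-day centroid so cluster 1 is always the
strongest late enrichment. Metric, linkage and $k$ are conventions; nothing
downstream depends on them.

# Tiling screens

Two complementary readouts:

* **Survival rates** `survival_rates()`: counts per million per sample, a
  0.5 pseudocount (tiny libraries make zero counts likely; the ratio would
  otherwise be undefined), replicate means per (condition, day), the ratio
  $\rho_i = \mathrm{DAC}_i/\mathrm{DMSO}_i$, and rescaling by the mean
  $\rho$ over the non-targeting controls. The control mean is therefore
  exactly 1 at every day — an identity, tested to $10^{-9}$ — and the
  statistic is invariant to any per-sample depth rescaling. CPM rather than
  median-ratio is used because the source analyses distinguish this
  depth normalization from the control-based one of the genome-wide screen;
  a median-ratio variant can be had by passing explicit size factors to the
  $\beta$ route instead.
* **Domain-as-gene $\beta$** `domain_beta()`: guides are regrouped by their
  domain label and fitted exactly as genes; non-targeting and
  positive-control guides stay out of the groups. Relabelling all guides
  into one domain reproduces the pooled single-gene fit, which the tests
  assert.

The default domain layout (`kdm1a_domain_spec()`) is a synthetic stand-in
emulating a demethylase scanning design — five domains over a 2559-nt
coding sequence with guide counts 10/10/14/10/14 — since the real
per-domain coordinates are not public. Only the structure (a neutral
N-terminal flexible region among depleted domains) matters for the tests.

# The simulator

`simulate_screen()` draws counts from the generative counterpart of the
fitted model, so parameter recovery is well-posed:

$$p_i(t) \propto p_i(0)\,
  \exp\!\big[(g_{g} + \mathbb{1}[\mathrm{DAC}]\,e_{g})\,w_i\,t/\tau\big],
\qquad K \sim \mathrm{NB}(\mathrm{depth}\cdot p_i(t),\ \alpha_{\mathrm{sim}})$$

* $g_g$ — condition-shared log-fitness per $\tau$ days,
  $\mathcal N(0, 0.1)$ by default: most knockouts are near-neutral, a
  minority mildly essential or advantageous.
* $e_g$ — treatment interaction, planted as $\pm$`effect_size` in chosen
  gene fractions; the remainder 0. The true effect-size distribution of
  real hits is unknown; $\pm 1$ per $\tau = 2$ days is the declared
  convention for recovery tests, chosen as a moderate effect (an $e$-fold
  abundance change per two days at full efficiency).
* $w_i \sim \mathrm{Beta}(5,1)$ — guide efficiency in $[0,1]$ (most guides
  cut well, a tail does not); non-targeting guides have $g = e = w = 0$.
* $p_i(0)$ — log-normal with SD 0.5, normalized: real libraries are
  skewed; the magnitude is a free parameter.
* Defaults mirror the study design: 1000 genes × 4 guides + 100
  non-targeting controls, 2 replicates, days 0/2/4/6/8/10, expected depth
  $10^6$ per sample (≈100-fold representation), $\alpha_{\mathrm{sim}} =
  0.05$. Day 0 is one shared sample per replicate, as in the experimental
  design where arms split after baseline collection.

Counts are drawn by a Gamma–Poisson mixture (valid for non-integer
$1/\alpha$), with one derived sub-seed per (replicate, condition, day) so
results are independent of sampling order and byte-identical across runs.

What the simulator does **not** emulate: multiplicity of infection and
multiple integrations, PCR jackpotting beyond NB overdispersion,
guide-specific off-target toxicity, day-dependent dispersion, or copy-number
artifacts. Passing recovery tests therefore certifies the estimator against
its own model class, not against every failure mode of real screens.

# Problem sizes and runtime choices

The acceptance-level checks run the full study design (1000 genes, two
replicates, six timepoints; three seeds for recovery), which completes in
well under a minute per screen; unit tests use 40–250-gene screens to keep
the suite fast. The MLE-vs-oracle comparison uses 20 random instances of at
most 4 guides, as small instances make the exhaustive grid search exact and
cheap. These sizes are statements about where the properties are already
measurable, not limits of the implementation.

# Known limitations

* The cell-cycle rescaling is a stand-in with the right equivariance
  properties, not a reproduction of the unpublished original; exact
  numerical agreement with the published tool's scores is not a goal
  (the whole $\beta$ model is a re-derivation of the standard log-linear
  NB formulation).
* Whether the original analyses fitted replicates jointly or separately,
  and whether their $\sigma$ was computed on a trimmed gene set, is
  unstated; this package's choices (separate fits, all genes) are
  documented defaults with flags where alternatives exist.
* No permutation p-values, sgRNA-level rank aggregation, FDR machinery or
  copy-number correction — calling here is deliberately the threshold rule.
* Guide-level dispersion from two replicates is noisy; with other designs,
  supply `dispersions` explicitly or increase replication.
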