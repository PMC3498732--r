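---
title: "Methods: retentostat kinetics and growth-rate-dependent expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retentostat kinetics and growth-rate-dependent expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearzero)
```

## The biological setting

A retentostat is a chemostat whose effluent leaves through a filter, so
no biomass is washed out. Under glucose limitation the accumulating
biomass progressively consumes the fixed glucose supply for maintenance
(turnover of damaged components, ion gradients) rather than growth, and
the specific growth rate $\mu$ falls asymptotically towards zero while
the cells stay metabolically active. This gives experimental access to
near-zero growth rates that neither batch nor chemostat cultures can
reach. `nearzero` implements the two quantitative halves of such a
study: (i) the maintenance-energy kinetics that convert measured
biomass/viability time series into $\mu(t)$ and glucose-flux
partitions, and (ii) the statistics that turn a combined chemostat +
retentostat expression dataset into growth-rate-dependent gene sets,
clusters and enrichments.

## Kinetic model

Biomass accumulation under "ideal" retentostat conditions
(growth-rate-independent maintenance, no lysis) follows

$$\frac{dC_x}{dt} = Y_{sx}^{max}\left(D\,(C_{s,in} - C_s) - m_s C_x\right),$$

with $D$ the dilution rate (h$^{-1}$), $C_{s,in}$ and $C_s$ the feed and
residual glucose concentrations (g L$^{-1}$), $m_s$ the maintenance
coefficient (here in g glucose g$^{-1}$ h$^{-1}$ after converting the
conventional mmol figure with a glucose molar mass of 180.16 g mol$^{-1}$)
and $Y_{sx}^{max}$ the maximum biomass yield (g g$^{-1}$). The unique
solution is the three-parameter exponential

$$C_x(t) = C_{x,\infty} + (C_{x,0} - C_{x,\infty})e^{-kt},\qquad
k = m_s Y_{sx}^{max},\quad C_{x,\infty} = \frac{D (C_{s,in}-C_s)}{m_s},$$

i.e. exactly the $A e^{Bt} + C$ shape fitted by `fit_biomass_curve()`.
$C_{x,\infty}$ is the steady state at which the entire glucose supply is
spent on maintenance. Defaults ($D = 0.025$, $C_{s,in} = 50$,
$m_s = 0.50$ mmol g$^{-1}$ h$^{-1}$, $Y_{sx}^{max} = 0.097$) describe an
anaerobic, glucose-limited *S. cerevisiae* retentostat; with them
$A \approx -10.28$, $B \approx -0.0087$ h$^{-1}$, $C \approx 13.88$
g L$^{-1}$. $C_s$ defaults to zero because measured residual glucose
(sub-mM) is three orders of magnitude below the feed. The starting
biomass $C_{x,0}$ defaults to the parent chemostat's steady state under
the maintenance-corrected (Pirt) yield $1/Y_{obs} = 1/Y_{sx}^{max} + m_s/D$.

Because only viable cells replicate, and assuming no lysis (dead cells
stay in the measured dry weight), the specific growth rate follows from
the fitted *total* biomass curve and measured viability $v(t)$:

$$\mu(t) = \frac{dC_x/dt}{v(t)\, C_x(t)}.$$

`specific_growth_rate()` differentiates the fit analytically,
interpolates viability linearly between sampling points, and clips
negative derivatives to $\mu = 0$ with a flag (a negative derivative
would contradict the no-lysis assumption, so it is reported rather than
propagated). Glucose is then partitioned between maintenance
($m_s C_{x,viable}$) and growth ($\mu C_{x,viable}/Y_{sx}^{max}$);
the fractions always sum to one by construction.

### Numerical choices

* `fit_biomass_curve()` uses derivative-free Nelder–Mead simplex search
  (`stats::optim`) on the sum of squared residuals, initialised at
  $C_0 = 1.05\max(C_x)$, $A_0 = C_x(0) - C_0$, $B_0 = -0.01$ h$^{-1}$,
  with relative tolerance $10^{-12}$ and a cap of 10 000 evaluations,
  restarted once from its own optimum to polish the simplex.
  Non-convergence is reported in the `converged` flag with best-so-far
  values, never as an error.
* `predict_biomass()` evaluates the solution as
  $C_{x,0} e^{-kt} + C_{x,\infty}(1 - e^{-kt})$, which returns the
  initial condition exactly at $t = 0$.
* `residual_glucose_monod()` inverts Monod uptake kinetics,
  $C_s = K_s\,q_s/(q_{s,max} - q_s)$ with
  $q_s = \mu/(Y_{sx}^{max} M_{glc}) + m_s$. Maintenance keeps $q_s$
  positive as $\mu \to 0$, so residual glucose levels off at
  $K_s m_s/(q_{s,max} - m_s)$ instead of vanishing. The defaults
  ($q_{s,max} = 15$ mmol g$^{-1}$ h$^{-1}$, $K_s = 3.8$ mM) were chosen
  once so that the relation stays unsaturated over the full design
  range ($\mu \le 0.2$ h$^{-1}$, where implied uptake reaches
  ~12 mmol g$^{-1}$ h$^{-1}$) and the near-zero-growth floor sits at
  ~0.13 mM, the level at which residual glucose is observed to level
  off; a single inverted Monod curve cannot simultaneously reproduce
  every printed residual-glucose value across the whole rate range, and
  the floor is the anchor that matters for near-zero growth.

## Expression preprocessing

Single-channel array intensities are normalized by global scaling:
every array is multiplied by $300/\text{mean}$ so the average over all
features is 300. This assumes the overall mRNA pool is comparable
across samples; the package follows the field's standard check —
housekeeping genes should keep a coefficient of variation below 0.20
across all arrays (`housekeeping_cv()`). Values below 12 are floored to
12 and genes whose across-array maximum never reaches 20 are discarded
(`floor_and_filter()`); an ORF filter (`select_orfs()`) then restricts
features to verified open reading frames. Profiles for clustering and
display are replicate-averaged per condition and divided by their
across-condition mean (`mean_normalize_profiles()`), making them pure
shapes with unit mean.

One caveat worth knowing: when responsive genes are numerous and
unbalanced (more up than down at low $\mu$, say), the per-array scaling
factor itself acquires a condition dependence and imprints a small
common-mode trend on *every* gene. In synthetic data this is visible as
a modest excess of significant calls among constant genes after
scaling. This is a genuine property of global scaling, not of the
implementation; the housekeeping CV check is exactly the guard the
field uses against its severe form.

## Significance of growth-rate-dependent expression

For each gene the package compares, by least squares, an intercept-only
model against a natural cubic spline in the covariate with 3 basis
functions plus intercept (knots at covariate quantiles):

$$F = \frac{(RSS_0 - RSS_1)/(d_1 - d_0)}{RSS_1/(n - d_1)}.$$

The covariate defaults to $\log_{10}\mu$ because the combined design
spans 2.5 orders of magnitude in growth rate and expression trends are
smooth on that scale; for a pure retentostat time course the
configuration accepts time instead. Replicates enter as independent
samples sharing a covariate value. The null distribution is obtained by
permuting whole sample columns — the same permutation set for every
gene, which preserves gene–gene correlation — with the add-one
estimator $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(B + 1)$, whose
smallest attainable value is $1/(B+1)$ and which is valid (never
anti-conservative) by construction. $B$ defaults to 1000. The F
statistic is invariant to affine transformation of a gene's profile,
so it is pivotal across genes of any scale.

q-values follow Storey's estimator: $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0.05, \dots, 0.90$ (step 0.05), smoothed by a cubic
polynomial and evaluated at $\lambda = 0.90$, clamped to $(0, 1]$, with
$q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \text{rank}(p_j)$. If
the smoother misbehaves (non-finite or non-positive $\hat\pi_0$) the
estimate falls back to $\pi_0 = 1$, i.e. plain Benjamini–Hochberg. The
printed significance convention is a p-value threshold of 0.01 with the
corresponding q-value reported alongside; any particular p↔q pairing
(such as 0.01 ↔ 0.000188 for the original 22-array dataset) is a
property of a dataset, not of the method, and is therefore
configuration, not contract.

## Clustering under a positive-correlation distance

Significant genes' mean-normalized condition profiles are clustered by
k-means with distance $d = 1 - r$ (Pearson), $k = 7$ by default and at
most 1000 Lloyd iterations. Design choices where the method is genuinely
open:

* **Centroid update**: arithmetic mean of member profiles,
  re-mean-normalized to stay on the profile scale. The mean is not the
  exact minimizer of summed correlation distance (that would be an
  eigen-profile), so the objective is monitored and the iteration stops
  if an update ever fails to decrease it — monotonicity is enforced,
  not assumed.
* **Initialisation**: distance-weighted random seeding (k-means++ style
  with $d = 1 - r$), best of 10 restarts by total objective,
  deterministic at a fixed seed.
* **Ties and degeneracies**: assignment ties go to the lowest cluster
  index; an emptied cluster is re-seeded with the point farthest from
  its centroid; two constant profiles are at distance 0 from each other
  (same shape after mean normalization) and at distance 1 from any
  non-constant profile.

`detect_threshold()` operationalises "expression becomes constant below
a threshold growth rate": for every interior condition it fits a
continuous flat-then-linear model in $\log_{10}\mu$, keeps the
breakpoint with the smallest SSE, and accepts it only if an F-test
(one extra parameter) beats a single straight line at $\alpha = 0.05$.
Flat and purely log-linear profiles therefore return "no threshold".

## Enrichment

Over-representation of an annotation set (size $K$) in a cluster
(size $n$) within a universe of $N$ analyzable genes — the genes that
survived preprocessing, not the whole genome — uses the exact
hypergeometric tail $P(X \ge k)$, computed in log space via
`stats::phyper` (the tests verify it against exhaustive enumeration of
all draws for $N \le 12$). The enrichment factor is the ratio
$(k/n)/(K/N)$. Raw p-values are thresholded at $10^{-6}$ by default,
with per-collection Bonferroni adjustment reported alongside.

Promoter motifs are written in the IUPAC alphabet (e.g. `TCGTTYAG`,
Y = C or T) and matched exactly — degenerate codes expand in the
pattern only, an `N` in a promoter is an unknown base and never
matches — on both strands by default over 800 bp upstream regions. The
motif enrichment factor is again the cluster/universe ratio of
promoter hit fractions, with hypergeometric significance on hit counts.
No position-weight matrices, background Markov models or motif
discovery: exact degenerate matching only.

## The synthetic-data generator

The generator exists so that every downstream stage can be scored
against known truth. It emulates the combined design of the study it
models: 22 arrays — chemostats at $\mu$ = 0.2, 0.1, 0.05, 0.03,
0.025 h$^{-1}$ with 3/3/2/3/3 replicates, plus retentostat days 2, 9,
16, 22 at $\mu \approx$ 0.0084, 0.0024, 0.0011, 0.00063 h$^{-1}$ in
duplicate. Its components:

* **Archetypes** (`default_archetypes()`): seven smooth shapes in
  $\log_{10}\mu$ — logistic rises and falls with configurable midpoint,
  width and amplitude, plus a near-zero-only Gaussian dip — standing in
  for the recurring growth-rate response classes (ribosomal-like rise,
  tRNA-synthetase-like fall to a plateau, glucose derepression,
  retentostat-specific shifts near 0.008 h$^{-1}$, a broad stress
  response). Logistic transitions were chosen because the described
  shapes are smooth monotone segments with plateaus; the data give
  shapes, not formulas.
* **Noise**: multiplicative lognormal with unit mean, CV 0.14 for
  responsive and null genes (typical replicate reproducibility of
  steady-state cultures) and 0.10 for housekeeping genes, which are
  expected to pass the CV < 0.20 stability criterion. Lognormal because
  intensities are positive and replicate scatter is ratio-scaled.
* **Trajectories**: viable biomass follows the ideal kinetic model;
  viability decays as $v(t) = v_\infty + (1-v_\infty)e^{-\lambda t}$
  with defaults $v_\infty = 0.8$, $\lambda = 0.005$ h$^{-1}$ (a
  stand-in consistent with roughly 80% viability after three weeks);
  measured total biomass is viable biomass divided by viability with
  2% lognormal measurement noise, and the exact $\mu(t)$ is recorded
  for recovery studies.
* **Gene sets**: planted sets sample members at configurable odds
  (default 8:1) from a target archetype; decoys sample uniformly.
* **Promoters**: i.i.d. bases at GC 0.38 (yeast-like). The planting
  probabilities are target *hit rates*: because an 800 bp random
  sequence already matches an 8-mer degenerate motif spontaneously a
  few percent of the time, the stamping probability is calibrated
  against the realized spontaneous rate ($q = (p - s)/(1 - s)$) so the
  final hit fraction of each group matches its target. Spontaneous
  matches are never removed.

What the generator deliberately does **not** emulate: probe-level
physics (cross-hybridisation, scanner saturation), sequence-driven
probe effects, heteroscedasticity beyond the single CV, correlated
noise between genes, and real annotation structure (sets here are
random draws). Passing the planted-truth tests therefore demonstrates
that the statistics recover structure of the assumed form at realistic
noise levels — not that they are robust to every artefact of real
arrays.

## Problem sizes used by the tests

The test suite and acceptance script run at sizes chosen to make the
statistical checks sharp while keeping a full run in the tens of
seconds: 20 random parameter sets for the kinetic oracle; 100 replicate
trajectories for $\mu$ recovery (median relative error at day 22,
bound 25%); 500 null genes × 1000 permutations for test calibration;
five replicates of 2000 genes (400 responders at 3× noise sd) pooled
for sensitivity/FDR — pooling because a single 1600-null draw leaves
the FDR estimate a standard error of ~0.009, a third of its distance
to the bound; 100 genes for clustering recovery and a 12-gene instance
for the exhaustive k-means optimum; 2000 promoters of 800 bp for the
motif enrichment factor.

## Known limitations

* The kinetic fit attributes the $A e^{Bt} + C$ shape to *total*
  biomass, but when viability declines the total-biomass curve is the
  ideal solution divided by $v(t)$ and is no longer exactly
  exponential; the fit is then an approximation whose $\mu$ estimate at
  day 22 carries a few percent of systematic error (well inside the
  25% recovery bound, but not zero).
* Permutation p-values have resolution $1/(B+1)$; with the default
  $B = 1000$ the smallest q-values are bounded accordingly, and very
  small printed q thresholds are only meaningful for much larger $B$.
* k-means with a correlation distance and mean-based centroids has no
  global optimality guarantee; restarts mitigate, and cluster
  memberships near boundaries remain initialisation-dependent in
  principle.
* The EF has no variance attached; its hypergeometric p-value is the
  significance statement.
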