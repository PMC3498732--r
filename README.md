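# nearzero

Physiology and gene expression of microbes at **near-zero specific
growth rates**, as studied in glucose-limited retentostat cultures.

A retentostat is a chemostat whose effluent is removed through a
filter, so biomass is fully retained. At a fixed glucose supply the
accumulating biomass drives the specific growth rate μ asymptotically
towards zero — cells all but stop dividing yet stay metabolically
active, fed just enough to cover maintenance. `nearzero` is for
researchers analysing such experiments (or the combined
chemostat + retentostat designs built around them): it turns
biomass/viability time series into growth-rate and glucose-flux
estimates, and expression matrices into growth-rate-dependent gene
sets, profile clusters and enrichments.

## What it computes

**Kinetics.** Biomass accumulation under ideal retentostat conditions
obeys dC·x/dt = Y·sx·max (D(C·s,in − C·s) − m·s C·x), whose solution is
C·x(t) = C·x,∞ + (C·x,0 − C·x,∞)e^(−kt) with k = m·s·Y·sx·max and
C·x,∞ = D(C·s,in − C·s)/m·s. Measured total biomass is fitted with
A·e^(Bt) + C by Nelder–Mead least squares; since only viable cells
replicate (and assuming no lysis), μ(t) = (dC·x/dt)/(v(t)·C·x(t)) with
v(t) the measured viable fraction. Glucose is partitioned between
maintenance (m·s·C·x,viable) and growth (μ·C·x,viable/Y·sx·max).

**Expression statistics.** Global scaling of each array to a mean
target intensity of 300, flooring at 12, discarding genes never
reaching 20, ORF selection, and mean-normalized condition profiles.
Growth-rate dependence is tested per gene by a natural-cubic-spline
F-statistic in log10(μ) with a column-permutation null (add-one
estimator, same permutations for all genes) and Storey q-values.
Significant genes are clustered by k-means under the
positive-correlation distance d = 1 − r (k = 7 by default, ≤ 1000
iterations); clusters are tested for gene-set over-representation by
the exact hypergeometric tail and for promoter-motif enrichment by
IUPAC scanning (e.g. `TCGTTYAG`) with the enrichment factor
EF = (cluster hit fraction)/(universe hit fraction).

**Synthetic data.** A first-class generator emulates the 22-array
combined design (chemostat μ ∈ {0.2, 0.1, 0.05, 0.03, 0.025} h⁻¹,
retentostat days {2, 9, 16, 22} ≈ μ {0.0084, 0.0024, 0.0011,
0.00063} h⁻¹), with seven planted profile archetypes, 14% replicate
CV, stable housekeeping genes, planted annotation enrichments, planted
promoter motifs and model-consistent biomass/viability trajectories —
so every stage of the pipeline can be scored against known truth.

## Worked example

```r
library(nearzero)

p <- retentostat_params()     # anaerobic glucose-limited defaults
p
#> Retentostat parameters
#>   D        0.025 h-1
#>   Cs_in    50 g/L   Cs 0 g/L
#>   ms       0.5 mmol/g/h (0.09008 g/g/h)
#>   Ysx_max  0.097 g/g
#>   Cx0      3.594 g/L

# a simulated 22-day run: noisy total biomass + declining viability
sim <- generate_retentostat_series(p, noise_cv = 0.02, seed = 7)
fit <- fit_biomass_curve(sim$series)
fit
#> Cx(t) = -14.34 * exp(-0.005791 t) + 18.15   (sse 0.639, converged)

prof <- specific_growth_rate(fit, sim$series)
last <- prof[prof$time_h == 528, ]
doubling_time(last$mu)        # 2528 h at mu = 2.74e-4 /h
glucose_partition(p, last$cx_viable, last$mu)$frac_maintenance  # 0.97
```

By day 22 the culture grows at a few 10⁻⁴ per hour — doubling times of
thousands of hours — and ~97% of the glucose goes to maintenance, the
signature of the near-zero-growth regime.

```r
# full pipeline on synthetic data: simulate -> preprocess -> test ->
# cluster -> enrich -> kinetics
report <- run_pipeline(run_config(outdir = tempfile(), seed = 42,
                                  n_permutations = 200,
                                  n_genes_per_archetype = 60,
                                  n_housekeeping = 30, n_null = 400))
report
#> nearzero pipeline report (seed 42)
#>   significant genes: 459 / 850
#>   cluster sizes: 60, 86, 77, 121, 59, 28, 28
#>   final mu 0.000198 /h (doubling time 3506 h), maintenance fraction 0.98
```

The 420 planted responders dominate the 459 significant calls, the
seven clusters track the seven planted archetypes, and every
intermediate (expression, clean matrix, test results, clusters,
centroids, enrichments, motif EFs, growth profile) is written as TSV
under the output directory, with a JSON report. `inst/scripts/nearzero.R`
wraps the same pipeline for shell use.

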