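# hybridclines

Bayesian genomic-cline analysis of admixed populations: locate genomic
regions of **restricted introgression** — candidate genomic
incompatibilities or targets of selection against foreign ancestry — from
genome-wide biallelic genotypes of hybrids and reference samples of the two
ancestral source populations (S0 and S1).

The package is written for population geneticists working on hybrid zones
or admixed domesticated populations. It takes a multi-sample VCF and an
ADMIXTURE-style Q matrix, and produces per-locus cline parameters,
steep-cline variant calls, pooled candidate regions, and the downstream
association statistics, all as tibbles that compose with the tidyverse.

## The model

Each individual has a hybrid index $h \in [0,1]$, the proportion of its
genome inherited from S1. At a locus with cline steepness $v$ and centre
$c$, an allele copy carried by an individual with hybrid index $h$ is of S1
ancestry with probability

$$\phi(h; v, c) = \mathrm{logistic}\big(v\,[\mathrm{logit}(h) - \mathrm{logit}(c)]\big),$$

and, conditional on ancestry, is the focal allele with the source-specific
frequency $p_1$ or $p_0$. The neutral cline is $v = 1$, $c = 0.5$
($\phi = h$); $v > 1$ marks restricted gene flow and a shifted centre marks
introgression biased towards one ancestry. Both parameters are estimated
per locus by MCMC on the latent scale ($\ln v$, $\mathrm{logit}\,c$), each
locus is additionally fitted under the reduced neutral model
($v$ fixed at 1), and the two fits are compared by WAIC:
$\Delta\mathrm{WAIC} = \mathrm{WAIC}_{\mathrm{full}} -
\mathrm{WAIC}_{\mathrm{reduced}}$, negative values supporting non-neutral
steepness. **Steep-cline variants (SCVs)** satisfy $\ln v > 2.3$ (i.e.
$v > 10$) and $\Delta\mathrm{WAIC} < -10$; SCVs within 50 kb of each other
are pooled into candidate regions (minimum 10 variants).

A hybrid-zone simulator with known per-locus truth
(`simulate_dataset()`) backs the whole validation suite.

## Worked example

Simulate a small hybrid zone with a cluster of 20 barrier loci
(true $\ln v = 2.7$, centre 0.4) and run the analysis:

```r
library(hybridclines)
library(dplyr)

cfg <- sim_config(
  n_s0 = 50, n_s1 = 50, n_test = 150, n_loci = 400,
  chrom_layout = list(list(chrom = "chr1", n_loci = 400, spacing_bp = 5000L)),
  freq_model = list(p0_range = c(0, 0.05), p1_range = c(0.95, 1)),
  barrier_spec = list(list(frac = 0.05, lnv = 2.7, centre = 0.4,
                           clustered = TRUE)),
  missing_rate = 0.02, seed = 2026)
sim <- simulate_dataset(cfg)
sim
#> <hz_sim> 250 individuals (50 S0, 50 S1, 150 test), 400 loci, 20 barrier loci

sf <- estimate_source_freqs(sim$genotypes, sim$assignments)
retained <- filter_ci_overlap(sf$freqs)
#> filter_ci_overlap: retained 400 of 400 loci.

h_fit <- esth(sf$genotypes, retained, sim$assignments, seed = 1)
glance(h_fit)
#> # A tibble: 1 × 7
#>   n_samples n_loci  nitt burnin  seed min_ess mean_accept
#>       <int>  <int> <dbl>  <dbl> <int>   <dbl>       <dbl>
#> 1       250    400  2000   1000     1    69.2       0.443

full    <- fit_clines(sf$genotypes, h_fit, retained, sim$assignments, seed = 2)
reduced <- fit_clines(sf$genotypes, h_fit, retained, sim$assignments,
                      fix_v = TRUE, seed = 3)
cline_tbl <- tidy(full) |>
  left_join(compare_models(full, reduced), by = "locus_id")

scv <- identify_scv(cline_tbl)   # ln v > 2.3 and delta-WAIC < -10
scv |> select(locus_id, lnv_mean, c_mean, delta_waic, centre_class)
#> # A tibble: 9 × 5
#>   locus_id    lnv_mean c_mean delta_waic centre_class
#>   <chr>          <dbl>  <dbl>      <dbl> <chr>
#> 1 chr1_5000       2.37  0.403      -145. S1_biased
#> 2 chr1_10000      2.63  0.407      -151. S1_biased
#> 3 chr1_15000      2.35  0.406      -124. S1_biased
#> 4 chr1_30000      2.32  0.402      -158. S1_biased
#> 5 chr1_35000      2.61  0.403      -144. S1_biased
#> 6 chr1_40000      2.60  0.406      -146. S1_biased
#> 7 chr1_55000      3.14  0.393      -129. S1_biased
#> 8 chr1_65000      2.58  0.391      -129. S1_biased
#> 9 chr1_100000     2.42  0.415      -135. S1_biased

pool_regions(scv, min_variants = 5)   # default minimum is 10 at genome scale
#> # A tibble: 1 × 7
#>   region_id chrom start    end n_scv mean_lnv centre_class
#>   <chr>     <chr> <int>  <int> <int>    <dbl> <chr>
#> 1 REG_0001  chr1   5000 100000     9     2.56 S1_biased
```

Every variant called at this desk scale sits inside the simulated barrier
cluster (positions 5–100 kb), the estimated centres (~0.40) recover the
simulated introgression bias towards the S1 allele, and pooling recovers
the cluster as one candidate region. At this small panel size
hybrid-index noise attenuates steepness, so the weakest cluster members
stay below the stringent thresholds — the vignette discusses this effect
and the panel sizes at which the validation suite verifies >80% detection
power.

`run_pipeline(run_config(...))` chains every stage (including the optional
variant-effect, FST and recombination statistics) from file inputs and
writes TSVs, a BED of regions and a manifest; `autoplot()` methods plot
hybrid indices and cline steepness along the genome; `compare_approaches()`
reports SCV/region overlap between two runs (e.g. alternative S1 source
choices).

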