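---
title: "QTL mapping in four-way cross populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL mapping in four-way cross populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourwayqtl)
library(dplyr)
```

## The four-way cross design

A four-way (double) cross starts from four inbred parents A, B, C and D:
two single crosses A×B and C×D are made, and their F1 hybrids are
intercrossed. Every resulting individual carries one allele from {A, B}
(transmitted by the first single cross' meiosis) and one from {C, D} at
each locus, so a locus has up to four distinguishable genotype classes —
AC, AD, BC, BD. Relative to a biparental cross, four alleles segregate at
once, and a locus has three estimable genetic contrasts instead of one.

Writing $\mu_1,\dots,\mu_4$ for the genotypic values of AC, AD, BC and BD,
the effects are quarter-contrasts:

$$a_F = \tfrac14(\mu_1+\mu_2-\mu_3-\mu_4), \quad
  a_M = \tfrac14(\mu_1-\mu_2+\mu_3-\mu_4), \quad
  d   = \tfrac14(\mu_1-\mu_2-\mu_3+\mu_4).$$

$a_F$ is the additive effect of the first single cross (A vs B), $a_M$ of
the second (C vs D), and $d$ the dominance between the two single crosses.
`effects_from_means()` and `means_from_effects()` implement this exact
linear bijection.

```{r}
effects_from_means(32.49, 31.10, 33.44, 33.10)
```

### Family means halve the dominance

When lines are phenotyped as selfed-progeny family means (the usual way to
replicate an outbred F1 across environments), a heterozygous locus
contributes through its 1:2:1 selfing ratio: the family mean is
$\tfrac14(\mu+a) + \tfrac12(\mu+d) + \tfrac14(\mu-a) = \mu + d/2$. The
additive effects survive intact; the dominance effect is halved. The
simulator therefore generates phenotypes directly at the family-mean scale
with $d/2$ in the genetic value, which is exactly what the downstream
analysis observes; `selfed_family_mean()` exposes the identity.

## Marker information categories

With SSR-style markers, the four parents need not carry four
distinguishable alleles. Which parents share alleles determines a marker's
information category, and the five usable patterns are:

| category | confounding | observable classes |
|----------|-------------|--------------------|
| `ABCD`   | none        | AC, AD, BC, BD |
| `A=B`    | A and B share an allele | only C vs D (codes `-C`, `-D`) |
| `C=D`    | C and D share an allele | only A vs B (codes `A-`, `B-`) |
| `A=CB=D` | A≡C and B≡D | AC, BD, and the merged class {AD, BC} |
| `A=DB=C` | A≡D and B≡C | AD, BC, and the merged class {AC, BD} |

`classify_marker()` rejects every other pattern (monomorphic markers,
`A=B` and `C=D` simultaneously, three parents sharing an allele) because
those segregate informatively in neither single cross.
`collapse_observed()` is the deterministic projection from latent ordered
genotypes to observed classes; its preimages partition the four classes,
which the test suite asserts for every category.

## Recombination fractions with partial information

For two markers, the latent state is a pair of haplotype transmissions in
each of the two meioses: 16 equally structured configurations whose
probabilities are $\tfrac14 (1-r)^{2-k} r^k$, with $k$ the number of
recombinant meioses. The same recombination fraction is used for both
meioses (a sex-equal assumption; the analysis estimates a single $r$ per
pair). Observed-class probabilities are sums of latent probabilities
through both markers' code tables, and `estimate_rf()` maximises the
resulting multinomial log-likelihood over $r \in [0, 0.5]$ by bounded
scalar optimisation (`optimize()`), with the boundary points checked
explicitly so that perfect cosegregation returns exactly $\hat r = 0$.

Two markers are jointly informative only if at least one meiosis is
visible at both: an `A=B` marker (maternal information only) paired with a
`C=D` marker (paternal only) has a likelihood that is constant in $r$.
Such pairs are flagged `estimable = FALSE` — detected numerically by
comparing the log-likelihood at $r = 0.1$ and $r = 0.4$ — and carry no
estimate. The linkage LOD reported for estimable pairs is
$[\ell(\hat r) - \ell(0.5)]/\ln 10$.

## Marker ordering and map building

Markers are anchored to chromosomes by an anchor table (physical-map
anchoring is the expected workflow; `group_markers()` offers de novo
single-linkage grouping at LOD ≥ 3 as a diagnostic). Within a chromosome,
ordering is an open travelling-salesman problem minimising the sum of
adjacent recombination fractions (SARF). `order_markers()` builds a greedy
nearest-neighbour tour from every possible start and polishes each with
2-opt segment reversals (first improvement, deterministic scan order,
ties broken towards the lexicographically smallest marker sequence), which
makes the result reproducible run to run. For eight or fewer markers the
result provably matches exhaustive enumeration in the test suite.

Distances for pairs that are individually inestimable are completed
before the tour search: on a linear map, for a third marker $k$ outside
the interval $(i,j)$, $|d_{ik} - d_{jk}| = d_{ij}$ exactly, so a missing
entry is filled by distance subtraction through the nearest informative
marker (smallest $d_{ik}+d_{jk}$), falling back to shortest chains where
even that is impossible. Completion by shortest path alone was rejected:
an adjacent but mutually uninformative pair can only be detoured around,
which inflates rebuilt chromosome lengths by tens of percent, whereas
subtraction keeps rebuilt 25-marker chromosomes within a few percent of
their true length in simulation.

Positions accumulate through the map function (`build_map_positions()`),
Haldane by default — $d = -50\ln(1-2r)$ — with Kosambi selectable
throughout; nothing in the data dictates one, and Haldane matches the
no-interference meiosis model of both the simulator and the QTL
probability calculations. `subset_map()` produces the two single-cross
maps (the AB map cannot contain `A=B` markers, nor the CD map `C=D`
markers), and `map_summary()` reports lengths, category tallies and the
mean interval, defined as total length over (markers − chromosomes).

## Inclusive composite interval mapping

`icim_scan()` implements the two-step ICIM strategy, which separates
cofactor selection from interval mapping.

**Step 1 — background control.** Each marker is encoded
(`encode_design()`) as three regressors: $x_F \in \{-1,0,+1\}$ for the
paternal haplotype, $x_M$ for the maternal one, and $z$ for their
interaction, with 0 wherever the haplotype is unobservable and, for the
merged classes of the cross-confounded categories, the within-class
expectation ($z = -1$ for {AD, BC}, $z = +1$ for {AC, BD}). Under this
coding the regression coefficients of a fully informative marker are
exactly $a_F$, $a_M$ and $d$ — the coding makes the field's effect
definitions the regression parameters, which is why it was chosen.
`stepwise_select()` then runs two-threshold stepwise regression over all
marker variables with entry and removal probabilities 0.001 and 0.002
(the reference operating point), each variable entering independently.

**Step 2 — scanning.** The genome is walked at 1 cM (configurable). For
each interval the phenotype is adjusted by subtracting fitted cofactor
contributions, excluding every variable belonging to the flanking markers
or to any marker within 10 cM of the interval (a standard CIM exclusion
window; scan results are insensitive to moderate changes because the
flanks themselves are always excluded). At each position,
`qtl_class_probs()` gives each individual's four genotype-class
probabilities: paternal P(A vs B) from the paternal information of the two
flanks under no interference, maternal P(C vs D) likewise, multiplied
because the meioses are independent. Merged-class codes contribute no
haplotype information at this step (their paternal/maternal coupling is
deliberately not exploited; it degrades the flanks gracefully rather than
biasing them). `em_fit_scanpoint()` fits a four-component normal mixture
with common variance and individual-specific priors by EM: means
initialised from probability-weighted class means, variance from the
total variance, tolerance $10^{-6}$ on the log-likelihood, at most 100
iterations (non-convergence returns the last iterate with a warning), an
empty component's mean tied to the overall mean, and the EM monotonicity
guarantee asserted at every iteration. The statistic is
$\mathrm{LOD} = (\ell_1 - \ell_0)/\ln 10$ against a single-normal null —
three free contrasts, hence 3 degrees of freedom for thresholds — and PVE
is $100\,(1 - \hat\sigma^2_1/\hat\sigma^2_0)$ against the null variance
of the adjusted phenotype at that position. Because the adjusted
phenotype has background variance removed, PVE values are explained
shares of the *adjusted* variance and run higher than shares of raw
phenotypic variance; they are comparable across positions within a scan
but are not calibrated against any external PVE convention.

QTL are called at local LOD maxima at or above the threshold; two maxima
are considered distinct QTL only when separated by at least 20 cM or by a
LOD valley at least 1 below the lower peak. This peak-separation rule is
an operational choice — one QTL per clearly separated LOD hill — not a
statement about the underlying genetics.

The phenotype entering a scan is the per-line mean across whatever
replicates and environments are supplied (`env = "mean"`), or a single
environment via `env = "E1"` etc.; lines with missing phenotype are
dropped listwise for that scan.

## Genome-wide thresholds

`lod_threshold_formula()` converts a genome-wide error rate into a
per-test rate through an effective number of independent tests,
$M_{\mathrm{eff}} = 0.072 \times \text{genome length (cM)}$, and returns
$\chi^2_{\alpha_p}(3) / (2\ln 10)$. The 0.072 density factor is
appropriate for marker spacing near 10 cM and is exposed as an argument
rather than recomputed, since denser maps behave as more tests per cM. At
the reference genome length of 1799.03 cM and $\alpha_g = 0.05$ this
gives a threshold of 3.97.

A calibration caveat that our own simulations make explicit: the
pointwise null distribution of the scan LOD matches
$\chi^2(3)/(2\ln 10)$ essentially exactly (through the 99.9th
percentile), but a dense 1 cM-step scan makes more effective excursions
than $0.072$ per cM — on 60-marker, 570 cM null maps the formula
threshold delivers a genome-wide error nearer 0.09–0.10 than 0.05,
implying roughly 0.15 effective tests per cM for this statistic, whether
or not the markers are fully informative. The permutation threshold
(below) correctly absorbs this, sitting a few tenths of a LOD above the
formula value even for exactly normal phenotypes; treat the formula as a
fast reference point and permutation as the calibrated default where
error control matters.

`lod_threshold_permutation()` shuffles the phenotype against genotype
rows, re-runs the entire scan — including cofactor selection, a
conservative and self-contained choice — and returns the empirical
$(1-\alpha_g)$ quantile of the genome-wide maximum LOD, storing all
maxima for audit. Permutation preserves the trait distribution: for a
clearly non-normal trait the shuffled data are not a credible no-QTL
normal sample, and the permutation threshold runs above the normal-theory
formula value. The test suite demonstrates both the agreement on normal
data and the excess on skewed data.

## Variance components and heritability

`anova_components()` fits the fixed-effects ANOVA with environment,
replicate-within-environment (the randomised-complete-block structure per
location), genotype and genotype×environment terms, and equates observed
to expected mean squares:
$\hat\sigma^2_e = MS_\varepsilon$,
$\hat\sigma^2_{ge} = (MS_{ge}-MS_\varepsilon)/r$,
$\hat\sigma^2_g = (MS_g - MS_{ge})/(er)$. Block variance is removed by
the replicate term and its remainder stays in $MS_\varepsilon$, because
the heritability formula used downstream has no block term. Negative
estimates are truncated at zero and flagged rather than propagated.
Entry-mean heritability is

$$H = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_e/(er)},$$

with the single-environment reduction $\sigma^2_g/(\sigma^2_g +
\sigma^2_e/r)$ when the interaction is not separable. Method-of-moments
was chosen over REML deliberately: it is exactly the estimator implied by
the $H$ formula, it is exact on noise-free balanced data (asserted in the
tests), and it keeps the estimator analytically checkable.

```{r}
heritability(29.0, 5.1, 10.7, e = 2, r = 3)
```

`describe_phenotypes()` summarises line means per environment and
combined; `test_normality()` wraps the Shapiro–Wilk test used to annotate
scans with the permutation caveat above; and `nil_contrast()` analyses a
near-isogenic-line pair at a validated locus — effect as the absolute
difference of pair means, significance by a two-sample t-test on the
replicate values at the 0.01 level (the conventional marking for such
validation tables; no specific test is dictated by the design).

## The simulator and what it does (and does not) emulate

`sim_map()`, `study_qtl_effects()` and `sim_cross()` generate populations
with the structure the analysis assumes, calibrated by default to a real
maize four-way study design: 277 lines, 221 SSR markers on 10 chromosomes
(25, 28, 25, 25, 21, 19, 18, 17, 25, 18 per chromosome), a 1799.03 cM
genome at a uniform 8.53 cM mean spacing, the study's per-chromosome mix
of the five information categories, phenotypes over 2 environments × 3
replicates with $\sigma^2_{ge} = 5.1$, $\sigma^2_e = 10.7$, a population
mean of 33.2 and environment offsets of ±5.1 trait units (degrees of leaf
angle in the motivating design; $\sigma^2_e$ is the plot-level residual
consistent with the published $H = 0.87$ at those design constants, and
includes the plants-per-plot averaging). The default QTL set carries the
study's 14 reported loci at their printed positions and effect signs,
rescaled by one common factor so the closed-form genetic variance —
per-locus $a_F^2 + a_M^2 + (d/2)^2$ plus linkage covariances
$2[a_Fa_F'\rho + a_Ma_M'\rho + \tfrac{dd'}{4}\rho^2]$ with
$\rho = 1-2r$ — equals the published $\sigma^2_g = 29.0$
(`expected_genetic_variance()` implements the algebra and the tests check
it against brute-force simulation).

Meiosis is simulated without interference under the chosen map function,
one independent meiosis per single cross with a common $r$ per interval.
Missingness is uniform at random per (individual, marker) at a default
2% — the real pattern of failed SSR calls is unknown, so nothing more
structured is attempted. What the simulator deliberately does *not*
emulate: segregation distortion, genotyping error (as opposed to
missingness), selfing-generation residual heterozygosity within family
lines, spatial field trends, interference, and sex-specific recombination.
Passing tests therefore certify the statistical machinery under the
stated model, not robustness to those artefacts of real data.

```{r}
map <- sim_map(seed = 1)
map_summary(map)$overall
pop <- sim_cross(map, study_qtl_effects(29.0), n = 120, seed = 7)
glance(anova_components(pop$phenotypes))
```

## Numerical choices and degenerate inputs

* Likelihood maximisation for $\hat r$: `optimize()` on $[0, 0.5]$ at
  tolerance $10^{-8}$, with both boundaries evaluated and preferred when
  they dominate (so cosegregation returns exactly 0). Class probabilities
  are floored at $10^{-300}$ inside logs.
* $\hat r \ge 0.5$ never enters a map: distances cap the estimate just
  below 0.5; `map_distance(0.5)` itself is an error (infinite distance).
* Ordering is fully deterministic: fixed scan order in 2-opt, all
  nearest-neighbour starts, lexicographic tie-breaks, orientation
  normalised by the terminal marker names.
* EM: individual priors with zero mass everywhere would make the model
  undefined; at least 20 individuals with positive mass are required.
  Scan positions exactly on a marker use that marker plus the next flank
  (the zero-distance flank dominates); single-marker chromosomes are
  scanned at the marker alone.
* ANOVA requires near-balance; missing cells trigger a warning and
  sequential-sums method-of-moments rather than silent renormalisation.
* All file outputs round to 2 decimals in report tables while
  full-precision companions are written alongside.

## Problem sizes used in the test suite

The packaged checks run the full chain at the study scale where that is
what is being claimed — 277 lines and the 221-marker map for variance
components and scan power (20 replicates each) — and at reduced but
structurally faithful scale elsewhere: a 3-chromosome, 60-marker, 570 cM
map at 10 cM spacing (the density for which the default effective-test
factor is stated) for the 200-replicate null false-positive study and
the 200-permutation threshold comparisons, and 4–8 marker instances for
the exhaustive ordering oracle. These sizes were picked so each property
is tested at the smallest scale at which it is scientifically
meaningful.

## Known limitations

* QTL analysis is single-environment (or environment-mean); no
  multi-environment joint model, no epistasis scan, and no bootstrap
  confidence intervals for QTL position.
* Two-point ordering cannot fully resolve very close or weakly
  informative markers; orders are SARF-optimal for the estimates at hand,
  which at 8.5 cM spacing and n = 277 typically means a small number of
  local inversions relative to truth.
* The mixture likelihood treats merged-class codes as flank-uninformative
  during scanning; their (small) paternal–maternal coupling information
  is used in cofactor encoding but not in the interval probabilities.
* PVE is defined against the adjusted-phenotype variance (see above) and
  should not be compared numerically against PVE conventions defined on
  raw variance.
* The density factor 0.072 is a maps-like-this constant, not a universal
  law; for substantially denser maps a permutation threshold is the safer
  default.
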