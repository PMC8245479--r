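---
title: "Genomic selection across harvests: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection across harvests: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harvestgs)
```

## The problem

Perennial crops such as *Jatropha curcas* need several harvest seasons
before phenotypic selection becomes reliable, which makes each breeding
cycle long and expensive. Genome-wide selection (GWS) predicts each
individual's genetic merit from a dense panel of SNP markers instead of
waiting for repeated phenotypes, and so can shorten the cycle — typically
by half — at the cost of some selection accuracy. `harvestgs` implements
the full analysis chain used to evaluate that trade-off in a breeding
population measured over repeated harvests: marker quality control,
RR-BLUP genomic prediction with REML variance components, k-fold
cross-validation, the derived selection statistics (accuracy, implied QTL
number, required population size, efficiency versus phenotypic selection),
and cross-harvest model-transfer validation.

Because trial data of this kind are rarely public, the package also ships
a synthetic breeding-population generator whose defaults emulate the
structure of a realistic perennial trial: 386 progeny from crosses among
42 parents, 811 SNPs, grain yield over three harvests in a randomized
block design with six replicates and narrow-sense heritabilities around
0.18–0.25.

## The model

For one harvest, phenotypic records follow the mixed linear model

$$y = X\beta + Za + \varepsilon,$$

where $y$ holds the plot records, $X\beta$ the fixed effects (intercept
and block), $Z$ the standardized marker dosages (one row per record, one
column per marker) and $a$ the random marker effects with
$a \sim N(0, I\sigma^2_m)$, $\varepsilon \sim N(0, I\sigma^2_e)$. With
$n$ markers the total genetic variance is $\sigma^2_g = n\sigma^2_m$.
Effects solve Henderson's mixed-model equations

$$\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + I\lambda \end{bmatrix}
\begin{bmatrix} \hat\beta \\ \hat a \end{bmatrix} =
\begin{bmatrix} X'y \\ Z'y \end{bmatrix},
\qquad \lambda = \frac{\sigma^2_e}{\sigma^2_g / n},$$

and genomic estimated breeding values are $\hat g_j = \sum_i Z_{ij}\hat
a_i$. This is ridge regression on the markers; it is numerically
identical to GBLUP with genomic covariance $ZZ'\sigma^2_m$, an identity
the test suite asserts to $10^{-6}$ on dense random instances.

### REML by spectral decomposition

Variance components are estimated by REML, profiling the single ratio
$\theta = \sigma^2_e/\sigma^2_g$. Writing $K = ZZ'/n$ with eigenvalues
$d_i$, the profiled restricted likelihood depends on $\theta$ only
through weighted least squares in the eigenbasis, so the optimization is
one-dimensional. The implementation obtains the non-null spectrum from
`eigen(Z'Z)` (an $n \times n$ problem rather than one in the number of
records) and handles the directions orthogonal to the column space of
$Z$ — which carry residual variance only — in closed form. This makes a
fit on 2,300 plot records with 800 markers take well under a second.

Numerical choices:

* the ratio is optimized on the log scale over $[10^{-8}, 10^8]$ with
  `optimize()` at tolerance $10^{-10}$; a solution at the boundary (pure
  noise, or noise-free data) is flagged in the returned object rather
  than treated as an error, since it is the correct REML answer for
  degenerate data;
* the profile evaluations are kept as a trace in the result for
  inspection;
* eigenvalues below $10^{-10}$ of the largest are treated as null;
* if the genetic variance collapses to exactly zero the ridge is
  infinite and the fit degenerates, by construction, to ordinary least
  squares with all marker effects zero.

### Marker standardization

Dosages are imputed by the marker mean and each column centered and
scaled to unit variance. The scaling uses the population variance
(divide by $n$); this is a pure convention, fixed so that the
RR-BLUP/GBLUP equivalence is exact, and switchable via
`standardize_markers(var = "sample")`. Standardization parameters are
frozen from the training individuals and applied unchanged to validation
or newly genotyped individuals — the cross-validation engine never lets
validation rows influence the scaling, and a dedicated test demonstrates
that "leaky" all-data scaling produces different out-of-fold predictions.

## Marker quality control

Markers are excluded on two rules: call rate $\ge$ 0.95, and minor
allele frequency strictly above a threshold. The default threshold is
the population-size critical level

$$\mathrm{MAF}_{crit} = \frac{1}{\sqrt{2N}},$$

which at $N = 386$ equals 0.036 (0.04 at two decimals). The strict
inequality for MAF and the closed inequality for call rate follow the
usual reporting conventions ("MAF > 4%", "call rate = 95%"). A fixed
threshold (e.g. `maf_min = 0.04`) can be supplied instead, since trial
reports often round the formula value before applying it. A marker
failing both rules is counted under both in the QC report, so the
failure counts can legitimately exceed the number of markers removed.

## Cross-validation and predictive ability

Tenfold cross-validation partitions the individuals into balanced,
non-overlapping folds (sizes differing by at most one; for 386
individuals, six folds of 39 and four of 38). Within each fold the model
is trained on the other nine tenths — variance components re-estimated
from scratch, standardization frozen from the training rows — and the
held-out individuals are scored, so each individual receives exactly one
out-of-fold GEBV. The predictive ability $r_{yg}$ is the Pearson
correlation between out-of-fold GEBV and the observed individual means
across blocks. One repetition of the tenfold split is the default;
`repetitions` averages over independent splits. A marker that happens to
be monomorphic within a training fold carries no information there and
is dropped for that fold only.

Phenotypes can enter as raw plot records with block fixed effects (the
default) or as individual means with an intercept only (`aggregate =
"means"`); trial reports rarely state which aggregation was used, so
both are first-class.

## Derived selection statistics

* **GWS accuracy**: $r_{g\hat g} = r_{yg}/\sqrt{h^2_a h^2_g}$, which
  treats the genomic heritability as the fraction of heritability the
  marker panel captures. Because $r_{yg}$ is computed against entry
  means, the heritabilities in the denominator are taken on the
  entry-mean scale, $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e/r)$ with
  $r$ records per individual; using the single-record value would push
  the ratio above 1 for any replicated trial. The single-record
  heritability is reported alongside (`h2_record`). Values above 1 —
  still possible with noisy inputs — are clamped with a warning.
* **Genomic heritability** $h^2_g$ defaults to $h^2_a$ (with purely
  marker-based variance components the two ratios coincide) and can be
  supplied externally when an independent estimate of the
  marker-captured fraction exists.
* **Implied QTL number**: $n_{qtl} = (1-q)\,N h^2_g / q$ and its inverse
  **required population size** $N_i = q\, n_{qtl} / ((1-q) h^2_g)$. The
  `scale` flag sets $q = r$ (`"reliability"`, default) or $q = r^2$
  (`"accuracy"`). The default follows the odds structure of published
  required-population tables, whose within-column ratios (e.g.
  $2788/207 = 13.47$) match $q/(1-q)$ scaling with the tabled accuracies
  entering as $q$ directly; `"accuracy"` implements the printed formulas
  literally. Both interpretations satisfy the exact round-trip identity
  $N_i(r; n_{qtl}(r, N)) = N$, asserted over a parameter grid.
* **Phenotypic accuracy**: $r_{y\hat y} = \sqrt{1 - \mathrm{PEV}/
  \sigma^2_g}$, with PEV the prediction-error variance of individual
  genetic-value BLUPs, computed exactly from the marker-effect block of
  the inverse mixed-model coefficient matrix
  ($\mathrm{PEV}_j = \sigma^2_e\, z_j' C^{aa} z_j$) and averaged over
  individuals.
* **Efficiency and IRPS**: $\mathrm{eff} = (r_{g\hat g} T_f)/(r_{y\hat y}
  T_{GWS})$ and $\mathrm{IRPS} = (\mathrm{eff}-1)\times 100\%$, where
  $T_f$ and $T_{GWS}$ are the phenotypic and genomic cycle lengths. Only
  their ratio matters (asserted by test); the default $T_f = 2\,T_{GWS}$
  encodes the usual halving of the cycle by selecting at the seedling
  stage.

## Cross-harvest transfer

To ask whether a model trained at harvest $i$ still ranks individuals
correctly at a later harvest $j$, marker effects are estimated on
harvest-$i$ phenotypes inside the same k-fold machinery, and the
out-of-fold GEBV are correlated with the individuals' estimated breeding
values (EBV) at harvest $j$. EBV are genomic-relationship BLUPs from the
full harvest-$j$ data — the package has no pedigree beyond the parent
count, so pedigree BLUP is not an option; block-adjusted phenotypic
means are available as an alternative target. With $i = j$ and a
phenotype target the computation reduces exactly to the within-harvest
cross-validation, which is asserted to $10^{-12}$. Training may pool
several harvests (`train_harvest = c(1, 2)`).

## The synthetic population generator

The generator emulates the data-generating process the analysis assumes,
with every default chosen once to match a realistic perennial breeding
trial:

* **Genotypes.** Parent genotypes are drawn from Hardy–Weinberg
  proportions at allele frequencies uniform on
  $[\mathrm{maf\_floor}, 1-\mathrm{maf\_floor}]$ (default floor 0.05);
  progeny arise by Mendelian gamete sampling under a round-robin crossing
  plan (parent $i$ with parent $i{+}1$, progeny spread as evenly as
  integer division allows — trial descriptions typically state only the
  parent count, so the plan is the simplest balanced one). Loci are unlinked:
  linkage disequilibrium arises from family structure only, which is what
  ridge-regression prediction exploits. Calls are masked missing at 2%
  by default so QC has something to do.
* **Phenotypes.** A random subset of markers (default 400 of 811) is
  causal; effects are drawn per marker from a multivariate normal across
  harvests with correlation matrix `genetic_corr`, so the same
  individuals' breeding values are genetically correlated between
  harvests. Default correlations are 0.3 between harvest 1 and the later
  harvests and 0.8 between harvests 2 and 3 — young plants still growing
  express their potential poorly, so early-harvest models should transfer
  badly and late-harvest models well. Residual variance is scaled per
  harvest so the narrow-sense heritability of single plot records equals
  its target (defaults 0.18/0.19/0.20); the heritability denominator
  excludes block variance because blocks are design fixed effects removed
  by the model. Block effects (SD 10 g/plant, roughly the genetic SD)
  are drawn once per harvest × block; harvest means default to
  173.76/760.85/1075.52 g/plant, the yield progression typical of a
  maturing perennial. One record is emitted per individual × harvest ×
  block, leaving any aggregation to the analysis.

What the generator does *not* emulate: genetic maps and local linkage,
dominance and epistasis, genotype-by-block interaction, spatial field
trends, selection or attrition between harvests. Passing tests therefore
demonstrate correctness of the machinery under the stated model, not
robustness to those real-data features.

A note on calibration checks: the realized genetic correlation between
harvests in any single simulated population deviates from `genetic_corr`
by sampling noise from both the finite number of causal effect draws and
the family structure (roughly ±0.05–0.1 even at 2,000 progeny), so the
calibration tests assert the match on means across seeds rather than
pretending a single replicate is exact.

## Problem sizes used by the test suite

The suite was sized to exercise every claim at meaningful scale while
staying fast: algebraic identities on 50 × 100 dense instances at
tolerances $10^{-8}$/$10^{-6}$; REML heritability recovery at 1,000
individuals × 500 markers × 20 seeds per target (targets 0.20 and 0.25,
mean error bound 0.05); transfer monotonicity across genetic
correlations {0, 0.3, 0.6, 0.9, 1} with 12 paired seeds per level on
240-progeny populations; and one full trial-scale end-to-end run (386 ×
811 × 3 harvests, tenfold CV) which completes in well under a minute.

## Known limitations

* $h^2_g$ cannot be separated from $h^2_a$ with marker-based components
  alone; it is a user input whenever that distinction matters.
* The accuracy rescaling $r_{yg}/\sqrt{h^2_a h^2_g}$ is undefined for
  zero heritability and can exceed 1 under sampling noise; the clamp is
  reported, and the efficiency/required-population formulas are
  evaluated just inside the open unit interval when it triggers.
* Only additive effects are modelled end to end; traits with strong
  non-additive architecture will show optimistic within-harvest accuracy
  relative to reality.
* Transfer validation targets EBV, which are themselves model estimates;
  with very low heritability the target is noisy and transfer accuracy
  correspondingly unstable.
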