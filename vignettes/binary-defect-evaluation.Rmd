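---
title: "Single-step genetic evaluation of binary morphological defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genetic evaluation of binary morphological defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defectEval)
```

## The problem

Morphological defects in beef cattle — malformed feet and legs, deviated
muzzle (chamfer), hump and loin irregularities, jaw abnormalities,
depigmentation, pendulous navel — are recorded as binary presence/absence
scores at low prevalence (typically 4–8%). Routine genetic evaluation of
such traits poses three linked methodological questions that this package
implements end to end:

1. **Model choice.** A *linear* animal model fits the 0/1 record directly
   and estimates variance components on the *observed* scale; a
   *threshold* (probit liability) model posits a latent normal liability
   that crosses a fixed threshold, and works on the *liability* scale.
   Both are fitted here by Gibbs sampling with a single-step relationship
   matrix combining pedigree and SNP information.
2. **Scale comparability.** Observed- and liability-scale heritabilities
   differ systematically for binary traits; the Dempster–Lerner conversion
   $h^2_o = z^2 h^2_l / (\alpha(1-\alpha))$ (with $t = \Phi^{-1}(1-\alpha)$
   and $z = \varphi(t)$) makes them comparable.
3. **Interpretability.** Breeding values on either estimation scale are
   hard to communicate; mapped to the *probability* of expressing the
   defect, $P_i = 1 - \Phi\big(t - (U_i - \mu_U)\big)$, they have a direct
   management meaning.

## The models

Both models share the structure $y = X\beta + Za + e$ (liability
$l = X\beta + Za + e$ for the threshold model), where $\beta$ are
contemporary-group (CG) effects with a vague normal prior (variance
$10^{10}$), and $a \sim N(0, H\sigma^2_a)$ are additive genetic effects.
$H^{-1}$ is the single-step matrix
$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{bmatrix}$,
with $A$ the pedigree numerator relationship matrix (tabular method with
inbreeding), $A_{22}$ its genotyped block, and
$G = ZZ' / (2\sum_i p_i(1-p_i))$ the allele-frequency-centred genomic
matrix. Before inversion $G$ is blended with $A_{22}$
($G_b = 0.95\,G + 0.05\,A_{22}$) to guarantee invertibility; the weight is
a configuration knob, 0.95 being standard single-step practice.

The Gibbs sampler uses single-site updates for $\beta$ and $a$, latent
truncated-normal draws for the liabilities of the threshold model (defect
records above the threshold, others below), and scaled-inverse-chi-square
full conditionals for the variance components. Identification of the
threshold model fixes the residual variance at 1 and the threshold at 0;
the threshold location is absorbed by the CG effects, so a separate $t$
would not be identifiable. Truncated normals are drawn by inverse CDF in
the body of the distribution with an exponential-rejection fallback in
the far tail, which keeps the sampler stable when fitted values are many
residual SDs from the threshold.

### Priors, defaults, and a known small-data pathology

Variance components get flat scaled-inverse-chi-square priors
($\nu = -2$, scale 0) by default; the CG-effect prior variance is
$10^{10}$. These are assumptions exposed as arguments of `model_spec()`,
not estimates. With a single binary record per animal, flat variance
priors, and *small* data sets (a few hundred records), the threshold
model's additive variance can drift upward essentially without brake:
the truncation likelihood saturates once every record is fitted on its
correct side, and only information from discordant relatives restrains
the drift. This is a property of the posterior, not of the sampler; at
the problem sizes used for parameter recovery here (3,000 animals in
three generations) the chains are stable and the truth is recovered. The
test suite exercises the pathological regime only with variances held
fixed.

### Chain lengths

The package defaults are desk-scale: 50,000 iterations, 10,000 burn-in,
thinning 50 (800 retained draws). Production evaluations of this kind
run into the hundreds of thousands of iterations; all lengths are plain
arguments. Convergence support follows common practice for these
evaluations: Geweke window comparison and Heidelberger–Welch
stationarity/halfwidth checks (both with batch-means spectral standard
errors), plus shortest-interval 95% HPD summaries. No numeric
convergence threshold is enforced — the diagnostics are advisory, with
$|z| < 2$ the conventional reading.

## Scale machinery

* `h2_liability_to_observed()` / `h2_observed_to_liability()` implement
  the Dempster–Lerner conversion and its exact inverse; the round trip is
  the identity to machine precision, and $h^2_o < h^2_l$ strictly for all
  $\alpha$ because $z^2 < \alpha(1-\alpha)$.
* Two observed→liability GEBV rescalings are provided. The
  *variance–heritability* adjustment divides by the observed-scale
  residual variance and the heritability-ratio complement; its flattened
  printed form admits two algebraic readings
  ($BV_o/\sigma^2_{e_o} \times (1 - h^2_o/h^2_l)$ versus
  $BV_o / (\sigma^2_{e_o}(1 - h^2_o/h^2_l))$), so both are implemented
  (`parse = "product"` default, `parse = "ratio"`); both are linear, so
  downstream rankings are identical. The *threshold-density* adjustment
  divides by $z^* = \sqrt{(h^2_o/h^2_l)\,\alpha(1-\alpha)}$; the square
  root is the only reading under which $z^*$ equals the normal ordinate
  $\varphi(t)$ whenever $h^2_o$ and $h^2_l$ are Dempster–Lerner
  consistent — which is exactly what the adjustment's name promises.
* `gebv_to_probability()` anchors the reference mean $\mu_U$ at the mean
  GEBV of all evaluated animals, so the average animal maps to
  $P = \alpha$ exactly. The transform is implemented in the orientation
  where the probability of *presenting* the defect increases with the
  liability GEBV; the reflected form (decreasing in the GEBV, as
  sometimes printed) is available via `orientation = "printed"`. The
  residual SD defaults to 1, the liability-scale identification.

## The synthetic-population generator

`simulate_population()` emulates the statistical structure the analysis
assumes, not any particular herd:

* discrete non-overlapping generations; monogamous random pairing, each
  pair leaving `offspring_per_mating` offspring — the simplest scheme
  with controllable size;
* infinitesimal-model breeding values: founders $N(0, h^2_l)$,
  descendants midparent plus a Mendelian-sampling deviate with variance
  $\tfrac12 h^2_l (1 - (F_s+F_d)/2)$; total liability variance
  standardized to 1 so the simulated $h^2_l$ is directly comparable to
  threshold-model estimates;
* neutral biallelic SNPs gene-dropped from founder frequencies drawn in
  `maf_range` — markers carry relationship information only through
  family structure, matching the pedigree/genomic BLUP setting (no
  marker-effect architecture, no LD map);
* `n_cgs` management groups with normal effects; membership is
  randomized within each generation, so groups are independent of the
  genetics *and* every group spans the generations, which keeps the CG
  graph sire-connected under the connectedness check;
* the binary phenotype compares the CG-centred liability (breeding value
  plus residual) against $t = \Phi^{-1}(1-\alpha)$, so realized
  prevalence converges to the configured $\alpha$ regardless of the
  CG-effect spread — CG effects shift the stored liabilities but not the
  binary outcome, a deliberate simplification that keeps the simulation
  truth exactly on the nominal scale;
* a `prop_genotyped` random subset of animals carries genotypes,
  emulating partial genotyping.

What the generator does **not** emulate: selection and overlapping
generations, genotyping biased toward elite animals, LD and genotyping
error, classification noise in the visual scoring, or informative
CG–genetics association. Passing parameter-recovery tests on this
generator therefore demonstrates correctness of the machinery under the
model's own assumptions, not robustness to the many ways real defect
records violate them.

Default conditions mirror the published setting this package
re-implements: prevalence 4–8% (default 0.06), liability heritability in
the 0.18–0.54 range (default 0.35), CG-effect SD 0.25 on the liability
scale, 20% of animals genotyped.

## Quality control

The QC sequence is fixed: CG size ≥ 10 → phenotypic variability within
CG → CG connectedness → SNP filters. Connectedness is an internal
stand-in for the dedicated software used in production pipelines: CGs
are nodes, an edge joins two CGs sharing at least `min_links` sires of
phenotyped animals (weakest defensible rule as default; stricter values
exposed), and only the largest component is kept. SNP filters are the
published thresholds: 1-df Hardy–Weinberg chi-square $p < 10^{-15}$
(asymptotic test — an exact test would be noise at such a threshold),
call rate < 0.90, MAF < 0.02; an animal call-rate filter exists but is
off by default since only marker filters are specified for this kind of
pipeline. Missing genotypes surviving QC are mean-imputed ($2p_i$)
before $G$ is built, as the centring in $G$ requires complete gene
contents.

## Numerical choices

* $A^{-1}$ is assembled sparsely by Henderson's rules with inbreeding
  (Mendelian-sampling variance $1 - 0.25(a_{ss} + a_{dd})$), verified in
  the tests against dense inversion of the tabular $A$; sparsity is what
  lets the sampler visit non-genotyped animals cheaply.
* $G$, $A_{22}$ and their inverses are handled densely — genotyped sets
  at desk scale are small; the matrices are symmetrized after assembly
  to remove floating-point asymmetry.
* Allele frequencies default to those observed among genotyped animals
  (base-population frequencies are not available in the data this
  mirrors); `freq_source = "supplied"` overrides.
* Pedigree truncation keeps anchors (phenotyped and/or genotyped
  animals by default) plus 3 ancestral generations, recoding parents on
  the horizon as unknown.
* `select_top()` uses $k = \lceil 0.10\,n \rceil$: the ceiling is the
  only convention consistent with the full set of published
  selected-group sizes (804 sires → 81; nearest-rounding would give 80).
  Ties are broken by animal id for determinism. For defect traits the
  desirable direction is the *low* GEBV; the flag exists because the
  convention is a choice, not a law.
* HPD intervals are the shortest window containing
  $\lceil 0.95 n \rceil$ sorted draws (exhaustive scan).

## Problem sizes used in the tests

Closed-form and bookkeeping checks run on published counts and tiny
fixtures. Sampler validation uses a 40-animal fixture against the exact
mixed-model-equation solve (agreement within 3 Monte-Carlo SEs).
Parameter recovery uses 3,000 animals (1,000 founders, two further
generations), $h^2_l = 0.35$, $\alpha = 0.10$, 20% genotyped at 1,000
SNPs, 50,000-iteration chains — the scale at which the threshold model
is comfortably identified while a full linear + threshold pair of fits
completes in a couple of minutes. The HPD-coverage smoke test repeats
pedigree-only threshold fits over five seeds at the same population size.

## Known limitations

Single-trait models only (multi-trait defect models are notoriously
fragile for exactly the data structure simulated here; GEBV Pearson
correlations over a common sire set are provided as the standard proxy).
No REML, no marker-effect parameterizations, no metafounders or
unknown-parent groups, no sparse approximations of $G^{-1}$; dense
inversion bounds practical population sizes to roughly $10^4$ genotyped
animals. The connectedness check is a graph heuristic, not a full
genetic-link count. The probability scale is bounded and compresses
differences in the tails; ranking should be read from the liability
scale when in doubt — the two agree rank-for-rank by construction.
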