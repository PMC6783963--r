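---
title: "Methods: integrated diversity analysis of olive germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated diversity analysis of olive germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleadiv)
```

`oleadiv` analyses olive germplasm collections characterised on four
layers: projected coordinates, morphometric traits, fatty-acid profiles of
the oils, and codominant SSR genotypes. This vignette documents the models
and conventions behind each module, the tunable parameters that matter, the
synthetic-data generator the test suite relies on, and the limits of what
the passing tests demonstrate.

## Data model and conventions

Genotypes are two allele sizes (bp, positive integers) per sample and
locus. Pairs are stored sorted (a1 ≤ a2); a call with either allele blank
is missing for the whole locus, because a half-call cannot be distinguished
from a homozygote on a capillary trace. CSV readers sniff comma vs
semicolon separators and refuse decimal commas outright rather than
misparse. The wide, two-columns-per-locus layout is canonical (it matches
the GenAlEx convention most SSR tables use); a long layout is also read.
Dendrograms are exported as Newick under the ultrametric convention: each
leaf sits at depth half the root merge height, so a two-leaf tree merged at
h is `(A:h/2,B:h/2);`.

## SSR diversity statistics

Allele frequencies at a locus are counted over the 2N draws of the typed
samples. The package reports the GenAlEx-style pair of expected
heterozygosities: the biased `He = 1 − Σf²` and the small-sample-corrected
`uHe = 2N/(2N−1) · He`, printed as separate quantities because both are
standard in germplasm reports. Ne = 1/Σf² is the effective number of
alleles. The Brookfield estimator of the null-allele frequency,
`r = (He − Ho)/(1 + He)`, is the variant that does not require an observed
null-homozygote class; negative values (Ho > He) are clamped to 0, which is
the typical outcome at most loci of a diverse collection.

The Hardy–Weinberg test is a Monte-Carlo exact test: the statistic is the
conditional probability of the genotype array given the allele counts, and
the null is sampled by reshuffling the 2N-allele vector and re-pairing it.
Only the permutation-varying part of the probability (2^het / Π n_g!) is
evaluated, in log space. The p-value is `(1 + hits)/(n_perm + 1)`;
`n_perm = 100000` by default (the survey-scale choice), and the test suite
uses 300–20000 depending on the check. With a fixed seed the p-value is
bit-reproducible. A monomorphic locus returns p = 1 with a warning.

Pgen multiplies `f²` (homozygous) or `2ff′` (heterozygous) factors over the
sample's non-missing loci; loci missing for the sample contribute factor 1
and are listed. Frequencies are pooled over the whole table by default,
with a per-site option, since reports commonly quote Pgen ranges per
collection site without fixing the pool.

Clone (multilocus genotype) grouping compares samples at the loci typed in
both, with two knobs: `max_mismatch_loci` (default 0) and
`allele_tolerance_bp` (default 0). Somatic variants of a vegetatively
propagated genet typically differ by 2–3 bp, so tolerance 2 is the natural
setting for clone hunting. Matching within tolerance is not transitive;
groups are the connected components of the pairwise relation, which is the
permissive convention and is stated here because two genuinely distinct
genets can occasionally fall within tolerance and merge.

## Genetic distances and clustering

The binary allele matrix has one column per (locus, allele); a homozygote
sets one column, a heterozygote two; the columns of a locus missing for a
sample are masked NA, never 0. Dice–Sørensen similarity
`s = 2a/(2a + b + c)` is computed over mutually unmasked columns
(pairwise-complete loci), so a sample typed at only two loci is still
placeable. The genetic distance is `d = √(1 − s)` by default — the
Euclidean-embeddable transform customary with Dice similarity — with
`transform = "linear"` giving plain `1 − s`; both are provided because
printed formulas in the area are often ambiguous between the two.
Dendrograms use Ward.D2 (Lance–Williams update on squared dissimilarities,
heights on the original scale), which is monotone on metric input;
identical profiles merge at height 0.

Evanno ΔK takes externally produced admixture log-likelihood runs (the
admixture MCMC itself is out of scope) and computes
`ΔK = |L̄(K+1) − 2L̄(K) + L̄(K−1)| / sd(L(K))` for interior K, flagging
zero-sd K as undefined rather than dividing by zero. Hard assignment from a
Q-matrix takes the arg-max column, breaking ties toward the lowest index
with a warning. Partition agreement is the adjusted (Hubert–Arabie) Rand
index.

## Nonparametric trait statistics

The group-comparison pipeline mirrors standard practice when normality
(Shapiro–Wilk) or homoscedasticity (Levene, mean-centred as originally
defined; a median-centred flag gives Brown–Forsythe) fails: Kruskal–Wallis
with tie correction, then the Siegel–Castellan pairwise post-hoc on mean
ranks with the Bonferroni-type critical value
`z(α/(k(k−1))) · √((N(N+1)/12)(1/nᵢ + 1/nⱼ))`. α = 0.05 throughout by
default. Raw per-variable results are reported; an optional flag adds a
Bonferroni column across variables, since multiplicity handling across a
table of 13 traits is a reporting choice, not part of the test.

The MUFA/PUFA ratio uses the chemical classification MUFA = {C16:1, C17:1,
C18:1, C18:1t, C20:1}, PUFA = {C18:2, C18:3}; saturated acids are excluded.
Samples with zero PUFA are flagged infinite and excluded from summaries.
Note that the mean of per-sample ratios is not the ratio of mean
compositions; both are meaningful, and the package computes the ratio on
whatever matrix it is given.

## PCA, PAM and model selection

PCA is centred and, by default, unit-scaled — fatty-acid variables span
trace (<0.1%) to dominant (~80%) abundances, and unscaled PCA would be a
palmitic/oleic axis only. Missing values are refused, not imputed. The sign
of each component is fixed by making its largest-magnitude loading
positive, so results are deterministic across platforms.

PAM is the BUILD+SWAP k-medoids algorithm; on small instances it attains
the exhaustive optimum (property-checked in the tests over random draws).
The gap statistic compares log within-cluster dispersion (squared-distance
form) against B = 50 reference draws, uniform over the observed per-feature
ranges — the simpler of the two reference schemes, adequate for
2-dimensional PC scores. k is chosen by the firstSEmax rule (smallest k
within one simulation SE of the first local maximum), a conservative
reading of "where the gap levels off". Silhouette widths use the standard
(b − a)/max(a, b) with singletons assigned 0.

## Distance integration

Geography (UTM metres — Euclidean on easting/northing is the point of
using a projected CRS) and morphometrics use Euclidean distance;
morphometrics are left in raw units by default (a z-scaling flag exists
because g, cm and cm² are heterogeneous). Fatty acids use Canberra
distance, `Σ |x−y|/(x+y)` with 0/0 terms contributing 0 — implemented
directly because the common library convention rescales the sum when such
terms are dropped, which is not the behaviour wanted here: an acid present
at 0.1% in one sample and absent in the other should contribute a full
unit, making structural-zero acids geographic bio-markers. SSR uses the
Dice–Sørensen distance above.

The Mantel statistic is the Pearson correlation of the n(n−1)/2
upper-triangle entries; significance is one-tailed for positive association
(the directional question these surveys ask), permuting rows and columns of
the second matrix jointly, `p = (1 + hits)/(n_perm + 1)`. For n ≤ 8 an
exact mode enumerates all n! permutations. The 6-pair descriptor report is
seeded and bit-reproducible; a genets-only subset (members of clone groups
of ≥ 4 trees) supports the clone-restricted comparison.

## The synthetic generator

`default_sim_config()` emulates a four-site survey: OIR (48 trees), OSE
(26), CE (62), CM (33); site centroids 20–40 km apart with 1.5 km isotropic
spread; six SSR loci whose allele pools and whole-collection frequencies
are the published reference inventory (9–13 alleles per locus, 64 in
total); per-site frequency profiles derived deterministically by boosting a
site-specific quarter of each pool (×6) and renormalising; clone fraction
0.55 (about 45% unique genotypes, as observed in such collections), with
clone copies carrying ±2 bp somatic variants at rate 0.1 per allele and
shifts clamped to the pool; per-call missing rate 0.01; trait means and sds
equal to the published site values, with structural-zero acids held at
exactly 0, noise truncated at 0, and each profile renormalised to the site
mean total. Pool alleles that a finite draw misses are planted as single
copies in uncopied genets, mirroring the singleton alleles real
collections carry; the realised inventory therefore equals the configured
one. Everything is a deterministic function of one seed.

What the generator does **not** emulate: linkage between loci, genuine
stepwise-mutation allele spectra, compositional covariance between acids
(noise is independent truncated Gaussian plus renormalisation, not
logistic-normal), environmental gradients within sites, and measurement
batch effects. Passing tests on this generator therefore demonstrate the
statistical machinery and its wiring, not field realism.

Two derived configurations serve the end-to-end checks.
`shared_fatty_profile = c("OIR", "OSE")` plants three biochemical profiles
across four sites; a perfect three-cluster solution against the four site
labels then caps the adjusted Rand index at 0.799 for these group sizes, so
tests expect k = 3 with ARI in (0.6, 1). Because cluster recovery at
published noise is genuinely stochastic, that property is asserted over
three replicate seeds (majority rule) rather than one draw.
`strong_separation_config()` is a planted stress condition, not a survey
emulation: the published OIR and OSE oil profiles genuinely overlap on the
first two PCs (which is why such surveys resolve three biochemical
clusters), so four-site recovery requires planting four distinct profiles —
site fatty-mean deviations from the grand mean are doubled (clamped at 0,
structural zeros kept) and trait noise is scaled to 0.3 of the published
sds. Under it, PAM on two PCs recovers all four sites (ARI ≥ 0.8) and the
geography–oil Mantel correlation is strongly positive.

## Numerical choices and degenerate inputs

Permutation p-values always use the add-one convention, so p ≥ 1/(n_perm+1)
and p > 0. HWE and Mantel comparisons use a 1e-9/1e-12 slack when counting
ties so that floating-point noise cannot flip a hit. Monomorphic loci,
constant vectors, all-tied Kruskal–Wallis inputs, zero-PUFA samples,
zero-variance columns under scaling, singleton silhouette clusters and
zero-sd Evanno runs all have defined, warned or erroring behaviour rather
than silent NaNs; the relevant tests pin each one. Problem sizes in the
test suite (169-tree simulations, 300–20000 permutations, B = 30–50 gap
references, 80–100 replicate HWE tables) were chosen to keep the full
suite under a minute on one core while leaving every stochastic assertion
comfortable margins.

## Known limitations

The HWE test reports raw per-locus p-values; sequential correction across
loci is left to the caller. The Mantel test is the plain two-matrix form
(no partial Mantel or correlograms). PAM is exact BUILD+SWAP, suitable for
collection-scale n (hundreds), not subsampled for very large n. The
admixture model itself is never fitted — only its outputs are
post-processed. Shapefiles are not read or written; points export to
GeoJSON in the coordinates given.
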