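---
title: "Methods: multi-kingdom rumen community analysis under a diet shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-kingdom rumen community analysis under a diet shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenshift)
```

## The design and its statistical consequences

The package targets a two-period crossover: every animal is sampled under a
non-grazing diet (`CON`, ryegrass hay plus concentrate) and again under a
grazing diet (`PAS`, ryegrass pasture). Each sample carries per-kingdom
taxon read counts (bacteria, methanogens, fungi; protozoa as optically
counted percentage compositions of four groups) and a fermentation profile
(pH; ammonia-N in mg/L; total VFA in mM; eight VFA molar proportions in %
summing to ~100; lactate in mM; the D/L lactate ratio; protozoal
concentration in log10 cells/mL).

Two consequences of the pairing run through every method:

1. **Per-taxon inference.** The repeated-measures model
   Y = mean + diet + animal + error, with animal random, has — in a
   complete two-level design — a diet contrast that is *identical* to the
   paired t-test on per-animal differences. `paired_diet_test()` and
   `group_summary()` therefore compute the paired test directly: SED is
   the standard error of the differences, p is two-sided, and any
   animal-specific constant is absorbed exactly (a tested invariant).
2. **Permutation inference.** Free relabelling would break the animal
   stratification, so `permanova()` permutes by swapping the two diet
   labels *within* each animal. In a one-factor paired design this
   restricted scheme coincides with permutation of residuals under the
   reduced model. With n paired animals there are 2^n distinct
   relabellings; the implementation enumerates them exhaustively whenever
   that is cheaper than the requested number of random draws, making the
   permutation p exact. Only the permutation p is reported; no asymptotic
   Monte-Carlo p is attached to it.

## Normalization and transforms

Sequencing depth is equalized "to the lowest number of reads" by seeded
subsampling without replacement (`rarefy_to_min()`). Subsampling rather
than proportional scaling is the default because it preserves integer
counts, which Good's coverage needs (the singleton count F1 is meaningless
on scaled data); proportional scaling is available via
`normalize_table(method = "scale")`. Abundances are analyzed as
log10(count + 1): the pseudocount of one maps absence to zero and keeps
the transform strictly monotone, and base 10 keeps per-taxon values on the
familiar "logs of reads" scale. Presence is strict (`count > 0`) wherever
prevalence is computed.

## Alpha diversity conventions

`alpha_panel()` fixes the conventions that make the five indices mutually
consistent: Shannon in nats, so that Pielou J = H/ln S is the matching
evenness; the Gini–Simpson form 1 − Σ p², so that very diverse communities
approach (not exceed) one; Good's coverage computed after rarefaction,
since coverage is a function of depth. Richness one yields an undefined
evenness, reported as missing. These choices are locked by tests on the
bundled reference panel: all six published (H, S, J) triples satisfy the
identity to within ±0.005.

## Ordination

`bray_curtis()` computes d(x, y) = Σ|x−y| / Σ(x+y) on the depth-normalized
counts. PERMANOVA partitions squared dissimilarities (SS_total from all
pairs over N; SS_within from within-diet pairs over group size) and reports
pseudo-F with (a−1, N−a) degrees of freedom. A descriptive per-diet
"similarity" is also reported as 100 × (1 − mean within-diet dissimilarity);
this is an interpretation of a common report format, not a test statistic.

`cca_fermentation()` delegates the canonical correspondence analysis to
vegan: chi-square standardization of the community, weighted regression on
standardized covariates, eigen-decomposition of the fitted part. The wrapper
adds strict input contracts (no missing covariate values; collinear columns
are an error naming the dependent ones, never silently dropped) and a
seeded marginal permutation test per covariate. Reported scores use
taxon-focused scaling (scaling 2). Total inertia equals the community
chi-square statistic divided by the grand total — a toy-table identity the
tests check to 1e-10 — and a constraint equal to the first unconstrained
axis reproduces that axis' eigenvalue.

## Association screens

Spearman correlations are computed with average ranks (tie-corrected) and
two-sided p from the t approximation t = ρ√((n−2)/(1−ρ²)), uniformly for
the fermentation screens and the network edges, so that the edge filter
behaves identically everywhere. Screens are within-diet only: correlation
structure is not assumed stable across diets, and pooling diets would
manufacture correlations from any shared diet response. Cells below
|ρ| = 0.30 are masked for display — the smallest magnitude worth reporting
at n = 24, where weaker correlations are indistinguishable from noise —
and the threshold is configurable. Taxa enter the per-taxon diet tests
only above a mean relative abundance of 0.05 % (configurable); below that,
log10(count+1) is dominated by discretization at these depths.

## Core microbiota and networks

A taxon is core under a diet when present in at least 95 % of that diet's
animals; the shared core requires both diets, and a diet-specific core
member reaches the threshold under exactly one diet. Summed mean relative
abundances report how much of the community each set represents.

Networks are built per diet across kingdoms: taxa present in more than half
of the diet's samples (strict), all-pairs Spearman on log10 abundances,
edges kept when |ρ| > 0.5 (strict) and the adjusted p is below 0.05.
Multiplicity adjustment spans all tested pairs and defaults to
Benjamini–Hochberg: with thousands of candidate pairs at n = 24, Bonferroni
admits essentially no edges, and BH is the accepted convention for
co-occurrence screens; Bonferroni remains one configuration flag away.
Protozoa enter as log10 cells/mL (group percentage × total concentration)
when a fermentation profile is supplied, since group percentages alone are
not comparable across samples of different total load. Nodes are the taxa
incident to at least one retained edge; betweenness is unnormalized
shortest-path counting with unit edge weights; "community contribution"
sums node taxa's mean relative abundances within their own kingdom (a
protozoa value near 90 % therefore means the counted groups in the network
dominate the *protozoal* community, not the whole ecosystem).

## Hydrogen stoichiometry

The VFA profile implies a metabolic hydrogen budget through per-acid
reducing-equivalent coefficients: H₂ (mM) = Σ coeffₖ · VFA · propₖ/100.
The default set {acetate 2, propionate 1, butyrate 4, valerate 2,
caproate 2, iso-acids 0} is the classical carbohydrate fermentation
balance; the branched-chain iso-acids arise from amino-acid skeletons and
carry no coefficient. This is the unique small-integer balance that
reproduces both bundled reference H₂ values (173 and 117 mM) from the
reference VFA means, which is how the default was fixed; the coefficients
are exposed as configuration (`stoich_coefficients()`).

## The synthetic generator: what it emulates, what it does not

`default_truth()` encodes the reference study conditions: 24 animals × 2
diets; 70/20/40 bacterial/methanogen/fungal genera with planted shared
cores of 34/9/13; 8 CON-specific and 10 PAS-specific bacterial taxa
(planted ≥ 95 % prevalence in the home diet, ≤ 40 % in the other, via a
±3 log10 diet effect); a tail of rare taxa; per-kingdom depths uniform in
10,000–15,000 / 900–1,300 / 7,100–10,700 reads (midpoints within a few
percent of the emulated platforms); protozoa as four groups around their
reference percentages; and fermentation covariates centred on the bundled
reference means with SED-derived noise.

The abundance model is log-normal/softmax: expected log10 score =
baseline + diet effect + module loading × latent factor + animal intercept
+ residual; the softmax of the scores is the sample's composition, and
reads are drawn multinomially at the sampled depth (depth is conserved
exactly). The animal intercept (sd 0.2 log10 per taxon) is shared across
diets, mirroring the random animal term; the residual sd is 0.2 log10.
Three 5-taxon correlation modules (one spanning bacteria, a methanogen and
a fungus) share unit-variance latent factors; loadings are derived from the
target correlation 0.9 as λ = σ√(ρ/(1−ρ)), with module members given lower
idiosyncratic noise (sd 0.1) — tightly co-varying guild members — so the
planted correlation is reachable without destabilizing the composition.
Module factors also drive lactate/butyrate, ammonia/propionate and total
VFA/acetate through a small coupling matrix, which is what gives the CCA
and the taxon–fermentation screens their signal. No published effect-size
distribution exists for the diet effects, so the planted ±0.25–0.5 log10
shifts on a subset of core taxa are an arbitrary, documented choice fixed
once.

The generator does **not** emulate: sequence-level artefacts (chimeras,
OTU clustering error), phylogenetic correlation, overdispersion beyond the
log-normal layer, thousands-of-OTU richness (richness here is tens of
genera per kingdom, so absolute richness values are not comparable to real
OTU tables even though richness *contrasts* behave correctly), or
compositional effects stronger than the planted modules induce. Passing
recovery tests therefore demonstrates that the *analysis chain* is correct
and calibrated under its own assumptions — not that real data satisfy
those assumptions.

## Numerical and degenerate-input choices

Near-zero-variance paired differences are classified by a relative
tolerance (1e-12): all-zero differences give p = 1; constant nonzero
differences are flagged `degenerate` with p reported at the double floor.
Constant vectors yield missing correlation cells rather than errors. A
simulated composition putting > 99.9 % of mass on one taxon aborts as
degenerate. Permutation p-values use a 1e-12 tolerance on F comparisons so
ties count as exceedances. Empty networks (fewer than two gated taxa, or
no surviving edge) return a flagged empty object rather than an error.
All serialized numbers carry six significant digits, edge lists are sorted
lexicographically, and every stage is seeded, so a report directory is
byte-reproducible from its config.

## Problem sizes in the test suite

The suite exercises the full reference condition (n = 24) where the claim
depends on it: exact core recovery over 50 simulated studies, module edge
recovery and spurious-edge rate over 100, paired-test calibration over 100
(≈3,000 tests), and PERMANOVA null uniformity over 200 small studies with
exhaustive (2^8) enumeration — sizes chosen to make the Monte-Carlo
assertions stable at fixed seeds while the whole suite stays fast.

## Known limitations

* The mixed model is implemented only as its paired equivalent; incomplete
  designs (animals missing one diet) are dropped from paired contrasts.
* CCA covariates must be supplied pre-selected; the eight molar proportions
  sum to 100 and cannot all enter together (the collinearity error says
  so explicitly).
* Compositional correlation estimators (SparCC-style) are out of scope;
  the network inherits the known biases of correlation on relative data.
* Between-diet "similarity" is a descriptive interpretation, as noted.
* Real-data surfaces that depend on deposited raw reads (absolute
  pseudo-F magnitudes, real core sizes and node/edge counts) are outside
  what synthetic recovery can certify.
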