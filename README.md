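# rumenshift

Multi-layer analysis of the rumen microbiota across a two-diet crossover —
typically a shift from a non-grazing diet (ryegrass hay plus concentrate,
`CON`) to grazing (ryegrass pasture, `PAS`) — spanning four microbial
kingdoms: bacteria, methanogenic archaea, anaerobic fungi, and protozoa.
It is aimed at rumen microbiologists and animal scientists who have
per-kingdom taxon count tables (or want realistic simulated ones) together
with rumen fermentation chemistry, and who want the full "systems" readout:
diversity, community structure, per-taxon diet responses,
taxon–fermentation correlations, core membership, co-occurrence networks,
and the metabolic-hydrogen budget implied by the VFA profile.

## What it computes

* **Depth normalization** — seeded rarefaction of each sample to the
  minimum observed depth (proportional scaling available), then
  log10(x + 1) abundances and per-sample relative abundances.
* **Alpha diversity** — richness *S*, Shannon *H* = −Σ pᵢ ln pᵢ (nats),
  Pielou evenness *J* = *H*/ln *S*, Gini–Simpson 1 − Σ pᵢ², and Good's
  coverage 1 − F₁/N, with paired CON/PAS summaries (mean, SED, p).
* **PERMANOVA** on Bray–Curtis dissimilarity
  d(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ), with pseudo-F =
  (SS_B/(a−1)) / (SS_W/(N−a)) and permutations that respect the
  repeated-measures design by swapping diet labels **within animal**
  (exhaustive enumeration of all 2ⁿ relabellings when feasible).
* **CCA** — canonical correspondence analysis of the chi-square
  standardized community against fermentation covariates, with seeded
  marginal permutation tests per covariate (via vegan).
* **Paired diet tests** — per taxon, the mixed model diet contrast
  (diet fixed, animal random) computed as its exact paired-design
  equivalent: a paired t-test on per-animal log10 abundance differences,
  with Bonferroni control across the kingdom and an abundance gate at
  mean relative abundance > 0.05 %.
* **Spearman screens** — within-diet rank correlations between taxon
  abundances and fermentation variables, reported at |ρ| ≥ 0.30.
* **Core microbiota** — taxa present in ≥ 95 % of animals under both
  diets (shared core) or under exactly one diet (diet-specific core),
  with the community fraction each set represents.
* **Co-occurrence networks** — per diet, all-pairs Spearman among taxa
  (pooled across kingdoms) present in > 50 % of animals; edges require
  |ρ| > 0.5 and Benjamini–Hochberg adjusted p < 0.05; node/edge counts,
  mean neighbors 2E/N, betweenness, and community contribution.
* **Hydrogen stoichiometry** — H₂ (mM) = Σₖ coeffₖ · VFA · propₖ/100 with
  reducing-equivalent coefficients {acetate 2, propionate 1, butyrate 4,
  valerate 2, caproate 2, iso-acids 0}, plus percent/fold-change helpers.
* **Synthetic data** — a seeded multi-kingdom generator with planted
  cores, diet-specific taxa, correlation modules, uneven depths and
  community-coupled fermentation chemistry, carrying its ground truth for
  recovery and calibration testing.

## Worked example

```r
library(rumenshift)

study <- simulate_study(n_animals = 24, seed = 1)   # 48 samples, 4 kingdoms
norm  <- lapply(study$tables, normalize_table, seed = 1)

diversity_summary(norm$bacteria, study$metadata)[, 1:5]
#>   variable mean_CON mean_PAS      SED p_value
#> 1 richness   49.125   50.125 0.803074  0.2256
#> 2  shannon    3.470    3.425 0.036523  0.2308
#> 3 evenness    0.891    0.875 0.009390  0.0968
#> 4  simpson    0.960    0.954 0.003625  0.0841
#> 5    goods    0.999    0.999 0.000067  0.2496

permanova(bray_curtis(norm$bacteria), study$metadata, n_perm = 999, seed = 1)
#> PERMANOVA (within-animal monte-carlo permutations, n = 999)
#>   pseudo-F = 19.902 (df 1, 46), p = 0.001
#>   group similarity (%): CON 59.5, PAS 61.3

core_partition(norm$bacteria, study$metadata)
#> core partition [bacteria] at prevalence >= 0.95
#>   shared core: 34 taxa (83.8% CON / 82.6% PAS of community)
#>   CON-specific: 8 taxa; PAS-specific: 10 taxa

build_network(combine_kingdoms(norm, study$fermentation),
              study$metadata, diet = "PAS")
#> co-occurrence network (PAS): 19 nodes, 33 edges (33+/0-)
#>   mean neighbors 3.47; kingdom contribution (%): bacteria 35.8, ...
```

The diet separates the communities sharply (pseudo-F ≈ 20 at the smallest
possible permutation p), the planted 34-genus bacterial core and the 8/10
diet-specific taxa are recovered exactly, and the network's 33 edges are
dominated by the three planted correlation modules. On the bundled
reference group means the hydrogen budget gives:

```r
ref  <- reference_group_means()
ferm <- ref[ref$block == "fermentation", ]
con  <- setNames(ferm$CON, ferm$variable)
pas  <- setNames(ferm$PAS, ferm$variable)
h2_production(con)                                  # 173.3 mM
h2_production(pas)                                  # 117.1 mM
percent_change(h2_production(pas), h2_production(con))  # -32.4 %
```

i.e. the grazing diet implies about a third less metabolic hydrogen,
driven by the lower fermentation rate and the propionate shift.

A whole run — simulation or your own tables, through every stage, into a
deterministic report directory with an MD5 manifest — is one call:

```r
run_all(list(out_dir = "report", seed = 42, simulate = list(n_animals = 24)))
```

or from a shell, `inst/scripts/rumenshift run-all --config config.yaml`.

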