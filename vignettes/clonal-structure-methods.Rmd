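---
title: "Detecting and dating clonal structure in microsatellite-genotyped stands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating clonal structure in microsatellite-genotyped stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In harsh treeline environments, many conifers reproduce vegetatively:
lateral branches pressed to the ground root and, once the connecting
tissue rots, become physically separate trees that share one genotype
(layering).  A stand of visually distinct individuals can therefore hide
a much smaller number of genetic individuals (genets), some of them very
old.  Given diploid microsatellite genotypes with GPS positions, plus
tree-ring counts along branch sections, this package answers three
questions:

1. Which individuals are clones of each other, allowing for the somatic
   mutations that accumulate during vegetative spread?
2. How much of the stand's recruitment is clonal rather than sexual?
3. How long ago did clonal ramets separate, given how fast branches grow
   laterally?

```{r}
library(genets)
```

## Clone detection

The genetic distance between two samples is the number of alleles not
shared between their diploid genotypes, summed over loci.  Per locus the
comparison is a multiset intersection, so the distance takes values 0, 1
or 2: a homozygote (a,a) against a heterozygote (a,b) counts 1, not 2.
Loci missing in either sample are skipped; pairs sharing fewer than
`min_shared_loci` typed loci (default 12 of 16) are flagged not
comparable and never enter clonal calls.  Missing loci are *not* counted
as differences — for clone calling this is the conservative choice, and
the flag keeps low-information pairs auditable rather than silently
dropped.

Identical multilocus genotypes (distance 0) are read as clones.
Distances of 1 to `somatic_threshold` (default 3) are read as clones
with somatic mutations: microsatellite mutation is stepwise and rare, so
a handful of one-step differences between large multilocus genotypes is
far more plausibly somatic than a sexual near-miss, which would require
an extreme coincidence across 16 multiallelic loci.  Clonal groups are
the connected components of the thresholded pair graph (single-linkage
transitive closure): a group may contain pairs at several difference
levels, exactly as mutation accumulating along a spreading front
produces.  Replicate samples from one individual are merged into one
node first; replicate pairs differing by 1–3 alleles are reported
separately as within-plant somatic mutations.

```{r}
sim <- simulate_population(simulation_config(seed = 1))
d   <- attach_geo_distances(pairwise_allele_distance(sim$table), sim$table)
net <- build_clonal_network(d, sim$table)
clonality_summary(net)
```

Two clonality statistics summarise the stand of `N` individuals with
`n_singletons` genotypes seen once and `n_groups` groups of two or more:

* clonal fraction `(N - n_singletons) / N` — the share of individuals
  sitting in clonal groups;
* clonal growth excess `(N - n_singletons - n_groups) / N` — the share
  of individuals attributable to clonal duplication beyond one founder
  per group.

The identity `excess = fraction - n_groups / N` holds exactly and is
property-tested.  Multilocus genotypes can be collapsed at tolerance 0
(`policy = "identical"`) or with somatic mutants merged
(`policy = "tolerant"`); the tolerant count equals
`n_singletons + n_groups` and can never exceed the identical-only count.

Censoring returns one representative per group — the sample with the
fewest missing loci, ties broken lexicographically by sample id — so
that population-genetic statistics are not pseudo-replicated by clones.
The choice is deterministic and data-quality-maximising; any other
representative rule changes results only through missing-data patterns.

## Population-genetic statistics

All statistics drop missing genotypes per locus (complete-case per
locus).  Per locus the package reports allele counts, observed
heterozygosity, Nei's unbiased expected heterozygosity
`H_E = (1 - Σp²)·2n/(2n-1)` (the small-sample correction is switchable
off via `unbiased = FALSE`, since published tables do not always state
which flavour they used), E5 evenness of the allele frequencies, and the
missing fraction.

Hardy–Weinberg departure is tested by Monte Carlo: the statistic is the
Pearson chi-squared distance between observed genotype counts and their
HW expectations, and the null re-pairs the pooled 2n alleles at random
(default 1000 permutations).  This permutation-of-alleles null is the
simplest construction that conditions on the observed allele counts; its
p-values are calibration-tested against uniformity under simulated HW
draws.  All permutation p-values use `(1 + k) / (n_perm + 1)`, which
cannot return zero.

F-statistics follow Weir & Cockerham (1984): per allele and locus the
among-population, among-individual and within-individual variance
components are accumulated, and `F_ST = Σa/Σ(a+b+c)`,
`F_IS = 1 - Σc/Σ(b+c)` are ratios of summed components — slightly
negative estimates are legitimate sampling noise around zero.  The
implementation is verified against a transliterated biallelic oracle and
against the limit cases (fixed populations give 1, a panmictic split
gives ≈ 0).

The index of association measures multilocus linkage disequilibrium:
with per-locus pairwise distances `d_j` and their sum `D`,
`I_A = Var(D)/Σ Var(d_j) - 1`, and the standardised
`rbarD = (V_O - V_E) / (2 Σ_{j<k} sqrt(Var d_j · Var d_k))`.  Loci are
independent under sexual recombination (`I_A ≈ 0`); clonal duplication
couples them.  The null permutes each locus's genotype column
independently across samples.  Missing per-locus distances are imputed
with the locus mean distance before the variance computation — a
neutral fill that leaves complete-data results untouched.  The
diagnostic triple the analysis relies on — I_A significant with all
individuals, weaker when clones are censored, non-significant once
somatic mutants are merged too — reproduces on synthetic stands.

## Growth rates and clone ages

A branch section's ring count is its age, so between two aged sections
the growth rate is `(pos₂ - pos₁) / (rings₁ - rings₂)` cm/yr.  Rates
are pooled per segment by default; `weighting = "per_branch"` averages
within branches first.  The spread is the sample standard deviation
(n−1).  Sections with equal ring counts span no measurable time and are
skipped with a warning; ring counts increasing toward the tip are a data
error.

Geographic distances are great-circle (haversine, WGS84 mean radius
6371008.8 m); at stand scale (< 2 km) this is exchangeable with a local
planar projection to well under 0.01 %.  Assuming a ramet reached its
position by lateral growth, the time since separation is
`age = distance × 100 / rate`.  Pairs farther apart than
`outlier_dist_m` (default 100 m) are flagged as putative transport
events (e.g. zoochory) and excluded from distance summaries, the 200-yr
age histogram and the quantile curve, but reported: observed stand
distances cluster well under 50 m, so any cutoff between that and the
kilometre scale makes the same split.  A group's age is the maximum
unflagged pair age within it, and one pooled regional rate is applied to
all pairs, mirroring how a single field-estimated rate would be used.
No halving correction for a vanished central parent is applied — when
the founder died midway between two surviving ramets, their pair
distance doubles the true spread path and the age is overestimated;
this is a documented bias, not a corrected one.

Two distance-decay regressions close the analysis: allele differences
against distance for non-clonal pairs (isolation by distance; pairwise
points are not independent, so a Mantel-style permutation p is available
next to the parametric F-test), and, within clonal groups holding at
least one somatic-mutation pair, the group's maximum-allele-difference
pair against its distance.  The alternative reading — the
maximum-*distance* pair per group — is exposed via
`max_rule = "dist"`.  The sexual regression defaults to pairs of the
clone-and-mutation-censored individuals so that clonal duplicates do not
leak into the sexual signal.

## What the generator emulates — and what it does not

`simulate_population()` encodes the processes the analysis assumes:

* Founder genets drawn in Hardy–Weinberg proportions from per-locus
  Dirichlet allele frequencies (16 loci, 8–36 alleles, concentration 1);
  defaults of 124 founders and Poisson(0.57) ramets per founder follow
  from the observed tallies (124 genotypes, ~70 clonal extras among 194
  individuals).
* Ramets placed at distance separation-age × 1.74 cm/yr, ages uniform
  on 0–2500 yr — the regional cooling horizon that plausibly opened the
  clonal-spread era.
* Stepwise ±1-repeat (2 bp) somatic mutations per allele copy per metre
  of spread (default 3 × 10⁻⁴/m, at which roughly a fifth of clonal
  separations carry a mutation, matching how rarely somatic variants
  are observed).  Mutation is parameterised per metre, not per year,
  because the observable is difference-versus-distance; a per-year mode
  would be an equivalent reparameterisation at constant rate.
* ~1 % of ramets displaced ~1 km with their genotype unchanged
  (transport), ~3.6 % missing genotypes per locus, 20 within-plant
  replicate samples, and an optional allele-frequency cline
  (`ibd_strength`) for isolation-by-distance tests.

The truth record stores each individual's genet, parent, separation age
and mutation count, so recovery is scored against known answers:
network components equal the true genet partition exactly whenever no
clone accumulates more than `somatic_threshold` mutations.

Branch sections grow at the configured rate perturbed by mean-preserving
lognormal branch noise (default cv 0.9, matching the wide observed
spread), are cut at 10-cm positions, and 2–4 sections per branch are
aged with ring counts rounded to years.  One honest caveat: under heavy
branch noise, branches too slow and short to yield two aged sections
cannot be measured at all, so the measurable-branch pool is biased
toward faster branches.  The pooled estimator is accurate for the
branches actually measured (within ~7 % on average), which is also all
a field campaign can see.

The generator does **not** emulate inbreeding or selfing (simulated
stands show H_O ≈ H_E, unlike the marked heterozygote deficits real
stands can display), pollen inflow from outside populations, spatially
autocorrelated microhabitat, allele-size homoplasy, or genotyping error
beyond missingness.  Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to those
real-data features.

## Numerical and design choices

* Distances and components are integer-exact; no floating-point
  thresholds enter clone calls.
* Permutation seeds: every stochastic stage takes an explicit seed, and
  `run_pipeline()` derives fixed offsets from one master seed, so a
  rerun is byte-identical (regression-tested on the full artifact set).
* Degenerate inputs: monomorphic loci report `H_E = 0`, evenness 1 and
  HWE p = 1; a locus typed in fewer than two populations is skipped for
  F-statistics with a warning; an all-identical table errors on the
  index of association ("no variance"); zero-age branch segments are
  skipped with a warning.
* Ties in the censoring representative and in the somatic-decay group
  maxima are broken deterministically (lexicographic id; larger
  distance).
* Problem sizes in the test suite (stands of 40–200 individuals, 500
  HWE calibration replicates at n = 100, 50 index-of-association
  replicates, 15 branch-noise replicates) were chosen as the smallest
  sizes at which the calibration statements are stable across seeds.

## Known limitations

* Clone calling is threshold-based, not probabilistic: no psex-style
  statistic guards against sexual near-duplicates, which matters only
  in stands with far lower marker diversity than the 16-locus panels
  targeted here.
* Age dating inherits every bias of a single constant growth rate:
  historically slower growth, rotted founders and transport all shift
  individual ages; only transport is flagged.
* The accession-scale reproduction of published tallies requires the
  deposited field tables; the package validates the machinery on
  accession-shaped synthetic data instead.
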