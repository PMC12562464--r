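---
title: "Screening Y-STR haplotype clusters for an old cross-population substrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening Y-STR haplotype clusters for an old cross-population substrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

When one population expands into the territory of another, the paternal
gene pool of the resulting population can retain lineages of the earlier,
autochthonous inhabitants. `strclock` operationalises the search for such a
substrate in Y-chromosome data: a lineage cluster is evidence of a shared
substrate when (1) it contains men from *both* present-day population
groups — the descendants of the newcomers and of the presumed
autochthonous population — and (2) its most recent common ancestor
predates the colonisation horizon. Everything in the package serves that
two-criterion screen: building haplotype phylogenies, dating their
clusters, and quantifying how much of each group's gene pool the flagged
clusters contain.

```{r}
library(strclock)
```

## Data model

A haplotype is a vector of integer repeat counts over a configurable
Y-STR locus panel. The default panel has 37 loci (the union of two
commercial typing kits plus eight additional markers, counting the two
copies of the duplicated markers DYS385 and DYF387S1 separately) and a
uniform average mutation rate of 0.0039 mutations/locus/generation; both
the marker list and the per-locus rates are plain-text configuration, not
code. Multi-copy markers are stored as sorted copy pairs: for an absolute
step-difference cost, comparing sorted copies *is* the minimum-cost
assignment between the two repeat multisets, so no separate matching step
is needed. Intermediate (non-integer) alleles such as "15.2" are treated
as missing at that locus, because a step metric is undefined for
fractional repeats; they are reported, never rounded. Loci missing in
either haplotype are skipped in distances, and the ASD clock rescales its
locus average to the compared loci only.

## Median-joining networks and parsimony trees

Within each Y-SNP-defined search group, haplotype phylogeny is represented
as a median-joining network: identical haplotypes collapse into nodes with
a sample multiplicity and per-population tally; an epsilon-relaxed minimum
spanning network connects the states; and consensus ("median") states of
MSN-connected triplets are inserted whenever they shorten the minimal
network, iterating to a fixed point before unused medians are discarded.
Defaults are epsilon 0 and a uniform locus weight of 10, the published
settings for this analysis. Median generation is restricted to
MSN-connected triplets — the feasibility rule of the published heuristic —
rather than the full quasi-median closure, which is exponentially larger
and adds nothing for the single-step data the pipeline targets.

The rho clock needs a tree, not a network, so reticulations are resolved
by taking a minimum-length spanning tree of the network's own edges with a
deterministic (length, then lexicographic label) edge ordering. A greedy
pass with that ordering provably attains the global minimum, and the test
suite confirms equality with exhaustive spanning-tree enumeration on small
reticulated instances. All tie-breaks throughout the package are
lexicographic on canonical node labels: two runs, or two orderings of the
input file, give byte-identical results. The resolution is a documented
reconstruction — the closed-source program used in the original analyses
does not publish its post-processing configuration — so topologies may
differ in ties while total lengths cannot.

The founder (root) of a cluster is the network node minimising the
multiplicity-weighted sum of distances to the cluster's members. When an
ancient sample sits within one mutation step of that optimum, it is
preferred as root: a sampled ancient chromosome is better direct evidence
of the ancestral state than an unobserved reconstruction.

## Two clocks, and why they disagree on old clusters

Both clocks assume the symmetric single-step mutation model (SMM) and
convert generations to years with a 31.5-year generation interval.

**ASD.** The average squared repeat difference between members and founder
has expectation mu·t per locus under SMM — exactly, including back
mutations — so ASD divided by the mean per-locus rate is an unbiased age
in generations. The standard error comes from a seeded bootstrap over loci
(default 1000 resamples), capturing locus-to-locus variance in accumulated
mutations. ASD is computed to the inferred founder, the convention of the
founder-based dating literature this pipeline follows; a founder-free
variant (half the mean pairwise ASD) is available behind a flag for
comparison.

**Rho.** The multiplicity-weighted mean number of mutations on the tree
path from root to each sample, divided by the total per-haplotype rate
L·mu, with the genealogy-based (Saillard-type) variance
sigma² = (1/n²)·sum over branches of m_b·n_b². The package reports
standard errors and labels them as such.

The two clocks are *not* expected to agree on old clusters, and the
package deliberately reports both. Rho counts net repeat changes on a
most-parsimonious tree; mutations that cancel (back mutations) or coincide
are invisible to it. Under SMM the per-locus net displacement is a signed
Poisson difference, whose expected absolute value falls below the expected
mutation count as mu·t grows: at mu = 0.0039 and 31.5 y/generation the rho
clock's expectation is ~94% of truth at 1000 YBP, ~89% at 2000 YBP and
~84% at 3000 YBP. ASD has no such saturation. The test suite checks ASD
for unbiasedness and checks rho against this closed-form expectation; on
real old clusters the same mechanism shows up as rho ages sitting below
ASD ages. Treating the *minimum* of the two point ages as the age
criterion in the screen is therefore the conservative choice: a cluster
passes only if even the saturating clock clears the horizon.

## The informative-cluster screen

Samples are partitioned into disjoint search groups by Y-SNP branch
(labels may be hierarchical, `"Z92>B03"`, with the part before `>` naming
the search group). Within a group, clusters are delimited by terminal SNP
label — the validated mode, since Y-STR clusters in this kind of data
correspond well to Y-SNP branches. For data without fine SNP typing the
package adds its own label-free mode: the parsimony tree is cut wherever
an observed-to-observed path (through sample-free median chains) exceeds
`cut_steps` mutations (default 3), and the components become clusters.
That mode is honest only when founders are separated by clearly more than
the cut and within-cluster diversity stays below the separation; the tests
exercise it with young, tight clusters at founder separation ≥ 6 steps.

A dated cluster is **informative** when every required population group
contributes at least one member and min(ASD age, rho age) exceeds the age
threshold (default 1000 YBP, the operational reading of "before the
colonisation"). Failures carry a reason (`single-group`, `too young`).
The screen is monotone: relaxing either criterion can only enlarge the
informative set. Membership summaries report, per group, the share of
haplogroup carriers inside informative clusters, and — when per-group
haplogroup frequencies are supplied — the population-level share, i.e.
carrier share × haplogroup frequency.

## Frequency statistics and maps

Haplogroup frequency tables are pooled by sample-size weighting
(sum n_i·f_i / sum n_i, printed at 1 d.p.), and pool-vs-split decisions
rest on Pearson chi-squared homogeneity tests without continuity
correction; haplogroup categories with any expected count below 1 are
merged into "other" first — our rule, stated because the source analyses
do not publish one. The frequency-table reader flags cells above 100%
(one such cell in the shipped regional table is a probable lost decimal
point) rather than guessing a correction.

Frequency surfaces use average-weighted (inverse-distance) interpolation
with the published parameters — a 400 km search radius and weight
1/d² — on a regular lat/lon grid with haversine distances (R = 6371 km).
A distance floor of half the grid spacing keeps coincident points finite;
the reference implementation's internal handling is unpublished, so the
floor is this package's choice. Grid cells with no observation in range
are NA, and interpolated values are provably bounded by the observed
range.

## The simulator and what passing tests mean

The generator is first-class code with known ground truth, not a fixture.
`simulate_star()` evolves n lineages independently from a founder for
round(T/31.5) generations; per lineage and locus the mutation count is
Poisson(mu·t) with a signed ±1 random walk — mathematically equivalent to
per-generation simulation for mu·t ≪ 1 and much faster; the exact
per-generation mode is kept behind a flag and tested against the shortcut.
`simulate_coalescent()` draws a Kingman tree (time unit 2·Ne generations,
so E[TMRCA] = 2·Ne at n = 2 — the haploid convention used here) and drops
Poisson mutations on branches. `simulate_region_scenario()` builds the
full study-shaped dataset: by default ~400 haplotypes in one
Slavic-labelled and three Finnic-labelled populations, 10 old mixed
clusters (true ages uniform on 1600–2900 y, sizes 8–45, spanning the
published cluster-size range), 2 young mixed decoys (300–600 y) and 2 old
single-population decoys, with founders at least 8 steps apart and
hierarchical SNP labels over five search branches. The acceptance suite
requires sensitivity ≥ 0.9 on the planted clusters and rejection of every
decoy over 50 seeds.

The simulator idealises: no multi-step mutations, no allele range
constraints, no population structure within clusters, star genealogies
for cluster growth (appropriate for expanding lineages, optimistic for
constant-size ones), and noise-free SNP labels. Passing tests therefore
demonstrate the correctness of the machinery under the model the clocks
assume — they do not certify rate calibration, genealogy shape or typing
error behaviour in real data.

## Numerical choices and reproducibility

Problem sizes in the shipped tests are chosen to keep the full suite in
the minutes range: 200 replicates for estimator-recovery checks, 50 seeds
for the scenario screen, 6-state instances for exhaustive oracles. All
randomness flows from explicit integer seeds; the ASD bootstrap seed is a
recorded parameter, and the pipeline derives per-cluster seeds
deterministically from the run seed, so reruns are byte-identical. Ages
are reported in years before present without a calibration offset —
"present" is simply the analysis date, as the convention in this
literature leaves the reference year undefined. Whether published ±
values are standard errors or wider intervals is likewise unstated there;
this package emits standard errors and says so.

## Known limitations

* The rho clock's homoplasy saturation (above) is inherent to counting
  net steps; for clusters older than ~2000 y, ASD should be treated as
  the primary clock and rho as a lower bound.
* Median-joining is a heuristic: it restricts medians to MSN-connected
  triplets and does not guarantee a globally minimal Steiner topology,
  though the tests confirm it never lengthens the network and attains
  brute-force optima on small instances.
* The subtree delimitation mode fails gracefully but inevitably when
  within-cluster diversity approaches founder separation; use SNP labels
  whenever available.
* A single average mutation rate is the published convention and the
  default; per-locus rates are supported but real panels mix loci whose
  rates differ several-fold, which widens true dating uncertainty beyond
  the reported bootstrap SE.

## A worked example

```{r, eval = FALSE}
sc <- simulate_region_scenario(seed = 42)
crit <- filter_criteria(list(Slavic = "Ryazan-Russian",
                             Finnic = c("Erzya", "Moksha", "Shoksha")),
                        min_age_ybp = 1000)
run <- run_pipeline(sc$haplotypes, crit, seed = 1)
run$cluster_table
run$summary
```

The cluster table mirrors the shape of a published dual-dating table
(branch, n, ASD age ± SE, rho age ± SE, informative flag with reason);
the summary gives per-group carrier shares. The README shows the actual
numbers this example prints.
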