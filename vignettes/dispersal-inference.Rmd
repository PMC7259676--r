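---
title: "Inferring dispersal from isolation by distance: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dispersal from isolation by distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(waspibd)
```

# The inference problem

Social wasps such as *Polistes fuscatus* combine strong nest-site fidelity
of foundresses with surprisingly weak regional genetic structure. Direct
tracking of dispersing gynes and males is impractical at the kilometer
scale, so dispersal must be inferred from its genetic footprint: under
limited dispersal, genetic differentiation between local populations
increases with the geographic distance separating them (isolation by
distance, IBD). `waspibd` implements that inference end to end and, just as
importantly, ships a simulator with known truth so the whole chain can be
validated quantitatively.

# The model chain

## From genotypes to pairwise differentiation

Nuclear differentiation between two populations is estimated with the
Weir–Cockerham (1984) weighted estimator,
$\hat\theta = \sum_s a_s / \sum_s (a_s + b_s + c_s)$, accumulating the
among-population, among-individual and within-individual variance
components over sites. The ratio-of-sums form is used (not a mean of
per-site ratios) because per-site ratios are wildly unstable at low minor
allele frequency. Sites missing entirely in either population are skipped;
the estimate is left unclamped, so slightly negative values communicate
"no detectable differentiation".

Mitochondrial differentiation uses Hudson's estimator
$F_{ST} = 1 - H_w/H_b$ on the concatenated mitochondrial genes, where
$H_w$ averages the two within-population mean pairwise Hamming distances
and $H_b$ is the between-population mean. The estimator choice is a design
decision: a haploid single-locus sequence has no within-individual
component, and $1 - H_w/H_b$ is the standard sequence-based statistic.
Alignment columns containing any character outside A/C/G/T in any retained
sample are removed globally before all computations — a deterministic rule
that makes within- and between-population comparisons use identical sites.

## The IBD regression and Rousset's σ

For populations sampled along a transect, linearized differentiation
$F_{ST}/(1-F_{ST})$ is regressed on great-circle distance (haversine on
population centroids, Earth radius 6371.0088 km). The slope $b$ (per km)
feeds the dispersal estimator

$$\sigma^2 = \frac{1}{4\pi D_e b},$$

with $D_e$ the effective density of breeders per km², approximated in this
system by nest density; $\sigma$ is reported in meters. Two standing
caveats are attached to every estimate: an overestimate of $D_e$
underestimates dispersal, and haplodiploid autosomes coalesce at 3/4 the
diploid rate, which tends to make $\sigma$ an overestimate.

Because the $n(n-1)/2$ pairwise points share populations, the parametric
OLS p-value is optimistic; a seeded two-sided Mantel permutation test
(population labels permuted, default 999–9,999 permutations) is reported
alongside it. The OLS p remains primary, matching standard practice for
these regressions; the Mantel p is there so users can see when the two
disagree.

A negative or zero slope yields an explicit error ("no dispersal
estimate") rather than an imaginary σ.

## Sex-biased dispersal

With maternally inherited haploid mitochondria at one quarter the
autosomal effective size, equal male and female dispersal implies
$F_{ST(mito)} = 4F/(1+3F)$ where $F$ is nuclear $F_{ST}$. The test computes
this expectation per population pair from the observed nuclear value and
runs a two-sided one-sample t-test on the differences (observed mito −
expected). Interpretation is deliberately asymmetric in the field: observed
mitochondrial structure *above* expectation is the classic
female-philopatry/male-dispersal signature, while observed *below*
expectation argues against extra female structure and is likewise read as
male-biased gene flow. The result object therefore carries the raw signed
difference, both means, and a `direction_rule` string, so no convention is
hidden.

## Model-free structure summaries

Classical (Torgerson) MDS is run on identity-by-state distances (allele
sharing 1/0.5/0 per dosage difference 0/1/2), after 10-kb thinning to
reduce linkage between markers. Eigenvector signs are arbitrary, so each
axis is canonicalized (largest-magnitude loading positive) to make
coordinates deterministic; negative eigenvalues are dropped with a warning
rather than imputed. The haplotype network collapses identical mitochondrial
sequences, connects unique haplotypes by a Kruskal minimum spanning tree
with a deterministic (weight, node id, node id) tie-break, and flags
non-tree edges that could replace a tree edge at identical total weight as
`is_alternative` (exact ties only, ε = 0 — the strictest reading of the
reference network construction).

# Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_missing` | 0.8 | fraction | minimum non-missing call rate per site (boundary inclusive) |
| `mac` | 3 | alleles | minor-allele count over non-missing calls (boundary inclusive; removes singletons that distort structure estimates) |
| `kinship_threshold` | 0.1 | φ | close-kin pruning cutoff (looser than second-degree) |
| `window_bp` | 10,000 | bp | diversity window; π divides by the full window span for comparability with whole-genome per-bp values |
| `thin_bp` | 10,000 | bp | one SNP per window before MDS (greedy, first-kept, deterministic) |
| `densities` | 1080, 2500 | nests/km² | the two available breeder-density estimates; one σ is reported per density |

F_IS is aggregated as a ratio of sums across windows,
$F_{IS} = 1 - \sum_w H_{o,w} / \sum_w H_{e,w}$, which is stable when
individual windows have tiny $H_e$. Within this ratio $H_e$ carries the
small-sample factor $2n/(2n-1)$: without it $F_{IS}$ is biased by
$-1/(2n-1)$ and would read negative in perfectly panmictic data. The
reported `He` column itself stays on the raw $2\hat p\hat q$ scale, which
respects the per-site bound $H_e \le 0.5$. Whether any given published
table aggregated per-window means instead of ratio-of-sums is usually
unstated; small discrepancies between tools are expected at that level.

How the `max_missing` filter interacts with kin pruning is exposed rather
than fixed: `run_pipeline()` filters sites first and prunes kin second, but
both functions are public, so any order can be composed when a study's
protocol differs.

# The synthetic-data generator

`simulate_cohort()` is a forward-time, non-overlapping-generations
Wright–Fisher simulator on a torus lattice of demes:

- each offspring's mother is drawn from a deme displaced by a discretized
  Gaussian kernel (axial SD σ_f, integrated over unit bins, truncated at
  4 SD, renormalized); the father's deme uses σ_m. Gene dispersal for
  autosomes is therefore σ² = (σ_f² + σ_m²)/2, and σ_f² for the
  mitochondrion;
- nuclear sites are unlinked biallelic loci starting from intermediate
  standing frequencies (uniform 0.05–0.95) under symmetric two-allele
  mutation;
- the mitochondrion is a maternally inherited sequence whose genealogy is
  tracked exactly and converted to sequences under infinite sites at
  sampling time (only mutations on sampled ancestry paths materialize);
- with `haplodiploid = TRUE`, males are haploid, arise from unfertilized
  eggs, and transmit their single allele;
- everything is deterministic given `seed`, and a truth record carries the
  realized (discretized) kernel SDs, $D_e =$ breeders/spacing², expected
  slopes $b = 1/(4\pi D_e \sigma^2)$, and the final-generation pedigree.

Deme spacing defaults to 3 km. That choice is deliberate: on a
one-dimensional lattice the expected slope constant is $1/(4 D_{lin}
\sigma^2)$ with $D_{lin}$ the linear breeder density, while the estimator
applies the $4\pi D_e$ form; with 3-km spacing the two constants agree to
within ~2% ($\sqrt{s/\pi}$ with $s = 3$), so the simulator tests the
estimator in its intended regime rather than testing a unit-convention
mismatch. It is also a realistic spacing for breeding neighborhoods
sampled a few km apart.

What the generator does *not* emulate: linkage and recombination maps,
selection and background selection, range expansion and glacial-refugia
history, uneven deme sizes, landscape anisotropy, and genotyping error.
Passing tests therefore demonstrate the estimators' correctness and the
method's calibration under its own assumptions — not robustness to
historical non-equilibrium, which in real data can depress differentiation
basin-wide.

# Validation design and problem sizes

The test suite validates each estimator against an independent oracle:
Weir–Cockerham against a scalar per-site transcription of the 1984
components on dozens of random instances (agreement to 1e−10); Hudson
against exhaustive pair enumeration; the network MST against exhaustive
spanning-tree enumeration (n ≤ 6) and an independent library MST; KING
kinship against the exact φ = 0.5 duplicate identity and simulated
parent–offspring pairs (φ ≈ 0.25); single-deme diversity against the exact
stationary distribution of the 41-state Wright–Fisher mutation chain; and
pairwise F_ST in a finite island model against an exact second-moment
recursion derived for the very simulation scheme the test uses.

Calibration runs use three simulation arms, sized to finish in minutes:

- **σ recovery**: 20 replicates of the 20-deme ring (30 breeders/deme,
  σ = 1.5 km, 300 SNPs, 600 generations, 8 demes × 12 females sampled on a
  half-ring arc). The recovered σ must fall within a factor of 2 of the
  realized kernel σ in ≥ 80% of replicates — Rousset's documented accuracy
  regime. The ring geometry flattens the F_ST–distance curve near half the
  circumference, biasing σ̂ upward by ~1.2–1.4×; this is inside the
  calibration band and documented here rather than "corrected".
- **sex-bias contrast**: 20 + 20 replicates of a 10-deme ring run for 1,200
  generations, long enough for the single-locus mitochondrial genealogy to
  reach migration–drift equilibrium (founding the population monomorphic
  truncates deep mitochondrial divergence for hundreds of generations, so
  shorter runs systematically understate mito F_ST). With σ_m/σ_f = 10 the
  observed mitochondrial F_ST must exceed the nuclear-predicted expectation
  (sign test over replicates); with σ_m = σ_f the mean difference must sit
  within 3 SE of zero.
- **panmixia/Wahlund controls**: single-deme simulations give F_IS within
  3 SE of 0; pooling two exact-HWE demes fixed at p = 0.1 and 0.9
  reproduces the closed-form Wahlund excess.

A single mitochondrial locus has large genealogical variance: replicate
ring simulations with identical parameters produce mito F_ST anywhere from
~0.03 to ~0.4. This is faithful to nature (real mitochondria are also one
genealogy) and is why the sex-bias calibration works with replicate-level
sign tests rather than per-replicate point predictions.

# Numerical and degenerate-input choices

- Dosage coding {0, 1, 2}; phase ignored (all statistics are frequency
  based). Positions are 1-based; windows half-open, anchored at position 1.
- Filters use inclusive boundaries (`mac = 3` keeps count 3), matching the
  conventions of the tools these filters mirror.
- Kinship pruning removes the member of the worst pair with the higher
  missing fraction, breaking ties toward the lexicographically larger id —
  fully reproducible. Undefined φ (no shared heterozygous sites) is treated
  as unrelated but reported.
- `fst = 1` linearizes to ∞ and the pair is excluded from the regression;
  pairs with undefined mito F_ST ($H_b = 0$) propagate as `NA` and are
  dropped from the t-test with the pair count reported.
- Zero-variance difference vectors in the sex-bias test yield |t| = ∞ with
  a warning instead of NaN.
- MDS with non-Euclidean input truncates to the positive-eigenvalue
  subspace with a warning.

# Known limitations

- The dispersal formula is the two-dimensional Rousset constant applied to
  a linear-distance regression, as in the empirical literature this
  implements; on strictly one-dimensional habitats the strict constant is
  $1/(4 D_{lin} \sigma^2)$ and estimates differ by $\sqrt{s/\pi}$-type
  factors.
- No block-jackknife confidence intervals for F_ST or the slope (future
  work); the Mantel permutation is the only resampling provided.
- The simulator's two-allele nuclear model starts from standing variation,
  so nuclear diversity *levels* (as opposed to ratios and slopes) are only
  at mutation–drift equilibrium in the long single-deme runs used for the
  diversity tests.
- Haplodiploid mode changes transmission but the estimators deliberately
  apply unmodified diploid formulas — quantifying the resulting ~3/4-Ne
  bias in $b$ is possible with the simulator but has no published value to
  compare against.
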