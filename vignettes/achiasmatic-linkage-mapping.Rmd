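---
title: "Linkage mapping under achiasmatic female meiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping under achiasmatic female meiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achiasmap)
```

## The biological setting

`achiasmap` builds genetic linkage maps for F2 intercrosses in species in
which one sex does not recombine. The motivating system is the copepod
*Tigriopus californicus*: females transmit each chromosome whole, so every
crossover observed in an F2 panel happened in the father. This asymmetry is
not a nuisance — it reshapes the two-locus genotype distribution in a way
that makes linkage inference unusually crisp, and it gives an orthogonal
confirmation tool (the non-recombinant backcross) for free.

## The two-point model

Label the P1 (e.g. San Diego line) allele A and the P2 (Santa Cruz) allele
B. An F2 individual unites a non-recombinant maternal gamete (AB or ab for
a marker pair, probability 1/2 each) with a paternal gamete recombinant
with probability $r$: AB and ab each at $(1-r)/2$, Ab and aB each at
$r/2$. The nine two-locus classes then have probabilities

$$P(\mathrm{AABB}) = P(\mathrm{aabb}) = \tfrac{1-r}{4},\quad
  P(\mathrm{AaBb}) = \tfrac{1-r}{2},$$
$$P(\mathrm{AABb}) = P(\mathrm{AaBB}) = P(\mathrm{Aabb}) = P(\mathrm{aaBb})
  = \tfrac{r}{4},\quad
  P(\mathrm{AAbb}) = P(\mathrm{aaBB}) = 0.$$

Two classes are *impossible* under the model. Individuals falling in them
can only arise from genotyping error or genuine female recombination, so
`estimate_r_achiasmatic()` excludes them from the estimate and reports
their count. The MLE is closed-form — the recombinant fraction among the
remaining individuals, clamped to $[0, 0.5]$ — and the LOD score is the
base-10 likelihood ratio against $r = 0.5$ under this same achiasmatic
likelihood, not the standard both-sex F2 likelihood, because the cross
biology says the standard likelihood is wrong here. A practical corollary,
exploited throughout: for unlinked markers on different chromosomes the
*conditional* recombinant fraction among possible classes is $4/7 > 1/2$,
so their estimates clamp to 0.5 with LOD 0, and spurious cross-chromosome
linkage is far rarer than in a both-sex cross of the same size.

`estimate_r_sexspecific()` drops the achiasmy assumption and fits
$(r_f, r_m)$ jointly; at $r_f = 0$ it reduces exactly to the achiasmatic
model. The class probabilities are symmetric in $(r_f, r_m)$, so the
labels are not identifiable from F2 genotypes alone; the package reports
the canonical solution with $r_f \le r_m$, the conservative assignment
when female recombination is the rare event under scrutiny. In practice
$r_f$ is identified almost entirely by the impossible-class counts.
Maximization is a 0.005-step grid over $[0, 0.5]^2$ followed by bounded
local refinement, with ties broken toward smaller $r_f$.

Distances come from the Kosambi map function,
$d = \tfrac14 \ln\frac{1+2r}{1-2r}$ Morgans, inverse
$r = \tfrac12\tanh 2d$, which tolerates moderate crossover interference.

## Map construction

Grouping is single-linkage transitive closure over marker pairs satisfying
both LOD $\ge$ 1.0 and $\hat r \le$ 0.4 (defaults; both are pipeline
configuration). The two thresholds are combined conjunctively — the
conservative reading when only the two values are specified. Group ids are
assigned by descending size, then smallest member id, making the partition
invariant to input order.

Within a group, markers are ordered by minimizing the sum of adjacent
Kosambi distances (SARF): the chain is seeded with the most distant pair
(typically the chromosome ends), remaining markers are inserted greedily
at the SARF-minimizing position (ties to the smaller marker id), and 2-opt
segment reversals run to convergence. Orientation is canonicalized so the
lexicographically smaller terminal marker comes first. This is a fully
specified, testable procedure rather than a re-implementation of any
proprietary ordering algorithm; at study scale it attains the SARF of the
generating order, and residual order differences are confined to
equal-distance adjacent pairs that no two-point method can resolve.

Positions are cumulative `kosambi(r_hat)` sums over adjacent pairs.
Adjacent estimates at or above 0.5 (possible after QC exclusions) are
clamped to 0.4999 with a warning rather than producing infinite gaps.

The non-recombinant backcross — (P1 x P2) F1 female backcrossed to a P1
male — inherits whole maternal chromosomes, so within a true linkage group
every individual must be uniformly AA or uniformly AB. `confirm_with_nrbc()`
checks exactly that (BB calls are impossible and warn), and flags group
pairs with identical inheritance vectors as possibly same-chromosome:
fragments of one chromosome co-segregate perfectly, unrelated groups agree
across all 19 individuals with probability $2^{-19}$.

## Marker quality control

Two exclusion procedures mirror standard practice for this cross design:

* `segregation_test()` compares P1 vs P2 allele counts ($2\,n_{AA}+n_{AB}$
  vs $2\,n_{BB}+n_{AB}$) against 1:1 by chi-square with df = 1. The flag
  threshold defaults to $\chi^2 > 14$ — a deliberately conservative screen
  beyond the df = 1, $p<0.001$ critical value of 10.83 — and is
  configurable precisely because the two conventions differ; a df = 2
  genotype test against 1:2:1 sits behind `test = "genotype"`. Bonferroni
  p-values across tested markers are always reported.
* `female_recomb_filter()` asks, for each mapped marker, how much female
  recombination one would have to posit against its nearest neighbours to
  explain the data. A marker is excluded when even its better neighbour
  implies $\hat r_f$ above 0.25 (default): since female recombination does
  not occur at appreciable levels in this biology, such markers are
  genotyping artefacts — cryptic polymorphism being the usual suspect.
  Only nearest neighbours are consulted, and single-marker groups are
  skipped with an undefined estimate.

## Map statistics

`map_summary()` reports marker/group counts, summed length, mean and
maximum intermarker distance (mean = summed length over
$n - n_\mathrm{groups}$ intervals), the chromosome-end corrected length
$L_\mathrm{tot} = \sum_i (L_i + 2)(m_i+1)/(m_i-1)$, genome coverage
$c = 1 - e^{-2dn/L}$, recombination rate (cM/Mbp) and marker density
(Mbp/marker). Reference constants default to a 244.5 Mbp haploid genome
and a 484.8 cM previously published reference map length, both plain
configuration values.

Coverage deserves a note. Published coverage figures for maps of this kind
are reproduced by taking $d$ = summed length / $n$ and $L$ = the
*previously published* corrected map length — not by substituting the
map's own mean intermarker distance and its own corrected length, which
yields a noticeably higher number (the two conventions differ by several
points on a 190-marker map). `map_summary()` therefore exposes both: the
`"external"` convention (default) and the self-contained `"internal"` one.
`coverage()` itself takes $(d, n, L)$ explicitly so either convention is a
one-liner.

## The synthetic cross

`simulate_f2()`/`simulate_nrbc()` generate data with the statistical
structure the estimators assume, and are first-class, tested code — the
package's acceptance checks run on their output.

* **Genome.** `default_genome()` builds 12 chromosomes with genetic
  lengths evenly spanning 19–32 cM and 190 markers allocated
  proportionally to length (largest-remainder rounding, minimum two per
  chromosome), uniformly spaced. Real marker spacing is of course not
  uniform; uniform spacing is the neutral default given that only the
  length range and marker total are specified, and any genome can be
  supplied as a `(chrom, marker, pos_cM)` table.
* **Meiosis.** Female gametes carry whole chromosomes. Male crossovers
  follow a first-order Markov chain along each chromosome: the origin
  label switches between adjacent markers with probability
  `kosambi_inverse(spacing)`. Simulating at the level of adjacent
  recombination fractions keeps the simulation truth consistent with the
  Kosambi-based estimation stage by construction, without committing to an
  explicit interference model that the design does not specify.
* **Defaults.** 250 F2 and 19 backcross individuals; zero genotyping error
  and missingness; viability selection off (the emulated design genotypes
  early-stage larvae, where segregation distortion was not observed).
  The error model is symmetric between the two wrong codes because no
  assay-specific error structure is assumed; missingness is uniform.
  Viability weights, when supplied, act multiplicatively per marker and
  genotype class with rejection sampling to the target sample size.
* **What passing tests do not show.** The generator reproduces the
  *model's* assumptions, so estimator-recovery tests validate internal
  consistency, not robustness to real-data pathologies: clustered
  missingness, allele-specific dropout, batch effects, segregation
  distortion in adults, or non-uniform marker spacing. The QC tests probe
  such pathologies only through stylized corruption layers
  (`apply_noise()`, allele-polarity swaps, independent-redraw markers).

## Numerical choices and degenerate inputs

* Seeds fully determine simulated output; the internal seeding helper
  restores the caller's RNG state afterwards.
* Two-point estimates with every individual in the impossible classes are
  an error, not a number; all-missing markers yield `NA` statistics and
  are never flagged.
* The sex-specific likelihood is $-\infty$ on the $r_f = 0$ axis whenever
  impossible classes are present; the refinement box is floored at
  $10^{-9}$ there so bounded optimization stays finite.
* `group_markers()` treats absent pairs as unlinked; `build_map()` clamps
  $\hat r \ge 0.5$ adjacencies to 0.4999 with a warning; single-marker
  groups have length 0 and contribute $L_i + 2$ (with a warning) to the
  corrected length, whose multiplier is undefined at $m_i = 1$.
* The synteny permutation test uses the add-one estimator
  $p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(n_\mathrm{perm}+1)$,
  avoiding $p = 0$ from finite permutations; the reported threshold is the
  empirical $1 - \alpha/n_\mathrm{tests}$ quantile (Bonferroni-corrected,
  default $0.05/4 = 0.0125$), alongside the permutation maximum, because
  published "threshold" columns are ambiguous between the two.
* Syntenic units score $k - 1$ for any cell of $k \ge 2$ colocalizing
  homologs, generalizing the stated pair/triple scoring to arbitrary
  cluster sizes.

## Problem sizes used by the test suite

The suite exercises study-scale runs (190 markers x 250 individuals,
about 18,000 marker pairs — a couple of seconds via the indicator-matrix
counting in `pairwise_estimates()`), 10,000-gamete recombination-recovery
checks, a 100-seed ordering study on 8-marker chromosomes at n = 2000
with exhaustive-order verification on a subset, 1,000 random count vectors
against a grid-search MLE oracle, 10,000 marker-seeds for the null flag
rate of the segregation test, and exhaustive (6!) permutation enumeration
for the synteny test. These sizes were chosen to make each statistical
assertion sharp at conventional error rates while keeping a full run
comfortable on a laptop.

## Known limitations

* Two-point estimation only: no multilocus likelihood, no interference
  estimation, and ordering quality is bounded by what adjacent
  recombination fractions can resolve.
* The sex-specific fit cannot attribute recombination to a parent without
  external information; it reports the canonical $r_f \le r_m$ solution.
* Synteny inputs are best-hit homolog tables; alignment, E-value
  filtering and unanchored-scaffold policy happen upstream (the
  `include_unanchored` flag is carried as metadata).
* The CDS-based SNP classification assumes the standard genetic code and
  takes coding intervals as given; no ORF prediction is attempted, and
  anchors matching more than one location or transcript are refused
  rather than guessed.
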