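---
title: "Selecting marker panels that maximize haplotypic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting marker panels that maximize haplotypic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopanel)
```

## The problem

A genetic marker is useful for telling individuals apart in proportion to
its *haplotypic diversity* — the probability that two individuals drawn at
random from the population carry different haplotypes at the marker. In
forensic work this quantity is called the *exclusion capacity*. For
markers on different chromosomes the diversity of a panel follows from the
single-marker diversities by independence. Mitochondrial DNA offers no
such shortcut: the whole molecule is one linkage group, markers share
information to an unknown degree, and the diversity of a marker *set* can
only be measured on the joint haplotypes observed in a sample. Choosing,
say, the ten most informative SNPs out of hundreds of polymorphic sites
then becomes a combinatorial optimization problem. This package solves it
exactly for moderate instances and approximately, with a controlled
heuristic, for larger ones.

## Diversity as an integer

For a sample of $n$ sequences with $k$ haplotypes at frequencies $p_i$,
the classical estimator of haplotypic diversity is Nei's

$$\hat H \;=\; \frac{n}{n-1}\Bigl(1 - \sum_{i=1}^{k} p_i^2\Bigr).$$

Instead of frequencies we work with the haplotype class sizes
$c_i = n\,p_i$ and count the *separation index*

$$S \;=\; \frac{n^2 - \sum_i c_i^2}{2},$$

the number of unordered sequence pairs assigned to different haplotypes.
Its maximum is $S_{\max} = n(n-1)/2$, attained when all sequences are
distinct, and

$$\hat H \;=\; \frac{S}{S_{\max}}$$

is algebraically identical to Nei's estimator (the test suite checks the
identity to $10^{-12}$ on random inputs). The point of the
reformulation is that $S$ is an exact integer for every marker and every
marker set, so all bookkeeping during the search — scores, bounds,
comparisons — is free of rounding; diversities are derived only for
reporting.

## Haplocodes

Each polymorphic alignment column is encoded as an integer vector of
length $n$, the *haplocode*, assigning each sequence its haplotype label
at that column. We fix the canonical first-occurrence labeling (first
sequence gets 0, each new haplotype the next integer); any consistent
labeling carries the same information, and the canonical form makes
informational equality of markers a byte-wise comparison, which the
redundancy step exploits for hashing. Combining two markers is the common
refinement of their label partitions — two sequences stay together only if
both markers keep them together — computed in $O(n)$. Combination is
commutative, associative and idempotent, the monomorphic all-zero
haplocode is its identity, and refinement can only increase $S$.

Every distinct character is a distinct state by default, including the
gap `'-'` and ambiguity codes such as `N`: this never understates
differences that are visible in the data. Since treating an `N` as a
fifth state can also manufacture separation that deeper sequencing would
remove, a strict mode (`strict_bases = TRUE`) instead drops columns
containing anything outside `A/C/G/T/-`, making the choice auditable.

## Markers, widths, and reduction

A marker of width $w$ spans $w$ alignment columns and carries the
combined haplocode of the polymorphic columns inside its window. With
$w = 1$ there is one candidate per polymorphic column. For wider markers,
candidate windows are anchored at polymorphic columns and slid to cover
maximal runs of them; a window whose polymorphic-column set is a subset of
another window's set is discarded (it can never carry more information).
Anchoring at polymorphic columns rather than enumerating all $L$ window
starts yields the same marker contents with a much smaller candidate set.

Before searching, the candidate list is reduced: markers with identical
haplocodes are collapsed (hash on the canonical labels, smallest start
kept, which makes output deterministic), and a marker whose combination
with another retained marker equals that marker's haplocode is dropped as
informationally subsumed. Reduction changes neither the attainable
optimum for any set size — a property the tests verify against exhaustive
enumeration on random instances — nor the reported scores; it only
shrinks the search space. Markers are then sorted by decreasing $S$,
which the bounding step requires.

## Branch-and-bound search

The best set of at most $K$ markers is found by depth-first search over
the sorted list: each node extends the current set with a marker further
down the list. If the current set separates $S_c$ pairs and $k$ markers
may still be added, the extended set can separate at most

$$\min\Bigl(S_{\max},\; S_c + \sum_{j=1}^{k} S_{(j)}\Bigr)$$

pairs, where $S_{(1)} \ge S_{(2)} \ge \dots$ are the separation indices of
the markers still available. The bound assumes marker independence and is
therefore weak, but it is valid, and branches whose bound cannot
*strictly* beat the incumbent are pruned. The incumbent is initialized by
a greedy pass (strongest single marker, extended by the best immediate
improvement while it strictly helps); any admissible incumbent only
tightens pruning and cannot affect the optimum. With the bound at full
strength the returned $S$ is globally optimal over all subsets of size
$\le K$.

$K$ is a maximum, not a quota: when a smaller set reaches the same $S$,
the smaller set is returned (`prefer_smaller`, default on). Among equal
solutions the first one encountered in sorted order wins, so results are
reproducible run to run.

### The heuristic parameter $\alpha$

For large instances the bound can be scaled: each prospective marker is
assumed to contribute only a fraction $\alpha \in (0,1]$ of its separation
index, giving $S_c + \alpha \sum_j S_{(j)}$. Smaller $\alpha$ prunes more
aggressively; $\alpha = 1$ is the exact search. We adopt the plain
per-marker linear scaling; rank-dependent or non-linear scalings are a
known possible refinement, and because the effect of $\alpha$ on the
result is not monotone, a smaller $\alpha$ can occasionally produce a
worse set than a larger one. Two guarantees are unconditional: the
heuristic can only *understate* the optimum (never return an $S$ above
the $\alpha = 1$ result), and the reported $S$ and $H$ are always the
true values of the returned set — $\alpha$ affects search effort only,
never scoring. The CLI accepts `--alpha 0.8` or `--alpha "80%"`.

Two numerical choices keep search decisions bit-reproducible: $\alpha$ is
held as a reduced rational $p/q$ (rounded to four decimals, so
$q \le 10^4$), and every pruning comparison is evaluated by integer
cross-multiplication $q\,S_c + p\sum S_{(j)} > q\,S_{\text{inc}}$, whose
terms stay far below $2^{53}$ for any realistic $n$. The bound is
additionally capped at $S_{\max}$: adding information can never separate
more than all pairs, and the cap terminates search early once a
fully-resolving set is found.

## The synthetic population generator

The generator emulates the study design used to measure how sample size
affects estimation quality: a population of 10,000 sequences of
16,000 bp with ten disjoint 800 bp marker regions whose population
diversities are 0.18, 0.20, 0.22, 0.25, 0.28, 0.33, 0.39, 0.49, 0.64 and
0.86 (`ten_region_design()`). The published design does not disclose each
region's haplotype frequency spectrum, only its diversity, so a spectrum
must be chosen: `calibrate_counts()` uses the smallest number of classes
that can realize the target (a biallelic region tops out near
$H = 0.5$; $H = 0.86$ needs eight classes), configured as one dominant
class plus equal minor classes and refined by a local integer search
until the population diversity is within 0.005 of the target — at
$N = 10{,}000$ the integer grid is fine enough that targets are hit to
about $10^{-4}$. Mean diversity estimates depend only on the region's
$H$, so this choice does not affect the mean columns of the experiment;
the *spread* of the estimates does depend on the spectrum, which is why
the tests check standard deviations qualitatively (monotone decrease
with sample size, small at $n = 1000$) rather than as point values.

Sequences are only materialized when needed: each region assigns its
calibrated class counts to sequences by a seeded random permutation
(R's default Mersenne-Twister generator; the seed is a mandatory, logged
parameter), and the label matrix is all the estimation arithmetic needs.
`expand_population()` / `write_population_fasta()` realize the classes as
actual sequences — a constant random background with one substituted base
per extra haplotype class inside each region, so the region's haplotypes
are exactly the assigned classes. Regions are required to be disjoint
(distinct sets of polymorphic columns).

Sampling is uniform *without* replacement, the natural model for drawing
individuals from a population (with-replacement draws are available as a
flag for estimator-theory experiments). A useful exact fact follows:
every unordered pair of population members is equally likely to land in a
sample, so the expected sample diversity equals the population diversity
— the estimator is exactly unbiased under this design, and the sample-size
experiment (`sampling_experiment()`, 100 replicates at sizes 10/50/100
and 50 at size 1000 by default) measures only how its spread shrinks.
The test suite runs that experiment at the full design scale, which takes
seconds because it works at the label level.

What the generator does *not* emulate: coalescent genealogy, realistic
mutation processes, recombination (irrelevant for a single linkage
group), linkage between regions, or sequencing error. Passing tests show
that the estimator and search behave correctly on populations with known
structure; they do not validate any claim about real mtDNA panels, for
which a representative sample of real sequences is the input.

## Degenerate inputs and edge policies

* Monomorphic alignments yield no candidate markers; the pipeline stops
  with a clear error rather than returning an empty panel.
* Exclusion-list entries beyond the reference length are skipped with a
  warning, so generic genome-wide disease lists can be applied to partial
  alignments; excluding a reference position also excludes insertion
  columns attached to it (labelled `p+k` for the k-th inserted column
  after position p — the alignment-to-reference numbering for insertions
  is a convention this package fixes, as rCRS-style coordinates do not
  define one).
* A named reference sequence is excluded from every diversity computation
  and used for coordinate reporting only.
* `K` larger than the number of available markers degrades to using all
  markers, with a warning.
* Small populations offer a coarse grid of attainable diversities;
  calibration refuses (with an explanatory error) rather than silently
  missing the 0.005 tolerance.

## Problem sizes used by the tests

Search correctness is established against exhaustive enumeration on
hundreds of random instances of up to 10 sequences and 14 markers with
$K \le 4$ — small enough that the oracle is unquestionable, large enough
to exercise every pruning path. The sample-size experiment runs at the
full design scale (10,000 sequences, ten regions, 350 samples) at the
label level. Pipeline integration uses populations of a few hundred
sequences expanded to real FASTA. The heuristic's pruning behavior is
measured on skewed biallelic instances (20 sequences, 12 markers), where
the optimum stays well below $S_{\max}$ and the search tree is
non-trivial.
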