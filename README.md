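# haplopanel

Selection of genetic marker panels that maximize haplotypic diversity
(*exclusion capacity*) on linked, non-recombining sequences such as
mitochondrial DNA.

## The problem

Forensic and phylogenetic typing often relies on a small panel of markers
instead of full sequences. A marker's usefulness is its haplotypic
diversity — the probability that two individuals drawn at random differ
at the marker. For nuclear markers on different chromosomes, panel
diversity follows from the single-marker diversities by independence.
mtDNA is one linkage group: markers share information to an unknown
degree, the diversity of a *set* must be measured on the joint haplotypes
in a sample, and the most diverse individual markers frequently do **not**
form the most diverse panel. Finding the best subset is a combinatorial
optimization problem that until recently was attempted by eye.

## The method

For a sample of $n$ aligned sequences, each polymorphic column (or wider
window) is encoded as a **haplocode** — an integer vector giving each
sequence its haplotype label. Combining markers is the common refinement
of their label partitions, computed in $O(n)$. Diversity is carried as
the integer **separation index**

$$S = \tfrac{1}{2}\Bigl(n^2 - \sum_i c_i^2\Bigr),$$

the number of sequence pairs the marker (set) tells apart ($c_i$ =
haplotype class sizes). $H = S / \binom{n}{2}$ is algebraically identical
to Nei's estimator $\hat H = \frac{n}{n-1}(1 - \sum_i p_i^2)$, and the
integer form is exact throughout the computation. After collapsing
redundant markers (equal or informationally subsumed haplocodes), the
best set of at most $K$ markers is found by depth-first
**branch-and-bound**: markers sorted by decreasing $S$, branches pruned
when $\min(S_{\max},\ S_{\text{current}} + \alpha \sum_k S_{(k)})$ cannot
beat the incumbent. $\alpha = 1$ is exact; $\alpha < 1$ is a heuristic
that prunes harder, can only understate the optimum, and never misreports
the diversity of the set it returns.

A synthetic-population module generates populations whose marker regions
are calibrated to prescribed diversities, for studying how sample size
affects the quality of $\hat H$ estimates.

## Worked example

Four sequences with two polymorphic columns; either column alone splits
the sample into two pairs, together they resolve all four sequences:

```r
library(haplopanel)
aln <- alignment_matrix(c(s1 = "ACGT", s2 = "ACGA", s3 = "ATGA", s4 = "ATGT"))
markers <- sort_markers(reduce_markers(build_markers(aln, width = 1)))
best_marker_set(markers, K = 2)
#> Marker set: 2 marker(s), S = 6 of 6, H = 1.0000
#> Search: alpha = 1 (exact), 0 nodes expanded, 2 pruned
```

`S = 6 of 6` means all $\binom{4}{2} = 6$ sequence pairs are separated,
so the pair of markers has diversity $H = 1$: any two individuals can be
told apart. The greedy warm start already found this ceiling, so the
search proved optimality without expanding a node.

The sample-size experiment on the ten-region synthetic design (10,000
sequences, regions calibrated to diversities 0.18–0.86; 50 samples of
size 1000 shown):

```r
pop <- make_population_labels(10000, 16000, ten_region_design(), seed = 7)
exp <- sampling_experiment(pop, seed = 8)
subset(as.data.frame(exp), size == 1000)
#>  region true_H size mean_H    sd_H reps
#>       1   0.18 1000  0.179 0.01260   50
#>       2   0.20 1000  0.199 0.01501   50
#>       3   0.22 1000  0.218 0.01695   50
#>       4   0.25 1000  0.254 0.01457   50
#>       5   0.28 1000  0.280 0.01618   50
#>       6   0.33 1000  0.330 0.01608   50
#>       7   0.39 1000  0.391 0.01210   50
#>       8   0.49 1000  0.490 0.00378   50
#>       9   0.64 1000  0.640 0.00590   50
#>      10   0.86 1000  0.859 0.00337   50
```

Sample estimates are unbiased (means track the true diversities) and at
this sample size their spread is already small; at size 10 the standard
deviations are around 0.15–0.20 and single-sample estimates of weak
markers are close to worthless — the reason the experiment exists.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "haplopanel.R", package = "haplopanel"))')
Rscript "$CLI" find --msa aln.fa --set-size 10 --alpha 80% \
    --reference-id rCRS --exclude-positions hv_and_disease.txt --out report
Rscript "$CLI" simulate --out pop.fa --seed 1 --preset tenregion
Rscript "$CLI" experiment --out table.tsv --seed 1
```

`find` writes `report.tsv` (chosen markers with positions, widths, $S$
and per-marker $H$, plus a summary block) and a `report.json` twin with
identical numbers. Exclusion lists are plain text, one 1-based position
or `start-end` range per line.

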