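---
title: "chromaforge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromaforge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaforge)
```

chromaforge processes chromosome-conformation-capture (Hi-C) data from
filtered read pairs to normalised contact matrices, and analyses those
matrices for the three organisational scales of the genome: A/B
compartments, topologically associating domains (TADs), and chromatin
loops. This vignette explains the models behind each step, the parameters
that matter, and the numerical choices made where the design was open.
Everything is tibble-first: pairs, pixels, tracks and calls are plain
tables, and a `contact_matrix` is a light S3 wrapper around a bin table, a
sparse upper-triangle pixel table, a bias vector and a validity mask.

## From reads to a raw matrix

Hi-C reads are chimeric: a read can cross the ligation junction formed when
two cut-and-filled restriction ends are ligated. For a palindromic site
`s` of length `L` cut at offset `c` (5' overhang or blunt), the filled-in
junction is `s[1..c] + s[c+1..L-c] + s[c+1..L-c] + s[L-c+1..L]`
(`AAGCTAGCTT` for HindIII, `GATCGATC` for MboI; blunt cutters give the site
itself). `split_at_junction()` cuts reads at the junction midpoint so each
flank retains half of the junction; flanks under 20 bp are discarded.
Only 5'-overhang and blunt palindromic cutters are supported: the
re-ligation chemistry of 3'-overhang enzymes is ambiguous, and
non-palindromic sites do not define a unique junction, so both are rejected
explicitly rather than guessed. Digestion (`digest_genome()`) matches IUPAC
sites degenerately (supporting enzymes like ApoI) and takes the union of
cut positions for multi-enzyme (Arima-style) digests; the resulting
fragments tile each chromosome gaplessly.

Mapped mates are assigned to the fragment containing their 5' position.
The pair orientation — inward (converging), outward (diverging), or one of
the two same-strand classes — is read off the strands after putting mates
in genome order, and each mate's restriction-site distance is measured to
the fragment edge the read faces (downstream for `+`, upstream for `-`).

### The filter suite

`filter_pairs()` applies filters in a fixed, documented order and
attributes every removed pair to the *first* failing filter, so the
per-filter counts always sum to the total:

1. unmapped mate; 2. multimapping mate; 3. mapping quality < 3;
4. self-ligation (both mates on one fragment); 5. PCR duplicate (both
mates identical in chromosome, position and strand; first seen kept);
6. ligation error — inward/outward pairs whose faced restriction sites are
closer than 5 000 bp; 7. unexpected insert size — sum of the two
restriction-site distances above 10 kb; 8. unusual read density —
fragments whose pair count strictly exceeds the 0.9999 empirical quantile
of per-fragment counts. A custom predicate can be registered for anything
else (e.g. contamination screens).

The mapping-quality and ligation-error cutoffs are the standard operating
values for this kind of pipeline. The insert-size cutoff and density
quantile have no canonical value; 10 kb is far above any plausible sum of
two fragment-edge distances for common 4- and 6-cutters, and the type-1
(empirical) quantile, combined with a strict inequality, means the density
filter only fires on genuine outliers — integer pair counts are heavily
tied, so on clean data the cutoff coincides with the maximum and nothing
is removed. Inter-chromosomal pairs are exempt from the self-ligation,
ligation-error and insert-size filters, which are only meaningful within a
chromosome.

The diagnostics (`pair_diagnostics()`) reproduce the two standard QC
plots: orientation fractions against log-spaced genomic separation, which
must converge to 0.25 per orientation for true ligation products (inward /
outward excesses at short range expose uncut or re-ligated fragments), and
the insert-size density with its median.

## Contact matrices, balancing and expected values

Valid pairs increment the pixel of the bin pair containing the two
fragment midpoints (the midpoint rule is unambiguous for fragments that
straddle bin edges). Only the upper triangle is stored; raw counts are
never overwritten. Low-coverage bins are masked — by default below 25% of
the median non-zero marginal — and zero-coverage bins are always masked.
Masked means missing: no operation ever emits a value involving a masked
bin (the aggregate module can optionally impute masked cells from the
expected profile instead).

Balancing finds per-bin multipliers $b_i > 0$ such that the normalised
matrix $m_{ij} = b_i b_j x_{ij}$ has unit marginals over valid bins.
Two algorithms are provided: Knight–Ruiz (`method = "kr"`), an inner–outer
Newton iteration with conjugate-gradient inner solves, and iterative
correction (`method = "ice"`), the symmetric Sinkhorn iteration
$b \leftarrow b / \sqrt{r}$ on the current marginals $r$. Both are run to
a residual of $10^{-10}$ and then polished with a handful of Sinkhorn
steps to machine precision, so the two methods agree to well below
$10^{-5}$ on strictly positive inputs. Balancing is per chromosome by
default (`per_chrom = FALSE` gives whole-genome balancing); with unit
marginals the mean valid marginal is 1, which makes profiles comparable
across samples. The normalised value is always derived on the fly from
`count * b_i * b_j`, so the loop caller can go back to integer counts.

The expected profile $e_c(d)$ is the mean normalised value over *all*
valid bin pairs of chromosome $c$ at bin distance $d$ — implicit zero
pixels count in the denominator, masked bins do not. A genome-wide profile
pools the per-chromosome sums, and a single scalar summarises
inter-chromosomal expectation. Profiles are stored inside the matrix
container so observed/expected (O/E) transforms are cheap and dynamic.
O/E uses the per-chromosome profile by default; a flag switches to the
genome-wide one.

## Compartments

The compartment signal is read off the per-chromosome correlation matrix:
$C_{ij}$ is the Pearson correlation of the O/E profiles of bins $i$ and
$j$, pairwise-complete over valid bins (bins with more than 90% missing
O/E are masked; O/E is used as-is, without a prior z-transform). The first
eigenvector (EV) of $C$ — per chromosome, largest eigenvalue — partitions
bins into the A and B compartments by sign. Because eigenvector sign is
arbitrary, the EV can be oriented with genome sequence: the sign is
flipped per chromosome so that positive-EV bins have the higher mean GC
content (the A compartment is GC-rich). Without sequence the largest-
magnitude entry is made positive, which keeps results deterministic.
A chromosome whose correlation matrix is degenerate (e.g. constant O/E)
is flagged with a warning rather than silently returning an arbitrary
vector.

The saddle profile orders valid bins by EV and groups them at the
requested percentiles (rank-based, so percentiles 5, 10, ..., 100 on 100
bins give exactly 20 groups of 5); $S_{gh}$ is the mean O/E over all
intra-chromosomal bin pairs between groups $g$ and $h$, zeros included.
Compartment strength condenses the saddle into one number:

$$\mathrm{strength} = \log_2 \frac{AA \cdot BB}{AB^2}$$

with $AA$ the mean O/E among the top 20% of EV groups, $BB$ among the
bottom 20%, and $AB$ the cross term. A uniform O/E matrix gives exactly 0;
random EV labels give 0 in expectation; the statistic increases
monotonically with plaid contrast on synthetic series. The corner
fraction (default 0.2) is configurable.

## Domains

The insulation score of bin $i$ at window $w$ (given in bp, floored to
whole bins, minimum 2) is the mean normalised value in the off-diagonal
square $[i-w, i) \times (i, i+w]$, log2-ratioed against a per-chromosome
normaliser — the arithmetic mean of the defined raw scores by default, or
their geometric mean. Geometric normalisation is never smaller bin-wise
(AM–GM) and is more robust to a few very insulated bins. Windows touching
a chromosome end, or whose square is more than half masked, are missing.
The log2-ratio form makes the score exactly invariant to uniform scaling
of the matrix.

The directionality index contrasts a bin's upstream contact sum $A$
(bins $[i-w, i)$) with its downstream sum $B$ ($(i, i+w]$): with
$E = (A+B)/2$,

$$\mathrm{DI}_i = \mathrm{sign}(B - A)\left(\frac{(A-E)^2}{E} + \frac{(B-E)^2}{E}\right),$$

zero when $A = B$ or $E = 0$. This chi-square form scales linearly with
the matrix, so only its sign (not its magnitude) is scale-invariant — the
track is used for the sign flips at domain boundaries.

Boundaries are local minima of an insulation (or insulation-difference)
track. Tracks are split at missing runs and extrema never bridge the gaps;
plateau minima collapse to the central bin (left of centre on even
plateaus). The boundary score is the mean of the two deltas to the nearest
flanking local maxima — the two flanks are both informative, and the mean
is symmetric; a `min_of_deltas` flag gives the conservative alternative.
Boundaries at or above the score cutoff (default 1.0) are returned. The
same caller runs unchanged on difference tracks, where a cutoff of 0
(plus any margin) separates gained/lost boundaries from noise.

## Loops

The loop caller is a CPU implementation of the local-neighbourhood Poisson
test. For each intra-chromosomal pixel at least $w + p$ bins off the
diagonal and with a complete neighbourhood inside the matrix, four local
expectations are formed — donut, lower-left quadrant, horizontal stripe
and vertical stripe, each of radius $w$ (default 5) excluding the
$(2p+1)^2$ peak box (default $p = 2$). Estimation happens on the raw-count
scale so the Poisson model applies to integers: with the distance-decay
model carried back through the biases,
$\mathrm{model}(a,b) = e(|a-b|) / (b_a b_b)$,

$$\lambda_n(i,j) = \frac{\sum_{(a,b) \in n} x_{ab}}{\sum_{(a,b) \in n} \mathrm{model}(a,b)} \cdot \mathrm{model}(i,j),$$

and the observed count is tested against $\mathrm{Poisson}(\lambda_n)$.
Multiple testing uses lambda-chunking: expectations are binned into
chunks at powers of $2^{1/3}$ and Benjamini–Hochberg correction is applied
within each chunk, which reduces exactly to plain BH when all
expectations share a chunk. A pixel is reported when it passes the
q-value threshold (default 0.1) *and* an O/E enrichment threshold in all
four neighbourhoods (defaults 1.75 for donut and lower-left, 1.5 for the
stripes — the convention of the algorithm family; the values are fully
exposed). Significant pixels are merged by single-linkage clustering at a
Chebyshev merge distance (default 3 bins) and cluster centroids reported.
Isolated single-pixel clusters are the classic false-positive mode of
local-neighbourhood callers, so singletons are kept only when all four
q-values clear a stricter threshold (default 0.02), the post-processing
convention of the algorithm family; real loops either span several
significant pixels or are far more significant than the borderline.
The caller is deterministic: identical inputs give byte-identical call
tables.

## Aggregates

`aggregate_regions()` averages log2-O/E submatrices over a region list.
In rescaled mode each region is expanded by half its size on either side
(so the region occupies the central third of the plot) and interpolated to
a fixed grid by area-weighted averaging, which treats missing cells as
missing rather than zero. In fixed mode a window of constant bp size is
centred on each region midpoint — the boundary preset. Minus-strand
regions are flipped before averaging (a flag disables this).
`aggregate_pairs()` centres a fixed window on each region-pair pixel
(the APA-style loop pileup) and reports the centre-versus-outer-ring
enrichment. Cells with no contributors are missing, not zero, and region
order never affects the result.

## Comparisons

`compare_samples()` computes difference (minuend first: `compare(a, b)` is
positive where `a` has more) or fold-change (missing where the denominator
is 0, optionally log2) between matrices with identical bin sets or between
score tracks on their common bins. Matrices are deliberately *not*
re-binned on the fly — silent coarsening hides errors. The result behaves
like any other matrix or track, so insulation-difference tracks feed
straight into boundary calling.

`matrix_pca()` turns each sample's filtered pixel vector into one
observation and decomposes the centred sample-by-pixel matrix by SVD.
By default pixels are O/E, intra-chromosomal and between 100 kb and 10 Mb
of the diagonal — pixels far from the diagonal and inter-chromosomal
pixels are dominated by noise; top-k filters by cross-sample variance or
mean value narrow the features further.

## The synthetic generator

`simulate_matrix()` draws Poisson counts around the intensity

$$\mu_{ij} = \mathrm{scale} \cdot (1 + |i-j|)^{-\alpha} \cdot \mathrm{plaid}(i,j) \cdot \mathrm{tad}(i,j) \cdot \mathrm{loop}(i,j),$$

with alternating compartment blocks multiplying same-label pixels by
$(1+c)$ and cross-label pixels by $1/(1+c)$, a within-TAD enrichment
factor, and focal loop multipliers. Optional multiplicative log-normal
noise perturbs $\mu$ *before* the Poisson draw, so counts stay integer —
the loop caller's Poisson model and exact byte-level reproducibility both
require integer counts. One integer seed determines everything;
per-module sub-streams are derived deterministically from it, and truth
tables (boundary BED, loop BEDPE, compartment labels) use the same
dialects the analysis functions consume.

`simulate_pairs()` plants valid pairs and disjoint artefact classes
(duplicates, self-ligations, short inward/outward pairs, low-quality,
unmapped, multimapping mates) in exact numbers on a regular synthetic
fragment map, so each filter's removal count can be compared to its
planted count exactly.

What the generator emulates: distance decay, compartment plaid, domain
blocks, focal loops, Poisson counting noise, and the standard read-pair
artefact classes. What it does not: fragment-level biases (GC, mappability,
fragment length), inter-chromosomal structure, translocations, copy-number
variation, or polymer physics. Tests passing on these fixtures show the
algorithms recover the structures they model at realistic noise; they do
not certify behaviour on artefacts the generator does not produce.

### Fixture design and problem sizes

Simulated chromosomes of 150–1 000 bins at 50 kb (7.5–50 Mb), pair sets of
10 000–40 000, and 50 replicate null simulations keep the full test suite
within a couple of minutes while leaving every statistic well inside its
asymptotic regime. Two fixture choices deserve note. Planted TAD
boundaries use enrichment 3 with log-normal noise $\sigma = 0.2$, a
contrast comparable to clearly visible domains in real maps. Planted loops
are placed with pairwise Chebyshev separation of at least 12 bins — twice
the neighbourhood radius — so no loop contaminates another's donut, and
the simulated depth (scale 150) gives a background of about 2.5 expected
counts at the farthest planted offset, hence a planted 8-fold loop has
near-complete Poisson detection power. At substantially lower depth a
recovery test measures sequencing depth, not caller correctness.

## Numerical choices and degenerate inputs

* Balancing tolerance $10^{-10}$ on the marginal residual, Sinkhorn polish
  to $10^{-14}$; non-convergence is an error naming the chromosome, and
  bins with zero marginal inside a balanced group are excluded up front.
* Coordinates are 0-based half-open throughout; BED is native, GFF is
  converted on read. Chromosome order is FASTA/input order and fixes the
  global bin indexing.
* Expected values at distances with no valid pairs are missing; an O/E
  request hitting a zero expectation with a non-zero pixel is an error
  (inconsistent profile), not a silent infinity.
* Degenerate correlation matrices warn; eigenvector sign is always fixed
  deterministically.
* Insulation at bins whose raw score is 0 is missing under either
  normaliser (log of zero).
* Plateau extrema collapse to the central bin, left of centre on even
  plateaus, making boundary positions deterministic.
* The pair-filter order is fixed so that attribution is reproducible; the
  full failure mask is returned for anyone who wants joint attribution.

## Limitations

Per-chromosome dense operations (balancing, correlation, insulation,
loop neighbourhoods) are sized for chromosomes of up to a few thousand
bins — ample for binned analyses at 25 kb and coarser on mammalian
genomes, but not for fragment-level whole-genome matrices. The native
container is a plain-text directory (deterministic TSV/JSON), chosen for
transparency and exact round trips rather than storage density; binary
interchange formats are out of scope. FASTQ alignment, allele-specific
matrices and interactive browsing are likewise out of scope.
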