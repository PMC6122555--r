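---
title: "Learning chromatin-mark signatures with an unsupervised Hebbian network"
author: "hebbsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning chromatin-mark signatures with an unsupervised Hebbian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hebbsig)
library(GenomicRanges)
```

## The problem

ChIP-seq experiments report, for each histone modification, a set of genomic
intervals (peaks) where the mark is present. Given thousands of regions that
share a function -- all active promoters of a tissue, all enhancers, all
coding regions of expressed genes -- the question is whether these regions
share a *chromatin signature*: a consistent spatial arrangement of tens of
marks. Inspecting individual regions is hopeless (any single region is
noisy), and averaging blurs the picture. `hebbsig` learns one prototype
vector summarising all regions at once, using an unsupervised Hebbian
associative network, and renders it as a digitised red/blue image.

## Region digitisation

Every region is sampled at `n_lines` equally spaced vertical lines bounded
by the region: line $k$ of region $[s, e)$ (0-based half-open, as in BED)
sits at

$$p_k = s + k \frac{e - s}{n_{\text{lines}} - 1}, \qquad k = 0, \dots,
n_{\text{lines}} - 1 .$$

Entry $(i, j)$ of the region's matrix is $+1$ when some peak of mark $i$
contains line $j$ ($\text{start} \le p_j < \text{end}$, the same half-open
convention as the input intervals), else $-1$. The matrix is flattened --
column-wise by default -- into the *epigenetic vector* $b$. Because the
lines rescale with the region, fixed-size promoters and variable-size
coding regions are handled identically; `n_lines` is a resolution knob
(41 by default, 91 for long elements such as 4.4 kb promoter windows).

Line positions are kept as exact rationals of the region length; there is
no binning or rounding, so the encoding of synthetic data with
integer-aligned peaks is exact rather than approximate.

Three curation rules run before encoding, in this order: each region is
expanded by `fraction` (default 0.1) of its length on both ends, rounded to
the nearest base (ties away from zero), so the signature shows how marks
decay into the flanks; overlapping or abutting regions are merged;
and sets larger than 10,000 regions are down-sampled to 500 per chromosome
under a seed. The package samples *after* merging -- sampling first could
re-introduce overlaps through expansion. Expansion is truncated at
coordinate 0 but not at chromosome ends, since no sizes file is required;
regions within `fraction * L` of a chromosome end will extend past it, and
peaks cannot exist there, so the affected columns simply read $-1$.
The vertical lines are placed across the *expanded* region: the flanks are
part of what the signature is meant to show.

## Preprocessing

Two denoising steps, in this order:

1. **Background filter.** A vector whose similarity with the all-$(-1)$
   vector is at least 0.8 carries essentially no signal; such regions are
   likely false positives of the upstream caller and are removed. The
   boundary is inclusive, and the similarity of $\pm 1$ vectors is computed
   under a single square root so that e.g. a length-10 vector with nine
   $-1$ entries scores exactly $8/10 = 0.8$ and is removed, untroubled by
   floating-point rounding.
2. **Consensus denoising.** Each vector is compared with two reference
   vectors drawn uniformly from the same set -- two distinct indices,
   excluding the vector itself ("two *other* vectors"); entries that do not
   agree across all three are set to 0. Draws are independent per vector
   and seeded. A zero entry is an abstention: during training it leaves the
   corresponding weight unchanged (see below), which is exactly the
   behaviour one wants from "no evidence".

## The Hebbian network

The network associates two stimuli: the unconditioned stimulus $b$ (an
epigenetic vector) and the conditioned stimulus $p$, always the ones
vector. With the saturating linear transfer function

$$\mathrm{satlins}(x) = \begin{cases} +1 & x \ge 1 \\ x & -1 < x < 1 \\
-1 & x \le -1 \end{cases}$$

the response to a stimulus pair is $a(b, w, p) = \mathrm{satlins}(b + w
\odot p)$ and one presentation updates the weights by

$$w \leftarrow w + \alpha \, (a(b, w, p) - w) \odot p .$$

$\alpha \in (0, 1]$ is simultaneously the learning and the decay rate. For
$p = \mathbf{1}$ each update is a convex combination of $w$ and the
(bounded) response, so weights started at zero can never leave $[-1, 1]$.
After training, presenting $p$ alone ($b = 0$) returns $w$ itself: the
network recalls the learned prototype, and that prototype *is* the
chromatin signature. Where the presence of a mark at a line is consistent
across regions the weight saturates towards $\pm 1$; where it is
inconsistent the weight hovers near 0.

Choices the update rule leaves open, and what this package does:

* **Initial weights** are zero -- the natural "no prior association" state;
  the first response is then $\mathrm{satlins}(b)$.
* **$\alpha$ defaults to 0.1** with a **single epoch**. The rule only asks
  for a small $\alpha$; 0.1 makes the prototype reflect roughly the last
  few dozen presentations while still integrating hundreds, and one pass
  over 500+ vectors is ample for convergence of saturated entries (the
  closed form below reaches $|w| = 0.99$ after 44 consistent
  presentations). Both are exposed in `train_signature()`.
* **Presentation order** is shuffled under a seed (`shuffle = TRUE`).
  Order affects the result only at $O(\alpha)$; the seed makes any run
  bit-reproducible.
* For a constant input $v \in \{-1, +1\}^n$ the loop has the closed form
  $w_k = (1 - (1 - \alpha)^k)\, v$, which the tests pin to $10^{-12}$ --
  this, not the default constant, fixes the semantics of the update.

## Comparing signatures

`dotsim` is the dot product of norm-normalised vectors (cosine
similarity), applied either to whole signatures or to one mark's row of
the weight matrix. Values near $+1$ mean the mark behaves identically in
both signatures, near $-1$ that its distributions are opposite, near $0$
that at least one side is inconsistent and the mark should not drive the
comparison. `compare_signatures()` flags marks at $\pm\tau$ with
$\tau = 0.5$ by default, following the convention that averages below
$-0.5$ indicate a genuinely different mark. When a row has zero norm the
similarity is undefined; the package returns 0 and the flag
`inconsistent` rather than erroring, because zero rows arise routinely
from denoised or untrained data.

**Directional marks.** For promoter-like elements, a mark whose profile
over the first (upstream) third of the lines has *negative* dotsim with
its profile over the last (downstream) third is called directional. Thirds
take $\lfloor n/3 \rfloor$ columns from each end; the middle remainder is
ignored. Directionality is computed in the signature's stored column
order, so strand groups are analysed separately (or encoded with
`orient_by_strand = TRUE` first). `directional_percentage()` aggregates
calls across tissues, reporting only marks known in at least five tissues,
and `average_mark_dotsim()` averages paired per-mark similarities across
tissues.

## Visualisation

Mark rows of the weight matrix are clustered bottom-up with city-block
distances and WPGMA linkage: after merging clusters $A$ and $B$, the
distance to any $C$ is $(d(A,C) + d(B,C))/2$ regardless of cluster sizes.
Ties are broken by the lexicographically smallest pair of cluster indices
and leaves are read lower-index subtree first, so the dendrogram -- and
the rendered image -- is bit-reproducible. (WPGMA distances to a merged
cluster are averages of two distances that are each at least the current
merge height, so heights are monotone; the code still checks and warns.)

The image maps each weight $v$ (clipped to $[-1,1]$) to
$\text{red} = \lfloor 255 (v+1)/2 + 0.5 \rfloor$, $\text{blue} = 255 -
\text{red}$, green 0: $+1$ is pure red, $-1$ pure blue, 0 the purple
midpoint (128, 0, 127) under round-half-up. Each entry paints a
`cell_px` x `cell_px` block (default 10). `average_profile()` provides the
no-learning baseline (componentwise means), and `cluster_regions()` runs
the same linkage over whole region vectors (row-wise flattened, keeping
each mark's row contiguous) to check whether a set contains one signature
or several before training.

## The synthetic generator

`planted_signature()` + `simulate_tracks()` emit a BED region file, one
BED peak file per mark and a JSON truth file, from a planted $\pm 1$
profile per mark corrupted by independent flip noise. What it emulates:
per-mark peak tracks whose presence at each sampled position follows a
positional profile; region sets on one or both strands (minus-strand
regions follow the column-reversed profile, via `mirror_fixture()`);
seed-exact reproducibility. Defaults are 10 marks, 41 lines, 500 regions
of 400 bp, 10% expansion and flip noise 0.1 -- the scale of one tissue's
enhancer set after down-sampling, with noise high enough that single
regions look unreliable while the set carries a clear signal.

Two deliberate artificialities: peak boundaries are aligned to the line
grid (each present line contributes a window of one line-spacing centred
on it, runs merged), and noise is independent per (region, mark, line).
That makes the zero-noise round trip through `read_bed()`,
`expand_regions()`, `merge_overlaps()` and `encode_regions()` *exact* --
the geometry constraint that the expanded length be divisible into an even
integer line spacing is enforced by the constructor -- so encoding bugs
cannot hide inside Monte-Carlo tolerance. The cost is that passing tests
say nothing about ragged real peak boundaries, correlated noise along a
region, mark-mark correlations, or signal-strength variation; real
narrowPeak tracks have all of these. Recovery results on this generator
are therefore a correctness check of the pipeline, not a performance claim
about real epigenomes.

The planted profile is drawn under `seed` and the flip noise under
`seed + 1`, so both derive from one user-visible seed without sharing a
stream.

## Problem sizes and numerical notes

The shipped tests exercise, among others: full-pipeline recovery (10
marks x 41 lines x 500 regions, noise 0.1) across ten seeds, demanding
cosine similarity of at least 0.9 with the planted truth; the
strand-mirror experiment at the same scale; WPGMA against a brute-force
recursive oracle on fifty random 6-item distance matrices (plus agreement
with `hclust(method = "mcquitty")` on tie-free inputs); and byte-identical
TSV/PNG outputs across repeated seeded runs. Degenerate inputs are handled
as follows: zero-width regions error at encoding; empty training sets
error; all-zero vectors are removed with a warning at filtering; fewer
than three vectors skip denoising with a warning; a single mark renders
without clustering.

## Known limitations

* Binary peak membership only; no signal-valued (bigWig) encoding.
* One signature per trained network -- heterogeneous region sets should be
  clustered first and trained per cluster.
* No chromosome-end truncation of expanded regions.
* No significance testing of similarity values; they are descriptive.
* CpG-content partitioning of promoters and expression thresholding are
  upstream of this package: it consumes pre-partitioned BED files.
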