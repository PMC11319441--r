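---
title: "chromcore: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromcore: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcore)
```

# Overview

`chromcore` analyzes how a chromatin interaction network reorganizes between
cellular states. Its inputs are standard genomics artifacts on a fixed
genomic bin grid (default 200 kb): protein binding peaks (BED), tables of
differential chromatin interactions between two conditions (bin pairs with a
log fold change and an FDR), per-chromosome contact matrices, and a gene
expression table with per-contrast log fold changes. From these it:

1. calls **dense binding regions** from peak density,
2. builds per-chromosome **differential interaction networks**,
3. computes the **k-core decomposition** of the gained-interaction network,
4. assigns each network bin to one of five **connectivity classes**,
5. derives **A/B compartment scores** from the contact matrices, and
6. **integrates** classes with expression, compartments and binding.

All coordinates are 0-based, half-open. All text outputs are written with
LF line endings and full-precision `%.17g` floats so that repeated runs are
byte-identical.

# Dense binding regions

Peak density is measured with a rolling window (100 kb window, 5 kb step)
over peak *midpoints*. The calling threshold is found automatically as the
knee of the sorted window-count curve: counts are reduced to their
**distinct** sorted values, and the threshold is the value at maximal
perpendicular distance from the chord connecting the curve's endpoints.

Two deliberate numerical choices:

* **Distinct values, not raw ranks.** With raw ranks the knee position
  depends on how many windows share each count, so adding empty windows
  (e.g. longer chromosomes) would move the threshold. On distinct values the
  knee depends only on the shape of the count distribution.
* **Ties break toward the smaller rank** (smaller count), making the
  threshold deterministic; and stitching keeps windows with counts
  **strictly greater** than the threshold, so the degenerate all-equal curve
  selects nothing rather than everything.

Windows above threshold are stitched into regions by merging touching window
extents. Calling is monotone: adding peaks can only grow regions at a fixed
threshold.

One geometric caveat: an interior peak midpoint is covered by exactly
`window/step` windows, but midpoints within `window - step` of a chromosome
start (or near the end) are covered by fewer, because window starts cannot
be negative and windows are clipped at the chromosome end.

# Differential networks and k-core decomposition

Each differential interaction table is filtered (FDR ≤ 0.05 by default),
deduplicated deterministically (per unordered bin pair: smallest FDR, then
largest |logFC|), and split per chromosome into an undirected graph whose
vertices are bins and whose edges carry the logFC sign ("increased" /
"decreased").

The core decomposition is computed on the **increased-edge** subgraph with
the linear-time bucket-peeling algorithm: repeatedly remove the vertex of
minimum remaining degree; a vertex's core number is the largest k such that
it survives peeling to the k-core. This is O(V+E) and exact. The test suite
verifies it against a brute-force oracle (iterated deletion until the
minimum-degree condition stabilizes, for every k) and against an independent
third-party implementation. Bins are reported with their core number, a
coarse tier (low < 3, medium 3–5, high > 5), and the per-chromosome maximum
core (k-max) with its degeneracy-core membership.

# Five-class bin classification

Network bins are labeled with the first matching rule (precedence matters):

| Class   | Rule |
|---------|------|
| Core    | core number ≥ 6 in the gained network |
| AltCore | core number ≥ 4 inside a connected cluster *detached* from the Core |
| Peri    | ≥ 1 increased edge to a Core bin |
| ExCore  | ≥ 1 decreased edge to a Core or AltCore bin |
| Other   | any remaining network bin |

Bins outside the network are Background. The **AltCore attachment rule** is
deliberately robust: a high-core cluster counts as *attached* to the Core
(and therefore is absorbed rather than labeled AltCore) only if it has at
least `altcore_attach_min_edges` (default: equal to the AltCore core
threshold, 4) increased edges onto Core bins. A single spurious edge between
two dense communities — common at realistic noise levels — therefore cannot
collapse a genuine alternative core into the main one.

# Compartment scores

Per chromosome: bins whose total contact coverage falls below the 2 %
quantile (or is zero) are masked; the matrix is balanced with **ICE**
(iterative correction: divide rows/columns by their row sums, renormalized
each round). Iteration stops when the maximum relative deviation of row sums
from their mean falls below `tol = 1e-5` or after 200 iterations (with a
warning — never silently). The stopping statistic is scale-free, so the
tolerance means the same thing for raw counts and normalized matrices.

The balanced matrix is distance-corrected to observed/expected using
per-diagonal means, and the compartment score is the first eigenvector of
the Pearson correlation matrix of the O/E matrix. Eigenvector sign is
arbitrary, so the track is oriented against a reference bedGraph (e.g. a
gene-density or GC-content proxy): the sign is chosen to make the
correlation with the reference non-negative, and positive scores denote the
A compartment. Without a reference the track is returned unoriented with a
warning.

# Synthetic data generator

The generator plants known structure so every stage can be scored against
truth:

* **Peaks:** Poisson background (100 peaks/Mb-scaled default) plus a
  10-fold enriched 2 Mb interval per chromosome.
* **Differential network:** an increased-edge clique on the planted Core
  bins, a detached increased clique on the AltCore bins, increased edges
  from Peri bins to the Core, decreased edges from ExCore bins, sparse
  uniform noise edges with random signs. Edge logFCs are drawn as
  `sign × |N(role mean, 0.3)|`, which guarantees the sign structure while
  keeping realistic magnitude spread. The second contrast is the exact
  row-wise sign flip of the first, modeling a clean reversal experiment.
* **Contacts:** power-law distance decay (`scale · d^{-1}`), a checkerboard
  compartment boost (×1.5 within same-label 10-bin blocks), and
  multiplicative log-normal noise.
* **Expression:** per-class Gaussian logFC means (repressed in
  Core/Peri/AltCore, activated in ExCore in contrast 1; reversed in
  contrast 2), two genes per labeled bin plus background genes.

Determinism: each generator draws from its own substream,
`derive_seed(seed, offset) = (seed·7919 + offset) mod 2147483647`, so
simulating contacts never perturbs a later peak simulation.

**Realism and limits.** The generator captures the qualitative structure the
pipeline targets — dense cliques, detachment, sign-coherent reversal,
distance decay with plaid compartments — but it is not a biophysical model:
real Hi-C has domain structure below the compartment scale, differential
calls have correlated errors along the diagonal, and real "reversal"
contrasts are never exact sign flips. Recovery rates on synthetic data are
upper bounds on real-data performance.

# Problem sizes and performance

The implementation targets bin-level (≥ 100 kb) resolution on ordinary
hardware: ~15 000 bins genome-wide at 200 kb, networks of 10²–10⁴ edges per
chromosome, contact matrices up to a few thousand bins per chromosome
(the O/E correlation PCA is O(n³) in bins per chromosome, the practical
ceiling). The full synthetic pipeline (3 × 25 Mb chromosomes) runs in a few
seconds; peeling and stitching are linear.

# Limitations

* Only cis (intra-chromosomal) interactions are analyzed; trans rows are
  counted and dropped.
* Classification is binary per rule (an edge either qualifies or not);
  weighting by logFC magnitude is not attempted.
* The compartment sign convention is only as good as the reference track.
* The knee threshold assumes a convex-ish count curve with a genuine corner;
  flat or purely linear profiles are rejected as degenerate rather than
  guessed at.
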