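---
title: "Predicting receptive fields from connectome wiring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting receptive fields from connectome wiring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexelmap)
```

## The problem

Modular ("hexel") cell types of a retinotopic neuropil occur once per
column, so each cell stands for one hexagonal pixel of the visual image.
Given a cell table and a synapse edge list, the package (i) pins hexel
cells to integer lattice coordinates, (ii) turns synapse counts into
column-stochastic input fractions, (iii) builds spatial maps of mono-, di-
and tri-synaptic input to any downstream neuron, and (iv) summarizes those
maps geometrically. The maps are *anatomical predictions*: the
connectivity-predicted classical receptive field (pCRF) of a neuron is the
map of its direct hexel-type input, and multi-step pathway maps predict
extraclassical components (pERF). No dynamics are modelled; everything is
a function of the static wiring diagram.

## Lattice conventions

Axial coordinates $(p, q)$ embed as
$x = (p-q)\tfrac{\sqrt3}{2}a$, $y = (p+q)\tfrac{a}{2}$ with lattice
constant $a$ (default 1) and flat-topped hexagons of side
$s = a/\sqrt3$. All three cardinal axes point upward: $v$ at $0^\circ$
(step $(1,1)$), $p$ at $+60^\circ$ (step $(1,0)$), $q$ at $-60^\circ$
(step $(0,1)$); angles are measured clockwise from vertical, and
orientations are axial (mod $180^\circ$, reported in $(-90, 90]$). The
orthogonal axes $h, p^\perp, q^\perp$ point to next-nearest neighbours.
Anatomical axis names (dorsal, anterior, ...) are deliberately not
modelled: the lattice is treated as perfectly regular, which real
neuropils only approximate, so all directions are abstract lattice
directions.

## Lattice assignment

Cells of one type are placed by maximum-weight linear assignment against
an already-placed reference type, with affinity the synapse count between
each candidate pair. The direction of those counts is configuration; the
default sums both directions, which is symmetric and avoids an arbitrary
choice when the two types connect reciprocally. Assignment proceeds along
a chain from a single anchored type (the anchor is always an *input*:
from a grid file or from the generator — the package never infers it).
The default chain places L1–L5 from the anchor Mi1 and the remaining
hexel types from L1; which L type mediates the second stage is genuinely
open, and L1 was chosen once as the default because it is the most
numerous lamina monopolar type in practice. Rectangular cases solve a
rectangular assignment and leave the excess unmatched; zero-affinity
matches are discarded rather than invented. The solver is a shortest
augmenting path / dual potential ("Hungarian") implementation written
in-package and is validated against exhaustive permutation search for
$n \le 6$.

## Input fractions and pathway strength

$P_{ab} = W_{ab} / \sum_c W_{cb}$ is the probability that a backwards
random walk at $b$ steps to $a$; the type-level $P_{AB}$ is computed from
the *aggregated* type matrix $W_{AB}$, not as a mean of cell-level
fractions — the two differ whenever input totals vary across cells, and
the aggregate definition is the one with the random-walk interpretation.
Zero-input columns stay identically zero (never `NaN`) and their count is
logged. The anatomical strength of a disynaptic pathway
$A\!\to\!B\!\to\!C$ is $P_{AB}P_{BC}$, the probability of walking it
backwards; rankings constrain the source to the hexel roster and the
intermediary to non-hexel types, optionally filtered to presumed
excitatory intermediaries. Ties are broken deterministically (strength
descending, then intermediary, then source label).

## Connectivity maps

Monosynaptic maps place $W_{ab}$ (or $P_{ab}$) at the source cell's
lattice position; di-/tri-synaptic maps place products of input fractions.
Intermediaries need no lattice position — maps are indexed by source
position only, which is what makes pathway maps well-defined even for
unplaced interneuron types. Summed over positions, sources and
intermediaries, pathway maps total exactly 1 for any target whose every
contributing intermediary has input; this normalization is tested to
$10^{-9}$ on random connectomes in which every cell is guaranteed at
least one input synapse (a target fed by an input-less intermediary
absorbs that mass, so the guarantee is part of the fixture, not a fudge).

Map centres convolve with a filter of 1.1 at the centre and 1.0 at the six
neighbours and take the strict argmax; the 10% centre bonus breaks the
symmetry of flat map plateaus toward the supported column. Argmax ties are
resolved toward the smallest $p+q$, then smallest $p$ — an arbitrary but
fixed scan order. Averaging aligns each map's centre to the origin, crops
to a hexagonal ball (default radius 8 columns — the default is a display
window wide enough to contain a $k=3$ bar plus end-zone offsets of
$\pm 3$ with margin; it is configuration, not science), and treats hexels
absent from a map as 0, since maps are dense fields sampled sparsely.
The per-hexel spread across cells is the population (divide-by-$n$)
standard deviation. Which weight mode feeds ellipse fitting is
configuration: synapse counts for monosynaptic maps and probabilities for
multi-synaptic maps by default.

## Ellipse approximation

Normalizing a map gives point masses $p_i$ at hexel centres; the ellipse
is defined by the weighted covariance plus a hexagon correction:

$$C = \sum_i p_i
\begin{pmatrix}(x_i-\bar x)^2 & (x_i-\bar x)(y_i-\bar y)\\
(x_i-\bar x)(y_i-\bar y) & (y_i-\bar y)^2\end{pmatrix}
+ \frac{5s^2}{12} I$$

with length $2\sigma_{\max}$, width $2\sigma_{\min}$ from the
eigenvalues and orientation from the principal eigenvector. The
correction prevents single-hexel maps from collapsing to zero size: with
it, a lone hexel has length = width = $s\sqrt{5/3}$. The constant
$5s^2/12$ is the field's established convention for hexel images. It is
worth recording its geometric content precisely: the per-axis variance of
a uniform distribution over a flat-topped hexagon of side $s$ is
$5s^2/24$ (the package's `sample_hexagon()` Monte-Carlo confirms this to
three standard errors at $10^6$ samples), so $5s^2/12$ — twice that —
equals the hexagon's *total* planar variance
$\mathbb{E}[x^2+y^2]$ applied to each axis. Literal per-axis hexagon
smearing would give a lone hexel width $s\sqrt{5/6}$ instead of
$s\sqrt{5/3}$. The package keeps the $5s^2/12$ convention for
comparability, and the test suite documents both facts rather than
blurring them into one.

A $k$-column collinear bar with equal weights then has the closed-form
aspect $\sqrt{(3k^2+2)/5}$ ($\approx 2.408$ at $k=3$), the oracle used by
the recovery studies. Reported widths are $2\sigma$ — full width at
$e^{-1/2}\approx 0.6$ of maximum; `gaussian_width()` converts to FWHM
($2\sqrt{2\ln 2}\,\sigma \approx 2.4\sigma$). Isotropic covariances are
flagged degenerate and reported as orientation $0^\circ$, aspect 1,
rather than an arbitrary eigenvector direction.

## 1D projections

Cardinal projections group hexels by $p+q$, $2p-q$ or $2q-p$ and smooth
with $[0.5, 1, 0.5]$ at stride 2, sampled on even keys so a key-0 bin
always exists; the resulting coordinate is in lattice constants, and the
kernel splits odd-key mass between adjacent bins so totals are conserved
exactly. Orthogonal projections group by $q-p$, $q$ or $p$ with no
smoothing, in units of $a\sqrt3/2$. Population curves report per-bin mean
and population SD with absent bins as 0. Orientation populations use
axial statistics (doubled-angle construction) so clusters at
$\pm 89^\circ$ summarize near the $90^\circ$ boundary, not near zero.

## Wiring diagrams

Type-level edges are kept when $P_{AB} \ge$ threshold (inclusive, default
3%), signed by the presumed sign of the presynaptic type — signs are user
annotations (e.g. from neurotransmitter predictions), never computed.
Strong per-cell partners use a *strict* count cutoff (`> min_synapses`);
the asymmetry (inclusive fraction threshold, strict count threshold) is
intentional and mirrors how the two conventions are stated in this
literature. Raising the threshold is a monotone filtration, which the
tests assert over a sweep.

## The synthetic generator

The generator produces what the analysis assumes, with known truth:

- a lattice of $n_p \times n_q$ columns (default $15 \times 15$ for the
  study configurations), one cell of each of the 11 default hexel types
  per column, with same-column coupling synapses along the assignment
  chain (mean 10 per direction) carrying the assignment signal;
- target cells receiving input bars of $k$ collinear columns along a
  cardinal axis from a designated source type. The reference studies use
  $k = 3$, mean $\lambda = 8$ synapses per contacted column and 200 cells
  split over the three axes — an oriented-bar regime of realistic synapse
  scale for columnar inputs;
- intermediary cells relaying source input from longitudinal offsets
  beyond the bar ($\pm 2, \pm 3$ columns in the end-zone study), one
  intermediary cell per (target cell, offset), unplaced on the lattice;
- a signed type-to-type circuit: every pre-cell within kernel radius
  $\rho$ (default 1 column) of a post-cell connects, giving intended
  wiring edges for precision/recall scoring;
- background noise as independent spurious unit-count synapses per
  ordered cell pair. "Mild" noise in the recovery study is $2\times
  10^{-4}$ per pair — a handful of spurious inputs per cell, enough to
  perturb but not bury a 24-synapse bar.

Counts on intended edges are Poisson($\lambda$) truncated below at 1, so
intended topology is never lost; a `fixed_counts` switch makes every
count exactly $\lambda$ for the zero-noise configuration, because "exact
recovery" of the closed-form aspect is only a meaningful statement when
count noise is off (orientation, by contrast, is exact for any collinear
weights). Each generation stage draws from its own seeded stream, so
turning noise on does not move bars. Bars or end-zone pathways that would
leave the lattice are avoided by the placement margin where possible and
otherwise truncated and flagged; flagged cells are excluded from
geometric recovery metrics.

What the generator does **not** emulate: neuropil curvature and
eye-border distortion (beyond truncation flags), realistic per-type cell
counts, proofreading gaps (partial hexel coverage), reciprocal-synapse
statistics, or biological synapse-count overdispersion. Passing recovery
tests therefore demonstrate correctness of the pipeline's computations
under its stated assumptions — not that real tissue satisfies those
assumptions.

## Numerical choices and problem sizes

Zero-input columns pass through normalization as zeros; empty maps raise
on centre/ellipse/projection operations and exclude a cell from averaging
with a logged message. The test suite runs entirely on generated
fixtures: lattices from $3\times3$ to $21\times21$, random connectomes of
50–100 cells (50 seeds for the normalization property), 100 seeded
affinities for the assignment oracle, $10^6$ hexagon samples for the
Monte-Carlo moment check, and the three reference studies
(`study_config()`); the full suite runs in well under a minute. These
sizes were chosen as the smallest that make each statistical assertion
sharp.

## Known limitations

- Assignment quality degrades gracefully but silently when the
  connectivity signal between chained types is weak; only the recovery
  accuracy metric reveals it.
- The hexagon-correction convention (above) makes small maps slightly
  wider than literal column smearing would; comparisons across software
  should check which constant is in use.
- Orientation of near-isotropic maps is noise-dominated even when not
  flagged degenerate; population summaries should always be read together
  with aspect ratios.
- The pipeline assumes one cell per column per hexel type; genuinely
  non-modular types should not be placed on the lattice (intermediaries
  never need to be).
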