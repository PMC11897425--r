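---
title: "How jellyplot lays out spatio-temporal clonal evolution"
author: "jellyplot authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How jellyplot lays out spatio-temporal clonal evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellyplot)
```

## The problem

A solid tumor sampled at several anatomical sites and time points is a set
of bulk samples, each a mixture of subclones related by a phylogenetic
tree. Two structures must be shown together: the *phylogeny* (which
subclone descends from which) and the *sample tree* (which sample is
assumed to seed which — the metastasis route). jellyplot embeds the first
into the second: columns are time **ranks**, rectangles are samples,
stacked **slabs** are clonal prevalences, **bells** mark where a subclone
first emerges, and **tentacles** trace its inheritance along sample-tree
edges.

## Data model and validation

Inputs are three TSV tables (UTF-8, tab, header row; ids are opaque
tokens). The phylogeny must be a single rooted tree; the sample tree may
be a forest — parentless samples become children of a synthesized
inferred-root marker at rank 0 — and a parent's rank must be strictly
smaller than its child's, with rank gaps permitted so a path can skip a
rank. Per-sample prevalences must be non-negative and sum to 1 within
1e-6; sums *below* 1 (a normal-cell fraction removed upstream) are
renormalized with a warning so slabs fill the frame, while sums above
1 + 1e-6 are errors. After validation rows are rescaled by their exact
sum, which is why slab heights conserve frame height to machine precision
rather than merely to the input tolerance.

`import_clonevol()` accepts a consensus-tree style table (`lab`,
`parent` with `-1`/`0`/empty roots, optional `num.vars` as branch length,
per-sample `<sample>.frac` columns). Fraction cells in both the `45.0%`
and `0.45` dialects parse to the same value; bare values above 1.5 are
treated as percentages, since 0–100-scaled exports are common. When a
table carries several alternative clonal models (a `model` column or one
file per model in a directory), an explicit 1-based `model` index selects
one and defaults to the first — the upstream tool scores models, so the
first is its best.

`derive_sample_tree()` builds a sample tree from (sample, time point,
location) metadata: earlier time points are scanned **nearest first**, and
the first one containing *exactly one* same-location sample supplies the
parent; otherwise the inferred root does. We chose to keep scanning past
an ambiguous (two-candidate) time point rather than fall back to the root
immediately: an unambiguous ancestor two stages back is better evidence of
lineage than none at all. Ranks are 1-based time-point indices.

## Placement of emerging subclones

The emergence site of subclone $k$ is the lowest common ancestor, in the
sample tree, of every sample where any member of $k$'s clade (the founder
plus all descendants) is present. "Present" means prevalence above
$\varepsilon$, default $10^{-4}$: trace detections — a lymph-node sample
carrying a minute amount of a clade that dominates elsewhere is exactly
the polyclonal-seeding signal the plot should preserve — must count, so
$\varepsilon$ is small and configurable. If the founder itself is absent
at that LCA, the emergence is promoted upward to the nearest ancestor
sample containing it, or to the inferred root: the subclone must have
arisen in an earlier, possibly unobserved sample.

The inferred root sample is materialized only when it is needed: when two
or more real samples are parentless (concurrent diagnostic biopsies have
no common observed parent) or when some subclone is hosted there. A fully
specified tree with a single real root is left alone. Since the inferred
sample's composition is unknowable, the subclones hosted there — plus
their phylogenetic ancestors — are displayed in equal proportions.

## In-rank ordering

Within a rank, samples are ordered so that similar compositions sit
together. Two complementary measures are combined, because each fails
alone: the phylogenetic center of mass $c(s) = \sum_k p(s,k)\,
\mathrm{dfs}(k)$ is a cheap 1-D summary but degenerates for polyphyletic
samples (a mixture of the leftmost and rightmost clades can share a center
of mass with a pure middle clade), while the Jensen–Shannon divergence
(base 2, so it lives in $[0,1]$ bits) distinguishes any two distinct
compositions but induces no global axis. The objective summed over
adjacent pairs within each rank is

$$\sum_{\text{adjacent } (a,b)} w_{\mathrm{com}}
\frac{|c(a)-c(b)|}{n-1} + w_{\mathrm{jsd}} \, \mathrm{JSD}(p_a, p_b),$$

with default weights $(1, 1)$; dividing by $n-1$ puts the center-of-mass
term on the same $[0,1]$ scale as the divergence. The form is this
package's own declaration: it uses exactly the two measures above, is
invariant under reversing a rank, and is cheap to evaluate exactly.

Ranks with at most 8 samples ($8! = 40320$ permutations) are solved
exhaustively; larger ranks get a deterministic greedy nearest-neighbour
chain refined by 2-opt reversal passes (at most 100 sweeps), clamped so
the result is never worse than the input order. Real cohorts rarely put
more than 8 samples in one rank, so the exact path is the common case.
Ties are broken in a fixed order: total $|$parent slot $-$ child slot$|$
against already-placed earlier ranks (visual parent–child alignment,
shortening tentacles), then the orientation placing the
smaller-center-of-mass sample first, then input order. There is no
randomness anywhere in the optimizer, so figures are reproducible by
construction.

## Color scheme

Colors are assigned in OKLCH, the cylindrical form of the Oklab
perceptual space, where hue, chroma and lightness can be moved
independently. Hue is $(\mathrm{rotation} + \mathrm{dfs}(k)\cdot 360/n)
\bmod 360$: equal wheel segments in depth-first order, so adjacent slabs
get adjacent hues. Chroma and lightness are affine in the min–max scaled
total branch length, by default lightness $0.85 \to 0.45$ and chroma
$0.06 \to 0.16$: subclones with more accumulated mutations are darker and
more vibrant, pulling the eye toward the most evolved lineages. The
bounds keep the whole default ramp comfortably inside the sRGB gamut; a
degenerate (all-equal) branch-length range maps everyone to the midpoint,
and when no branch lengths are given every edge counts as 1, so depth
stands in for mutation count.

Mechanically darkened yellows read as brown, so hues in $[60°, 110°)$ at
lightness below 0.6 are blacklisted by default. 36 evenly spaced wheel
rotations are scored by the count, then the total penetration depth, of
dark hues inside blacklisted intervals; the best rotation wins and ties
go to the smallest rotation, keeping the scheme deterministic. If every
rotation is penalized the best one is still returned, flagged via the
`penalized` attribute. Out-of-gamut requests reduce chroma by bisection
at fixed lightness and hue — the two attributes that carry meaning — and
a `color` column in the phylogeny table overrides generation per
subclone. The root participates in the hue division like any other node;
users who want a neutral trunk can override it.

## Geometry

Frames are $100 \times 100$ abstract units with a 60-unit rank gap and
20-unit in-rank gap — pure rendering constants, configurable in
`layout_params()`. Slabs stack top-to-bottom in DFS order; because
preorder makes every clade a contiguous index interval, a clade's slabs
always form one contiguous band, and a bell's exit extent is defined as
that band. A bell outline is the clade's band center $\pm$ half-height
scaled by a logistic profile in the horizontal coordinate, renormalized
to be exactly 0 at the attachment point and exactly 1 at the frame's
right edge (a raw logistic reaches only $\sigma(s(1-m))$ there and would
break the exit-extent equality). Defaults: steepness 10, midpoint 0.6 of
frame width, and an attachment inset of 0.08 frame-widths per nesting
depth. Nested bells interpolate their center from the parent bell's
trajectory toward their own exit center along the same profile; combined
with the later attachment this guarantees a child outline never leaves
its parent's, with equality only possible at the shared frame edge —
which is why the nesting checks use a $10^{-9}$ tolerance rather than
strict inequality.

Tentacles exist for each (sample-tree edge, subclone) pair present above
$\varepsilon$ at both ends; each is a cubic Bézier between the subclone's
slab centers with both control points at the horizontal midpoint between
the two columns, so an edge's tentacles form a visually coherent bundle.
Edges that skip ranks simply span the intervening columns with no extra
waypoints. A subclone that disappears and later re-appears along a path
gets a new, tentacle-free slab at the re-appearance — the plot does not
invent continuity the data does not support.

The SVG serializer writes numbers at fixed 3-decimal precision and uses
the same downward-growing y axis as the layout, making byte-identical
output for identical inputs a testable invariant. Interactivity is out of
scope by design; static `<title>` tooltips carry prevalence and
branch-length details instead.

## The synthetic-data generator

`generate_fixture()` emulates the upstream decomposition a practitioner
would bring: a phylogeny grown by uniform attachment with integer branch
lengths up to 60 mutations, a sample tree in which every rank is occupied
and each sample picks a uniformly random earlier-rank parent (or the
inferred root, with probability 0.3), and compositions drawn per sample
by choosing one founding subclone (two with probability 0.3, producing
polyphyletic samples), dropping non-founder clade members with
probability 0.3, and normalizing Dirichlet(2) weights over the survivors.
Presence is therefore clade-coherent — every present subclone descends
from a founder that emerged in the sample's lineage — which is what
upstream tools emit. It does *not* emulate measurement noise in
prevalence estimates, shared trunks between unrelated founders being
absent, or longitudinal autocorrelation between a parent and child
sample's compositions; green tests therefore certify the layout algebra
(placement, ordering, conservation, nesting, determinism) on structurally
realistic inputs, not robustness to noisy clonal deconvolution.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` exercise: 200 random instances
(≤ 10 samples × ≤ 10 subclones) for host placement against a brute-force
oracle; 100 random single-rank instances of 2–8 samples against
exhaustive permutation search; 1000 random simplex pairs for the
divergence (agreement to $10^{-12}$); 100 random fixtures for slab
conservation ($10^{-9}$) and bell nesting at 100 sampled abscissae; and
1000 random colors for the Oklab round trip (error under 1/255 per
channel). These sizes cover the regime real cohorts occupy — tens of
samples, tens of subclones — where the whole pipeline runs in well under
a second per figure.

Degenerate inputs are handled explicitly: a subclone absent everywhere is
dropped from placement with a warning (it still gets a color and a legend
entry); a single-sample, single-subclone input yields one full-height
slab and no tentacles; an all-equal rank keeps its input order; and
validation failures name the offending row or sample.

## Known limitations

* No anatomical anchoring of samples to a body map, and no formal
  minimization of tentacle crossings; parent–child slot alignment is only
  a tie-break.
* The in-rank optimization is per rank (left to right), not a global
  multi-rank arrangement.
* Bell shapes are a declared parametrization, not a claim about any other
  renderer's pixel output.
* The inferred sample's equal-proportion composition is a display
  convention, not an estimate.
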