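# jellyplot

Spatio-temporal tumor evolution in one static figure.

Bulk tumor samples taken from different anatomical sites and time points
contain different mixtures of genetically distinct subclones. Fishplot-style
tools show how clonal fractions change over *time* in a single lineage;
anatomical maps show how they differ in *space*; jellyplot draws both at
once by embedding the subclone **phylogenetic tree** into a **sample tree**
that encodes the assumed metastasis/seeding route of the tumor. It is aimed
at cancer-genomics analysts who already have a clonal decomposition (e.g.
from ClonEvol) and want a single publication-ready figure of where each
subclone emerged and how it spread.

## The method

Three tab-separated tables go in:

* `phylogeny.tsv` — `subclone`, `parent`, optional `branchLength` (mutation
  count) and `color`;
* `samples.tsv` — `sample`, optional `parent`, integer `rank` (time point /
  treatment stage; a parent's rank must be strictly smaller than its
  child's), optional `rankTitle`;
* `compositions.tsv` — long-format `sample`, `subclone`,
  `clonalPrevalence` with per-sample prevalences p(s, k) ≥ 0,
  Σₖ p(s, k) = 1.

The layout engine then:

1. **Places emerging subclones.** For each subclone k, take all samples
   where any member of its clade (k plus descendants) is present and find
   their lowest common ancestor (LCA) in the sample tree. If
   p(LCA, k) ≈ 0, the emergence is promoted to the nearest ancestor sample
   where k is present, or to an *inferred root sample* — a hypothetical
   earlier sample drawn as the jellyfish "head" with all its subclones in
   equal proportions.
2. **Orders samples within each rank.** Each sample gets a phylogenetic
   center of mass c(s) = Σₖ p(s, k)·dfs(k), the prevalence-weighted mean of
   depth-first subclone indices, and pairs of samples get a Jensen–Shannon
   divergence JSD(p, q) = H((p+q)/2) − (H(p)+H(q))/2 in bits. The order
   minimizing Σ over adjacent pairs of |Δc|/(n−1) + JSD is found exactly
   (ranks of ≤ 8 samples) or by a deterministic greedy + 2-opt heuristic.
3. **Colors subclones.** Hues divide the OKLCH color wheel equally by
   depth-first position; chroma rises and lightness falls with total
   branch length, so highly mutated subclones are darker and more vibrant.
   A blacklist of murky dark-yellow hues is avoided by rotating the wheel.
4. **Renders SVG.** Samples are rectangles of stacked subclone slabs in
   rank columns; emerging subclones are nested logistic-growth bells;
   tentacle bundles connect a subclone's slabs across each sample-tree
   edge.

## Worked example

The package bundles a three-sample example (two concurrent diagnosis
samples `pAsc`, `pPer1` and an interval sample `iAsc` descending from
`pAsc`; three subclones with subclone 3 private to `iAsc`):

```r
library(jellyplot)
ex  <- system.file("extdata", package = "jellyplot")
phy <- read_phylogeny(file.path(ex, "phylogeny.tsv"))
st  <- read_sample_tree(file.path(ex, "samples.tsv"))
cm  <- read_compositions(file.path(ex, "compositions.tsv"), phy, st)
doc <- compose_layout(phy, st, cm)
doc
#> Jellyfish layout: 4 samples (1 inferred), 3 subclones, 6 tentacles, canvas 460x260
doc$hosts
#>               1               2               3
#> "inferred.root" "inferred.root"          "iAsc"
render_svg(doc, path = "example.svg")
```

Four samples are placed because the two concurrent diagnosis samples force
an inferred root (the head) at rank 0; subclones 1 and 2 emerge there
(their clades span both diagnosis samples, whose only common ancestor is
the inferred root) while subclone 3 emerges in `iAsc`, the only sample
containing it. Six tentacles = 2 shared subclones × 3 sample-tree edges.

The same figure from the command line:

```sh
Rscript inst/cli/jellyplot.R --phylogeny phylogeny.tsv --samples samples.tsv \
  --compositions compositions.tsv --out example.svg --stats
```

(exit codes: 0 ok, 1 I/O error, 2 validation error, 3 internal error).
`import_clonevol()` ingests ClonEvol-style consensus-tree tables directly,
and `derive_sample_tree()` builds a sample tree from per-sample time-point
and anatomical-location metadata.

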