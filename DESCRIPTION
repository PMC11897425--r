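Package: jellyplot
Title: Integrated Visualization of Spatio-Temporal Tumor Clonal Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds jellyfish plots that embed a subclone phylogeny into a
    sample tree, showing in a single static figure where tumor subclones
    emerge, how they are inherited across anatomical sites and time points,
    and how clonal compositions change along assumed metastasis routes.
    Reads tab-separated phylogeny, sample-tree and clonal-composition
    tables (or ClonEvol-style output), places emerging subclones by
    lowest-common-ancestor search in the sample tree, orders samples
    within each time rank by phylogenetic center of mass and
    Jensen-Shannon divergence, assigns a phylogeny-aware OKLCH color
    scheme, and renders the resulting layout as standalone SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
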