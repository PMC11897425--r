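# Input readers, validators, importer and sample-tree derivation.

test_that("phylogeny reading validates structure and defaults", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subclone\tparent\tcolor",
               "1\t\t#ff0000", "2\t1\t", "3\t1\t"), path)
  phy <- read_phylogeny(path)
  expect_s3_class(phy, "clone_phylogeny")
  expect_equal(phy$subclone, c("1", "2", "3"))
  expect_true(is.na(phy$parent[1]))
  expect_equal(phy$branch_length, rep(1, 3))  # absent column defaults to 1
  expect_equal(phy$color, c("#ff0000", NA, NA))

  expect_error(phylotree(data.frame(subclone = c("1", "2", "2"),
                                    parent = c("", "1", "1"))),
               "duplicate subclone", class = "jellyplot_validation_error")
  expect_error(phylotree(data.frame(subclone = c("1", "2"),
                                    parent = c("", ""))),
               "multiple roots", class = "jellyplot_validation_error")
  # mutual parents: no node reaches a root
  expect_error(phylotree(data.frame(subclone = c("1", "2"),
                                    parent = c("2", "1"))),
               class = "jellyplot_validation_error")
  # cycle off the root
  expect_error(phylotree(data.frame(subclone = c("r", "a", "b"),
                                    parent = c("", "b", "a"))),
               class = "jellyplot_validation_error")
  expect_error(phylotree(data.frame(subclone = c("1", "2"),
                                    parent = c("", "9"))),
               "unknown parent", class = "jellyplot_validation_error")
})

test_that("numeric-looking ids stay opaque tokens", {
  phy <- phylotree(data.frame(subclone = c("01", "1"), parent = c("", "01")))
  expect_identical(phy$subclone, c("01", "1"))
})

test_that("sample tree re-parents to the inferred root and checks ranks", {
  st <- sampletree(data.frame(sample = c("pAsc", "pPer1"),
                              parent = c("", ""), rank = c(1, 1)))
  root <- sample_tree_root(st)
  expect_equal(st$parent, rep(root, 2))
  expect_false(root %in% st$sample)

  expect_error(sampletree(data.frame(sample = c("a", "b"),
                                     parent = c("", "a"), rank = c(1, 1))),
               "earlier-rank", class = "jellyplot_validation_error")
  # paths may skip ranks
  st2 <- sampletree(data.frame(sample = c("a", "b"),
                               parent = c("", "a"), rank = c(1, 3)))
  expect_equal(st2$rank, c(1L, 3L))
  expect_error(sampletree(data.frame(sample = c("a", "b"),
                                     parent = c("", "zz"), rank = c(1, 2))),
               "unknown parent", class = "jellyplot_validation_error")
  # "-" and "NA" are root markers too
  st3 <- sampletree(data.frame(sample = c("a", "b"),
                               parent = c("-", "NA"), rank = c(1, 1)))
  expect_equal(st3$parent, rep(sample_tree_root(st3), 2))
})

test_that("compositions build a full matrix with absent pairs at zero", {
  cm <- compositions(data.frame(sample = c("s1", "s1"),
                                subclone = c("1", "2"),
                                clonalPrevalence = c(0.4, 0.6)))
  expect_equal(unname(cm["s1", ]), c(0.4, 0.6))

  phy <- phylotree(data.frame(subclone = c("1", "2"), parent = c("", "1")))
  cm2 <- compositions(data.frame(sample = "s1", subclone = "1",
                                 clonalPrevalence = 1),
                      phylogeny = phy)
  expect_equal(unname(cm2["s1", ]), c(1, 0))

  expect_error(compositions(data.frame(sample = c("s1", "s1"),
                                       subclone = c("1", "2"),
                                       clonalPrevalence = c(0.4, 0.7))),
               "sum to", class = "jellyplot_validation_error")
  expect_error(compositions(data.frame(sample = "s1", subclone = "1",
                                       clonalPrevalence = -0.1)),
               "negative", class = "jellyplot_validation_error")
  expect_error(compositions(data.frame(sample = "s1", subclone = "9",
                                       clonalPrevalence = 1),
                            phylogeny = phy),
               "unknown subclone", class = "jellyplot_validation_error")
})

test_that("sub-unit prevalence sums renormalize to 1 with a warning", {
  expect_warning(
    cm <- compositions(data.frame(sample = c("s1", "s1"),
                                  subclone = c("1", "2"),
                                  clonalPrevalence = c(0.3, 0.3))),
    "renormalizing")
  expect_equal(unname(cm["s1", ]), c(0.5, 0.5))
  expect_equal(sum(cm["s1", ]), 1)
})

test_that("tables round-trip through write and re-read unchanged", {
  dir <- withr::local_tempdir()
  phy <- toy_phylogeny()
  st <- toy_sample_tree()
  cm <- toy_compositions(phy, st)

  write_phylogeny(phy, file.path(dir, "p.tsv"))
  write_sample_tree(st, file.path(dir, "s.tsv"))
  write_compositions(cm, file.path(dir, "c.tsv"))

  expect_equal(read_phylogeny(file.path(dir, "p.tsv")), phy)
  expect_equal(read_sample_tree(file.path(dir, "s.tsv")), st,
               ignore_attr = FALSE)
  expect_equal(read_compositions(file.path(dir, "c.tsv"), phy, st), cm)
})

test_that("ClonEvol import converts one model to the native schema", {
  path <- system.file("extdata", "clonevol_tree.tsv", package = "jellyplot")
  res <- import_clonevol(path)
  expect_s3_class(res$phylogeny, "clone_phylogeny")
  expect_equal(res$phylogeny$subclone, c("1", "2", "3"))
  expect_equal(res$phylogeny$branch_length, c(120, 40, 65))
  expect_equal(unname(res$compositions["pAsc", ]), c(0.5, 0.5, 0))
  expect_equal(unname(res$compositions["iAsc", ]), c(0.2, 0.3, 0.5))

  # percent and plain decimal dialects parse identically
  tab <- function(cell) data.frame(lab = c("1", "2"), parent = c("-1", "1"),
                                   s1.frac = c(cell, "55%"),
                                   stringsAsFactors = FALSE)
  a <- import_clonevol(tab("45.0%"))
  b <- import_clonevol(tab("0.45"))
  expect_equal(a$compositions["s1", "1"], 0.45)
  expect_equal(a$compositions, b$compositions)

  expect_error(import_clonevol(data.frame()),
               "no clonal model", class = "jellyplot_validation_error")
  expect_error(import_clonevol(tab("forty-five")),
               class = "jellyplot_validation_error")
})

test_that("ClonEvol import selects among multiple models", {
  df <- data.frame(model = c(1, 1, 2, 2),
                   lab = c("1", "2", "1", "2"),
                   parent = c("-1", "1", "-1", "1"),
                   s1.frac = c("0.5", "0.5", "0.9", "0.1"),
                   stringsAsFactors = FALSE)
  m2 <- import_clonevol(df, model = 2)
  expect_equal(unname(m2$compositions["s1", ]), c(0.9, 0.1))
  expect_error(import_clonevol(df, model = 3),
               class = "jellyplot_validation_error")
})

test_that("derive_sample_tree follows the nearest exactly-one-match rule", {
  st <- derive_sample_tree(data.frame(
    sample = c("pAsc", "iAsc"), timePoint = c("T1", "T2"),
    location = c("Asc", "Asc")))
  expect_equal(st$parent[st$sample == "iAsc"], "pAsc")
  expect_equal(st$rank, c(1L, 2L))

  # two same-location candidates at the earlier time point: root wins
  st2 <- derive_sample_tree(data.frame(
    sample = c("pOva1", "pOva2", "iOva"),
    timePoint = c("T1", "T1", "T2"),
    location = c("Ova", "Ova", "Ova")))
  expect_equal(st2$parent[st2$sample == "iOva"], sample_tree_root(st2))

  # ambiguity at the nearest time point, unique match one step earlier
  st3 <- derive_sample_tree(data.frame(
    sample = c("p1", "i1", "i2", "r1"),
    timePoint = c("T1", "T2", "T2", "T3"),
    location = c("Asc", "Asc", "Asc", "Asc")))
  expect_equal(st3$parent[st3$sample == "r1"], "p1")

  st4 <- derive_sample_tree(data.frame(sample = "only", timePoint = "T1",
                                       location = "Asc"))
  expect_equal(st4$parent, sample_tree_root(st4))
})

test_that("derived trees always satisfy the rank invariant", {
  locations <- c("Asc", "Ova", "Per", "Ome")
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(1:12, 1)
    meta <- data.frame(sample = sprintf("s%d", seq_len(n)),
                       timePoint = sprintf("T%d", sample(1:4, n, TRUE)),
                       location = sample(locations, n, TRUE))
    meta$timePoint <- factor(meta$timePoint,
                             levels = sort(unique(meta$timePoint)))
    st <- derive_sample_tree(
      data.frame(sample = meta$sample,
                 timePoint = as.character(meta$timePoint),
                 location = meta$location),
      time_order = levels(meta$timePoint))
    rank_of <- setNames(c(st$rank, 0L), c(st$sample, sample_tree_root(st)))
    expect_true(all(st$rank > rank_of[st$parent]))
  }
})
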