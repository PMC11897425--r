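# Host placement, inferred samples, slabs, bells and tentacles.

test_that("hosts follow the clade-LCA rule with upward promotion", {
  phy <- phylotree(data.frame(subclone = c("1", "2"), parent = c("", "1")))
  st <- sampletree(data.frame(sample = c("s1", "s2"), parent = c("", "s1"),
                              rank = c(1, 2)))
  cm <- suppressWarnings(compositions(data.frame(
    sample = c("s1", "s2", "s2"), subclone = c("1", "1", "2"),
    clonalPrevalence = c(1, 0.5, 0.5)), phy, st))
  hosts <- place_emerging_subclones(phy, st, cm)
  expect_equal(hosts[["1"]], "s1")
  expect_equal(hosts[["2"]], "s2")  # present only in s2: singleton LCA

  # subclone in two siblings, zero in their (inferred) parent: root hosts it
  st2 <- sampletree(data.frame(sample = c("a", "b"), parent = c("", ""),
                               rank = c(1, 1)))
  cm2 <- compositions(data.frame(
    sample = c("a", "a", "b", "b"), subclone = c("1", "2", "1", "2"),
    clonalPrevalence = c(0.5, 0.5, 0.5, 0.5)), phy, st2)
  hosts2 <- place_emerging_subclones(phy, st2, cm2)
  expect_equal(unname(hosts2[c("1", "2")]),
               rep(sample_tree_root(st2), 2))

  # subclone absent everywhere is dropped with a warning
  phy3 <- phylotree(data.frame(subclone = c("1", "2", "3"),
                               parent = c("", "1", "1")))
  cm3 <- compositions(data.frame(
    sample = c("a", "b"), subclone = c("1", "1"),
    clonalPrevalence = c(1, 1)), phy3, st2)
  expect_warning(h3 <- place_emerging_subclones(phy3, st2, cm3), "dropped")
  expect_false("2" %in% names(h3))
})

test_that("host placement matches the brute-force oracle", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    hosts <- suppressWarnings(
      place_emerging_subclones(inst$phy, inst$st, inst$cm))
    for (k in inst$phy$subclone) {
      want <- oracle_host(inst$phy, inst$st, inst$cm, k)
      if (is.na(want)) {
        expect_false(k %in% names(hosts))
      } else {
        expect_equal(hosts[[k]], want,
                     label = sprintf("seed %d subclone %s", seed, k))
      }
    }
  }
})

test_that("inferred root sample is added exactly when needed", {
  phy <- toy_phylogeny()
  st <- toy_sample_tree()
  cm <- toy_compositions(phy, st)
  hosts <- place_emerging_subclones(phy, st, cm)
  aug <- synthesize_inferred_samples(st, hosts, phy, cm)
  expect_true(aug$added)
  root <- sample_tree_root(st)
  expect_true(root %in% aug$sample_tree$sample)
  expect_equal(aug$sample_tree$rank[aug$sample_tree$sample == root], 0L)
  # subclones 1 and 2 are hosted at the root: equal proportions
  expect_equal(unname(aug$compositions[root, ]), c(0.5, 0.5, 0))

  # fully specified linear tree, all hosts real: nothing added
  stl <- sampletree(data.frame(sample = c("s1", "s2"),
                               parent = c("", "s1"), rank = c(1, 2)))
  phyl <- phylotree(data.frame(subclone = c("1", "2"), parent = c("", "1")))
  cml <- suppressWarnings(compositions(data.frame(
    sample = c("s1", "s2", "s2"), subclone = c("1", "1", "2"),
    clonalPrevalence = c(1, 0.5, 0.5)), phyl, stl))
  hl <- place_emerging_subclones(phyl, stl, cml)
  augl <- synthesize_inferred_samples(stl, hl, phyl, cml)
  expect_false(augl$added)
  expect_identical(augl$sample_tree, stl)
})

test_that("concurrent samples sharing only the trunk get a one-clone head", {
  phy <- phylotree(data.frame(subclone = "1", parent = ""))
  st <- sampletree(data.frame(sample = c("a", "b"), parent = c("", ""),
                              rank = c(1, 1)))
  cm <- compositions(data.frame(sample = c("a", "b"), subclone = c("1", "1"),
                                clonalPrevalence = c(1, 1)), phy, st)
  hosts <- place_emerging_subclones(phy, st, cm)
  aug <- synthesize_inferred_samples(st, hosts, phy, cm)
  expect_true(aug$added)
  expect_equal(unname(aug$compositions[sample_tree_root(st), ]), 1)

  # three subclones hosted at the root: equal thirds
  phy3 <- phylotree(data.frame(subclone = c("1", "2", "3"),
                               parent = c("", "1", "1")))
  cm3 <- compositions(data.frame(
    sample = c("a", "a", "a", "b", "b", "b"),
    subclone = rep(c("1", "2", "3"), 2),
    clonalPrevalence = rep(1 / 3, 6)), phy3, st)
  hosts3 <- place_emerging_subclones(phy3, st, cm3)
  aug3 <- synthesize_inferred_samples(st, hosts3, phy3, cm3)
  expect_equal(unname(aug3$compositions[sample_tree_root(st), ]),
               rep(1 / 3, 3))
})

test_that("slabs stack in DFS order and conserve the frame height", {
  phy <- toy_phylogeny()
  st <- toy_sample_tree()
  cm <- toy_compositions(phy, st)
  idx <- index_phylogeny(phy)
  sl <- stack_slabs("pAsc", cm, idx, frame_height = 100)
  expect_equal(sl$subclone, c("1", "2"))  # subclone 3 has prevalence 0
  expect_equal(sl$height, c(50, 50))
  sl2 <- stack_slabs("iAsc", cm, idx, frame_height = 80)
  expect_equal(sl2$height, c(0.2, 0.3, 0.5) * 80)
  expect_equal(sum(sl2$height), 80)

  for (seed in 1:20) {
    inst <- random_instance(seed)
    idx <- index_phylogeny(inst$phy)
    for (s in rownames(inst$cm)) {
      sl <- stack_slabs(s, inst$cm, idx)
      expect_lt(abs(sum(sl$height) - 100), 1e-9)
      # DFS order and contiguity
      expect_true(!is.unsorted(idx$dfs_index[sl$subclone], strictly = TRUE))
      expect_equal(sl$y0[-1], sl$y1[-nrow(sl)])
    }
  }
})

test_that("bell profile hits its logistic landmarks", {
  params <- layout_params(bell_steepness = 50, bell_midpoint = 0.5)
  bell <- shape_bell(prevalence = 0.6, depth = 0, params = params)
  expect_equal(bell$half_height, 0.6 * params$frame_height / 2)
  # half of final height at the midpoint (steep limit)
  expect_equal(bell_half_height(bell, 0.5), bell$half_height / 2,
               tolerance = 1e-3)
  # saturation at the right edge
  expect_gte(bell_half_height(bell, 1), 0.99 * bell$half_height)
  expect_equal(bell_half_height(bell, 1), bell$half_height)  # pinned exit
  expect_equal(bell_half_height(bell, 0), 0)                 # pinned start
  expect_error(shape_bell(0, 0), class = "jellyplot_validation_error")
  # nesting shifts the attachment rightward
  expect_gt(shape_bell(0.5, 2, params)$attachment,
            shape_bell(0.5, 1, params)$attachment)
})

test_that("nested bells stay inside their parents at every x", {
  xs <- seq(0, 1, length.out = 100)
  for (seed in 1:20) {
    inst <- random_instance(seed)
    doc <- suppressWarnings(compose_layout(inst$phy, inst$st, inst$cm))
    for (host in names(doc$bells)) {
      bells <- doc$bells[[host]]
      for (k in names(bells)) {
        pk <- bells[[k]]$parent_bell
        if (is.na(pk)) next
        child <- bell_outline(bells, k, xs)
        parent <- bell_outline(bells, pk, xs)
        expect_true(all(child$top >= parent$top - 1e-9),
                    label = sprintf("seed %d host %s bell %s top", seed,
                                    host, k))
        expect_true(all(child$bottom <= parent$bottom + 1e-9),
                    label = sprintf("seed %d host %s bell %s bottom", seed,
                                    host, k))
      }
      # exit extent equals the clade's slab extent
      for (k in names(bells)) {
        o <- bell_outline(bells, k, 1)
        expect_equal(o$top, bells[[k]]$exit_y0, tolerance = 1e-9)
        expect_equal(o$bottom, bells[[k]]$exit_y1, tolerance = 1e-9)
      }
    }
  }
})

test_that("tentacles exist iff a subclone is present at both edge ends", {
  phy <- toy_phylogeny()
  st <- toy_sample_tree()
  cm <- toy_compositions(phy, st)
  doc <- compose_layout(phy, st, cm)
  tt <- doc$tentacles
  # 3 edges (root->pAsc, root->pPer1, pAsc->iAsc), subclones 1 and 2 shared
  expect_equal(nrow(tt), 6)
  expect_false(any(tt$subclone == "3"))  # 3 only exists in iAsc

  # widths proportional to prevalence at both ends
  t12 <- tt[tt$from == "pAsc" & tt$to == "iAsc" & tt$subclone == "1", ]
  expect_equal(t12$width0, 0.5 * 100)
  expect_equal(t12$width1, 0.2 * 100)
  # bundle shares its control-point x
  bundle <- tt[tt$from == "pAsc" & tt$to == "iAsc", ]
  expect_equal(length(unique(bundle$cx0)), 1)

  # brute-force count on random instances
  for (seed in 1:15) {
    inst <- random_instance(seed)
    doc <- suppressWarnings(compose_layout(inst$phy, inst$st, inst$cm))
    st2 <- doc$sample_tree
    cm2 <- doc$compositions
    eps <- doc$params$epsilon
    want <- 0
    for (i in seq_len(nrow(st2))) {
      p <- st2$parent[[i]]
      if (!(p %in% st2$sample)) next
      want <- want + sum(cm2[p, ] > eps & cm2[st2$sample[[i]], ] > eps)
    }
    expect_equal(nrow(doc$tentacles), want)
    # rank monotonicity: tentacles always run left to right
    if (nrow(doc$tentacles) > 0) {
      expect_true(all(doc$tentacles$x1 > doc$tentacles$x0))
    }
  }
})

test_that("composed layouts satisfy their structural invariants", {
  # degenerate single-sample, single-subclone case
  phy1 <- phylotree(data.frame(subclone = "1", parent = ""))
  st1 <- sampletree(data.frame(sample = "s", parent = "", rank = 1))
  cm1 <- compositions(data.frame(sample = "s", subclone = "1",
                                 clonalPrevalence = 1), phy1, st1)
  doc1 <- compose_layout(phy1, st1, cm1)
  expect_equal(nrow(doc1$samples), 1)
  expect_equal(nrow(doc1$tentacles), 0)
  expect_equal(doc1$slabs$height, 100)

  for (seed in 1:10) {
    inst <- random_instance(seed)
    doc <- suppressWarnings(compose_layout(inst$phy, inst$st, inst$cm))
    # frames within a rank do not overlap; columns ordered by rank
    for (r in unique(doc$samples$rank)) {
      f <- doc$samples[doc$samples$rank == r, ]
      f <- f[order(f$y), ]
      if (nrow(f) > 1) {
        expect_true(all(f$y[-1] >= (f$y + f$height)[-nrow(f)]))
      }
      expect_equal(length(unique(f$x)), 1)
    }
    xr <- tapply(doc$samples$x, doc$samples$rank, unique)
    expect_true(!is.unsorted(xr[order(as.numeric(names(xr)))],
                             strictly = TRUE))
    # canvas contains all geometry
    expect_true(all(doc$samples$x + doc$samples$width <=
                      doc$canvas[["width"]]))
    expect_true(all(doc$samples$y + doc$samples$height <=
                      doc$canvas[["height"]]))
    # byte-identical JSON serialization across two runs
    doc2 <- suppressWarnings(compose_layout(inst$phy, inst$st, inst$cm))
    expect_identical(as.character(layout_to_json(doc)),
                     as.character(layout_to_json(doc2)))
  }
})
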