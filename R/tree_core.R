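# Shared tree machinery: depth-first indexing of the phylogeny (which fixes
# slab stacking order and the hue wheel), clade extraction, and
# lowest-common-ancestor queries on the sample tree.

#' Index a phylogeny by depth-first preorder
#'
#' Assigns each subclone its position in a depth-first preorder traversal
#' (root = 0) and accumulates branch lengths from the root. Children are
#' visited in input-file row order, so reordering rows reorders indices
#' (and hence stacking order and hues) without changing the tree.
#'
#' @param phy a [phylotree()]
#' @return An object of class `indexed_phylogeny`: a list with `phylogeny`,
#'   `root`, `dfs_index` (named 0-based integers), `total_branch_length`
#'   (named, root-to-node inclusive sums) and `children` (named list).
#' @export
index_phylogeny <- function(phy) {
  stopifnot(inherits(phy, "clone_phylogeny"))
  ids <- phy$subclone
  root <- ids[is.na(phy$parent)]
  children <- lapply(stats::setNames(ids, ids), function(id) {
    ids[!is.na(phy$parent) & phy$parent == id]  # input row order preserved
  })
  bl <- stats::setNames(phy$branch_length, ids)

  dfs <- stats::setNames(integer(length(ids)), ids)
  tbl <- stats::setNames(numeric(length(ids)), ids)
  counter <- 0L
  stack <- list(list(id = root, acc = 0))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    dfs[[top$id]] <- counter
    counter <- counter + 1L
    tbl[[top$id]] <- top$acc + bl[[top$id]]
    kids <- children[[top$id]]
    for (k in rev(kids)) {  # reversed push so pop order = input order
      stack[[length(stack) + 1L]] <- list(id = k, acc = tbl[[top$id]])
    }
  }
  structure(list(phylogeny = phy, root = root, dfs_index = dfs,
                 total_branch_length = tbl, children = children),
            class = "indexed_phylogeny")
}

#' @export
print.indexed_phylogeny <- function(x, ...) {
  cat(sprintf("Indexed phylogeny: %d subclones, root '%s'\n",
              length(x$dfs_index), x$root))
  print(data.frame(subclone = names(x$dfs_index), dfs_index = x$dfs_index,
                   total_branch_length = x$total_branch_length,
                   row.names = NULL), ...)
  invisible(x)
}

#' Extract a clade: a founding subclone and all its descendants
#'
#' @param phy a [phylotree()] or [index_phylogeny()] result
#' @param founder subclone id of the clade's founder
#' @return Character vector of clade member ids, founder first, in DFS order.
#' @export
clade_of <- function(phy, founder) {
  if (inherits(phy, "indexed_phylogeny")) phy <- phy$phylogeny
  ids <- phy$subclone
  if (!(founder %in% ids)) stop_validation("unknown subclone '%s'", founder)
  members <- founder
  frontier <- founder
  while (length(frontier) > 0L) {
    kids <- ids[!is.na(phy$parent) & phy$parent %in% frontier]
    members <- c(members, kids)
    frontier <- kids
  }
  members
}

# Ancestor path of a sample, self first, ending at the inferred root.
.sample_ancestry <- function(stree, sample_id) {
  root <- sample_tree_root(stree)
  parent_of <- stats::setNames(stree$parent, stree$sample)
  path <- character()
  cur <- sample_id
  while (cur != root) {
    path <- c(path, cur)
    cur <- parent_of[[cur]]
  }
  c(path, root)
}

#' Lowest common ancestor of a set of samples in the sample tree
#'
#' The inferred root counts as a node, so every non-empty query has an
#' answer. Trees here have tens of nodes at most; simple upward path
#' intersection is used.
#'
#' @param stree a [sampletree()]
#' @param samples non-empty character vector of sample ids (the inferred
#'   root id is permitted)
#' @return The deepest sample id that is an ancestor-or-self of every input.
#' @export
sample_lca <- function(stree, samples) {
  samples <- unique(samples)
  if (length(samples) == 0L) stop_validation("LCA of an empty sample set")
  root <- sample_tree_root(stree)
  bad <- setdiff(samples, c(stree$sample, root))
  if (length(bad) > 0L) stop_validation("unknown sample '%s'", bad[[1L]])
  paths <- lapply(samples, function(s) .sample_ancestry(stree, s))
  common <- Reduce(intersect, paths)
  # paths list ancestors shallowest-last; the common chain's deepest member
  # is the first element of any path restricted to the common set
  paths[[1L]][paths[[1L]] %in% common][[1L]]
}
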