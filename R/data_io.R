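# Readers, validators and writers for the three input tables (phylogeny,
# sample tree, clonal compositions), a ClonEvol-style importer, and the
# heuristic that derives a sample tree from per-sample metadata.
#
# All tables are UTF-8, tab-separated, with a header row. IDs are opaque
# character tokens; numeric-looking subclone ids are never coerced. In the
# parent column an empty string, "-" or "NA" all mean "no parent".

ROOT_MARKERS <- c("", "-", "NA")

.read_tsv <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_io("cannot read input file: %s", paste(format(path), collapse = ", "))
  }
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    fileEncoding = "UTF-8", quote = "")
}

.pick_col <- function(df, candidates) {
  hit <- intersect(candidates, names(df))
  if (length(hit) == 0L) NULL else df[[hit[[1L]]]]
}

.is_root_marker <- function(x) is.na(x) | x %in% ROOT_MARKERS

# ---------------------------------------------------------------------------
# Phylogeny

#' Construct and validate a subclone phylogeny
#'
#' A phylogeny is a rooted tree of subclones. Each row names a subclone, its
#' parent (empty/"-"/"NA" for the root), an optional branch length (mutation
#' count; defaults to 1) and an optional fixed sRGB hex color that overrides
#' the generated color scheme.
#'
#' @param df data frame with columns `subclone`, `parent`, and optionally
#'   `branch_length` (or `branchLength`) and `color`.
#' @return An object of class `clone_phylogeny`: a data frame with columns
#'   `subclone`, `parent` (`NA` for the root), `branch_length`, `color`,
#'   preserving input row order (which also fixes DFS child order).
#' @seealso [read_phylogeny()]
#' @export
phylotree <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop_validation("phylogeny table is empty")
  }
  subclone <- .pick_col(df, c("subclone", "lab", "id"))
  parent <- .pick_col(df, c("parent", "parent_id"))
  if (is.null(subclone) || is.null(parent)) {
    stop_validation("phylogeny table needs 'subclone' and 'parent' columns")
  }
  subclone <- as.character(subclone)
  parent <- as.character(parent)
  dup <- subclone[duplicated(subclone)]
  if (length(dup) > 0L) {
    stop_validation("duplicate subclone id '%s' (row %d)",
                    dup[[1L]], which(subclone == dup[[1L]])[2L])
  }
  parent[.is_root_marker(parent)] <- NA_character_
  roots <- which(is.na(parent))
  if (length(roots) == 0L) {
    stop_validation("phylogeny has no root (no row with an empty parent)")
  }
  if (length(roots) > 1L) {
    stop_validation("phylogeny has multiple roots: %s",
                    paste(subclone[roots], collapse = ", "))
  }
  bad <- which(!is.na(parent) & !(parent %in% subclone))
  if (length(bad) > 0L) {
    stop_validation("unknown parent '%s' for subclone '%s' (row %d)",
                    parent[bad[[1L]]], subclone[bad[[1L]]], bad[[1L]])
  }
  bl <- .pick_col(df, c("branch_length", "branchLength", "num.vars"))
  if (is.null(bl)) {
    bl <- rep(1, length(subclone))
  } else {
    bl <- suppressWarnings(as.numeric(bl))
    bl[is.na(bl)] <- 1
  }
  if (any(bl < 0)) {
    stop_validation("negative branch length for subclone '%s'",
                    subclone[which(bl < 0)[[1L]]])
  }
  col <- .pick_col(df, c("color", "colour"))
  if (is.null(col)) col <- rep(NA_character_, length(subclone))
  col[.is_root_marker(col)] <- NA_character_

  out <- data.frame(subclone = subclone, parent = parent,
                    branch_length = bl, color = as.character(col),
                    stringsAsFactors = FALSE)
  .check_tree_connected(out$subclone, out$parent, "subclone")
  class(out) <- c("clone_phylogeny", "data.frame")
  out
}

# Every node must reach the root by parent hops: detects cycles and
# disconnected components in one pass, naming the offending node.
.check_tree_connected <- function(ids, parents, what) {
  parent_of <- stats::setNames(parents, ids)
  for (id in ids) {
    seen <- character()
    cur <- id
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) {
        stop_validation("cycle in %s tree involving '%s'", what, cur)
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  invisible(TRUE)
}

#' Read a subclone phylogeny from a TSV file
#'
#' @param path path to a tab-separated file with a header row and columns
#'   `subclone`, `parent`, and optionally `branchLength` and `color`.
#' @return A validated [phylotree()] object.
#' @export
read_phylogeny <- function(path) phylotree(.read_tsv(path))

#' @export
print.clone_phylogeny <- function(x, ...) {
  cat(sprintf("Subclone phylogeny: %d subclones, root '%s'\n",
              nrow(x), x$subclone[is.na(x$parent)]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a phylogeny back to TSV
#' @param phy a `clone_phylogeny`
#' @param path output file path
#' @export
write_phylogeny <- function(phy, path) {
  df <- data.frame(subclone = phy$subclone,
                   parent = ifelse(is.na(phy$parent), "", phy$parent),
                   branchLength = phy$branch_length,
                   color = ifelse(is.na(phy$color), "", phy$color),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sample tree

INFERRED_ROOT_ID <- "inferred.root"

#' Construct and validate a sample tree
#'
#' The sample tree encodes the assumed metastasis/seeding route: edges point
#' from earlier to later samples. Every sample carries an integer `rank`
#' (time point, treatment stage, or depth); a parent's rank must be strictly
#' smaller than its child's, and paths may skip ranks. Samples without a
#' parent become children of a synthesized inferred-root marker at rank 0.
#'
#' @param df data frame with columns `sample`, `rank`, and optionally
#'   `parent` and `rank_title` (or `rankTitle`).
#' @return An object of class `sample_tree`: a data frame with columns
#'   `sample`, `parent` (the inferred-root marker for parentless samples),
#'   `rank` (integer), `rank_title`; attribute `root_id` holds the marker id.
#' @export
sampletree <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop_validation("sample table is empty")
  }
  sample_id <- .pick_col(df, c("sample", "sample_id"))
  rank <- .pick_col(df, c("rank"))
  if (is.null(sample_id) || is.null(rank)) {
    stop_validation("sample table needs 'sample' and 'rank' columns")
  }
  sample_id <- as.character(sample_id)
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup) > 0L) {
    stop_validation("duplicate sample id '%s'", dup[[1L]])
  }
  rank <- suppressWarnings(as.numeric(rank))
  if (any(is.na(rank)) || any(rank != floor(rank)) || any(rank < 0)) {
    stop_validation("ranks must be non-negative integers")
  }
  rank <- as.integer(rank)
  parent <- .pick_col(df, c("parent", "parent_id"))
  if (is.null(parent)) parent <- rep(NA_character_, length(sample_id))
  parent <- as.character(parent)
  parent[.is_root_marker(parent)] <- NA_character_

  root_id <- INFERRED_ROOT_ID
  while (root_id %in% sample_id) root_id <- paste0(".", root_id)
  parent[is.na(parent)] <- root_id

  bad <- which(parent != root_id & !(parent %in% sample_id))
  if (length(bad) > 0L) {
    stop_validation("unknown parent sample '%s' for sample '%s'",
                    parent[bad[[1L]]], sample_id[bad[[1L]]])
  }
  prank <- stats::setNames(c(rank, 0L), c(sample_id, root_id))
  viol <- which(rank <= prank[parent] & parent != root_id)
  if (any(rank < 1L & parent == root_id)) {
    stop_validation("sample '%s' has rank %d but ranks of real samples must be >= 1",
                    sample_id[which(rank < 1L)[[1L]]], rank[which(rank < 1L)[[1L]]])
  }
  if (length(viol) > 0L) {
    i <- viol[[1L]]
    stop_validation(
      "sample '%s' (rank %d) must have a strictly earlier-rank parent than '%s' (rank %d)",
      sample_id[i], rank[i], parent[i], prank[[parent[i]]])
  }
  .check_tree_connected(sample_id,
                        ifelse(parent == root_id, NA_character_, parent),
                        "sample")
  title <- .pick_col(df, c("rank_title", "rankTitle"))
  if (is.null(title)) title <- rep(NA_character_, length(sample_id))
  title[.is_root_marker(title)] <- NA_character_

  out <- data.frame(sample = sample_id, parent = parent, rank = rank,
                    rank_title = as.character(title), stringsAsFactors = FALSE)
  attr(out, "root_id") <- root_id
  class(out) <- c("sample_tree", "data.frame")
  out
}

#' Read a sample tree from a TSV file
#' @param path tab-separated file with columns `sample`, `rank`, and
#'   optionally `parent`, `rankTitle`.
#' @return A validated [sampletree()] object.
#' @export
read_sample_tree <- function(path) sampletree(.read_tsv(path))

#' The id of a sample tree's inferred root
#' @param stree a `sample_tree`
#' @return The inferred-root marker (a sample id not used by any real sample).
#' @export
sample_tree_root <- function(stree) attr(stree, "root_id")

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf("Sample tree: %d samples over ranks %s (inferred root '%s')\n",
              nrow(x), paste(range(x$rank), collapse = "-"),
              sample_tree_root(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a sample tree back to TSV
#' @param stree a `sample_tree`
#' @param path output file path
#' @export
write_sample_tree <- function(stree, path) {
  root <- sample_tree_root(stree)
  df <- data.frame(sample = stree$sample,
                   parent = ifelse(stree$parent == root, "", stree$parent),
                   rank = stree$rank,
                   rankTitle = ifelse(is.na(stree$rank_title), "",
                                      stree$rank_title),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Compositions

#' Construct and validate a clonal composition matrix
#'
#' Long-format (sample, subclone, prevalence) rows become a samples x
#' subclones matrix. Missing pairs are prevalence 0. Per-sample sums above
#' 1 + 1e-6 are errors; sums below 1 (e.g. when a normal-cell fraction was
#' excluded upstream) are renormalized to 1 with a warning so stacked
#' rectangles stay full height.
#'
#' @param df long-format data frame with columns `sample`, `subclone` and
#'   `clonalPrevalence` (or `prevalence`).
#' @param phylogeny optional `clone_phylogeny`; fixes column order to the
#'   phylogeny's row order and rejects unknown subclone ids.
#' @param sample_tree optional `sample_tree`; fixes row order and rejects
#'   unknown sample ids. Samples missing entirely from the table are errors.
#' @return Numeric matrix (rows = samples, columns = subclones) of class
#'   `clonal_compositions`; every row sums to 1.
#' @export
compositions <- function(df, phylogeny = NULL, sample_tree = NULL) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop_validation("compositions table is empty")
  }
  sample_id <- .pick_col(df, c("sample", "sample_id"))
  subclone <- .pick_col(df, c("subclone", "clone"))
  prev <- .pick_col(df, c("clonalPrevalence", "prevalence", "frac", "proportion"))
  if (is.null(sample_id) || is.null(subclone) || is.null(prev)) {
    stop_validation(
      "compositions table needs 'sample', 'subclone', 'clonalPrevalence' columns")
  }
  sample_id <- as.character(sample_id)
  subclone <- as.character(subclone)
  prev <- suppressWarnings(as.numeric(prev))
  if (any(is.na(prev))) {
    stop_validation("unparsable prevalence in row %d", which(is.na(prev))[[1L]])
  }
  if (any(prev < 0)) {
    i <- which(prev < 0)[[1L]]
    stop_validation("negative prevalence %g for (%s, %s)",
                    prev[i], sample_id[i], subclone[i])
  }
  samples <- if (is.null(sample_tree)) unique(sample_id) else sample_tree$sample
  subclones <- if (is.null(phylogeny)) unique(subclone) else phylogeny$subclone
  bad <- setdiff(sample_id, samples)
  if (length(bad) > 0L) {
    stop_validation("composition row refers to unknown sample '%s'", bad[[1L]])
  }
  bad <- setdiff(subclone, subclones)
  if (length(bad) > 0L) {
    stop_validation("composition row refers to unknown subclone '%s'", bad[[1L]])
  }
  m <- matrix(0, nrow = length(samples), ncol = length(subclones),
              dimnames = list(samples, subclones))
  for (i in seq_along(prev)) {
    m[sample_id[i], subclone[i]] <- m[sample_id[i], subclone[i]] + prev[i]
  }
  sums <- rowSums(m)
  if (any(sums > 1 + 1e-6)) {
    s <- samples[which(sums > 1 + 1e-6)[[1L]]]
    stop_validation("prevalences of sample '%s' sum to %.6f > 1", s, sums[[s]])
  }
  if (any(sums == 0)) {
    stop_validation("sample '%s' has no composition",
                    samples[which(sums == 0)[[1L]]])
  }
  if (any(sums < 1 - 1e-6)) {
    low <- samples[sums < 1 - 1e-6]
    warning(sprintf(
      "prevalences of %d sample(s) sum to < 1 (e.g. '%s': %.4f); renormalizing to 1",
      length(low), low[[1L]], sums[[low[[1L]]]]), call. = FALSE)
  }
  m <- m / sums  # exact unit rows, also absorbs harmless ~1e-7 drift
  class(m) <- c("clonal_compositions", class(m))
  m
}

#' Read clonal compositions from a long-format TSV file
#' @inheritParams compositions
#' @param path tab-separated file with columns `sample`, `subclone`,
#'   `clonalPrevalence`.
#' @return A validated [compositions()] matrix.
#' @export
read_compositions <- function(path, phylogeny = NULL, sample_tree = NULL) {
  compositions(.read_tsv(path), phylogeny, sample_tree)
}

#' Write a composition matrix back to long-format TSV
#'
#' Zero entries are omitted, mirroring the sparse long input format.
#' @param comp a `clonal_compositions` matrix
#' @param path output file path
#' @export
write_compositions <- function(comp, path) {
  idx <- which(comp > 0, arr.ind = TRUE)
  df <- data.frame(sample = rownames(comp)[idx[, 1L]],
                   subclone = colnames(comp)[idx[, 2L]],
                   clonalPrevalence = comp[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$sample, rownames(comp)),
                 match(df$subclone, colnames(comp))), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# ClonEvol import

# "45.0%" and "0.45" dialects both parse to 0.45; values > 1.5 without a
# percent sign are taken as percentages too (ClonEvol frequently emits 0-100
# scaled fractions).
.parse_fraction <- function(x) {
  x <- trimws(as.character(x))
  pct <- grepl("%", x, fixed = TRUE)
  v <- suppressWarnings(as.numeric(gsub("%", "", x, fixed = TRUE)))
  v[pct] <- v[pct] / 100
  big <- !pct & !is.na(v) & v > 1.5
  v[big] <- v[big] / 100
  v
}

#' Import a ClonEvol-style consensus tree table
#'
#' Converts one clonal model from a ClonEvol-style export into the native
#' phylogeny + composition representation. The table must have columns `lab`
#' (subclone label) and `parent` (with `-1`, `0` or empty marking the root),
#' and one fraction column per sample named `<sample>.frac` or
#' `frac.<sample>`. Optional columns: `num.vars` (branch length), `color`,
#' and `model` (groups rows into alternative clonal models).
#'
#' @param x a data frame, a path to a TSV file, or a directory containing
#'   one or more `*.tsv` model tables (sorted by name; `model` selects one).
#' @param model 1-based index of the clonal model to import.
#' @return A list with elements `phylogeny` (a [phylotree()]) and
#'   `compositions` (a [compositions()] matrix).
#' @export
import_clonevol <- function(x, model = 1L) {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.tsv$", full.names = TRUE))
    if (length(files) == 0L) stop_io("no .tsv model tables in directory %s", x)
    tabs <- lapply(files, .read_tsv)
    if (length(tabs) >= model && !("model" %in% names(tabs[[1L]]))) {
      df <- tabs[[model]]
      model <- 1L
    } else {
      df <- do.call(rbind, tabs)
    }
  } else if (is.character(x)) {
    df <- .read_tsv(x)
  } else {
    df <- x
  }
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop_validation("no clonal model present in ClonEvol input")
  }
  if ("model" %in% names(df)) {
    models <- unique(df$model)
    if (model > length(models)) {
      stop_validation("requested model %d but only %d present",
                      model, length(models))
    }
    df <- df[df$model == models[[model]], , drop = FALSE]
  } else if (model != 1L) {
    stop_validation("requested model %d but table has a single model", model)
  }
  if (nrow(df) == 0L) stop_validation("no clonal model present in ClonEvol input")

  lab <- .pick_col(df, c("lab", "subclone", "clone"))
  parent <- .pick_col(df, c("parent"))
  if (is.null(lab) || is.null(parent)) {
    stop_validation("ClonEvol table needs 'lab' and 'parent' columns")
  }
  parent <- as.character(parent)
  parent[parent %in% c("-1", "0")] <- NA_character_

  frac_cols <- grep("(\\.frac$)|(^frac\\.)", names(df), value = TRUE)
  if (length(frac_cols) == 0L) {
    stop_validation("ClonEvol table has no per-sample '.frac' columns")
  }
  samples <- sub("^frac\\.", "", sub("\\.frac$", "", frac_cols))

  phy <- phylotree(data.frame(
    subclone = as.character(lab), parent = parent,
    branch_length = .pick_col(df, c("num.vars", "branchLength")) %||%
      rep("1", nrow(df)),
    color = .pick_col(df, c("color")) %||% rep("", nrow(df)),
    stringsAsFactors = FALSE))

  long <- do.call(rbind, lapply(seq_along(frac_cols), function(j) {
    v <- .parse_fraction(df[[frac_cols[[j]]]])
    if (any(is.na(v))) {
      stop_validation("unparsable fraction cell '%s' in column '%s'",
                      df[[frac_cols[[j]]]][which(is.na(v))[[1L]]],
                      frac_cols[[j]])
    }
    data.frame(sample = samples[[j]], subclone = as.character(lab),
               clonalPrevalence = v, stringsAsFactors = FALSE)
  }))
  long <- long[long$clonalPrevalence > 0, , drop = FALSE]
  comp <- suppressWarnings(compositions(long, phylogeny = phy))
  list(phylogeny = phy, compositions = comp)
}

# ---------------------------------------------------------------------------
# Sample-tree derivation from metadata

#' Derive a sample tree from time-point and location metadata
#'
#' For each sample, earlier time points are scanned from nearest to
#' earliest; the first time point containing exactly one sample from the
#' same anatomical location supplies the parent. If no time point qualifies
#' (none earlier, none at the location, or ambiguity from multiple
#' candidates at every earlier time point), the sample becomes a child of
#' the inferred root. Ranks are the 1-based time-point indices.
#'
#' @param meta data frame with columns `sample`, `timePoint` (or
#'   `time_point`), `location`.
#' @param time_order optional character vector giving the total order of
#'   time points; defaults to order of first appearance in `meta`.
#' @return A validated [sampletree()] with `rank_title` set to the time
#'   point names.
#' @export
derive_sample_tree <- function(meta, time_order = NULL) {
  if (!is.data.frame(meta) || nrow(meta) == 0L) {
    stop_validation("metadata table is empty")
  }
  sample_id <- .pick_col(meta, c("sample", "sample_id"))
  tp <- .pick_col(meta, c("timePoint", "time_point", "timepoint"))
  loc <- .pick_col(meta, c("location", "anatomical_location", "site"))
  if (is.null(sample_id) || is.null(tp) || is.null(loc)) {
    stop_validation("metadata needs 'sample', 'timePoint', 'location' columns")
  }
  sample_id <- as.character(sample_id)
  tp <- as.character(tp)
  loc <- as.character(loc)
  if (anyDuplicated(sample_id)) {
    stop_validation("duplicate sample id '%s' in metadata",
                    sample_id[duplicated(sample_id)][[1L]])
  }
  if (is.null(time_order)) time_order <- unique(tp)
  if (!all(tp %in% time_order)) {
    stop_validation("time point '%s' missing from declared time order",
                    setdiff(tp, time_order)[[1L]])
  }
  rank <- match(tp, time_order)

  parent <- rep(NA_character_, length(sample_id))
  for (i in seq_along(sample_id)) {
    for (r in rev(seq_len(rank[i] - 1L))) {
      cand <- which(rank == r & loc == loc[i])
      if (length(cand) == 1L) {
        parent[i] <- sample_id[cand]
        break
      }
    }
  }
  sampletree(data.frame(sample = sample_id,
                        parent = ifelse(is.na(parent), "", parent),
                        rank = rank, rank_title = tp,
                        stringsAsFactors = FALSE))
}
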