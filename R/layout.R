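# Jellyfish geometry. Samples are rectangles arranged in rank columns with
# subclone slabs stacked in phylogeny DFS order; a subclone's first
# appearance in the sample tree is drawn as a logistic-growth bell nested
# inside its phylogenetic ancestors' bells; tentacle bundles connect the
# slabs of a subclone across each sample-tree edge. All geometry lives in
# abstract plot units with y growing downward (the SVG convention).

#' Default layout parameters
#'
#' @param frame_width,frame_height sample rectangle size in plot units
#' @param rank_gap horizontal gap between rank columns
#' @param sample_gap vertical gap between samples within a rank
#' @param padding canvas padding on all sides
#' @param epsilon prevalence threshold under which a subclone is treated as
#'   absent from a sample (hosting, tentacles); small so trace detections
#'   survive
#' @param bell_steepness logistic steepness of bell outlines
#' @param bell_midpoint logistic midpoint as a fraction of frame width
#' @param bell_inset attachment inset per nesting depth (fraction of frame
#'   width)
#' @return Named list of layout parameters.
#' @export
layout_params <- function(frame_width = 100, frame_height = 100,
                          rank_gap = 60, sample_gap = 20, padding = 20,
                          epsilon = 1e-4, bell_steepness = 10,
                          bell_midpoint = 0.6, bell_inset = 0.08) {
  as.list(environment())
}

# ---------------------------------------------------------------------------
# Host placement

#' Place emerging subclones in the sample tree
#'
#' Each subclone emerges (is drawn as a bell) in the lowest common ancestor,
#' in the sample tree, of all samples where any member of its clade is
#' present above `epsilon`. If the subclone's own prevalence at that LCA is
#' at or below `epsilon`, the host is promoted to the nearest ancestor
#' sample where the subclone is present, or to the inferred root if none
#' exists — the subclone must then have emerged in an earlier, possibly
#' hypothetical sample. Subclones absent from every sample are dropped with
#' a warning.
#'
#' @param phy a [phylotree()]
#' @param stree a [sampletree()]
#' @param comp a [compositions()] matrix
#' @param epsilon presence threshold
#' @return Named character vector subclone id -> host sample id (possibly
#'   the inferred-root id, see [sample_tree_root()]).
#' @export
place_emerging_subclones <- function(phy, stree, comp, epsilon = 1e-4) {
  root <- sample_tree_root(stree)
  hosts <- character(0)
  dropped <- character(0)
  for (k in phy$subclone) {
    members <- intersect(clade_of(phy, k), colnames(comp))
    support <- rownames(comp)[
      rowSums(comp[, members, drop = FALSE] > epsilon) > 0]
    support <- intersect(support, stree$sample)
    if (length(support) == 0L) {
      dropped <- c(dropped, k)
      next
    }
    host <- sample_lca(stree, support)
    if (host != root &&
        (!(k %in% colnames(comp)) || comp[host, k] <= epsilon)) {
      # promote upward to the nearest ancestor where k itself is present
      path <- .sample_ancestry(stree, host)
      path <- setdiff(path, c(host, root))
      host <- root
      for (anc in path) {
        if (comp[anc, k] > epsilon) {
          host <- anc
          break
        }
      }
    }
    hosts[[k]] <- host
  }
  if (length(dropped) > 0L) {
    warning(sprintf("subclone(s) absent from every sample, dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  hosts
}

#' Materialize the inferred root sample
#'
#' An inferred root sample (the jellyfish "head") is added at rank 0 when
#' two or more real samples are parentless (e.g. concurrent diagnostic
#' biopsies) or when any subclone's host is the inferred root. Its subclonal
#' proportions are unknown, so all subclones hosted there — together with
#' their phylogenetic ancestors — are displayed in equal proportions. A
#' fully specified tree whose hosts are all real samples is returned
#' unchanged.
#'
#' @param stree a [sampletree()]
#' @param hosts result of [place_emerging_subclones()]
#' @param phy a [phylotree()]
#' @param comp a [compositions()] matrix
#' @return List with `sample_tree` and `compositions` (augmented with the
#'   inferred sample when added), `hosts` (re-pointed at it), and `added`.
#' @export
synthesize_inferred_samples <- function(stree, hosts, phy, comp) {
  root <- sample_tree_root(stree)
  parentless <- sum(stree$parent == root)
  need <- parentless >= 2L || any(hosts == root)
  if (!need) {
    return(list(sample_tree = stree, compositions = comp, hosts = hosts,
                added = FALSE))
  }
  hosted <- names(hosts)[hosts == root]
  if (length(hosted) == 0L) {
    # concurrent samples but every subclone hosted in a real sample: the
    # head still needs contents; use the subclones shared by all parentless
    # samples' compositions' common ancestors -- minimally, the phylo root.
    hosted <- phy$subclone[is.na(phy$parent)]
  }
  shown <- unique(unlist(lapply(hosted, function(k) .phylo_ancestry(phy, k))))
  shown <- intersect(phy$subclone, shown)  # DFS-stable order

  df <- data.frame(sample = c(root, stree$sample),
                   parent = c("", stree$parent),
                   rank = c(0L, stree$rank),
                   rank_title = c(NA_character_, stree$rank_title),
                   stringsAsFactors = FALSE)
  df$parent[df$parent == root & df$sample != root] <- root
  # rebuild via the validator but permit the materialized rank-0 root
  out <- df
  attr(out, "root_id") <- sampletree_marker_for(df$sample)
  out$parent[out$parent == ""] <- attr(out, "root_id")
  class(out) <- c("sample_tree", "data.frame")

  row <- matrix(0, nrow = 1, ncol = ncol(comp),
                dimnames = list(root, colnames(comp)))
  row[1, shown] <- 1 / length(shown)
  comp2 <- rbind(row, comp)
  class(comp2) <- class(comp)

  hosts[hosts == root] <- root  # id unchanged; root is now a real row
  list(sample_tree = out, compositions = comp2, hosts = hosts, added = TRUE)
}

# Marker for the super-root above a materialized inferred sample.
sampletree_marker_for <- function(ids) {
  m <- INFERRED_ROOT_ID
  while (m %in% ids) m <- paste0(".", m)
  m
}

.phylo_ancestry <- function(phy, id) {
  parent_of <- stats::setNames(phy$parent, phy$subclone)
  path <- id
  while (!is.na(parent_of[[id]])) {
    id <- parent_of[[id]]
    path <- c(path, id)
  }
  path
}

# ---------------------------------------------------------------------------
# Slabs

#' Stack a sample's subclone slabs
#'
#' Slabs are stacked top to bottom in phylogeny DFS order with heights
#' proportional to prevalence; zero-prevalence subclones are omitted.
#' Heights are computed from a cumulative sum so they always total the
#' frame height exactly.
#'
#' @param sample sample id
#' @param comp a [compositions()] matrix
#' @param indexed an [index_phylogeny()] result
#' @param frame_height frame height in plot units
#' @return Data frame with columns `subclone`, `y0`, `y1`, `height`
#'   (offsets from the frame top).
#' @export
stack_slabs <- function(sample, comp, indexed, frame_height = 100) {
  ids <- names(sort(indexed$dfs_index))
  p <- comp[sample, ids]
  ids <- ids[p > 0]
  p <- p[p > 0]
  edges <- c(0, cumsum(p)) * frame_height
  data.frame(subclone = ids, y0 = edges[-length(edges)], y1 = edges[-1L],
             height = diff(edges), row.names = NULL, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Bells

# Logistic growth profile pinned to 0 at the attachment point and 1 at the
# frame's right edge, so a bell meets its exit extent exactly.
.bell_profile <- function(x, attachment, steepness, midpoint) {
  u <- (x - attachment) / max(1 - attachment, 1e-9)
  u <- pmin(pmax(u, 0), 1)
  sig <- function(z) 1 / (1 + exp(-z))
  lo <- sig(steepness * (0 - midpoint))
  hi <- sig(steepness * (1 - midpoint))
  (sig(steepness * (u - midpoint)) - lo) / (hi - lo)
}

#' Shape a bell outline
#'
#' The outline of an emerging subclone is a logistic growth curve: at
#' horizontal position `x` (fraction of the host frame) the bell's
#' half-height is `prevalence * frame_height / 2` scaled by a logistic
#' profile that starts at 0 at the attachment point and saturates to 1 at
#' the frame's right edge. Nested bells attach `bell_inset` frame-widths
#' later per nesting depth, which guarantees a child's profile never
#' exceeds its parent's.
#'
#' @param prevalence clade prevalence at the host (fraction of the frame
#'   height the bell occupies on exit)
#' @param depth nesting depth (number of phylogenetic ancestors emerging in
#'   the same host)
#' @param params a [layout_params()] list
#' @return List of class `bell_shape` with `attachment`, `steepness`,
#'   `midpoint`, `half_height` (exit half-height in plot units).
#' @export
shape_bell <- function(prevalence, depth, params = layout_params()) {
  if (prevalence <= 0) stop_validation("bell prevalence must be positive")
  structure(list(attachment = min(depth * params$bell_inset, 0.95),
                 steepness = params$bell_steepness,
                 midpoint = params$bell_midpoint,
                 half_height = prevalence * params$frame_height / 2),
            class = "bell_shape")
}

#' Evaluate a bell's half-height profile
#' @param bell a [shape_bell()] result
#' @param x horizontal positions as fractions of the frame width in `[0, 1]`
#' @return Half-heights in plot units at each `x`.
#' @export
bell_half_height <- function(bell, x) {
  bell$half_height * .bell_profile(x, bell$attachment, bell$steepness,
                                   bell$midpoint)
}

# Build the bells of one host sample. Exit extents are clade extents (the
# contiguous DFS run of the clade's slabs); centers of nested bells converge
# to their parent's trajectory toward the attachment point so child outlines
# stay inside parent outlines at every x.
.build_host_bells <- function(host, hosted, phy, slabs, params) {
  parent_of <- stats::setNames(phy$parent, phy$subclone)
  hosted <- stats::setNames(hosted, hosted)
  emerge_parent <- vapply(hosted, function(k) {
    p <- parent_of[[k]]
    while (!is.na(p) && !(p %in% hosted)) p <- parent_of[[p]]
    if (is.na(p)) NA_character_ else p
  }, character(1))
  depth <- vapply(hosted, function(k) {
    d <- 0L
    p <- emerge_parent[[k]]
    while (!is.na(p)) {
      d <- d + 1L
      p <- emerge_parent[[p]]
    }
    d
  }, integer(1))

  extent <- lapply(stats::setNames(hosted, hosted), function(k) {
    members <- intersect(clade_of(phy, k), slabs$subclone)
    rows <- slabs[slabs$subclone %in% members, , drop = FALSE]
    c(min(rows$y0), max(rows$y1))
  })

  bells <- vector("list", length(hosted))
  names(bells) <- hosted
  for (i in seq_along(hosted)) {
    k <- hosted[[i]]
    ext <- extent[[k]]
    shape <- shape_bell(prevalence = (ext[2] - ext[1]) / params$frame_height,
                        depth = depth[[i]], params = params)
    bells[[k]] <- list(subclone = k, host = host,
                       parent_bell = emerge_parent[[i]], depth = depth[[i]],
                       attachment = shape$attachment,
                       steepness = shape$steepness,
                       midpoint = shape$midpoint,
                       half_height = shape$half_height,
                       exit_center = mean(ext), exit_y0 = ext[1],
                       exit_y1 = ext[2])
  }
  bells
}

#' Evaluate a bell's outline (top and bottom edges) within its host frame
#'
#' The center trajectory of a nested bell interpolates from its parent's
#' trajectory at the attachment point to its own exit center at the frame's
#' right edge, following the same logistic profile as its half-height.
#'
#' @param bells named list of a host's bells (internal structure built by
#'   [compose_layout()])
#' @param id subclone id of the bell to evaluate
#' @param x fractions of frame width in `[0, 1]`
#' @return List with vectors `top` and `bottom` (frame-relative y).
#' @export
bell_outline <- function(bells, id, x) {
  b <- bells[[id]]
  prof <- .bell_profile(x, b$attachment, b$steepness, b$midpoint)
  if (is.na(b$parent_bell)) {
    center <- rep(b$exit_center, length(x))
  } else {
    pc <- bell_outline(bells, b$parent_bell, x)
    pcenter <- (pc$top + pc$bottom) / 2
    pexit <- bells[[b$parent_bell]]$exit_center
    center <- pcenter + (b$exit_center - pexit) * prof
  }
  half <- b$half_height * prof
  list(top = center - half, bottom = center + half)
}

# ---------------------------------------------------------------------------
# Tentacles

#' Route tentacles across sample-tree edges
#'
#' One tentacle is created per (sample-tree edge, subclone) pair whose
#' prevalence exceeds `epsilon` at both endpoints. Each tentacle is a cubic
#' Bezier from the subclone's slab on the parent's right edge to its slab
#' on the child's left edge; all tentacles of one edge share the horizontal
#' midpoint between the two columns as their control-point x, forming a
#' bundle. End widths are the slab heights, i.e. proportional to the two
#' prevalences.
#'
#' @param placed data frame of placed samples (from [compose_layout()])
#'   with columns `sample`, `x`, `y`, `width`, `height`
#' @param stree the (possibly augmented) [sampletree()]
#' @param comp the matching [compositions()] matrix
#' @param indexed an [index_phylogeny()] result
#' @param epsilon presence threshold
#' @return Data frame with one row per tentacle: `subclone`, `from`, `to`,
#'   Bezier anchors/controls `x0,y0,cx0,cy0,cx1,cy1,x1,y1` (anchors at slab
#'   centers), and `width0`, `width1`.
#' @export
route_tentacles <- function(placed, stree, comp, indexed, epsilon = 1e-4) {
  root <- sample_tree_root(stree)
  out <- list()
  for (i in seq_len(nrow(stree))) {
    child <- stree$sample[[i]]
    parent <- stree$parent[[i]]
    if (!(parent %in% placed$sample) || !(child %in% placed$sample)) next
    pf <- placed[placed$sample == parent, ]
    cf <- placed[placed$sample == child, ]
    pslabs <- stack_slabs(parent, comp, indexed, pf$height)
    cslabs <- stack_slabs(child, comp, indexed, cf$height)
    shared <- colnames(comp)[comp[parent, ] > epsilon & comp[child, ] > epsilon]
    if (length(shared) == 0L) next
    midx <- (pf$x + pf$width + cf$x) / 2
    for (k in shared) {
      ps <- pslabs[pslabs$subclone == k, ]
      cs <- cslabs[cslabs$subclone == k, ]
      y0 <- pf$y + (ps$y0 + ps$y1) / 2
      y1 <- cf$y + (cs$y0 + cs$y1) / 2
      out[[length(out) + 1L]] <- data.frame(
        subclone = k, from = parent, to = child,
        x0 = pf$x + pf$width, y0 = y0,
        cx0 = midx, cy0 = y0, cx1 = midx, cy1 = y1,
        x1 = cf$x, y1 = y1,
        width0 = ps$height, width1 = cs$height,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(subclone = character(), from = character(),
                      to = character(), x0 = numeric(), y0 = numeric(),
                      cx0 = numeric(), cy0 = numeric(), cx1 = numeric(),
                      cy1 = numeric(), x1 = numeric(), y1 = numeric(),
                      width0 = numeric(), width1 = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# Full layout

#' Compose the full jellyfish layout
#'
#' Runs the complete geometric pipeline: index the phylogeny, place
#' emerging subclones by LCA, materialize the inferred root sample if
#' needed, optimize in-rank sample order, assign colors, place rank
#' columns left to right and samples top to bottom, stack slabs, build
#' nested bells, and route tentacle bundles. The result is deterministic
#' for identical inputs and parameters.
#'
#' @param phy a [phylotree()]
#' @param stree a [sampletree()]
#' @param comp a [compositions()] matrix covering `stree`'s samples
#' @param params a [layout_params()] list
#' @param weights ordering-objective weights, see [optimize_rank_order()]
#' @param colors optional precomputed [build_color_scheme()]; built with
#'   defaults when `NULL`
#' @param rotation_steps forwarded to [build_color_scheme()]
#' @return An object of class `jellyfish_layout`: list with `samples`
#'   (placed frames), `slabs`, `bells`, `tentacles`, `ranks`, `colors`,
#'   `arrangement`, `canvas`, `params`, plus the augmented `sample_tree`,
#'   `compositions`, `indexed` and `hosts` used.
#' @export
compose_layout <- function(phy, stree, comp, params = layout_params(),
                           weights = c(1, 1), colors = NULL,
                           rotation_steps = 36L) {
  indexed <- index_phylogeny(phy)
  hosts <- place_emerging_subclones(phy, stree, comp, params$epsilon)
  aug <- synthesize_inferred_samples(stree, hosts, phy, comp)
  stree2 <- aug$sample_tree
  comp2 <- aug$compositions
  if (is.null(colors)) {
    colors <- build_color_scheme(indexed, rotation_steps = rotation_steps)
  }
  arrangement <- optimize_rank_order(stree2, comp2, indexed, weights)

  ranks <- sort(unique(stree2$rank))
  rank_pos <- stats::setNames(seq_along(ranks) - 1L, as.character(ranks))
  placed <- list()
  for (r in ranks) {
    ord <- arrangement$order[[as.character(r)]]
    for (pos in seq_along(ord)) {
      s <- ord[[pos]]
      placed[[length(placed) + 1L]] <- data.frame(
        sample = s, rank = r, slot = pos - 1L,
        x = params$padding +
          rank_pos[[as.character(r)]] * (params$frame_width + params$rank_gap),
        y = params$padding +
          (pos - 1L) * (params$frame_height + params$sample_gap),
        width = params$frame_width, height = params$frame_height,
        is_inferred = aug$added && s == sample_tree_root(stree),
        stringsAsFactors = FALSE)
    }
  }
  placed <- do.call(rbind, placed)

  slabs <- do.call(rbind, lapply(placed$sample, function(s) {
    sl <- stack_slabs(s, comp2, indexed, params$frame_height)
    if (nrow(sl) == 0L) return(NULL)
    cbind(sample = s, sl, stringsAsFactors = FALSE)
  }))

  bells <- list()
  for (s in unique(placed$sample)) {
    hosted <- names(aug$hosts)[aug$hosts == s]
    if (placed$is_inferred[placed$sample == s]) {
      # every subclone shown in the head emerges there
      hosted <- union(hosted,
                      slabs$subclone[slabs$sample == s])
      hosted <- intersect(phy$subclone, hosted)
    }
    hosted <- hosted[hosted %in% slabs$subclone[slabs$sample == s] |
                       vapply(hosted, function(k) {
                         any(clade_of(phy, k) %in%
                               slabs$subclone[slabs$sample == s])
                       }, logical(1))]
    if (length(hosted) == 0L) next
    bells[[s]] <- .build_host_bells(
      s, hosted, phy, slabs[slabs$sample == s, , drop = FALSE], params)
  }

  tentacles <- route_tentacles(placed, stree2, comp2, indexed, params$epsilon)

  titles <- vapply(ranks, function(r) {
    t <- stree2$rank_title[stree2$rank == r]
    t <- t[!is.na(t)]
    if (length(t) > 0L) t[[1L]] else if (r == 0L) "Inferred" else paste("Rank", r)
  }, character(1))
  ranks_df <- data.frame(
    rank = ranks,
    x0 = params$padding + rank_pos[as.character(ranks)] *
      (params$frame_width + params$rank_gap),
    x1 = params$padding + rank_pos[as.character(ranks)] *
      (params$frame_width + params$rank_gap) + params$frame_width,
    title = titles, row.names = NULL, stringsAsFactors = FALSE)

  canvas <- c(width = max(placed$x + placed$width) + params$padding,
              height = max(placed$y + placed$height) + params$padding)

  structure(list(samples = placed, slabs = slabs, bells = bells,
                 tentacles = tentacles, ranks = ranks_df, colors = colors,
                 arrangement = arrangement, canvas = canvas, params = params,
                 sample_tree = stree2, compositions = comp2,
                 indexed = indexed, hosts = aug$hosts,
                 inferred_added = aug$added),
            class = "jellyfish_layout")
}

#' @export
print.jellyfish_layout <- function(x, ...) {
  cat(sprintf(
    "Jellyfish layout: %d samples (%d inferred), %d subclones, %d tentacles, canvas %.0fx%.0f\n",
    nrow(x$samples), sum(x$samples$is_inferred),
    length(x$indexed$dfs_index), nrow(x$tentacles),
    x$canvas[["width"]], x$canvas[["height"]]))
  invisible(x)
}

#' Serialize a layout to JSON
#'
#' A renderer-agnostic export of the placed geometry: samples, slabs,
#' bells (with their shape parameters and exit extents), tentacles, rank
#' columns, colors and canvas size.
#'
#' @param doc a [compose_layout()] result
#' @param path optional output file; when `NULL` the JSON string is
#'   returned
#' @return The JSON string, invisibly when written to a file.
#' @export
layout_to_json <- function(doc, path = NULL) {
  bells_flat <- do.call(rbind, lapply(unname(doc$bells), function(host_bells) {
    do.call(rbind, lapply(host_bells, function(b) {
      data.frame(subclone = b$subclone, host = b$host,
                 parent_bell = b$parent_bell, depth = b$depth,
                 attachment = b$attachment, steepness = b$steepness,
                 midpoint = b$midpoint, half_height = b$half_height,
                 exit_y0 = b$exit_y0, exit_y1 = b$exit_y1,
                 stringsAsFactors = FALSE)
    }))
  }))
  obj <- list(canvas = as.list(doc$canvas),
              params = doc$params,
              samples = doc$samples,
              slabs = doc$slabs,
              bells = bells_flat,
              tentacles = doc$tentacles,
              ranks = doc$ranks,
              colors = as.data.frame(doc$colors))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
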