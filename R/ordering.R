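# In-rank sample ordering. Two complementary similarity measures — the
# phylogenetic center of mass and the Jensen-Shannon divergence between
# subclonal compositions — enter an objective summed over adjacent pairs
# within each rank; the arrangement minimizing it clusters similar samples.

#' Phylogenetic center of mass of a sample
#'
#' The prevalence-weighted mean of the DFS indices of the subclones in a
#' sample: the sample's average position in the phylogenetic tree. Since
#' prevalences sum to 1 this is a plain dot product with the index vector.
#'
#' @param sample sample id (a row of `comp`)
#' @param comp a [compositions()] matrix
#' @param indexed an [index_phylogeny()] result
#' @return A single number in `[0, n_subclones - 1]`.
#' @export
center_of_mass <- function(sample, comp, indexed) {
  if (!(sample %in% rownames(comp))) {
    stop_validation("unknown sample '%s'", sample)
  }
  p <- comp[sample, names(indexed$dfs_index)]
  if (sum(p) <= 0) stop_validation("sample '%s' has an all-zero row", sample)
  sum(p * indexed$dfs_index)
}

#' Jensen-Shannon divergence between two discrete distributions (bits)
#'
#' `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m = (p + q) / 2` and Shannon
#' entropy `H` in base 2 (`0 log 0 = 0`). Symmetric, zero iff `p == q`, and
#' bounded by 1 bit (attained on disjoint supports).
#'
#' @param p,q non-negative numeric vectors of equal length, each summing
#'   to 1 (tolerance 1e-6)
#' @return The divergence in bits, in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    stop_validation("distributions differ in length (%d vs %d)",
                    length(p), length(q))
  }
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop_validation("arguments must be probability distributions")
  }
  h <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  d <- h((p + q) / 2) - (h(p) + h(q)) / 2
  min(max(d, 0), 1)  # clamp float dust at the boundaries
}

# Pairwise cost between two samples: the same two terms the objective sums.
.pair_cost <- function(a, b, comp, indexed, weights, com) {
  n <- length(indexed$dfs_index)
  denom <- max(n - 1L, 1L)
  ids <- names(indexed$dfs_index)
  weights[[1L]] * abs(com[[a]] - com[[b]]) / denom +
    weights[[2L]] * js_divergence(comp[a, ids], comp[b, ids])
}

#' Objective value of an in-rank arrangement
#'
#' Sum over ranks, over adjacent sample pairs within the rank, of
#' `w_com * |delta center-of-mass| / (n - 1) + w_jsd * JSD` (center-of-mass
#' indices normalized to `[0, 1]`). Lower is better; ranks with a single
#' sample contribute 0. Reversing any rank leaves the value unchanged.
#'
#' @param arrangement named list: rank (as character) -> ordered sample ids
#' @param comp a [compositions()] matrix
#' @param indexed an [index_phylogeny()] result
#' @param weights length-2 non-negative numeric `(w_com, w_jsd)`
#' @return The objective value (a single non-negative number).
#' @export
rank_objective <- function(arrangement, comp, indexed, weights = c(1, 1)) {
  if (length(weights) != 2L || any(weights < 0)) {
    stop_validation("weights must be two non-negative numbers")
  }
  com <- stats::setNames(
    vapply(rownames(comp), center_of_mass, numeric(1),
           comp = comp, indexed = indexed),
    rownames(comp))
  total <- 0
  for (ord in arrangement) {
    if (length(ord) < 2L) next
    for (i in seq_len(length(ord) - 1L)) {
      total <- total + .pair_cost(ord[[i]], ord[[i + 1L]], comp, indexed,
                                  weights, com)
    }
  }
  total
}

# All permutations of seq_len(n) as rows, identity first (lexicographic).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# Objective contribution of one rank's order.
.rank_cost <- function(ord, cost) {
  if (length(ord) < 2L) return(0)
  sum(cost[cbind(ord[-length(ord)], ord[-1L])])
}

# Cross-rank tie-break: sum over samples with an already-placed parent of
# |own slot - parent slot| (0-based slots; the inferred root sits at slot 0).
.alignment_cost <- function(ids, ord, parent_of, slot_of) {
  cost <- 0
  for (pos in seq_along(ord)) {
    p <- parent_of[[ids[[ord[[pos]]]]]]
    if (!is.null(slot_of[[p]])) cost <- cost + abs((pos - 1L) - slot_of[[p]])
  }
  cost
}

#' Optimal order of samples within each rank
#'
#' Ranks with at most `exhaustive_max` samples are solved by exhaustive
#' permutation search, so the returned order attains the minimum of
#' [rank_objective()]. Larger ranks use a deterministic greedy
#' nearest-neighbour chain refined by 2-opt passes; its objective never
#' exceeds the input order's. Ties are broken by (1) parent-child slot
#' alignment with earlier ranks, (2) placing the smaller-center-of-mass
#' sample first, (3) input order.
#'
#' @param stree a [sampletree()]
#' @param comp a [compositions()] matrix covering every sample in `stree`
#' @param indexed an [index_phylogeny()] result
#' @param weights objective weights `(w_com, w_jsd)`
#' @param exhaustive_max largest rank size solved exhaustively (8! = 40320
#'   permutations at the default)
#' @return An object of class `rank_arrangement`: list with `order` (named
#'   list rank -> ordered sample ids) and `objective`.
#' @export
optimize_rank_order <- function(stree, comp, indexed, weights = c(1, 1),
                                exhaustive_max = 8L) {
  if (length(weights) != 2L || any(weights < 0)) {
    stop_validation("weights must be two non-negative numbers")
  }
  subclone_ids <- names(indexed$dfs_index)
  com <- stats::setNames(
    vapply(stree$sample, center_of_mass, numeric(1),
           comp = comp, indexed = indexed),
    stree$sample)
  parent_of <- stats::setNames(as.list(stree$parent), stree$sample)
  slot_of <- list()
  slot_of[[sample_tree_root(stree)]] <- 0L

  ranks <- sort(unique(stree$rank))
  order_out <- stats::setNames(vector("list", length(ranks)),
                               as.character(ranks))
  total <- 0
  for (r in ranks) {
    ids <- stree$sample[stree$rank == r]
    k <- length(ids)
    if (k == 1L) {
      order_out[[as.character(r)]] <- ids
      slot_of[[ids]] <- 0L
      next
    }
    cost <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        cost[i, j] <- cost[j, i] <-
          .pair_cost(ids[[i]], ids[[j]], comp, indexed, weights, com)
      }
    }
    best <- if (k <= exhaustive_max) {
      .solve_rank_exhaustive(ids, cost, com, parent_of, slot_of)
    } else {
      .solve_rank_heuristic(ids, cost, com, parent_of, slot_of)
    }
    order_out[[as.character(r)]] <- ids[best]
    for (pos in seq_along(best)) slot_of[[ids[[best[[pos]]]]]] <- pos - 1L
    total <- total + .rank_cost(best, cost)
  }
  structure(list(order = order_out, objective = total),
            class = "rank_arrangement")
}

.solve_rank_exhaustive <- function(ids, cost, com, parent_of, slot_of) {
  perms <- .permutations(length(ids))
  best <- NULL
  best_key <- c(Inf, Inf, Inf)
  for (j in seq_len(nrow(perms))) {
    ord <- perms[j, ]
    key <- c(.rank_cost(ord, cost),
             .alignment_cost(ids, ord, parent_of, slot_of),
             com[[ids[[ord[[1L]]]]]])
    for (d in 1:3) {
      if (key[[d]] < best_key[[d]] - 1e-12) {
        best <- ord
        best_key <- key
        break
      }
      if (key[[d]] > best_key[[d]] + 1e-12) break
    }
  }
  best
}

.solve_rank_heuristic <- function(ids, cost, com, parent_of, slot_of) {
  k <- length(ids)
  # greedy chain from the smallest-center-of-mass sample
  start <- order(com[ids])[[1L]]
  ord <- start
  left <- setdiff(seq_len(k), start)
  while (length(left) > 0L) {
    nxt <- left[[order(cost[ord[[length(ord)]], left])[[1L]]]]
    ord <- c(ord, nxt)
    left <- setdiff(left, nxt)
  }
  # 2-opt segment reversals until no improvement (bounded sweeps)
  for (sweep in seq_len(100L)) {
    improved <- FALSE
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        if (.rank_cost(cand, cost) < .rank_cost(ord, cost) - 1e-12) {
          ord <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  identity_ord <- seq_len(k)
  if (.rank_cost(ord, cost) > .rank_cost(identity_ord, cost) + 1e-12) {
    ord <- identity_ord  # never worse than the input order
  }
  revo <- rev(ord)
  key <- function(o) c(.alignment_cost(ids, o, parent_of, slot_of),
                       com[[ids[[o[[1L]]]]]])
  ka <- key(revo)
  kb <- key(ord)
  if (ka[[1L]] < kb[[1L]] - 1e-12 ||
      (abs(ka[[1L]] - kb[[1L]]) <= 1e-12 && ka[[2L]] < kb[[2L]] - 1e-12)) {
    ord <- revo
  }
  ord
}

#' @export
print.rank_arrangement <- function(x, ...) {
  cat(sprintf("Rank arrangement (objective %.6f):\n", x$objective))
  for (r in names(x$order)) {
    cat(sprintf("  rank %s: %s\n", r, paste(x$order[[r]], collapse = ", ")))
  }
  invisible(x)
}
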