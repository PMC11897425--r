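# Shared fixture builders and independent oracles. Oracles are coded from
# first principles (brute force / closed form) and never call the package
# routines they are used to check.

# -- fixture builders --------------------------------------------------------

toy_phylogeny <- function() {
  phylotree(data.frame(subclone = c("1", "2", "3"),
                       parent = c("", "1", "1"),
                       branchLength = c(120, 40, 65)))
}

toy_sample_tree <- function() {
  sampletree(data.frame(sample = c("pAsc", "pPer1", "iAsc"),
                        parent = c("", "", "pAsc"),
                        rank = c(1, 1, 2),
                        rankTitle = c("Diagnosis", "Diagnosis", "Interval")))
}

toy_compositions <- function(phy = toy_phylogeny(), st = toy_sample_tree()) {
  compositions(data.frame(
    sample = c("pAsc", "pAsc", "pPer1", "pPer1", "iAsc", "iAsc", "iAsc"),
    subclone = c("1", "2", "1", "2", "1", "2", "3"),
    clonalPrevalence = c(0.5, 0.5, 0.4, 0.6, 0.2, 0.3, 0.5)), phy, st)
}

# parse a generated fixture into validated objects
parse_fixture <- function(fix) {
  phy <- phylotree(fix$phylogeny)
  st <- sampletree(fix$samples)
  cm <- suppressWarnings(compositions(fix$compositions, phy, st))
  list(phy = phy, st = st, cm = cm)
}

random_instance <- function(seed, n_subclones = NULL, n_samples = NULL,
                            n_ranks = NULL) {
  set.seed(seed)
  if (is.null(n_subclones)) n_subclones <- sample(2:10, 1)
  if (is.null(n_samples)) n_samples <- sample(2:10, 1)
  if (is.null(n_ranks)) n_ranks <- sample(1:min(4, n_samples), 1)
  parse_fixture(generate_fixture(n_subclones, n_samples, n_ranks,
                                 seed = seed))
}

# -- tree oracles ------------------------------------------------------------

# ancestor path (self first, ending at the inferred root) by parent lookups
oracle_ancestry <- function(st, s) {
  root <- sample_tree_root(st)
  parent_of <- setNames(st$parent, st$sample)
  path <- character()
  while (s != root) {
    path <- c(path, s)
    s <- parent_of[[s]]
  }
  c(path, root)
}

# brute-force LCA: intersect full ancestor paths, take the deepest member
oracle_lca <- function(st, samples) {
  root <- sample_tree_root(st)
  depth_of <- function(s) length(oracle_ancestry(st, s))
  common <- Reduce(intersect, lapply(samples, oracle_ancestry, st = st))
  common[[which.max(vapply(common, depth_of, numeric(1)))]]
}

# clade membership by repeated parent lookups
oracle_clade <- function(phy, founder) {
  parent_of <- setNames(phy$parent, phy$subclone)
  is_desc <- function(k) {
    while (!is.na(k)) {
      if (k == founder) return(TRUE)
      k <- parent_of[[k]]
    }
    FALSE
  }
  phy$subclone[vapply(phy$subclone, is_desc, logical(1))]
}

# brute-force host: deepest covering ancestor-or-self of the clade's support
# in which the founder itself is present above eps; else the inferred root
oracle_host <- function(phy, st, cm, k, eps = 1e-4) {
  members <- oracle_clade(phy, k)
  support <- rownames(cm)[rowSums(cm[, members, drop = FALSE] > eps) > 0]
  if (length(support) == 0) return(NA_character_)
  root <- sample_tree_root(st)
  covering <- Reduce(intersect, lapply(support, oracle_ancestry, st = st))
  covering <- setdiff(covering, root)
  depth <- vapply(covering, function(s) length(oracle_ancestry(st, s)),
                  numeric(1))
  covering <- covering[order(-depth)]
  for (s in covering) {
    if (cm[s, k] > eps) return(s)
  }
  root
}

# -- ordering oracles --------------------------------------------------------

# all permutations of 1..n, rows of a matrix
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# direct entropy-formula JSD in bits
oracle_jsd <- function(p, q) {
  h <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  m <- (p + q) / 2
  h(m) - (h(p) + h(q)) / 2
}

# exhaustive minimum of the in-rank objective for one rank of samples
oracle_rank_minimum <- function(ids, cm, indexed, weights = c(1, 1)) {
  n_sub <- length(indexed$dfs_index)
  subcl <- names(indexed$dfs_index)
  com <- vapply(ids, function(s) sum(cm[s, subcl] * indexed$dfs_index),
                numeric(1))
  k <- length(ids)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      cost[i, j] <- weights[1] * abs(com[i] - com[j]) / max(n_sub - 1, 1) +
        weights[2] * oracle_jsd(cm[ids[i], subcl], cm[ids[j], subcl])
    }
  }
  perms <- oracle_perms(k)
  vals <- vapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    sum(cost[cbind(p[-k], p[-1])])
  }, numeric(1))
  min(vals)
}

# -- color oracle ------------------------------------------------------------

# independent Oklab reference conversion (published matrices, coded apart
# from the package implementation)
oracle_srgb_to_oklab <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  l <- 0.4122214708 * lin[1] + 0.5363325363 * lin[2] + 0.0514459929 * lin[3]
  m <- 0.2119034982 * lin[1] + 0.6806995451 * lin[2] + 0.1073969566 * lin[3]
  s <- 0.0883024619 * lin[1] + 0.2817188376 * lin[2] + 0.6299787005 * lin[3]
  l <- l^(1 / 3); m <- m^(1 / 3); s <- s^(1 / 3)
  c(0.2104542553 * l + 0.7936177850 * m - 0.0040720468 * s,
    1.9779984951 * l - 2.4285922050 * m + 0.4505937099 * s,
    0.0259040371 * l + 0.7827717662 * m - 0.8086757660 * s)
}

oracle_oklab_to_srgb <- function(lab) {
  l <- lab[1] + 0.3963377774 * lab[2] + 0.2158037573 * lab[3]
  m <- lab[1] - 0.1055613458 * lab[2] - 0.0638541728 * lab[3]
  s <- lab[1] - 0.0894841775 * lab[2] - 1.2914855480 * lab[3]
  lin <- c(4.0767416621 * l^3 - 3.3077115913 * m^3 + 0.2307590544 * s^3,
           -1.2684380046 * l^3 + 2.6097574011 * m^3 - 0.3413193965 * s^3,
           -0.0041960863 * l^3 - 0.7034186147 * m^3 + 1.7076147010 * s^3)
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
}

# random point on the probability simplex
random_simplex <- function(n) {
  g <- rgamma(n, shape = 1)
  g / sum(g)
}
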