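# Synthetic fixture generation: random phylogenies, rank-respecting sample
# trees and Dirichlet clonal compositions that always pass the package's
# own validation. Used by the test suite and by the CLI's --fixture mode;
# generation is fully deterministic under a seed.

#' Generate a synthetic jellyfish input fixture
#'
#' Builds the three input tables from scratch: a random phylogeny by
#' uniform attachment (each new subclone picks an existing parent uniformly
#' at random), a random sample tree in which every parent sits at a strictly
#' earlier rank, and per-sample compositions drawn by choosing one or two
#' founding subclones, masking members of their clades with probability
#' `sparsity`, and Dirichlet-normalizing prevalences over the surviving
#' subclones. Presence is therefore always clade-coherent: every present
#' subclone descends from a founder that emerged in the sample's lineage.
#'
#' @param n_subclones number of subclones (>= 1)
#' @param n_samples number of samples (>= 1)
#' @param n_ranks number of time ranks (>= 1, <= `n_samples`)
#' @param concentration Dirichlet concentration for prevalences; larger
#'   values give more even compositions
#' @param sparsity probability that a non-founder clade member is absent
#'   from a sample
#' @param polyphyly_prob probability a sample gets a second, independent
#'   founding subclone (making it polyphyletic)
#' @param seed integer seed; identical specs and seeds yield identical
#'   tables
#' @return List with data frames `phylogeny`, `samples`, `compositions`
#'   (the TSV schemas of [read_phylogeny()], [read_sample_tree()],
#'   [read_compositions()]).
#' @export
generate_fixture <- function(n_subclones, n_samples, n_ranks,
                             concentration = 2, sparsity = 0.3,
                             polyphyly_prob = 0.3, seed = 1L) {
  if (n_subclones < 1L || n_samples < 1L || n_ranks < 1L) {
    stop_validation("fixture sizes must be >= 1")
  }
  if (n_ranks > n_samples) {
    stop_validation("infeasible fixture: n_ranks (%d) > n_samples (%d)",
                    n_ranks, n_samples)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  subclones <- as.character(seq_len(n_subclones))
  parent <- c("", if (n_subclones > 1L) {
    vapply(2:n_subclones, function(i) {
      subclones[[sample.int(i - 1L, 1L)]]
    }, character(1))
  })
  phy_df <- data.frame(subclone = subclones, parent = parent,
                       branchLength = sample.int(60L, n_subclones,
                                                 replace = TRUE),
                       stringsAsFactors = FALSE)
  phy <- phylotree(phy_df)

  samples <- sprintf("s%02d", seq_len(n_samples))
  # every rank 1..n_ranks occupied; extras scattered uniformly
  rank <- c(seq_len(n_ranks),
            if (n_samples > n_ranks) {
              sample.int(n_ranks, n_samples - n_ranks, replace = TRUE)
            })
  sparent <- character(n_samples)
  for (i in seq_len(n_samples)) {
    earlier <- which(rank < rank[[i]])
    sparent[[i]] <- if (length(earlier) == 0L || stats::runif(1) < 0.3) {
      ""
    } else {
      samples[[earlier[[sample.int(length(earlier), 1L)]]]]
    }
  }
  samp_df <- data.frame(sample = samples, parent = sparent, rank = rank,
                        rankTitle = sprintf("T%d", rank),
                        stringsAsFactors = FALSE)

  rows <- list()
  for (s in samples) {
    founders <- subclones[[sample.int(n_subclones, 1L)]]
    if (stats::runif(1) < polyphyly_prob && n_subclones > 1L) {
      founders <- unique(c(founders, subclones[[sample.int(n_subclones, 1L)]]))
    }
    present <- unique(unlist(lapply(founders, clade_of, phy = phy)))
    keep <- present %in% founders | stats::runif(length(present)) >= sparsity
    present <- present[keep]
    alpha <- rep(concentration, length(present))
    g <- stats::rgamma(length(present), shape = alpha)
    if (sum(g) == 0) g <- rep(1, length(present))
    prev <- g / sum(g)
    rows[[s]] <- data.frame(sample = s, subclone = present,
                            clonalPrevalence = prev, stringsAsFactors = FALSE)
  }
  comp_df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  list(phylogeny = phy_df, samples = samp_df, compositions = comp_df)
}

#' Write a fixture's tables to TSV files
#' @param fixture a [generate_fixture()] result
#' @param dir output directory (created if missing)
#' @return Named character vector of the three file paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(phylogeny = file.path(dir, "phylogeny.tsv"),
             samples = file.path(dir, "samples.tsv"),
             compositions = file.path(dir, "compositions.tsv"))
  utils::write.table(fixture$phylogeny, paths[["phylogeny"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(fixture$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(fixture$compositions, paths[["compositions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  paths
}
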