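# End-to-end pipeline: read -> validate -> order -> color -> lay out ->
# render, with the exit-code contract used by the command-line wrapper
# (0 success, 1 I/O error, 2 validation error, 3 internal error).

#' Run the full jellyfish pipeline
#'
#' Reads the input tables (or takes pre-parsed objects), derives a sample
#' tree from metadata when no sample table is given, composes the layout
#' and writes the SVG (and optionally the layout JSON). Stage progress and
#' counts go to standard error when `verbose`.
#'
#' @param phylogeny path to a phylogeny TSV or a [phylotree()]
#' @param samples path to a sample-tree TSV or a [sampletree()]; may be
#'   `NULL` when `metadata` is given
#' @param compositions path to a compositions TSV or a [compositions()]
#'   matrix
#' @param metadata optional path to a metadata TSV (columns `sample`,
#'   `timePoint`, `location`); used via [derive_sample_tree()] when
#'   `samples` is `NULL`
#' @param clonevol optional path to a ClonEvol-style table or directory;
#'   replaces `phylogeny` and `compositions` via [import_clonevol()]
#' @param out path for the SVG output (`NULL` to skip writing)
#' @param layout_json optional path for the layout-JSON export
#' @param weights ordering-objective weights `(w_com, w_jsd)`
#' @param epsilon presence threshold, see [layout_params()]
#' @param rotation_steps color-wheel rotations evaluated, see
#'   [build_color_scheme()]
#' @param params a [layout_params()] list; `epsilon` overrides its entry
#' @param seed integer seed (the pipeline is deterministic; the seed only
#'   affects `--fixture`-style callers that generate inputs)
#' @param verbose log stage progress to standard error
#' @return Invisibly, a list with `status` (0 on success, else the exit
#'   code), `layout`, `svg`, and `stats` (named counts). On error `layout`
#'   and `svg` are `NULL` and `message` holds the failure text.
#' @export
run_pipeline <- function(phylogeny = NULL, samples = NULL,
                         compositions = NULL, metadata = NULL,
                         clonevol = NULL, out = NULL, layout_json = NULL,
                         weights = c(1, 1), epsilon = 1e-4,
                         rotation_steps = 36L, params = layout_params(),
                         seed = 42L, verbose = FALSE) {
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[jellyplot] ", fmt), ...))
  }
  fail <- function(status, e) {
    invisible(list(status = status, layout = NULL, svg = NULL, stats = NULL,
                   message = conditionMessage(e)))
  }
  result <- tryCatch({
    t0 <- Sys.time()
    if (!is.null(clonevol)) {
      log_stage("importing ClonEvol tables from %s", clonevol)
      imported <- import_clonevol(clonevol)
      phy <- imported$phylogeny
      comp_raw <- imported$compositions
    } else {
      phy <- if (inherits(phylogeny, "clone_phylogeny")) phylogeny
             else read_phylogeny(phylogeny)
      comp_raw <- NULL
    }
    stree <- if (inherits(samples, "sample_tree")) {
      samples
    } else if (!is.null(samples)) {
      read_sample_tree(samples)
    } else if (!is.null(metadata)) {
      log_stage("deriving sample tree from metadata %s", metadata)
      derive_sample_tree(.read_tsv(metadata))
    } else {
      stop_validation("either a sample table or metadata must be given")
    }
    comp <- if (inherits(compositions, "clonal_compositions")) {
      compositions
    } else if (!is.null(compositions)) {
      read_compositions(compositions, phylogeny = phy, sample_tree = stree)
    } else if (!is.null(comp_raw)) {
      # restrict the ClonEvol matrix to the sample tree's samples
      missing <- setdiff(stree$sample, rownames(comp_raw))
      if (length(missing) > 0L) {
        stop_validation("sample '%s' has no composition", missing[[1L]])
      }
      m <- comp_raw[stree$sample, , drop = FALSE]
      class(m) <- class(comp_raw)
      m
    } else {
      stop_validation("compositions are required")
    }
    log_stage("validated %d samples, %d subclones", nrow(stree), nrow(phy))

    params$epsilon <- epsilon
    doc <- compose_layout(phy, stree, comp, params = params,
                          weights = weights, rotation_steps = rotation_steps)
    log_stage("layout: %d placed samples (%d inferred), %d tentacles",
              nrow(doc$samples), sum(doc$samples$is_inferred),
              nrow(doc$tentacles))
    svg <- render_svg(doc, path = out)
    if (!is.null(out)) log_stage("wrote %s", out)
    if (!is.null(layout_json)) {
      layout_to_json(doc, layout_json)
      log_stage("wrote %s", layout_json)
    }
    log_stage("done in %.2f s", as.numeric(Sys.time() - t0, units = "secs"))
    stats <- c(samples = nrow(doc$samples),
               inferred_samples = sum(doc$samples$is_inferred),
               subclones = length(doc$indexed$dfs_index),
               tentacles = nrow(doc$tentacles),
               objective = doc$arrangement$objective)
    invisible(list(status = 0L, layout = doc, svg = svg, stats = stats,
                   message = NULL))
  },
  jellyplot_io_error = function(e) fail(1L, e),
  jellyplot_validation_error = function(e) fail(2L, e),
  error = function(e) fail(3L, e))
  result
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper around [run_pipeline()], used by the
#' bundled `inst/cli/jellyplot.R` script. Errors are reported on standard
#' error and mapped to exit codes: 1 for I/O problems, 2 for validation
#' failures, 3 for anything else.
#'
#' @param args character vector of command-line arguments
#' @return Integer exit status (invisibly).
#' @export
jellyplot_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_flag <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    if (i[[1L]] == length(args)) return(default)
    args[[i[[1L]] + 1L]]
  }
  has_flag <- function(flag) flag %in% args
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)

  weights <- get_flag("--weights", "1,1")
  weights <- as.numeric(strsplit(weights, ",", fixed = TRUE)[[1L]])
  res <- run_pipeline(
    phylogeny = get_flag("--phylogeny"),
    samples = get_flag("--samples"),
    compositions = get_flag("--compositions"),
    metadata = get_flag("--metadata"),
    clonevol = get_flag("--clonevol"),
    out = get_flag("--out"),
    layout_json = get_flag("--layout-json"),
    weights = weights,
    epsilon = num(get_flag("--epsilon", "1e-4")),
    rotation_steps = as.integer(get_flag("--rotation-steps", "36")),
    seed = as.integer(get_flag("--seed", "42")),
    verbose = has_flag("--verbose"))
  if (res$status != 0L) {
    message(sprintf("jellyplot error (%d): %s", res$status, res$message))
  } else if (has_flag("--stats")) {
    cat(jsonlite::toJSON(as.list(res$stats), auto_unbox = TRUE, digits = NA),
        "\n", sep = "")
  }
  invisible(res$status)
}
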