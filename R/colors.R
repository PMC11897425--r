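# Phylogeny-aware color scheme in the OKLCH (cylindrical Oklab) space.
# Hue encodes the subclone's depth-first position on a color wheel divided
# into equal segments; chroma and lightness encode the total phylogenetic
# branch length, so highly evolved subclones appear darker and more vibrant.
# A blacklist of murky hue regions (dark yellows that read as brown) is
# avoided by rotating the wheel.

# Oklab <-> linear sRGB matrices (Bjorn Ottosson's published constants).
.OKLAB_TO_LMS <- matrix(c(
  1,  0.3963377774,  0.2158037573,
  1, -0.1055613458, -0.0638541728,
  1, -0.0894841775, -1.2914855480), nrow = 3, byrow = TRUE)
.LMS_TO_RGB <- matrix(c(
   4.0767416621, -3.3077115913,  0.2307590544,
  -1.2684380046,  2.6097574011, -0.3413193965,
  -0.0041960863, -0.7034186147,  1.7076147010), nrow = 3, byrow = TRUE)
.RGB_TO_LMS <- matrix(c(
  0.4122214708, 0.5363325363, 0.0514459929,
  0.2119034982, 0.6806995451, 0.1073969566,
  0.0883024619, 0.2817188376, 0.6299787005), nrow = 3, byrow = TRUE)
.LMS_TO_OKLAB <- matrix(c(
  0.2104542553,  0.7936177850, -0.0040720468,
  1.9779984951, -2.4285922050,  0.4505937099,
  0.0259040371,  0.7827717662, -0.8086757660), nrow = 3, byrow = TRUE)

.srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}
.srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

.oklab_to_linear <- function(lab) {
  lms <- (.OKLAB_TO_LMS %*% lab)^3
  drop(.LMS_TO_RGB %*% lms)
}

#' Convert an sRGB color to Oklab
#' @param rgb numeric length-3 vector of gamma-encoded sRGB channels in
#'   `[0, 1]`
#' @return Numeric `(L, a, b)` triple.
#' @export
srgb_to_oklab <- function(rgb) {
  lms <- (.RGB_TO_LMS %*% .srgb_decode(rgb))^(1 / 3)
  drop(.LMS_TO_OKLAB %*% lms)
}

#' Convert an Oklab color to sRGB
#' @param lab numeric `(L, a, b)` triple
#' @return Gamma-encoded sRGB channels in `[0, 1]` (unclamped).
#' @export
oklab_to_srgb <- function(lab) {
  .srgb_encode(.oklab_to_linear(lab))
}

.oklch_to_lab <- function(l, c, h) {
  hr <- h * pi / 180
  c(l, c * cos(hr), c * sin(hr))
}

.in_gamut <- function(linear, tol = 1e-7) {
  all(linear >= -tol & linear <= 1 + tol)
}

#' Convert an OKLCH color to sRGB, with chroma-reduction gamut mapping
#'
#' Out-of-gamut requests are mapped back by bisecting chroma toward 0 at
#' fixed lightness and hue, preserving the two attributes the scheme
#' encodes. The result is always representable without channel clipping.
#'
#' @param l lightness in `[0, 1]`
#' @param c chroma (non-negative)
#' @param h hue in degrees
#' @return List with `rgb` (encoded channels in `[0, 1]`), `hex` (7-char
#'   lowercase sRGB hex) and `clipped` (`TRUE` if chroma was reduced).
#' @export
oklch_to_srgb <- function(l, c, h) {
  lin <- .oklab_to_linear(.oklch_to_lab(l, c, h))
  clipped <- FALSE
  if (!.in_gamut(lin)) {
    clipped <- TRUE
    lo <- 0
    hi <- c
    for (i in seq_len(40L)) {
      mid <- (lo + hi) / 2
      if (.in_gamut(.oklab_to_linear(.oklch_to_lab(l, mid, h)))) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    lin <- .oklab_to_linear(.oklch_to_lab(l, lo, h))
  }
  rgb <- pmin(pmax(.srgb_encode(pmin(pmax(lin, 0), 1)), 0), 1)
  list(rgb = rgb, hex = sprintf("#%02x%02x%02x", round(rgb[1] * 255),
                                round(rgb[2] * 255), round(rgb[3] * 255)),
       clipped = clipped)
}

#' Assign hues by depth-first position on the color wheel
#'
#' `hue(k) = (rotation + dfs_index(k) * 360 / n) mod 360`: the wheel is
#' divided into `n` equal segments so distinct subclones get distinct hues
#' at least `360 / n` degrees apart.
#'
#' @param indexed an [index_phylogeny()] result
#' @param rotation wheel rotation in degrees
#' @return Named numeric vector of hues in `[0, 360)`.
#' @export
assign_hues <- function(indexed, rotation = 0) {
  n <- length(indexed$dfs_index)
  (rotation + indexed$dfs_index * 360 / n) %% 360
}

#' Assign chroma and lightness from total branch length
#'
#' Total root-to-node branch length (typically the accumulated mutation
#' count) is min-max scaled and mapped affinely: lightness falls from
#' `lightness[2]` to `lightness[1]` and chroma rises from `chroma[1]` to
#' `chroma[2]`, so subclones with more mutations appear darker and more
#' vibrant. A degenerate (all-equal) range maps every subclone to the
#' midpoint of both bounds.
#'
#' @param indexed an [index_phylogeny()] result
#' @param lightness `(min, max)` lightness bounds
#' @param chroma `(min, max)` chroma bounds
#' @return Named list with numeric vectors `chroma` and `lightness`.
#' @export
assign_chroma_lightness <- function(indexed, lightness = c(0.45, 0.85),
                                    chroma = c(0.06, 0.16)) {
  tbl <- indexed$total_branch_length
  rng <- range(tbl)
  t <- if (diff(rng) == 0) rep(0.5, length(tbl)) else (tbl - rng[1]) / diff(rng)
  list(chroma = stats::setNames(chroma[1] + t * diff(chroma), names(tbl)),
       lightness = stats::setNames(lightness[2] - t * diff(lightness),
                                   names(tbl)))
}

# Penetration depth of hue h into interval [a, b) on the circle; 0 if
# outside. Intervals with a > b wrap around 360.
.hue_penetration <- function(h, a, b) {
  inside <- if (a <= b) h >= a & h < b else h >= a | h < b
  width <- if (a <= b) b - a else 360 - a + b
  d <- pmin((h - a) %% 360, (a + width - h) %% 360)
  ifelse(inside, pmin(d, width / 2), 0)
}

#' Build the full phylogeny-aware color scheme
#'
#' Evaluates `rotation_steps` evenly spaced rotations of the hue wheel and
#' scores each by the number (then the total penetration depth) of
#' low-lightness subclone hues landing inside blacklisted intervals; the
#' best-scoring rotation wins (ties go to the smaller rotation). Fixed
#' colors from the phylogeny table's `color` column bypass generation.
#'
#' @param indexed an [index_phylogeny()] result
#' @param blacklist list of intervals, each a list with `hue = c(from, to)`
#'   degrees (half-open, may wrap) and `lightness_below`, the lightness
#'   threshold under which the interval applies. The default excludes the
#'   dark-yellow/brown zone.
#' @param rotation_steps number of candidate rotations to evaluate
#' @param lightness,chroma bounds passed to [assign_chroma_lightness()]
#' @return An object of class `color_assignment`: data frame with columns
#'   `subclone`, `hue`, `chroma`, `lightness`, `hex`, `fixed`; attributes
#'   `rotation` (chosen rotation) and `penalized` (`TRUE` if even the best
#'   rotation leaves a dark hue blacklisted).
#' @export
build_color_scheme <- function(indexed,
                               blacklist = list(list(hue = c(60, 110),
                                                     lightness_below = 0.6)),
                               rotation_steps = 36L,
                               lightness = c(0.45, 0.85),
                               chroma = c(0.06, 0.16)) {
  cl <- assign_chroma_lightness(indexed, lightness, chroma)
  ids <- names(indexed$dfs_index)

  score_rotation <- function(rot) {
    hues <- assign_hues(indexed, rot)
    count <- 0L
    depth <- 0
    for (iv in blacklist) {
      dark <- cl$lightness < iv$lightness_below
      pen <- .hue_penetration(hues, iv$hue[[1L]], iv$hue[[2L]])
      count <- count + sum(dark & pen > 0)
      depth <- depth + sum(pen[dark])
    }
    c(count, depth)
  }

  rotations <- (seq_len(max(rotation_steps, 1L)) - 1L) *
    360 / max(rotation_steps, 1L)
  best_rot <- rotations[[1L]]
  best_score <- score_rotation(best_rot)
  for (rot in rotations[-1L]) {
    sc <- score_rotation(rot)
    if (sc[[1L]] < best_score[[1L]] ||
        (sc[[1L]] == best_score[[1L]] && sc[[2L]] < best_score[[2L]] - 1e-12)) {
      best_rot <- rot
      best_score <- sc
    }
  }

  hues <- assign_hues(indexed, best_rot)
  fixed <- stats::setNames(indexed$phylogeny$color, indexed$phylogeny$subclone)
  hex <- character(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    hex[[i]] <- if (!is.na(fixed[[id]])) {
      tolower(fixed[[id]])
    } else {
      oklch_to_srgb(cl$lightness[[id]], cl$chroma[[id]], hues[[id]])$hex
    }
  }
  out <- data.frame(subclone = ids, hue = hues[ids], chroma = cl$chroma[ids],
                    lightness = cl$lightness[ids], hex = hex,
                    fixed = !is.na(fixed[ids]), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "rotation") <- best_rot
  attr(out, "penalized") <- best_score[[1L]] > 0L
  class(out) <- c("color_assignment", "data.frame")
  out
}

#' @export
print.color_assignment <- function(x, ...) {
  cat(sprintf("Color assignment: %d subclones, rotation %.1f deg%s\n",
              nrow(x), attr(x, "rotation"),
              if (isTRUE(attr(x, "penalized"))) " (penalized)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}
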