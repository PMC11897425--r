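# Standalone SVG 1.1 serialization of a jellyfish layout. Deterministic:
# numbers are written with fixed 3-decimal precision so identical layouts
# yield byte-identical files. Interactivity is out of scope; static <title>
# tooltips carry prevalence and branch-length details instead.

#' Rendering configuration
#'
#' @param padding extra canvas padding in plot units
#' @param font_family,font_size text style for rank titles and the legend
#' @param stroke_width outline width for sample frames
#' @param legend draw per-subclone legend swatches
#' @param tooltips embed `<title>` elements with per-element details
#' @param background canvas background color (7-char hex)
#' @param bell_segments number of straight segments used to trace a bell
#'   outline
#' @return Named list of render settings.
#' @export
render_config <- function(padding = 10, font_family = "sans-serif",
                          font_size = 12, stroke_width = 1,
                          legend = TRUE, tooltips = TRUE,
                          background = "#ffffff", bell_segments = 32L) {
  stopifnot(padding >= 0, font_size > 0, stroke_width > 0, bell_segments >= 4L)
  as.list(environment())
}

# fixed-precision, negative-zero-free number formatting
.fmt <- function(x) {
  x <- round(x, 3)
  x[x == 0] <- 0
  formatC(x, format = "f", digits = 3)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a jellyfish layout to SVG
#'
#' Produces well-formed SVG 1.1 text: one group per sample (frame plus
#' slab rectangles), per bell, and per tentacle bundle, each tagged with
#' its source ids as `data-*` attributes; rank titles as column headers;
#' and an optional legend of subclone color swatches.
#'
#' @param doc a [compose_layout()] result
#' @param config a [render_config()] list
#' @param path optional output file; when given the SVG is written there
#' @return The SVG text as a single character string (invisibly when
#'   written to a file).
#' @export
render_svg <- function(doc, config = render_config(), path = NULL) {
  p <- config$padding
  legend_w <- if (config$legend) 140 else 0
  title_h <- config$font_size * 2
  w <- doc$canvas[["width"]] + 2 * p + legend_w
  h <- doc$canvas[["height"]] + 2 * p + title_h
  ox <- p              # content offset
  oy <- p + title_h
  hex_of <- stats::setNames(doc$colors$hex, doc$colors$subclone)
  tbl <- doc$indexed$total_branch_length

  out <- character(0)
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="',
       .fmt(w), '" height="', .fmt(h), '" viewBox="0 0 ', .fmt(w), ' ',
       .fmt(h), '">')
  push('<rect class="background" x="0" y="0" width="', .fmt(w),
       '" height="', .fmt(h), '" fill="', config$background, '"/>')

  # rank column titles
  for (i in seq_len(nrow(doc$ranks))) {
    r <- doc$ranks[i, ]
    push('<text class="rank-title" x="', .fmt(ox + (r$x0 + r$x1) / 2),
         '" y="', .fmt(p + config$font_size),
         '" text-anchor="middle" font-family="', config$font_family,
         '" font-size="', .fmt(config$font_size), '">',
         .xml_escape(r$title), '</text>')
  }

  # tentacle bundles, grouped per sample-tree edge, drawn under the samples
  if (nrow(doc$tentacles) > 0L) {
    edges <- unique(doc$tentacles[, c("from", "to")])
    for (i in seq_len(nrow(edges))) {
      tt <- doc$tentacles[doc$tentacles$from == edges$from[[i]] &
                            doc$tentacles$to == edges$to[[i]], , drop = FALSE]
      push('<g class="tentacle-bundle" data-from="',
           .xml_escape(edges$from[[i]]), '" data-to="',
           .xml_escape(edges$to[[i]]), '">')
      for (j in seq_len(nrow(tt))) {
        t <- tt[j, ]
        push('<path class="tentacle" data-subclone-id="',
             .xml_escape(t$subclone), '" d="M', .fmt(ox + t$x0), ' ',
             .fmt(oy + t$y0), ' C', .fmt(ox + t$cx0), ' ', .fmt(oy + t$cy0),
             ', ', .fmt(ox + t$cx1), ' ', .fmt(oy + t$cy1), ', ',
             .fmt(ox + t$x1), ' ', .fmt(oy + t$y1), '" fill="none" stroke="',
             hex_of[[t$subclone]], '" stroke-width="',
             .fmt((t$width0 + t$width1) / 8), '" stroke-opacity="0.85">',
             if (config$tooltips) {
               paste0('<title>', .xml_escape(t$subclone), ': ',
                      .xml_escape(t$from), ' → ', .xml_escape(t$to),
                      '</title>')
             } else "",
             '</path>')
      }
      push('</g>')
    }
  }

  # sample groups: frame + slabs (inherited subclones) then nested bells
  for (i in seq_len(nrow(doc$samples))) {
    s <- doc$samples[i, ]
    push('<g class="sample" data-sample-id="', .xml_escape(s$sample),
         '" data-rank="', s$rank, '"',
         if (s$is_inferred) ' data-inferred="true"' else "", '>')
    sl <- doc$slabs[doc$slabs$sample == s$sample, , drop = FALSE]
    host_bells <- doc$bells[[s$sample]]
    bell_ids <- names(host_bells)
    for (j in seq_len(nrow(sl))) {
      k <- sl$subclone[[j]]
      if (k %in% bell_ids) next  # emerging here: drawn as a bell
      push('<rect class="slab" data-subclone-id="', .xml_escape(k),
           '" x="', .fmt(ox + s$x), '" y="', .fmt(oy + s$y + sl$y0[[j]]),
           '" width="', .fmt(s$width), '" height="', .fmt(sl$height[[j]]),
           '" fill="', hex_of[[k]], '">',
           if (config$tooltips) {
             paste0('<title>', .xml_escape(k), ' in ',
                    .xml_escape(s$sample), ': prevalence ',
                    .fmt(sl$height[[j]] / s$height), ', branch length ',
                    .fmt(tbl[[k]]), '</title>')
           } else "",
           '</rect>')
    }
    if (length(bell_ids) > 0L) {
      xs <- seq(0, 1, length.out = config$bell_segments + 1L)
      # parents before children so nested bells paint on top
      bell_ids <- bell_ids[order(vapply(host_bells, function(b) b$depth,
                                        integer(1)))]
      for (k in bell_ids) {
        o <- bell_outline(host_bells, k, xs)
        px <- ox + s$x + xs * s$width
        d <- paste0("M", .fmt(px[1]), " ", .fmt(oy + s$y + o$top[1]),
                    paste0(" L", .fmt(px[-1]), " ",
                           .fmt(oy + s$y + o$top[-1]), collapse = ""),
                    paste0(" L", .fmt(rev(px)), " ",
                           .fmt(oy + s$y + rev(o$bottom)), collapse = ""),
                    " Z")
        push('<path class="bell" data-subclone-id="', .xml_escape(k),
             '" data-sample-id="', .xml_escape(s$sample), '" d="', d,
             '" fill="', hex_of[[k]], '">',
             if (config$tooltips) {
               paste0('<title>', .xml_escape(k), ' emerges in ',
                      .xml_escape(s$sample), ': prevalence ',
                      .fmt((host_bells[[k]]$exit_y1 -
                              host_bells[[k]]$exit_y0) / s$height),
                      ', branch length ', .fmt(tbl[[k]]), '</title>')
             } else "",
             '</path>')
      }
    }
    push('<rect class="frame" x="', .fmt(ox + s$x), '" y="', .fmt(oy + s$y),
         '" width="', .fmt(s$width), '" height="', .fmt(s$height),
         '" fill="none" stroke="#333333" stroke-width="',
         .fmt(config$stroke_width), '"/>')
    push('<text class="sample-label" x="', .fmt(ox + s$x + s$width / 2),
         '" y="', .fmt(oy + s$y + s$height + config$font_size + 2),
         '" text-anchor="middle" font-family="', config$font_family,
         '" font-size="', .fmt(config$font_size * 0.9), '">',
         .xml_escape(s$sample), '</text>')
    push('</g>')
  }

  if (config$legend) {
    lx <- doc$canvas[["width"]] + 2 * p
    push('<g class="legend">')
    for (i in seq_len(nrow(doc$colors))) {
      y <- oy + (i - 1L) * (config$font_size + 6)
      push('<rect class="legend-swatch" data-subclone-id="',
           .xml_escape(doc$colors$subclone[[i]]), '" x="', .fmt(lx),
           '" y="', .fmt(y), '" width="', .fmt(config$font_size),
           '" height="', .fmt(config$font_size), '" fill="',
           doc$colors$hex[[i]], '"/>')
      push('<text class="legend-label" x="',
           .fmt(lx + config$font_size + 6), '" y="',
           .fmt(y + config$font_size - 2), '" font-family="',
           config$font_family, '" font-size="', .fmt(config$font_size * 0.9),
           '">', .xml_escape(doc$colors$subclone[[i]]), '</text>')
    }
    push('</g>')
  }

  push('</svg>')
  svg <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(svg), con)
    return(invisible(svg))
  }
  svg
}
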