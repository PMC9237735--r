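# Figure layout and rendering.
#
# The layout stacks one row per read, grouped by cluster inside each cell
# type, on the compressed plot axis; exon rectangles carry the cell-type
# color, exons flagged as alternative are recolored orange, passing mismatch
# sites appear as dots on every read row carrying the observation (SNV blue,
# insertion green, deletion red), and the annotation's transcripts are drawn
# in black at the bottom, restricted to those overlapping the read-covered
# span. Rendering is deterministic for a fixed layout: the SVG emitter
# produces one element per glyph, so element counts equal glyph counts.

feature_colors <- c(
  alt_exon = "orange", SNV = "blue", insertion = "green", deletion = "red",
  annotation = "black"
)

default_cell_palette <- function(cell_types) {
  stats::setNames(grDevices::hcl.colors(max(length(cell_types), 2L),
                                        "Dark 3")[seq_along(cell_types)],
                  cell_types)
}

#' Compute the read-stack figure layout
#'
#' @param clusters Ordered clusters from [order_clusters()].
#' @param reads The reads tibble the clusters were built from.
#' @param map A `coord_map` for the gene.
#' @param alt_calls Optional alternative-exon call tibble; flagged exons are
#'   recolored. A read exon block *equal* to a flagged candidate takes the
#'   alternative color; a block strictly containing it (retained intron)
#'   keeps the cell-type color and only the matching sub-interval is
#'   overlaid (disable with `recolor_contained = FALSE`).
#' @param sites Optional mismatch site tibble; only passing sites are drawn.
#' @param observations Optional observation tibble (attribute of
#'   [find_mismatches()] output); when given, dots are placed on each read
#'   row carrying the observation, otherwise passing sites are drawn once on
#'   a summary row.
#' @param annotation Optional `gene_annotation`; transcripts overlapping the
#'   read-covered span are drawn at the bottom (unclipped).
#' @param cell_type_order Optional character vector fixing the top-to-bottom
#'   cell-type order; defaults to factor levels or lexicographic order.
#' @param palette Named colors for cell types; defaults to a fixed HCL
#'   palette. Feature colors can be overridden via `feature_palette`.
#' @param feature_palette Named colors for `alt_exon`, `SNV`, `insertion`,
#'   `deletion`, `annotation`.
#' @param recolor_contained Overlay the alternative color on sub-intervals of
#'   containing blocks (default `TRUE`).
#' @return A `stack_layout` object (list of tibbles; see Details) with
#'   `autoplot()`, [render_static()] and [render_interactive()] methods.
#' @export
compute_layout <- function(clusters, reads, map, alt_calls = NULL,
                           sites = NULL, observations = NULL,
                           annotation = NULL, cell_type_order = NULL,
                           palette = NULL, feature_palette = feature_colors,
                           recolor_contained = TRUE) {
  if (is.null(clusters) || nrow(clusters) == 0L) {
    stop("nothing to plot: empty cluster list", call. = FALSE)
  }
  feature_palette <- utils::modifyList(as.list(feature_colors),
                                       as.list(feature_palette))
  cts <- unique(clusters$cell_type)
  if (!is.null(cell_type_order)) {
    cts <- intersect(cell_type_order, cts)
  } else if (is.factor(reads$cell_type)) {
    cts <- intersect(levels(reads$cell_type), cts)
  } else {
    cts <- sort(cts)
  }
  if (is.null(palette)) palette <- default_cell_palette(cts)

  # assign one row per read, top-down: cell types in order, clusters by rank,
  # reads in canonical order within each cluster
  read_by_id <- reads[match(unlist(clusters$read_ids),
                            reads$read_id), , drop = FALSE]
  rows <- list()
  row_i <- 0L
  for (ct in cts) {
    cl_ct <- clusters[clusters$cell_type == ct, , drop = FALSE]
    cl_ct <- cl_ct[order(cl_ct$rank), , drop = FALSE]
    for (j in seq_len(nrow(cl_ct))) {
      sub <- reads[reads$read_id %in% cl_ct$read_ids[[j]], , drop = FALSE]
      sub <- order_reads_within_cluster(sub)
      for (k in seq_len(nrow(sub))) {
        row_i <- row_i + 1L
        rows[[row_i]] <- tibble::tibble(
          read_id = sub$read_id[k], cell_type = ct,
          cluster_rank = cl_ct$rank[j], cluster_size = cl_ct$size[j],
          row = row_i
        )
      }
    }
  }
  rows <- dplyr::bind_rows(rows)

  alt_flagged <- if (!is.null(alt_calls)) {
    dplyr::filter(alt_calls, .data$is_alternative)
  } else tibble::tibble(start = integer(), end = integer())

  exon_rects <- list()
  alt_overlays <- list()
  connectors <- list()
  for (i in seq_len(nrow(rows))) {
    ex <- reads$exons[[match(rows$read_id[i], reads$read_id)]]
    pe <- to_plot_interval(map, ex$start, ex$end)
    is_alt <- vapply(seq_len(nrow(ex)), function(j) {
      any(alt_flagged$start == ex$start[j] & alt_flagged$end == ex$end[j])
    }, logical(1))
    exon_rects[[i]] <- tibble::tibble(
      row = rows$row[i], read_id = rows$read_id[i],
      cell_type = rows$cell_type[i],
      xmin = pe$plot_start, xmax = pe$plot_end, is_alt = is_alt
    )
    if (recolor_contained && nrow(alt_flagged)) {
      for (j in seq_len(nrow(ex))) {
        contains <- !is_alt[j] & alt_flagged$start >= ex$start[j] &
          alt_flagged$end <= ex$end[j] &
          !(alt_flagged$start == ex$start[j] & alt_flagged$end == ex$end[j])
        if (any(contains)) {
          sub <- alt_flagged[contains, , drop = FALSE]
          pv <- to_plot_interval(map, sub$start, sub$end)
          alt_overlays[[length(alt_overlays) + 1L]] <- tibble::tibble(
            row = rows$row[i], xmin = pv$plot_start, xmax = pv$plot_end
          )
        }
      }
    }
    if (nrow(ex) > 1L) {
      connectors[[i]] <- tibble::tibble(
        row = rows$row[i],
        xmin = to_plot(map, ex$end[-nrow(ex)]),
        xmax = to_plot(map, ex$start[-1L])
      )
    }
  }
  exon_rects <- dplyr::bind_rows(exon_rects)
  alt_overlays <- if (length(alt_overlays)) dplyr::bind_rows(alt_overlays) else
    tibble::tibble(row = integer(), xmin = numeric(), xmax = numeric())
  connectors <- if (length(connectors)) dplyr::bind_rows(connectors) else
    tibble::tibble(row = integer(), xmin = numeric(), xmax = numeric())

  # mismatch dots
  dots <- tibble::tibble(x = numeric(), row = integer(), kind = character(),
                         freq_pct = numeric(), read_id = character())
  summary_row <- NULL
  if (!is.null(sites) && nrow(sites)) {
    pass <- dplyr::filter(sites, .data$passes)
    if (nrow(pass)) {
      if (!is.null(observations) && nrow(observations)) {
        keyed <- dplyr::inner_join(
          observations,
          dplyr::select(pass, "ref_pos", "kind", "ref", "alt", "freq_pct"),
          by = c("ref_pos", "kind", "ref", "alt")
        )
        keyed <- dplyr::inner_join(keyed, rows, by = "read_id")
        if (nrow(keyed)) {
          dots <- tibble::tibble(
            x = to_plot(map, pmin(pmax(keyed$ref_pos, map$span[1]),
                                  map$span[2])),
            row = keyed$row, kind = keyed$kind,
            freq_pct = keyed$freq_pct, read_id = keyed$read_id
          )
        }
      } else {
        summary_row <- nrow(rows) + 1L
        dots <- tibble::tibble(
          x = to_plot(map, pmin(pmax(pass$ref_pos, map$span[1]),
                                map$span[2])),
          row = summary_row, kind = pass$kind,
          freq_pct = pass$freq_pct, read_id = NA_character_
        )
      }
    }
  }

  # annotation section, below the read rows (and summary row, if any)
  ann_rects <- tibble::tibble(row = integer(), xmin = numeric(),
                              xmax = numeric(), transcript_id = character())
  ann_connectors <- tibble::tibble(row = integer(), xmin = numeric(),
                                   xmax = numeric())
  n_read_rows <- nrow(rows)
  ann_start_row <- n_read_rows + (if (is.null(summary_row)) 0L else 1L) + 2L
  if (!is.null(annotation)) {
    covered <- range(unlist(lapply(reads$exons,
                                   function(e) c(e$start[1], e$end[nrow(e)]))))
    tx <- annotation$transcripts
    keep <- vapply(tx$exons, function(e) {
      e$start[1] < covered[2] && e$end[nrow(e)] > covered[1]
    }, logical(1))
    tx <- tx[keep, , drop = FALSE]
    r <- ann_start_row
    for (i in seq_len(nrow(tx))) {
      ex <- tx$exons[[i]]
      ex <- ex[ex$start >= map$span[1] & ex$end <= map$span[2], , drop = FALSE]
      if (nrow(ex) == 0L) next
      pe <- to_plot_interval(map, ex$start, ex$end)
      ann_rects <- dplyr::bind_rows(ann_rects, tibble::tibble(
        row = r, xmin = pe$plot_start, xmax = pe$plot_end,
        transcript_id = tx$transcript_id[i]
      ))
      if (nrow(ex) > 1L) {
        ann_connectors <- dplyr::bind_rows(ann_connectors, tibble::tibble(
          row = r, xmin = to_plot(map, ex$end[-nrow(ex)]),
          xmax = to_plot(map, ex$start[-1L])
        ))
      }
      r <- r + 1L
    }
  }

  n_rows_total <- max(c(rows$row, summary_row, ann_rects$row, 1L))
  axis_length <- plot_axis_length(map)
  structure(
    list(
      rows = rows, exon_rects = exon_rects, alt_overlays = alt_overlays,
      connectors = connectors, dots = dots, ann_rects = ann_rects,
      ann_connectors = ann_connectors, summary_row = summary_row,
      cell_types = cts, palette = palette,
      feature_palette = feature_palette,
      axis_length = axis_length, n_rows = n_rows_total,
      dims = c(width = max(5, axis_length / 500),
               height = 1.2 + 0.035 * n_rows_total)
    ),
    class = "stack_layout"
  )
}

#' @export
print.stack_layout <- function(x, ...) {
  cat("<stack_layout> ", nrow(x$rows), " read row(s) across ",
      length(x$cell_types), " cell type(s); ", nrow(x$exon_rects),
      " exon rectangle(s), ", nrow(x$dots), " mismatch dot(s), ",
      nrow(x$ann_rects), " annotation exon(s)\n", sep = "")
  invisible(x)
}

#' Tidy a stack layout into its row table
#' @param x A `stack_layout`.
#' @param ... Unused.
#' @return The per-read row tibble.
#' @exportS3Method generics::tidy
tidy.stack_layout <- function(x, ...) x$rows

#' ggplot2 figure for a stack layout
#'
#' @param object A `stack_layout`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stack_layout <- function(object, ...) {
  s <- object
  h <- 0.38
  rect_df <- dplyr::mutate(
    s$exon_rects,
    fill = ifelse(.data$is_alt, s$feature_palette$alt_exon,
                  unname(s$palette[.data$cell_type]))
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = s$connectors,
      ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                   y = -.data$row, yend = -.data$row),
      linewidth = 0.2, color = "grey40"
    ) +
    ggplot2::geom_rect(
      data = rect_df,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -.data$row - h, ymax = -.data$row + h,
                   fill = .data$fill)
    ) +
    ggplot2::scale_fill_identity()
  if (nrow(s$alt_overlays)) {
    p <- p + ggplot2::geom_rect(
      data = s$alt_overlays,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -.data$row - h, ymax = -.data$row + h),
      fill = s$feature_palette$alt_exon
    )
  }
  if (nrow(s$dots)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(
        s$dots, color = unlist(s$feature_palette[.data$kind])),
      ggplot2::aes(x = .data$x, y = -.data$row, color = .data$color),
      size = 0.8
    ) + ggplot2::scale_color_identity()
  }
  if (nrow(s$ann_rects)) {
    p <- p +
      ggplot2::geom_segment(
        data = s$ann_connectors,
        ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                     y = -.data$row, yend = -.data$row),
        linewidth = 0.2, color = s$feature_palette$annotation
      ) +
      ggplot2::geom_rect(
        data = s$ann_rects,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -.data$row - h, ymax = -.data$row + h),
        fill = s$feature_palette$annotation
      )
  }
  labels <- s$rows |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(y = -mean(range(.data$row)), .groups = "drop")
  p +
    ggplot2::geom_text(
      data = labels,
      ggplot2::aes(x = -0.01 * s$axis_length, y = .data$y,
                   label = .data$cell_type),
      hjust = 1, size = 3
    ) +
    ggplot2::scale_x_continuous(
      name = "compressed genomic axis (exons at real scale)",
      limits = c(-0.25 * s$axis_length, s$axis_length),
      expand = ggplot2::expansion(mult = c(0, 0.01))
    ) +
    ggplot2::theme_void() +
    ggplot2::theme(axis.title.x = ggplot2::element_text(size = 9))
}

# -- deterministic SVG emitter ------------------------------------------------

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Emit the layout as SVG text. One <rect> per exon rectangle / overlay /
# annotation exon, one <line> per intron connector, one <circle> per mismatch
# dot; read rows are grouped in one <g class="celltype"> per cell type. With
# interactive = TRUE each glyph carries a <title> hover tooltip.
layout_svg_lines <- function(s, interactive = FALSE) {
  px_w <- 1000
  sx <- px_w / s$axis_length
  row_h <- 8
  pad_top <- 12
  px_h <- pad_top + row_h * (s$n_rows + 1L)
  X <- function(x) sprintf("%.2f", x * sx)
  Y <- function(row) sprintf("%.2f", pad_top + (row - 0.5) * row_h)
  rect_el <- function(xmin, xmax, row, fill, class, title = NULL) {
    body <- if (!is.null(title)) {
      sprintf("<title>%s</title></rect>", svg_escape(title))
    } else "</rect>"
    sprintf(
      '<rect class="%s" x="%s" y="%.2f" width="%s" height="%.2f" fill="%s">%s',
      class, X(xmin), pad_top + (row - 1) * row_h + 1, X(xmax - xmin),
      row_h - 2, fill, body
    )
  }
  line_el <- function(xmin, xmax, row, stroke, class) {
    sprintf(
      '<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="0.7"/>',
      class, X(xmin), Y(row), X(xmax), Y(row), stroke
    )
  }
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    px_w, px_h, px_w, px_h
  ))
  for (ct in s$cell_types) {
    out <- c(out, sprintf('<g class="celltype" data-celltype="%s">',
                          svg_escape(ct)))
    rws <- s$rows[s$rows$cell_type == ct, , drop = FALSE]
    cn <- s$connectors[s$connectors$row %in% rws$row, , drop = FALSE]
    for (i in seq_len(nrow(cn))) {
      out <- c(out, line_el(cn$xmin[i], cn$xmax[i], cn$row[i],
                            "grey", "intron"))
    }
    er <- s$exon_rects[s$exon_rects$row %in% rws$row, , drop = FALSE]
    for (i in seq_len(nrow(er))) {
      fill <- if (er$is_alt[i]) s$feature_palette$alt_exon else
        unname(s$palette[er$cell_type[i]])
      title <- if (interactive) {
        rw <- rws[match(er$row[i], rws$row), ]
        sprintf("read %s | %s | cluster size %d", er$read_id[i], ct,
                rw$cluster_size)
      } else NULL
      out <- c(out, rect_el(er$xmin[i], er$xmax[i], er$row[i], fill,
                            if (er$is_alt[i]) "exon altexon" else "exon",
                            title))
    }
    ao <- s$alt_overlays[s$alt_overlays$row %in% rws$row, , drop = FALSE]
    for (i in seq_len(nrow(ao))) {
      out <- c(out, rect_el(ao$xmin[i], ao$xmax[i], ao$row[i],
                            s$feature_palette$alt_exon, "altoverlay"))
    }
    dt <- s$dots[s$dots$row %in% rws$row, , drop = FALSE]
    for (i in seq_len(nrow(dt))) {
      title_attr <- if (interactive) {
        sprintf("<title>%s %.1f%% | read %s</title></circle>",
                dt$kind[i], dt$freq_pct[i], svg_escape(dt$read_id[i]))
      } else "</circle>"
      out <- c(out, sprintf(
        '<circle class="mismatch mismatch-%s" cx="%s" cy="%s" r="2" fill="%s">%s',
        dt$kind[i], X(dt$x[i]), Y(dt$row[i]),
        s$feature_palette[[dt$kind[i]]], title_attr
      ))
    }
    out <- c(out, "</g>")
  }
  if (!is.null(s$summary_row)) {
    dt <- s$dots[s$dots$row == s$summary_row, , drop = FALSE]
    out <- c(out, '<g class="site-summary">')
    for (i in seq_len(nrow(dt))) {
      title_attr <- if (interactive) {
        sprintf("<title>%s %.1f%%</title></circle>", dt$kind[i],
                dt$freq_pct[i])
      } else "</circle>"
      out <- c(out, sprintf(
        '<circle class="mismatch mismatch-%s" cx="%s" cy="%s" r="2" fill="%s">%s',
        dt$kind[i], X(dt$x[i]), Y(dt$row[i]),
        s$feature_palette[[dt$kind[i]]], title_attr
      ))
    }
    out <- c(out, "</g>")
  }
  if (nrow(s$ann_rects)) {
    out <- c(out, '<g class="annotation">')
    for (i in seq_len(nrow(s$ann_connectors))) {
      cn <- s$ann_connectors[i, ]
      out <- c(out, line_el(cn$xmin, cn$xmax, cn$row,
                            s$feature_palette$annotation, "ann-intron"))
    }
    for (i in seq_len(nrow(s$ann_rects))) {
      ar <- s$ann_rects[i, ]
      title <- if (interactive) ar$transcript_id else NULL
      out <- c(out, rect_el(ar$xmin, ar$xmax, ar$row,
                            s$feature_palette$annotation, "ann-exon", title))
    }
    out <- c(out, "</g>")
  }
  c(out, "</svg>")
}

#' Render a stack layout to a static file
#'
#' `svg` uses the package's own emitter (one SVG element per glyph, byte
#' deterministic for a fixed layout); `pdf` and `png` render the
#' [autoplot.stack_layout()] figure through the corresponding graphics
#' device. Dimensions come from the layout (`dims`), proportional to the row
#' count.
#'
#' @param spec A `stack_layout`.
#' @param path Output file.
#' @param format One of `"svg"`, `"pdf"`, `"png"`.
#' @return `path`, invisibly.
#' @export
render_static <- function(spec, path, format = c("svg", "pdf", "png")) {
  format <- match.arg(format)
  if (format == "svg") {
    writeLines(layout_svg_lines(spec, interactive = FALSE), path)
    return(invisible(path))
  }
  w <- spec$dims[["width"]]
  h <- spec$dims[["height"]]
  if (format == "pdf") {
    grDevices::pdf(path, width = w, height = h)
  } else {
    grDevices::png(path, width = w, height = h, units = "in", res = 150)
  }
  on.exit(grDevices::dev.off())
  print(autoplot.stack_layout(spec))
  invisible(path)
}

#' Render a stack layout as a standalone interactive HTML page
#'
#' Writes a self-contained HTML file embedding the layout as SVG with native
#' hover tooltips: each read's exon rectangles report the read id, cell type
#' and cluster size, and each mismatch dot reports its kind and frequency.
#' Read rows are grouped into one SVG group per cell type.
#'
#' @param spec A `stack_layout`.
#' @param path Output `.html` file.
#' @param title Page title.
#' @return `path`, invisibly.
#' @export
render_interactive <- function(spec, path, title = "read stack") {
  svg <- layout_svg_lines(spec, interactive = TRUE)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s</title>", svg_escape(title)),
    "<style>body{font-family:sans-serif;margin:1em} svg{width:100%;height:auto}",
    "rect.exon:hover, circle.mismatch:hover{stroke:black;stroke-width:1}</style>",
    "</head><body>",
    sprintf("<h3>%s</h3>", svg_escape(title)),
    svg,
    "</body></html>"
  )
  writeLines(html, path)
  invisible(path)
}
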