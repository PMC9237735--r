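# Exon-preserving coordinate compression.
#
# Exons separated by introns up to ~100-fold larger cannot be drawn usefully
# at genomic scale. The coordinate map keeps every base that carries exonic
# evidence (annotated or observed in any read) at real scale and shrinks each
# maximal exon-free gap to a fixed plot width (default 100 bases). Gaps no
# longer than the compressed width are left at real scale: compression must
# never enlarge. Retained introns observed in a read count as exonic evidence
# and therefore stay at real scale — a documented property of the method,
# not a defect.

#' Pool exonic evidence from reads and annotation
#'
#' @param reads A reads tibble (may be `NULL`).
#' @param annotation A `gene_annotation` (may be `NULL`).
#' @return Tibble of `start`, `end` exon intervals (not merged).
#' @export
collect_exonic_intervals <- function(reads = NULL, annotation = NULL) {
  parts <- list()
  if (!is.null(reads) && nrow(reads) > 0L) {
    parts <- c(parts, reads$exons)
  }
  if (!is.null(annotation)) {
    parts <- c(parts, annotation$transcripts$exons)
  }
  if (length(parts) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  dplyr::bind_rows(parts)
}

#' Build an exon-preserving compressed coordinate map
#'
#' Unions the exonic intervals into maximal blocks; blocks become real-scale
#' segments, and each maximal exon-free gap between them (including the flanks
#' out to `span`) becomes a compressed segment of plot length
#' `min(gap length, compressed_width)`. A gap no longer than
#' `compressed_width` therefore stays at genomic scale.
#'
#' @param exonic Tibble of `start`, `end` exon intervals (from reads and/or
#'   annotation); see [collect_exonic_intervals()].
#' @param span Numeric length-2 `c(start, end)` of the region to map. Defaults
#'   to the footprint of `exonic`.
#' @param compressed_width Plot width, in bases, given to an exon-free gap
#'   (default 100).
#' @return A `coord_map` object. Its `segments` tibble tiles the span:
#'   `genomic_start`, `genomic_end`, `plot_start`, `plot_length`,
#'   `compressed`.
#' @export
build_coordinate_map <- function(exonic, span = NULL, compressed_width = 100) {
  stopifnot(compressed_width >= 1)
  blocks <- merge_intervals(exonic)
  if (is.null(span)) {
    if (nrow(blocks) == 0L) stop("no exonic intervals and no span", call. = FALSE)
    span <- c(blocks$start[1], blocks$end[nrow(blocks)])
  }
  stopifnot(length(span) == 2L, span[1] < span[2])
  if (nrow(blocks) > 0L &&
      (blocks$start[1] < span[1] || blocks$end[nrow(blocks)] > span[2])) {
    stop("exonic intervals extend outside the span", call. = FALSE)
  }
  if (nrow(blocks) == 0L) {
    warning("no exonic intervals: whole span kept at real scale")
    segs <- tibble::tibble(
      genomic_start = span[1], genomic_end = span[2],
      compressed = FALSE
    )
  } else {
    gaps <- interval_gaps(blocks, span = span)
    segs <- dplyr::bind_rows(
      tibble::tibble(genomic_start = blocks$start, genomic_end = blocks$end,
                     compressed = FALSE),
      tibble::tibble(genomic_start = gaps$start, genomic_end = gaps$end,
                     compressed = TRUE)
    ) |>
      dplyr::arrange(.data$genomic_start)
  }
  glen <- segs$genomic_end - segs$genomic_start
  # a gap <= compressed_width is drawn at real scale
  segs$compressed <- segs$compressed & glen > compressed_width
  plot_length <- ifelse(segs$compressed, compressed_width, glen)
  segs$plot_start <- cumsum(c(0, plot_length[-length(plot_length)]))
  segs$plot_length <- plot_length
  structure(
    list(
      segments = segs[, c("genomic_start", "genomic_end", "plot_start",
                          "plot_length", "compressed")],
      span = span,
      compressed_width = compressed_width
    ),
    class = "coord_map"
  )
}

#' @export
print.coord_map <- function(x, ...) {
  cat("<coord_map> span ", x$span[1], "-", x$span[2], " (",
      x$span[2] - x$span[1], " bases) -> plot axis of ",
      plot_axis_length(x), "; ", sum(x$segments$compressed),
      " compressed gap(s) at width ", x$compressed_width, "\n", sep = "")
  invisible(x)
}

#' Total plot-axis length of a coordinate map
#' @param map A `coord_map`.
#' @return Numeric scalar.
#' @export
plot_axis_length <- function(map) {
  sum(map$segments$plot_length)
}

#' Tidy the segments of a coordinate map
#' @param x A `coord_map`.
#' @param ... Unused.
#' @return The `segments` tibble.
#' @exportS3Method generics::tidy
tidy.coord_map <- function(x, ...) x$segments

#' Transform genomic positions to plot positions
#'
#' Within a real-scale segment the transform is an exact shift (distances are
#' preserved); within a compressed segment positions are interpolated linearly
#' onto the compressed width. The transform is globally non-decreasing and
#' strictly increasing between positions in real segments.
#'
#' @param map A `coord_map`.
#' @param pos Numeric vector of genomic positions within the map's span
#'   (the span end itself is allowed and maps to the axis end).
#' @return Numeric vector of plot positions (real-valued; the span start maps
#'   to 0).
#' @export
to_plot <- function(map, pos) {
  if (any(pos < map$span[1] | pos > map$span[2])) {
    stop("position outside the mapped span [", map$span[1], ", ",
         map$span[2], "]", call. = FALSE)
  }
  s <- map$segments
  idx <- findInterval(pos, s$genomic_start)
  idx[idx < 1L] <- 1L
  glen <- s$genomic_end[idx] - s$genomic_start[idx]
  off <- (pos - s$genomic_start[idx]) / glen
  s$plot_start[idx] + off * s$plot_length[idx]
}

#' Transform a genomic interval to a plot interval
#'
#' @param map A `coord_map`.
#' @param start,end Genomic interval (0-based half-open), within the span.
#' @return Tibble with `plot_start`, `plot_end` (never empty when the input
#'   interval is non-empty).
#' @export
to_plot_interval <- function(map, start, end) {
  stopifnot(all(end > start))
  tibble::tibble(plot_start = to_plot(map, start), plot_end = to_plot(map, end))
}

#' Export a coordinate map as a tab-delimited table
#'
#' Debug/inspection export: one row per segment with `genomic_start`,
#' `genomic_end`, `plot_start`.
#'
#' @param map A `coord_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coordinate_map <- function(map, path) {
  utils::write.table(
    map$segments[, c("genomic_start", "genomic_end", "plot_start")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
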