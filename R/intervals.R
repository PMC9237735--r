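# Interval helpers. All intervals are 0-based half-open tibbles with
# integer-valued `start` < `end` columns.

#' Merge possibly overlapping or book-ended intervals
#'
#' Computes the union of a set of intervals: overlapping intervals and
#' book-ended intervals (gap of zero) are merged into maximal blocks.
#'
#' @param intervals A data frame with `start` and `end` columns
#'   (0-based half-open).
#' @return A tibble with `start`, `end`, sorted, strictly disjoint with
#'   gaps of at least one base between consecutive rows.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  if (any(intervals$end <= intervals$start)) {
    stop("interval with end <= start", call. = FALSE)
  }
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  red <- IRanges::reduce(ir, min.gapwidth = 1L)
  tibble::tibble(
    start = as.integer(IRanges::start(red) - 1L),
    end = as.integer(IRanges::end(red))
  )
}

#' Gaps between merged interval blocks
#'
#' @param blocks A tibble of disjoint sorted intervals (as produced by
#'   [merge_intervals()]).
#' @param span Optional numeric length-2 `c(start, end)`; when given,
#'   flanking gaps before the first and after the last block are included.
#' @return Tibble of `start`, `end` gap intervals (possibly empty).
#' @export
interval_gaps <- function(blocks, span = NULL) {
  starts <- integer()
  ends <- integer()
  if (nrow(blocks) > 1L) {
    starts <- blocks$end[-nrow(blocks)]
    ends <- blocks$start[-1L]
  }
  if (!is.null(span)) {
    stopifnot(length(span) == 2L, span[1] < span[2])
    if (nrow(blocks) == 0L) {
      starts <- span[1]
      ends <- span[2]
    } else {
      if (span[1] < blocks$start[1]) {
        starts <- c(span[1], starts)
        ends <- c(blocks$start[1], ends)
      }
      if (span[2] > blocks$end[nrow(blocks)]) {
        starts <- c(starts, blocks$end[nrow(blocks)])
        ends <- c(ends, span[2])
      }
    }
  }
  out <- tibble::tibble(start = as.integer(starts), end = as.integer(ends))
  dplyr::arrange(dplyr::filter(out, .data$end > .data$start), .data$start)
}

# Validate one read's exon block tibble: sorted, non-overlapping, separated
# by >= 1 base (book-ended blocks must be merged upstream).
check_exon_blocks <- function(exons, read_id = "?") {
  if (!is.data.frame(exons) || nrow(exons) == 0L) {
    stop("read ", read_id, ": needs at least one exon block", call. = FALSE)
  }
  if (any(exons$end <= exons$start)) {
    stop("read ", read_id, ": exon with end <= start", call. = FALSE)
  }
  if (nrow(exons) > 1L) {
    gap <- exons$start[-1L] - exons$end[-nrow(exons)]
    if (any(gap < 1L)) {
      stop("read ", read_id, ": exon blocks overlap or are book-ended", call. = FALSE)
    }
  }
  invisible(exons)
}

#' Validate a reads tibble
#'
#' Checks the structural invariants of the per-read table: at least one exon
#' block per read, blocks sorted and separated by at least one base, and
#' TSS/polyA positions (when present) inside the read's genomic footprint.
#'
#' @param reads A reads tibble (see package overview).
#' @return `reads`, invisibly; errors describe the offending read.
#' @export
validate_reads <- function(reads) {
  needed <- c("read_id", "cell_type", "chrom", "exons")
  missing <- setdiff(needed, names(reads))
  if (length(missing)) {
    stop("reads tibble lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reads$read_id)) {
    stop("duplicate read_id: ",
         reads$read_id[duplicated(reads$read_id)][1], call. = FALSE)
  }
  for (i in seq_len(nrow(reads))) {
    ex <- reads$exons[[i]]
    check_exon_blocks(ex, reads$read_id[i])
    lo <- ex$start[1]
    hi <- ex$end[nrow(ex)]
    for (key in c("tss", "polya")) {
      if (key %in% names(reads)) {
        v <- reads[[key]][i]
        if (!is.na(v) && (v < lo || v > hi)) {
          stop("read ", reads$read_id[i], ": ", key,
               " outside the read's footprint", call. = FALSE)
        }
      }
    }
  }
  invisible(reads)
}

# Genomic footprint (span) of each read: first exon start, last exon end.
read_spans <- function(reads) {
  tibble::tibble(
    read_id = reads$read_id,
    span_start = vapply(reads$exons, function(e) e$start[1], numeric(1)),
    span_end = vapply(reads$exons, function(e) e$end[nrow(e)], numeric(1))
  )
}
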