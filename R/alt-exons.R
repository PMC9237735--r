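# Alternative (cassette) exon calling by percent spliced in.
#
# Candidates are the exact (start, end) exon variants pooled from the
# annotation and from every read's exon blocks. For each candidate, the
# denominator is the number of reads whose genomic footprint overlaps the
# exon by at least one base — pooled over ALL cell types — and the numerator
# is the number of those reads having an exon block that fully contains the
# candidate (so a read retaining the surrounding intron still counts as
# including). Psi = included / overlapping; an exon is alternative when
# 100 * psi falls inside the closed user window (default [5, 95]; for
# noisier chemistries such as Oxford Nanopore a [20, 80] window is a better
# default).

#' Enumerate candidate exons
#'
#' Unique exact (start, end) exon intervals pooled from the annotation's
#' transcripts and from the reads' exon blocks, sorted. Novel (read-only)
#' exons are candidates too.
#'
#' @param reads A reads tibble.
#' @param annotation Optional `gene_annotation`.
#' @return Tibble `start`, `end`, deduplicated and sorted.
#' @export
enumerate_candidate_exons <- function(reads, annotation = NULL) {
  collect_exonic_intervals(reads, annotation) |>
    dplyr::distinct(.data$start, .data$end) |>
    dplyr::arrange(.data$start, .data$end)
}

#' Compute exon inclusion (psi) over all reads
#'
#' @param reads A reads tibble, pooled across all cell types.
#' @param exons Candidate exon tibble (`start`, `end`); defaults to
#'   [enumerate_candidate_exons()] on the reads alone.
#' @param annotation Optional `gene_annotation` used when enumerating
#'   candidates.
#' @param lower_pct,upper_pct Alternative-exon window on `100 * psi`,
#'   boundaries included (defaults 5 and 95).
#' @return Tibble of calls: `chrom`, `start`, `end`, `included`,
#'   `overlapping`, `psi`, `is_alternative`, plus the window used. `psi` is
#'   `NA` (and the exon never alternative) when no read overlaps.
#' @export
compute_inclusion <- function(reads, exons = NULL, annotation = NULL,
                              lower_pct = 5, upper_pct = 95) {
  if (is.null(exons)) exons <- enumerate_candidate_exons(reads, annotation)
  sp <- read_spans(reads)
  n <- nrow(exons)
  included <- integer(n)
  overlapping <- integer(n)
  for (i in seq_len(n)) {
    s <- exons$start[i]
    e <- exons$end[i]
    ov <- sp$span_start < e & sp$span_end > s
    overlapping[i] <- sum(ov)
    included[i] <- sum(vapply(reads$exons[ov], function(ex) {
      any(ex$start <= s & ex$end >= e)
    }, logical(1)))
  }
  calls <- tibble::tibble(
    chrom = if (nrow(reads)) reads$chrom[1] else NA_character_,
    start = exons$start,
    end = exons$end,
    included = included,
    overlapping = overlapping,
    psi = ifelse(overlapping > 0, included / overlapping, NA_real_)
  )
  flag_alternative(calls, lower_pct, upper_pct)
}

#' Flag alternative exons under a psi window
#'
#' Sets `is_alternative` for calls whose `100 * psi` lies in the closed
#' window `[lower_pct, upper_pct]` ("at least ... at most ..."); all other
#' fields are untouched. An exon with no overlapping reads is never flagged.
#'
#' @param calls Call tibble from [compute_inclusion()].
#' @param lower_pct,upper_pct Window bounds in percent, `0 <= lower <= upper
#'   <= 100`. The degenerate window `(0, 100)` flags every covered exon.
#' @return `calls` with `is_alternative`, `lower_pct`, `upper_pct` columns.
#' @export
flag_alternative <- function(calls, lower_pct = 5, upper_pct = 95) {
  if (lower_pct > upper_pct) {
    stop("lower_pct (", lower_pct, ") exceeds upper_pct (", upper_pct, ")",
         call. = FALSE)
  }
  if (lower_pct < 0 || upper_pct > 100) {
    stop("psi window must lie within [0, 100]", call. = FALSE)
  }
  calls$is_alternative <- !is.na(calls$psi) &
    100 * calls$psi >= lower_pct & 100 * calls$psi <= upper_pct
  calls$lower_pct <- lower_pct
  calls$upper_pct <- upper_pct
  calls
}

#' Export an alternative-exon call table
#'
#' Tab-delimited: `chrom`, `start`, `end`, `included`, `overlapping`, `psi`,
#' `is_alternative`.
#'
#' @param calls Call tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alt_exon_table <- function(calls, path) {
  cols <- c("chrom", "start", "end", "included", "overlapping", "psi",
            "is_alternative")
  utils::write.table(as.data.frame(calls[, cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
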