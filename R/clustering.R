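# Intron-chain derivation and per-cell-type read clustering.
#
# The intron chain — the ordered list of a read's introns, i.e. the gaps
# between its exon blocks — is the default clustering key. Chain equality is
# exact coordinate equality of every intron: two reads differing by one base
# at one splice site form distinct clusters. TSS and polyA values are used
# exactly as provided (they are binned upstream); when the clustering mode
# requires them, reads lacking the key are excluded and counted.

#' Derive a read's intron chain
#'
#' @param exons One read's exon-block tibble (`start`, `end`).
#' @return Tibble of introns (`start`, `end`); empty for a mono-exonic read.
#' @export
derive_intron_chain <- function(exons) {
  check_exon_blocks(exons)
  interval_gaps(exons)
}

# Canonical string key for a chain: "s1-e1;s2-e2;..."; "" for mono-exonic.
chain_key <- function(introns) {
  if (nrow(introns) == 0L) return("")
  paste(sprintf("%d-%d", introns$start, introns$end), collapse = ";")
}

# Sortable key: each coordinate zero-padded so lexicographic string order
# equals numeric elementwise order on the chain coordinates.
chain_sort_key <- function(key) {
  vapply(key, function(k) {
    if (k == "") return("")
    nums <- as.numeric(strsplit(k, "[-;]")[[1]])
    paste(sprintf("%012.0f", nums), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Add intron-chain columns to a reads tibble
#'
#' @param reads A reads tibble.
#' @return `reads` with `chain` (canonical string key) and `n_introns`.
#' @export
add_intron_chain <- function(reads) {
  reads |>
    dplyr::mutate(
      chain = vapply(.data$exons,
                     function(e) chain_key(derive_intron_chain(e)),
                     character(1)),
      n_introns = vapply(.data$exons, function(e) nrow(e) - 1L, integer(1))
    )
}

cluster_modes <- c("chain", "tss+chain", "chain+polya", "tss+chain+polya")

#' Cluster reads by intron chain (and optionally TSS / polyA) per cell type
#'
#' Within each cell type, reads are partitioned by the clustering key. Under
#' `mode = "chain"` every read is retained. When the mode includes the TSS
#' (respectively polyA), reads lacking that key are excluded from the plot and
#' their per-cell-type counts reported in the `excluded` attribute; a cell
#' type whose reads are all excluded is omitted with a warning.
#'
#' @param reads A reads tibble (one gene).
#' @param mode One of `"chain"`, `"tss+chain"`, `"chain+polya"`,
#'   `"tss+chain+polya"`.
#' @return Tibble of clusters: `cell_type`, `chain`, `n_introns`, `tss`,
#'   `polya`, `size`, `read_ids` (list-column). Attribute `excluded`:
#'   tibble of `cell_type`, `n_excluded`.
#' @export
cluster_reads <- function(reads, mode = c("chain", "tss+chain", "chain+polya",
                                          "tss+chain+polya")) {
  mode <- match.arg(mode)
  if (length(unique(reads$gene_id)) > 1L) {
    stop("reads from more than one gene: ",
         paste(unique(reads$gene_id), collapse = ", "), call. = FALSE)
  }
  use_tss <- grepl("tss", mode, fixed = TRUE)
  use_polya <- grepl("polya", mode, fixed = TRUE)
  rr <- add_intron_chain(reads)
  retained <- rr
  if (use_tss) retained <- dplyr::filter(retained, !is.na(.data$tss))
  if (use_polya) retained <- dplyr::filter(retained, !is.na(.data$polya))
  excluded <- rr |>
    dplyr::anti_join(retained, by = "read_id") |>
    dplyr::count(.data$cell_type, name = "n_excluded")
  lost_ct <- setdiff(unique(rr$cell_type), unique(retained$cell_type))
  if (length(lost_ct)) {
    warning("cell type(s) with no retained reads omitted: ",
            paste(lost_ct, collapse = ", "))
  }
  clusters <- retained |>
    dplyr::mutate(
      tss_key = if (use_tss) .data$tss else NA_real_,
      polya_key = if (use_polya) .data$polya else NA_real_
    ) |>
    dplyr::group_by(.data$cell_type, .data$chain, .data$n_introns,
                    .data$tss_key, .data$polya_key) |>
    dplyr::summarise(
      size = dplyr::n(),
      read_ids = list(.data$read_id),
      .groups = "drop"
    ) |>
    dplyr::rename(tss = "tss_key", polya = "polya_key")
  attr(clusters, "excluded") <- excluded
  attr(clusters, "mode") <- mode
  clusters
}

#' Order clusters for display
#'
#' Deterministic total order within each cell type. `by = "size"` (default):
#' descending size, then more introns first, then elementwise comparison of
#' chain coordinates, then TSS and polyA. `by = "position"`: elementwise
#' chain-coordinate order first, then descending size.
#'
#' @param clusters Output of [cluster_reads()].
#' @param by `"size"` or `"position"`.
#' @return `clusters`, reordered; a `rank` column is added within cell type.
#' @export
order_clusters <- function(clusters, by = c("size", "position")) {
  by <- match.arg(by)
  cc <- dplyr::mutate(clusters, .ckey = chain_sort_key(.data$chain))
  cc <- if (by == "size") {
    dplyr::arrange(cc, .data$cell_type, dplyr::desc(.data$size),
                   dplyr::desc(.data$n_introns), .data$.ckey,
                   .data$tss, .data$polya)
  } else {
    dplyr::arrange(cc, .data$cell_type, .data$.ckey,
                   dplyr::desc(.data$size), .data$tss, .data$polya)
  }
  out <- cc |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-".ckey")
  attr(out, "excluded") <- attr(clusters, "excluded")
  attr(out, "mode") <- attr(clusters, "mode")
  out
}

#' Canonical read order within a cluster
#'
#' Reads are ordered by alignment start, then alignment end, then read id —
#' a deterministic order independent of input order.
#'
#' @param reads A reads tibble (typically one cluster's reads).
#' @return `reads`, reordered.
#' @export
order_reads_within_cluster <- function(reads) {
  sp <- read_spans(reads)
  o <- order(sp$span_start, sp$span_end, reads$read_id)
  reads[o, ]
}

#' Export a cluster table
#'
#' Tab-delimited: `cell_type`, `rank`, `size`, `chain`, `tss`, `polya`.
#'
#' @param clusters Ordered clusters (see [order_clusters()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  cols <- intersect(c("cell_type", "rank", "size", "chain", "tss", "polya"),
                    names(clusters))
  utils::write.table(as.data.frame(clusters[, cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
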