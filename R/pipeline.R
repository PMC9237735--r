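# End-to-end pipeline: parse -> assemble -> (optional mismatch finding) ->
# compress -> cluster -> call alternative exons -> layout -> render ->
# browser-track export, with a machine-readable run report.

#' Run the full read-stack pipeline for one gene
#'
#' Executes the whole visualization pipeline and writes every output next to
#' `out_prefix`: the figure(s), the BED12 browser track, the cluster,
#' alternative-exon and (when alignments are given) mismatch tables, and a
#' JSON run report.
#'
#' @param gene_id Gene to plot.
#' @param allinfo Path to an AllInfo file (combined per-read records), or
#'   `NULL` when using `gff` + `assignment`.
#' @param gff,assignment Paths to a per-read exon GFF and a read-to-gene/
#'   cell-type assignment table (the two-file input mode).
#' @param annotation Optional annotation GTF/GFF path (or a
#'   `gene_annotation`).
#' @param alignments,reference Optional SAM/BAM and reference FASTA for
#'   mismatch finding; alternatively `mismatch_table` reuses a table written
#'   by [write_mismatch_table()].
#' @param mismatch_table Optional cached mismatch table path.
#' @param mode Clustering mode (see [cluster_reads()]).
#' @param order_by Cluster display order (see [order_clusters()]).
#' @param ci_lower,ci_upper Alternative-exon psi window in percent
#'   (defaults 5, 95; 20/80 suits noisier chemistries).
#' @param mismatch_lower,mismatch_upper Mismatch frequency window in percent
#'   (defaults 5, 95).
#' @param end_margin Alignment-end exclusion margin in bases (default 20).
#' @param compressed_width Plot width given to exon-free gaps (default 100).
#' @param cell_type_order Optional top-to-bottom cell-type order.
#' @param formats Figure formats among `"svg"`, `"pdf"`, `"png"`,
#'   `"html"`.
#' @param out_prefix Output path prefix (directory part is created).
#' @return A `stack_report` list (also written as JSON): read counts in /
#'   retained / excluded per cell type, cluster count, flagged exons, passing
#'   mismatch sites and output paths. The layout is attached as the
#'   `layout` attribute.
#' @export
run_pipeline <- function(gene_id,
                         allinfo = NULL, gff = NULL, assignment = NULL,
                         annotation = NULL,
                         alignments = NULL, reference = NULL,
                         mismatch_table = NULL,
                         mode = "chain", order_by = "size",
                         ci_lower = 5, ci_upper = 95,
                         mismatch_lower = 5, mismatch_upper = 95,
                         end_margin = 20, compressed_width = 100,
                         cell_type_order = NULL,
                         formats = c("svg", "html"),
                         out_prefix = "stack") {
  t0 <- Sys.time()
  # --- inputs
  reads <- if (!is.null(allinfo)) {
    read_allinfo(allinfo, gene_filter = gene_id)
  } else if (!is.null(gff) && !is.null(assignment)) {
    assemble_reads(read_read_gff(gff, gene_filter = gene_id),
                   read_assignment_table(assignment),
                   gene_filter = gene_id)
  } else {
    stop("provide either `allinfo` or both `gff` and `assignment`",
         call. = FALSE)
  }
  if (nrow(reads) == 0L) {
    stop("no reads found for gene ", gene_id,
         " (check the gene identifier and input files)", call. = FALSE)
  }
  ann <- NULL
  if (!is.null(annotation)) {
    ann <- if (inherits(annotation, "gene_annotation")) annotation else
      read_gene_annotation(annotation, gene_id)
  }

  # --- mismatches (optional)
  sites <- NULL
  obs <- NULL
  aln_region <- list(chrom = reads$chrom[1],
                     start = min(vapply(reads$exons, function(e) e$start[1],
                                        numeric(1))),
                     end = max(vapply(reads$exons, function(e) e$end[nrow(e)],
                                      numeric(1))))
  if (!is.null(mismatch_table)) {
    sites <- read_mismatch_table(mismatch_table)
  } else if (!is.null(alignments) && !is.null(reference)) {
    sites <- find_mismatches(alignments, reference, region = aln_region,
                             margin = end_margin,
                             lower_pct = mismatch_lower,
                             upper_pct = mismatch_upper)
    obs <- attr(sites, "observations")
  }

  # --- core computation
  map <- build_coordinate_map(collect_exonic_intervals(reads, ann),
                              compressed_width = compressed_width)
  clusters <- cluster_reads(reads, mode = mode) |>
    order_clusters(by = order_by)
  calls <- compute_inclusion(reads, annotation = ann,
                             lower_pct = ci_lower, upper_pct = ci_upper)
  layout <- compute_layout(clusters, reads, map, alt_calls = calls,
                           sites = sites, observations = obs,
                           annotation = ann,
                           cell_type_order = cell_type_order)

  # --- outputs
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  for (fmt in formats) {
    p <- paste0(out_prefix, ".", fmt)
    if (fmt == "html") render_interactive(layout, p, title = gene_id)
    else render_static(layout, p, format = fmt)
    outputs[[fmt]] <- p
  }
  outputs$track <- paste0(out_prefix, ".bed")
  write_ucsc_track(reads, outputs$track,
                   track_name = paste(gene_id, "long reads"))
  outputs$clusters <- paste0(out_prefix, ".clusters.tsv")
  write_cluster_table(clusters, outputs$clusters)
  outputs$alt_exons <- paste0(out_prefix, ".alt_exons.tsv")
  write_alt_exon_table(calls, outputs$alt_exons)
  if (!is.null(sites)) {
    outputs$mismatches <- paste0(out_prefix, ".mismatches.tsv")
    write_mismatch_table(sites, outputs$mismatches)
  }

  excluded <- attr(clusters, "excluded")
  if (is.null(excluded)) {
    excluded <- tibble::tibble(cell_type = character(),
                               n_excluded = integer())
  }
  report <- structure(list(
    gene_id = gene_id,
    mode = mode,
    n_reads_in = nrow(reads),
    n_reads_retained = sum(clusters$size),
    n_reads_excluded = sum(excluded$n_excluded),
    excluded_by_cell_type = excluded,
    n_clusters = nrow(clusters),
    n_cell_types = length(unique(clusters$cell_type)),
    n_candidate_exons = nrow(calls),
    n_alternative_exons = sum(calls$is_alternative),
    n_mismatch_sites = if (is.null(sites)) NA_integer_ else nrow(sites),
    n_passing_sites = if (is.null(sites)) NA_integer_ else sum(sites$passes),
    axis_length = plot_axis_length(map),
    compressed_width = compressed_width,
    psi_window = c(ci_lower, ci_upper),
    mismatch_window = c(mismatch_lower, mismatch_upper),
    end_margin = end_margin,
    outputs = outputs,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "stack_report")
  jsonlite::write_json(unclass(report), paste0(out_prefix, ".report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  attr(report, "layout") <- layout
  report
}

#' @export
print.stack_report <- function(x, ...) {
  cat("<stack_report> gene ", x$gene_id, " (mode ", x$mode, ")\n",
      "  reads: ", x$n_reads_in, " in, ", x$n_reads_retained, " retained, ",
      x$n_reads_excluded, " excluded\n",
      "  clusters: ", x$n_clusters, " across ", x$n_cell_types,
      " cell type(s)\n",
      "  exons: ", x$n_alternative_exons, " alternative of ",
      x$n_candidate_exons, " candidates\n", sep = "")
  if (!is.na(x$n_mismatch_sites)) {
    cat("  mismatch sites: ", x$n_passing_sites, " passing of ",
        x$n_mismatch_sites, "\n", sep = "")
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `stack_report`.
#' @param ... Unused.
#' @return One-row tibble of the run's headline counts.
#' @exportS3Method generics::glance
glance.stack_report <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, mode = x$mode,
    n_reads_in = x$n_reads_in, n_reads_retained = x$n_reads_retained,
    n_reads_excluded = x$n_reads_excluded, n_clusters = x$n_clusters,
    n_cell_types = x$n_cell_types,
    n_alternative_exons = x$n_alternative_exons,
    n_passing_sites = x$n_passing_sites,
    axis_length = x$axis_length
  )
}

#' Run mismatch finding alone and write the table
#'
#' @param alignments SAM/BAM path.
#' @param reference FASTA path.
#' @param out Output table path (reusable by [run_pipeline()] via
#'   `mismatch_table`).
#' @param region Optional region list (`chrom`, `start`, `end`).
#' @param end_margin,lower_pct,upper_pct Filter parameters (defaults 20, 5,
#'   95).
#' @return The site tibble, invisibly.
#' @export
run_mismatch <- function(alignments, reference, out, region = NULL,
                         end_margin = 20, lower_pct = 5, upper_pct = 95) {
  sites <- find_mismatches(alignments, reference, region = region,
                           margin = end_margin, lower_pct = lower_pct,
                           upper_pct = upper_pct)
  write_mismatch_table(sites, out)
  invisible(sites)
}
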