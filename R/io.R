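# Readers and writers for the external formats the pipeline touches.
#
# Conventions: GFF/GTF files are 1-based inclusive, BED is 0-based half-open,
# AllInfo files are 1-based inclusive. Everything is converted to the internal
# 0-based half-open convention at this boundary and nowhere else.

# Open a path as a (possibly gzipped) text connection for line validation.
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Structural pre-check of GFF/GTF lines: 9 tab-separated fields, numeric
# coordinates with end >= start. Errors name the 1-based line number.
check_gff_lines <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("malformed GFF line ", i, ": expected 9 tab-separated fields, got ",
           length(f), call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || e < s) {
      stop("malformed GFF line ", i, ": bad coordinates '", f[4], "'..'",
           f[5], "'", call. = FALSE)
    }
  }
  invisible(path)
}

#' Parse a per-read exon GFF/GTF
#'
#' Reads a GFF/GTF whose `exon` features are grouped by read via the
#' `transcript_id` attribute (the read identifier), as produced by upstream
#' single-cell long-read pipelines. Coordinates are converted from 1-based
#' inclusive to 0-based half-open, exon blocks of each read are sorted, and
#' book-ended blocks (zero gap) are merged: a zero-length gap is a
#' representation artifact, not a splice.
#'
#' @param path GFF/GTF file (optionally gzip-compressed).
#' @param gene_filter Optional gene identifier; only reads whose `gene_id`
#'   attribute matches are returned. An empty result is not an error.
#' @return Tibble with one row per read: `read_id`, `gene_id`, `chrom`,
#'   `strand` and the `exons` list-column.
#' @export
read_read_gff <- function(path, gene_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  check_gff_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0L) {
    return(empty_read_records())
  }
  tb <- tibble::tibble(
    read_id = as.character(gr$transcript_id),
    gene_id = if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$gene_id)
    } else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gene_filter)) {
    tb <- dplyr::filter(tb, .data$gene_id == gene_filter)
    if (nrow(tb) == 0L) return(empty_read_records())
  }
  tb |>
    dplyr::arrange(.data$read_id, .data$start) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      exons = list(merge_intervals(
        tibble::tibble(start = start, end = end)
      )),
      .groups = "drop"
    )
}

empty_read_records <- function() {
  tibble::tibble(
    read_id = character(), gene_id = character(), chrom = character(),
    strand = character(), exons = list()
  )
}

#' Parse a read-to-gene/cell-type assignment table
#'
#' Tab-delimited, one row per read, with a header line naming at least
#' `read_id`, `gene_id` and `cell_type`; a `barcode` column is optional.
#' A read assigned twice is a format error.
#'
#' @param path Assignment table (optionally gzip-compressed).
#' @return Tibble `read_id`, `gene_id`, `cell_type`, `barcode`.
#' @export
read_assignment_table <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  tb <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("read_id", "gene_id", "cell_type")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    stop("assignment table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- tb$read_id[duplicated(tb$read_id)]
  if (length(dup)) {
    stop("read assigned more than once: ", dup[1], call. = FALSE)
  }
  if (!"barcode" %in% names(tb)) tb$barcode <- NA_character_
  tibble::as_tibble(tb[, c("read_id", "gene_id", "cell_type", "barcode")])
}

#' Join per-read exon records with their assignments
#'
#' Reads present in the exon records but absent from the assignment table are
#' dropped (they were not assigned to a gene); the count is reported as a
#' message and in the `n_unassigned` attribute.
#'
#' @param exon_records Output of [read_read_gff()].
#' @param assignments Output of [read_assignment_table()].
#' @param gene_filter Optional gene identifier to restrict to.
#' @return A reads tibble.
#' @export
assemble_reads <- function(exon_records, assignments, gene_filter = NULL) {
  asn <- assignments
  if (!is.null(gene_filter)) asn <- dplyr::filter(asn, .data$gene_id == gene_filter)
  joined <- exon_records |>
    dplyr::select(-dplyr::any_of("gene_id")) |>
    dplyr::inner_join(asn, by = "read_id")
  n_unassigned <- nrow(exon_records) - nrow(joined)
  if (n_unassigned > 0) {
    message(n_unassigned, " read(s) without assignment dropped")
  }
  out <- joined |>
    dplyr::mutate(tss = NA_real_, polya = NA_real_) |>
    dplyr::select("read_id", "gene_id", "cell_type", "barcode", "chrom",
                  "strand", "tss", "polya", "exons")
  attr(out, "n_unassigned") <- n_unassigned
  validate_reads(out)
  out
}

# AllInfo column schema (a documented choice of this package; upstream tools
# use a similar combined per-read record but the exact layout varies):
# 10 tab-separated columns, no header, 1-based inclusive coordinates,
# "." for a missing TSS/polyA:
#   read_id  gene_id  cell_type  barcode  chrom  strand  tss  polya
#   intron_chain ("s-e;s-e" or ".")  exons ("s-e,s-e")
allinfo_columns <- c("read_id", "gene_id", "cell_type", "barcode", "chrom",
                     "strand", "tss", "polya", "intron_chain", "exons")

parse_coord_pairs <- function(s, sep) {
  if (s == "." || s == "") {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  parts <- strsplit(s, sep, fixed = TRUE)[[1]]
  m <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
  tibble::tibble(
    start = as.integer(m[, 1]) - 1L,  # 1-based inclusive -> 0-based half-open
    end = as.integer(m[, 2])
  )
}

#' Parse a combined per-read ("AllInfo") record file
#'
#' Each line carries a read's gene, cell type, TSS, polyA site, intron chain
#' and exon blocks (see the package vignette for the column schema). The
#' stated intron chain must agree with the gaps between the exon blocks;
#' records that fail this self-consistency check are an error in strict mode,
#' or skipped with a reported count in lenient mode.
#'
#' @param path AllInfo file (optionally gzip-compressed).
#' @param gene_filter Gene identifier to extract.
#' @param strict If `TRUE` (default) inconsistent records abort with all
#'   offending read ids; if `FALSE` they are skipped (`n_skipped` attribute).
#' @return A reads tibble with `tss`/`polya` set (`NA` for the "."
#'   sentinel).
#' @export
read_allinfo <- function(path, gene_filter = NULL, strict = TRUE) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad_shape <- which(lengths(fields) != length(allinfo_columns))
  if (length(bad_shape)) {
    stop("AllInfo line ", bad_shape[1], ": expected ",
         length(allinfo_columns), " fields, got ",
         length(fields[[bad_shape[1]]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  tb <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(tb) <- allinfo_columns
  if (!is.null(gene_filter)) tb <- dplyr::filter(tb, .data$gene_id == gene_filter)
  if (nrow(tb) == 0L) {
    out <- empty_read_records()
    out$cell_type <- character()
    out$barcode <- character()
    out$tss <- numeric()
    out$polya <- numeric()
    return(out)
  }
  exons <- lapply(tb$exons, parse_coord_pairs, sep = ",")
  chains <- lapply(tb$intron_chain, parse_coord_pairs, sep = ";")
  # Self-consistency: the stated chain must equal the gaps between exons.
  bad <- vapply(seq_len(nrow(tb)), function(i) {
    expect <- interval_gaps(exons[[i]])
    !isTRUE(all.equal(as.data.frame(expect), as.data.frame(chains[[i]])))
  }, logical(1))
  if (any(bad)) {
    ids <- tb$read_id[bad]
    if (strict) {
      stop("AllInfo intron chain disagrees with exon gaps for read(s): ",
           paste(ids, collapse = ", "), call. = FALSE)
    }
    message(length(ids), " inconsistent AllInfo record(s) skipped")
  }
  keep <- !bad
  sentinel_na <- function(x) ifelse(x == ".", NA_real_, suppressWarnings(as.numeric(x)) - 1)
  out <- tibble::tibble(
    read_id = tb$read_id[keep],
    gene_id = tb$gene_id[keep],
    cell_type = tb$cell_type[keep],
    barcode = ifelse(tb$barcode[keep] == ".", NA_character_, tb$barcode[keep]),
    chrom = tb$chrom[keep],
    strand = tb$strand[keep],
    tss = sentinel_na(tb$tss[keep]),
    polya = sentinel_na(tb$polya[keep]),
    exons = exons[keep]
  )
  attr(out, "n_skipped") <- sum(bad)
  validate_reads(out)
  out
}

#' Parse a gene annotation from GTF/GFF
#'
#' Extracts one gene's transcript models from a GENCODE-style annotation.
#' The gene may be named by `gene_id` or `gene_name`. Exons are sorted
#' within each transcript and converted to 0-based half-open coordinates.
#'
#' @param path GTF or GFF3 annotation file.
#' @param gene_id Gene identifier or symbol.
#' @return A `gene_annotation` object: a list with `gene_id`, `gene_name`,
#'   `chrom`, `strand`, `start`, `end` and a `transcripts` tibble
#'   (`transcript_id`, `exons` list-column). Use [tidy()][tidy.gene_annotation]
#'   for a long exon table.
#' @export
read_gene_annotation <- function(path, gene_id) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3" else "gtf"
  gr <- rtracklayer::import(path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  hit <- rep(FALSE, length(gr))
  for (col in c("gene_id", "gene_name")) {
    if (col %in% names(mc)) hit <- hit | (!is.na(mc[[col]]) & mc[[col]] == gene_id)
  }
  gr <- gr[hit & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) {
    stop("gene not found in annotation: ", gene_id, call. = FALSE)
  }
  tb <- tibble::tibble(
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  transcripts <- tb |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      exons = list(tibble::tibble(start = start, end = end)),
      .groups = "drop"
    )
  gene_name <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_name[1])
  } else gene_id
  structure(
    list(
      gene_id = gene_id,
      gene_name = if (is.na(gene_name)) gene_id else gene_name,
      chrom = tb$chrom[1],
      strand = tb$strand[1],
      start = min(tb$start),
      end = max(tb$end),
      transcripts = transcripts
    ),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation> ", x$gene_id, " (", x$chrom, ":", x$start, "-",
      x$end, " ", x$strand, "), ", nrow(x$transcripts), " transcript(s)\n",
      sep = "")
  invisible(x)
}

#' Tidy a gene annotation into a long exon table
#'
#' @param x A `gene_annotation`.
#' @param ... Unused.
#' @return Tibble `transcript_id`, `chrom`, `strand`, `start`, `end`.
#' @exportS3Method generics::tidy
tidy.gene_annotation <- function(x, ...) {
  x$transcripts |>
    tidyr::unnest("exons") |>
    dplyr::mutate(chrom = x$chrom, strand = x$strand, .after = "transcript_id")
}

#' Write reads as a UCSC Genome Browser BED12 track
#'
#' One BED12 line per read: the line spans the read's genomic footprint and
#' the block fields encode its exon structure exactly (0-based half-open).
#' A `track name=...` header line is written first so the file can be
#' uploaded to the browser as-is.
#'
#' @param reads A reads tibble (non-empty, single chromosome).
#' @param path Output file.
#' @param track_name Track name for the header line.
#' @return `path`, invisibly.
#' @export
write_ucsc_track <- function(reads, path, track_name = "single-cell long reads") {
  if (nrow(reads) == 0L) stop("no reads to export", call. = FALSE)
  if (length(unique(reads$chrom)) != 1L) {
    stop("reads span multiple chromosomes: ",
         paste(unique(reads$chrom), collapse = ", "), call. = FALSE)
  }
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    ex <- reads$exons[[i]]
    chrom_start <- ex$start[1]
    chrom_end <- ex$end[nrow(ex)]
    strand <- reads$strand[i]
    if (!strand %in% c("+", "-")) strand <- "."
    paste(
      reads$chrom[i], chrom_start, chrom_end, reads$read_id[i], 0L, strand,
      chrom_start, chrom_end, "0",
      nrow(ex),
      paste0(paste(ex$end - ex$start, collapse = ","), ","),
      paste0(paste(ex$start - chrom_start, collapse = ","), ","),
      sep = "\t"
    )
  }, character(1))
  header <- sprintf('track name="%s" itemRgb="Off"', track_name)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED12 track back into a reads tibble
#'
#' Round-trip companion of [write_ucsc_track()]; cell-type and gene columns
#' are not represented in BED and come back as `NA`.
#'
#' @param path BED12 file (a `track` header line is allowed).
#' @return Tibble `read_id`, `chrom`, `strand`, `exons`.
#' @export
read_ucsc_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  exons <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]  # block ranges relative to chromStart, 1-based
    tibble::tibble(
      start = GenomicRanges::start(gr)[i] - 1L + IRanges::start(b) - 1L,
      end = GenomicRanges::start(gr)[i] - 1L + IRanges::end(b)
    )
  })
  tibble::tibble(
    read_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exons = exons
  )
}
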