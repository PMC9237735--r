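# Reference-mismatch finding from long-read alignments.
#
# Every aligned read is walked along its CIGAR against the reference: aligned
# bases disagreeing with the reference yield SNV observations, insertion and
# deletion gap operations yield one observation per event per read (keyed by
# position and allele string, not per base). Observations within a margin of
# either alignment end (default 20 reference bases) are discarded as likely
# alignment artifacts. Observations are then aggregated to sites, the
# denominator being the number of alignments whose reference span covers the
# site, and frequency-filtered by a closed window (default [5, 95] percent)
# so that both rare sequencing errors and near-fixed genome differences are
# suppressed; the (0, 100) window surfaces every disagreement.

#' Read alignments from SAM/BAM into a tibble
#'
#' SAM input is converted (and indexed) on the fly. Alignments without a
#' CIGAR (unmapped) are skipped with a reported count.
#'
#' @param path SAM or BAM file.
#' @param region Optional list with `chrom`, `start`, `end` (0-based
#'   half-open) restricting the alignments fetched.
#' @return Tibble: `read_id`, `chrom`, `ref_start` (0-based), `ref_end`
#'   (exclusive), `cigar`, `seq`.
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  param_args <- list(what = c("qname", "rname", "pos", "cigar", "seq"))
  if (!is.null(region)) {
    param_args$which <- GenomicRanges::GRanges(
      region$chrom, IRanges::IRanges(region$start + 1L, region$end)
    )
  }
  res <- Rsamtools::scanBam(bam, param = do.call(Rsamtools::ScanBamParam,
                                                 param_args))
  res <- res[[1]]
  tb <- tibble::tibble(
    read_id = res$qname,
    chrom = as.character(res$rname),
    ref_start = res$pos - 1L,
    cigar = res$cigar,
    seq = as.character(res$seq)
  )
  n_nocigar <- sum(is.na(tb$cigar) | is.na(tb$ref_start))
  if (n_nocigar > 0) {
    message(n_nocigar, " alignment(s) without CIGAR/position skipped")
    tb <- dplyr::filter(tb, !is.na(.data$cigar) & !is.na(.data$ref_start))
  }
  tb$ref_end <- tb$ref_start +
    GenomicAlignments::cigarWidthAlongReferenceSpace(tb$cigar)
  dplyr::select(tb, "read_id", "chrom", "ref_start", "ref_end", "cigar", "seq")
}

# Load a reference as a named character vector of chromosome sequences.
load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(reference)) return(reference)
  stop("reference must be a FASTA path, DNAStringSet or named character",
       call. = FALSE)
}

#' Collect per-read mismatch observations
#'
#' Walks each alignment's CIGAR against the reference. `dist_from_start` and
#' `dist_from_end` are 1-based offsets along the reference within the read's
#' own alignment; an insertion is anchored on the base to its left and its
#' `ref_pos` is the reference position of the base following the insertion
#' point.
#'
#' @param alignments Tibble from [read_alignments()].
#' @param reference FASTA path, `DNAStringSet`, or named character vector of
#'   chromosome sequences.
#' @param region Optional list with `chrom`, `start`, `end` (0-based
#'   half-open); observations outside it are dropped.
#' @return Tibble of observations: `read_id`, `ref_pos` (0-based), `kind`
#'   (`"SNV"`, `"insertion"`, `"deletion"`), `ref`, `alt`,
#'   `dist_from_start`, `dist_from_end`.
#' @export
collect_mismatches <- function(alignments, reference, region = NULL) {
  refs <- load_reference(reference)
  miss <- setdiff(unique(alignments$chrom), names(refs))
  if (length(miss)) {
    stop("reference lacks sequence(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(region)) {
    if (nchar(refs[[region$chrom]]) < region$end) {
      stop("reference sequence shorter than the requested region",
           call. = FALSE)
    }
  }
  ops_all <- GenomicAlignments::explodeCigarOps(alignments$cigar)
  lens_all <- GenomicAlignments::explodeCigarOpLengths(alignments$cigar)
  out <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    out[[i]] <- walk_one_alignment(
      read_id = alignments$read_id[i],
      ref_seq = refs[[alignments$chrom[i]]],
      ref_start = alignments$ref_start[i],
      ref_end = alignments$ref_end[i],
      seq = alignments$seq[i],
      ops = ops_all[[i]],
      lens = lens_all[[i]]
    )
  }
  obs <- dplyr::bind_rows(out)
  if (nrow(obs) == 0L) return(empty_observations())
  if (!is.null(region)) {
    obs <- dplyr::filter(obs, .data$ref_pos >= region$start,
                         .data$ref_pos < region$end)
  }
  obs
}

empty_observations <- function() {
  tibble::tibble(
    read_id = character(), ref_pos = integer(), kind = character(),
    ref = character(), alt = character(),
    dist_from_start = integer(), dist_from_end = integer()
  )
}

walk_one_alignment <- function(read_id, ref_seq, ref_start, ref_end,
                               seq, ops, lens) {
  rpos <- ref_start   # 0-based reference cursor
  qpos <- 1L          # 1-based cursor into the read sequence
  rows <- list()
  for (j in seq_along(ops)) {
    op <- ops[j]
    len <- lens[j]
    if (op %in% c("M", "=", "X")) {
      ref_piece <- substr(ref_seq, rpos + 1L, rpos + len)
      read_piece <- substr(seq, qpos, qpos + len - 1L)
      if (ref_piece != read_piece) {
        rb <- strsplit(ref_piece, "", fixed = TRUE)[[1]]
        qb <- strsplit(read_piece, "", fixed = TRUE)[[1]]
        hit <- which(rb != qb)
        if (length(hit)) {
          p <- rpos + hit - 1L
          rows[[length(rows) + 1L]] <- tibble::tibble(
            read_id = read_id, ref_pos = as.integer(p), kind = "SNV",
            ref = rb[hit], alt = qb[hit],
            dist_from_start = as.integer(p - ref_start + 1L),
            dist_from_end = as.integer(ref_end - p)
          )
        }
      }
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op == "I") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        read_id = read_id, ref_pos = as.integer(rpos), kind = "insertion",
        ref = "", alt = substr(seq, qpos, qpos + len - 1L),
        dist_from_start = as.integer(rpos - ref_start),    # left anchor base
        dist_from_end = as.integer(ref_end - rpos)
      )
      qpos <- qpos + len
    } else if (op == "D") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        read_id = read_id, ref_pos = as.integer(rpos), kind = "deletion",
        ref = substr(ref_seq, rpos + 1L, rpos + len), alt = "",
        dist_from_start = as.integer(rpos - ref_start + 1L),
        dist_from_end = as.integer(ref_end - (rpos + len) + 1L)
      )
      rpos <- rpos + len
    } else if (op == "N") {
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
    # H and P consume neither cursor
  }
  dplyr::bind_rows(rows)
}

#' Exclude observations near alignment ends
#'
#' Removes observations whose distance from either alignment end is at most
#' `margin` reference bases (default 20); alignment artifacts concentrate at
#' read ends. `margin = 0` is the identity; the operation is idempotent.
#'
#' @param obs Observation tibble from [collect_mismatches()].
#' @param margin Non-negative integer.
#' @return Filtered observation tibble.
#' @export
apply_end_exclusion <- function(obs, margin = 20) {
  stopifnot(margin >= 0)
  dplyr::filter(obs, .data$dist_from_start > margin,
                .data$dist_from_end > margin)
}

#' Aggregate observations into frequency-filtered mismatch sites
#'
#' Observations are grouped by (position, kind, alleles); `support` counts
#' distinct reads, and `overlapping` counts alignments whose reference span
#' covers the site — the full deleted interval for a deletion, both flanking
#' bases for an insertion. A site passes when its frequency lies in the
#' closed window `[lower_pct, upper_pct]` percent.
#'
#' @param obs End-filtered observation tibble.
#' @param alignments Alignment tibble (for per-site coverage).
#' @param lower_pct,upper_pct Frequency window in percent (defaults 5, 95).
#' @return Site tibble: `chrom`, `ref_pos`, `kind`, `ref`, `alt`, `support`,
#'   `overlapping`, `freq_pct`, `passes`.
#' @export
aggregate_sites <- function(obs, alignments, lower_pct = 5, upper_pct = 95) {
  if (lower_pct > upper_pct) {
    stop("lower_pct (", lower_pct, ") exceeds upper_pct (", upper_pct, ")",
         call. = FALSE)
  }
  if (lower_pct < 0 || upper_pct > 100) {
    stop("frequency window must lie within [0, 100]", call. = FALSE)
  }
  if (nrow(obs) == 0L) {
    return(tibble::tibble(
      chrom = character(), ref_pos = integer(), kind = character(),
      ref = character(), alt = character(), support = integer(),
      overlapping = integer(), freq_pct = numeric(), passes = logical()
    ))
  }
  sites <- obs |>
    dplyr::group_by(.data$ref_pos, .data$kind, .data$ref, .data$alt) |>
    dplyr::summarise(support = dplyr::n_distinct(.data$read_id),
                     .groups = "drop")
  cover_start <- ifelse(sites$kind == "insertion",
                        sites$ref_pos - 1L, sites$ref_pos)
  cover_end <- dplyr::case_when(
    sites$kind == "deletion" ~ sites$ref_pos + nchar(sites$ref),
    sites$kind == "insertion" ~ sites$ref_pos + 1L,
    TRUE ~ sites$ref_pos + 1L
  )
  sites$overlapping <- vapply(seq_len(nrow(sites)), function(i) {
    sum(alignments$ref_start <= cover_start[i] &
          alignments$ref_end >= cover_end[i])
  }, integer(1))
  sites |>
    dplyr::mutate(
      chrom = alignments$chrom[1],
      freq_pct = 100 * .data$support / .data$overlapping,
      passes = .data$freq_pct >= lower_pct & .data$freq_pct <= upper_pct
    ) |>
    dplyr::arrange(.data$ref_pos, .data$kind) |>
    dplyr::select("chrom", "ref_pos", "kind", "ref", "alt", "support",
                  "overlapping", "freq_pct", "passes")
}

#' Find reference mismatches for a gene region
#'
#' One-call orchestrator: read alignments, collect observations, apply the
#' alignment-end exclusion, aggregate and frequency-filter.
#'
#' @param path SAM/BAM file.
#' @param reference FASTA path, `DNAStringSet` or named character.
#' @param region Optional region list (`chrom`, `start`, `end`).
#' @param margin Alignment-end exclusion margin (default 20).
#' @param lower_pct,upper_pct Frequency window (defaults 5, 95).
#' @return Site tibble (see [aggregate_sites()]) with the end-filtered
#'   observations in the `observations` attribute.
#' @export
find_mismatches <- function(path, reference, region = NULL, margin = 20,
                            lower_pct = 5, upper_pct = 95) {
  aln <- read_alignments(path, region)
  obs <- collect_mismatches(aln, reference, region) |>
    apply_end_exclusion(margin)
  sites <- aggregate_sites(obs, aln, lower_pct, upper_pct)
  attr(sites, "observations") <- obs
  sites
}

#' Export a mismatch site table
#'
#' Tab-delimited: `chrom`, `pos`, `kind`, `ref`, `alt`, `support`,
#' `overlapping`, `freq_pct`, `passes`.
#'
#' @param sites Site tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mismatch_table <- function(sites, path) {
  out <- as.data.frame(sites)
  names(out)[names(out) == "ref_pos"] <- "pos"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mismatch site table written by [write_mismatch_table()]
#' @param path Table file.
#' @return Site tibble.
#' @export
read_mismatch_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ref = "character", alt = "character"))
  names(tb)[names(tb) == "pos"] <- "ref_pos"
  tb$ref[is.na(tb$ref)] <- ""
  tb$alt[is.na(tb$alt)] <- ""
  tibble::as_tibble(tb)
}

#' Write passing sites as a minimal VCF-like text
#'
#' Positions are 1-based in the output; insertions use the left anchor base
#' convention with a "." placeholder for the unknown anchor allele, so the
#' file is a site list for inspection rather than a normalized VCF.
#'
#' @param sites Site tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mismatch_vcf <- function(sites, path) {
  pass <- dplyr::filter(sites, .data$passes)
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(pass)) {
    body <- vapply(seq_len(nrow(pass)), function(i) {
      ref <- if (pass$ref[i] == "") "." else pass$ref[i]
      alt <- if (pass$alt[i] == "") "." else pass$alt[i]
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tKIND=%s;FREQ=%.3f;SUPPORT=%d;DEPTH=%d",
              pass$chrom[i], pass$ref_pos[i] + 1L, ref, alt, pass$kind[i],
              pass$freq_pct[i], pass$support[i], pass$overlapping[i])
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
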