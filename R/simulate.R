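# Seeded synthetic fixtures: a toy multi-exon gene, a reference sequence,
# ground-truthed reads at controlled isoform proportions per cell type, and
# alignments with injected substitutions / insertions / deletions at
# controlled per-site frequencies. All randomness is drawn from R's
# Mersenne-Twister under an explicit seed, restored afterwards, so fixtures
# are fully deterministic across platforms.

local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

BASES <- c("A", "C", "G", "T")

# Deterministic alternative allele: next base in a fixed cyclic order.
next_base <- function(b) {
  BASES[(match(b, BASES) %% 4L) + 1L]
}

#' Simulate a toy multi-exon gene and its reference sequence
#'
#' Builds a deterministic (seeded) annotation for one gene: a full-length
#' transcript using every exon, plus one skip-variant per interior exon.
#' The reference sequence is random with the given seed and covers the gene
#' plus flanks.
#'
#' @param n_exons Number of exons (at least 2).
#' @param exon_lengths,intron_lengths Integer vectors of lengths
#'   (`n_exons` and `n_exons - 1` entries); all at least 1.
#' @param chrom Chromosome name.
#' @param origin 0-based genomic start of the first exon.
#' @param gene_id,gene_name Identifiers for the gene.
#' @param seed RNG seed for the reference sequence.
#' @return List with `gene` (a `gene_annotation`), `genome_seq` (named
#'   character, one chromosome), `exon_table` (tibble `start`, `end`) and the
#'   arguments used.
#' @export
sim_gene <- function(n_exons = 5,
                     exon_lengths = c(200L, 150L, 120L, 150L, 200L),
                     intron_lengths = c(1500L, 10000L, 80L, 2000L),
                     chrom = "chrS", origin = 1000L,
                     gene_id = "GENE1", gene_name = "Toy1", seed = 1L) {
  if (n_exons < 2L) stop("need at least 2 exons", call. = FALSE)
  if (length(exon_lengths) != n_exons || length(intron_lengths) != n_exons - 1L) {
    stop("need ", n_exons, " exon lengths and ", n_exons - 1L,
         " intron lengths", call. = FALSE)
  }
  if (any(c(exon_lengths, intron_lengths) < 1L)) {
    stop("exon and intron lengths must be positive", call. = FALSE)
  }
  starts <- origin + cumsum(c(0L, exon_lengths[-n_exons] + intron_lengths))
  exon_table <- tibble::tibble(start = as.integer(starts),
                               end = as.integer(starts + exon_lengths))
  span_end <- exon_table$end[n_exons]
  glen <- span_end + 200L
  genome <- local_seed(seed, paste(sample(BASES, glen, replace = TRUE),
                                   collapse = ""))
  names(genome) <- NULL
  genome_seq <- stats::setNames(genome, chrom)

  interior <- if (n_exons > 2L) seq(2L, n_exons - 1L) else integer()
  tx <- list(tibble::tibble(transcript_id = paste0(gene_id, ".t_full"),
                            keep = list(seq_len(n_exons))))
  for (k in interior) {
    tx[[length(tx) + 1L]] <- tibble::tibble(
      transcript_id = sprintf("%s.t_skip%d", gene_id, k),
      keep = list(setdiff(seq_len(n_exons), k))
    )
  }
  transcripts <- dplyr::bind_rows(tx) |>
    dplyr::mutate(exons = lapply(.data$keep, function(k) exon_table[k, ])) |>
    dplyr::select("transcript_id", "exons")
  gene <- structure(
    list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
         strand = "+", start = exon_table$start[1], end = span_end,
         transcripts = transcripts),
    class = "gene_annotation"
  )
  list(gene = gene, genome_seq = genome_seq, exon_table = exon_table,
       n_exons = n_exons, chrom = chrom, seed = seed)
}

default_isoforms <- function(toy) {
  n <- toy$n_exons
  keep_sets <- list(full = seq_len(n))
  if (n >= 3L) keep_sets$skip3 <- setdiff(seq_len(n), 3L)
  if (n >= 5L) keep_sets$skip4 <- setdiff(seq_len(n), 4L)
  tibble::tibble(
    isoform_id = names(keep_sets),
    exon_idx = unname(keep_sets)
  )
}

default_proportions <- function(isoform_ids, cell_types) {
  base <- list(
    full = c(0.6, 0.2, 0.4),
    skip3 = c(0.3, 0.5, 0.3),
    skip4 = c(0.1, 0.3, 0.3)
  )
  m <- do.call(rbind, base[isoform_ids])
  m <- m[, seq_along(cell_types), drop = FALSE]
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(isoform_ids, cell_types)
  m
}

#' Assemble a ground-truthed fixture definition
#'
#' Couples a toy gene with an isoform table (intron chains with per-cell-type
#' proportions) and mismatch sites to inject at controlled frequencies. The
#' defaults describe a 5-exon gene in three cell types whose two interior
#' cassette exons are included at different rates per cell type, with one
#' substitution, one 2-base insertion and one 3-base deletion injected in the
#' constitutive flanking exons at frequencies 0.10, 0.30 and 0.25.
#'
#' @param toy Output of [sim_gene()].
#' @param cell_types Character vector of cell-type labels.
#' @param proportions Numeric matrix, isoforms x cell types, columns summing
#'   to 1; defaults to a fixed table over the full-length and skip variants.
#' @param injected_sites Tibble `ref_pos`, `kind`, `len`, `freq`; alleles are
#'   derived deterministically from the reference (next base in a fixed
#'   cyclic order). `NULL` for the defaults; pass a 0-row tibble for none.
#' @param p_tss,p_polya Probability that a read carries an assigned TSS /
#'   polyA site (reads lacking one are excluded under TSS/polyA clustering
#'   modes).
#' @return A `fixture_truth` list.
#' @export
sim_fixture <- function(toy = sim_gene(),
                        cell_types = c("ExciteNeuron", "InhibNeuron", "Astro"),
                        proportions = NULL,
                        injected_sites = NULL,
                        p_tss = 0.8, p_polya = 0.8) {
  isoforms <- default_isoforms(toy)
  if (is.null(proportions)) {
    proportions <- default_proportions(isoforms$isoform_id, cell_types)
  }
  stopifnot(nrow(proportions) == nrow(isoforms),
            ncol(proportions) == length(cell_types))
  if (max(abs(colSums(proportions) - 1)) > 1e-8) {
    stop("isoform proportions must sum to 1 per cell type", call. = FALSE)
  }
  ex <- toy$exon_table
  if (is.null(injected_sites)) {
    n <- nrow(ex)
    injected_sites <- tibble::tibble(
      ref_pos = as.integer(c(ex$start[1] + 100L,
                             ex$start[n] + 80L,
                             ex$start[n] + 130L)),
      kind = c("SNV", "insertion", "deletion"),
      len = c(1L, 2L, 3L),
      freq = c(0.10, 0.30, 0.25)
    )
  }
  if (nrow(injected_sites)) {
    stopifnot(all(injected_sites$freq >= 0 & injected_sites$freq <= 1))
    seqs <- toy$genome_seq[[toy$chrom]]
    injected_sites$ref <- vapply(seq_len(nrow(injected_sites)), function(i) {
      s <- injected_sites$ref_pos[i]
      switch(injected_sites$kind[i],
             SNV = substr(seqs, s + 1L, s + 1L),
             deletion = substr(seqs, s + 1L, s + injected_sites$len[i]),
             insertion = "")
    }, character(1))
    injected_sites$alt <- vapply(seq_len(nrow(injected_sites)), function(i) {
      s <- injected_sites$ref_pos[i]
      base_at <- substr(seqs, s + 1L, s + 1L)
      switch(injected_sites$kind[i],
             SNV = next_base(injected_sites$ref[i]),
             insertion = strrep(next_base(base_at), injected_sites$len[i]),
             deletion = "")
    }, character(1))
  } else {
    injected_sites$ref <- character(0)
    injected_sites$alt <- character(0)
  }
  isoforms$exons <- lapply(isoforms$exon_idx, function(k) ex[k, ])
  isoforms$chain <- vapply(isoforms$exons,
                           function(e) chain_key(interval_gaps(e)),
                           character(1))
  structure(
    list(toy = toy, gene = toy$gene, genome_seq = toy$genome_seq,
         chrom = toy$chrom, cell_types = cell_types,
         isoforms = isoforms, proportions = proportions,
         injected_sites = injected_sites,
         p_tss = p_tss, p_polya = p_polya),
    class = "fixture_truth"
  )
}

# True pooled inclusion rate of each candidate exon given read counts per
# cell type (every isoform spans the whole gene, so every read overlaps
# every exon).
true_inclusion_rates <- function(truth, n_per_celltype) {
  w <- n_per_celltype[truth$cell_types] / sum(n_per_celltype)
  ex <- truth$toy$exon_table
  vapply(seq_len(nrow(ex)), function(i) {
    inc <- vapply(truth$isoforms$exon_idx, function(k) i %in% k, logical(1))
    sum(w * colSums(truth$proportions[inc, , drop = FALSE]))
  }, numeric(1))
}

#' Simulate reads and alignments from a fixture definition
#'
#' Draws each cell type's reads from the isoform table (multinomial), assigns
#' TSS/polyA with the fixture's probabilities, injects each mismatch site
#' into covering reads as an independent Bernoulli draw at its true
#' frequency, and emits consistent SAM alignment records whose CIGARs encode
#' the splices (`N`), insertions (`I`) and deletions (`D`) exactly
#' (substitutions stay inside `M` runs).
#'
#' @param truth A `fixture_truth` from [sim_fixture()].
#' @param n_per_celltype Named integer vector of read counts per cell type.
#' @param seed RNG seed.
#' @return A `sim_result` list: `reads` (reads tibble), `sam` (character
#'   lines), `events` (per-read injected events), `truth` (with
#'   `true_psi` and `n_per_celltype` added).
#' @export
sim_reads <- function(truth,
                      n_per_celltype = c(ExciteNeuron = 120L,
                                         InhibNeuron = 120L, Astro = 120L),
                      seed = 1L) {
  stopifnot(inherits(truth, "fixture_truth"))
  stopifnot(all(truth$cell_types %in% names(n_per_celltype)))
  local_seed(seed, {
    rows <- list()
    counter <- 0L
    for (ct in truth$cell_types) {
      n <- n_per_celltype[[ct]]
      iso_draw <- sample(truth$isoforms$isoform_id, n, replace = TRUE,
                         prob = truth$proportions[, ct])
      for (iso in iso_draw) {
        counter <- counter + 1L
        ex <- truth$isoforms$exons[[match(iso, truth$isoforms$isoform_id)]]
        has_tss <- stats::runif(1) < truth$p_tss
        has_polya <- stats::runif(1) < truth$p_polya
        rows[[counter]] <- tibble::tibble(
          read_id = sprintf("r%05d", counter),
          gene_id = truth$gene$gene_id,
          cell_type = ct,
          barcode = sprintf("BC%05d", counter),
          chrom = truth$chrom,
          strand = truth$gene$strand,
          tss = if (has_tss) ex$start[1] else NA_real_,
          polya = if (has_polya) ex$end[nrow(ex)] else NA_real_,
          exons = list(ex),
          isoform_id = iso
        )
      }
    }
    reads <- dplyr::bind_rows(rows)

    # Bernoulli event injection per covering read
    events <- list()
    for (i in seq_len(nrow(truth$injected_sites))) {
      site <- truth$injected_sites[i, ]
      need_end <- site$ref_pos +
        (if (site$kind == "deletion") site$len else 1L)
      covers <- vapply(reads$exons, function(ex) {
        any(ex$start <= site$ref_pos & ex$end >= need_end)
      }, logical(1))
      hit <- covers & (stats::runif(nrow(reads)) < site$freq)
      if (any(hit)) {
        events[[length(events) + 1L]] <- tibble::tibble(
          read_id = reads$read_id[hit],
          ref_pos = site$ref_pos, kind = site$kind,
          ref = site$ref, alt = site$alt, len = site$len
        )
      }
    }
    events <- if (length(events)) dplyr::bind_rows(events) else
      tibble::tibble(read_id = character(), ref_pos = integer(),
                     kind = character(), ref = character(),
                     alt = character(), len = integer())

    sam <- build_sam(reads, events, truth)
    truth$true_psi <- true_inclusion_rates(truth, n_per_celltype)
    truth$n_per_celltype <- n_per_celltype
    structure(list(reads = dplyr::select(reads, -"isoform_id"),
                   isoform_of = stats::setNames(reads$isoform_id,
                                                reads$read_id),
                   events = events, sam = sam, truth = truth, seed = seed),
              class = "sim_result")
  })
}

# Build SAM text lines (header + one record per read) encoding the simulated
# exon structure and injected events.
build_sam <- function(reads, events, truth) {
  genome <- truth$genome_seq[[truth$chrom]]
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", truth$chrom, nchar(genome))
  )
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    ex <- reads$exons[[i]]
    ev <- events[events$read_id == reads$read_id[i], , drop = FALSE]
    ev <- ev[order(ev$ref_pos), , drop = FALSE]
    cigar <- character()
    seq_parts <- character()
    for (j in seq_len(nrow(ex))) {
      if (j > 1L) {
        cigar <- c(cigar, sprintf("%dN", ex$start[j] - ex$end[j - 1L]))
      }
      s <- ex$start[j]
      e <- ex$end[j]
      ev_in <- ev[ev$ref_pos >= s & ev$ref_pos < e, , drop = FALSE]
      cur <- s
      for (k in seq_len(nrow(ev_in))) {
        p <- ev_in$ref_pos[k]
        kind <- ev_in$kind[k]
        if (kind == "SNV") {
          if (p > cur) {
            cigar <- c(cigar, sprintf("%dM", p - cur))
            seq_parts <- c(seq_parts, substr(genome, cur + 1L, p))
          }
          cigar <- c(cigar, "1M")
          seq_parts <- c(seq_parts, ev_in$alt[k])
          cur <- p + 1L
        } else if (kind == "insertion") {
          if (p > cur) {
            cigar <- c(cigar, sprintf("%dM", p - cur))
            seq_parts <- c(seq_parts, substr(genome, cur + 1L, p))
          }
          cigar <- c(cigar, sprintf("%dI", nchar(ev_in$alt[k])))
          seq_parts <- c(seq_parts, ev_in$alt[k])
          cur <- p
        } else if (kind == "deletion") {
          if (p > cur) {
            cigar <- c(cigar, sprintf("%dM", p - cur))
            seq_parts <- c(seq_parts, substr(genome, cur + 1L, p))
          }
          cigar <- c(cigar, sprintf("%dD", ev_in$len[k]))
          cur <- p + ev_in$len[k]
        }
      }
      if (e > cur) {
        cigar <- c(cigar, sprintf("%dM", e - cur))
        seq_parts <- c(seq_parts, substr(genome, cur + 1L, e))
      }
    }
    # collapse adjacent identical ops (e.g. M runs around an SNV)
    cigar_str <- collapse_cigar(cigar)
    paste(reads$read_id[i], 0L, reads$chrom[i], ex$start[1] + 1L, 60L,
          cigar_str, "*", 0L, 0L, paste(seq_parts, collapse = ""), "*",
          sep = "\t")
  }, character(1))
  c(header, recs)
}

collapse_cigar <- function(parts) {
  if (length(parts) == 0L) return("*")
  len <- as.integer(sub("[A-Z=]$", "", parts))
  op <- sub("^[0-9]+", "", parts)
  out_len <- integer()
  out_op <- character()
  for (k in seq_along(op)) {
    m <- length(out_op)
    if (m > 0L && out_op[m] == op[k]) {
      out_len[m] <- out_len[m] + len[k]
    } else {
      out_len <- c(out_len, len[k])
      out_op <- c(out_op, op[k])
    }
  }
  paste0(out_len, out_op, collapse = "")
}

#' Write a simulated fixture to disk in every supported dialect
#'
#' Emits the reference FASTA (with index), the annotation GTF, the per-read
#' exon GFF, the read-to-gene/cell-type assignment table, the combined
#' AllInfo file, the SAM alignments, and a truth JSON for test oracles.
#'
#' @param sim A `sim_result` from [sim_reads()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sim$truth
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    gff = file.path(dir, "reads.gff"),
    assignment = file.path(dir, "assignments.tsv"),
    allinfo = file.path(dir, "allinfo.tsv"),
    sam = file.path(dir, "reads.sam"),
    truth = file.path(dir, "truth.json")
  )
  dna <- Biostrings::DNAStringSet(truth$genome_seq)
  Biostrings::writeXStringSet(dna, paths$fasta)
  Rsamtools::indexFa(paths$fasta)
  write_annotation_gtf(truth$gene, paths$annotation)
  write_read_gff(sim$reads, paths$gff)
  write_assignment_table(sim$reads, paths$assignment)
  write_allinfo(sim$reads, paths$allinfo)
  writeLines(sim$sam, paths$sam)
  jsonlite::write_json(
    list(
      gene_id = truth$gene$gene_id,
      chrom = truth$chrom,
      seed = sim$seed,
      n_per_celltype = as.list(truth$n_per_celltype),
      exon_table = truth$toy$exon_table,
      true_psi = truth$true_psi,
      isoforms = truth$isoforms[, c("isoform_id", "chain")],
      proportions = as.data.frame(truth$proportions),
      injected_sites = truth$injected_sites
    ),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  paths
}

#' Write a gene annotation as GTF
#'
#' @param annotation A `gene_annotation`.
#' @param path Output file (1-based inclusive coordinates, GTF attributes).
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  a <- annotation
  attr_str <- function(tx) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
            a$gene_id, tx, a$gene_name)
  }
  lines <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   a$chrom, a$start + 1L, a$end, a$strand,
                   sprintf('gene_id "%s"; gene_name "%s";', a$gene_id,
                           a$gene_name))
  for (i in seq_len(nrow(a$transcripts))) {
    tx <- a$transcripts$transcript_id[i]
    ex <- a$transcripts$exons[[i]]
    lines <- c(lines,
               sprintf("%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       a$chrom, ex$start[1] + 1L, ex$end[nrow(ex)], a$strand,
                       attr_str(tx)),
               sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
                       a$chrom, ex$start + 1L, ex$end, a$strand,
                       attr_str(tx)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a reads tibble as a per-read exon GFF (GTF dialect)
#'
#' @param reads A reads tibble.
#' @param path Output file; exon features carry `gene_id` and
#'   `transcript_id` (the read id), 1-based inclusive.
#' @return `path`, invisibly.
#' @export
write_read_gff <- function(reads, path) {
  lines <- unlist(lapply(seq_len(nrow(reads)), function(i) {
    ex <- reads$exons[[i]]
    sprintf('%s\treads\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            reads$chrom[i], ex$start + 1L, ex$end, reads$strand[i],
            reads$gene_id[i], reads$read_id[i])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a read-to-gene/cell-type assignment table
#'
#' @param reads A reads tibble.
#' @param path Output file (tab-delimited with header).
#' @return `path`, invisibly.
#' @export
write_assignment_table <- function(reads, path) {
  utils::write.table(
    data.frame(read_id = reads$read_id, gene_id = reads$gene_id,
               cell_type = reads$cell_type, barcode = reads$barcode),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a reads tibble as an AllInfo file
#'
#' Column schema (tab-delimited, no header, 1-based inclusive, "." for
#' missing): `read_id gene_id cell_type barcode chrom strand tss polya
#' intron_chain exons`.
#'
#' @param reads A reads tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_allinfo <- function(reads, path) {
  fmt_pairs <- function(tb, sep) {
    if (nrow(tb) == 0L) return(".")
    paste(sprintf("%d-%d", tb$start + 1L, tb$end), collapse = sep)
  }
  fmt_pos <- function(x) ifelse(is.na(x), ".", format(x + 1, scientific = FALSE))
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    ex <- reads$exons[[i]]
    paste(reads$read_id[i], reads$gene_id[i], reads$cell_type[i],
          ifelse(is.na(reads$barcode[i]), ".", reads$barcode[i]),
          reads$chrom[i], reads$strand[i],
          fmt_pos(reads$tss[i]), fmt_pos(reads$polya[i]),
          fmt_pairs(interval_gaps(ex), ";"), fmt_pairs(ex, ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
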