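# Shared test fixtures, all generated in code.

# One-row reads tibble built by hand.
make_read <- function(read_id, starts, ends, cell_type = "CT1",
                      gene_id = "G1", chrom = "chr1", strand = "+",
                      tss = NA_real_, polya = NA_real_,
                      barcode = NA_character_) {
  tibble::tibble(
    read_id = read_id, gene_id = gene_id, cell_type = cell_type,
    barcode = barcode, chrom = chrom, strand = strand,
    tss = tss, polya = polya,
    exons = list(tibble::tibble(start = starts, end = ends))
  )
}

make_reads <- function(...) dplyr::bind_rows(...)

# The default simulated fixture, built once per test run and reused.
.fx_cache <- new.env(parent = emptyenv())
get_fixture <- function() {
  if (!exists("fx", envir = .fx_cache)) {
    sim <- sim_reads(sim_fixture(), seed = 42)
    dir <- file.path(tempdir(), "splicestack-fx")
    paths <- write_fixture(sim, dir)
    assign("fx", list(sim = sim, truth = sim$truth, paths = paths),
           envir = .fx_cache)
  }
  get("fx", envir = .fx_cache)
}

# Random exon layout on a small genome, for transform property tests.
random_layout <- function() {
  n <- sample(1:6, 1)
  starts <- sort(sample(0:5000, n))
  widths <- sample(20:400, n, replace = TRUE)
  merge_intervals(tibble::tibble(start = starts, end = starts + widths))
}

# Independent total-plot-length oracle: per-base scan over the span.
scan_axis_length <- function(blocks, width = 100) {
  span <- c(blocks$start[1], blocks$end[nrow(blocks)])
  exonic <- rep(FALSE, span[2] - span[1])
  for (i in seq_len(nrow(blocks))) {
    exonic[(blocks$start[i] - span[1] + 1):(blocks$end[i] - span[1])] <- TRUE
  }
  r <- rle(exonic)
  sum(ifelse(r$values, r$lengths, pmin(r$lengths, width)))
}
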