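# Layout and rendering: row accounting, glyph conservation, color contract,
# deterministic SVG element counts, and the interactive HTML structure.

layout_for <- function(reads, ...) {
  map <- build_coordinate_map(collect_exonic_intervals(reads))
  clusters <- order_clusters(cluster_reads(reads, "chain"))
  compute_layout(clusters, reads, map, ...)
}

count_nodes <- function(path, xpath) {
  doc <- xml2::read_xml(paste(readLines(path), collapse = "\n"))
  xml2::xml_ns_strip(doc)
  length(xml2::xml_find_all(doc, xpath))
}

test_that("layout gives one row per retained read and sections per cell type", {
  fx <- get_fixture()
  reads <- fx$sim$reads
  lay <- layout_for(reads)
  expect_equal(nrow(lay$rows), nrow(reads))
  expect_equal(sort(lay$cell_types), sort(unique(reads$cell_type)))
  # rows within a cell type are contiguous
  for (ct in lay$cell_types) {
    r <- lay$rows$row[lay$rows$cell_type == ct]
    expect_equal(r, seq(min(r), max(r)))
  }
  # exon rectangle count equals the total exon block count
  expect_equal(nrow(lay$exon_rects),
               sum(vapply(reads$exons, nrow, integer(1))))
  # no glyph extends beyond the axis
  expect_true(all(lay$exon_rects$xmin >= 0 &
                    lay$exon_rects$xmax <= lay$axis_length + 1e-9))
  expect_error(compute_layout(NULL, reads, NULL), "nothing to plot")
})

test_that("alternative exons are recolored and mismatch dots placed per read", {
  fx <- get_fixture()
  reads <- fx$sim$reads
  calls <- compute_inclusion(reads, annotation = fx$truth$gene)
  sites <- find_mismatches(fx$paths$sam, fx$paths$fasta)
  obs <- attr(sites, "observations")
  ann <- read_gene_annotation(fx$paths$annotation, "GENE1")
  lay <- layout_for(reads, alt_calls = calls, sites = sites,
                    observations = obs, annotation = ann)
  flagged <- calls[calls$is_alternative, ]
  n_alt_rects <- sum(vapply(seq_len(nrow(reads)), function(i) {
    ex <- reads$exons[[i]]
    sum(vapply(seq_len(nrow(ex)), function(j) {
      any(flagged$start == ex$start[j] & flagged$end == ex$end[j])
    }, logical(1)))
  }, numeric(1)))
  expect_equal(sum(lay$exon_rects$is_alt), n_alt_rects)
  # one dot per (read, passing site) observation
  pass <- sites[sites$passes, ]
  n_dots <- nrow(dplyr::semi_join(
    obs, pass, by = c("ref_pos", "kind", "ref", "alt")))
  expect_equal(nrow(lay$dots), n_dots)
  # annotation section contains only transcripts overlapping the reads
  expect_equal(length(unique(lay$ann_rects$transcript_id)),
               nrow(ann$transcripts))
  expect_gt(min(lay$ann_rects$row), max(lay$rows$row))
})

test_that("zero passing sites leave the layout dot-free but otherwise unchanged", {
  fx <- get_fixture()
  reads <- fx$sim$reads[1:30, ]
  sites <- find_mismatches(fx$paths$sam, fx$paths$fasta,
                           lower_pct = 99, upper_pct = 100)
  expect_equal(sum(sites$passes), 0L)
  lay0 <- layout_for(reads)
  lay <- layout_for(reads, sites = sites,
                    observations = attr(sites, "observations"))
  expect_equal(nrow(lay$dots), 0L)
  expect_equal(lay$exon_rects, lay0$exon_rects)
})

test_that("SVG element counts equal glyph counts and renders are deterministic", {
  fx <- get_fixture()
  reads <- fx$sim$reads[1:40, ]
  calls <- compute_inclusion(reads)
  sites <- find_mismatches(fx$paths$sam, fx$paths$fasta)
  ann <- read_gene_annotation(fx$paths$annotation, "GENE1")
  lay <- layout_for(reads, alt_calls = calls, sites = sites,
                    observations = attr(sites, "observations"),
                    annotation = ann)
  f1 <- tempfile(fileext = ".svg")
  render_static(lay, f1, format = "svg")
  n_exon_rects <- count_nodes(f1, "//rect[contains(@class,'exon') and not(contains(@class,'ann'))]")
  expect_equal(n_exon_rects, nrow(lay$exon_rects))
  expect_equal(count_nodes(f1, "//circle"), nrow(lay$dots))
  expect_equal(count_nodes(f1, "//rect[@class='ann-exon']"),
               nrow(lay$ann_rects))
  expect_equal(count_nodes(f1, "//g[@class='celltype']"),
               length(lay$cell_types))
  f2 <- tempfile(fileext = ".svg")
  render_static(lay, f2, format = "svg")
  expect_identical(readLines(f1), readLines(f2))
  expect_error(render_static(lay, tempfile(), format = "tiff"))
})

test_that("the color contract holds: SNV blue, insertion green, deletion red, alt exon orange", {
  fx <- get_fixture()
  reads <- fx$sim$reads[1:40, ]
  calls <- compute_inclusion(reads)
  sites <- find_mismatches(fx$paths$sam, fx$paths$fasta)
  lay <- layout_for(reads, alt_calls = calls, sites = sites,
                    observations = attr(sites, "observations"))
  f <- tempfile(fileext = ".svg")
  render_static(lay, f, format = "svg")
  svg <- readLines(f)
  for (spec in list(c("SNV", "blue"), c("insertion", "green"),
                    c("deletion", "red"))) {
    hits <- grep(sprintf('mismatch-%s', spec[1]), svg, value = TRUE)
    if (length(hits)) expect_true(all(grepl(spec[2], hits)))
  }
  alt_hits <- grep('class="exon altexon"', svg, value = TRUE)
  expect_true(length(alt_hits) > 0 && all(grepl("orange", alt_hits)))
})

test_that("six cell types yield six read-stack sections plus the annotation section", {
  toy <- sim_gene()
  cts <- paste0("CT", 1:6)
  props <- matrix(
    rep(c(0.5, 0.3, 0.2), 6), ncol = 6,
    dimnames = list(c("full", "skip3", "skip4"), cts))
  truth <- sim_fixture(toy, cell_types = cts, proportions = props)
  sim <- sim_reads(truth, n_per_celltype = stats::setNames(rep(15L, 6), cts),
                   seed = 8)
  lay <- layout_for(sim$reads, annotation = truth$gene)
  expect_equal(length(lay$cell_types), 6L)
  f <- tempfile(fileext = ".svg")
  render_static(lay, f, "svg")
  expect_equal(count_nodes(f, "//g[@class='celltype']"), 6L)
  expect_equal(count_nodes(f, "//g[@class='annotation']"), 1L)
})

test_that("interactive HTML embeds one group per cell type with hover payloads", {
  fx <- get_fixture()
  reads <- fx$sim$reads[1:30, ]
  sites <- find_mismatches(fx$paths$sam, fx$paths$fasta)
  lay <- layout_for(reads, sites = sites,
                    observations = attr(sites, "observations"))
  f <- tempfile(fileext = ".html")
  render_interactive(lay, f, title = "toy gene")
  html <- readLines(f)
  txt <- paste(html, collapse = "\n")
  expect_equal(length(gregexpr('<g class="celltype"', txt)[[1]]),
               length(lay$cell_types))
  expect_match(txt, "<title>read r", fixed = TRUE)
  if (nrow(lay$dots)) {
    expect_match(txt, sprintf("%.1f%%", lay$dots$freq_pct[1]), fixed = TRUE)
  }
  # no annotation was given, so no annotation group
  expect_false(grepl('class="annotation"', txt))
})

test_that("without read-level observations, passing sites go to a summary row", {
  fx <- get_fixture()
  reads <- fx$sim$reads[1:20, ]
  sites <- find_mismatches(fx$paths$sam, fx$paths$fasta)
  lay <- layout_for(reads, sites = sites)
  expect_equal(nrow(lay$dots), sum(sites$passes))
  expect_true(all(lay$dots$row == lay$summary_row))
})

test_that("autoplot returns a ggplot and pdf rendering produces a file", {
  fx <- get_fixture()
  lay <- layout_for(fx$sim$reads[1:20, ])
  p <- ggplot2::autoplot(lay)
  expect_s3_class(p, "ggplot")
  f <- tempfile(fileext = ".pdf")
  render_static(lay, f, format = "pdf")
  expect_gt(file.size(f), 1000)
})
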