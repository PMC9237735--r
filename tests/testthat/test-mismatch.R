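# Mismatch finding: CIGAR walk, end exclusion, site aggregation and the
# frequency window; the fixture's BAM is cross-checked against an
# independent pileup.

REF <- stats::setNames(strrep("ACGT", 100), "chr1")  # 400 bases

ref_sub <- function(from, to) substr(REF[["chr1"]], from + 1, to)  # 0-based half-open

empty_obs <- function() {
  tibble::tibble(read_id = character(), ref_pos = integer(),
                 kind = character(), ref = character(), alt = character(),
                 dist_from_start = integer(), dist_from_end = integer())
}

make_aln <- function(read_id, ref_start, cigar, seq, chrom = "chr1") {
  tibble::tibble(
    read_id = read_id, chrom = chrom, ref_start = ref_start,
    ref_end = ref_start +
      GenomicAlignments::cigarWidthAlongReferenceSpace(cigar),
    cigar = cigar, seq = seq
  )
}

test_that("a read identical to the reference yields zero observations", {
  aln <- make_aln("r1", 50, "100M", ref_sub(50, 150))
  expect_equal(nrow(collect_mismatches(aln, REF)), 0L)
  # splices (N) are not mismatches either
  spliced <- make_aln("r2", 0, "40M200N40M",
                      paste0(ref_sub(0, 40), ref_sub(240, 280)))
  expect_equal(nrow(collect_mismatches(spliced, REF)), 0L)
})

test_that("substitution, insertion and deletion are located exactly with end distances", {
  seq <- paste0(ref_sub(50, 80), "TT", ref_sub(80, 100), ref_sub(103, 133))
  snv_at <- 60  # 0-based; 11th base of the alignment
  substr(seq, 11, 11) <- "G"  # reference base at 60 is 'A' (cycle ACGT)
  aln <- make_aln("r1", 50, "30M2I20M3D30M", seq)
  obs <- collect_mismatches(aln, REF) |> dplyr::arrange(ref_pos)
  expect_equal(nrow(obs), 3L)
  expect_equal(obs$kind, c("SNV", "insertion", "deletion"))
  expect_equal(obs$ref_pos, c(60L, 80L, 100L))
  expect_equal(obs$ref, c("A", "", ref_sub(100, 103)))
  expect_equal(obs$alt, c("G", "TT", ""))
  expect_equal(obs$dist_from_start, c(11L, 30L, 51L))
  expect_equal(obs$dist_from_end, c(73L, 53L, 31L))
})

test_that("end exclusion removes offsets up to the margin, keeps the rest, and is idempotent", {
  # substitutions at aligned offsets 1..30 from the alignment start
  seq <- ref_sub(100, 200)
  for (k in 1:30) substr(seq, k, k) <- "N"  # N never matches the reference
  aln <- make_aln("r1", 100, "100M", seq)
  obs <- collect_mismatches(aln, REF)
  expect_equal(sort(obs$dist_from_start), 1:30)
  kept <- apply_end_exclusion(obs, margin = 20)
  expect_equal(sort(kept$dist_from_start), 21:30)
  expect_equal(apply_end_exclusion(kept, 20), kept)      # idempotent
  expect_equal(apply_end_exclusion(obs, 0), obs)          # identity at 0
  # and symmetrically from the alignment end
  seq2 <- ref_sub(100, 200)
  substr(seq2, 80, 80) <- "N"   # dist_from_end = 21
  substr(seq2, 81, 81) <- "N"   # dist_from_end = 20
  obs2 <- collect_mismatches(make_aln("r2", 100, "100M", seq2), REF)
  kept2 <- apply_end_exclusion(obs2)
  expect_equal(kept2$dist_from_end, 21L)
})

test_that("sites aggregate distinct reads and the closed frequency window applies", {
  n <- 100L
  aln <- dplyr::bind_rows(lapply(1:n, function(i) {
    make_aln(sprintf("r%03d", i), 0, "200M", ref_sub(0, 200))
  }))
  for (s in c(0L, 4L, 5L, 50L, 95L, 96L, 100L)) {
    obs <- if (s == 0) empty_obs() else tibble::tibble(
      read_id = sprintf("r%03d", 1:s), ref_pos = 120L, kind = "SNV",
      ref = "A", alt = "G", dist_from_start = 121L, dist_from_end = 80L
    )
    sites <- aggregate_sites(obs, aln)
    if (s == 0) {
      expect_equal(nrow(sites), 0L)
    } else {
      expect_equal(sites$support, s)
      expect_equal(sites$overlapping, n)
      expect_equal(sites$passes, s >= 5 && s <= 95)
    }
  }
  # duplicate observations from one read are not double counted
  dup <- tibble::tibble(
    read_id = c("r001", "r001"), ref_pos = 120L, kind = "SNV",
    ref = "A", alt = "G", dist_from_start = 121L, dist_from_end = 80L
  )
  expect_equal(aggregate_sites(dup, aln)$support, 1L)
  expect_error(aggregate_sites(dup, aln, 50, 20), "exceeds")
})

test_that("deletion and insertion denominators require covering the whole event", {
  aln <- dplyr::bind_rows(
    make_aln("covers", 0, "50M", ref_sub(0, 50)),
    make_aln("clips_event", 0, "42M", ref_sub(0, 42))  # ends inside the deletion
  )
  obs <- tibble::tibble(
    read_id = "covers", ref_pos = 40L, kind = "deletion",
    ref = ref_sub(40, 45), alt = "", dist_from_start = 41L,
    dist_from_end = 6L
  )
  sites <- aggregate_sites(obs, aln, 0, 100)
  expect_equal(sites$overlapping, 1L)
  ins <- tibble::tibble(
    read_id = "covers", ref_pos = 42L, kind = "insertion",
    ref = "", alt = "TT", dist_from_start = 42L, dist_from_end = 9L
  )
  # flanking pair is [41,43): the 42M alignment covers only up to 42
  expect_equal(aggregate_sites(ins, aln, 0, 100)$overlapping, 1L)
})

test_that("widening the frequency window never removes a passing site", {
  fx <- get_fixture()
  sites <- find_mismatches(fx$paths$sam, fx$paths$fasta)
  wide <- find_mismatches(fx$paths$sam, fx$paths$fasta,
                          lower_pct = 0, upper_pct = 100)
  key <- function(s) paste(s$ref_pos, s$kind, s$alt)
  expect_true(all(key(sites[sites$passes, ]) %in% key(wide[wide$passes, ])))
})

test_that("event-free simulations produce zero observations", {
  truth <- sim_fixture(injected_sites = tibble::tibble(
    ref_pos = integer(), kind = character(), len = integer(),
    freq = numeric()
  ))
  sim <- sim_reads(truth, n_per_celltype = c(ExciteNeuron = 10L,
                                             InhibNeuron = 10L, Astro = 10L),
                   seed = 3)
  dir <- tempfile()
  paths <- write_fixture(sim, dir)
  sites <- find_mismatches(paths$sam, paths$fasta, margin = 0,
                           lower_pct = 0, upper_pct = 100)
  expect_equal(nrow(sites), 0L)
  expect_equal(nrow(attr(sites, "observations")), 0L)
})

test_that("fixture observations equal the generator's injected events and an independent pileup", {
  fx <- get_fixture()
  aln <- read_alignments(fx$paths$sam)
  obs <- collect_mismatches(aln, fx$paths$fasta)
  # exact truth equality: every observation is an injected event and vice versa
  got <- obs |>
    dplyr::arrange(read_id, ref_pos) |>
    dplyr::select(read_id, ref_pos, kind, ref, alt)
  want <- fx$sim$events |>
    dplyr::arrange(read_id, ref_pos) |>
    dplyr::select(read_id, ref_pos, kind, ref, alt)
  expect_equal(as.data.frame(got), as.data.frame(want))

  # independent oracle: SNV support equals non-reference pileup depth
  snv <- fx$truth$injected_sites[fx$truth$injected_sites$kind == "SNV", ]
  bam <- Rsamtools::asBam(fx$paths$sam, tempfile(), overwrite = TRUE)
  pu <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(which = GenomicRanges::GRanges(
      fx$truth$chrom, IRanges::IRanges(snv$ref_pos + 1L, snv$ref_pos + 1L))),
    pileupParam = Rsamtools::PileupParam(min_base_quality = 0L,
                                         distinguish_strands = FALSE,
                                         max_depth = 10000L)
  )
  alt_depth <- pu$count[pu$nucleotide == snv$alt]
  support <- sum(obs$ref_pos == snv$ref_pos & obs$kind == "SNV")
  expect_equal(support, alt_depth)
})

test_that("mismatch tables round-trip through disk", {
  fx <- get_fixture()
  sites <- find_mismatches(fx$paths$sam, fx$paths$fasta)
  f <- tempfile(fileext = ".tsv")
  write_mismatch_table(sites, f)
  back <- read_mismatch_table(f)
  expect_equal(as.data.frame(back), as.data.frame(sites),
               ignore_attr = TRUE)
  v <- tempfile(fileext = ".vcf")
  write_mismatch_vcf(sites, v)
  expect_equal(sum(!startsWith(readLines(v), "#")), sum(sites$passes))
})
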