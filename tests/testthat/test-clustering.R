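# Intron chains, per-cell-type partition, exclusion under TSS/polyA modes,
# and deterministic display order.

test_that("intron chains are the gaps between exon blocks", {
  expect_equal(
    derive_intron_chain(tibble::tibble(start = c(0, 200), end = c(100, 300))),
    tibble::tibble(start = 100L, end = 200L)
  )
  expect_equal(nrow(derive_intron_chain(tibble::tibble(start = 0, end = 100))),
               0L)
})

test_that("fixture chain multiset equals the generator's isoform truth table", {
  fx <- get_fixture()
  reads <- add_intron_chain(fx$sim$reads)
  truth_chain <- fx$truth$isoforms$chain[
    match(fx$sim$isoform_of[reads$read_id], fx$truth$isoforms$isoform_id)]
  expect_equal(reads$chain, unname(truth_chain))
})

test_that("mode=chain partitions all reads; sizes sum to retained reads", {
  reads <- make_reads(
    make_read("a", c(0, 200), c(100, 300)),
    make_read("b", c(0, 200), c(100, 300)),
    make_read("c", c(0, 250), c(100, 300)),
    make_read("d", 0, 300),
    make_read("e", c(0, 200), c(100, 300), cell_type = "CT2")
  )
  cl <- cluster_reads(reads, mode = "chain")
  expect_equal(sum(cl$size), nrow(reads))
  expect_setequal(unlist(cl$read_ids), reads$read_id)
  expect_equal(nrow(cl[cl$cell_type == "CT1", ]), 3L)  # 3 distinct chains
})

test_that("chain equality is exact: a 1-base splice-site shift separates clusters", {
  reads <- make_reads(
    make_read("a", c(0, 200), c(100, 300)),
    make_read("b", c(0, 201), c(100, 300))
  )
  cl <- cluster_reads(reads, mode = "chain")
  expect_equal(nrow(cl), 2L)
})

test_that("TSS/polyA modes exclude exactly the reads lacking the key", {
  reads <- make_reads(
    make_read("a", c(0, 200), c(100, 300), tss = 0, polya = 300),
    make_read("b", c(0, 200), c(100, 300), tss = 0),
    make_read("c", c(0, 200), c(100, 300), polya = 300),
    make_read("d", c(0, 200), c(100, 300))
  )
  cl_tss <- cluster_reads(reads, mode = "tss+chain")
  expect_equal(sum(cl_tss$size), 2L)
  expect_equal(attr(cl_tss, "excluded")$n_excluded, 2L)
  cl_both <- cluster_reads(reads, mode = "tss+chain+polya")
  expect_equal(sum(cl_both$size), 1L)
  cl_chain <- cluster_reads(reads, mode = "chain")
  expect_equal(sum(cl_chain$size), 4L)
})

test_that("partition matches brute-force grouping by exact chain equality on the fixture", {
  fx <- get_fixture()
  reads <- fx$sim$reads
  cl <- cluster_reads(reads, mode = "chain")
  # brute force: group read ids by (cell type, chain string)
  rr <- add_intron_chain(reads)
  brute <- split(rr$read_id, paste(rr$cell_type, rr$chain, sep = "|"))
  got <- split(unlist(cl$read_ids),
               rep(paste(cl$cell_type, cl$chain, sep = "|"), cl$size))
  expect_equal(lapply(got[sort(names(got))], sort),
               lapply(brute[sort(names(brute))], sort))
  # every retained read in exactly one cluster
  expect_equal(anyDuplicated(unlist(cl$read_ids)), 0L)
})

test_that("a cell type whose reads are all excluded is omitted with a warning", {
  reads <- make_reads(
    make_read("a", c(0, 200), c(100, 300), tss = 0),
    make_read("b", c(0, 200), c(100, 300), cell_type = "CT2")
  )
  expect_warning(cl <- cluster_reads(reads, mode = "tss+chain"), "CT2")
  expect_equal(unique(cl$cell_type), "CT1")
})

test_that("cluster ordering is deterministic: size, then intron count, then chain", {
  reads <- make_reads(
    make_read("a1", c(0, 200), c(100, 300)),
    make_read("a2", c(0, 200), c(100, 300)),
    make_read("b1", c(0, 150, 250), c(100, 200, 300)),
    make_read("c1", c(0, 250), c(100, 300))
  )
  cl <- order_clusters(cluster_reads(reads, "chain"))
  expect_equal(cl$size, c(2L, 1L, 1L))
  expect_equal(cl$n_introns[2], 2L)  # tie on size broken by intron count
  # permuted input yields the identical order
  cl2 <- order_clusters(cluster_reads(reads[sample(nrow(reads)), ], "chain"))
  expect_equal(cl$chain, cl2$chain)
})

test_that("ordering agrees with an independent sort on 100 random clusters", {
  set.seed(33)
  clusters <- tibble::tibble(
    cell_type = "CT1",
    chain = replicate(100, {
      n <- sample(0:3, 1)
      if (n == 0) "" else {
        s <- sort(sample(1:5000, 2 * n))
        paste(sprintf("%d-%d", s[seq(1, 2 * n, 2)], s[seq(2, 2 * n, 2)]),
              collapse = ";")
      }
    }),
    size = sample(1:20, 100, replace = TRUE),
    tss = NA_real_, polya = NA_real_,
    read_ids = replicate(100, character(), simplify = FALSE)
  )
  clusters$n_introns <- lengths(gregexpr("-", clusters$chain)) *
    (clusters$chain != "")
  out <- order_clusters(clusters)
  expect_setequal(out$chain, clusters$chain)
  # independent comparator: verify the pairwise order of consecutive rows
  key <- function(i) {
    nums <- if (out$chain[i] == "") numeric() else
      as.numeric(strsplit(out$chain[i], "[-;]")[[1]])
    list(size = out$size[i], n = out$n_introns[i], nums = nums)
  }
  for (i in seq_len(nrow(out) - 1)) {
    a <- key(i); b <- key(i + 1)
    ok <- a$size > b$size ||
      (a$size == b$size && a$n > b$n) ||
      (a$size == b$size && a$n == b$n && {
        cmp <- 0
        for (k in seq_len(min(length(a$nums), length(b$nums)))) {
          if (a$nums[k] != b$nums[k]) { cmp <- sign(a$nums[k] - b$nums[k]); break }
        }
        cmp <= 0
      })
    expect_true(ok)
  }
})

test_that("reads within a cluster take a stable canonical order", {
  reads <- make_reads(
    make_read("r2", c(0, 200), c(100, 300)),
    make_read("r1", c(0, 200), c(100, 300)),
    make_read("r0", c(10, 200), c(100, 300))
  )
  out <- order_reads_within_cluster(reads)
  expect_equal(out$read_id, c("r1", "r2", "r0"))
  set.seed(5)
  shuffled <- order_reads_within_cluster(reads[sample(3), ])
  expect_equal(shuffled$read_id, out$read_id)
  one <- make_read("solo", 0, 10)
  expect_equal(order_reads_within_cluster(one)$read_id, "solo")
})
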