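test_that("quality filter requires a run strictly longer than the threshold", {
  seq101 <- strrep("A", 101)
  expect_true(quality_filter(seq101, rep(10L, 101)))
  # exactly 100 qualifying bases embedded in low quality: discarded
  seq110 <- strrep("A", 110)
  q <- c(rep(5L, 5), rep(10L, 100), rep(5L, 5))
  expect_false(quality_filter(seq110, q))
  expect_true(quality_filter(strrep("A", 500), rep(40L, 500)))
  expect_error(quality_filter("ACGT", c(10L, 10L)), "length")
})

test_that("low-complexity masking lowercases tracts and preserves length", {
  s <- paste0(rand_dna_fixed <- "CGTACGTTGC", strrep("A", 20), "GCGCGTTAAC")
  m <- mask_low_complexity(s)
  expect_equal(nchar(m), nchar(s))
  expect_equal(substr(m, 11, 30), strrep("a", 20))
  expect_equal(substr(m, 1, 10), "CGTACGTTGC")
  # dinucleotide repeat of 10 units (flanks chosen not to phase-shift it)
  s2 <- paste0("CCGGTTACGC", strrep("AT", 10), "CCGGTTACGT")
  expect_equal(substr(mask_low_complexity(s2), 11, 30), strrep("at", 10))
  # nothing at threshold - 1
  s3 <- paste0("CGTAC", strrep("A", 11), "GTCGC")
  expect_equal(mask_low_complexity(s3), s3)
})

test_that("clustering joins a read with its 5'-extended superstring", {
  set.seed(1)
  core <- rand_dna(200)
  reads <- c(long = paste0(rand_dna(50), core), short = core)
  res <- cluster_ests(reads)
  expect_equal(nrow(res$contigs), 2L)
  expect_equal(length(res$singlets), 0L)
  expect_equal(res$contigs$read_id, c("long", "short"))  # 5'-most first
  expect_equal(res$contigs$offset, c(0L, 50L))
  expect_equal(res$consensus[[1]], paste0(substr(reads[["long"]], 1, 50), core))
})

test_that("reads without a shared seed stay singlets", {
  set.seed(2)
  reads <- c(a = rand_dna(150), b = rand_dna(150))
  res <- cluster_ests(reads)
  expect_equal(nrow(res$contigs), 0L)
  expect_setequal(res$singlets, c("a", "b"))
})

test_that("clustering partitions reads and recovers a one-gene contig", {
  cfg <- noiseless_config(seed = 3, n_genes = 1, n_reads = 50, full_length_prob = 1)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  masked <- vapply(setNames(as.character(rd$reads), names(rd$reads)),
                   mask_low_complexity, character(1))
  res <- cluster_ests(masked)
  expect_equal(nrow(res$contigs), 50L)
  expect_equal(length(unique(res$contigs$contig_id)), 1L)
  expect_equal(length(res$singlets), 0L)
  # partition: every read in exactly one contig or the singlet list
  ids <- c(res$contigs$read_id, res$singlets)
  expect_setequal(ids, names(masked))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("contig size distribution reports exact histogram and summary bins", {
  contigs <- data.frame(contig_id = c("c1", "c1", "c2", "c2", "c3", "c3", "c3"))
  d <- contig_size_distribution(contigs)
  expect_equal(d$histogram, c(`2` = 2L, `3` = 1L))
  expect_equal(d$n_contigs, 3L)
  expect_equal(d$n_lt_20, 3L)
  expect_equal(d$n_ge_30, 0L)
  empty <- contig_size_distribution(contigs[0, , drop = FALSE])
  expect_equal(empty$n_contigs, 0L)
  expect_length(empty$histogram, 0L)
})

test_that("clone selection picks the 5'-most contig member deterministically", {
  contigs <- data.frame(contig_id = "c1", read_id = c("r1", "r2"),
                        offset = c(5L, 0L), read_length = c(500L, 400L),
                        stringsAsFactors = FALSE)
  sel <- select_clones(contigs, character())
  expect_equal(sel$read_id, "r2")
  expect_equal(sel$reason, "forefront")
  # stable under member re-ordering
  sel2 <- select_clones(contigs[2:1, ], character())
  expect_identical(sel, sel2)
  # offset tie broken by longer read, then id
  tie <- data.frame(contig_id = "c1", read_id = c("rA", "rB"),
                    offset = c(0L, 0L), read_length = c(300L, 600L),
                    stringsAsFactors = FALSE)
  expect_equal(select_clones(tie, character())$read_id, "rB")
})

test_that("incremental selection appends upstream clones without dropping picks", {
  contigs <- data.frame(contig_id = "c1", read_id = c("r1", "r2"),
                        offset = c(5L, 0L), read_length = c(500L, 400L),
                        stringsAsFactors = FALSE)
  first <- select_clones(contigs, character())
  grown <- rbind(contigs,
                 data.frame(contig_id = "c1", read_id = "r3", offset = -3L,
                            read_length = 450L, stringsAsFactors = FALSE))
  second <- select_clones(grown, character(), prior = first)
  expect_setequal(second$read_id, c("r2", "r3"))
  expect_equal(second$reason[second$read_id == "r3"], "upstream_update")
  expect_equal(second$reason[second$read_id == "r2"], "forefront")
})

test_that("singlets are selected only for genes with no contig counterpart", {
  contigs <- data.frame(contig_id = "c1", read_id = c("r1", "r2"),
                        offset = c(0L, 10L), read_length = c(500L, 400L),
                        stringsAsFactors = FALSE)
  hits <- data.frame(query_id = c("r1", "s1", "s2"),
                     gene_id = c("gA", "gA", "gB"), stringsAsFactors = FALSE)
  sel <- select_clones(contigs, c("s1", "s2"), hits)
  expect_setequal(sel$read_id, c("r1", "s2"))  # s1 covered by r1's gene
  expect_equal(sel$reason[sel$read_id == "s2"], "novel_gene_singlet")
  expect_false(anyDuplicated(sel$read_id) > 0)
})

test_that("detection-miss probability matches the closed form and its limits", {
  expect_equal(detection_miss_probability(6e-5, 10000), (1 - 6e-5)^10000)
  expect_equal(round(detection_miss_probability(6e-5, 10000), 4), 0.5488)
  expect_gt(detection_miss_probability(6e-5, 10000), 0.5)
  expect_equal(detection_miss_probability(0, 5000), 1)
  expect_equal(detection_miss_probability(1, 1), 0)
  expect_error(detection_miss_probability(1.5, 10), "freq")
  expect_error(detection_miss_probability(0.1, -1), "n_clones")
})

test_that("miss probability is strictly decreasing in frequency and depth", {
  freqs <- c(1e-5, 1e-4, 1e-3, 1e-2)
  p <- detection_miss_probability(freqs, 1000)
  expect_true(all(diff(p) < 0))
  ns <- c(10, 100, 1000, 10000)
  p2 <- vapply(ns, function(n) detection_miss_probability(1e-4, n), numeric(1))
  expect_true(all(diff(p2) < 0))
})
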