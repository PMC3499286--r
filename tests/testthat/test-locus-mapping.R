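test_that("anchor selection takes the best alignment above strict thresholds", {
  aln <- alignment_records(query_id = c("q", "q"), subject_id = "chr1",
                           sstart = c(1000L, 5000L), send = c(1300L, 5300L),
                           score = c(250, 180), pident = c(95, 99))
  anchor <- select_anchor(aln)
  expect_equal(anchor$score, 250)
  # score exactly 100 does not qualify
  a100 <- alignment_records("q", "chr1", 0L, 300L, score = 100, pident = 95)
  expect_null(select_anchor(a100))
  # identity exactly 90 does not qualify
  a90 <- alignment_records("q", "chr1", 0L, 300L, score = 150, pident = 90)
  expect_null(select_anchor(a90))
  # just above both boundaries qualifies
  ok <- alignment_records("q", "chr1", 0L, 300L, score = 100.5, pident = 90.1)
  expect_equal(nrow(select_anchor(ok)), 1L)
  mixed <- alignment_records(c("q1", "q2"), "chr1", c(0L, 0L), c(300L, 300L),
                             score = 200, pident = 95)
  expect_error(select_anchor(mixed), "single query")
})

test_that("locus extension bridges sub-1-Mb gaps from the growing region", {
  thr <- mapping_thresholds()
  aln <- alignment_records(query_id = rep("q", 2), subject_id = "chr1",
                           sstart = c(999999L, 1499999L),
                           send = c(1001000L, 1500500L),
                           score = c(400, 300), pident = 99)
  anchor <- select_anchor(aln, thr)
  locus <- extend_locus(anchor, aln, thr)
  expect_equal(locus$start, 999999L)
  expect_equal(locus$end, 1500500L)
})

test_that("extension runs to fixpoint so absorbed alignments chain onward", {
  thr <- mapping_thresholds()
  # third block is 2.0 Mb past the anchor but 0.9 Mb past the second block
  aln <- alignment_records(query_id = rep("q", 3), subject_id = "chr1",
                           sstart = c(0L, 900000L, 1801000L),
                           send = c(1000L, 901000L, 1802000L),
                           score = c(500, 300, 300), pident = 99)
  locus <- extend_locus(select_anchor(aln, thr), aln, thr)
  expect_equal(locus$end, 1802000L)
})

test_that("extension ignores opposite-strand and other-subject alignments", {
  thr <- mapping_thresholds()
  aln <- rbind(
    alignment_records("q", "chr1", 0L, 1000L, score = 500, pident = 99),
    alignment_records("q", "chr1", 10000L, 11000L, strand = "-",
                      score = 300, pident = 99),
    alignment_records("q", "chr2", 2000L, 3000L, score = 300, pident = 99))
  locus <- extend_locus(select_anchor(aln, thr), aln, thr)
  expect_equal(locus$end, 1000L)
  expect_equal(locus$chrom, "chr1")
})

test_that("overlapping same-strand loci merge; opposite strands never do", {
a <- data.frame(locus_id = "a", chrom = "chr2", start = 100L, end = 500L,
                  strand = "+", n_members = 1L, is_unplaced = FALSE,
                  stringsAsFactors = FALSE)
  a$members <- list("qa")
  b <- a; b$locus_id <- "b"; b$start <- 400L; b$end <- 900L; b$members <- list("qb")
  merged <- merge_loci(rbind(a, b))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 900L)
  expect_setequal(merged$members[[1]], c("qa", "qb"))
  # same interval, opposite strands
  c_ <- a; c_$locus_id <- "c"; c_$strand <- "-"; c_$members <- list("qc")
  merged2 <- merge_loci(rbind(a, c_))
  expect_equal(nrow(merged2), 2L)
  # touching intervals do not overlap
  d <- a; d$locus_id <- "d"; d$start <- 500L; d$end <- 700L; d$members <- list("qd")
  expect_equal(nrow(merge_loci(rbind(a, d))), 2L)
})

test_that("merging is transitive, idempotent and permutation-invariant", {
  rows <- lapply(list(c(0L, 500L), c(400L, 900L), c(850L, 1200L)), function(iv) {
    r <- data.frame(locus_id = paste0("q", iv[1]), chrom = "chr1",
                    start = iv[1], end = iv[2], strand = "+", n_members = 1L,
                    is_unplaced = FALSE, stringsAsFactors = FALSE)
    r$members <- list(paste0("q", iv[1]))
    r
  })
  loci <- do.call(rbind, rows)
  merged <- merge_loci(loci)
  expect_equal(nrow(merged), 1L)       # a-b and b-c overlap, a-c need not
  expect_equal(merged$n_members, 3L)
  again <- merge_loci(merged)
  expect_equal(again$start, merged$start)
  expect_equal(again$end, merged$end)
  perm <- merge_loci(loci[c(3, 1, 2), ])
  expect_equal(perm$start, merged$start)
  expect_equal(perm$members, merged$members)
})

test_that("merge agrees with a brute-force union-find oracle", {
  set.seed(123)
  for (trial in 1:50) {
    loci <- random_loci(sample(2:50, 1))
    merged <- merge_loci(loci)
    oracle <- brute_force_merge(loci)
    expect_equal(merged$start, oracle$start)
    expect_equal(merged$end, oracle$end)
    expect_equal(merged$chrom, oracle$chrom)
    expect_equal(merged$strand, oracle$strand)
    expect_equal(merged$n_members, oracle$n)
  }
})

test_that("locus tables count by chromosome and strand with totals", {
mk <- function(id, chrom, strand, unplaced = FALSE) {
    r <- data.frame(locus_id = id, chrom = chrom, start = 0L, end = 100L,
                    strand = strand, n_members = 1L, is_unplaced = unplaced,
                    stringsAsFactors = FALSE)
    r$members <- list(id)
    r
  }
  loci <- rbind(mk("a", "chr1", "+"), mk("b", "chr1", "+"), mk("c", "chr1", "-"))
  tab <- tabulate_loci(loci)
  row1 <- tab[tab$chromosome == "chr1", ]
  expect_equal(c(row1$forward, row1$reverse, row1$total), c(2L, 1L, 3L))
  tot <- tab[tab$chromosome == "Total", ]
  expect_equal(tot$total, sum(tab$total[tab$chromosome != "Total"]))
  # scaffold-only loci populate only the scaffold row
  sc <- rbind(mk("s1", "scaffold_1", "+", TRUE), mk("s2", "scaffold_2", "-", TRUE))
  tab2 <- tabulate_loci(sc, chromosomes = c("chr1", "chr2"))
  expect_true(all(tab2$total[tab2$chromosome %in% c("chr1", "chr2")] == 0L))
  expect_equal(tab2$total[tab2$chromosome == "Unplaced scaffolds"], 2L)
})

test_that("window densities count interval intersections per strand", {
  mk <- function(id, start, end, strand) {
    r <- data.frame(locus_id = id, chrom = "chr1", start = start, end = end,
                    strand = strand, n_members = 1L, is_unplaced = FALSE,
                    stringsAsFactors = FALSE)
    r$members <- list(id)
    r
  }
  loci <- rbind(mk("a", 2400000L, 2500000L, "+"), mk("b", 2400000L, 2500000L, "-"))
  d <- locus_density(loci, c(chr1 = 10000000L), window = 5000000L, step = 100000L)
  # direct enumeration oracle
  expected <- as.integer(d$window_start < 2500000 & d$window_end > 2400000)
  expect_equal(d$fwd, expected)
  expect_equal(d$rev, expected)
  expect_equal(sum(d$fwd), 25L)  # windows starting 0 .. 2.4 Mb
  # empty chromosome: all-zero track
  d2 <- locus_density(loci[0, ], c(chr1 = 1000000L), window = 500000L,
                      step = 100000L)
  expect_true(all(d2$fwd == 0L) && all(d2$rev == 0L))
})

test_that("no merged locus mixes strands and counts are bounded by queries", {
  set.seed(77)
  for (trial in 1:10) {
    loci <- random_loci(30)
    merged <- merge_loci(loci)
    expect_lte(nrow(merged), 30L)
    # members of a merged locus all came from rows with its strand
    for (i in seq_len(nrow(merged))) {
      src <- loci[loci$locus_id %in% merged$members[[i]], ]
      expect_true(all(src$strand == merged$strand[i]))
      expect_true(all(src$chrom == merged$chrom[i]))
    }
  }
})
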