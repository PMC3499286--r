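test_that("best-aligned region maximises query coverage, then identity", {
  aln <- alignment_records(query_id = c("q", "q"), subject_id = "chr1",
                           sstart = c(0L, 5000L), send = c(900L, 5400L),
                           qstart = c(0L, 0L), qend = c(900L, 400L),
                           score = c(800, 900), pident = c(95, 99))
  best <- best_aligned_region(aln, 1000L)
  expect_equal(best$send, 900L)  # 90% coverage beats 40%
  tie <- alignment_records(query_id = c("q", "q"), subject_id = "chr1",
                           sstart = c(0L, 5000L), send = c(500L, 5500L),
                           qstart = 0L, qend = 500L, pident = c(95, 99))
  expect_equal(best_aligned_region(tie, 1000L)$pident, 99)
  expect_null(best_aligned_region(aln[0, ], 1000L))
  single <- aln[1, ]
  expect_equal(best_aligned_region(single, 1000L), single)
})

test_that("flanked change counting follows the 5-base exact-match rule", {
  g <- "CCCCCACCCCC"; d <- "CCCCCGCCCCC"  # center genome A -> cDNA G
  expect_equal(count_flanked_changes(make_pairing(g, d)),
               c(n_AG = 1L, n_GA = 0L))
  # one flank base mismatched: nothing counts
  d2 <- "TCCCCGCCCCC"
  expect_equal(count_flanked_changes(make_pairing(g, d2)),
               c(n_AG = 0L, n_GA = 0L))
  # gap in a flank window disqualifies
  g3 <- "CCCC-ACCCCC"; d3 <- "CCCCCGCCCCC"
  expect_equal(count_flanked_changes(make_pairing(g3, d3)),
               c(n_AG = 0L, n_GA = 0L))
  # symmetric G -> A
  expect_equal(count_flanked_changes(make_pairing("CCCCCGCCCCC", "CCCCCACCCCC")),
               c(n_AG = 0L, n_GA = 1L))
  # too short for any flanked column
  expect_equal(count_flanked_changes(make_pairing("CCACC", "CCGCC")),
               c(n_AG = 0L, n_GA = 0L))
})

test_that("two A->G and one G->A qualify in a long pairing", {
  core <- "TTTTTTTTTT"
  g <- paste0(core, "A", core, "G", core, "A", core)
  d <- paste0(core, "G", core, "A", core, "G", core)
  expect_equal(count_flanked_changes(make_pairing(g, d)),
               c(n_AG = 2L, n_GA = 1L))
})

test_that("flank counting equals a brute-force column scan on random pairings", {
  set.seed(41)
  for (trial in 1:60) {
    n <- sample(15:120, 1)
    g <- strsplit(rand_dna(n), "")[[1]]
    d <- g
    flip <- runif(n) < 0.12
    d[flip] <- sample(c("A", "C", "G", "T"), sum(flip), TRUE)
    p <- structure(list(genome = g, cdna = d, qstart = 0L), class = "cm_pairing")
    expect_equal(count_flanked_changes(p), brute_force_flank_count(p))
  }
})

test_that("increasing the flank requirement never increases counts", {
  set.seed(42)
  for (trial in 1:20) {
    g <- strsplit(rand_dna(200), "")[[1]]
    d <- g
    flip <- runif(200) < 0.1
    d[flip] <- sample(c("A", "C", "G", "T"), sum(flip), TRUE)
    p <- structure(list(genome = g, cdna = d, qstart = 0L), class = "cm_pairing")
    counts <- vapply(3:8, function(f) count_flanked_changes(p, f), integer(2))
    expect_true(all(diff(counts["n_AG", ]) <= 0L))
    expect_true(all(diff(counts["n_GA", ]) <= 0L))
  }
})

test_that("minus-strand pairings are normalised once to the transcribed strand", {
  # plus-strand genomic region whose reverse complement is the transcript
  region <- "GGGGGTGGGGG"        # revcomp = CCCCCACCCCC (transcript, center A)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0("TTTT", region, "TTTT")))
  cdna <- "CCCCCGCCCCC"          # center edited A -> G
  aln <- alignment_records("q", "chr1", sstart = 4L, send = 15L, strand = "-",
                           qstart = 0L, qend = 11L, score = 100, pident = 91)
  p <- pairing_from_alignment(cdna, genome, aln)
  expect_equal(paste(p$genome, collapse = ""), "CCCCCACCCCC")
  expect_equal(count_flanked_changes(p), c(n_AG = 1L, n_GA = 0L))
})

test_that("editing fraction is the excess asymmetry of the counts", {
  expect_equal(editing_fraction(142, 97), 45 / 239)
  expect_equal(editing_fraction(100, 100), 0)
  expect_equal(editing_fraction(50, 0), 1)
  expect_error(editing_fraction(0, 0), "undefined")
  expect_gte(editing_fraction(1, 99), -1)
})

test_that("editing report tallies per-cDNA only-A->G / only-G->A flags", {
  pairings <- list(
    ag = make_pairing("CCCCCACCCCC", "CCCCCGCCCCC"),
    ga = make_pairing("CCCCCGCCCCC", "CCCCCACCCCC"),
    none = make_pairing("CCCCCCCCCCC", "CCCCCCCCCCC"))
  rep <- editing_report(pairings)
  expect_equal(rep$summary$n_AG_total, 1L)
  expect_equal(rep$summary$n_GA_total, 1L)
  expect_equal(rep$summary$only_AG_cdnas, 1L)
  expect_equal(rep$summary$only_GA_cdnas, 1L)
  expect_equal(rep$summary$editing_fraction, 0)
  expect_true(rep$per_query$only_AG[rep$per_query$query_id == "ag"])
})

test_that("3'-UTR intervals run from the ORF end to the poly(A) tail", {
  set.seed(43)
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(nonstop, 40, TRUE), collapse = ""), "TAA")
  utr <- "CGTCGTACGGTCGTTGCGCG"  # must not end in A (tail detection)
  s <- paste0("CC", cds, utr, strrep("A", 12))
  iv <- utr3_interval(s)
  expect_equal(iv[1], 2L + nchar(cds))
  expect_equal(iv[2], 2L + nchar(cds) + nchar(utr))
  expect_null(utr3_interval("CCCCCCCC"))  # no ORF
})

test_that("UTR mismatch rates aggregate mismatches over aligned columns", {
  p0 <- make_pairing(strrep("C", 200), strrep("C", 200))
  g <- strrep("C", 100)
  d1 <- paste0(strrep("C", 50), "T", strrep("C", 49))
  res <- utr_mismatch_rate(list(a = p0, b = make_pairing(g, g),
                                c = make_pairing(g, d1)))
  expect_equal(res$per_query$n_mismatches, c(0L, 0L, 1L))
  expect_true(res$per_query$perfect_match[1])
  expect_equal(res$n_perfect, 2L)
  expect_equal(res$n_total, 3L)
  expect_equal(res$aggregate_rate, 1 / 400)
})

test_that("UTR mismatch rate recovers the configured polymorphism rate", {
  cfg <- sim_config(seed = 44, n_genes = 6, n_reads = 200,
                    polymorphism_rate = 0.004, seq_error_rate = 0,
                    editing_rate = 0, low_quality_read_frac = 0,
                    full_length_prob = 1, frac_duplicated = 0,
                    frac_pseudogene = 0)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  pairings <- truth_pairings(sim, rd)
  mm <- vapply(pairings, function(p) sum(p$genome != p$cdna), integer(1))
  cols <- vapply(pairings, function(p) length(p$genome), integer(1))
  rate <- sum(mm) / sum(cols)
  se <- sqrt(0.004 * 0.996 / sum(cols))
  expect_lt(abs(rate - 0.004), 4 * se)
})
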