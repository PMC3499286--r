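prot_aln <- function(plen, pstart, pend) {
  data.frame(query_id = "q", protein_id = "p", protein_length = plen,
             pstart = pstart, pend = pend, score = pend - pstart + 1,
             stringsAsFactors = FALSE)
}

test_that("full-length CDS calls require both trims strictly below 10 aa", {
  fl <- classify_full_length(prot_aln(100L, 5L, 97L))
  expect_equal(fl$n_term_trim, 4L)
  expect_equal(fl$c_term_trim, 3L)
  expect_true(fl$has_full_length_cds)
  # boundary: trim of exactly 9 passes, 10 fails
  expect_true(classify_full_length(prot_aln(100L, 10L, 100L))$has_full_length_cds)
  expect_false(classify_full_length(prot_aln(100L, 11L, 100L))$has_full_length_cds)
  expect_false(classify_full_length(prot_aln(100L, 1L, 90L))$has_full_length_cds)
  expect_true(classify_full_length(prot_aln(100L, 1L, 91L))$has_full_length_cds)
})

test_that("start-codon estimation is the N-terminal analogue of the rule", {
  expect_true(classify_start_codon(prot_aln(100L, 1L, 50L)))
  expect_true(classify_start_codon(prot_aln(100L, 10L, 50L)))
  expect_false(classify_start_codon(prot_aln(100L, 11L, 50L)))
  expect_false(classify_start_codon(NULL))  # no protein hit
})

test_that("full-length is monotone under alignment extension", {
  set.seed(21)
  for (trial in 1:50) {
    plen <- sample(50:500, 1)
    ps <- sample.int(plen, 1)
    pe <- sample(ps:plen, 1)
    base <- classify_full_length(prot_aln(plen, ps, pe))$has_full_length_cds
    ext <- classify_full_length(prot_aln(plen, max(1L, ps - sample(0:5, 1)),
                                         min(plen, pe + sample(0:5, 1))))
    expect_true(!base || ext$has_full_length_cds)
  }
})

test_that("ORF length boundary at more-than-30 amino acids is strict", {
  set.seed(3)
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  utr <- "CCGCGC"
  orf31 <- paste0(utr, "ATG", paste(sample(nonstop, 30, TRUE), collapse = ""), "TAA")
  r31 <- find_longest_orf(orf31)
  expect_equal(r31$longest_orf_aa, 31L)
  expect_false(r31$is_noncoding)
  orf30 <- paste0(utr, "ATG", paste(sample(nonstop, 29, TRUE), collapse = ""), "TGA")
  r30 <- find_longest_orf(orf30)
  expect_equal(r30$longest_orf_aa, 30L)
  expect_true(r30$is_noncoding)
})

test_that("sequences without a complete ATG..stop span are non-coding", {
  expect_equal(find_longest_orf("CCCCCCCCCCCC")$longest_orf_aa, 0L)
  # ATG but no in-frame stop: ORF runs off the 3' end, not counted
  open_orf <- paste0("ATG", strrep("GCA", 50))
  expect_equal(find_longest_orf(open_orf)$longest_orf_aa, 0L)
})

test_that("ORF finder agrees with a brute-force scanner on random sequences", {
  set.seed(17)
  for (trial in 1:60) {
    s <- rand_dna(sample(30:400, 1))
    expect_equal(find_longest_orf(s)$longest_orf_aa, brute_force_longest_orf(s),
                 info = s)
  }
})

test_that("locus representatives maximise ORF length with documented ties", {
  mk_locus <- function(members) {
    r <- data.frame(locus_id = "L1", chrom = "chr1", start = 0L, end = 100L,
                    strand = "+", n_members = length(members),
                    is_unplaced = FALSE, stringsAsFactors = FALSE)
    r$members <- list(members)
    r
  }
  st <- data.frame(query_id = c("r1", "r2", "r3"),
                   longest_orf_aa = c(120L, 300L, 300L), stringsAsFactors = FALSE)
  lens <- c(r1 = 800L, r2 = 1000L, r3 = 1400L)
  rep1 <- pick_locus_representatives(mk_locus(c("r1", "r2")), st, lens)
  expect_equal(rep1$query_id, "r2")
  # ORF tie broken by longer sequence
  rep2 <- pick_locus_representatives(mk_locus(c("r2", "r3")), st, lens)
  expect_equal(rep2$query_id, "r3")
  rep3 <- pick_locus_representatives(mk_locus("r1"), st, lens)
  expect_equal(rep3$query_id, "r1")
  empty <- mk_locus(character())
  expect_error(pick_locus_representatives(empty, st, lens), "no members")
})

test_that("duplication screen lists shared proteins and flags shorter ORFs", {
  reps <- data.frame(locus_id = c("L1", "L2", "L3"),
                     query_id = c("r1", "r2", "r3"),
                     longest_orf_aa = c(300L, 120L, 200L), stringsAsFactors = FALSE)
  pa <- data.frame(query_id = c("r1", "r2", "r3"),
                   protein_id = c("P", "P", "Q"),
                   protein_length = 300L, pstart = 1L, pend = 300L,
                   score = c(300, 120, 200), stringsAsFactors = FALSE)
  dup <- detect_duplications(reps, pa)
  expect_equal(unique(dup$protein_id), "P")
  expect_equal(dup$flagged_shorter[dup$locus_id == "L1"], FALSE)
  expect_equal(dup$flagged_shorter[dup$locus_id == "L2"], TRUE)
  # every protein matched once: empty table
  pa1 <- pa; pa1$protein_id <- c("P", "Q", "R")
  expect_equal(nrow(detect_duplications(reps, pa1)), 0L)
})

test_that("a clean duplication yields two loci with equal unflagged ORFs", {
  cfg <- sim_config(seed = 31, n_genes = 5, n_reads = 150,
                    frac_duplicated = 0.2, frac_pseudogene = 0,
                    polymorphism_rate = 0, seq_error_rate = 0, editing_rate = 0,
                    low_quality_read_frac = 0, full_length_prob = 1)
  bundle <- suppressMessages(run_pipeline(pipeline_config(sim = cfg)))
  dup <- bundle$duplications
  expect_equal(length(unique(dup$protein_id)), 1L)
  expect_equal(nrow(dup), 2L)
  expect_false(any(dup$flagged_shorter))  # synonymous copies: equal ORFs
})

test_that("CDS status invariants hold on simulated classifications", {
  cfg <- sim_config(seed = 32, n_genes = 10, n_reads = 150,
                    frac_pseudogene = 0.1, frac_duplicated = 0)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  pa <- match_proteins(rd$reads, sim$truth$proteins)
  st <- cds_status(rd$reads, pa)
  expect_true(all(!st$has_full_length_cds | st$has_start_codon))
  expect_true(all(!st$is_noncoding | !st$has_full_length_cds))
})

test_that("noiseless full-length transcripts classify as full-length CDS", {
  cfg <- noiseless_config(seed = 33, n_genes = 6, n_reads = 80,
                          full_length_prob = 1)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  pa <- match_proteins(rd$reads, sim$truth$proteins)
  st <- cds_status(rd$reads, pa)
  expect_true(all(st$has_full_length_cds))
})
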