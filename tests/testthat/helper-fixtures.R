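# Shared fixture builders for the test suite.

# A noiseless simulation configuration: no polymorphism, sequencing error,
# editing or low-quality reads; truncation controlled by full_length_prob.
noiseless_config <- function(seed = 1L, n_genes = 5L, n_reads = 100L, ...) {
  sim_config(seed = seed, n_genes = n_genes, n_reads = n_reads,
             polymorphism_rate = 0, seq_error_rate = 0, editing_rate = 0,
             low_quality_read_frac = 0, frac_duplicated = 0, frac_pseudogene = 0,
             ...)
}

# Write a 12-column tabular alignment file from a list of row vectors.
write_aln_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(lines, paste, character(1), collapse = "\t"), path)
  path
}

# One standard 12-column line with overridable fields (1-based inclusive
# file coordinates, minus strand as sstart > send).
aln_line <- function(query = "q1", subject = "chr1", pident = 99, len = 100,
                     mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
                     sstart = 1001, send = 1100, evalue = 1e-30, score = 180) {
  c(query, subject, pident, len, mismatch, gapopen, qstart, qend,
    sstart, send, evalue, score)
}

# Random DNA string helper for tests.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Build a pairing object directly from two equal-length strings.
make_pairing <- function(genome, cdna) {
  structure(list(genome = strsplit(genome, "")[[1]],
                 cdna = strsplit(cdna, "")[[1]], qstart = 0L),
            class = "cm_pairing")
}

# Brute-force transitive-closure merge of loci via pairwise union-find:
# the independent oracle for merge_loci.
brute_force_merge <- function(loci) {
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      same <- loci$chrom[i] == loci$chrom[j] && loci$strand[i] == loci$strand[j]
      overlap <- loci$start[i] < loci$end[j] && loci$end[i] > loci$start[j]
      if (same && overlap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix) {
    data.frame(chrom = loci$chrom[ix[1]], start = min(loci$start[ix]),
               end = max(loci$end[ix]), strand = loci$strand[ix[1]],
               n = length(ix), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random per-query locus set on a couple of chromosomes (for oracle trials).
random_loci <- function(n, chroms = c("chr1", "chr2"), span = 10000L) {
  starts <- sample.int(span, n, replace = TRUE)
  widths <- sample.int(2000L, n, replace = TRUE)
  df <- data.frame(locus_id = paste0("q", seq_len(n)),
                   chrom = sample(chroms, n, TRUE),
                   start = starts, end = starts + widths,
                   strand = sample(c("+", "-"), n, TRUE),
                   n_members = 1L, is_unplaced = FALSE,
                   stringsAsFactors = FALSE)
  df$members <- as.list(paste0("q", seq_len(n)))
  df
}

# Brute-force flank-validated change counter (independent of the cumsum
# implementation in the package).
brute_force_flank_count <- function(pairing, flank = 5L) {
  g <- toupper(pairing$genome); d <- toupper(pairing$cdna)
  n <- length(g)
  ag <- 0L; ga <- 0L
  for (i in seq_len(n)) {
    if (i <= flank || i + flank > n) next
    win <- c((i - flank):(i - 1L), (i + 1L):(i + flank))
    ok <- all(g[win] == d[win] & g[win] != "-" & d[win] != "-")
    if (!ok) next
    if (g[i] == "A" && d[i] == "G") ag <- ag + 1L
    if (g[i] == "G" && d[i] == "A") ga <- ga + 1L
  }
  c(n_AG = ag, n_GA = ga)
}

# Brute-force longest forward-frame ORF scanner: for every ATG, walk codon
# by codon to the first in-frame stop.
brute_force_longest_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i
    len <- 0L
    repeat {
      if (j + 2L > n) { len <- 0L; break }  # ran off the 3' end: not an ORF
      cod <- substr(s, j, j + 2L)
      if (cod %in% stops) break
      len <- len + 1L
      j <- j + 3L
    }
    best <- max(best, len)
  }
  best
}
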