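# Synthetic full-length-enriched cDNA library generator.
#
# The generator emulates the structure of a 5'-end-anchored cDNA resource:
# a small draft genome (chromosomes + unplaced scaffolds) carrying multi-exon
# genes on both strands, some duplicated and some pseudogenized; transcripts
# biased toward 5'-completeness; a long-tailed expression law; A-to-G editing
# at fixed sites; per-molecule polymorphism and sequencing error. Every read
# is traceable to its source gene through the ground-truth ledger.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Parameters of the synthetic cDNA-library generator. Defaults encode the
#' design conditions of a full-length-enriched library: about three-fourths
#' of clones retain the transcription start (`full_length_prob = 0.75`),
#' the remainder are 5'-truncated with a geometric tail, and expression
#' follows a Zipf law so that rare transcripts (frequencies down to ~1e-4
#' at the default gene count) appear.
#'
#' @param n_chromosomes,n_unplaced_scaffolds Number of chromosome and
#'   unplaced-scaffold sequences.
#' @param chromosome_length,scaffold_length Sequence lengths (bp).
#' @param n_genes Total gene models, including duplicated and pseudogene
#'   copies.
#' @param frac_duplicated,frac_pseudogene Fractions of `n_genes` that are
#'   near-identical duplicate copies / pseudogenized copies of another gene.
#' @param full_length_prob Probability that a read begins at the
#'   transcription start.
#' @param truncation_geometric_p Geometric parameter of the extra 5'
#'   truncation beyond the start region for non-full-length reads.
#' @param expression_zipf Zipf exponent of the per-gene expression law.
#' @param rare_gene_freq Optional forced expression frequency for the
#'   lowest-ranked gene (used to study detection-miss probabilities).
#' @param editing_rate Per-eligible-A probability that a transcript position
#'   is an A-to-G editing site (sites are fixed per gene; all reads covering
#'   a site carry G).
#' @param polymorphism_rate Per-base substitution rate on the read haplotype
#'   (cross-individual divergence from the reference genome; symmetric).
#' @param seq_error_rate Per-base sequencing-error substitution rate.
#' @param n_reads Number of reads to emit.
#' @param read_length Maximum read length (bp); clone-insert scale, so a
#'   full-length read normally covers its whole transcript.
#' @param n_exons_range,exon_length_range,intron_length_range Structural
#'   ranges for gene models.
#' @param utr5_length_range,utr3_length_range UTR length ranges (nt).
#' @param polya_length Poly(A) tail appended to each read (nt).
#' @param dup_divergence Divergence of duplicate/pseudogene copies from
#'   their template, applied at synonymous codon positions and non-coding
#'   bases so the encoded protein is preserved.
#' @param low_quality_read_frac Fraction of reads given uniformly low
#'   (Q < 10) quality tracks.
#' @param gene_spacing Minimum genomic gap between placed genes (bp).
#' @param seed Integer seed fixing the full output bit-exactly.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 2L, n_unplaced_scaffolds = 2L,
                       chromosome_length = 100000L, scaffold_length = 20000L,
                       n_genes = 12L, frac_duplicated = 0.1, frac_pseudogene = 0.05,
                       full_length_prob = 0.75, truncation_geometric_p = 0.01,
                       expression_zipf = 1.0, rare_gene_freq = NULL,
                       editing_rate = 0.001, polymorphism_rate = 0.001,
                       seq_error_rate = 0.0005, n_reads = 300L, read_length = 2000L,
                       n_exons_range = c(1L, 3L), exon_length_range = c(150L, 400L),
                       intron_length_range = c(200L, 1500L),
                       utr5_length_range = c(10L, 60L), utr3_length_range = c(60L, 150L),
                       polya_length = 20L, dup_divergence = 0.01,
                       low_quality_read_frac = 0.02, gene_spacing = 2000L,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("frac_duplicated", "frac_pseudogene", "full_length_prob",
             "truncation_geometric_p", "editing_rate", "polymorphism_rate",
             "seq_error_rate", "low_quality_read_frac")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) cm_stop("%s must be in [0, 1]", p)
  }
  if (!is.null(rare_gene_freq) && (rare_gene_freq <= 0 || rare_gene_freq >= 1)) {
    cm_stop("rare_gene_freq must be in (0, 1)")
  }
  for (p in c("n_chromosomes", "chromosome_length", "n_genes", "n_reads",
              "read_length", "gene_spacing")) {
    if (cfg[[p]] < 1) cm_stop("%s must be positive", p)
  }
  if (n_unplaced_scaffolds < 0) cm_stop("n_unplaced_scaffolds must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Zipf expression frequencies
#'
#' Rank-frequency law `p_r` proportional to `r^-s` over `n` genes. If
#' `rare_gene_freq` is given, the last rank is pinned to exactly that
#' frequency and the remaining mass is rescaled.
#'
#' @param n Number of genes.
#' @param s Zipf exponent.
#' @param rare_gene_freq Optional forced frequency of rank `n`.
#' @return Numeric vector of frequencies summing to 1 (rank order).
#' @export
zipf_frequencies <- function(n, s = 1, rare_gene_freq = NULL) {
  p <- (seq_len(n))^(-s)
  p <- p / sum(p)
  if (!is.null(rare_gene_freq)) {
    if (n < 2) cm_stop("rare_gene_freq requires at least 2 genes")
    p <- p[-n] / sum(p[-n]) * (1 - rare_gene_freq)
    p <- c(p, rare_gene_freq)
  }
  p
}

#' Draw source genes for reads under an expression law
#'
#' The sampling step of [simulate_reads()], exposed so that detection /
#' frequency-recovery properties can be studied at scale without
#' synthesising sequences.
#'
#' @param freqs Per-gene frequencies (sum to 1).
#' @param n_reads Number of reads.
#' @return Integer vector of gene indices, length `n_reads`.
#' @export
draw_source_genes <- function(freqs, n_reads) {
  sample.int(length(freqs), n_reads, replace = TRUE, prob = freqs)
}

# Build one transcript: 5'UTR + (ATG, non-stop codons, stop) + 3'UTR.
# Returns list(seq, utr5, cds_len).
build_transcript <- function(tx_len, utr5, utr3) {
  cds_len <- tx_len - utr5 - utr3
  cds_len <- cds_len - (cds_len %% 3L)
  utr3 <- tx_len - utr5 - cds_len
  codons <- names(Biostrings::GENETIC_CODE)
  nonstop <- setdiff(codons, STOP_CODONS)
  n_mid <- cds_len / 3L - 2L
  cds <- paste0("ATG", paste(sample(nonstop, n_mid, replace = TRUE), collapse = ""),
                sample(STOP_CODONS, 1L))
  u5 <- random_dna(utr5)
  if (utr5 >= 3L) {
    # in-frame stop immediately upstream of the CDS so no upstream ATG can
    # extend the reading frame past the true start codon
    substr(u5, utr5 - 2L, utr5) <- sample(STOP_CODONS, 1L)
  }
  list(seq = paste0(u5, cds, random_dna(utr3)),
       utr5 = utr5, cds_len = cds_len)
}

# Synonymous + non-coding divergence of a copied transcript. Peptide is
# preserved exactly; nucleotide sequence diverges at ~rate per base.
diverge_transcript <- function(seq, utr5, cds_len, rate) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  # non-coding positions: independent substitutions
  nc <- c(seq_len(utr5), seq((utr5 + cds_len + 1L), n))
  hit <- nc[runif(length(nc)) < rate]
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  # internal codons: synonymous swaps at ~3*rate per codon
  n_codons <- cds_len / 3L
  for (k in seq(2L, n_codons - 1L)) {
    if (runif(1) < 3 * rate) {
      at <- utr5 + (k - 1L) * 3L + 1L
      cod <- paste(chars[at:(at + 2L)], collapse = "")
      syn <- setdiff(by_aa[[gc[[cod]]]], cod)
      if (length(syn)) chars[at:(at + 2L)] <- strsplit(sample(syn, 1L), "")[[1]]
    }
  }
  paste(chars, collapse = "")
}

# Insert a premature stop near the middle of the CDS.
pseudogenize_transcript <- function(seq, utr5, cds_len) {
  chars <- strsplit(seq, "")[[1]]
  k <- floor(cds_len / 3L / 2L)  # codon index (1-based), ~mid-CDS
  at <- utr5 + (k - 1L) * 3L + 1L
  chars[at:(at + 2L)] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
  paste(chars, collapse = "")
}

#' Simulate a toy draft genome with gene models
#'
#' Builds random chromosome and unplaced-scaffold sequences, constructs
#' spliced gene models on both strands (optionally with near-identical
#' duplicate copies and pseudogenized copies carrying a premature stop),
#' writes the exonic transcript sequence into the genome, chooses fixed
#' A-to-G editing sites on each transcript, and records everything in a
#' ground-truth ledger. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `cdna_sim` with elements `genome`
#'   ([Biostrings::DNAStringSet]), `models` (gene-model `data.frame` with
#'   list-column `exons`, 0-based half-open), `truth` (ledger: transcripts,
#'   proteins, editing sites, homolog and GO maps, chromosome lengths) and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_private_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  n_dup <- round(config$frac_duplicated * config$n_genes)
  n_pseudo <- round(config$frac_pseudogene * config$n_genes)
  n_orig <- config$n_genes - n_dup - n_pseudo
  if (n_orig < 1) cm_stop("n_genes too small for requested duplicate/pseudogene fractions")

  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  scaf_names <- if (config$n_unplaced_scaffolds > 0)
    paste0("scaffold_", seq_len(config$n_unplaced_scaffolds)) else character()
  chrom_lengths <- setNames(
    c(rep(config$chromosome_length, config$n_chromosomes),
      rep(config$scaffold_length, length(scaf_names))),
    c(chrom_names, scaf_names))

  # --- transcripts -----------------------------------------------------
  kinds <- c(rep("original", n_orig), rep("duplicate", n_dup), rep("pseudogene", n_pseudo))
  transcripts <- character(config$n_genes)
  meta <- vector("list", config$n_genes)
  min_cds <- 240L  # >= 78-aa peptide, comfortably above the 50-score floor
  for (i in seq_len(config$n_genes)) {
    if (kinds[i] == "original") {
      n_ex <- sample(config$n_exons_range[1]:config$n_exons_range[2], 1L)
      ex_len <- sample(config$exon_length_range[1]:config$exon_length_range[2],
                       n_ex, replace = TRUE)
      utr5 <- sample(config$utr5_length_range[1]:config$utr5_length_range[2], 1L)
      utr3 <- sample(config$utr3_length_range[1]:config$utr3_length_range[2], 1L)
      deficit <- (utr5 + utr3 + min_cds) - sum(ex_len)
      if (deficit > 0) ex_len[n_ex] <- ex_len[n_ex] + deficit
      tx <- build_transcript(sum(ex_len), utr5, utr3)
      transcripts[i] <- tx$seq
      meta[[i]] <- list(template = NA_integer_, ex_len = ex_len,
                        utr5 = tx$utr5, cds_len = tx$cds_len)
    } else {
      tmpl <- sample.int(n_orig, 1L)
      m <- meta[[tmpl]]
      seq <- diverge_transcript(transcripts[tmpl], m$utr5, m$cds_len,
                                config$dup_divergence)
      if (kinds[i] == "pseudogene") seq <- pseudogenize_transcript(seq, m$utr5, m$cds_len)
      transcripts[i] <- seq
      # copies get a fresh (possibly single-exon) structure of the same total length
      meta[[i]] <- list(template = tmpl, ex_len = m$ex_len, utr5 = m$utr5,
                        cds_len = m$cds_len)
    }
  }

  # --- placement -------------------------------------------------------
  cursors <- setNames(rep(config$gene_spacing, config$n_chromosomes), chrom_names)
  template_chrom <- character(config$n_genes)
  rows <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    m <- meta[[i]]
    n_ex <- length(m$ex_len)
    introns <- if (n_ex > 1)
      sample(config$intron_length_range[1]:config$intron_length_range[2],
             n_ex - 1L, replace = TRUE) else integer()
    footprint <- sum(m$ex_len) + sum(introns)
    avoid <- if (!is.na(m$template)) template_chrom[m$template] else NA_character_
    room <- config$chromosome_length - cursors - footprint - config$gene_spacing
    cand <- names(room)[room > 0]
    if (!length(cand)) cm_stop("genes requested exceed placeable capacity")
    pref <- setdiff(cand, avoid)
    chrom <- if (length(pref)) pref[which.max(room[pref])] else cand[which.max(room[cand])]
    start <- cursors[[chrom]]
    ex_start <- start + cumsum(c(0L, head(m$ex_len, -1L) + introns))
    exons <- cbind(start = as.integer(ex_start),
                   end = as.integer(ex_start + m$ex_len))
    cursors[[chrom]] <- start + footprint + config$gene_spacing
    template_chrom[i] <- chrom
    strand <- sample(c("+", "-"), 1L)
    rows[[i]] <- data.frame(
      gene_id = sprintf("gene%03d", i), chromosome = chrom, strand = strand,
      tx_length = nchar(transcripts[i]), cds_start_offset = m$utr5,
      cds_length = m$cds_len,
      protein_id = sprintf("prot%03d", if (is.na(m$template)) i else m$template),
      is_pseudogene = kinds[i] == "pseudogene",
      duplicate_of = if (is.na(m$template)) NA_character_
                     else sprintf("gene%03d", m$template),
      stringsAsFactors = FALSE)
    rows[[i]]$exons <- list(exons)
  }
  models <- do.call(rbind, rows)

  # --- genome sequence -------------------------------------------------
  seqs <- vapply(chrom_lengths, random_dna, character(1))
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    pos <- tx_to_genome(g)  # genomic 0-based position of each transcript base
    base <- strsplit(transcripts[i], "")[[1]]
    if (g$strand == "-") base <- chartr("ACGT", "TGCA", base)  # per-base complement
    chars[[g$chromosome]][pos + 1L] <- base
  }
  genome <- Biostrings::DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
  names(genome) <- names(chrom_lengths)

  # --- editing sites ---------------------------------------------------
  ed <- list()
  for (i in seq_len(nrow(models))) {
    tx <- strsplit(transcripts[i], "")[[1]]
    n <- length(tx)
    elig <- which(tx == "A")
    elig <- elig[elig > 5L & elig <= n - 5L]
    sites <- elig[runif(length(elig)) < config$editing_rate]
    if (length(sites)) {
      pos <- tx_to_genome(models[i, ])[sites]
      ed[[length(ed) + 1L]] <- data.frame(
        gene_id = models$gene_id[i], tx_pos = sites - 1L,
        chromosome = models$chromosome[i], genome_pos = pos,
        strand = models$strand[i], stringsAsFactors = FALSE)
    }
  }
  editing_sites <- if (length(ed)) do.call(rbind, ed) else
    data.frame(gene_id = character(), tx_pos = integer(), chromosome = character(),
               genome_pos = integer(), strand = character(), stringsAsFactors = FALSE)

  # --- reference tables (proteins, homolog groups, GO) ----------------
  orig <- which(kinds == "original")
  proteins <- setNames(vapply(orig, function(i) {
    m <- meta[[i]]
    cds <- substr(transcripts[i], m$utr5 + 1L, m$utr5 + m$cds_len)
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    sub("\\*$", "", pep)
  }, character(1)), sprintf("prot%03d", orig))

  has_group <- runif(length(orig)) >= 0.1
  homolog_map <- data.frame(
    gene_id = models$gene_id[orig][has_group],
    group_id = sprintf("HG%04d", seq_len(sum(has_group))),
    stringsAsFactors = FALSE)

  namespaces <- c("molecular_function", "cellular_component", "biological_process")
  vocab <- expand.grid(ns = namespaces, k = 1:6, stringsAsFactors = FALSE)
  go <- list()
  for (i in orig) {
    for (ns in namespaces) {
      n_terms <- sample(0:3, 1L, prob = c(0.2, 0.4, 0.3, 0.1))
      if (n_terms == 0) next
      ks <- sample(1:6, n_terms)
      go[[length(go) + 1L]] <- data.frame(
        gene_id = models$gene_id[i], namespace = ns,
        term_id = sprintf("GO:%s%02d", toupper(substr(ns, 1, 2)), ks),
        term_name = sprintf("%s term %d", ns, ks), stringsAsFactors = FALSE)
    }
  }
  go_map <- do.call(rbind, go)

  truth <- list(transcripts = setNames(transcripts, models$gene_id),
                proteins = proteins, editing_sites = editing_sites,
                homolog_map = homolog_map, go_map = go_map,
                chrom_lengths = chrom_lengths,
                scaffold_prefix = "scaffold_")
  structure(list(genome = genome, models = models, truth = truth, config = config),
            class = "cdna_sim")
}

#' Genomic position of each transcript base
#'
#' Maps transcript coordinates (0-based, 5' to 3') to genomic 0-based
#' positions through the model's exon structure, honouring strand.
#'
#' @param model One row of the gene-model `data.frame`.
#' @return Integer vector of genomic positions, length `tx_length`.
#' @export
tx_to_genome <- function(model) {
  ex <- model$exons[[1]]
  per_exon <- lapply(seq_len(nrow(ex)), function(j) seq(ex[j, 1], ex[j, 2] - 1L))
  if (model$strand == "+") {
    as.integer(unlist(per_exon))
  } else {
    as.integer(unlist(lapply(rev(per_exon), rev)))
  }
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates exon sequences in transcription order (reverse-complemented
#' for minus-strand genes).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param model One row of the gene-model `data.frame`.
#' @return Character scalar transcript sequence.
#' @export
transcript_sequence <- function(genome, model) {
  seq <- as.character(genome[[model$chromosome]])
  pos <- tx_to_genome(model)
  base <- strsplit(seq, "")[[1]][pos + 1L]
  if (model$strand == "-") base <- chartr("ACGT", "TGCA", base)
  paste(base, collapse = "")
}

#' Simulate 5'-anchored cDNA reads from a synthetic genome
#'
#' Each read is drawn from a gene under a Zipf expression law; with
#' probability `full_length_prob` it begins at the transcription start,
#' otherwise it is 5'-truncated past the start region (5'UTR plus the first
#' ten codons) by an additional geometric offset, so truncated clones never
#' retain a usable CDS start. Editing sites appear as G, a poly(A) tail is
#' appended, and per-molecule polymorphism and sequencing-error
#' substitutions are applied. Deterministic under `config$seed`.
#'
#' @param sim A `cdna_sim` from [simulate_genome()].
#' @param config A [sim_config()]; defaults to the one inside `sim`.
#' @return List with `reads` ([Biostrings::DNAStringSet]), `quals` (named
#'   list of integer vectors) and `truth` (`data.frame`: read id, source
#'   gene, completeness flag, truncation offset, per-read event counts,
#'   plus attributes `gene_freq` and the per-read polymorphism /
#'   error position ledger).
#' @export
simulate_reads <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "cdna_sim"), inherits(config, "sim_config"))
  with_private_seed(config$seed + 1L, simulate_reads_impl(sim, config))
}

simulate_reads_impl <- function(sim, config) {
  models <- sim$models
  n_genes <- nrow(models)
  ranks <- sample.int(n_genes)  # random rank assignment
  freqs_by_rank <- zipf_frequencies(n_genes, config$expression_zipf,
                                    config$rare_gene_freq)
  gene_freq <- freqs_by_rank[ranks]
  draws <- draw_source_genes(gene_freq, config$n_reads)

  # edited transcript per gene (sites fully penetrant)
  tx <- sim$truth$transcripts
  ed <- sim$truth$editing_sites
  tx_ed <- tx
  for (g in unique(ed$gene_id)) {
    chars <- strsplit(tx_ed[[g]], "")[[1]]
    chars[ed$tx_pos[ed$gene_id == g] + 1L] <- "G"
    tx_ed[[g]] <- paste(chars, collapse = "")
  }

  bases <- c("A", "C", "G", "T")
  reads <- character(config$n_reads)
  quals <- vector("list", config$n_reads)
  poly_pos <- vector("list", config$n_reads)
  err_pos <- vector("list", config$n_reads)
  info <- vector("list", config$n_reads)
  for (i in seq_len(config$n_reads)) {
    gi <- draws[i]
    g <- models[gi, ]
    t_full <- tx_ed[[g$gene_id]]
    full <- runif(1) < config$full_length_prob
    offset <- 0L
    if (!full) {
      offset <- g$cds_start_offset + 31L + rgeom(1L, config$truncation_geometric_p)
      offset <- min(offset, max(0L, g$tx_length - 60L))
    }
    seq <- paste0(substr(t_full, offset + 1L, g$tx_length),
                  strrep("A", config$polya_length))
    chars <- strsplit(seq, "")[[1]]
    if (length(chars) > config$read_length) chars <- chars[seq_len(config$read_length)]
    pp <- which(runif(length(chars)) < config$polymorphism_rate)
    for (j in pp) chars[j] <- sample(setdiff(bases, chars[j]), 1L)
    ee <- which(runif(length(chars)) < config$seq_error_rate)
    for (j in ee) chars[j] <- sample(setdiff(bases, chars[j]), 1L)
    reads[i] <- paste(chars, collapse = "")
    n <- length(chars)
    if (runif(1) < config$low_quality_read_frac) {
      quals[[i]] <- sample(0:9, n, replace = TRUE)
    } else {
      quals[[i]] <- pmin(pmax(as.integer(round(rnorm(n, 35, 5))), 2L), 60L)
    }
    poly_pos[[i]] <- pp - 1L
    err_pos[[i]] <- ee - 1L
    info[[i]] <- data.frame(
      read_id = sprintf("read%05d", i), gene_id = g$gene_id,
      is_full_length = offset == 0L, truncation_offset = offset,
      n_polymorphisms = length(pp), n_errors = length(ee),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, info)
  attr(truth, "gene_freq") <- setNames(gene_freq, models$gene_id)
  attr(truth, "polymorphism_pos") <- setNames(poly_pos, truth$read_id)
  attr(truth, "error_pos") <- setNames(err_pos, truth$read_id)
  out_reads <- Biostrings::DNAStringSet(reads)
  names(out_reads) <- truth$read_id
  list(reads = out_reads, quals = setNames(quals, truth$read_id), truth = truth)
}

#' Write a simulation to disk
#'
#' Emits genome FASTA, reads FASTA, phred-style qualities, truth GFF3 and
#' truth TSV ledgers into a directory.
#'
#' @param sim A `cdna_sim`.
#' @param reads Result of [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_fasta(reads$reads, file.path(dir, "reads.fa"))
  write_quality(reads$quals, file.path(dir, "reads.qual"))
  write_truth_gff(sim$models, file.path(dir, "truth.gff3"), sim$truth$chrom_lengths)
  write_report_tsv(reads$truth, file.path(dir, "read_truth.tsv"))
  write_report_tsv(sim$truth$editing_sites, file.path(dir, "editing_sites.tsv"))
  invisible(dir)
}
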