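# RNA-editing and draft-accuracy estimation from cDNA/genome comparison:
# flank-validated A-to-G counting against the symmetric G-to-A background,
# the excess-asymmetry editing fraction, and 3'-UTR mismatch rates.

#' Best-aligned region of a cDNA
#'
#' Selects, among a query's alignment blocks, the one covering the largest
#' fraction of the cDNA (ties go to higher identity). Returns `NULL` when
#' the query has no alignments (unalignable; excluded from reports).
#'
#' @param aln Alignment records of one query.
#' @param query_length Length of the cDNA (bp).
#' @return One-row alignment `data.frame`, or `NULL`.
#' @export
best_aligned_region <- function(aln, query_length) {
  if (is.null(aln) || !nrow(aln)) return(NULL)
  cov <- (aln$qend - aln$qstart) / query_length
  o <- order(-cov, -aln$pident, aln$subject_id, aln$sstart)
  aln[o[1], , drop = FALSE]
}

#' Base-level pairing of a cDNA with its genomic region
#'
#' Builds the gap-free column pairing implied by an ungapped alignment
#' block, oriented along the cDNA (5' to 3'): minus-strand genomic regions
#' are reverse-complemented once, so a genome-A / cDNA-G column always
#' means A-to-G on the transcribed strand.
#'
#' @param read_seq cDNA sequence (character scalar).
#' @param genome [Biostrings::DNAStringSet].
#' @param aln One-row alignment `data.frame`.
#' @return List of class `cm_pairing` with equal-length character vectors
#'   `genome` and `cdna`, plus `qstart` (read offset of the first column).
#' @export
pairing_from_alignment <- function(read_seq, genome, aln) {
  stopifnot(nrow(aln) == 1L)
  g <- substr(as.character(genome[[aln$subject_id]]), aln$sstart + 1L, aln$send)
  if (aln$strand == "-") g <- revcomp(g)
  cdna <- substr(toupper(read_seq), aln$qstart + 1L, aln$qend)
  stopifnot(nchar(g) == nchar(cdna))
  structure(list(genome = strsplit(toupper(g), "")[[1]],
                 cdna = strsplit(cdna, "")[[1]],
                 qstart = aln$qstart),
            class = "cm_pairing")
}

#' Count flank-validated A-to-G and G-to-A changes
#'
#' A column counts as A-to-G when the genome shows A, the cDNA shows G, and
#' the `flank` columns on each side are all gap-free exact matches; G-to-A
#' is counted symmetrically. Columns too close to either end of the pairing
#' cannot satisfy the flank rule and never count. Gaps (`-`) disqualify
#' both the column itself and any flank window containing them.
#'
#' @param pairing A pairing (list with `genome`, `cdna`), e.g. from
#'   [pairing_from_alignment()].
#' @param flank Required exact-match flank length on each side.
#' @return Named integer vector `c(n_AG = ..., n_GA = ...)`.
#' @export
count_flanked_changes <- function(pairing, flank = 5L) {
  g <- toupper(pairing$genome)
  d <- toupper(pairing$cdna)
  n <- length(g)
  stopifnot(length(d) == n)
  if (n < 2L * flank + 1L) return(c(n_AG = 0L, n_GA = 0L))
  m <- g == d & g != "-" & d != "-"
  cm <- cumsum(m)
  idx <- (flank + 1L):(n - flank)
  left_ok <- (cm[idx - 1L] - c(0L, cm)[idx - flank]) == flank
  right_ok <- (cm[idx + flank] - cm[idx]) == flank
  ok <- left_ok & right_ok
  ag <- g[idx] == "A" & d[idx] == "G" & ok
  ga <- g[idx] == "G" & d[idx] == "A" & ok
  c(n_AG = sum(ag), n_GA = sum(ga))
}

#' Excess-asymmetry editing fraction
#'
#' Under a symmetric background (polymorphism, sequencing error, draft
#' errors) A-to-G and G-to-A discordances are equally likely; A-to-I
#' editing adds A-to-G only. The excess asymmetry
#' `(n_AG - n_GA) / (n_AG + n_GA)` therefore estimates the fraction of the
#' combined A/G discordance attributable to editing. Raw counts should
#' always be reported alongside.
#'
#' @param n_AG_total,n_GA_total Flank-validated change totals.
#' @return The editing fraction in `[-1, 1]`.
#' @export
editing_fraction <- function(n_AG_total, n_GA_total) {
  if (n_AG_total < 0 || n_GA_total < 0) cm_stop("counts must be non-negative")
  if (n_AG_total + n_GA_total == 0) {
    cm_stop("no flank-validated changes: editing fraction undefined")
  }
  (n_AG_total - n_GA_total) / (n_AG_total + n_GA_total)
}

#' Per-cDNA editing report
#'
#' Applies [count_flanked_changes()] to each query's pairing and summarises
#' the totals, the counts of cDNAs carrying only A-to-G or only G-to-A
#' changes, and the excess-asymmetry editing fraction.
#'
#' @param pairings Named list of pairings (one per query).
#' @param flank Flank length.
#' @return List with `per_query` (`data.frame`: query_id, n_AG, n_GA,
#'   only_AG, only_GA) and `summary` (totals, `only_AG_cdnas`,
#'   `only_GA_cdnas`, `editing_fraction`; fraction is `NA` when no changes
#'   were seen).
#' @export
editing_report <- function(pairings, flank = 5L) {
  rows <- lapply(names(pairings), function(id) {
    ct <- count_flanked_changes(pairings[[id]], flank)
    data.frame(query_id = id, n_AG = ct[["n_AG"]], n_GA = ct[["n_GA"]],
               only_AG = ct[["n_AG"]] > 0L && ct[["n_GA"]] == 0L,
               only_GA = ct[["n_GA"]] > 0L && ct[["n_AG"]] == 0L,
               stringsAsFactors = FALSE)
  })
  per_query <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), n_AG = integer(), n_GA = integer(),
               only_AG = logical(), only_GA = logical(), stringsAsFactors = FALSE)
  tot_ag <- sum(per_query$n_AG); tot_ga <- sum(per_query$n_GA)
  frac <- if (tot_ag + tot_ga > 0) editing_fraction(tot_ag, tot_ga) else NA_real_
  list(per_query = per_query,
       summary = list(n_AG_total = tot_ag, n_GA_total = tot_ga,
                      only_AG_cdnas = sum(per_query$only_AG),
                      only_GA_cdnas = sum(per_query$only_GA),
                      editing_fraction = frac))
}

#' 3'-UTR interval of a cDNA
#'
#' The region between the end of the longest forward-frame ORF (stop codon
#' included in the ORF) and the first poly(A) run of at least
#' `polya_min` A's at or after it (sequence end if none).
#'
#' @param sequence cDNA sequence.
#' @param polya_min Minimum poly(A) run length marking the tail.
#' @return Integer vector `c(start, end)`, 0-based half-open on the cDNA;
#'   `NULL` when the sequence has no ORF.
#' @export
utr3_interval <- function(sequence, polya_min = 8L) {
  coords <- longest_orf_coords(sequence)
  if (is.null(coords)) return(NULL)
  s <- toupper(sequence)
  tail_at <- regexpr(strrep("A", polya_min), substr(s, coords[2] + 1L, nchar(s)),
                     fixed = TRUE)
  end <- if (tail_at > 0L) coords[2] + as.integer(tail_at) - 1L else nchar(s)
  c(coords[2], end)
}

# 0-based half-open coordinates of the longest forward-frame ORF
# (ATG..stop, stop codon included), or NULL.
longest_orf_coords <- function(sequence) {
  orf <- best_orf(sequence)
  if (is.null(orf)) return(NULL)
  c(orf$start, orf$end)
}

#' 3'-UTR mismatch rate against the genome
#'
#' Per-query mismatch counts over the aligned 3'-UTR columns and the
#' aggregate rate (total mismatches over total aligned UTR columns), with
#' the count of perfectly matching UTRs -- the draft-accuracy estimate.
#'
#' @param utr_pairings Named list of pairings restricted to 3'-UTR columns.
#' @return List with `per_query` (`data.frame`: query_id, utr_length,
#'   n_mismatches, perfect_match), `aggregate_rate`, `n_perfect`,
#'   `n_total`.
#' @export
utr_mismatch_rate <- function(utr_pairings) {
  rows <- lapply(names(utr_pairings), function(id) {
    p <- utr_pairings[[id]]
    n <- length(p$genome)
    mm <- sum(toupper(p$genome) != toupper(p$cdna))
    data.frame(query_id = id, utr_length = n, n_mismatches = mm,
               perfect_match = mm == 0L, stringsAsFactors = FALSE)
  })
  per_query <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), utr_length = integer(),
               n_mismatches = integer(), perfect_match = logical(),
               stringsAsFactors = FALSE)
  total_cols <- sum(per_query$utr_length)
  list(per_query = per_query,
       aggregate_rate = if (total_cols > 0) sum(per_query$n_mismatches) / total_cols
                        else NA_real_,
       n_perfect = sum(per_query$perfect_match),
       n_total = nrow(per_query))
}

#' Truth-guided pairings for estimator validation
#'
#' Builds, for each read, the spliced cDNA/genome pairing implied by the
#' generator's ground truth (read placed at its known transcript offset,
#' genome read through the known exon structure). This bypasses alignment
#' so that the flank counter and editing-fraction estimator can be
#' validated against configured rates without aligner noise; the poly(A)
#' tail is excluded.
#'
#' @param sim A `cdna_sim` from [simulate_genome()].
#' @param reads Result of [simulate_reads()].
#' @return Named list of pairings (class `cm_pairing`).
#' @export
truth_pairings <- function(sim, reads) {
  gchars <- lapply(as.character(sim$genome), function(s) strsplit(s, "")[[1]])
  out <- list()
  for (i in seq_len(nrow(reads$truth))) {
    tr <- reads$truth[i, ]
    g <- sim$models[sim$models$gene_id == tr$gene_id, ]
    pos <- tx_to_genome(g)
    off <- tr$truncation_offset
    span <- seq(off + 1L, g$tx_length)
    rseq <- strsplit(as.character(reads$reads[[tr$read_id]]), "")[[1]]
    span <- span[seq_len(min(length(span), length(rseq)))]
    gb <- gchars[[g$chromosome]][pos[span] + 1L]
    if (g$strand == "-") gb <- chartr("ACGT", "TGCA", gb)
    out[[tr$read_id]] <- structure(
      list(genome = gb, cdna = rseq[seq_along(span)], qstart = 0L),
      class = "cm_pairing")
  }
  out
}
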