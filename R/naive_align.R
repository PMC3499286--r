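# Naive seed-and-extend aligner for synthetic tests.
#
# Exact k-mer seeds are located with Biostrings pattern matching and
# extended ungapped with an X-drop rule. This deliberately small aligner
# exists so the pipeline can be exercised end-to-end on simulated data; it
# consumes and produces the same 12-column-style alignment records as an
# external similarity search would.

#' Align reads to a genome by exact seeding and ungapped extension
#'
#' Both strands are searched; the simulator introduces no indels, so
#' ungapped extension recovers exon-level alignment blocks whose mismatch
#' columns reflect polymorphism, sequencing error and editing. Scoring is
#' +1 per match and -2 per mismatch; extension stops when the running score
#' drops `xdrop` below its maximum.
#'
#' @param reads Named character vector or [Biostrings::DNAStringSet].
#' @param genome [Biostrings::DNAStringSet] of chromosome/scaffold
#'   sequences.
#' @param seed_len Seed length (bp).
#' @param seed_step Seed sampling stride along the read (bp).
#' @param xdrop X-drop threshold for extension.
#' @param min_block Minimum block length to report (bp).
#' @return Alignment-record `data.frame` (see [alignment_records()]);
#'   query coordinates are on the read as given, minus-strand blocks mean
#'   the reverse complement of the read matches the forward genome.
#' @export
align_reads <- function(reads, genome, seed_len = 20L, seed_step = 40L,
                        xdrop = 12L, min_block = 30L) {
  seqs <- as_seq_chars(reads)
  seqs <- setNames(toupper(seqs), names(seqs))  # toupper also drops names
  gchars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  out <- list()
  for (id in names(seqs)) {
    for (strand in c("+", "-")) {
      r <- if (strand == "+") seqs[[id]] else revcomp(seqs[[id]])
      blocks <- align_one(r, genome, gchars, seed_len, seed_step, xdrop, min_block)
      if (is.null(blocks)) next
      L <- nchar(r)
      if (strand == "-") {
        qs <- L - blocks$qend
        qe <- L - blocks$qstart
        blocks$qstart <- qs
        blocks$qend <- qe
      }
      blocks$strand <- strand
      blocks$query_id <- id
      out[[length(out) + 1L]] <- blocks
    }
  }
  if (!length(out)) {
    return(alignment_records(character(), character(), integer(), integer())[0, ])
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  alignment_records(query_id = res$query_id, subject_id = res$subject_id,
                    sstart = res$sstart, send = res$send, strand = res$strand,
                    qstart = res$qstart, qend = res$qend, score = res$score,
                    pident = res$pident, aln_length = res$send - res$sstart,
                    mismatch = res$mismatch)
}

# Align one oriented read against the forward genome; returns blocks with
# 0-based half-open read/genome coordinates, or NULL.
align_one <- function(r, genome, gchars, seed_len, seed_step, xdrop, min_block) {
  L <- nchar(r)
  if (L < seed_len) return(NULL)
  rchars <- strsplit(r, "")[[1]]
  starts <- unique(c(seq(1L, L - seed_len + 1L, by = seed_step), L - seed_len + 1L))
  blocks <- list()
  seen <- character()
  for (p in starts) {
    seed <- substr(r, p, p + seed_len - 1L)
    if (grepl("N", seed, fixed = TRUE)) next
    hits <- Biostrings::vmatchPattern(seed, genome)
    for (ci in seq_along(hits)) {
      hs <- Biostrings::startIndex(hits)[[ci]]
      if (is.null(hs) || !length(hs)) next
      chrom <- names(genome)[ci]
      gc <- gchars[[chrom]]
      for (h in hs) {
        # extend from seed: read pos p..p+k-1 ~ genome pos h..h+k-1 (1-based)
        ext <- extend_ungapped(rchars, gc, p, h, seed_len, xdrop)
        key <- sprintf("%s:%d:%d", chrom, ext$sstart, ext$send)
        if (key %in% seen) next
        seen <- c(seen, key)
        len <- ext$qend - ext$qstart
        if (len < min_block) next
        blocks[[length(blocks) + 1L]] <- data.frame(
          subject_id = chrom, qstart = ext$qstart, qend = ext$qend,
          sstart = ext$sstart, send = ext$send, score = ext$score,
          pident = 100 * ext$matches / len, mismatch = len - ext$matches,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(blocks)) return(NULL)
  do.call(rbind, blocks)
}

# Ungapped X-drop extension around an exact seed.
# p, h are 1-based read/genome seed starts; returns 0-based half-open coords.
extend_ungapped <- function(rchars, gc, p, h, k, xdrop) {
  score_path <- function(idx_r, idx_g) {
    if (!length(idx_r)) return(0L)
    m <- rchars[idx_r] == gc[idx_g]
    cum <- cumsum(ifelse(m, 1L, -2L))
    peak <- cummax(cum)
    stop_at <- which(peak - cum > xdrop)
    lim <- if (length(stop_at)) stop_at[1] - 1L else length(cum)
    if (lim == 0L) return(0L)
    which.max(cum[seq_len(lim)])
  }
  # rightward from seed end
  nr <- min(length(rchars) - (p + k - 1L), length(gc) - (h + k - 1L))
  right <- if (nr > 0) score_path((p + k):(p + k - 1L + nr), (h + k):(h + k - 1L + nr)) else 0L
  # leftward from seed start
  nl <- min(p - 1L, h - 1L)
  left <- if (nl > 0) score_path((p - 1L):(p - nl), (h - 1L):(h - nl)) else 0L
  qs <- p - left; qe <- p + k - 1L + right
  ss <- h - left; se <- h + k - 1L + right
  m <- sum(rchars[qs:qe] == gc[ss:se])
  len <- qe - qs + 1L
  list(qstart = qs - 1L, qend = qe, sstart = ss - 1L, send = se,
       matches = m, score = m - 2L * (len - m))
}
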