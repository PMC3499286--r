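# Transcript-to-genome locus assignment: anchor the best alignment of each
# query, extend the locus with compatible same-strand alignments of the same
# query (possible introns), merge overlapping same-strand loci, and tabulate
# per-chromosome/strand counts and sliding-window densities.

#' Mapping thresholds
#'
#' The anchoring thresholds (score strictly above `min_score`, identity
#' strictly above `min_identity_pct`) and the maximum genomic gap bridged
#' during locus extension (an intron-scale bound).
#'
#' @param min_score Minimum anchor score (strict).
#' @param min_identity_pct Minimum anchor percent identity (strict).
#' @param max_gap Maximum gap (bp) between an alignment and the growing
#'   locus region during extension (strict upper bound).
#' @return A `mapping_thresholds` list.
#' @export
mapping_thresholds <- function(min_score = 100, min_identity_pct = 90,
                               max_gap = 1000000L) {
  if (min_score <= 0 || min_identity_pct <= 0 || max_gap <= 0) {
    cm_stop("mapping thresholds must be positive")
  }
  structure(list(min_score = min_score, min_identity_pct = min_identity_pct,
                 max_gap = as.integer(max_gap)), class = "mapping_thresholds")
}

#' Select the anchor alignment of a query
#'
#' Among a query's alignments with score strictly above `min_score` and
#' identity strictly above `min_identity_pct`, returns the one with maximal
#' score; ties go to higher identity, then longer alignment, then smallest
#' (subject, start). Returns `NULL` when no alignment qualifies (the query
#' is unmapped).
#'
#' @param aln Alignment records of a single query (see
#'   [alignment_records()]).
#' @param thresholds A [mapping_thresholds()].
#' @return A single-row alignment `data.frame`, or `NULL`.
#' @export
select_anchor <- function(aln, thresholds = mapping_thresholds()) {
  if (!nrow(aln)) return(NULL)
  if (length(unique(aln$query_id)) != 1L) {
    cm_stop("select_anchor expects alignments of a single query")
  }
  ok <- aln$score > thresholds$min_score & aln$pident > thresholds$min_identity_pct
  if (!any(ok)) return(NULL)
  cand <- aln[ok, , drop = FALSE]
  o <- order(-cand$score, -cand$pident, -cand$aln_length, cand$subject_id, cand$sstart)
  cand[o[1], , drop = FALSE]
}

#' Extend a locus from its anchor
#'
#' Starting from the anchored alignment, iteratively absorbs other
#' alignments of the same query that (1) lie on the same subject sequence
#' and strand and (2) sit less than `max_gap` bp from the current locus
#' region. Absorption runs to a fixpoint, so an absorbed alignment can
#' bridge to further ones (serial introns). The locus interval is the union
#' hull of the absorbed alignments.
#'
#' @param anchor Single-row alignment `data.frame` from [select_anchor()].
#' @param aln All alignment records of the same query.
#' @param thresholds A [mapping_thresholds()].
#' @param scaffold_prefix Subject-name prefix marking unplaced scaffolds.
#' @return One-row locus `data.frame`: `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `n_members`, list-column `members`
#'   (query ids) and `is_unplaced`.
#' @export
extend_locus <- function(anchor, aln, thresholds = mapping_thresholds(),
                         scaffold_prefix = "scaffold_") {
  stopifnot(nrow(anchor) == 1L)
  cand <- aln[aln$query_id == anchor$query_id &
                aln$subject_id == anchor$subject_id &
                aln$strand == anchor$strand, , drop = FALSE]
  lo <- anchor$sstart
  hi <- anchor$send
  used <- rep(FALSE, nrow(cand))
  repeat {
    gap <- pmax(0L, pmax(cand$sstart - hi, lo - cand$send))
    take <- !used & gap < thresholds$max_gap
    if (!any(take)) break
    lo2 <- min(lo, cand$sstart[take])
    hi2 <- max(hi, cand$send[take])
    used <- used | take
    if (lo2 == lo && hi2 == hi) break
    lo <- lo2; hi <- hi2
  }
  locus <- data.frame(locus_id = paste0("locus_", anchor$query_id),
                      chrom = anchor$subject_id, start = lo, end = hi,
                      strand = anchor$strand, n_members = 1L,
                      is_unplaced = startsWith(anchor$subject_id, scaffold_prefix),
                      stringsAsFactors = FALSE)
  locus$members <- list(anchor$query_id)
  locus
}

#' Anchor and extend all queries
#'
#' Runs [select_anchor()] and [extend_locus()] per query over a full
#' alignment table.
#'
#' @param aln Alignment records (all queries).
#' @param thresholds A [mapping_thresholds()].
#' @param scaffold_prefix Subject-name prefix marking unplaced scaffolds.
#' @return Locus `data.frame`, one row per anchored query (unmapped queries
#'   are absent).
#' @export
call_query_loci <- function(aln, thresholds = mapping_thresholds(),
                            scaffold_prefix = "scaffold_") {
  out <- list()
  for (q in unique(aln$query_id)) {
    sub <- aln[aln$query_id == q, , drop = FALSE]
    anchor <- select_anchor(sub, thresholds)
    if (is.null(anchor)) next
    out[[length(out) + 1L]] <- extend_locus(anchor, sub, thresholds, scaffold_prefix)
  }
  if (!length(out)) return(empty_loci())
  do.call(rbind, out)
}

empty_loci <- function() {
  df <- data.frame(locus_id = character(), chrom = character(), start = integer(),
                   end = integer(), strand = character(), n_members = integer(),
                   is_unplaced = logical(), stringsAsFactors = FALSE)
  df$members <- list()
  df
}

#' Merge overlapping same-strand loci
#'
#' Loci are regarded as identical when their extended regions overlap on the
#' same chromosome and strand; overlapping regions on opposite strands stay
#' distinct. Merging is the transitive closure of the overlap relation
#' (implemented as a coordinate sweep per chromosome/strand); the merged
#' interval is the union hull and member sets are unioned. Output order is
#' deterministic: (chromosome, start, strand). Idempotent and
#' permutation-invariant.
#'
#' @param loci Locus `data.frame` from [call_query_loci()].
#' @return Merged locus `data.frame` with fresh sequential `locus_id`s.
#' @export
merge_loci <- function(loci) {
  if (!nrow(loci)) return(empty_loci())
  out <- list()
  for (key in unique(paste(loci$chrom, loci$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    grp <- loci[loci$chrom == parts[1] & loci$strand == parts[2], , drop = FALSE]
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    cur_start <- grp$start[1]; cur_end <- grp$end[1]
    cur_members <- grp$members[[1]]
    flush <- function() {
      row <- data.frame(locus_id = NA_character_, chrom = parts[1],
                        start = cur_start, end = cur_end, strand = parts[2],
                        n_members = length(unique(cur_members)),
                        is_unplaced = grp$is_unplaced[1], stringsAsFactors = FALSE)
      row$members <- list(sort(unique(cur_members)))
      row
    }
    for (i in seq_len(nrow(grp))[-1]) {
      if (grp$start[i] < cur_end) {  # strict overlap required, touching is distinct
        cur_end <- max(cur_end, grp$end[i])
        cur_members <- c(cur_members, grp$members[[i]])
      } else {
        out[[length(out) + 1L]] <- flush()
        cur_start <- grp$start[i]; cur_end <- grp$end[i]
        cur_members <- grp$members[[i]]
      }
    }
    out[[length(out) + 1L]] <- flush()
  }
  merged <- do.call(rbind, out)
  merged <- merged[order(merged$chrom, merged$start, merged$strand), , drop = FALSE]
  merged$locus_id <- sprintf("L%05d", seq_len(nrow(merged)))
  rownames(merged) <- NULL
  merged
}

#' Per-chromosome locus table
#'
#' Counts merged loci by chromosome and strand, with a separate
#' "Unplaced scaffolds" row and a totals row whose cells equal the column
#' sums.
#'
#' @param loci Merged locus `data.frame`.
#' @param chromosomes Optional character vector fixing the chromosome row
#'   order (defaults to the chromosomes observed).
#' @return `data.frame` with columns `chromosome`, `forward`, `reverse`,
#'   `total`; last two rows are "Unplaced scaffolds" and "Total".
#' @export
tabulate_loci <- function(loci, chromosomes = NULL) {
  placed <- loci[!loci$is_unplaced, , drop = FALSE]
  if (is.null(chromosomes)) chromosomes <- sort(unique(placed$chrom))
  count <- function(df, strand) {
    v <- table(factor(df$chrom[df$strand == strand], levels = chromosomes))
    as.integer(v)
  }
  fwd <- count(placed, "+"); rev_ <- count(placed, "-")
  unpl <- loci[loci$is_unplaced, , drop = FALSE]
  rows <- data.frame(chromosome = c(chromosomes, "Unplaced scaffolds"),
                     forward = c(fwd, sum(unpl$strand == "+")),
                     reverse = c(rev_, sum(unpl$strand == "-")),
                     stringsAsFactors = FALSE)
  rows$total <- rows$forward + rows$reverse
  rbind(rows, data.frame(chromosome = "Total", forward = sum(rows$forward),
                         reverse = sum(rows$reverse), total = sum(rows$total),
                         stringsAsFactors = FALSE))
}

#' Sliding-window locus density
#'
#' Counts, for every window `[i*step, i*step + window)` (clipped at the
#' chromosome end), the loci whose interval intersects the window,
#' separately per strand.
#'
#' @param loci Merged locus `data.frame`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window Window width (bp).
#' @param step Window stride (bp).
#' @return `data.frame`: `chrom`, `window_start`, `window_end`, `fwd`,
#'   `rev`.
#' @export
locus_density <- function(loci, chrom_lengths, window = 5000000L, step = 100000L) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    sub <- loci[loci$chrom == chrom, , drop = FALSE]
    fwd <- integer(length(starts)); rev_ <- integer(length(starts))
    for (s in c("+", "-")) {
      ss <- sub[sub$strand == s, , drop = FALSE]
      cnt <- vapply(seq_along(starts), function(i) {
        sum(ss$start < ends[i] & ss$end > starts[i])
      }, integer(1))
      if (s == "+") fwd <- cnt else rev_ <- cnt
    }
    out[[chrom]] <- data.frame(chrom = chrom, window_start = starts,
                               window_end = ends, fwd = fwd, rev = rev_,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
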