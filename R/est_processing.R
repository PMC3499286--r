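# EST-read processing: quality filtering, low-complexity masking, a greedy
# clustering stand-in for a full assembler, contig statistics, clone
# selection for full-insert sequencing, and the detection-miss probability.

#' Quality-filter a read
#'
#' A read is kept if and only if it contains a contiguous run of strictly
#' more than `min_run` bases whose quality is at least `min_q`; a run of
#' exactly `min_run` bases is discarded.
#'
#' @param sequence Read sequence (character scalar), used for the length
#'   check.
#' @param qualities Integer vector of per-base qualities.
#' @param min_run Required run length (strict lower bound).
#' @param min_q Per-base quality threshold (inclusive).
#' @return `TRUE` (kept) or `FALSE` (discarded).
#' @export
quality_filter <- function(sequence, qualities, min_run = 100L, min_q = 10L) {
  if (nchar(sequence) != length(qualities)) {
    cm_stop("sequence length (%d) != quality length (%d)",
            nchar(sequence), length(qualities))
  }
  r <- rle(qualities >= min_q)
  any(r$values & r$lengths > min_run)
}

#' Quality-filter a read set
#'
#' Vectorised [quality_filter()] over matching sequence/quality sets.
#'
#' @param reads Named character vector or [Biostrings::DNAStringSet].
#' @param quals Named list of integer quality vectors.
#' @inheritParams quality_filter
#' @return Named logical vector (`TRUE` = kept).
#' @export
filter_reads <- function(reads, quals, min_run = 100L, min_q = 10L) {
  seqs <- as_seq_chars(reads)
  ids <- names(seqs)
  setNames(vapply(ids, function(id) {
    quality_filter(seqs[[id]], quals[[id]], min_run, min_q)
  }, logical(1)), ids)
}

#' Mask low-complexity tracts
#'
#' Replaces homopolymer runs of at least `homopolymer_min` bases and
#' dinucleotide repeats of at least `dinucleotide_min_units` units by
#' lowercase (soft masking). Length is preserved. This is a deliberately
#' simple screen for poly(A) tracts and microsatellite-like repeats, not a
#' repeat-library-driven masker.
#'
#' @param sequence DNA string.
#' @param homopolymer_min Minimum homopolymer run length to mask.
#' @param dinucleotide_min_units Minimum number of dinucleotide repeat units
#'   to mask.
#' @return The soft-masked sequence.
#' @export
mask_low_complexity <- function(sequence, homopolymer_min = 12L,
                                dinucleotide_min_units = 8L) {
  chars <- strsplit(sequence, "")[[1]]
  mask <- rep(FALSE, length(chars))
  pats <- c(sprintf("([ACGTN])\\1{%d,}", homopolymer_min - 1L),
            sprintf("([ACGTN]{2})\\1{%d,}", dinucleotide_min_units - 1L))
  for (pat in pats) {
    m <- gregexpr(pat, toupper(sequence))[[1]]
    if (m[1] != -1L) {
      for (k in seq_along(m)) {
        span <- m[k]:(m[k] + attr(m, "match.length")[k] - 1L)
        mask[span] <- TRUE
      }
    }
  }
  chars[mask] <- tolower(chars[mask])
  paste(chars, collapse = "")
}

# Ungapped identity of two reads at a fixed relative shift.
# shift = offset of read b relative to read a in the common layout.
overlap_identity <- function(a, b, shift) {
  la <- nchar(a); lb <- nchar(b)
  from <- max(0L, shift); to <- min(la, shift + lb)
  len <- to - from
  if (len <= 0L) return(list(len = 0L, identity = 0))
  sa <- strsplit(toupper(substr(a, from + 1L, to)), "")[[1]]
  sb <- strsplit(toupper(substr(b, from - shift + 1L, to - shift)), "")[[1]]
  list(len = len, identity = 100 * sum(sa == sb) / len)
}

#' Greedy single-linkage EST clustering
#'
#' A documented stand-in for a full overlap assembler: reads are linked when
#' they share an exact seed (of `seed_k` unmasked bases) whose implied
#' ungapped overlap is at least `min_overlap` bases at `min_identity`%
#' identity or better; clusters are the transitive closure of the links.
#' Per-read offsets in the cluster layout come from the accepted pairwise
#' shifts (first verified shift wins, most-supported first), and the
#' consensus is a per-column majority vote (ties broken alphabetically).
#' Deterministic under input order.
#'
#' @param reads Named character vector or [Biostrings::DNAStringSet]
#'   (soft-masked lowercase bases are excluded from seeding but participate
#'   in overlap verification, uppercased).
#' @param min_overlap Minimum ungapped overlap (bp).
#' @param min_identity Minimum percent identity over the overlap.
#' @param seed_k Seed length (bp).
#' @param seed_step Seed sampling stride (bp).
#' @return List with `contigs` (`data.frame`: contig_id, read_id, offset,
#'   read_length; members ordered 5'-most first), `consensus` (named
#'   character) and `singlets` (character ids).
#' @export
cluster_ests <- function(reads, min_overlap = 40L, min_identity = 95,
                         seed_k = 20L, seed_step = 10L) {
  seqs <- as_seq_chars(reads)
  ids <- names(seqs)
  n <- length(seqs)
  if (!n) {
    return(list(contigs = data.frame(contig_id = character(), read_id = character(),
                                     offset = integer(), read_length = integer(),
                                     stringsAsFactors = FALSE),
                consensus = character(), singlets = character()))
  }

  # seed index ----------------------------------------------------------
  seed_tab <- list()
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    L <- nchar(s)
    if (L < seed_k) next
    starts <- seq(1L, L - seed_k + 1L, by = seed_step)
    kmers <- substring(s, starts, starts + seed_k - 1L)
    ok <- !grepl("[a-z]", kmers)
    if (any(ok)) {
      seed_tab[[length(seed_tab) + 1L]] <-
        data.frame(kmer = kmers[ok], read = i, pos = starts[ok] - 1L,
                   stringsAsFactors = FALSE)
    }
  }
  links <- list()
  if (length(seed_tab)) {
    seed_tab <- do.call(rbind, seed_tab)
    shared <- split(seed_tab, seed_tab$kmer)
    shared <- shared[vapply(shared, function(d) length(unique(d$read)) > 1, logical(1))]
    # candidate shifts per unordered read pair
    cand <- list()
    for (d in shared) {
      rs <- split(d$pos, d$read)
      reads_here <- as.integer(names(rs))
      for (ai in seq_along(reads_here)) {
        for (bi in seq_along(reads_here)) {
          if (bi <= ai) next
          a <- reads_here[ai]; b <- reads_here[bi]
          for (pa in rs[[ai]]) for (pb in rs[[bi]]) {
            key <- sprintf("%d:%d", a, b)
            cand[[key]] <- c(cand[[key]], pa - pb)
          }
        }
      }
    }
    for (key in names(cand)) {
      ab <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
      shifts <- cand[[key]]
      tab <- sort(table(shifts), decreasing = TRUE)
      for (sh in as.integer(names(tab))) {
        ov <- overlap_identity(seqs[[ab[1]]], seqs[[ab[2]]], sh)
        if (ov$len >= min_overlap && ov$identity >= min_identity) {
          links[[length(links) + 1L]] <- c(ab[1], ab[2], sh)
          break
        }
      }
    }
  }

  # union-find ----------------------------------------------------------
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (lk in links) {
    ra <- find(lk[1]); rb <- find(lk[2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_len(n), find, integer(1))

  # offsets via BFS over accepted shifts --------------------------------
  adj <- vector("list", n)
  for (lk in links) {
    adj[[lk[1]]] <- rbind(adj[[lk[1]]], c(lk[2], lk[3]))   # b at a_off + shift? see below
    adj[[lk[2]]] <- rbind(adj[[lk[2]]], c(lk[1], -lk[3]))
  }
  offsets <- rep(NA_integer_, n)
  contigs <- list()
  consensus <- character()
  singlets <- character()
  cid <- 0L
  for (root in sort(unique(comp))) {
    members <- which(comp == root)
    if (length(members) == 1L) {
      singlets <- c(singlets, ids[members])
      next
    }
    offsets[members[1]] <- 0L
    queue <- members[1]
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      nb <- adj[[a]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        b <- nb[k, 1]
        if (is.na(offsets[b])) {
          # shift stored as pos_a - pos_b: b starts at offset_a + shift
          offsets[b] <- offsets[a] + nb[k, 2]
          queue <- c(queue, b)
        }
      }
    }
    offs <- offsets[members] - min(offsets[members])
    lens <- nchar(seqs[members])
    cid <- cid + 1L
    contig_id <- sprintf("contig%04d", cid)
    ord <- order(offs, -lens, ids[members])
    contigs[[cid]] <- data.frame(contig_id = contig_id,
                                 read_id = ids[members][ord],
                                 offset = offs[ord],
                                 read_length = lens[ord],
                                 stringsAsFactors = FALSE)
    consensus[contig_id] <- majority_consensus(toupper(seqs[members]), offs)
  }
  list(contigs = if (length(contigs)) do.call(rbind, contigs) else
         data.frame(contig_id = character(), read_id = character(),
                    offset = integer(), read_length = integer(),
                    stringsAsFactors = FALSE),
       consensus = consensus, singlets = singlets)
}

# Per-column majority vote over reads laid out at given offsets.
majority_consensus <- function(seqs, offsets) {
  len <- max(offsets + nchar(seqs))
  counts <- matrix(0L, nrow = 5L, ncol = len,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    chars[!chars %in% rownames(counts)] <- "N"
    cols <- offsets[i] + seq_along(chars)
    for (b in rownames(counts)) {
      hit <- cols[chars == b]
      counts[b, hit] <- counts[b, hit] + 1L
    }
  }
  paste(rownames(counts)[apply(counts, 2, which.max)], collapse = "")
}

#' Contig size distribution
#'
#' Exact histogram of contig sizes (number of member ESTs), with the summary
#' bins used for library reporting: contigs with fewer than 20 members and
#' contigs with at least 30.
#'
#' @param contigs Contig membership `data.frame` from [cluster_ests()], or
#'   any `data.frame` with a `contig_id` column (one row per member).
#' @return List with `histogram` (named integer vector, size -> count),
#'   `n_contigs`, `n_lt_20` and `n_ge_30`.
#' @export
contig_size_distribution <- function(contigs) {
  if (!nrow(contigs)) {
    return(list(histogram = integer(), n_contigs = 0L, n_lt_20 = 0L, n_ge_30 = 0L))
  }
  sizes <- table(contigs$contig_id)
  hist <- table(factor(as.integer(sizes)))
  out <- setNames(as.integer(hist), names(hist))
  list(histogram = out, n_contigs = length(sizes),
       n_lt_20 = sum(sizes < 20L), n_ge_30 = sum(sizes >= 30L))
}

#' Select clones for full-insert sequencing
#'
#' Implements the resource's clone-selection policy: from every contig the
#' member lying 5'-most in the consensus layout is selected (ties broken by
#' longer read, then id). When a prior selection is supplied (incremental
#' operation), previously selected clones are retained and a newly appeared
#' 5'-most member is *added* with reason `upstream_update`. Singlets are
#' added when their assigned gene has no counterpart among the contig-derived
#' picks (`novel_gene_singlet`); unassigned singlets are never selected.
#'
#' @param contigs Contig membership `data.frame` (contig_id, read_id,
#'   offset, read_length).
#' @param singlets Character vector of singlet read ids.
#' @param gene_hits Gene assignments (`data.frame` with `query_id`,
#'   `gene_id`), e.g. from [assign_genes()].
#' @param prior Optional previous selection `data.frame` (as returned here)
#'   for incremental updates.
#' @return `data.frame` with `read_id`, `contig_id` (`NA` for singlets) and
#'   `reason` (`forefront`, `upstream_update` or `novel_gene_singlet`).
#' @export
select_clones <- function(contigs, singlets, gene_hits = NULL, prior = NULL) {
  picks <- list()
  if (!is.null(prior) && nrow(prior)) picks[[1]] <- prior
  if (nrow(contigs)) {
    for (cid in unique(contigs$contig_id)) {
      mem <- contigs[contigs$contig_id == cid, ]
      mem <- mem[order(mem$offset, -mem$read_length, mem$read_id), ]
      forefront <- mem$read_id[1]
      already <- if (!is.null(prior)) prior$read_id[prior$contig_id %in% cid] else character()
      if (!forefront %in% already) {
        reason <- if (length(already)) "upstream_update" else "forefront"
        picks[[length(picks) + 1L]] <- data.frame(
          read_id = forefront, contig_id = cid, reason = reason,
          stringsAsFactors = FALSE)
      }
    }
  }
  sel <- if (length(picks)) do.call(rbind, picks) else
    data.frame(read_id = character(), contig_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (length(singlets) && !is.null(gene_hits) && nrow(gene_hits)) {
    covered <- unique(gene_hits$gene_id[gene_hits$query_id %in% sel$read_id])
    sing <- gene_hits[gene_hits$query_id %in% singlets, , drop = FALSE]
    sing <- sing[order(sing$query_id), , drop = FALSE]
    for (k in seq_len(nrow(sing))) {
      if (!sing$gene_id[k] %in% covered && !sing$query_id[k] %in% sel$read_id) {
        sel <- rbind(sel, data.frame(read_id = sing$query_id[k],
                                     contig_id = NA_character_,
                                     reason = "novel_gene_singlet",
                                     stringsAsFactors = FALSE))
        covered <- c(covered, sing$gene_id[k])
      }
    }
  }
  rownames(sel) <- NULL
  stopifnot(!anyDuplicated(sel$read_id))
  sel
}

#' Probability that a rare transcript is missed
#'
#' Closed-form probability that a transcript with expression frequency
#' `freq` is absent from a sample of `n_clones` independently cloned
#' transcripts: `(1 - freq)^n_clones`. A transcript at frequency 0.006%
#' is missed in a 10,000-clone sample with probability ~0.549.
#'
#' @param freq Expression frequency in `[0, 1]`.
#' @param n_clones Number of cloned transcripts (>= 0).
#' @return Miss probability in `[0, 1]`.
#' @export
detection_miss_probability <- function(freq, n_clones) {
  if (!is.numeric(freq) || any(freq < 0) || any(freq > 1)) {
    cm_stop("freq must be in [0, 1]")
  }
  if (any(n_clones < 0)) cm_stop("n_clones must be >= 0")
  (1 - freq)^n_clones
}
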