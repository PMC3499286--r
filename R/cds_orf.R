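# Coding-content classification of cDNA sequences: full-length CDS coverage
# from protein alignments, start-codon inclusion, ORF finding, non-coding
# flagging, locus representatives, and duplication screening.

#' Classify full-length CDS coverage from a protein alignment
#'
#' A cDNA contains a full-length CDS when its best protein alignment trims
#' the protein at both ends by fewer than `max_trim` amino acids:
#' `n_term_trim = pstart - 1`, `c_term_trim = protein_length - pend`,
#' full-length iff both are strictly below `max_trim`.
#'
#' @param aln One-row protein alignment `data.frame` with `protein_length`,
#'   `pstart`, `pend` (1-based inclusive aligned protein residues), or
#'   `NULL` when the query has no protein hit.
#' @param max_trim Maximum tolerated trim (strict; default 10 aa).
#' @return List with `has_full_length_cds`, `has_start_codon`,
#'   `n_term_trim`, `c_term_trim`.
#' @export
classify_full_length <- function(aln, max_trim = 10L) {
  if (is.null(aln) || !nrow(aln)) {
    return(list(has_full_length_cds = FALSE, has_start_codon = FALSE,
                n_term_trim = NA_integer_, c_term_trim = NA_integer_))
  }
  stopifnot(nrow(aln) == 1L, aln$pstart >= 1L, aln$pend <= aln$protein_length)
  n_trim <- aln$pstart - 1L
  c_trim <- aln$protein_length - aln$pend
  list(has_full_length_cds = n_trim < max_trim && c_trim < max_trim,
       has_start_codon = n_trim < max_trim,
       n_term_trim = n_trim, c_term_trim = c_trim)
}

#' Start-codon inclusion from a protein alignment
#'
#' N-terminal analogue of the full-length rule: the cDNA is estimated to
#' include the start codon iff the N-terminal trim of its best protein
#' alignment is strictly below `max_trim` amino acids. Queries without a
#' protein hit are `FALSE`.
#'
#' @inheritParams classify_full_length
#' @return Logical scalar.
#' @export
classify_start_codon <- function(aln, max_trim = 10L) {
  classify_full_length(aln, max_trim)$has_start_codon
}

#' Find the longest forward-frame ORF
#'
#' Scans the three forward reading frames for ATG...stop spans under the
#' standard nuclear code. ORFs require both a start and an in-frame stop
#' within the sequence; ORFs running off the 3' end are not counted. The
#' sequence is declared non-coding when the longest peptide (stop excluded)
#' is not strictly longer than `min_aa`.
#'
#' @param sequence cDNA sense-strand sequence.
#' @param min_aa Coding threshold in amino acids (strict; default 30).
#' @return List with `longest_orf_aa` and `is_noncoding`.
#' @export
find_longest_orf <- function(sequence, min_aa = 30L) {
  orf <- best_orf(sequence)
  best <- if (is.null(orf)) 0L else orf$len_aa
  list(longest_orf_aa = best, is_noncoding = best <= min_aa)
}

# Longest forward-frame ORF of a sequence.
# Within each frame an ORF opens at the first ATG after the previous stop;
# the longest (earliest frame, then earliest position, on ties) wins.
# Returns list(len_aa, start, end) with 0-based half-open nucleotide
# coordinates including the stop codon, or NULL when there is no ORF.
best_orf <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  best_len <- 0L; best_start <- NA_integer_; best_end <- NA_integer_
  for (frame in 0:2) {
    if (n - 2L < 1L + frame) next
    starts <- seq(1L + frame, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    stops <- which(codons %in% STOP_CODONS)
    atgs <- which(codons == "ATG")
    if (!length(stops) || !length(atgs)) next
    prev <- c(0L, stops[-length(stops)])
    idx <- findInterval(prev, atgs) + 1L            # first ATG after previous stop
    ok <- idx <= length(atgs)
    a <- rep(NA_integer_, length(stops))
    a[ok] <- atgs[idx[ok]]
    len <- stops - a
    len[is.na(a) | len <= 0L] <- NA_integer_
    if (all(is.na(len))) next
    j <- which.max(ifelse(is.na(len), -1L, len))
    if (len[j] > best_len) {
      best_len <- len[j]
      best_start <- starts[a[j]] - 1L
      best_end <- starts[stops[j]] + 2L
    }
  }
  if (best_len == 0L) return(NULL)
  list(len_aa = best_len, start = best_start, end = best_end)
}

#' Align cDNA-derived peptides to reference proteins
#'
#' A naive protein aligner for synthetic data: the longest forward-frame
#' peptide of each query is located as an exact substring of each reference
#' protein; the score is the matched length in residues. Real resources use
#' a similarity search here; this exact matcher supplies structurally
#' identical records for testing the classification layer.
#'
#' @param sequences Named character vector (or `DNAStringSet`) of cDNA
#'   sequences.
#' @param proteins Named character vector of reference protein sequences
#'   (no stop symbol).
#' @param min_aa Minimum peptide length to attempt matching.
#' @return Protein-alignment `data.frame`: `query_id`, `protein_id`,
#'   `protein_length`, `pstart`, `pend`, `score`.
#' @export
match_proteins <- function(sequences, proteins, min_aa = 10L) {
  seqs <- as_seq_chars(sequences)
  out <- list()
  plen <- nchar(proteins)
  for (id in names(seqs)) {
    orf <- longest_orf_peptide(seqs[[id]])
    if (is.null(orf) || nchar(orf) < min_aa) next
    hit <- regexpr(orf, proteins, fixed = TRUE)
    found <- which(hit > 0L)
    if (!length(found)) next
    out[[length(out) + 1L]] <- data.frame(
      query_id = id, protein_id = names(proteins)[found],
      protein_length = as.integer(plen[found]),
      pstart = as.integer(hit[found]),
      pend = as.integer(hit[found]) + nchar(orf) - 1L,
      score = nchar(orf), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(query_id = character(), protein_id = character(),
                      protein_length = integer(), pstart = integer(),
                      pend = integer(), score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Peptide (character) of the longest forward-frame ORF, or NULL.
longest_orf_peptide <- function(sequence) {
  orf <- best_orf(sequence)
  if (is.null(orf)) return(NULL)
  nt <- substr(toupper(sequence), orf$start + 1L, orf$end - 3L)  # stop excluded
  starts <- seq(1L, nchar(nt), by = 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(nt, starts, starts + 2L)])
  if (anyNA(aa)) return(NULL)  # ambiguous base in a codon
  paste(aa, collapse = "")
}

#' Per-query CDS status table
#'
#' Combines ORF scanning and best protein alignments into the per-cDNA
#' classification record: full-length CDS flag, start-codon flag, longest
#' ORF length and non-coding flag.
#'
#' @param sequences Named character vector (or `DNAStringSet`) of cDNAs.
#' @param protein_aln Protein-alignment `data.frame` (e.g. from
#'   [match_proteins()]); per query the best-scoring row is used.
#' @param max_trim Trim threshold for [classify_full_length()].
#' @param min_aa ORF coding threshold for [find_longest_orf()].
#' @return `data.frame`: `query_id`, `has_full_length_cds`,
#'   `has_start_codon`, `longest_orf_aa`, `is_noncoding`, `n_term_trim`,
#'   `c_term_trim`.
#' @export
cds_status <- function(sequences, protein_aln, max_trim = 10L, min_aa = 30L) {
  seqs <- as_seq_chars(sequences)
  by_query <- split(protein_aln, protein_aln$query_id)
  rows <- lapply(names(seqs), function(id) {
    orf <- find_longest_orf(seqs[[id]], min_aa)
    sub <- by_query[[id]]
    best <- if (!is.null(sub) && nrow(sub))
      sub[order(-sub$score, sub$protein_id)[1], , drop = FALSE] else NULL
    fl <- classify_full_length(best, max_trim)
    data.frame(query_id = id,
               has_full_length_cds = fl$has_full_length_cds && !orf$is_noncoding,
               has_start_codon = fl$has_start_codon,
               longest_orf_aa = orf$longest_orf_aa,
               is_noncoding = orf$is_noncoding,
               n_term_trim = fl$n_term_trim, c_term_trim = fl$c_term_trim,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pick the representative cDNA of each locus
#'
#' Per locus, the member with the longest ORF; ties go to the longer
#' sequence, then id order.
#'
#' @param loci Merged locus `data.frame` (with `members` list-column).
#' @param statuses CDS status table from [cds_status()].
#' @param seq_lengths Named integer vector of cDNA lengths (tie-break).
#' @return `data.frame`: `locus_id`, `query_id`, `longest_orf_aa`.
#' @export
pick_locus_representatives <- function(loci, statuses, seq_lengths) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    members <- loci$members[[i]]
    if (!length(members)) cm_stop("locus %s has no members", loci$locus_id[i])
    orf <- statuses$longest_orf_aa[match(members, statuses$query_id)]
    orf[is.na(orf)] <- 0L
    len <- seq_lengths[members]
    pick <- order(-orf, -len, members)[1]
    data.frame(locus_id = loci$locus_id[i], query_id = members[pick],
               longest_orf_aa = orf[pick], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen for duplicated loci via shared protein hits
#'
#' For every reference protein matched by the representatives of two or more
#' loci, lists the loci and flags each locus whose representative ORF is
#' shorter than the longest ORF in the group -- the signature of a
#' pseudogenized or artefactual duplicate.
#'
#' @param representatives Output of [pick_locus_representatives()].
#' @param protein_aln Protein-alignment `data.frame`; per representative the
#'   best-scoring hit is used.
#' @return `data.frame`: `protein_id`, `locus_id`, `query_id`,
#'   `longest_orf_aa`, `flagged_shorter`. Empty when no protein is matched
#'   by more than one locus.
#' @export
detect_duplications <- function(representatives, protein_aln) {
  empty <- data.frame(protein_id = character(), locus_id = character(),
                      query_id = character(), longest_orf_aa = integer(),
                      flagged_shorter = logical(), stringsAsFactors = FALSE)
  if (!nrow(representatives) || !nrow(protein_aln)) return(empty)
  best <- protein_aln[order(protein_aln$query_id, -protein_aln$score,
                            protein_aln$protein_id), , drop = FALSE]
  best <- best[!duplicated(best$query_id), , drop = FALSE]
  df <- merge(representatives, best[c("query_id", "protein_id")], by = "query_id")
  dup_prot <- names(which(table(df$protein_id) >= 2L))
  if (!length(dup_prot)) return(empty)
  df <- df[df$protein_id %in% dup_prot, , drop = FALSE]
  df <- df[order(df$protein_id, df$locus_id), , drop = FALSE]
  out <- do.call(rbind, lapply(split(df, df$protein_id), function(g) {
    data.frame(protein_id = g$protein_id, locus_id = g$locus_id,
               query_id = g$query_id, longest_orf_aa = g$longest_orf_aa,
               flagged_shorter = g$longest_orf_aa < max(g$longest_orf_aa),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
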