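# Readers/writers for the external formats the pipeline touches.
#
# Dialects are strict on purpose: an input that does not match the documented
# format is an error, never a silent reinterpretation.

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. Record order is
#' preserved. Duplicate ids and empty sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id (first
#'   whitespace-delimited token of the header); the full header line is kept
#'   in the `description` metadata column.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) cm_stop("FASTA file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (anyNA(ids) || any(!nzchar(ids))) cm_stop("FASTA record with empty id in %s", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) cm_stop("duplicate FASTA id '%s' in %s", dup[1], path)
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0)) {
    cm_stop("empty sequence for FASTA id '%s' in %s", ids[nchar(seqs) == 0][1], path)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- headers
  out
}

#' Write DNA sequences to FASTA
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read per-base quality values
#'
#' Two dialects are accepted: FASTQ, and phred-style `.qual` files
#' (FASTA-like `>id` headers followed by whitespace-separated integers).
#' Qualities must lie in 0--93.
#'
#' @param path Path to a `.qual` or FASTQ file.
#' @param format `"auto"` (by extension), `"qual"` or `"fastq"`.
#' @return Named list of integer vectors, one per read.
#' @export
read_quality <- function(path, format = c("auto", "qual", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq" else "qual"
  }
  if (format == "fastq") {
    qs <- Biostrings::readQualityScaledDNAStringSet(path)
    quals <- as(Biostrings::quality(qs), "IntegerList")
    out <- setNames(as.list(quals), names(qs))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!length(lines) || !hdr[1]) cm_stop("malformed quality file (no '>' header): %s", path)
    grp <- cumsum(hdr)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    out <- lapply(split(lines[!hdr], grp[!hdr]), function(x) {
      v <- suppressWarnings(as.integer(strsplit(paste(x, collapse = " "), "\\s+")[[1]]))
      v[!is.na(v)]
    })
    names(out) <- ids
  }
  bad <- vapply(out, function(q) any(q < 0L | q > 93L), logical(1))
  if (any(bad)) cm_stop("quality value outside 0-93 for read '%s'", names(out)[bad][1])
  out
}

#' Write phred-style quality file
#' @param quals Named list of integer vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quality <- function(quals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(quals)) {
    writeLines(c(paste0(">", id), paste(quals[[id]], collapse = " ")), con)
  }
  invisible(path)
}

ALN_COLS <- c("query_id", "subject_id", "pident", "aln_length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send", "evalue", "score")

#' Construct alignment records in internal coordinates
#'
#' Builds the canonical alignment table used throughout the package:
#' all intervals 0-based half-open with `start < end`, subject strand
#' carried in `strand`.
#'
#' @param query_id,subject_id Character vectors.
#' @param sstart,send 0-based half-open subject interval (already normalised).
#' @param strand `"+"` or `"-"`.
#' @param qstart,qend 0-based half-open query interval.
#' @param score Alignment score.
#' @param pident Percent identity (0--100).
#' @param aln_length Alignment length; defaults to `send - sstart`.
#' @param mismatch,gapopen,evalue Optional extra columns.
#' @return A `data.frame` of alignment records.
#' @export
alignment_records <- function(query_id, subject_id, sstart, send, strand = "+",
                              qstart = 0L, qend = send - sstart, score = send - sstart,
                              pident = 100, aln_length = send - sstart,
                              mismatch = 0L, gapopen = 0L, evalue = 0) {
  if (!length(query_id)) {
    df <- data.frame(query_id = character(), subject_id = character(),
                     pident = numeric(), aln_length = integer(),
                     mismatch = integer(), gapopen = integer(),
                     qstart = integer(), qend = integer(),
                     sstart = integer(), send = integer(),
                     evalue = numeric(), score = numeric(), strand = character(),
                     stringsAsFactors = FALSE)
    return(df)
  }
  df <- data.frame(query_id = query_id, subject_id = subject_id,
                   pident = pident, aln_length = as.integer(aln_length),
                   mismatch = as.integer(mismatch), gapopen = as.integer(gapopen),
                   qstart = as.integer(qstart), qend = as.integer(qend),
                   sstart = as.integer(sstart), send = as.integer(send),
                   evalue = evalue, score = score,
                   strand = if (length(query_id)) strand else character(),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$sstart < df$send), all(df$qstart < df$qend),
            all(df$strand %in% c("+", "-")))
  df
}

#' Read a 12-column tabular alignment file
#'
#' The dialect is the classic tab-separated search-output table:
#' query, subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, score -- all coordinates 1-based
#' inclusive, minus-strand subject hits encoded as `sstart > send`.
#'
#' On read, strand is inferred from the subject coordinate order and all
#' intervals are normalised to the package-internal 0-based half-open
#' convention with `start < end`. Lines with a column count other than 12 or
#' non-numeric coordinates are errors reported with their line number.
#'
#' @param path Path to the alignment table.
#' @return A `data.frame` of alignment records (see [alignment_records()]).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) cm_stop("alignment file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(alignment_records(character(), character(), integer(), integer())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    cm_stop("line %d of %s has %d columns, expected 12", i, path, nf[i])
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(j, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) cm_stop("non-numeric %s on line %d of %s", what, which(is.na(v))[1], path)
    if (integer) as.integer(v) else v
  }
  qs <- num(7, "qstart", TRUE); qe <- num(8, "qend", TRUE)
  ss <- num(9, "sstart", TRUE); se <- num(10, "send", TRUE)
  if (any(qs > qe)) cm_stop("qstart > qend on line %d of %s", which(qs > qe)[1], path)
  if (any(qs < 1L) || any(ss < 1L) || any(se < 1L)) {
    cm_stop("coordinate below 1 (1-based convention) on line %d of %s",
            which(qs < 1L | ss < 1L | se < 1L)[1], path)
  }
  strand <- ifelse(ss <= se, "+", "-")
  alignment_records(
    query_id = m[, 1], subject_id = m[, 2],
    sstart = pmin(ss, se) - 1L, send = pmax(ss, se),
    strand = strand, qstart = qs - 1L, qend = qe,
    score = num(12, "score"), pident = num(3, "pident"),
    aln_length = num(4, "aln_length", TRUE), mismatch = num(5, "mismatch", TRUE),
    gapopen = num(6, "gapopen", TRUE), evalue = num(11, "evalue"))
}

#' Write alignment records back to the 12-column tabular dialect
#'
#' Inverse of [read_alignments()]: coordinates are re-expressed 1-based
#' inclusive and minus-strand records are re-serialised with `sstart > send`.
#'
#' @param aln Alignment record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  minus <- aln$strand == "-"
  ss <- ifelse(minus, aln$send, aln$sstart + 1L)
  se <- ifelse(minus, aln$sstart + 1L, aln$send)
  out <- data.frame(aln$query_id, aln$subject_id, aln$pident, aln$aln_length,
                    aln$mismatch, aln$gapopen, aln$qstart + 1L, aln$qend,
                    ss, se, aln$evalue, aln$score)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write loci to a BED6 file
#'
#' Coordinates are already 0-based half-open internally, so they are written
#' unchanged. Output is sorted by (chromosome, start, end, strand) so files
#' are byte-identical regardless of input order.
#'
#' @param loci Locus `data.frame` (see [merge_loci()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  if (!nrow(loci)) {
    file.create(path)
    return(invisible(path))
  }
  o <- order(loci$chrom, loci$start, loci$end, loci$strand)
  loci <- loci[o, ]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   loci$chrom, loci$start, loci$end, loci$locus_id, loci$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write synthetic gene models to GFF3
#'
#' Emits gene, mRNA and exon features (1-based inclusive per the GFF3
#' specification) for the ground-truth models produced by
#' [simulate_genome()]. Exons outside the chromosome bounds are an error.
#'
#' @param models Gene-model `data.frame` (see [simulate_genome()]).
#' @param path Output path.
#' @param chrom_lengths Named integer vector of sequence lengths, used for
#'   bounds validation; optional.
#' @return `path`, invisibly.
#' @export
write_truth_gff <- function(models, path, chrom_lengths = NULL) {
  feats <- list()
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    ex <- g$exons[[1]]  # matrix: start, end (0-based half-open)
    if (!is.null(chrom_lengths)) {
      len <- chrom_lengths[[g$chromosome]]
      if (is.null(len) || any(ex[, 1] < 0) || any(ex[, 2] > len)) {
        cm_stop("exon of gene '%s' outside bounds of %s", g$gene_id, g$chromosome)
      }
    }
    span <- c(min(ex[, 1]), max(ex[, 2]))
    gid <- g$gene_id
    feats[[length(feats) + 1L]] <- data.frame(
      chrom = g$chromosome,
      type = c("gene", "mRNA", rep("exon", nrow(ex))),
      start = c(span[1], span[1], ex[, 1]) + 1L,
      end = c(span[2], span[2], ex[, 2]),
      strand = g$strand,
      attr = c(sprintf("ID=%s", gid),
               sprintf("ID=%s.t1;Parent=%s", gid, gid),
               sprintf("ID=%s.t1.exon%d;Parent=%s.t1", gid, seq_len(nrow(ex)), gid)),
      stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, feats)
  lines <- "##gff-version 3"
  if (!is.null(feats)) {
    lines <- c(lines, sprintf("%s\tcapmap\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              feats$chrom, feats$type, feats$start, feats$end,
                              feats$strand, feats$attr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models back from a truth GFF3 file
#'
#' Inverse of [write_truth_gff()] for the fields it writes
#' (gene id, chromosome, strand, exon intervals).
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `gene_id`, `chromosome`, `strand` and
#'   list-column `exons` (0-based half-open interval matrices).
#' @export
read_truth_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  gene_of <- sub("\\.t1$", "", unlist(ex$Parent))
  genes <- gr[gr$type == "gene"]
  ord <- match(genes$ID, unique(gene_of))
  out <- data.frame(gene_id = as.character(genes$ID),
                    chromosome = as.character(GenomicRanges::seqnames(genes)),
                    strand = as.character(GenomicRanges::strand(genes)),
                    stringsAsFactors = FALSE)
  out$exons <- lapply(out$gene_id, function(g) {
    e <- ex[gene_of == g]
    m <- cbind(start = GenomicRanges::start(e) - 1L, end = GenomicRanges::end(e))
    m[order(m[, 1]), , drop = FALSE]
  })
  out
}

#' Write a report table as TSV
#'
#' All report tables share one dialect: UTF-8, tab separator, header row,
#' no quoting, no row names.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
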