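# End-to-end orchestration and the report/accounting layer.

#' Pipeline configuration
#'
#' Either a self-contained simulated run (`sim` given) or a file-driven run
#' (paths to genome/reads/qualities, and either an alignment table or none,
#' in which case the built-in naive aligner is used).
#'
#' @param sim Optional [sim_config()] for a self-contained run.
#' @param genome,reads,quals,alignments Input paths for file-driven runs.
#' @param proteins Optional named character vector of reference protein
#'   sequences (derived from the simulation truth when `sim` is given).
#' @param homolog_map,go_map Optional reference tables (see
#'   [count_unique_genes()], [go_classify()]).
#' @param thresholds A [mapping_thresholds()].
#' @param library_id Label used in the run summary.
#' @param density_window,density_step Sliding-window parameters for
#'   [locus_density()].
#' @param out_dir Optional output directory for report files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, genome = NULL, reads = NULL, quals = NULL,
                            alignments = NULL, proteins = NULL,
                            homolog_map = NULL, go_map = NULL,
                            thresholds = mapping_thresholds(),
                            library_id = "SIM01",
                            density_window = 50000L, density_step = 10000L,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(sim)) {
    for (field in c("genome", "reads")) {
      if (is.null(cfg[[field]])) cm_stop("pipeline config missing field '%s'", field)
      if (!file.exists(cfg[[field]])) cm_stop("pipeline config: %s file not found: %s",
                                              field, cfg[[field]])
    }
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("capmap stage=%s in=%d out=%d", stage, n_in, n_out))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> quality filter -> mask -> cluster ->
#' map -> annotate -> CDS classify -> clone selection -> editing ->
#' reports. Each stage logs its in/out record counts to stderr. The run is
#' deterministic under the simulation seed.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle (list): inputs, per-stage results, `summary`
#'   (library-level counts) and `accounting` (identity-check ledger).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  # --- inputs ----------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- simulate_genome(config$sim)
    rd <- simulate_reads(sim)
    genome <- sim$genome
    reads <- as_seq_chars(rd$reads)
    quals <- rd$quals
    proteins <- sim$truth$proteins
    protein_gene <- protein_gene_map(sim$models)
    homolog_map <- sim$truth$homolog_map
    go_map <- sim$truth$go_map
    scaffold_prefix <- sim$truth$scaffold_prefix
    chrom_lengths <- sim$truth$chrom_lengths
  } else {
    sim <- NULL; rd <- NULL
    genome <- read_fasta(config$genome)
    reads <- as_seq_chars(read_fasta(config$reads))
    quals <- if (!is.null(config$quals)) read_quality(config$quals) else
      lapply(setNames(nchar(reads), names(reads)), function(n) rep(40L, n))
    proteins <- config$proteins
    protein_gene <- setNames(names(proteins), names(proteins))
    homolog_map <- config$homolog_map
    go_map <- config$go_map
    scaffold_prefix <- "scaffold_"
    chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  }
  stage_log("input", length(reads), length(reads))

  # --- filter ----------------------------------------------------------
  kept <- filter_reads(reads, quals)
  reads_kept <- reads[kept]
  stage_log("quality_filter", length(reads), length(reads_kept))

  # --- mask + cluster --------------------------------------------------
  masked <- vapply(reads_kept, mask_low_complexity, character(1))
  clustering <- cluster_ests(masked)
  stage_log("cluster", length(reads_kept),
            length(unique(clustering$contigs$contig_id)) + length(clustering$singlets))

  # --- map -------------------------------------------------------------
  aln <- if (!is.null(config$alignments)) read_alignments(config$alignments)
         else align_reads(reads_kept, genome)
  query_loci <- call_query_loci(aln, config$thresholds, scaffold_prefix)
  loci <- merge_loci(query_loci)
  locus_table <- tabulate_loci(loci)
  density <- locus_density(loci, chrom_lengths,
                           config$density_window, config$density_step)
  stage_log("map", length(unique(aln$query_id)), nrow(loci))

  # --- annotate --------------------------------------------------------
  protein_aln <- if (!is.null(proteins)) match_proteins(reads_kept, proteins) else
    match_proteins(character(), character())
  hits <- data.frame(query_id = protein_aln$query_id,
                     species = rep("reference", nrow(protein_aln)),
                     gene_id = unname(protein_gene[protein_aln$protein_id]),
                     score = protein_aln$score, stringsAsFactors = FALSE)
  assignments <- assign_genes(hits)
  gene_counts <- if (!is.null(homolog_map)) count_unique_genes(assignments, homolog_map)
                 else NULL
  go_counts <- if (!is.null(go_map)) go_classify(assignments, go_map) else NULL
  stage_log("annotate", length(reads_kept), nrow(assignments))

  # --- CDS classify ----------------------------------------------------
  statuses <- cds_status(reads_kept, protein_aln)
  stage_log("cds", length(reads_kept), nrow(statuses))

  # --- clone selection -------------------------------------------------
  selection <- select_clones(clustering$contigs, clustering$singlets, assignments)
  stage_log("select", nrow(clustering$contigs) + length(clustering$singlets),
            nrow(selection))

  # --- representatives & duplication screen ---------------------------
  reps <- if (nrow(loci)) pick_locus_representatives(loci, statuses,
                                                     nchar(reads_kept)) else NULL
  duplications <- if (!is.null(reps)) detect_duplications(reps, protein_aln) else NULL

  # --- editing ---------------------------------------------------------
  pairings <- list(); utr_pairings <- list()
  for (id in names(reads_kept)) {
    sub <- aln[aln$query_id == id, , drop = FALSE]
    best <- best_aligned_region(sub, nchar(reads_kept[[id]]))
    if (is.null(best)) next
    p <- pairing_from_alignment(reads_kept[[id]], genome, best)
    pairings[[id]] <- p
    utr <- utr3_interval(reads_kept[[id]])
    if (!is.null(utr) && utr[2] > utr[1]) {
      from <- max(utr[1], best$qstart); to <- min(utr[2], best$qend)
      if (to > from) {
        cols <- (from - best$qstart + 1L):(to - best$qstart)
        utr_pairings[[id]] <- structure(
          list(genome = p$genome[cols], cdna = p$cdna[cols], qstart = from),
          class = "cm_pairing")
      }
    }
  }
  editing <- editing_report(pairings)
  utr <- utr_mismatch_rate(utr_pairings)
  stage_log("editing", length(reads_kept), nrow(editing$per_query))

  # --- summary + accounting -------------------------------------------
  mapped_ids <- unique(unlist(loci$members))
  summary <- data.frame(
    library_id = config$library_id,
    n_ests_in_contigs = nrow(clustering$contigs),
    n_ests_singlets = length(clustering$singlets),
    n_ests_total = nrow(clustering$contigs) + length(clustering$singlets),
    n_clones_sequenced = nrow(selection),
    n_clones_mapped = sum(selection$read_id %in% mapped_ids),
    n_loci = nrow(loci), stringsAsFactors = FALSE)

  bundle <- list(sim = sim, read_truth = if (!is.null(rd)) rd$truth else NULL,
                 kept = kept, clustering = clustering, alignments = aln,
                 loci = loci, locus_table = locus_table, density = density,
                 assignments = assignments, gene_counts = gene_counts,
                 go_counts = go_counts, cds = statuses, selection = selection,
                 representatives = reps, duplications = duplications,
                 editing = editing, utr = utr, summary = summary)
  bundle$accounting <- check_accounting(library_table = summary,
                                        est_locus_table = locus_table)
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

protein_gene_map <- function(models) {
  orig <- models[is.na(models$duplicate_of), ]
  setNames(orig$gene_id, orig$protein_id)
}

write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_loci_bed(bundle$loci, file.path(dir, "loci.bed"))
  write_report_tsv(bundle$locus_table, file.path(dir, "locus_table.tsv"))
  write_report_tsv(bundle$density, file.path(dir, "locus_density.tsv"))
  write_report_tsv(bundle$cds, file.path(dir, "cds_status.tsv"))
  write_report_tsv(bundle$selection, file.path(dir, "clone_selection.tsv"))
  write_report_tsv(bundle$editing$per_query, file.path(dir, "editing.tsv"))
  write_report_tsv(bundle$summary, file.path(dir, "library_summary.tsv"))
  write_report_tsv(bundle$accounting, file.path(dir, "accounting.tsv"))
  invisible(dir)
}

#' Build a library-level resource table with totals
#'
#' One row per library plus a totals row equal to the column sums of every
#' numeric column. The accounting identity
#' `n_ests_total = n_ests_in_contigs + n_ests_singlets` is asserted per
#' row and for the totals; a violation is an error (a data-corruption
#' signal, not a reportable condition).
#'
#' @param libraries `data.frame` with columns `library_id`,
#'   `n_ests_in_contigs`, `n_ests_singlets`, `n_ests_total` and any further
#'   numeric columns (summed into the totals row).
#' @return The table with a final `Total` row.
#' @export
build_library_table <- function(libraries) {
  req <- c("library_id", "n_ests_in_contigs", "n_ests_singlets", "n_ests_total")
  missing <- setdiff(req, names(libraries))
  if (length(missing)) cm_stop("library table missing column '%s'", missing[1])
  bad <- libraries$n_ests_in_contigs + libraries$n_ests_singlets != libraries$n_ests_total
  if (any(bad)) {
    cm_stop("EST accounting identity violated for library '%s'",
            libraries$library_id[bad][1])
  }
  num <- vapply(libraries, is.numeric, logical(1))
  total <- libraries[1, , drop = FALSE]
  total[!num] <- NA
  total$library_id <- "Total"
  total[num] <- lapply(libraries[num], sum)
  out <- rbind(libraries, total)
  rownames(out) <- NULL
  out
}

#' Verify report accounting identities
#'
#' Checks the internal identities that a consistent report bundle must
#' satisfy and returns a pass/fail ledger (failures are listed, not
#' raised): EST totals equal contig members plus singlets; mapped clones
#' never exceed sequenced clones; per-chromosome strand counts sum to the
#' row totals; table totals equal recomputed column sums.
#'
#' @param library_table Library summary rows (with or without a Total row).
#' @param est_locus_table,clone_locus_table Per-chromosome tables whose
#'   strand columns should sum to totals (column pairs `fwd_*`/`rev_*`
#'   against `total_*`, or `forward`/`reverse` against `total`).
#' @return `data.frame` ledger: `identity`, `pass`, `detail`. Zero checks
#'   yields an empty ledger with a warning (vacuous pass).
#' @export
check_accounting <- function(library_table = NULL, est_locus_table = NULL,
                             clone_locus_table = NULL) {
  ledger <- list()
  note <- function(identity, pass, detail = "") {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      identity = identity, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  if (!is.null(library_table)) {
    lib <- library_table[library_table$library_id != "Total", , drop = FALSE]
    ok <- all(lib$n_ests_in_contigs + lib$n_ests_singlets == lib$n_ests_total)
    note("ests_total = ests_in_contigs + singlets", ok,
         if (ok) "" else
           paste(lib$library_id[lib$n_ests_in_contigs + lib$n_ests_singlets !=
                                  lib$n_ests_total], collapse = ","))
    if (all(c("n_clones_sequenced", "n_clones_mapped") %in% names(lib))) {
      ok <- all(lib$n_clones_mapped <= lib$n_clones_sequenced)
      note("mapped_clones <= sequenced_clones", ok)
    }
    if ("Total" %in% library_table$library_id) {
      tot <- library_table[library_table$library_id == "Total", , drop = FALSE]
      num <- vapply(lib, is.numeric, logical(1))
      ok <- all(vapply(names(lib)[num], function(cn) sum(lib[[cn]]) == tot[[cn]],
                       logical(1)))
      note("library totals equal column sums", ok)
    }
  }
  for (nm in c("est_locus_table", "clone_locus_table")) {
    tab <- get(nm)
    if (is.null(tab)) next
    key <- names(tab)[1]
    rows <- tab[!(tab[[key]] %in% "Total"), , drop = FALSE]
    pairs <- if ("forward" %in% names(tab)) {
      list(c("forward", "reverse", "total"))
    } else {
      tot_cols <- grep("^total_", names(tab), value = TRUE)
      lapply(tot_cols, function(tc) {
        stem <- sub("^total_", "", tc)
        c(paste0("fwd_", stem), paste0("rev_", stem), tc)
      })
    }
    for (p in pairs) {
      if (!all(p %in% names(tab))) next
      ok <- all(rows[[p[1]]] + rows[[p[2]]] == rows[[p[3]]])
      note(sprintf("%s: %s + %s = %s", nm, p[1], p[2], p[3]), ok)
    }
    if ("Total" %in% tab[[key]]) {
      tot <- tab[tab[[key]] == "Total", , drop = FALSE]
      num <- vapply(rows, is.numeric, logical(1))
      ok <- all(vapply(names(rows)[num], function(cn) sum(rows[[cn]]) == tot[[cn]],
                       logical(1)))
      note(sprintf("%s totals equal column sums", nm), ok)
    }
  }
  if (!length(ledger)) {
    warning("no reports supplied: vacuous accounting pass")
    return(data.frame(identity = character(), pass = logical(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ledger)
  rownames(out) <- NULL
  out
}

#' Load the bundled resource report fixtures
#'
#' Transcribed report tables of a large-scale pig full-length-enriched
#' cDNA/EST sequencing resource, shipped to exercise the report/accounting
#' layer: per-library EST and sequenced-clone tallies, per-chromosome EST
#' assembly locus counts, and per-chromosome sequenced-clone locus counts
#' (with the genome-reference Duroc animal subset in `*_duroc` columns).
#'
#' @param which One of `"libraries"`, `"est_loci"`, `"clone_loci"`.
#' @return A `data.frame`.
#' @export
load_resource_table <- function(which = c("libraries", "est_loci", "clone_loci")) {
  which <- match.arg(which)
  file <- switch(which,
                 libraries = "library_summaries.tsv",
                 est_loci = "est_assembly_loci.tsv",
                 clone_loci = "clone_loci.tsv")
  path <- system.file("extdata", file, package = "capmap", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
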