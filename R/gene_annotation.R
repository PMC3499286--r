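# Gene correspondence, homolog-group roll-up, and Gene Ontology
# classification with redundant counting.

#' Assign genes to queries from similarity hits
#'
#' Per (query, species), keeps the highest-scoring hit with score strictly
#' above `min_score`; a hit at exactly the threshold does not qualify. Ties
#' are broken by gene id order. Queries with no qualifying hit are absent
#' from the output.
#'
#' @param hits `data.frame` with columns `query_id`, `species`, `gene_id`,
#'   `score`.
#' @param min_score Score threshold (strict).
#' @return `data.frame` with one row per (query, species): `query_id`,
#'   `species`, `gene_id`, `best_score`.
#' @export
assign_genes <- function(hits, min_score = 50) {
  empty <- data.frame(query_id = character(), species = character(),
                      gene_id = character(), best_score = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  ok <- hits[hits$score > min_score, , drop = FALSE]
  if (!nrow(ok)) return(empty)
  ok <- ok[order(ok$query_id, ok$species, -ok$score, ok$gene_id), , drop = FALSE]
  keep <- !duplicated(paste(ok$query_id, ok$species, sep = "\r"))
  out <- data.frame(query_id = ok$query_id[keep], species = ok$species[keep],
                    gene_id = ok$gene_id[keep], best_score = ok$score[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Unique gene and homolog-group counts
#'
#' Rolls assignments for one species up to the counts reported in resource
#' tables: unique gene ids, unique genes lacking a homolog-group id, and
#' unique homolog groups (a group is counted once however many genes map
#' to it).
#'
#' @param assignments Output of [assign_genes()] restricted to one species.
#' @param homolog_map `data.frame` with `gene_id`, `group_id`.
#' @return List with `n_unique_gene_ids`, `n_without_homologene`,
#'   `n_unique_homologene`.
#' @export
count_unique_genes <- function(assignments, homolog_map) {
  genes <- unique(assignments$gene_id)
  grouped <- homolog_map$group_id[match(genes, homolog_map$gene_id)]
  list(n_unique_gene_ids = length(genes),
       n_without_homologene = sum(is.na(grouped)),
       n_unique_homologene = length(unique(grouped[!is.na(grouped)])))
}

#' Classify queries by Gene Ontology terms
#'
#' Each classified query contributes one count to *every* term its assigned
#' gene maps to within a namespace (redundant counting), so the term-count
#' sum can exceed the number of classified queries. Queries whose gene has
#' no term in a namespace are omitted from that namespace.
#'
#' @param assignments Output of [assign_genes()].
#' @param go_map `data.frame` with `gene_id`, `namespace`, `term_id`,
#'   `term_name`; namespaces must be the three ontology roots.
#' @return Named list (one element per namespace) of `data.frame`s with
#'   `term_id`, `term_name`, `count`, plus attribute `n_classified`
#'   (queries contributing at least one term).
#' @export
go_classify <- function(assignments, go_map) {
  roots <- c("molecular_function", "cellular_component", "biological_process")
  bad <- setdiff(unique(go_map$namespace), roots)
  if (length(bad)) cm_stop("unknown GO namespace '%s'", bad[1])
  go_map <- unique(go_map[c("gene_id", "namespace", "term_id", "term_name")])
  out <- list()
  for (ns in roots) {
    sub <- go_map[go_map$namespace == ns, , drop = FALSE]
    joined <- merge(assignments[c("query_id", "gene_id")], sub, by = "gene_id")
    if (!nrow(joined)) {
      tab <- data.frame(term_id = character(), term_name = character(),
                        count = integer(), stringsAsFactors = FALSE)
      attr(tab, "n_classified") <- 0L
      out[[ns]] <- tab
      next
    }
    counts <- table(joined$term_id)
    tab <- data.frame(term_id = names(counts),
                      term_name = sub$term_name[match(names(counts), sub$term_id)],
                      count = as.integer(counts), stringsAsFactors = FALSE)
    tab <- tab[order(-tab$count, tab$term_id), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "n_classified") <- length(unique(joined$query_id))
    out[[ns]] <- tab
  }
  out
}

#' Fold rare terms into "Others"
#'
#' Aggregation view of a per-namespace term-count table: terms counted
#' fewer times than `floor` are collapsed into a single "Others" row.
#'
#' @param term_table One element of [go_classify()] output.
#' @param floor Minimum count for a term to keep its own row.
#' @return `data.frame` with `term` and `count`.
#' @export
fold_rare_terms <- function(term_table, floor = 1000L) {
  keep <- term_table$count >= floor
  out <- data.frame(term = term_table$term_id[keep],
                    count = term_table$count[keep], stringsAsFactors = FALSE)
  if (any(!keep)) {
    out <- rbind(out, data.frame(term = "Others",
                                 count = sum(term_table$count[!keep]),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
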