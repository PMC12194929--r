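#' Orthology thresholds
#'
#' The retention criteria for all-vs-all similarity hits: E-value strictly
#' under `max_evalue`, identity strictly over `min_identity`, and query
#' coverage at least `min_query_coverage`.
#'
#' @param max_evalue Maximum E-value, exclusive (default 1e-10).
#' @param min_identity Minimum percent identity, exclusive (default 60).
#' @param min_query_coverage Minimum percent query coverage, inclusive
#'   (default 60).
#' @return A list of class `orthology_thresholds`.
#' @export
orthology_thresholds <- function(max_evalue = 1e-10, min_identity = 60,
                                 min_query_coverage = 60) {
  stopifnot(max_evalue > 0, min_identity > 0, min_identity <= 100,
            min_query_coverage > 0, min_query_coverage <= 100)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 min_query_coverage = min_query_coverage),
            class = "orthology_thresholds")
}

#' Filter similarity hits by orthology thresholds
#'
#' Retains hits with `evalue < max_evalue`, `pct_identity > min_identity`
#' and `query_coverage >= min_query_coverage`; self-hits are removed.
#'
#' @param hits Similarity-hit tibble from [read_similarity_table()].
#' @param thresholds An [orthology_thresholds()] object.
#' @return The retained hits.
#' @export
filter_similarity_hits <- function(hits, thresholds = orthology_thresholds()) {
  hits %>%
    filter(
      .data$query_id != .data$subject_id,
      .data$evalue < thresholds$max_evalue,
      .data$pct_identity > thresholds$min_identity,
      .data$query_coverage >= thresholds$min_query_coverage
    )
}

#' Reciprocal best hits between genomes
#'
#' For every ordered genome pair (A, B) and every query protein in A, the
#' best subject in B is the hit with maximal bitscore (ties broken by
#' smaller E-value, then lexicographically smaller subject id). An
#' unordered protein pair is a reciprocal best hit (RBH) when each member
#' is the other's best hit. Intra-genome hits are ignored. The result is
#' symmetric by construction and invariant to input row order.
#'
#' @param hits Filtered similarity hits (see [filter_similarity_hits()]).
#' @param genome_map Tibble with columns `protein_id`, `genome_id` mapping
#'   every protein to exactly one genome.
#' @return Tibble of unordered pairs `protein_a`, `protein_b`
#'   (`protein_a < protein_b`), sorted.
#' @export
reciprocal_best_hits <- function(hits, genome_map) {
  stopifnot(all(c("protein_id", "genome_id") %in% names(genome_map)))
  empty <- tibble(protein_a = character(), protein_b = character())
  if (nrow(hits) == 0L) return(empty)
  missing <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                     genome_map$protein_id)
  if (length(missing) > 0L) {
    abort(paste0("protein(s) missing from genome map: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  gm <- setNames(genome_map$genome_id, genome_map$protein_id)
  h <- hits %>%
    mutate(query_genome = unname(gm[.data$query_id]),
           subject_genome = unname(gm[.data$subject_id])) %>%
    filter(.data$query_genome != .data$subject_genome)
  if (nrow(h) == 0L) return(empty)
  best <- h %>%
    arrange(desc(.data$bitscore), .data$evalue, .data$subject_id) %>%
    group_by(.data$query_id, .data$subject_genome) %>%
    slice(1) %>%
    ungroup() %>%
    select("query_id", "subject_id")
  rbh <- best %>%
    inner_join(best, by = c(query_id = "subject_id", subject_id = "query_id")) %>%
    mutate(protein_a = pmin(.data$query_id, .data$subject_id),
           protein_b = pmax(.data$query_id, .data$subject_id)) %>%
    distinct(.data$protein_a, .data$protein_b) %>%
    arrange(.data$protein_a, .data$protein_b)
  rbh
}

#' Cluster reciprocal-best-hit pairs into ortholog groups
#'
#' Ortholog groups (OGs) are the connected components of the undirected RBH
#' graph, ordered by decreasing size with ties broken by the
#' lexicographically smallest member. Proteins appearing in no pair can be
#' appended as singleton OGs.
#'
#' @param pairs RBH pair tibble from [reciprocal_best_hits()].
#' @param genome_map Tibble (`protein_id`, `genome_id`); used to annotate
#'   members and, with `include_singletons`, to enumerate unpaired
#'   proteins.
#' @param include_singletons Emit singleton OGs for unpaired proteins
#'   (default `FALSE`).
#' @return Tibble with columns `og_id`, `protein_id`, `genome_id`.
#' @export
cluster_ogs <- function(pairs, genome_map, include_singletons = FALSE) {
  members <- list()
  if (nrow(pairs) > 0L) {
    g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
  }
  if (include_singletons) {
    alone <- setdiff(genome_map$protein_id, unlist(members))
    members <- c(members, as.list(alone))
  }
  if (length(members) == 0L) {
    return(tibble(og_id = character(), protein_id = character(),
                  genome_id = character()))
  }
  sizes <- vapply(members, length, integer(1))
  mins <- vapply(members, min, character(1))
  ord <- order(-sizes, mins)
  members <- members[ord]
  gm <- setNames(genome_map$genome_id, genome_map$protein_id)
  out <- list_rbind(lapply(seq_along(members), function(k) {
    prots <- sort(members[[k]])
    tibble(og_id = sprintf("OG%04d", k), protein_id = prots)
  }))
  mutate(out, genome_id = unname(gm[.data$protein_id]))
}

#' Genome-by-OG copy-number matrix
#'
#' Counts how many members each genome contributes to each OG; a capped
#' view (`min(count, cap)`) supports 0-2 style displays.
#'
#' @param ogs OG membership tibble from [cluster_ogs()].
#' @param genomes Character vector of genome ids to report (rows); defaults
#'   to the genomes present in `ogs`.
#' @param cap Optional integer cap applied to each entry (e.g. 2).
#' @return Integer matrix, genomes as rows and OG ids as columns.
#' @export
og_count_matrix <- function(ogs, genomes = NULL, cap = NULL) {
  if (is.null(genomes)) genomes <- sort(unique(ogs$genome_id))
  og_ids <- unique(ogs$og_id)
  m <- matrix(0L, nrow = length(genomes), ncol = length(og_ids),
              dimnames = list(genomes, og_ids))
  if (nrow(ogs) > 0L) {
    tab <- ogs %>% dplyr::count(.data$genome_id, .data$og_id)
    tab <- tab[tab$genome_id %in% genomes, ]
    m[cbind(tab$genome_id, tab$og_id)] <- tab$n
  }
  if (!is.null(cap)) m <- pmin(m, as.integer(cap))
  m
}
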