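#' Infer transcriptional units from intergenic distances
#'
#' Scans each replicon's genes in coordinate order and joins adjacent genes
#' into the same transcriptional unit (TU) when they lie on the same strand
#' and the intergenic gap (`next.start - prev.end - 1`, the bases strictly
#' between the coding spans) is at most `max_gap`. A strand switch or a gap
#' of more than `max_gap` bases starts a new TU. Overlapping same-strand
#' genes are joined (gap treated as 0) with a message.
#'
#' @param genes Gene tibble as returned by [read_gff3()].
#' @param max_gap Largest intergenic gap joined into one TU (default 40 bp,
#'   the classic "more than 40 bases defines an upstream region" rule).
#' @return A tibble with one row per TU: `tu_id`, `replicon_id`, `strand`,
#'   `gene_ids` (list column, ordered 5' to 3'), `n_genes`,
#'   `leader_gene_id`, `tu_start`, `tu_end`.
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("a", "b"), replicon_id = "chr", start = c(1L, 931L),
#'   end = c(900L, 1800L), strand = "+", product = ""
#' )
#' infer_tus(genes)
#' @export
infer_tus <- function(genes, max_gap = 40L) {
  if (nrow(genes) == 0L) {
    return(tibble(tu_id = character(), replicon_id = character(),
                  strand = character(), gene_ids = list(),
                  n_genes = integer(), leader_gene_id = character(),
                  tu_start = integer(), tu_end = integer()))
  }
  genes <- arrange(genes, .data$replicon_id, .data$start, .data$end)
  out <- genes %>%
    group_by(.data$replicon_id) %>%
    mutate(
      gap = .data$start - lag(.data$end) - 1L,
      new_tu = is.na(.data$gap) |
        .data$strand != lag(.data$strand) |
        pmax(.data$gap, 0L) > max_gap,
      tu_index = cumsum(.data$new_tu)
    ) %>%
    ungroup()
  overlapping <- out$gap < 0L & !out$new_tu
  if (any(overlapping, na.rm = TRUE)) {
    inform(sprintf(
      "%d overlapping same-strand gene pair(s) joined (gap treated as 0)",
      sum(overlapping, na.rm = TRUE)))
  }
  out %>%
    group_by(.data$replicon_id, .data$tu_index) %>%
    summarise(
      strand = first(.data$strand),
      gene_ids = list(if (first(.data$strand) == "+") .data$gene_id
                      else rev(.data$gene_id)),
      n_genes = n(),
      leader_gene_id = if (first(.data$strand) == "+") first(.data$gene_id)
                       else dplyr::last(.data$gene_id),
      tu_start = min(.data$start),
      tu_end = max(.data$end),
      .groups = "drop"
    ) %>%
    mutate(tu_id = sprintf("%s_TU%04d", .data$replicon_id, .data$tu_index)) %>%
    select("tu_id", "replicon_id", "strand", "gene_ids", "n_genes",
           "leader_gene_id", "tu_start", "tu_end")
}

#' Long-format TU-to-gene map
#' @param tus TU tibble from [infer_tus()].
#' @return Tibble with `tu_id`, `gene_id`, `position` (1 = leader).
#' @export
tu_gene_map <- function(tus) {
  tus %>%
    select("tu_id", "gene_ids") %>%
    tidyr::unnest_longer("gene_ids", values_to = "gene_id") %>%
    group_by(.data$tu_id) %>%
    mutate(position = row_number()) %>%
    ungroup()
}

#' Extract upstream regions for transcriptional units
#'
#' The upstream region runs from the base after the previous genomic
#' feature (any strand) to the base before the TU's leader gene, capped at
#' `max_len`. Minus-strand TUs take the mirror interval downstream in
#' genome coordinates and the returned string is reverse-complemented so it
#' always reads toward the gene, ending at the base before the leader
#' start. A zero-length gap yields no upstream region (`NA`).
#'
#' @param tus TU tibble from [infer_tus()].
#' @param genes The gene tibble the TUs were inferred from.
#' @param sequences Named character vector of replicon sequences (or a
#'   tibble with `id`/`sequence`).
#' @param max_len Maximum upstream length in nt (default 300).
#' @return `tus` with added columns `upstream_start`, `upstream_end`
#'   (1-based inclusive genome coordinates) and `upstream_seq`
#'   (strand-oriented).
#' @export
extract_upstream <- function(tus, genes, sequences, max_len = 300L) {
  seqs <- as_named_sequences(sequences)
  genes <- arrange(genes, .data$replicon_id, .data$start, .data$end)
  res <- purrr::pmap(tus, function(tu_id, replicon_id, strand, gene_ids,
                                   leader_gene_id, tu_start, tu_end, ...) {
    if (!replicon_id %in% names(seqs)) {
      abort(sprintf("replicon '%s' absent from supplied sequences",
                    replicon_id))
    }
    chrom <- seqs[[replicon_id]]
    clen <- nchar(chrom)
    g <- genes[genes$replicon_id == replicon_id, ]
    leader <- g[g$gene_id == leader_gene_id, ]
    if (nrow(leader) != 1L) {
      abort(sprintf("leader gene '%s' not found on replicon '%s'",
                    leader_gene_id, replicon_id))
    }
    if (strand == "+") {
      prev_end <- suppressWarnings(max(g$end[g$end < leader$start]))
      lo <- max(prev_end + 1L, leader$start - max_len, 1L)
      hi <- leader$start - 1L
    } else {
      next_start <- suppressWarnings(min(g$start[g$start > leader$end]))
      lo <- leader$end + 1L
      hi <- min(next_start - 1L, leader$end + max_len, clen)
    }
    if (!is.finite(lo)) lo <- max(leader$start - max_len, 1L)
    if (!is.finite(hi)) hi <- min(leader$end + max_len, clen)
    if (hi < lo) {
      return(tibble(upstream_start = NA_integer_, upstream_end = NA_integer_,
                    upstream_seq = NA_character_))
    }
    s <- substr(chrom, lo, hi)
    if (strand == "-") s <- revcomp(s)
    tibble(upstream_start = as.integer(lo), upstream_end = as.integer(hi),
           upstream_seq = s)
  })
  bind_cols(tus, list_rbind(res))
}

#' Upstream regions as a named sequence vector
#'
#' @param tus TU tibble after [extract_upstream()].
#' @return Named character vector (names are TU ids) of the non-empty
#'   upstream sequences, ready for [scan_sequences()].
#' @export
upstream_sequences <- function(tus) {
  keep <- !is.na(tus$upstream_seq)
  setNames(tus$upstream_seq[keep], tus$tu_id[keep])
}

#' Write upstream regions to FASTA
#'
#' Headers carry `tu_id|replicon|start|end|strand`.
#'
#' @param tus TU tibble after [extract_upstream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_upstream_fasta <- function(tus, path) {
  keep <- tus[!is.na(tus$upstream_seq), ]
  df <- tibble(
    id = sprintf("%s|%s|%d|%d|%s", keep$tu_id, keep$replicon_id,
                 keep$upstream_start, keep$upstream_end, keep$strand),
    sequence = keep$upstream_seq
  )
  write_fasta(df, path)
}
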