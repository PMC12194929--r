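#' Default sigma-class promoter PWMs
#'
#' Built from the conserved promoter elements only: for sigma54 the "GC"
#' ending at -24 and "TGC" ending at -12 (14 columns spanning -25..-12,
#' spacer uniform); for sigma70 the -35 "TTGACA" and -10 "TATAAT"
#' hexamers (29 columns spanning -35..-7). Informative positions carry
#' probability 0.94.
#'
#' @return A [pwm] object.
#' @name promoter_pwms
NULL

#' @rdname promoter_pwms
#' @export
sigma54_promoter_pwm <- function() {
  consensus_pwm("GCNNNNNNNNNTGC", motif_id = "sigma54_promoter")
}

#' @rdname promoter_pwms
#' @export
sigma70_promoter_pwm <- function() {
  consensus_pwm(paste0("TTGACA", strrep("N", 17), "TATAAT"),
                motif_id = "sigma70_promoter")
}

#' Call the promoter class of a transcriptional unit
#'
#' Scans the sigma-class PWMs over the window immediately upstream of each
#' TU leader; the class of the best surviving hit (smallest p-value) wins.
#' TUs with no hit under `p_max`, or no upstream region, are called
#' `none`.
#'
#' The default `p_max` of 1e-3 reflects the short, partially informative
#' promoter PWMs: the sigma54 -24/-12 elements carry only five strongly
#' conserved positions, so even a perfect match cannot reach genome-scan
#' stringencies.
#'
#' @param tus TU tibble after [extract_upstream()].
#' @param sigma54_pwm PWM for the sigma54 promoter.
#' @param sigma70_pwms A [pwm] or list of PWMs for sigma70 promoters.
#' @param background A `markov_background` (uniform when `NULL`).
#' @param p_max Hit threshold (default 1e-3).
#' @param window Search window in nt upstream of the leader (default 60).
#' @return A tibble with `tu_id`, `promoter_class` (`sigma54_like`,
#'   `sigma70_like`, `none`), `site_start`, `site_end`, `site_strand`,
#'   `site_score`, `site_pvalue`.
#' @export
call_promoter <- function(tus, sigma54_pwm = sigma54_promoter_pwm(),
                          sigma70_pwms = sigma70_promoter_pwm(),
                          background = NULL, p_max = 1e-3, window = 60L) {
  if (inherits(sigma70_pwms, "pwm")) sigma70_pwms <- list(sigma70_pwms)
  class_of <- c(
    setNames("sigma54_like", sigma54_pwm$motif_id),
    setNames(rep("sigma70_like", length(sigma70_pwms)),
             map_chr(sigma70_pwms, "motif_id"))
  )
  proximal <- tus %>%
    filter(!is.na(.data$upstream_seq)) %>%
    mutate(scan_seq = substr(.data$upstream_seq,
                             pmax(nchar(.data$upstream_seq) - window + 1L, 1L),
                             nchar(.data$upstream_seq)))
  none_row <- function(tu) {
    tibble(tu_id = tu, promoter_class = "none",
           site_start = NA_integer_, site_end = NA_integer_,
           site_strand = NA_character_, site_score = NA_real_,
           site_pvalue = NA_real_)
  }
  if (nrow(proximal) == 0L) {
    return(list_rbind(lapply(tus$tu_id, none_row)))
  }
  hits <- scan_sequences(c(list(sigma54_pwm), sigma70_pwms),
                         setNames(proximal$scan_seq, proximal$tu_id),
                         background = background, p_max = p_max)
  best <- hits %>%
    rename(tu_id = "seq_id") %>%
    group_by(.data$tu_id) %>%
    arrange(.data$pvalue, desc(.data$score), .data$start, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  calls <- lapply(tus$tu_id, function(tu) {
    b <- best[best$tu_id == tu, ]
    if (nrow(b) == 0L) return(none_row(tu))
    tibble(tu_id = tu,
           promoter_class = unname(class_of[[b$motif_id]]),
           site_start = b$start, site_end = b$end, site_strand = b$strand,
           site_score = b$score, site_pvalue = b$pvalue)
  })
  list_rbind(calls)
}

#' Assemble the regulator-to-operon network
#'
#' Builds one edge per (regulator, target TU) pair supported by a
#' surviving binding-site hit in the TU's upstream region (evidence
#' `site_hit`, best p-value recorded), adds a `colocalization` edge for
#' every bEBP gene divergently oriented toward a TU within
#' `max_coloc_dist` nt, and merges the two evidence kinds when both apply.
#'
#' @param site_hits Overlap-filtered hits from [scan_sequences()] run on
#'   upstream regions, so `seq_id` is a TU id. An optional
#'   `regulator_class` column overrides the default class `"bEBP"` per
#'   motif (use `"sigma_factor"` for sigma PWMs).
#' @param tus TU tibble (targets must exist here).
#' @param calls Optional regulator calls from [classify_regulators()];
#'   needed for colocalization edges.
#' @param genes Optional gene tibble; needed for colocalization edges.
#' @param motif_classes Optional named character vector mapping motif ids
#'   to `sigma_factor` or `bEBP`.
#' @param max_coloc_dist Maximum intergenic distance for divergent
#'   colocalization (default 300 nt).
#' @return A tibble of regulatory edges: `regulator_id`,
#'   `regulator_class`, `target_tu_id`, `evidence` (`site_hit`,
#'   `colocalization`, `both`), `best_site_pvalue`.
#' @export
assemble_network <- function(site_hits, tus, calls = NULL, genes = NULL,
                             motif_classes = NULL, max_coloc_dist = 300L) {
  edges <- tibble(regulator_id = character(), regulator_class = character(),
                  target_tu_id = character(), evidence = character(),
                  best_site_pvalue = numeric())
  if (!is.null(site_hits) && nrow(site_hits) > 0L) {
    unknown <- setdiff(unique(site_hits$seq_id), tus$tu_id)
    if (length(unknown) > 0L) {
      abort(paste0("site hit(s) reference unknown TU(s): ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    cls <- function(m) {
      if (!is.null(motif_classes) && m %in% names(motif_classes)) {
        motif_classes[[m]]
      } else "bEBP"
    }
    edges <- site_hits %>%
      group_by(.data$motif_id, .data$seq_id) %>%
      summarise(best_site_pvalue = min(.data$pvalue), .groups = "drop") %>%
      mutate(regulator_id = .data$motif_id,
             regulator_class = map_chr(.data$motif_id, cls),
             target_tu_id = .data$seq_id,
             evidence = "site_hit") %>%
      select("regulator_id", "regulator_class", "target_tu_id",
             "evidence", "best_site_pvalue")
  }
  if (!is.null(calls) && !is.null(genes) && any(calls$is_bebp)) {
    coloc <- divergent_colocalization(calls, genes, tus, max_coloc_dist)
    edges <- bind_rows(edges, coloc)
  }
  edges %>%
    group_by(.data$regulator_id, .data$regulator_class,
             .data$target_tu_id) %>%
    summarise(
      evidence = if (dplyr::n_distinct(.data$evidence) > 1L) "both"
                 else first(.data$evidence),
      best_site_pvalue = if (all(is.na(.data$best_site_pvalue))) NA_real_
                         else min(.data$best_site_pvalue, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    arrange(.data$regulator_id, .data$target_tu_id)
}

# bEBP genes divergently oriented toward a TU leader within the distance
# cap gain a colocalization edge (the HupR / hupSL layout)
divergent_colocalization <- function(calls, genes, tus, max_coloc_dist) {
  bebps <- calls$protein_id[calls$is_bebp]
  rows <- list()
  for (b in bebps) {
    gb <- genes[genes$gene_id == b, ]
    if (nrow(gb) != 1L) next
    for (i in seq_len(nrow(tus))) {
      tu <- tus[i, ]
      if (tu$replicon_id != gb$replicon_id) next
      if (tu$strand == gb$strand) next
      if (b %in% tu$gene_ids[[1]]) next
      # divergent: the 5' ends face each other across the gap
      if (gb$strand == "-" && tu$strand == "+") {
        gap <- tu$tu_start - gb$end - 1L
        ok <- gb$end < tu$tu_start
      } else {
        gap <- gb$start - tu$tu_end - 1L
        ok <- tu$tu_end < gb$start
      }
      if (ok && gap >= 0L && gap <= max_coloc_dist) {
        rows[[length(rows) + 1L]] <- tibble(
          regulator_id = b, regulator_class = "bEBP",
          target_tu_id = tu$tu_id, evidence = "colocalization",
          best_site_pvalue = NA_real_
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(regulator_id = character(), regulator_class = character(),
                  target_tu_id = character(), evidence = character(),
                  best_site_pvalue = numeric()))
  }
  list_rbind(rows)
}

#' Run the full regulatory-circuit pipeline
#'
#' Orchestrates orthology, regulator classification, TU inference,
#' upstream extraction, motif scanning and network assembly from a single
#' configuration, writing every intermediate artifact plus a
#' machine-readable run manifest. Identical configuration and inputs give
#' identical outputs.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `inputs` (named list of paths: `fasta`, `gff`, `domains`,
#'   `similarity`, `genome_map`, `motifs` (MEME file)); `out_dir`;
#'   optional `params` (`max_gap`, `max_upstream`, `p_max`, `max_evalue`,
#'   `min_identity`, `min_query_coverage`, `max_coloc_dist`); optional
#'   `seed`. `fasta` and `gff` may be vectors (one per genome).
#' @return A list with the pipeline tables (`ogs`, `calls`, `tus`,
#'   `site_hits`, `edges`, `manifest`), invisibly writing them under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  params <- config$params %||% list()
  p <- list(
    max_gap = params$max_gap %||% 40L,
    max_upstream = params$max_upstream %||% 300L,
    p_max = params$p_max %||% 1e-4,
    max_evalue = params$max_evalue %||% 1e-10,
    min_identity = params$min_identity %||% 60,
    min_query_coverage = params$min_query_coverage %||% 60,
    max_coloc_dist = params$max_coloc_dist %||% 300L
  )
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  stages_done <- character(0)

  io <- stage("read_inputs", {
    seqs <- unlist(lapply(unname(unlist(inputs$fasta)), function(f) {
      df <- read_fasta(f, type = "dna")
      setNames(df$sequence, df$id)
    }))
    genes <- list_rbind(lapply(unname(unlist(inputs$gff)), read_gff3))
    domains <- read_domain_table(inputs$domains)
    list(seqs = seqs, genes = genes, domains = domains)
  })
  stages_done <- c(stages_done, "read_inputs")

  ogs <- NULL
  if (!is.null(inputs$similarity)) {
    ogs <- stage("orthology", {
      gm <- readr::read_tsv(inputs$genome_map, show_col_types = FALSE,
                            progress = FALSE)
      hits <- read_similarity_table(inputs$similarity)
      kept <- filter_similarity_hits(hits, orthology_thresholds(
        p$max_evalue, p$min_identity, p$min_query_coverage))
      pairs <- reciprocal_best_hits(kept, gm)
      cluster_ogs(pairs, gm)
    })
    stages_done <- c(stages_done, "orthology")
  }

  calls <- stage("classify", {
    classify_regulators(io$domains, protein_ids = io$genes$gene_id)
  })
  stages_done <- c(stages_done, "classify")

  tus <- stage("tus", {
    infer_tus(io$genes, max_gap = p$max_gap) %>%
      extract_upstream(io$genes, io$seqs, max_len = p$max_upstream)
  })
  stages_done <- c(stages_done, "tus")

  hits <- stage("scan", {
    motifs <- read_meme_motifs(inputs$motifs)
    ups <- upstream_sequences(tus)
    raw <- scan_sequences(motifs, ups, p_max = p$p_max)
    filter_overlaps(raw)
  })
  stages_done <- c(stages_done, "scan")

  edges <- stage("network", {
    assemble_network(hits, tus, calls = calls, genes = io$genes,
                     max_coloc_dist = p$max_coloc_dist)
  })
  stages_done <- c(stages_done, "network")

  # artifacts
  if (!is.null(ogs)) {
    readr::write_tsv(ogs, file.path(out_dir, "ogs.tsv"), progress = FALSE)
  }
  readr::write_tsv(calls, file.path(out_dir, "calls.tsv"), progress = FALSE)
  tus_flat <- tus %>%
    mutate(gene_ids = map_chr(.data$gene_ids, paste, collapse = ",")) %>%
    select(-"upstream_seq")
  readr::write_tsv(tus_flat, file.path(out_dir, "tus.tsv"), progress = FALSE)
  write_upstream_fasta(tus, file.path(out_dir, "upstream.fna"))
  write_sites_bed(hits, file.path(out_dir, "sites.bed"))
  readr::write_tsv(edges, file.path(out_dir, "edges.tsv"), progress = FALSE)

  manifest <- list(
    tool = "regcircuit",
    version = as.character(utils::packageVersion("regcircuit")),
    parameters = p,
    seed = config$seed %||% NA,
    stages = as.list(stages_done),
    inputs = lapply(
      Filter(Negate(is.null), inputs),
      function(f) as.list(unname(tools::md5sum(unlist(f))))
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(ogs = ogs, calls = calls, tus = tus, site_hits = hits,
                 edges = edges, manifest = manifest))
}
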