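# pinned Pfam accessions for the classification rules
PFAM <- list(
  sigma54_aid = "PF00309", sigma54_cbd = "PF04963", sigma54_dbd = "PF04552",
  sigma70_r1_2 = "PF00140", sigma70_r2 = "PF04542", sigma70_r3 = "PF04539",
  sigma70_r4 = "PF04545", sigma70_r4_2 = "PF08281",
  bebp_activator = "PF00158", response_reg = "PF00072",
  hiska = "PF00512", hatpase = "PF02518"
)

#' Resolve overlapping domain hits on each protein
#'
#' Greedy by descending bitscore (ties: smaller alignment start, then
#' accession): a hit is retained only if it overlaps every already-retained
#' hit on the same protein by at most 50% of the shorter interval. The
#' result is the protein's domain architecture, ordered by alignment start.
#'
#' @param hits Domain-hit tibble (one or many proteins) as returned by
#'   [read_domain_table()].
#' @param max_overlap_frac Overlap tolerance as a fraction of the shorter
#'   hit (default 0.5).
#' @return The retained hits, sorted by `(protein_id, ali_start)`.
#' @export
resolve_domain_overlaps <- function(hits, max_overlap_frac = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$protein_id, -hits$bitscore, hits$ali_start,
                     hits$pfam_acc), ]
  keep <- logical(nrow(hits))
  for (pid in unique(hits$protein_id)) {
    idx <- which(hits$protein_id == pid)
    rs <- integer(0)
    re <- integer(0)
    for (i in idx) {
      s <- hits$ali_start[[i]]
      e <- hits$ali_end[[i]]
      if (length(rs) > 0L) {
        ov <- pmin(re, e) - pmax(rs, s) + 1L
        shorter <- pmin(re - rs + 1L, e - s + 1L)
        if (any(ov > max_overlap_frac * shorter)) next
      }
      keep[[i]] <- TRUE
      rs <- c(rs, s)
      re <- c(re, e)
    }
  }
  out <- hits[keep, ]
  arrange(out, .data$protein_id, .data$ali_start)
}

# domain-presence helpers over one protein's resolved architecture;
# accessions are authoritative, Pfam names are accepted as fallback since
# the sigma70 region domains are usually cited by name
has_dom <- function(arch, acc, name = NULL) {
  hit <- arch$pfam_acc == acc
  if (!is.null(name) && "pfam_name" %in% names(arch)) {
    hit <- hit | arch$pfam_name == name
  }
  any(hit)
}

sigma70_region_present <- function(arch) {
  accs <- unlist(PFAM[c("sigma70_r1_2", "sigma70_r2", "sigma70_r3",
                        "sigma70_r4", "sigma70_r4_2")])
  any(arch$pfam_acc %in% accs) ||
    ("pfam_name" %in% names(arch) &&
       any(startsWith(arch$pfam_name, "Sigma70_")))
}

#' Classify a protein's sigma-factor family from its domain architecture
#'
#' Rule cascade, first match wins:
#' 1. Sigma54_AID + Sigma54_CBD + Sigma54_DBD all present: sigma54 (RpoN).
#' 2. Sigma70_r1_2 and Sigma70_r3 both present: sigma70 groups 1-2
#'    (housekeeping RpoD/RpoS/RpoH-like).
#' 3. Sigma70_r3 alone (no r1_2, r2 or r4_2): group 3, FliA-like.
#' 4. Sigma70_r2 + Sigma70_r4_2 without r1_2/r3: group 4, RpoE-like.
#' 5. Any other sigma70-region domain: generic sigma70-like.
#' 6. Otherwise unclassified.
#'
#' @param arch One protein's resolved architecture (tibble with `pfam_acc`
#'   and optionally `pfam_name`), or a character vector of accessions.
#' @return A list with `family` (`sigma54`, `sigma70` or `none`) and
#'   `group_label`.
#' @export
classify_sigma_factor <- function(arch) {
  if (is.character(arch)) arch <- tibble(pfam_acc = arch)
  s54 <- has_dom(arch, PFAM$sigma54_aid, "Sigma54_AID") &&
    has_dom(arch, PFAM$sigma54_cbd, "Sigma54_CBD") &&
    has_dom(arch, PFAM$sigma54_dbd, "Sigma54_DBD")
  if (s54) return(list(family = "sigma54", group_label = "RpoN"))
  r1_2 <- has_dom(arch, PFAM$sigma70_r1_2, "Sigma70_r1_2")
  r2 <- has_dom(arch, PFAM$sigma70_r2, "Sigma70_r2")
  r3 <- has_dom(arch, PFAM$sigma70_r3, "Sigma70_r3")
  r4_2 <- has_dom(arch, PFAM$sigma70_r4_2, "Sigma70_r4_2")
  if (r1_2 && r3) return(list(family = "sigma70", group_label = "group1_2"))
  if (r3 && !r1_2 && !r2 && !r4_2) {
    return(list(family = "sigma70", group_label = "group3_FliA-like"))
  }
  if (r2 && r4_2 && !r1_2 && !r3) {
    return(list(family = "sigma70", group_label = "group4_RpoE-like"))
  }
  if (sigma70_region_present(arch)) {
    return(list(family = "sigma70", group_label = "sigma70_like"))
  }
  list(family = "none", group_label = "unclassified")
}

#' Is this architecture a bacterial enhancer-binding protein (bEBP)?
#'
#' A bEBP carries both the sigma54 activator (AAA+) domain PF00158 and the
#' response-regulator (REC) domain PF00072.
#'
#' @param arch Architecture tibble or character vector of accessions.
#' @return Logical scalar.
#' @export
detect_bebp <- function(arch) {
  if (is.character(arch)) arch <- tibble(pfam_acc = arch)
  has_dom(arch, PFAM$bebp_activator, "Sigma54_activat") &&
    has_dom(arch, PFAM$response_reg, "Response_reg")
}

#' Is this architecture a histidine-kinase sensor (HKS)?
#'
#' Requires the phosphoacceptor HisKA domain (PF00512) together with the
#' catalytic HATPase_c domain; accessory signalling domains (PAS, HAMP,
#' cache) are allowed.
#'
#' @param arch Architecture tibble or character vector of accessions.
#' @return Logical scalar.
#' @export
detect_hks <- function(arch) {
  if (is.character(arch)) arch <- tibble(pfam_acc = arch)
  hiska <- has_dom(arch, PFAM$hiska, "HisKA")
  hatp <- has_dom(arch, PFAM$hatpase, "HATPase_c") ||
    ("pfam_name" %in% names(arch) &&
       any(startsWith(arch$pfam_name, "HATPase")))
  hiska && hatp
}

#' Classify every protein in a domain table
#'
#' Resolves overlapping hits per protein, applies the sigma-factor cascade,
#' and flags bEBPs and HKS sensors. Every protein in `protein_ids` (or,
#' when `NULL`, every protein in `domain_hits`) receives exactly one call.
#' Hybrid sensors carrying all four bEBP + HKS domains are reported as
#' bEBPs with `hybrid_kinase = TRUE` and a warning.
#'
#' @param domain_hits Domain-hit tibble from [read_domain_table()].
#' @param protein_ids Optional character vector of all proteins to call
#'   (proteins without hits become `none`/`unclassified`).
#' @return A tibble with `protein_id`, `family` (`sigma54`, `sigma70`,
#'   `bEBP`, `HKS`, `none`), `group_label`, `is_bebp`, `is_hks`,
#'   `hybrid_kinase`.
#' @export
classify_regulators <- function(domain_hits, protein_ids = NULL) {
  resolved <- resolve_domain_overlaps(domain_hits)
  ids <- protein_ids %||% unique(domain_hits$protein_id)
  archs <- split(resolved, factor(resolved$protein_id, levels = ids))
  calls <- list_rbind(lapply(ids, function(pid) {
    arch <- archs[[pid]] %||% tibble(pfam_acc = character(),
                                     pfam_name = character())
    sf <- classify_sigma_factor(arch)
    bebp <- detect_bebp(arch)
    hks <- detect_hks(arch)
    family <- sf$family
    label <- sf$group_label
    if (family == "none") {
      if (bebp) {
        family <- "bEBP"
        label <- "bEBP"
      } else if (hks) {
        family <- "HKS"
        label <- "HKS"
      }
    }
    tibble(protein_id = pid, family = family, group_label = label,
           is_bebp = bebp, is_hks = hks, hybrid_kinase = bebp && hks)
  }))
  if (any(calls$hybrid_kinase)) {
    warn(sprintf(
      "%d hybrid sensor(s) carry both bEBP and HKS domains; reported as bEBP with hybrid_kinase = TRUE",
      sum(calls$hybrid_kinase)))
  }
  calls
}

#' Pair bEBPs with their cognate histidine-kinase sensors
#'
#' For each bEBP gene, searches its own transcriptional unit and the TUs
#' immediately flanking it on the same replicon for an HKS gene. The
#' nearest HKS by genomic distance wins; distance ties go to the downstream
#' neighbor relative to the bEBP's strand. A bEBP with no HKS in the window
#' is reported as a one-component regulator.
#'
#' @param calls Regulator calls from [classify_regulators()]; protein ids
#'   must match gene ids.
#' @param genes Gene tibble.
#' @param tus TU tibble from [infer_tus()].
#' @param flank Number of flanking TUs searched on each side (default 1).
#' @return Tibble with `bebp_id`, `hks_id` (`NA` for one-component),
#'   `tu_id` (the bEBP's TU), `mode`.
#' @export
pair_tcs <- function(calls, genes, tus, flank = 1L) {
  bebps <- calls$protein_id[calls$is_bebp]
  hks_ids <- calls$protein_id[calls$is_hks & !calls$is_bebp]
  gmap <- tu_gene_map(tus)
  tu_of <- setNames(gmap$tu_id, gmap$gene_id)
  gx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  # TU order along each replicon
  tu_order <- tus %>%
    arrange(.data$replicon_id, .data$tu_start) %>%
    group_by(.data$replicon_id) %>%
    mutate(tu_rank = row_number()) %>%
    ungroup()
  rank_of <- setNames(tu_order$tu_rank, tu_order$tu_id)
  repl_of <- setNames(tu_order$replicon_id, tu_order$tu_id)
  out <- lapply(bebps, function(b) {
    if (!b %in% names(tu_of)) {
      abort(sprintf("bEBP gene '%s' is not assigned to any TU", b))
    }
    tu_b <- tu_of[[b]]
    rk <- rank_of[[tu_b]]
    cand_tus <- tu_order$tu_id[
      tu_order$replicon_id == repl_of[[tu_b]] &
        abs(tu_order$tu_rank - rk) <= flank]
    cand <- gmap$gene_id[gmap$tu_id %in% cand_tus]
    cand <- intersect(cand, hks_ids)
    if (length(cand) == 0L) {
      return(tibble(bebp_id = b, hks_id = NA_character_, tu_id = tu_b,
                    mode = "one_component"))
    }
    gb <- genes[gx[[b]], ]
    dist <- vapply(cand, function(h) {
      gh <- genes[gx[[h]], ]
      max(0L, max(gb$start, gh$start) - min(gb$end, gh$end) - 1L)
    }, numeric(1))
    downstream <- vapply(cand, function(h) {
      gh <- genes[gx[[h]], ]
      if (gb$strand == "+") gh$start > gb$end else gh$end < gb$start
    }, logical(1))
    ord <- order(dist, !downstream, cand)
    tibble(bebp_id = b, hks_id = cand[[ord[[1]]]], tu_id = tu_b,
           mode = "two_component")
  })
  list_rbind(out)
}
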