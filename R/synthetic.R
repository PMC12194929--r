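#' Simulation configuration for synthetic genome sets
#'
#' Defines the generative conditions for every downstream stage: operon
#' structure under the 40 bp gap rule, planted Pfam domain architectures,
#' planted binding sites drawn from PWMs under a ZOOPS occupancy model, and
#' a similarity table consistent with the planted orthology.
#'
#' Defaults give 3 genomes of 40 operons with two planted width-12 motifs
#' (occupancy 0.9, about 1.6 bits/column) each targeting half the operons,
#' and one copy per genome of each architecture in
#' [planted_architecture_catalog()]. Intra-operon gaps are uniform on
#' `[0, 40]` and inter-operon gaps uniform on `[700, 1000]`, so divergently
#' transcribed neighbors never share upstream search windows at the default
#' 300 nt cap.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param n_operons_per_genome Operons per genome.
#' @param genes_per_operon Length-2 integer range (min, max).
#' @param gene_length Length-2 integer range of gene lengths (nt).
#' @param intra_operon_gap Length-2 range within `[0, 40]`.
#' @param inter_operon_gap Length-2 range, both ends > 40.
#' @param background_order Markov order of the background generator.
#' @param background Optional `markov_background` to sample from (uniform
#'   of `background_order` when `NULL`).
#' @param planted_architectures Tibble with columns `label`, `domains`
#'   (list column of ordered Pfam accessions), `copies`.
#' @param planted_motifs List of lists with elements `motif_id`, `pwm`,
#'   `gamma`, `targets` (operon indices; `NULL` = all).
#' @param seed Mandatory integer seed; there is no hidden global
#'   randomness.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 3L,
                              n_operons_per_genome = 40L,
                              genes_per_operon = c(2L, 5L),
                              gene_length = c(300L, 900L),
                              intra_operon_gap = c(0L, 40L),
                              inter_operon_gap = c(700L, 1000L),
                              background_order = 0L,
                              background = NULL,
                              planted_architectures = planted_architecture_catalog(),
                              planted_motifs = default_planted_motifs(n_operons_per_genome),
                              seed = 1L) {
  stopifnot(n_genomes >= 1L, n_operons_per_genome >= 1L,
            length(genes_per_operon) == 2L, length(gene_length) == 2L)
  if (intra_operon_gap[[2]] > 40L || intra_operon_gap[[1]] < 0L) {
    abort("intra-operon gaps must lie in [0, 40]")
  }
  if (inter_operon_gap[[1]] <= 40L) {
    abort("inter-operon gaps must exceed 40")
  }
  for (pm in planted_motifs) {
    if (pm$gamma < 0 || pm$gamma > 1) abort("motif occupancy gamma must be in [0, 1]")
  }
  if (is.null(seed)) abort("simulation seed is mandatory")
  structure(
    list(n_genomes = as.integer(n_genomes),
         n_operons_per_genome = as.integer(n_operons_per_genome),
         genes_per_operon = as.integer(genes_per_operon),
         gene_length = as.integer(gene_length),
         intra_operon_gap = as.integer(intra_operon_gap),
         inter_operon_gap = as.integer(inter_operon_gap),
         background_order = as.integer(background_order),
         background = background %||% uniform_background(background_order),
         planted_architectures = planted_architectures,
         planted_motifs = planted_motifs,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Catalog of unambiguous planted domain architectures
#'
#' One representative per classification outcome: RpoN (sigma54), sigma70
#' groups 1-2, 3 and 4, a lone sigma70-region protein, a bEBP, an HKS, and
#' a decoy protein whose domains match no rule.
#'
#' @param copies Copies of each architecture per genome (default 1).
#' @return Tibble with `label`, `family`, `group_label`, `domains` (list
#'   column of accessions), `names` (list column of Pfam names), `copies`.
#' @export
planted_architecture_catalog <- function(copies = 1L) {
  tibble(
    label = c("rpoN", "sigma70_group1_2", "sigma70_group3",
              "sigma70_group4", "sigma70_orphan", "bebp", "hks", "decoy"),
    family = c("sigma54", "sigma70", "sigma70", "sigma70", "sigma70",
               "bEBP", "HKS", "none"),
    group_label = c("RpoN", "group1_2", "group3_FliA-like",
                    "group4_RpoE-like", "sigma70_like", "bEBP", "HKS",
                    "unclassified"),
    domains = list(
      c("PF00309", "PF04963", "PF04552"),
      c("PF00140", "PF04542", "PF04539"),
      c("PF04539"),
      c("PF04542", "PF08281"),
      c("PF04542"),
      c("PF00072", "PF00158"),
      c("PF00512", "PF02518"),
      c("PF00001")
    ),
    names = list(
      c("Sigma54_AID", "Sigma54_CBD", "Sigma54_DBD"),
      c("Sigma70_r1_2", "Sigma70_r2", "Sigma70_r3"),
      c("Sigma70_r3"),
      c("Sigma70_r2", "Sigma70_r4_2"),
      c("Sigma70_r2"),
      c("Response_reg", "Sigma54_activat"),
      c("HisKA", "HATPase_c"),
      c("7tm_1")
    ),
    copies = as.integer(copies)
  )
}

#' Default planted motifs: two informative width-12 PWMs
#'
#' Each consensus base carries probability 0.94 (about 1.6 bits per column
#' after the entropy of the off-consensus mass), occupancy gamma = 0.9.
#' The first motif targets odd-numbered operons, the second even-numbered.
#'
#' @param n_operons Operons per genome (to split the targets).
#' @param gamma Per-target occupancy probability.
#' @return List of planted-motif descriptors.
#' @export
default_planted_motifs <- function(n_operons = 40L, gamma = 0.9) {
  ops <- seq_len(n_operons)
  list(
    list(motif_id = "tspR_like",
         pwm = consensus_pwm("TGGCACGATTTG", prob = 0.94,
                             motif_id = "tspR_like"),
         gamma = gamma, targets = ops[ops %% 2L == 1L]),
    list(motif_id = "ntrC_like",
         pwm = consensus_pwm("TGCACCATTAGC", prob = 0.94,
                             motif_id = "ntrC_like"),
         gamma = gamma, targets = ops[ops %% 2L == 0L])
  )
}

#' Build a PWM from a consensus string
#'
#' @param consensus `ACGT` string; `N` positions are uniform.
#' @param prob Probability of the consensus base (rest split evenly).
#' @param motif_id Motif identifier.
#' @param nsites Nominal site count stored on the PWM.
#' @return A [pwm] object.
#' @export
consensus_pwm <- function(consensus, prob = 0.94, motif_id = "motif",
                          nsites = 20L) {
  b <- strsplit(consensus, "")[[1]]
  m <- vapply(b, function(ch) {
    if (ch == "N") return(rep(0.25, 4))
    v <- rep((1 - prob) / 3, 4)
    v[match(ch, DNA_BASES)] <- prob
    v
  }, numeric(4))
  new_pwm(m, motif_id = motif_id, nsites = nsites)
}

#' Sample a sequence from a Markov background model
#'
#' The generative inverse of [train_markov_background()]: the first `k`
#' characters are drawn from the lower-order conditionals, then each
#' character from the order-`k` conditional given its context.
#'
#' @param background A `markov_background`.
#' @param length Sequence length (>= the background order).
#' @param seed Integer seed; the same seed always yields the same
#'   sequence.
#' @return A nucleotide string.
#' @export
sample_background_sequence <- function(background, length, seed = 1L) {
  stopifnot(inherits(background, "markov_background"))
  k <- background$order
  if (length < k) abort("requested length is shorter than the model order")
  if (length == 0L) return("")
  with_seed(seed, {
    if (k == 0L) {
      q <- background$cond[[1]][1, ]
      return(paste(sample(DNA_BASES, length, replace = TRUE, prob = q),
                   collapse = ""))
    }
    out <- integer(length)
    # warm-up from the lower-order conditionals
    for (t in seq_len(min(k, length))) {
      # the order-0 context is the empty string, addressed positionally
      p <- if (t == 1L) background$cond[[1]][1, ] else {
        ctx <- paste(DNA_BASES[out[seq_len(t - 1L)]], collapse = "")
        background$cond[[t]][ctx, ]
      }
      out[[t]] <- sample.int(4L, 1L, prob = p)
    }
    if (length > k) {
      # order-k chain over context states encoded base-4
      tm <- background$cond[[k + 1L]]
      cum <- t(apply(tm, 1, cumsum))
      pow <- 4L^(k - 1L)
      state <- sum((out[seq_len(k)] - 1L) * 4L^((k - 1L):0)) + 1L
      r <- runif(length - k)
      for (t in (k + 1L):length) {
        b <- findInterval(r[[t - k]], cum[state, ]) + 1L
        out[[t]] <- b
        state <- ((state - 1L) %% pow) * 4L + b
      }
    }
    paste(DNA_BASES[out], collapse = "")
  })
}

#' Plant ZOOPS binding sites into sequences
#'
#' Each sequence independently receives one site with probability `gamma`,
#' at a uniformly random offset and uniformly random strand, sampled
#' column-wise from the PWM and overwriting the background letters.
#'
#' @param sequences Named character vector (or `id`/`sequence` tibble).
#' @param pwm A [pwm] object; must be no wider than the shortest sequence.
#' @param gamma Per-sequence site probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `sequences` (modified named vector) and `truth`, a
#'   tibble of `(seq_id, start, end, strand, site_seq)` for every planted
#'   site.
#' @export
plant_sites <- function(sequences, pwm, gamma, seed = 1L) {
  seqs <- as_named_sequences(sequences)
  w <- pwm_width(pwm)
  if (w > min(nchar(seqs))) {
    abort("PWM is wider than the shortest sequence")
  }
  stopifnot(gamma >= 0, gamma <= 1)
  with_seed(seed, {
    truth <- list()
    for (i in seq_along(seqs)) {
      if (runif(1) > gamma) next
      L <- nchar(seqs[[i]])
      start <- sample.int(L - w + 1L, 1L)
      strand <- sample(c("+", "-"), 1L)
      site <- sample_pwm_site(pwm)
      planted <- if (strand == "+") site else revcomp(site)
      substr(seqs[[i]], start, start + w - 1L) <- planted
      truth[[length(truth) + 1L]] <- tibble(
        seq_id = names(seqs)[[i]], start = start, end = start + w - 1L,
        strand = strand, site_seq = site
      )
    }
    list(
      sequences = seqs,
      truth = if (length(truth) > 0L) list_rbind(truth) else
        tibble(seq_id = character(), start = integer(), end = integer(),
               strand = character(), site_seq = character())
    )
  })
}

# one site drawn column-wise from a PWM (uses the current RNG stream)
sample_pwm_site <- function(pwm) {
  m <- pwm$matrix
  paste(vapply(seq_len(ncol(m)), function(j) {
    sample(DNA_BASES, 1L, prob = m[, j])
  }, character(1)), collapse = "")
}

#' Plant the sigma54 -24/-12 promoter elements into an upstream region
#'
#' Writes the conserved "GC" ending at position -24 and "TGC" ending at
#' position -12, counting back from the TU start (position -1 is the last
#' base of the upstream string). The operation is idempotent.
#'
#' @param upstream Upstream nucleotide string, at least 30 nt, whose final
#'   base immediately precedes the TU leader start.
#' @return The modified upstream string.
#' @export
plant_sigma54_promoter <- function(upstream) {
  L <- nchar(upstream)
  if (L < 30L) abort("upstream region must be at least 30 nt")
  # position -k maps to string index L - k + 1
  substr(upstream, L - 24L, L - 23L) <- "GC"   # -25..-24
  substr(upstream, L - 13L, L - 11L) <- "TGC"  # -14..-12
  upstream
}

#' Plant the sigma70 -35/-10 promoter elements into an upstream region
#'
#' Writes "TTGACA" at positions -35..-30 and "TATAAT" at -12..-7 relative
#' to the TU start. Idempotent.
#'
#' @param upstream Upstream nucleotide string, at least 40 nt.
#' @return The modified upstream string.
#' @export
plant_sigma70_promoter <- function(upstream) {
  L <- nchar(upstream)
  if (L < 40L) abort("upstream region must be at least 40 nt")
  substr(upstream, L - 34L, L - 29L) <- "TTGACA"  # -35..-30
  substr(upstream, L - 11L, L - 6L) <- "TATAAT"   # -12..-7
  upstream
}

#' Generate a synthetic genome set with full ground truth
#'
#' Composes the generators above into a complete input bundle: replicon
#' sequences with operons placed on alternating strands, gene coordinates
#' obeying the gap rule (intra-operon gaps <= 40, inter-operon gaps > 40),
#' random protein sequences, a domain table asserting the planted
#' architectures, a similarity table with reciprocal hits (identity 90,
#' coverage 100, E-value 1e-50) between planted orthologs plus
#' sub-threshold noise, and planted binding sites upstream of target
#' operon leaders. The truth bundle records every operon, architecture,
#' ortholog set and site. Identical config and seed give byte-identical
#' output.
#'
#' @param config A [simulation_config()].
#' @return A list of class `genome_set` with elements `sequences` (named
#'   replicon strings), `genes`, `proteins`, `domain_hits`, `similarity`,
#'   `genome_map`, and `truth` (list of tibbles: `operons`,
#'   `architectures`, `sites`, `orthologs`).
#' @export
generate_genome_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genomes <- sprintf("g%d", seq_len(config$n_genomes))
    arch <- config$planted_architectures
    per_genome <- lapply(seq_along(genomes), function(gi) {
      build_one_genome(config, genomes[[gi]], gi)
    })
    sequences <- unlist(lapply(per_genome, `[[`, "sequence_list"))
    genes <- list_rbind(lapply(per_genome, `[[`, "genes"))
    operons <- list_rbind(lapply(per_genome, `[[`, "operons"))
    sites <- list_rbind(lapply(per_genome, `[[`, "sites"))
    architectures <- list_rbind(lapply(per_genome, `[[`, "architectures"))
    domain_hits <- list_rbind(lapply(per_genome, `[[`, "domain_hits"))
    proteins <- list_rbind(lapply(per_genome, `[[`, "proteins"))
    genome_map <- tibble(
      protein_id = genes$gene_id,
      genome_id = sub("_.*$", "", genes$replicon_id)
    )
    orthologs <- architectures %>%
      group_by(.data$label, .data$copy) %>%
      filter(n() > 1L) %>%
      ungroup() %>%
      mutate(og_label = paste0(.data$label, "_", .data$copy)) %>%
      select("og_label", "genome_id", "protein_id")
    similarity <- build_similarity_table(orthologs, proteins, genome_map)
    structure(
      list(sequences = sequences, genes = genes, proteins = proteins,
           domain_hits = domain_hits, similarity = similarity,
           genome_map = genome_map,
           truth = list(operons = operons, architectures = architectures,
                        sites = sites, orthologs = orthologs),
           config = config),
      class = "genome_set"
    )
  })
}

# lay out one genome: operons left to right, strand alternating by operon;
# a minus-strand operon's leader is its rightmost gene so its upstream
# region extends into the following inter-operon gap
build_one_genome <- function(config, genome_id, genome_index) {
  replicon <- paste0(genome_id, "_chr")
  n_op <- config$n_operons_per_genome
  gpo <- config$genes_per_operon
  glen <- config$gene_length
  intra <- config$intra_operon_gap
  inter <- config$inter_operon_gap
  runs <- list()
  gene_rows <- list()
  op_rows <- list()
  cursor <- sample(seq(inter[[1]], inter[[2]]), 1L)
  for (o in seq_len(n_op)) {
    strand <- if (o %% 2L == 1L) "+" else "-"
    ng <- sample(seq(gpo[[1]], gpo[[2]]), 1L)
    lens <- sample(seq(glen[[1]], glen[[2]]), ng, replace = TRUE)
    gaps <- if (ng > 1L) sample(seq(intra[[1]], intra[[2]]), ng - 1L,
                                replace = TRUE) else integer(0)
    starts <- integer(ng)
    ends <- integer(ng)
    pos <- cursor
    for (k in seq_len(ng)) {
      starts[[k]] <- pos
      ends[[k]] <- pos + lens[[k]] - 1L
      pos <- ends[[k]] + 1L + (if (k < ng) gaps[[k]] else 0L)
    }
    ids <- sprintf("%s_o%02d_g%d", genome_id, o, seq_len(ng))
    op_label <- sprintf("%s_op%02d", genome_id, o)
    gene_rows[[o]] <- tibble(
      gene_id = ids, replicon_id = replicon, start = starts, end = ends,
      strand = strand, product = "hypothetical protein"
    )
    tx_ids <- if (strand == "+") ids else rev(ids)
    op_rows[[o]] <- tibble(
      op_label = op_label, genome_id = genome_id, replicon_id = replicon,
      op_index = o, strand = strand, gene_ids = list(tx_ids),
      leader_gene_id = tx_ids[[1]], op_start = starts[[1]],
      op_end = ends[[ng]]
    )
    cursor <- ends[[ng]] + 1L + sample(seq(inter[[1]], inter[[2]]), 1L)
  }
  genes <- list_rbind(gene_rows)
  operons <- list_rbind(op_rows)
  total_len <- cursor + 50L
  seq_chr <- sample_background_sequence(
    config$background, total_len,
    seed = sample.int(.Machine$integer.max, 1L))
  # plant binding sites upstream of target leaders
  sites <- list()
  for (pm in config$planted_motifs) {
    w <- pwm_width(pm$pwm)
    targets <- pm$targets %||% operons$op_index
    for (o in intersect(targets, operons$op_index)) {
      if (runif(1) > pm$gamma) next
      op <- operons[operons$op_index == o, ]
      d <- sample(10:80, 1L)  # distance from leader start to site end
      if (op$strand == "+") {
        e <- op$op_start - d - 1L
        s <- e - w + 1L
      } else {
        s <- op$op_end + d + 1L
        e <- s + w - 1L
      }
      if (s < 1L || e > total_len) next
      site_strand <- sample(c("+", "-"), 1L)
      site <- sample_pwm_site(pm$pwm)
      genomic <- if (site_strand == "+") site else revcomp(site)
      substr(seq_chr, s, e) <- genomic
      sites[[length(sites) + 1L]] <- tibble(
        genome_id = genome_id, replicon_id = replicon,
        op_label = op$op_label, motif_id = pm$motif_id,
        start = s, end = e, strand = site_strand, site_seq = site
      )
    }
  }
  sites <- if (length(sites) > 0L) list_rbind(sites) else
    tibble(genome_id = character(), replicon_id = character(),
           op_label = character(), motif_id = character(),
           start = integer(), end = integer(), strand = character(),
           site_seq = character())
  # assign planted architectures to successive genes in layout order
  arch <- config$planted_architectures
  arch_rows <- list()
  dom_rows <- list()
  slot <- 0L
  for (a in seq_len(nrow(arch))) {
    for (cp in seq_len(arch$copies[[a]])) {
      slot <- slot + 1L
      if (slot > nrow(genes)) {
        abort("more planted architecture copies than genes")
      }
      pid <- genes$gene_id[[slot]]
      doms <- arch$domains[[a]]
      dnames <- arch$names[[a]]
      arch_rows[[slot]] <- tibble(
        genome_id = genome_id, protein_id = pid, label = arch$label[[a]],
        copy = cp, family = arch$family[[a]],
        group_label = arch$group_label[[a]]
      )
      dom_rows[[slot]] <- tibble(
        protein_id = pid, pfam_acc = doms, pfam_name = dnames,
        ali_start = 10L + (seq_along(doms) - 1L) * 120L,
        ali_end = 10L + (seq_along(doms) - 1L) * 120L + 99L,
        bitscore = 120 - seq_along(doms), evalue = 1e-30
      )
    }
  }
  architectures <- list_rbind(arch_rows)
  domain_hits <- list_rbind(dom_rows)
  # random amino-acid sequences; domain hits are asserted, not detected
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  plen <- pmax((genes$end - genes$start + 1L) %/% 3L - 1L, 50L)
  proteins <- tibble(
    protein_id = genes$gene_id,
    length = plen,
    sequence = vapply(plen, function(n) {
      paste(sample(aa, n, replace = TRUE), collapse = "")
    }, character(1))
  )
  list(
    sequence_list = setNames(list(seq_chr), replicon),
    genes = genes, operons = operons, sites = sites,
    architectures = architectures, domain_hits = domain_hits,
    proteins = proteins
  )
}

# reciprocal high-scoring hits between planted orthologs across genomes,
# plus sub-threshold noise pairs that the orthology filter must discard
build_similarity_table <- function(orthologs, proteins, genome_map) {
  plen <- setNames(proteins$length, proteins$protein_id)
  rows <- list()
  for (og in unique(orthologs$og_label)) {
    members <- orthologs[orthologs$og_label == og, ]
    if (nrow(members) < 2L) next
    combos <- utils::combn(members$protein_id, 2L)
    for (j in seq_len(ncol(combos))) {
      p1 <- combos[1L, j]
      p2 <- combos[2L, j]
      for (pair in list(c(p1, p2), c(p2, p1))) {
        q <- pair[[1]]
        s <- pair[[2]]
        al <- unname(plen[[q]])
        rows[[length(rows) + 1L]] <- tibble(
          query_id = q, subject_id = s, pct_identity = 90,
          aln_length = al, mismatches = round(al * 0.1), gap_opens = 0L,
          q_start = 1L, q_end = al, s_start = 1L,
          s_end = min(al, unname(plen[[s]])),
          evalue = 1e-50, bitscore = 800, query_coverage = 100
        )
      }
    }
  }
  # noise: cross-genome pairs of non-orthologs, all below threshold
  other <- setdiff(genome_map$protein_id, orthologs$protein_id)
  n_noise <- min(length(other) %/% 2L, 60L)
  if (n_noise > 0L) {
    picks <- matrix(sample(other, 2L * n_noise), nrow = 2L)
    gm <- setNames(genome_map$genome_id, genome_map$protein_id)
    for (j in seq_len(n_noise)) {
      q <- picks[1L, j]
      s <- picks[2L, j]
      if (gm[[q]] == gm[[s]]) next
      al <- round(unname(plen[[q]]) * 0.4)
      rows[[length(rows) + 1L]] <- tibble(
        query_id = q, subject_id = s, pct_identity = 35,
        aln_length = al, mismatches = round(al * 0.6), gap_opens = 2L,
        q_start = 1L, q_end = al, s_start = 1L, s_end = al,
        evalue = 1e-3, bitscore = 45, query_coverage = 40
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  pct_identity = numeric(), aln_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = numeric(), bitscore = numeric(),
                  query_coverage = numeric()))
  }
  list_rbind(rows)
}

#' Write a genome set to disk in the pipeline's input formats
#'
#' Emits, under `dir`: `<genome>.fna` (replicons), `<genome>.gff3` (CDS
#' coordinates), `<genome>.faa` (proteins), `domains.tsv`,
#' `similarity.tsv`, `genome_map.tsv`, and `truth.txt` (the sectioned
#' truth bundle).
#'
#' @param gs A `genome_set` from [generate_genome_set()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_genome_set <- function(gs, dir) {
  stopifnot(inherits(gs, "genome_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- unique(gs$genome_map$genome_id)
  paths <- list()
  for (g in genomes) {
    reps <- gs$sequences[startsWith(names(gs$sequences), paste0(g, "_"))]
    fna <- file.path(dir, paste0(g, ".fna"))
    write_fasta(reps, fna)
    gff <- file.path(dir, paste0(g, ".gff3"))
    write_gff3(gs$genes[startsWith(gs$genes$replicon_id, paste0(g, "_")), ],
               gff)
    faa <- file.path(dir, paste0(g, ".faa"))
    prot <- gs$proteins[gs$proteins$protein_id %in%
                          gs$genome_map$protein_id[gs$genome_map$genome_id == g], ]
    write_fasta(tibble(id = prot$protein_id, sequence = prot$sequence), faa)
    paths[[g]] <- c(fna = fna, gff = gff, faa = faa)
  }
  paths$domains <- file.path(dir, "domains.tsv")
  write_domain_table(gs$domain_hits, paths$domains)
  paths$similarity <- file.path(dir, "similarity.tsv")
  write_similarity_table(gs$similarity, paths$similarity)
  paths$genome_map <- file.path(dir, "genome_map.tsv")
  readr::write_tsv(gs$genome_map, paths$genome_map, progress = FALSE)
  paths$truth <- file.path(dir, "truth.txt")
  write_truth_bundle(gs$truth, paths$truth)
  invisible(paths)
}

#' Write the truth bundle as one sectioned text file
#'
#' Each section starts with `#>> <name>` followed by a TSV table (list
#' columns are comma-joined).
#'
#' @param truth The `truth` element of a `genome_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bundle <- function(truth, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(truth)) {
    df <- truth[[nm]]
    df <- mutate(df, across(dplyr::where(is.list),
                            ~ map_chr(.x, paste, collapse = ",")))
    writeLines(paste0("#>> ", nm), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df) > 0L) {
      writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
    }
  }
  invisible(path)
}

#' Read a sectioned truth bundle
#' @param path Path written by [write_truth_bundle()].
#' @return Named list of tibbles.
#' @export
read_truth_bundle <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- which(startsWith(lines, "#>> "))
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    nm <- sub("^#>> ", "", lines[[heads[[i]]]])
    block <- lines[(heads[[i]] + 1L):(bounds[[i + 1L]] - 1L)]
    out[[nm]] <- readr::read_tsv(I(paste(block, collapse = "\n")),
                                 show_col_types = FALSE, progress = FALSE)
  }
  out
}

#' Sample standalone planted domain architectures
#'
#' Draws `n` proteins whose domain tables realize the architectures in
#' [planted_architecture_catalog()] (uniformly at random), with jittered
#' alignment coordinates and bitscores. Used to exercise the classifier at
#' scale without building genomes.
#'
#' @param n Number of proteins.
#' @param seed Integer seed.
#' @return A list with `domain_hits` (tibble) and `truth` (tibble of
#'   `protein_id`, `label`, `family`, `group_label`).
#' @export
sample_planted_architectures <- function(n, seed = 1L) {
  catalog <- planted_architecture_catalog()
  with_seed(seed, {
    pick <- sample.int(nrow(catalog), n, replace = TRUE)
    truth <- tibble(
      protein_id = sprintf("p%04d", seq_len(n)),
      label = catalog$label[pick],
      family = catalog$family[pick],
      group_label = catalog$group_label[pick]
    )
    dh <- list_rbind(lapply(seq_len(n), function(i) {
      doms <- catalog$domains[[pick[[i]]]]
      dnames <- catalog$names[[pick[[i]]]]
      k <- length(doms)
      starts <- 10L + (seq_len(k) - 1L) * 120L + sample.int(20L, k)
      tibble(
        protein_id = truth$protein_id[[i]], pfam_acc = doms,
        pfam_name = dnames, ali_start = starts, ali_end = starts + 99L,
        bitscore = 80 + round(runif(k, 0, 40), 1), evalue = 1e-20
      )
    }))
    list(domain_hits = dh, truth = truth)
  })
}
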