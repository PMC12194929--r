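test_that("promoter calls recover planted sigma54 and sigma70 elements", {
  bg <- uniform_background(0)
  mk_tu <- function(up, id) {
    tibble::tibble(tu_id = id, replicon_id = "chr", strand = "+",
                   gene_ids = list("g"), n_genes = 1L,
                   leader_gene_id = "g", tu_start = 1000L, tu_end = 2000L,
                   upstream_start = 1000L - nchar(up),
                   upstream_end = 999L, upstream_seq = up)
  }
  up54 <- plant_sigma54_promoter(
    sample_background_sequence(bg, 60, seed = 81))
  up70 <- plant_sigma70_promoter(
    sample_background_sequence(bg, 60, seed = 82))
  scrambled <- sample_background_sequence(bg, 60, seed = 83)
  tus <- dplyr::bind_rows(mk_tu(up54, "t54"), mk_tu(up70, "t70"),
                          mk_tu(scrambled, "t0"))
  calls <- call_promoter(tus, p_max = 1e-3)
  expect_equal(calls$promoter_class[calls$tu_id == "t54"], "sigma54_like")
  expect_equal(calls$promoter_class[calls$tu_id == "t70"], "sigma70_like")
  # sigma70 hexamers are informative enough for scan stringency
  calls70 <- call_promoter(tus[2, ], p_max = 1e-4)
  expect_equal(calls70$promoter_class, "sigma70_like")
  # scrambled upstream: no call at 1e-4
  calls0 <- call_promoter(tus[3, ], p_max = 1e-4)
  expect_equal(calls0$promoter_class, "none")
  # a TU without an upstream region is "none" as well
  tu_na <- mk_tu(NA_character_, "tna")
  expect_equal(call_promoter(tu_na)$promoter_class, "none")
})

test_that("network assembly builds site, colocalization and merged edges", {
  tus <- tibble::tibble(
    tu_id = c("TU1", "TU2"), replicon_id = "chr",
    strand = c("+", "+"),
    gene_ids = list("a1", "b1"), n_genes = 1L,
    leader_gene_id = c("a1", "b1"),
    tu_start = c(1000L, 5000L), tu_end = c(2000L, 6000L)
  )
  hits <- tibble::tibble(
    motif_id = c("ntrC", "ntrC", "tspR"), seq_id = c("TU1", "TU1", "TU2"),
    start = c(10L, 40L, 12L), end = c(21L, 51L, 23L),
    strand = "+", score = c(15, 12, 14),
    pvalue = c(1e-6, 1e-5, 2e-6)
  )
  edges <- assemble_network(hits, tus)
  expect_equal(nrow(edges), 2L)  # duplicate (ntrC, TU1) collapsed
  e1 <- edges[edges$regulator_id == "ntrC", ]
  expect_equal(e1$best_site_pvalue, 1e-6)
  expect_equal(e1$evidence, "site_hit")
  # unknown target TU is an error
  bad <- dplyr::mutate(hits, seq_id = "TUX")
  expect_error(assemble_network(bad, tus), "unknown TU")
  # divergent bEBP gene within 300 nt gains a colocalization edge
  genes <- tibble::tibble(
    gene_id = c("hupR", "a1", "b1"), replicon_id = "chr",
    start = c(400L, 1000L, 5000L), end = c(850L, 2000L, 6000L),
    strand = c("-", "+", "+"), product = ""
  )
  calls <- tibble::tibble(protein_id = "hupR", family = "bEBP",
                          group_label = "bEBP", is_bebp = TRUE,
                          is_hks = FALSE, hybrid_kinase = FALSE)
  edges2 <- assemble_network(hits, tus, calls = calls, genes = genes)
  coloc <- edges2[edges2$evidence == "colocalization", ]
  expect_equal(coloc$regulator_id, "hupR")
  expect_equal(coloc$target_tu_id, "TU1")
  # no hits and no adjacency: empty network
  empty <- assemble_network(hits[0, ], tus)
  expect_equal(nrow(empty), 0L)
  # merged evidence when a site hit names the same regulator id
  hits_hupR <- dplyr::mutate(hits[1, ], motif_id = "hupR")
  edges3 <- assemble_network(hits_hupR, tus, calls = calls, genes = genes)
  both <- edges3[edges3$regulator_id == "hupR" &
                   edges3$target_tu_id == "TU1", ]
  expect_equal(both$evidence, "both")
  expect_equal(both$best_site_pvalue, 1e-6)
  # input row order never changes the edge list
  perm <- hits[c(3, 1, 2), ]
  expect_equal(assemble_network(perm, tus), edges)
})

test_that("the full pipeline recovers planted circuitry deterministically", {
  cfg <- simulation_config(n_genomes = 2L, n_operons_per_genome = 20L,
                           seed = 19L)
  gs <- generate_genome_set(cfg)
  dir <- withr::local_tempdir()
  paths <- write_genome_set(gs, dir)
  motif_path <- file.path(dir, "motifs.meme")
  write_meme_motifs(lapply(cfg$planted_motifs, function(m) m$pwm),
                    motif_path)
  genomes <- c("g1", "g2")
  run_cfg <- list(
    inputs = list(
      fasta = vapply(genomes, function(g) paths[[g]][["fna"]], character(1)),
      gff = vapply(genomes, function(g) paths[[g]][["gff"]], character(1)),
      domains = paths$domains, similarity = paths$similarity,
      genome_map = paths$genome_map, motifs = motif_path
    ),
    out_dir = file.path(dir, "out1"), seed = 1L
  )
  res <- run_pipeline(run_cfg)
  expect_setequal(unlist(res$manifest$stages),
                  c("read_inputs", "orthology", "classify", "tus", "scan",
                    "network"))
  # no dangling references
  expect_true(all(res$edges$target_tu_id %in% res$tus$tu_id))
  # truth comparison
  gmap <- tu_gene_map(res$tus)
  tu_of <- setNames(gmap$tu_id, gmap$gene_id)
  leaders <- setNames(gs$truth$operons$leader_gene_id,
                      gs$truth$operons$op_label)
  truth <- unique(paste(gs$truth$sites$motif_id,
                        tu_of[leaders[gs$truth$sites$op_label]]))
  pred <- paste(res$edges$regulator_id, res$edges$target_tu_id)
  expect_gte(mean(pred %in% truth), 0.9)   # precision
  expect_gte(mean(truth %in% pred), 0.9)   # recall
  # rerun with the same seed: byte-identical artifacts
  run_cfg$out_dir <- file.path(dir, "out2")
  run_pipeline(run_cfg)
  for (f in c("edges.tsv", "sites.bed", "tus.tsv", "calls.tsv", "ogs.tsv")) {
    expect_identical(readLines(file.path(dir, "out1", f)),
                     readLines(file.path(dir, "out2", f)), label = f)
  }
  # a corrupt GFF3 aborts naming the reading stage
  broken <- run_cfg
  bad_gff <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3", "chr\t.\tCDS\t9\t5\t.\t+\t0\tID=x"),
             bad_gff)
  broken$inputs$gff <- bad_gff
  broken$out_dir <- file.path(dir, "out3")
  expect_error(run_pipeline(broken), "read_inputs")
})

test_that("pipeline configs load from YAML", {
  cfg <- simulation_config(n_genomes = 1L, n_operons_per_genome = 6L,
                           seed = 29L)
  gs <- generate_genome_set(cfg)
  dir <- withr::local_tempdir()
  paths <- write_genome_set(gs, dir)
  motif_path <- file.path(dir, "motifs.meme")
  write_meme_motifs(lapply(cfg$planted_motifs, function(m) m$pwm),
                    motif_path)
  yml <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(
    inputs = list(fasta = paths$g1[["fna"]], gff = paths$g1[["gff"]],
                  domains = paths$domains, similarity = paths$similarity,
                  genome_map = paths$genome_map, motifs = motif_path),
    out_dir = file.path(dir, "out"),
    params = list(p_max = 1e-4), seed = 4L
  ), yml)
  res <- run_pipeline(yml)
  expect_true(file.exists(file.path(dir, "out", "manifest.yaml")))
  expect_true(nrow(res$edges) > 0L)
})
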