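test_that("background sampling hits the law of large numbers and is seeded", {
  bg <- uniform_background(0)
  s <- sample_background_sequence(bg, 1e5, seed = 1)
  freq <- table(strsplit(s, "")[[1]]) / nchar(s)
  expect_true(all(freq >= 0.24 & freq <= 0.26))
  expect_identical(s, sample_background_sequence(bg, 1e5, seed = 1))
  expect_false(identical(substr(s, 1, 100),
                         substr(sample_background_sequence(bg, 1e5, 2), 1, 100)))
})

test_that("an absorbing order-1 chain generates a constant sequence", {
  bg <- uniform_background(1)
  bg$cond[[1]][1, ] <- c(1, 0, 0, 0)           # always start at A
  bg$cond[[2]]["A", ] <- c(1, 0, 0, 0)         # P(A|A) = 1
  s <- sample_background_sequence(bg, 50, seed = 3)
  expect_equal(s, strrep("A", 50))
  expect_error(sample_background_sequence(uniform_background(4), 3),
               "shorter than the model order")
})

test_that("higher-order sampling reproduces trained conditionals", {
  # train an order-2 model on structured text, sample, retrain, compare
  # on well-supported contexts (rare contexts carry add-one smoothing bias)
  src <- paste(rep(c("AAGT", "CCAG", "TTGA"), 400), collapse = "")
  bg <- train_markov_background(src, order = 2L)
  s <- sample_background_sequence(bg, 6e4, seed = 9)
  bg2 <- train_markov_background(s, order = 2L)
  chars <- strsplit(s, "")[[1]]
  ctx <- paste0(chars[-length(chars)][-(length(chars) - 1L)],
                chars[-1][-(length(chars) - 1L)])
  common <- names(which(table(ctx) >= 2000))
  expect_gte(length(common), 6L)
  expect_lt(max(abs(bg$cond[[3]][common, ] - bg2$cond[[3]][common, ])),
            0.05)
})

test_that("site planting follows the ZOOPS generative model", {
  seqs <- uniform_seqs(50, 80, seed0 = 2000)
  cons <- consensus_pwm("TTGACATGCA", prob = 1 - 1e-12)
  # gamma = 1 with a consensus-only PWM: every sequence gets the consensus
  pl <- plant_sites(seqs, cons, gamma = 1, seed = 3)
  expect_equal(nrow(pl$truth), 50L)
  ok <- vapply(seq_len(nrow(pl$truth)), function(i) {
    tr <- pl$truth[i, ]
    sl <- substr(pl$sequences[[tr$seq_id]], tr$start, tr$end)
    if (tr$strand == "-") sl <- revcomp(sl)
    sl == "TTGACATGCA"
  }, logical(1))
  expect_true(all(ok))
  # gamma = 0 leaves everything untouched
  pl0 <- plant_sites(seqs, cons, gamma = 0, seed = 3)
  expect_identical(pl0$sequences, seqs)
  expect_equal(nrow(pl0$truth), 0L)
  # gamma = 0.8, 50 sequences: count inside the binomial 99% interval
  pl8 <- plant_sites(seqs, cons, gamma = 0.8, seed = 7)
  expect_gte(nrow(pl8$truth), qbinom(0.005, 50, 0.8))  # 30
  expect_lte(nrow(pl8$truth), 50L)
  expect_error(plant_sites(c(a = "ACGT"), cons, 1, 1), "wider")
})

test_that("sigma54 promoter planting writes -24 GC and -12 TGC", {
  up <- strrep("A", 40)
  out <- plant_sigma54_promoter(up)
  # position -k is string index L - k + 1 (L = 40)
  expect_equal(substr(out, 16, 17), "GC")   # -25, -24
  expect_equal(substr(out, 27, 29), "TGC")  # -14..-12
  expect_equal(plant_sigma54_promoter(out), out)  # idempotent
  expect_error(plant_sigma54_promoter(strrep("A", 10)), "at least 30")
  s70 <- plant_sigma70_promoter(strrep("C", 60))
  expect_equal(substr(s70, 26, 31), "TTGACA")  # -35..-30
  expect_equal(substr(s70, 49, 54), "TATAAT")  # -12..-7
})

test_that("generated genome sets are internally consistent", {
  cfg <- simulation_config(n_genomes = 2L, n_operons_per_genome = 8L,
                           seed = 5L)
  gs <- generate_genome_set(cfg)
  # gene conservation: GFF rows equal truth genes
  expect_equal(nrow(gs$genes),
               sum(lengths(gs$truth$operons$gene_ids)))
  # gap rule: intra-operon gaps <= 40, inter-operon gaps > 40
  for (rep_id in unique(gs$genes$replicon_id)) {
    g <- dplyr::arrange(gs$genes[gs$genes$replicon_id == rep_id, ], start)
    gaps <- g$start[-1] - g$end[-nrow(g)] - 1L
    same_op <- vapply(seq_len(nrow(g) - 1L), function(i) {
      sub("_g\\d+$", "", g$gene_id[[i]]) == sub("_g\\d+$", "", g$gene_id[[i + 1L]])
    }, logical(1))
    expect_true(all(gaps[same_op] <= 40L))
    expect_true(all(gaps[!same_op] > 40L))
  }
  # every truth site's genomic slice matches its recorded letters
  tr <- gs$truth$sites
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    sl <- substr(gs$sequences[[tr$replicon_id[[i]]]], tr$start[[i]],
                 tr$end[[i]])
    if (tr$strand[[i]] == "-") sl <- revcomp(sl)
    sl == tr$site_seq[[i]]
  }, logical(1))
  expect_true(all(ok))
  # planted orthologs appear as reciprocal rows in the similarity table
  og1 <- gs$truth$orthologs[gs$truth$orthologs$og_label == "rpoN_1", ]
  expect_equal(nrow(og1), 2L)
  both_dir <- sum(gs$similarity$query_id %in% og1$protein_id &
                    gs$similarity$subject_id %in% og1$protein_id)
  expect_equal(both_dir, 2L)
})

test_that("generation is byte-identical under the same config and seed", {
  cfg <- simulation_config(n_genomes = 1L, n_operons_per_genome = 6L,
                           seed = 17L)
  gs1 <- generate_genome_set(cfg)
  gs2 <- generate_genome_set(cfg)
  expect_identical(gs1$sequences, gs2$sequences)
  expect_identical(gs1$genes, gs2$genes)
  expect_identical(gs1$similarity, gs2$similarity)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genome_set(gs1, d1)
  write_genome_set(gs2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("truth bundles round-trip through the sectioned text format", {
  cfg <- simulation_config(n_genomes = 1L, n_operons_per_genome = 5L,
                           seed = 2L)
  gs <- generate_genome_set(cfg)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_truth_bundle(gs$truth, tf)
  back <- read_truth_bundle(tf)
  expect_setequal(names(back), names(gs$truth))
  expect_equal(nrow(back$sites), nrow(gs$truth$sites))
  expect_equal(back$sites$start, gs$truth$sites$start)
  expect_equal(back$operons$leader_gene_id, gs$truth$operons$leader_gene_id)
})

test_that("config validation rejects gap-rule violations", {
  expect_error(simulation_config(intra_operon_gap = c(0L, 50L)), "\\[0, 40\\]")
  expect_error(simulation_config(inter_operon_gap = c(30L, 100L)),
               "exceed 40")
  pm <- default_planted_motifs(10)
  pm[[1]]$gamma <- 1.5
  expect_error(simulation_config(planted_motifs = pm), "gamma")
})
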