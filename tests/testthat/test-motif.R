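test_that("PWM construction follows the pseudocount formula", {
  # unanimous counts, no pseudocount
  p <- build_pwm_from_sites(c("AC", "AC"), pseudocount = 0)
  expect_equal(p$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(p$matrix[, 2], c(A = 0, C = 1, G = 0, T = 0))
  # split column
  p2 <- build_pwm_from_sites(c("A", "C"), pseudocount = 0)
  expect_equal(unname(p2$matrix[1:2, 1]), c(0.5, 0.5))
  # (count + alpha q) / (n + alpha) with alpha = 1, uniform q
  p3 <- build_pwm_from_sites("A", pseudocount = 1)
  expect_equal(unname(p3$matrix[, 1]), c(0.625, 0.125, 0.125, 0.125))
  # raw frequencies reproduced exactly at alpha = 0
  sites <- c("ACGT", "ACGA", "TCGA")
  p4 <- build_pwm_from_sites(sites, pseudocount = 0)
  expect_equal(unname(p4$matrix["A", 1]), 2 / 3)
  expect_error(build_pwm_from_sites(c("A", "AC")), "equal length")
  expect_error(build_pwm_from_sites(character()), "zero sites")
})

test_that("Markov background training matches hand counts with smoothing", {
  bg0 <- train_markov_background("AACC", order = 0L)
  expect_equal(unname(background_marginal(bg0)),
               c(3, 3, 1, 1) / 8)  # counts 2,2,0,0 with add-one
  # order 1 on AAAAAAA: 6 AA transitions; P(A|A) = 7/10, others 1/10
  bg1 <- train_markov_background("AAAAAAA", order = 1L)
  expect_equal(unname(bg1$cond[[2]]["A", ]), c(7, 1, 1, 1) / 10)
  # contexts of every length <= k are present and normalized
  bg2 <- train_markov_background(strrep("ACGT", 50), order = 2L)
  expect_equal(nrow(bg2$cond[[3]]), 16L)
  expect_true(all(abs(rowSums(bg2$cond[[3]]) - 1) < 1e-9))
  expect_error(train_markov_background("ACG", order = 4L), "not enough")
  expect_error(train_markov_background("ACGT", order = 5L), "in \\[0, 4\\]")
})

test_that("log-odds scores are log2 ratios against the order-0 marginal", {
  p <- new_pwm(matrix(c(1, 0, 0, 0), 4), nsites = 1)
  # can't take log of 0 usefully, so use a pseudocounted unanimous column
  p2 <- build_pwm_from_sites(rep("A", 1000), pseudocount = 1e-9)
  lo <- log_odds(p2)
  expect_equal(unname(lo["A", 1]), 2, tolerance = 1e-6)  # log2(1/0.25)
  # PWM equal to background marginal gives all-zero scores
  bg <- uniform_background(0)
  pu <- new_pwm(matrix(0.25, 4, 3), nsites = 4)
  expect_true(all(abs(log_odds(pu, bg)) < 1e-12))
})

test_that("exact p-value DP matches brute-force enumeration (width <= 6)", {
  q0 <- setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  widths <- rep(c(2L, 3L, 4L, 5L, 6L), each = 2L)
  for (i in seq_along(widths)) {
    w <- widths[[i]]
    pwm <- random_pwm(w, seed = 100L + i)
    tab <- score_pvalue_table(pwm, eps = 1e-3)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    int_s <- integer(nrow(words))
    pr <- rep(1, nrow(words))
    for (j in seq_len(w)) {
      int_s <- int_s + tab$sint[cbind(words[, j], j)]
      pr <- pr * q0[words[, j]]
    }
    # the DP reproduces the enumerated tail mass on the common score grid
    p_enum <- vapply(int_s, function(s) sum(pr[int_s >= s]), numeric(1))
    p_dp <- regcircuit:::pvalue_of_int(tab, int_s)
    expect_lt(max(abs(p_dp - p_enum)), 1e-12)
    # p at an unattainably high score is 0
    expect_equal(regcircuit:::pvalue_of_int(tab, max(int_s) + 10L), 0)
  }
})

test_that("p-value table endpoints behave as required", {
  # width-1 PWM with a unique maximal-scoring base: p(max) = 1/4
  p <- new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 4), nsites = 10)
  tab <- score_pvalue_table(p)
  expect_equal(score_pvalue(tab, log2(0.7 / 0.25)), 0.25)
  # minimum attainable score has p = 1
  expect_equal(max(tab$pvalues), 1)
  rand <- random_pwm(8L, seed = 7)
  tab2 <- score_pvalue_table(rand)
  expect_equal(max(tab2$pvalues), 1)
  # monotone non-increasing in score
  expect_true(all(diff(tab2$pvalues) <= 1e-15))
})

test_that("scanner finds a planted site and respects strand symmetry", {
  pw <- reference_motif()
  s <- uniform_seqs(1, 200, seed0 = 4000)[[1]]
  substr(s, 100, 111) <- pwm_consensus(pw)
  hits <- scan_sequences(pw, c(fwd = s), p_max = 1e-4)
  expect_equal(hits$start, 100L)
  expect_equal(hits$strand, "+")
  expect_lt(hits$pvalue, 1e-4)
  # reverse complement of the whole sequence: same score/p on minus strand
  hits_rc <- scan_sequences(pw, c(rc = revcomp(s)), p_max = 1e-4)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)
  expect_equal(hits_rc$pvalue, hits$pvalue)
  expect_equal(hits_rc$start, 200L - 111L + 1L)
  # windows containing N are skipped, sequences shorter than W give no hits
  substr(s, 105, 105) <- "N"
  expect_equal(nrow(scan_sequences(pw, c(x = s), p_max = 1e-4)), 0L)
  expect_equal(nrow(scan_sequences(pw, c(tiny = "ACGT"), p_max = 0.5)), 0L)
})

test_that("overlap filtering keeps best scores and is idempotent", {
  h <- tibble::tibble(
    motif_id = "m", seq_id = "u",
    start = c(10L, 10L, 30L, 36L, 60L, 60L),
    end = c(21L, 21L, 41L, 47L, 71L, 71L),
    strand = c("+", "+", "+", "+", "+", "-"),
    score = c(10, 8, 5, 5, 7, 7),
    pvalue = c(1e-6, 1e-5, 1e-4, 1e-4, 1e-5, 1e-5)
  )
  f <- filter_overlaps(h)
  # coincident pair: score 10 wins; 30/36 overlap 6/12 = 50% -> both kept;
  # 60+/60- coincide with equal score and p -> leftmost (then strand) wins
  expect_equal(nrow(f), 4L)
  expect_true(all(c(10, 5, 5) %in% f$score))
  expect_equal(sum(f$start == 60L), 1L)
  # idempotent and permutation invariant
  expect_equal(filter_overlaps(f), f)
  perm <- h[sample.int(nrow(h)), ]
  expect_equal(filter_overlaps(perm), f)
})

test_that("information content implements the small-sample correction", {
  expect_equal(small_sample_correction(4), 3 / (8 * log(2)))
  p <- build_pwm_from_sites(rep("A", 4), pseudocount = 0)
  expect_equal(information_content(p)[[1]], 2 - 3 / (8 * log(2)),
               tolerance = 1e-9)
  # uniform column at large n -> ~0; clipped at 0 for small n
  pu <- new_pwm(matrix(0.25, 4, 1), nsites = 10000)
  expect_lt(information_content(pu)[[1]], 1e-3)
  pu_small <- new_pwm(matrix(0.25, 4, 1), nsites = 2)
  expect_equal(information_content(pu_small)[[1]], 0)
  expect_error(information_content(new_pwm(matrix(0.25, 4, 1), nsites = 0)),
               "nsites")
})

test_that("ZOOPS EM recovers a planted motif and its occupancy", {
  pw <- reference_motif()
  seqs <- uniform_seqs(30, 200)
  pl <- plant_sites(seqs, pw, gamma = 0.8, seed = 7)
  mot <- discover_motifs_zoops(pl$sequences, widths = 12L, n_motifs = 1L,
                               seed = 42)
  m <- mot[[1]]
  r_cols <- vapply(1:12, function(j) {
    cor(m$pwm$matrix[, j], pw$matrix[, j])
  }, numeric(1))
  rc <- pwm_reverse_complement(m$pwm)
  r_cols_rc <- vapply(1:12, function(j) {
    cor(rc$matrix[, j], pw$matrix[, j])
  }, numeric(1))
  expect_gte(max(mean(r_cols), mean(r_cols_rc)), 0.9)
  expect_lt(abs(m$gamma_hat - 0.8), 0.15)
  # the MAP-EM objective trace never decreases
  expect_true(all(diff(m$ll_trace) >= -1e-9))
})

test_that("ZOOPS on pure background yields a much weaker motif", {
  seqs <- uniform_seqs(30, 200)
  null_m <- discover_motifs_zoops(seqs, widths = 12L, n_motifs = 1L,
                                  seed = 1)[[1]]
  planted <- plant_sites(seqs, reference_motif(), gamma = 0.8, seed = 7)
  pl_m <- discover_motifs_zoops(planted$sequences, widths = 12L,
                                n_motifs = 1L, seed = 1)[[1]]
  ic_null <- mean(information_content(null_m$pwm))
  ic_pl <- mean(information_content(pl_m$pwm))
  expect_lt(ic_null, 1)          # spurious structure stays weak...
  expect_lt(ic_null, ic_pl - 0.5)  # ...and well below a genuine motif
  expect_true(all(diff(null_m$ll_trace) >= -1e-9))
})

test_that("multi-motif discovery separates two planted motifs via erasure", {
  pw1 <- consensus_pwm("TGGCACGATTTG", 0.97, motif_id = "m1")
  pw2 <- consensus_pwm("AACCGTTACCAA", 0.97, motif_id = "m2")
  seqs <- uniform_seqs(24, 160, seed0 = 6000)
  pl1 <- plant_sites(seqs, pw1, gamma = 1, seed = 21)
  pl2 <- plant_sites(pl1$sequences, pw2, gamma = 1, seed = 22)
  mots <- discover_motifs_zoops(pl2$sequences, widths = 12L, n_motifs = 2L,
                                seed = 5)
  expect_equal(length(mots), 2L)
  cons <- vapply(mots, function(m) m$consensus, character(1))
  canon <- function(x) {
    unname(vapply(x, function(s) min(s, revcomp(s)), character(1)))
  }
  expect_setequal(canon(cons),
                  canon(c(pwm_consensus(pw1), pwm_consensus(pw2))))
})

test_that("discovery input validation", {
  expect_error(discover_motifs_zoops(c(a = "ACGT"), widths = 4L),
               "at least 2")
  expect_error(discover_motifs_zoops(c(a = "ACGT", b = "ACG"),
                                     widths = 10L), "long enough")
})
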