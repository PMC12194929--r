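# shared fixtures, all built in code

uniform_seqs <- function(n, len, seed0 = 1000L) {
  setNames(
    vapply(seq_len(n), function(i) {
      sample_background_sequence(uniform_background(0L), len,
                                 seed = seed0 + i)
    }, character(1)),
    sprintf("s%02d", seq_len(n))
  )
}

# the planted reference motif used across motif-module tests
reference_motif <- function() {
  consensus_pwm("TGGCACGATTTG", prob = 0.94, motif_id = "planted")
}

# random strictly-positive PWM, columns renormalized
random_pwm <- function(width, seed) {
  m <- with_seed_local(seed, matrix(runif(4L * width, 0.05, 1), nrow = 4L))
  regcircuit::new_pwm(sweep(m, 2, colSums(m), "/"), motif_id = "rand",
                      renormalize = TRUE)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# brute-force oracle: exact p-values by enumerating all 4^W words under an
# order-0 background; returns P(score >= s) for the given real-valued score
enumerate_pvalue <- function(pwm, q0, score) {
  w <- ncol(pwm$matrix)
  lo <- log2(pwm$matrix / q0)
  words <- expand.grid(rep(list(1:4), w))
  sc <- as.matrix(words)
  tot <- numeric(nrow(sc))
  pr <- numeric(nrow(sc)) + 1
  for (j in seq_len(w)) {
    tot <- tot + lo[cbind(sc[, j], j)]
    pr <- pr * q0[sc[, j]]
  }
  vapply(score, function(s) sum(pr[tot >= s - 1e-12]), numeric(1))
}

# tiny similarity-table row builder
sim_hit <- function(q, s, bits = 100, ev = 1e-20, id = 80, cov = 90) {
  tibble::tibble(
    query_id = q, subject_id = s, pct_identity = id, aln_length = 100L,
    mismatches = 5L, gap_opens = 0L, q_start = 1L, q_end = 100L,
    s_start = 1L, s_end = 100L, evalue = ev, bitscore = bits,
    query_coverage = cov
  )
}
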