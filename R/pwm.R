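#' Position weight matrix objects
#'
#' A `pwm` is a 4 x W matrix of per-position base probabilities (rows
#' `A,C,G,T`) together with a motif id and the number of sites it was built
#' from. Every column must sum to 1; [build_pwm_from_sites()] with a
#' positive pseudocount guarantees strictly positive entries, which the
#' log-odds transform requires.
#'
#' @param matrix Numeric 4 x W matrix, rows in `A,C,G,T` order (rownames
#'   optional; enforced on construction).
#' @param motif_id Identifier string.
#' @param nsites Number of sites the matrix summarizes (used by the
#'   small-sample correction in [information_content()]).
#' @param renormalize Rescale columns to sum to exactly 1 (for matrices
#'   read back from fixed-precision files).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(matrix, motif_id = "motif", nsites = 0L,
                    renormalize = FALSE) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4L)
  if (any(matrix < 0)) abort("pwm entries must be non-negative")
  if (renormalize) {
    matrix <- sweep(matrix, 2, colSums(matrix), "/")
  }
  csums <- colSums(matrix)
  if (any(abs(csums - 1) > 1e-9)) {
    abort("pwm columns must sum to 1 (within 1e-9); use renormalize = TRUE")
  }
  rownames(matrix) <- DNA_BASES
  structure(
    list(motif_id = motif_id, matrix = matrix, nsites = as.integer(nsites)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  width=%d  nsites=%d  consensus=%s\n",
              x$motif_id, ncol(x$matrix), x$nsites, pwm_consensus(x)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Consensus string of a PWM (most probable base per column)
#' @param pwm A [pwm] object.
#' @return A character scalar of length `width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$matrix, 2, which.max)], collapse = "")
}

#' Width of a PWM
#' @param pwm A [pwm] object.
#' @return Integer number of columns.
#' @export
pwm_width <- function(pwm) ncol(pwm$matrix)

#' Reverse complement of a PWM
#' @param pwm A [pwm] object.
#' @return A [pwm] with columns reversed and complementary rows swapped.
#' @export
pwm_reverse_complement <- function(pwm) {
  m <- pwm$matrix[4:1, rev(seq_len(ncol(pwm$matrix))), drop = FALSE]
  new_pwm(m, motif_id = pwm$motif_id, nsites = pwm$nsites)
}

#' Build a PWM from aligned binding sites
#'
#' Column `j`'s probability for base `b` is
#' `(count_j(b) + alpha * q_b) / (n + alpha)` where `n` is the number of
#' sites and `q` the pseudocount composition (uniform by default).
#'
#' @param sites Character vector of equal-length `ACGT` strings.
#' @param pseudocount Total pseudocount `alpha`; defaults to `0.1 * n`,
#'   appropriate for curated site collections. Use `0` to reproduce raw
#'   frequencies exactly.
#' @param q Pseudocount composition over `A,C,G,T` (sums to 1).
#' @param motif_id Identifier for the resulting motif.
#' @return A [pwm] object with `nsites = length(sites)`.
#' @examples
#' build_pwm_from_sites(c("ACGT", "ACGA"), pseudocount = 0)
#' @export
build_pwm_from_sites <- function(sites, pseudocount = NULL,
                                 q = rep(0.25, 4), motif_id = "motif") {
  n <- length(sites)
  if (n == 0L) abort("cannot build a PWM from zero sites")
  w <- unique(nchar(sites))
  if (length(w) != 1L) abort("all sites must have equal length")
  if (any(grepl("[^ACGT]", sites))) abort("sites must be over ACGT")
  if (is.null(pseudocount)) pseudocount <- 0.1 * n
  chars <- matrix(unlist(strsplit(sites, "")), nrow = n, byrow = TRUE)
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(chars[, j], levels = DNA_BASES))
    as.numeric(tab)
  }, numeric(4))
  m <- (counts + pseudocount * q) / (n + pseudocount)
  new_pwm(m, motif_id = motif_id, nsites = n)
}

#' Train a kth-order Markov background model
#'
#' Estimates conditional base distributions from (k+1)-mer counts with
#' add-one smoothing, for every context length up to `order` (the shorter
#' contexts serve sequence starts). Windows containing `N` are skipped.
#'
#' @param sequences Character vector of nucleotide sequences, or a tibble
#'   with a `sequence` column.
#' @param order Markov order `k`, an integer in `[0, 4]`.
#' @return An object of class `markov_background` with elements `order` and
#'   `cond` (one conditional-probability matrix per context length:
#'   `cond[[m]]` has `4^(m-1)` context rows and 4 base columns).
#' @export
train_markov_background <- function(sequences, order = 0L) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  order <- as.integer(order)
  if (is.na(order) || order < 0L || order > 4L) {
    abort("background order must be an integer in [0, 4]")
  }
  sequences <- normalize_dna(sequences)
  usable <- sum(nchar(sequences))
  if (usable <= order) abort("not enough sequence to train this order")
  set <- Biostrings::DNAStringSet(sequences)
  cond <- lapply(seq_len(order + 1L), function(m) {
    counts <- colSums(Biostrings::oligonucleotideFrequency(set, width = m))
    # counts are in lexicographic kmer order: context-major, base-minor
    cm <- matrix(counts, ncol = 4L, byrow = TRUE)
    contexts <- if (m == 1L) "" else {
      kmers <- names(counts)
      unique(substr(kmers, 1L, m - 1L))
    }
    rownames(cm) <- contexts
    colnames(cm) <- DNA_BASES
    sm <- cm + 1
    sm / rowSums(sm)
  })
  structure(list(order = order, cond = cond), class = "markov_background")
}

#' Uniform background of a given order
#' @param order Markov order in `[0, 4]`.
#' @return A `markov_background` with all conditional probabilities 0.25.
#' @export
uniform_background <- function(order = 0L) {
  order <- as.integer(order)
  cond <- lapply(seq_len(order + 1L), function(m) {
    nctx <- 4L^(m - 1L)
    ctx <- if (m == 1L) "" else {
      apply(expand.grid(rep(list(DNA_BASES), m - 1L))[, (m - 1L):1, drop = FALSE],
            1, paste, collapse = "")
    }
    matrix(0.25, nrow = nctx, ncol = 4L,
           dimnames = list(sort(ctx), DNA_BASES))
  })
  structure(list(order = order, cond = cond), class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat(sprintf("<markov_background> order=%d  marginal: %s\n", x$order,
              paste(sprintf("%s=%.3f", DNA_BASES, background_marginal(x)),
                    collapse = " ")))
  invisible(x)
}

#' Order-0 marginal of a background model
#' @param background A `markov_background`.
#' @return Named numeric vector of base frequencies summing to 1.
#' @export
background_marginal <- function(background) {
  stopifnot(inherits(background, "markov_background"))
  setNames(as.numeric(background$cond[[1]][1, ]), DNA_BASES)
}

#' Log-odds score matrix of a PWM against a background
#'
#' Entry `(b, j)` is `log2(p_j(b) / q0_b)` where `q0` is the order-0
#' marginal of the background, in bits.
#'
#' @param pwm A [pwm] object with strictly positive entries.
#' @param background A `markov_background` (uniform order 0 when `NULL`).
#' @return A 4 x W numeric matrix in bits.
#' @export
log_odds <- function(pwm, background = NULL) {
  q0 <- if (is.null(background)) setNames(rep(0.25, 4), DNA_BASES)
        else background_marginal(background)
  log2(pwm$matrix / q0)
}

#' Exact p-value table for PWM log-odds scores
#'
#' Discretizes the log-odds matrix to multiples of `eps` bits and runs a
#' dynamic program over columns to accumulate the exact null distribution of
#' the total window score under the background's order-0 marginal.
#' `pvalue(s) = P(score >= s)`; the minimum attainable score has p-value 1.
#'
#' @param pwm A [pwm] object.
#' @param background A `markov_background` (uniform when `NULL`).
#' @param eps Score granularity in bits (default 1e-3).
#' @return An object of class `pwm_pvalue_table` used by [scan_sequences()]
#'   and [score_pvalue()].
#' @export
score_pvalue_table <- function(pwm, background = NULL, eps = 1e-3) {
  if (eps <= 0) abort("granularity eps must be > 0")
  q0 <- if (is.null(background)) setNames(rep(0.25, 4), DNA_BASES)
        else background_marginal(background)
  lo <- log_odds(pwm, background)
  if (any(!is.finite(lo))) {
    abort("log-odds matrix has non-finite entries; pseudocount the PWM first")
  }
  sint <- round(lo / eps)
  mode(sint) <- "integer"
  w <- ncol(sint)
  # DP: distribution of the running sum, one column at a time
  dist <- 1
  offset <- 0L  # int score of dist[1]
  for (j in seq_len(w)) {
    col <- sint[, j]
    cmin <- min(col)
    cmax <- max(col)
    newlen <- length(dist) + (cmax - cmin)
    newdist <- numeric(newlen)
    for (b in 1:4) {
      sh <- col[b] - cmin
      idx <- seq_along(dist) + sh
      newdist[idx] <- newdist[idx] + q0[b] * dist
    }
    dist <- newdist
    offset <- offset + cmin
  }
  pv <- rev(cumsum(rev(dist)))
  pv <- pmin(pmax(pv, 0), 1)
  structure(
    list(motif_id = pwm$motif_id, eps = eps, sint = sint, offset = offset,
         pvalues = pv, q0 = q0, lo = lo),
    class = "pwm_pvalue_table"
  )
}

#' Look up the p-value of a score
#'
#' @param table A `pwm_pvalue_table` from [score_pvalue_table()].
#' @param score Numeric score(s) in bits.
#' @return `P(window score >= score)` under the background null.
#' @export
score_pvalue <- function(table, score) {
  sint <- as.integer(round(score / table$eps))
  pvalue_of_int(table, sint)
}

# p-value of an integer (discretized) score; scores below the attainable
# minimum get p = 1, above the maximum get the smallest tail mass (0)
pvalue_of_int <- function(table, sint) {
  na <- is.na(sint)
  idx <- sint - table$offset + 1L
  idx[na | idx < 1L] <- 1L
  out <- numeric(length(idx))
  inrange <- idx <= length(table$pvalues)
  out[inrange] <- table$pvalues[idx[inrange]]
  out[!inrange] <- 0
  out[na] <- NA_real_
  out
}

#' Schneider-Stephens per-column information content
#'
#' `Rseq(j) = 2 - (H_j + e(n))` bits, with `H_j` the column's Shannon
#' entropy and `e(n) = 3 / (2 * ln(2) * n)` the small-sample correction for
#' `n` sites. Negative values are clipped to 0.
#'
#' @param pwm A [pwm] object.
#' @param nsites Number of sites; defaults to the PWM's own `nsites`.
#' @return Numeric vector of per-column information (bits).
#' @examples
#' p <- build_pwm_from_sites(c("AAAA", "AAAT"), pseudocount = 0)
#' information_content(p)
#' @export
information_content <- function(pwm, nsites = NULL) {
  n <- nsites %||% pwm$nsites
  if (is.null(n) || n < 1L) abort("information content requires nsites >= 1")
  m <- pwm$matrix
  h <- apply(m, 2, function(col) {
    nz <- col[col > 0]
    -sum(nz * log2(nz))
  })
  en <- small_sample_correction(n)
  pmax(2 - (h + en), 0)
}

#' Small-sample entropy correction `e(n) = 3 / (2 * ln(2) * n)`
#' @param n Number of sites.
#' @return Correction in bits.
#' @export
small_sample_correction <- function(n) {
  3 / (2 * log(2) * n)
}

# encode ACGTN string to integer codes 1..4 (NA for N), vector per sequence
encode_dna <- function(x) {
  v <- utf8ToInt(x)
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[v]
}

#' Reverse complement of nucleotide strings
#' @param x Character vector over `ACGTN`.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
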