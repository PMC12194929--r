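#' Scan sequences with a PWM and report significant sites
#'
#' Scores every window on one or both strands with the discretized log-odds
#' matrix and keeps windows whose exact null p-value is below `p_max`.
#' Windows containing `N` are skipped. Minus-strand hits are reported in
#' plus-strand coordinates of the scanned sequence and receive the same
#' score and p-value as their reverse complement would on the plus strand.
#'
#' @param pwm A [pwm] object, or a list of them (hits gain a `motif_id`
#'   column either way).
#' @param sequences Named character vector of nucleotide sequences, or a
#'   tibble with `id` and `sequence` columns.
#' @param background A `markov_background`; uniform order 0 when `NULL`.
#'   p-values are computed under its order-0 marginal.
#' @param p_max Report hits with `pvalue < p_max` (default 1e-4).
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @param eps Score granularity in bits passed to [score_pvalue_table()].
#' @return A tibble of site hits: `motif_id`, `seq_id`, `start`, `end`
#'   (1-based inclusive), `strand`, `score` (bits), `pvalue`, sorted by
#'   `(seq_id, start)`. Sequences shorter than the motif yield no hits.
#' @export
scan_sequences <- function(pwm, sequences, background = NULL, p_max = 1e-4,
                           both_strands = TRUE, eps = 1e-3) {
  if (p_max <= 0 || p_max > 1) abort("p_max must be in (0, 1]")
  seqs <- as_named_sequences(sequences)
  pwms <- if (inherits(pwm, "pwm")) list(pwm) else pwm
  out <- purrr::map(pwms, function(p) {
    tab <- score_pvalue_table(p, background, eps = eps)
    scan_one_pwm(tab, seqs, p_max, both_strands)
  })
  res <- list_rbind(out)
  arrange(res, .data$motif_id, .data$seq_id, .data$start, .data$strand)
}

as_named_sequences <- function(sequences) {
  if (is.data.frame(sequences)) {
    idcol <- intersect(c("id", "seq_id", "tu_id"), names(sequences))[1]
    if (is.na(idcol) || !"sequence" %in% names(sequences)) {
      abort("sequence table needs an id column and a `sequence` column")
    }
    return(setNames(sequences$sequence, sequences[[idcol]]))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  sequences
}

scan_one_pwm <- function(tab, seqs, p_max, both_strands) {
  w <- ncol(tab$sint)
  sint_fwd <- tab$sint
  # minus-strand scanning: PWM column j reads the complement of forward
  # position (start + W - j); equivalent to scoring forward windows with
  # the reverse-complemented score matrix
  sint_rev <- sint_fwd[4:1, rev(seq_len(w)), drop = FALSE]
  hits <- purrr::imap(seqs, function(s, sid) {
    enc <- encode_dna(normalize_dna(s))
    nw <- length(enc) - w + 1L
    if (nw < 1L) return(NULL)
    res <- list(
      score_windows(enc, sint_fwd, nw, w),
      if (both_strands) score_windows(enc, sint_rev, nw, w)
    )
    strands <- c("+", "-")
    rows <- purrr::imap(res, function(sc, k) {
      if (is.null(sc)) return(NULL)
      pv <- pvalue_of_int(tab, sc)
      keep <- which(!is.na(pv) & pv < p_max)
      if (length(keep) == 0L) return(NULL)
      tibble(
        seq_id = sid, start = keep, end = keep + w - 1L,
        strand = strands[[k]],
        score = sc[keep] * tab$eps, pvalue = pv[keep]
      )
    })
    list_rbind(purrr::compact(rows))
  })
  res <- list_rbind(purrr::compact(unname(hits)))
  if (nrow(res) == 0L) {
    return(tibble(motif_id = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = numeric(), pvalue = numeric()))
  }
  mutate(res, motif_id = tab$motif_id, .before = 1)
}

# integer window scores for all nw windows; NA where the window contains N
score_windows <- function(enc, sint, nw, w) {
  acc <- integer(nw)
  for (j in seq_len(w)) {
    b <- enc[j:(j + nw - 1L)]
    acc <- acc + sint[cbind(b, j)]
  }
  acc
}

#' Remove overlapping site hits, best score first
#'
#' Greedy filter within each scanned sequence: hits are visited by
#' descending score (ties: smaller p-value, then leftmost start, then
#' strand, then motif id) and a hit is retained only if it overlaps no
#' already-retained hit by more than 50% of the shorter hit's length. The
#' operation is idempotent and invariant to input row order.
#'
#' @param hits Tibble of site hits as returned by [scan_sequences()].
#' @param max_overlap_frac Maximum tolerated overlap as a fraction of the
#'   shorter hit (default 0.5; overlap strictly greater is removed).
#' @return The retained hits, sorted by `(seq_id, start)`.
#' @export
filter_overlaps <- function(hits, max_overlap_frac = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  mk <- if ("motif_id" %in% names(hits)) hits$motif_id else rep("", nrow(hits))
  ord <- order(hits$seq_id, -hits$score, hits$pvalue, hits$start,
               hits$strand, mk)
  hits <- hits[ord, ]
  keep <- logical(nrow(hits))
  for (sid in unique(hits$seq_id)) {
    idx <- which(hits$seq_id == sid)
    ret_start <- integer(0)
    ret_end <- integer(0)
    for (i in idx) {
      s <- hits$start[[i]]
      e <- hits$end[[i]]
      len <- e - s + 1L
      if (length(ret_start) > 0L) {
        ov <- pmin(ret_end, e) - pmax(ret_start, s) + 1L
        shorter <- pmin(ret_end - ret_start + 1L, len)
        if (any(ov > max_overlap_frac * shorter)) next
      }
      keep[[i]] <- TRUE
      ret_start <- c(ret_start, s)
      ret_end <- c(ret_end, e)
    }
  }
  out <- hits[keep, ]
  arrange(out, .data$seq_id, .data$start, .data$strand)
}
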