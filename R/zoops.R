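#' ZOOPS expectation-maximization motif discovery
#'
#' Discovers up to `n_motifs` ungapped motifs under the "zero or one
#' occurrence per sequence" model. For each candidate width, starting PWMs
#' are seeded from the most over-represented W-mers (observed count over
#' background expectation), then refined by EM: the E-step computes
#' per-window site posteriors and per-sequence occupancy given the current
#' PWM and occupancy rate gamma; the M-step re-estimates the PWM (with a
#' small pseudocount) and gamma. The best width/start is the one maximizing
#' per-site information content times the expected number of sites. Sites
#' of an accepted motif are probabilistically erased (letters down-weighted
#' by their site posterior) before the next motif is sought.
#'
#' @param sequences Named character vector of nucleotide sequences (or a
#'   tibble with `id`/`sequence` columns); at least 2 sequences, each at
#'   least as long as the largest width.
#' @param widths Integer vector of candidate motif widths (default `5:20`).
#' @param n_motifs Maximum number of motifs to return (default 1, up to 10).
#' @param background A `markov_background`; its order-0 marginal drives the
#'   likelihood ratios. Trained at order 0 from the input when `NULL`.
#' @param seed Integer seed controlling all stochastic choices.
#' @param n_starts Seed W-mers tried per width (default 5).
#' @param max_iter Maximum EM iterations per start (default 200).
#' @param tol Stop when the log-likelihood gain drops below this (1e-6).
#' @param pseudocount Per-base pseudocount inside the M-step (0.01).
#' @param both_strands Model sites on either strand (default `TRUE`).
#' @return A list of `zoops_motif` objects, each with elements `pwm`,
#'   `gamma_hat`, `objective`, `ll_trace`, `site_posteriors` (a tibble of
#'   the best window per sequence), and `consensus`.
#' @export
discover_motifs_zoops <- function(sequences, widths = 5:20, n_motifs = 1L,
                                  background = NULL, seed = 1L,
                                  n_starts = 5L, max_iter = 200L,
                                  tol = 1e-6, pseudocount = 0.01,
                                  both_strands = TRUE) {
  seqs <- as_named_sequences(sequences)
  if (length(seqs) < 2L) abort("motif discovery needs at least 2 sequences")
  n_motifs <- min(as.integer(n_motifs), 10L)
  widths <- sort(unique(as.integer(widths)))
  if (max(nchar(seqs)) < max(widths)) {
    abort("no sequence is long enough for the requested widths")
  }
  if (is.null(background)) background <- train_markov_background(seqs, 0L)
  q0 <- background_marginal(background)
  enc <- lapply(seqs, function(s) encode_dna(normalize_dna(s)))
  # per-position erasure weights, updated after each accepted motif
  wts <- lapply(enc, function(e) rep(1, length(e)))

  motifs <- list()
  for (r in seq_len(n_motifs)) {
    best <- NULL
    for (w in widths) {
      layout <- zoops_layout(enc, w, both_strands)
      if (is.null(layout)) next
      seeds <- seed_kmers(enc, w, q0, n_starts)
      if (length(seeds) == 0L) next
      u <- window_weights(wts, layout)
      for (k in seq_along(seeds)) {
        fit <- with_seed(seed + 1000L * r + 10L * w + k, {
          zoops_em(layout, seed_pwm(seeds[[k]]), q0, u,
                   max_iter = max_iter, tol = tol,
                   pseudocount = pseudocount)
        })
        nsites_eff <- max(1L, round(fit$gamma * layout$n_seq))
        ic <- information_content(
          new_pwm(fit$pwm, nsites = nsites_eff), nsites = nsites_eff)
        obj <- sum(ic) * fit$gamma * layout$n_seq
        cand <- list(fit = fit, layout = layout, objective = obj,
                     width = w, seed_kmer = seeds[[k]])
        if (is.null(best) || obj > best$objective + 1e-12) best <- cand
      }
    }
    if (is.null(best)) break
    fit <- best$fit
    layout <- best$layout
    nsites_eff <- max(1L, round(fit$gamma * layout$n_seq))
    pwm <- new_pwm(fit$pwm, motif_id = sprintf("motif_%d", r),
                   nsites = nsites_eff)
    post <- site_posterior_table(fit, layout)
    motifs[[r]] <- structure(
      list(pwm = pwm, gamma_hat = fit$gamma, objective = best$objective,
           ll_trace = fit$ll_trace, site_posteriors = post,
           consensus = pwm_consensus(pwm), width = best$width,
           iterations = length(fit$ll_trace),
           converged = fit$converged),
      class = "zoops_motif"
    )
    wts <- erase_sites(wts, fit, layout)
  }
  motifs
}

#' @export
print.zoops_motif <- function(x, ...) {
  cat(sprintf(
    "<zoops_motif> %s  width=%d  gamma_hat=%.3f  consensus=%s  iters=%d\n",
    x$pwm$motif_id, x$width, x$gamma_hat, x$consensus, x$iterations))
  invisible(x)
}

# flatten all scannable windows of all sequences (both strands) into one
# table of base-index rows; minus-strand rows already list the bases the
# PWM columns read, so scoring and counting treat all rows uniformly
zoops_layout <- function(enc, w, both_strands) {
  rows <- list()
  meta <- list()
  for (i in seq_along(enc)) {
    e <- enc[[i]]
    nw <- length(e) - w + 1L
    if (nw < 1L) next
    idx <- outer(seq_len(nw), 0:(w - 1L), "+")
    fwd <- matrix(e[idx], nrow = nw)
    ok <- !apply(is.na(fwd), 1, any)
    if (any(ok)) {
      rows[[length(rows) + 1L]] <- fwd[ok, , drop = FALSE]
      meta[[length(meta) + 1L]] <-
        tibble(seq_index = i, start = which(ok), strand = "+")
    }
    if (both_strands) {
      rev_ok <- fwd[ok, , drop = FALSE]
      rc <- 5L - rev_ok[, w:1, drop = FALSE]
      if (any(ok)) {
        rows[[length(rows) + 1L]] <- rc
        meta[[length(meta) + 1L]] <-
          tibble(seq_index = i, start = which(ok), strand = "-")
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  B <- do.call(rbind, rows)
  meta <- list_rbind(meta)
  m_per_seq <- tabulate(meta$seq_index, nbins = length(enc))
  used <- which(m_per_seq > 0L)
  list(B = B, meta = meta, w = w, n_seq = length(used), used = used,
       m_per_seq = m_per_seq, seq_ids = names(enc))
}

# erasure weight of each window = product of per-position weights it covers
window_weights <- function(wts, layout) {
  w <- layout$w
  vapply(seq_len(nrow(layout$meta)), function(r) {
    i <- layout$meta$seq_index[[r]]
    s <- layout$meta$start[[r]]
    prod(wts[[i]][s:(s + w - 1L)])
  }, numeric(1))
}

# top over-represented W-mers: observed count / expected count under q0
seed_kmers <- function(enc, w, q0, n_starts) {
  counts <- new.env(parent = emptyenv())
  total <- 0L
  for (e in enc) {
    nw <- length(e) - w + 1L
    if (nw < 1L) next
    idx <- outer(seq_len(nw), 0:(w - 1L), "+")
    m <- matrix(e[idx], nrow = nw)
    ok <- !apply(is.na(m), 1, any)
    if (!any(ok)) next
    words <- apply(m[ok, , drop = FALSE], 1, function(v) {
      paste(DNA_BASES[v], collapse = "")
    })
    total <- total + length(words)
    tb <- table(words)
    for (k in names(tb)) {
      counts[[k]] <- (counts[[k]] %||% 0L) + tb[[k]]
    }
  }
  kmers <- ls(counts)
  if (length(kmers) == 0L) return(character())
  obs <- vapply(kmers, function(k) counts[[k]], numeric(1))
  expd <- vapply(kmers, function(k) {
    total * prod(q0[strsplit(k, "")[[1]]])
  }, numeric(1))
  ratio <- obs / pmax(expd, .Machine$double.xmin)
  ord <- order(-ratio, -obs, kmers)
  kmers[ord][seq_len(min(n_starts, length(kmers)))]
}

# starting PWM: probability 0.7 at the seed base, 0.1 elsewhere
seed_pwm <- function(kmer) {
  b <- match(strsplit(kmer, "")[[1]], DNA_BASES)
  m <- matrix(0.1, nrow = 4L, ncol = length(b))
  m[cbind(b, seq_along(b))] <- 0.7
  m
}

zoops_em <- function(layout, pwm0, q0, u, max_iter, tol, pseudocount) {
  B <- layout$B
  w <- layout$w
  nwin <- nrow(B)
  seqidx <- layout$meta$seq_index
  m_i <- layout$m_per_seq[seqidx]      # windows per sequence, per row
  gamma <- 0.5
  pwm <- pwm0
  lq0 <- log(q0)
  bg_row <- rowSums(matrix(lq0[B], nrow = nwin))
  ll_trace <- numeric(0)
  converged <- FALSE
  z <- numeric(nwin)
  for (it in seq_len(max_iter)) {
    lp <- log(pwm)
    # log likelihood-ratio of each window under the motif vs background
    lr_log <- numeric(nwin)
    for (j in seq_len(w)) {
      lr_log <- lr_log + lp[cbind(B[, j], j)]
    }
    lr <- exp(lr_log - bg_row) * u
    num <- gamma * lr / m_i
    s_i <- rowsum(num, seqidx)            # per-sequence site mass
    denom_i <- (1 - gamma) + s_i[, 1]
    # objective = log likelihood plus the Dirichlet(1 + pseudocount) log
    # prior on the PWM; the pseudocounted M-step maximizes this posterior,
    # so the trace is non-decreasing (the raw likelihood alone need not be)
    ll <- sum(log(denom_i)) + pseudocount * sum(lp)
    z <- num / denom_i[match(seqidx, as.integer(rownames(s_i)))]
    # M-step
    counts <- matrix(pseudocount, nrow = 4L, ncol = w)
    for (j in seq_len(w)) {
      cs <- rowsum(z, B[, j])
      counts[as.integer(rownames(cs)), j] <-
        counts[as.integer(rownames(cs)), j] + cs[, 1]
    }
    pwm_new <- sweep(counts, 2, colSums(counts), "/")
    q_i <- rowsum(z, seqidx)[, 1]
    gamma_new <- mean(pmin(q_i, 1))
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && ll - ll_trace[[it - 1L]] < tol) {
      converged <- TRUE
      pwm <- pwm_new
      gamma <- gamma_new
      break
    }
    pwm <- pwm_new
    gamma <- gamma_new
  }
  list(pwm = pwm, gamma = gamma, z = z, ll_trace = ll_trace,
       converged = converged)
}

site_posterior_table <- function(fit, layout) {
  df <- layout$meta %>%
    mutate(
      posterior = fit$z,
      seq_id = layout$seq_ids[.data$seq_index],
      end = .data$start + layout$w - 1L
    )
  df %>%
    group_by(.data$seq_id) %>%
    arrange(desc(.data$posterior), .data$start, .data$strand,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("seq_id", "start", "end", "strand", "posterior") %>%
    arrange(.data$seq_id)
}

erase_sites <- function(wts, fit, layout) {
  z <- fit$z
  touch <- which(z > 1e-4)
  for (r in touch) {
    i <- layout$meta$seq_index[[r]]
    s <- layout$meta$start[[r]]
    span <- s:(s + layout$w - 1L)
    wts[[i]][span] <- wts[[i]][span] * (1 - z[[r]])
  }
  wts
}
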