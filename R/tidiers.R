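#' Tidy a PWM into long format
#'
#' @param x A [pwm] object.
#' @param ... Unused.
#' @return A tibble with `motif_id`, `position`, `base`, `prob`.
#' @method tidy pwm
#' @export
tidy.pwm <- function(x, ...) {
  w <- ncol(x$matrix)
  tibble(
    motif_id = x$motif_id,
    position = rep(seq_len(w), each = 4L),
    base = rep(DNA_BASES, w),
    prob = as.numeric(x$matrix)
  )
}

#' One-row summary of a PWM
#'
#' @param x A [pwm] object.
#' @param ... Unused.
#' @return A tibble with `motif_id`, `width`, `nsites`, `total_ic` (bits;
#'   `NA` when `nsites` is 0), `consensus`.
#' @method glance pwm
#' @export
glance.pwm <- function(x, ...) {
  tibble(
    motif_id = x$motif_id,
    width = ncol(x$matrix),
    nsites = x$nsites,
    total_ic = if (x$nsites >= 1L) sum(information_content(x)) else NA_real_,
    consensus = pwm_consensus(x)
  )
}

#' Tidy a discovered ZOOPS motif: per-sequence best site posteriors
#'
#' @param x A `zoops_motif` from [discover_motifs_zoops()].
#' @param ... Unused.
#' @return A tibble with `seq_id`, `start`, `end`, `strand`, `posterior`.
#' @method tidy zoops_motif
#' @export
tidy.zoops_motif <- function(x, ...) {
  x$site_posteriors
}

#' One-row summary of a discovered ZOOPS motif
#'
#' @param x A `zoops_motif`.
#' @param ... Unused.
#' @return A tibble with `motif_id`, `width`, `gamma_hat`, `objective`,
#'   `iterations`, `converged`, `consensus`.
#' @method glance zoops_motif
#' @export
glance.zoops_motif <- function(x, ...) {
  tibble(
    motif_id = x$pwm$motif_id,
    width = x$width,
    gamma_hat = x$gamma_hat,
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged,
    consensus = x$consensus
  )
}

#' Tidy a Markov background model
#'
#' @param x A `markov_background`.
#' @param ... Unused.
#' @return A tibble with `context_length`, `context`, `base`, `prob`.
#' @method tidy markov_background
#' @export
tidy.markov_background <- function(x, ...) {
  list_rbind(lapply(seq_along(x$cond), function(m) {
    cm <- x$cond[[m]]
    tibble(
      context_length = m - 1L,
      context = rep(rownames(cm), times = 4L),
      base = rep(colnames(cm), each = nrow(cm)),
      prob = as.numeric(cm)
    )
  }))
}
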