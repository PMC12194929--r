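#' Bar-style sequence logo of a PWM
#'
#' Plots each column as a stack of base-colored bars whose total height is
#' the column's Schneider-Stephens information content (bits) and whose
#' segments are proportional to the base frequencies, the standard logo
#' layout rendered with rectangles rather than glyph outlines.
#'
#' @param object A [pwm] object.
#' @param nsites Site count for the small-sample correction (defaults to
#'   the PWM's `nsites`, or 20 when unset).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pwm
#' @export
autoplot.pwm <- function(object, nsites = NULL, ...) {
  n <- nsites %||% (if (object$nsites >= 1L) object$nsites else 20L)
  ic <- information_content(object, nsites = n)
  df <- tidy(object) %>%
    group_by(.data$position) %>%
    arrange(.data$prob, .by_group = TRUE) %>%
    mutate(
      height = .data$prob * ic[.data$position],
      ymax = cumsum(.data$height),
      ymin = .data$ymax - .data$height
    ) %>%
    ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$position - 0.45, xmax = .data$position + 0.45,
      ymin = .data$ymin, ymax = .data$ymax, fill = .data$base
    )) +
    ggplot2::geom_text(
      data = df %>% group_by(.data$position) %>%
        arrange(desc(.data$prob), .by_group = TRUE) %>% slice(1) %>%
        ungroup(),
      ggplot2::aes(x = .data$position, y = .data$ymax + 0.08,
                   label = .data$base),
      size = 3
    ) +
    ggplot2::scale_fill_manual(values = c(
      A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839"
    )) +
    ggplot2::labs(
      title = object$motif_id, x = "position", y = "information (bits)",
      fill = "base"
    ) +
    ggplot2::ylim(0, 2.1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pwm
#' @method autoplot zoops_motif
#' @export
autoplot.zoops_motif <- function(object, ...) {
  autoplot.pwm(object$pwm) +
    ggplot2::labs(subtitle = sprintf("gamma_hat = %.2f, consensus %s",
                                     object$gamma_hat, object$consensus))
}

#' Heatmap of the genome-by-OG copy-number matrix
#'
#' The capped 0-2 view of ortholog copy numbers across genomes.
#'
#' @param counts Matrix from [og_count_matrix()].
#' @param cap Display cap (default 2).
#' @return A ggplot object.
#' @export
plot_og_heatmap <- function(counts, cap = 2L) {
  df <- as_tibble(as.data.frame.table(pmin(counts, cap),
                                      responseName = "copies")) %>%
    rename(genome = "Var1", og = "Var2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$og, y = .data$genome,
                                   fill = factor(.data$copies))) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "copies") +
    ggplot2::labs(x = "ortholog group", y = "genome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot the regulator-to-operon network
#'
#' Regulators and target TUs laid out with a deterministic force-directed
#' embedding; edge linetype encodes the evidence kind.
#'
#' @param edges Edge tibble from [assemble_network()].
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_regulatory_network <- function(edges, seed = 1L) {
  if (nrow(edges) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator_id", "target_tu_id")], directed = TRUE)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(
    name = igraph::V(g)$name,
    x = xy[, 1], y = xy[, 2],
    role = ifelse(igraph::V(g)$name %in% edges$regulator_id,
                  "regulator", "target TU")
  )
  seg <- edges %>%
    left_join(nodes, by = c(regulator_id = "name")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(nodes, by = c(target_tu_id = "name")) %>%
    rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$evidence),
      color = "grey50"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$role), size = 3
    ) +
    ggplot2::geom_text(
      data = nodes[nodes$role == "regulator", ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1, size = 3
    ) +
    ggplot2::theme_void()
}
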