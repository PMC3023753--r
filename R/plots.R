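# ggplot2 graphics for each result type.

#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_structure <- function(object, colour = NULL, ...) {
  s <- object$scores
  if (ncol(s) < 3L) {
    abort("need at least two principal coordinates to plot.",
          class = "bruisemap_input_error")
  }
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$PCo1, y = .data$PCo2))
  if (!is.null(colour)) {
    s$colour <- colour
    p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                         colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$explained[2]),
      title = "Principal coordinates of the marker panel") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.kinship_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$clone_i, y = .data$clone_j,
                                 fill = .data$kinship)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "kinship",
                  title = "Marker-estimated kinship") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.pk_scan <- function(object, p_highlight = 0.001, ...) {
  d <- as_tibble(object) |>
    mutate(neglog10p = -log10(.data$p_value))
  has_chr <- "chromosome" %in% names(d) && !all(is.na(d$chromosome))
  aes <- if (has_chr) {
    ggplot2::aes(x = stats::reorder(.data$fragment, .data$p_value),
                 y = .data$neglog10p, colour = .data$chromosome)
  } else {
    ggplot2::aes(x = stats::reorder(.data$fragment, .data$p_value),
                 y = .data$neglog10p)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(p_highlight),
                        linetype = "dashed") +
    ggplot2::labs(x = "fragment (ordered by p)",
                  y = expression(-log[10](p)),
                  title = unique(d$trait)[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.entry_means <- function(object, bins = 30, ...) {
  d <- filter(as_tibble(object), .data$estimable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = sprintf("adjusted entry mean (%s)",
                              attr(object, "trait") %||% ""),
                  y = "clones") +
    ggplot2::theme_minimal()
}

#' Scatter plot of two traits' adjusted entry means
#'
#' @param means_by_trait Named list of [adjusted_entry_means()] results
#'   (or one combined tibble).
#' @param trait_x,trait_y Traits to plot.
#' @return A ggplot.
#' @export
plot_trait_pair <- function(means_by_trait, trait_x, trait_y) {
  tbl <- if (is.data.frame(means_by_trait)) {
    as_tibble(means_by_trait)
  } else {
    purrr::list_rbind(purrr::map(means_by_trait, as_tibble))
  }
  wide <- tbl |>
    filter(.data$trait %in% c(trait_x, trait_y)) |>
    select("clone", "trait", "estimate") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "estimate")
  rho <- cor(wide[[trait_x]], wide[[trait_y]],
             use = "complete.obs")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[trait_x]],
                                     y = .data[[trait_y]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(title = sprintf("%s vs %s (rho = %.2f)", trait_y,
                                  trait_x, rho)) +
    ggplot2::theme_minimal()
}
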