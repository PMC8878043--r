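#' Heatmap of intergenomic similarity
#'
#' @param object `phage_similarity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phage_similarity <- function(object, ...) {
  plot_matrix_heatmap(object$matrix, "similarity (%)")
}

#' Heatmap of shared protein content
#'
#' @param object `phage_shared` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phage_shared <- function(object, ...) {
  plot_matrix_heatmap(object$matrix, "shared proteins (%)")
}

plot_matrix_heatmap <- function(m, fill_lab) {
  df <- as_tibble(m, rownames = "genome_a") %>%
    tidyr::pivot_longer(-"genome_a", names_to = "genome_b",
                        values_to = "value")
  ids <- rownames(m)
  df$genome_a <- factor(df$genome_a, levels = ids)
  df$genome_b <- factor(df$genome_b, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_a, .data$genome_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = fill_lab) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Stacked bar chart of a pangenome partition
#'
#' @param summaries Output of [pangenome_partition()].
#' @return A ggplot object.
#' @export
plot_pangenome <- function(summaries) {
  df <- summaries %>%
    dplyr::select("cluster_id", "n_core", "n_accessory", "n_unique") %>%
    tidyr::pivot_longer(-"cluster_id", names_to = "class",
                        values_to = "count") %>%
    dplyr::mutate(class = factor(sub("^n_", "", .data$class),
                                 levels = c("core", "accessory", "unique")))
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster_id, .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "protein groups / proteins",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Long-format pairwise similarities
#'
#' @param x `phage_similarity` object.
#' @param ... Unused.
#' @return Tibble of unordered genome pairs with similarity and
#'   aligned-fraction diagnostics.
#' @export
tidy.phage_similarity <- function(x, ...) {
  x$pairs
}

#' Long-format shared-content pairs
#'
#' @param x `phage_shared` object.
#' @param ... Unused.
#' @return Tibble: `genome_a`, `genome_b`, `shared_percent` (upper
#'   triangle).
#' @export
tidy.phage_shared <- function(x, ...) {
  m <- x$matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(genome_a = rownames(m)[idx[, 1]], genome_b = colnames(m)[idx[, 2]],
         shared_percent = m[idx])
}
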