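#' @exportS3Method ggplot2::autoplot
autoplot.qc_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("plate_id", "z_factor", "sb_ratio", "cv_dmso")],
    cols = -"plate_id", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$plate_id, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-plate assay QC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Activity heatmap in dendrogram order
#'
#' Tile plot of the integer-coded activity matrix with compounds ordered
#' by the clustering: red = active, light red = inconclusive, white =
#' inactive, grey = untested.
#'
#' @param object An [cluster_profiles()] result.
#' @param encoded The [encode_outcomes()] matrix it was built from.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.activity_clustering <- function(object, encoded, ...) {
  stopifnot(is.matrix(encoded))
  m <- encoded[object$order, , drop = FALSE]
  long <- tibble::as_tibble(m, rownames = "compound_id")
  long <- tidyr::pivot_longer(long, cols = -"compound_id",
                              names_to = "sample_id", values_to = "code")
  long$compound_id <- factor(long$compound_id, levels = rev(object$order))
  long$outcome <- factor(
    c("active", "inconclusive", "inactive", "untested")[long$code],
    levels = c("active", "inconclusive", "inactive", "untested")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$compound_id,
                                     fill = .data$outcome)) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(active = "#b2182b",
                                          inconclusive = "#f4a582",
                                          inactive = "white",
                                          untested = "grey70")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Outcome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}
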