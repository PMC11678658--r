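# ggplot2 displays for the result types.

#' @method autoplot mps_spectrum
#' @export
autoplot.mps_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$k), y = .data$exactly_k)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "number of disease groups with altered expression",
                  y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Bar chart of a sharing spectrum
#'
#' @param spectrum An `mps_spectrum` tibble.
#' @return A ggplot object.
#' @export
plot_sharing_spectrum <- function(spectrum) autoplot(spectrum)

#' @method autoplot mps_markers
#' @export
autoplot.mps_markers <- function(object, ...) {
  groups <- attr(object, "groups")
  long <- tidyr::pivot_longer(object, dplyr::all_of(groups),
                              names_to = "group", values_to = "log2fc")
  long$group <- factor(long$group, levels = groups)
  long$transcript_id <- factor(long$transcript_id, levels = rev(object$transcript_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$transcript_id,
                                     fill = .data$log2fc)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(data = long[is.na(long$log2fc), ], label = "X", size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  na.value = "grey90", name = "log2FC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Masked heatmap of a shared-marker table
#'
#' Tiles show the log2 fold change in each altered group; masked (not
#' altered) cells are grey and labelled "X".
#'
#' @param markers An `mps_markers` tibble.
#' @return A ggplot object.
#' @export
plot_marker_heatmap <- function(markers) autoplot(markers)
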