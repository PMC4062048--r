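#' Bar chart of linkage scores before and after digestion
#'
#' Mirrors the classic presentation of duplex linkage experiments: one bar
#' pair per sample and assay, undigested score beside the digested one. A
#' genuine linkage signal shows a tall undigested bar collapsing after
#' digestion.
#'
#' @param df A tibble from [digestion_contrast()] or [call_motif()]
#'   (columns `sample_id`, `percent_linked_undigested`,
#'   `percent_linked_digested`).
#' @return A ggplot object.
#' @export
plot_linkage <- function(df) {
  need <- c("sample_id", "percent_linked_undigested", "percent_linked_digested")
  if (!all(need %in% names(df))) {
    stop_ddpcr("need a digestion_contrast()-style tibble",
               class = "ddpcrlink_error_columns")
  }
  long <- df |>
    tidyr::pivot_longer(
      c("percent_linked_undigested", "percent_linked_digested"),
      names_to = "aliquot", values_to = "percent_linked"
    ) |>
    dplyr::mutate(aliquot = factor(
      ifelse(.data$aliquot == "percent_linked_undigested",
             "undigested", "digested"),
      levels = c("undigested", "digested")
    ))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sample_id, y = pmax(0, .data$percent_linked),
    fill = .data$aliquot
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(undigested = "grey10",
                                          digested = "grey65")) +
    ggplot2::labs(x = NULL, y = "%L (normalized linkage score)",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if ("assay" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$assay))
  }
  p
}

#' Scatter plot of raw copy-number estimates with integer calls
#'
#' One point per sample, ordered by estimate, coloured by its assigned
#' integer bin, with horizontal guides at the integers — the standard way
#' to eyeball how well raw estimates fit to integers and where clusters
#' sit.
#'
#' @param df Output of [assign_copy_numbers()] (columns `raw_cn`,
#'   `integer_cn`, optionally `ci_low`/`ci_high` and `review_flag`).
#' @return A ggplot object.
#' @export
plot_copy_numbers <- function(df) {
  if (!all(c("raw_cn", "integer_cn") %in% names(df))) {
    stop_ddpcr("need assign_copy_numbers() output",
               class = "ddpcrlink_error_columns")
  }
  df <- dplyr::arrange(tibble::as_tibble(df), .data$raw_cn)
  df$rank <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$raw_cn,
    colour = factor(.data$integer_cn)
  )) +
    ggplot2::geom_hline(yintercept = unique(df$integer_cn), linetype = 3,
                        colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "sample (ordered by estimate)",
                  y = "raw copy-number estimate", colour = "copies") +
    ggplot2::theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(df))) {
    p <- p + ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), alpha = 0.5
    )
  }
  if ("review_flag" %in% names(df) && any(df$review_flag)) {
    p <- p + ggplot2::geom_point(
      data = df[df$review_flag, ], shape = 1, size = 4, colour = "black"
    )
  }
  p
}
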