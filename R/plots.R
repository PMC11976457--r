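# ggplot2 views of the main result types.

#' Boxplots of omics features by cohort
#'
#' The TMB / SCNA / HRD / gain / loss / UPD / LOH / TAI / LST comparison
#' panel: one boxplot per feature, cohorts side by side.
#'
#' @param features Feature table from [cohort_features()].
#' @param feature_cols Features to show; defaults to the standard panel.
#' @return A ggplot object.
#' @export
plot_feature_comparison <- function(features,
                                    feature_cols = c("tmb", "scna_fraction",
                                                     "hrd_total",
                                                     "fraction_gain",
                                                     "fraction_loss",
                                                     "fraction_upd",
                                                     "hrd_loh", "tai",
                                                     "lst")) {
  features |>
    tidyr::pivot_longer(dplyr::all_of(feature_cols),
                        names_to = "feature", values_to = "value") |>
    dplyr::mutate(feature = factor(.data$feature, levels = feature_cols)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cohort, y = .data$value,
                                 fill = .data$cohort)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Arm-level copy-number landscape heatmap
#'
#' Tile map of arm states (gain / loss / UPD) per sample, ordered by
#' cohort.
#'
#' @param arm_ev Arm events from [arm_events()].
#' @param clinical Tibble with `sample` and `cohort` for column ordering.
#' @return A ggplot object.
#' @export
plot_arm_landscape <- function(arm_ev, clinical) {
  ord <- clinical |> dplyr::arrange(.data$cohort, .data$sample)
  arm_ev |>
    dplyr::left_join(ord, by = "sample") |>
    dplyr::mutate(
      sample = factor(.data$sample, levels = ord$sample),
      state = factor(.data$state,
                     levels = c("neutral", "gain", "loss", "upd"))
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample, y = .data$arm_id,
                                 fill = .data$state)) +
    ggplot2::geom_tile(color = "grey90", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(neutral = "grey95",
                                          gain = "#b2182b",
                                          loss = "#2166ac",
                                          upd = "#7b3294")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Stacked signature exposure bars per sample
#'
#' @param exposures Long exposure tibble from [fit_cohort_exposures()].
#' @param clinical Optional tibble with `sample` and `cohort` used to
#'   order and facet samples.
#' @return A ggplot object.
#' @export
plot_signature_exposures <- function(exposures, clinical = NULL) {
  p <- exposures |> dplyr::filter(.data$weight > 0)
  if (!is.null(clinical)) {
    ord <- clinical |> dplyr::arrange(.data$cohort, .data$sample)
    p <- p |>
      dplyr::left_join(ord, by = "sample") |>
      dplyr::mutate(sample = factor(.data$sample, levels = ord$sample))
  }
  gg <- ggplot2::ggplot(p, ggplot2::aes(x = .data$sample,
                                        y = .data$weight,
                                        fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "exposure weight", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
  if (!is.null(clinical)) {
    gg <- gg + ggplot2::facet_grid(~cohort, scales = "free_x",
                                   space = "free_x")
  }
  gg
}
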