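# ggplot2 views of the main result types.

#' Plot per-chain interaction counts by species
#'
#' Grouped bar chart of hydrogen-bond and salt-bridge counts, one panel per
#' interaction type, chains on the x axis, species as fill.
#'
#' @param counts A tibble with columns `species`, `chain`, `hbonds`,
#'   `saltbridges`.
#' @return A ggplot object.
#' @export
plot_interaction_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, c("hbonds", "saltbridges"),
                              names_to = "interaction", values_to = "count")
  long$interaction <- dplyr::recode(long$interaction,
                                    hbonds = "intrachain H-bonds",
                                    saltbridges = "intrachain salt bridges")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chain, y = .data$count,
                                     fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~interaction, scales = "free_y") +
    ggplot2::labs(x = "subunit chain", y = "count", fill = "species") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.conservation_partition
#' @export
plot_conservation <- function(object, ...) {
  autoplot.conservation_partition(object, ...)
}

#' Presence/absence map of a conservation partition
#'
#' Tile plot of salt-bridge pair labels against species, coloured by the
#' pair's conservation status.
#'
#' @param object A `conservation_partition` from [conserved_partition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_partition <- function(object, ...) {
  universe <- attr(object, "species_universe")
  long <- object |>
    dplyr::mutate(pair = factor(.data$pair, levels = rev(.data$pair))) |>
    tidyr::separate_rows("species", sep = ";")
  long$species <- factor(long$species, levels = universe)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$pair,
                                     fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      conserved = "#1b7837", shared_partial = "#fdb863", unique = "#762a83"
    )) +
    ggplot2::labs(x = NULL, y = "salt-bridge pair", fill = "status") +
    ggplot2::theme_minimal()
}

#' Bar chart of species interaction totals
#'
#' @param object An `icebonds_profiles` object from [species_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icebonds_profiles <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("hbonds", "saltbridges"),
                              names_to = "interaction", values_to = "total")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$species, -.data$total),
                                     y = .data$total)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~interaction, scales = "free_y") +
    ggplot2::labs(x = "species", y = "total count") +
    ggplot2::theme_minimal()
}
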