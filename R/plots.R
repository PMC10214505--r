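# ggplot2 methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a titration curve
#'
#' Species concentrations against total stabilizer dose on log-log axes; the
#' ternary complex shows the characteristic hook-effect peak.
#'
#' @param object A [titration_curve()] tibble.
#' @param species Columns to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.titration_curve <- function(object,
                                     species = c("rls", "rs", "ls"), ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            dplyr::all_of(species),
                            names_to = "species", values_to = "conc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s0, y = .data$conc,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "total stabilizer [S0] (M)",
                  y = "concentration (M)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an effective-affinity energy grid
#'
#' @param object An [energy_grid_scan()] tibble.
#' @param boundary Contour of interest, molar (default 1e-3, the
#'   millimolar/micromolar divide).
#' @param ... Unused.
#' @return A ggplot of log10 K_RL,eff over the (ddg_rs, ddg_ls) plane.
#' @export
autoplot.energy_grid_scan <- function(object, boundary = 1e-3, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ddg_rs, y = .data$ddg_ls,
                                        fill = log10(.data$k_rl_eff))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 K_RL,eff (M)") +
    ggplot2::labs(x = "ddG_RS (kcal/mol)", y = "ddG_LS (kcal/mol)") +
    ggplot2::theme_minimal()
  if (is.finite(boundary)) {
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = log10(.data$k_rl_eff)),
      breaks = log10(boundary), colour = "grey30", linetype = "dashed")
  }
  p
}

#' Mechanism map: weaker-side strength versus binding balance
#'
#' Scatter of `weaker_side` (max of the two per-partner energies) against the
#' binding balance, with the dual-binding selection box drawn; points inside
#' the box are shortlist candidates.
#'
#' @param energetics Aggregated tibble (needs `weaker_side` and
#'   `balance_mean` or `mean_gap`).
#' @param max_weaker,max_balance Selector cutoffs, kcal/mol.
#' @param label Optional column to label points by.
#' @return A ggplot.
#' @export
plot_mechanism_map <- function(energetics, max_weaker = -15,
                               max_balance = 10, label = NULL) {
  df <- tibble::as_tibble(energetics)
  if (!"weaker_side" %in% names(df)) {
    df$weaker_side <- pmax(df$ddg_rs_mean, df$ddg_ls_mean)
  }
  bal_col <- if ("balance_mean" %in% names(df)) "balance_mean" else "mean_gap"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$weaker_side,
                                        y = .data[[bal_col]])) +
    ggplot2::geom_vline(xintercept = max_weaker, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = max_balance, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "max(ddG_RS, ddG_LS) (kcal/mol)",
                  y = "|ddG_RS - ddG_LS| (kcal/mol)") +
    ggplot2::theme_minimal()
  if (!is.null(label) && label %in% names(df)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data[[label]]),
                                vjust = -0.6, size = 3)
  }
  p
}
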