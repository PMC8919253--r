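#' Plot a break-probability table
#'
#' Bar chart of per-class break probabilities with Wilson 95% CI bars.
#'
#' @param object a [break_probability_table()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.break_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$bond_class,
                                                      -.data$probability_pct),
                                   y = .data$probability_pct)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.15) +
    ggplot2::labs(x = NULL, y = "probability of breaking (%)",
                  title = sprintf("Bond break probabilities (%d trajectories, %s counting)",
                                  attr(object, "n_trajectories"),
                                  attr(object, "counting"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Plot an ion-yield scan
#'
#' PIY curves per fragment plus the summed ion yield.
#'
#' @param object an [piy_scan()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ion_yield_scan <- function(object, ...) {
  piy <- tibble::as_tibble(object)
  total <- dplyr::mutate(siy(object), fragment = "SIY")
  ggplot2::ggplot(piy, ggplot2::aes(.data$energy, .data$yield,
                                    colour = .data$fragment)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = total, linewidth = 1, colour = "black") +
    ggplot2::labs(x = "photon energy (eV)", y = "ion yield (arb.)",
                  colour = "fragment",
                  title = "Partial ion yields and summed ion yield (black)") +
    ggplot2::theme_minimal()
}

#' Plot a mass spectrum
#'
#' @param object a [mass_spectrum()].
#' @param ... unused.
#' @return A ggplot (line for dense spectra, sticks for peak lists).
#' @export
autoplot.mass_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mz, .data$intensity))
  p <- if (identical(attr(object, "kind"), "peaks")) {
    p + ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0))
  } else {
    p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "m/z", y = "intensity (arb.)") + ggplot2::theme_minimal()
}

#' Integrity traces of monitored bonds along a trajectory
#'
#' @param traj an explosion `trajectory`.
#' @param graph the molecular graph.
#' @param baselines tibble from [thermal_baselines()].
#' @param bonds bond labels to show (default: the heavy-atom backbone
#'   classes of [cystine_bond_classes()]).
#' @param decay_scale kernel decay length (A).
#' @return A ggplot of integrity vs time per bond.
#' @export
plot_bond_integrity <- function(traj, graph, baselines,
                                bonds = unlist(cystine_bond_classes(),
                                               use.names = FALSE),
                                decay_scale = 0.5) {
  df <- purrr::map_dfr(bonds, function(b) {
    bl <- baselines[baselines$bond == normalize_bond(b), ]
    dplyr::mutate(
      integrity_series(bond_distance_series(traj, bond = b, graph = graph),
                       bl, decay_scale),
      bond = normalize_bond(b)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_fs, .data$xi,
                                   colour = .data$bond)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (fs)", y = expression(Xi), colour = "bond",
                  title = "Bond integrity along the trajectory") +
    ggplot2::theme_minimal()
}
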