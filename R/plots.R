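# autoplot()/plot_*() methods for the main result types.

#' @export
autoplot.flatten_result <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$d_rep, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$selected_d_rep,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "inter-repeat distance (Å)",
                  y = "flattening score",
                  title = sprintf("selected d_rep = %.1f Å", object$selected_d_rep)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dock_result <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trajectory, c("energy", "best"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = stats::median(object$baseline),
                        linetype = "dotted") +
    ggplot2::labs(x = "MC step", y = "energy",
                  title = sprintf("binding score %.3g", object$e_binding)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cnt_barrier <- function(object, ...) {
  if (!object$barrier_finite) stop("no finite barrier to plot (S <= 1).")
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$r * 1e9, y = .data$dG / 1.380649e-23 / 298.15)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$r_star * 1e9, linetype = "dashed") +
    ggplot2::labs(x = "nucleus radius (nm)", y = expression(Delta * G / kT)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scaling_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$area_nm2,
                                            y = .data$inv_particle_area)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = expression("template interface area (nm"^2 * ")"),
                  y = expression("1 / particle surface area (nm"^-2 * ")")) +
    ggplot2::theme_minimal()
}

#' Plot a surface array in the template plane
#'
#' @param array A `surface_array`.
#' @return A ggplot object showing anchors coloured by residue identity.
#' @export
plot_surface_array <- function(array) {
  stopifnot(inherits(array, "surface_array"))
  pts <- array_points_2d(array)
  df <- tibble::tibble(u = pts[, 1], v = pts[, 2], residue = array$residue)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   colour = .data$residue)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "repeat axis (nm)", y = "helix axis (nm)",
                  title = attr(array, "array_name")) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
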