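# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a J-factor estimate
#'
#' `tidy()` returns the three closure factors with their counts, acceptance
#' windows and empirical densities; `glance()` returns a one-row summary.
#'
#' @param x A `j_estimate`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.j_estimate <- function(x, ...) {
  cfg <- x$cfg
  cts <- x$counts
  v_cap <- 4 / 3 * pi * cfg$capture_radius^3
  windows <- c(v_cap, 1 - cfg$cos_gamma_min, 2 * acos(cfg$cos_phi_min))
  num <- c(cts$n_r, cts$n_gamma, cts$n_phi)
  den <- c(cts$n_total, cts$n_r, cts$n_gamma)
  tibble::tibble(
    factor = c("W", "Gamma", "Phi"),
    description = c("circularity (end capture)",
                    "terminal normal alignment",
                    "torsional register"),
    hits = num, trials = den,
    window = windows,
    unit = c("A^3", "cos(gamma)", "radian"),
    density = ifelse(den > 0, (num / den) / windows, NA_real_))
}

#' @rdname tidy.j_estimate
#' @export
glance.j_estimate <- function(x, ...) {
  tibble::tibble(j_M = x$j, rel_error = x$rel_error,
                 n_total = x$counts$n_total, n_r = x$counts$n_r,
                 n_gamma = x$counts$n_gamma, n_phi = x$counts$n_phi,
                 floored = x$floored, method = x$method,
                 n_half = x$n_half, seed = x$seed,
                 parameter_set = x$parameter_set,
                 sequence_id = x$sequence_id)
}

#' Plot a concordance curve
#'
#' Percentage of sequences within t orders of magnitude of the reference,
#' against t; one line per stratum when present.
#'
#' @param object A [concordance_curve()] / [concordance_by_length()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_curve <- function(object, ...) {
  p <- if ("stratum" %in% names(object)) {
    ggplot2::ggplot(object,
                    ggplot2::aes(.data$threshold, .data$percent_within,
                                 colour = .data$stratum))
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(.data$threshold, .data$percent_within))
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "orders of magnitude difference",
                  y = "% of sequences within threshold") +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}

#' Plot a J(L) length scan
#'
#' Log-scale J factor against fragment length; floored lengths are marked
#' with open symbols.
#'
#' @param object A [j_length_scan()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.j_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$length, .data$j_M)) +
    ggplot2::geom_line(data = dplyr::filter(object, !.data$floored)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$floored)) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "fragment length (bp)", y = "J factor (M)")
}

#' Plot per-length J-factor distributions
#'
#' Median line with the 25-75 % quantile ribbon per fragment length.
#'
#' @param object A [length_stratified_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.j_length_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$length, .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fragment length (bp)",
                  y = "J factor (M), median and IQR")
}
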