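#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidiers for step-convolution fits
#'
#' @param x a `step_fit` from [fit_actin_linescan()] or
#'   [fit_myosin_penetration()].
#' @param ... unused.
#' @return `tidy()`: one row per fitted parameter; `glance()`: one-row
#'   model summary.
#' @export
tidy.step_fit <- function(x, ...) {
  keep <- c("x_m", "h_actin", "h_myo", "myosin_free_length_nm",
            "i_out", "i_cort", "i_in", "m_bg", "m_cort", "m_in")
  present <- keep[keep %in% names(x)]
  tibble::tibble(term = present,
                 estimate = purrr::map_dbl(present, ~ x[[.x]]))
}

#' @rdname tidy.step_fit
#' @export
glance.step_fit <- function(x, ...) {
  tibble::tibble(h_actin = x$h_actin,
                 h_myo = x$h_myo %||% NA_real_,
                 myosin_free_length_nm = x$myosin_free_length_nm %||% NA_real_,
                 psf_sigma_nm = x$psf_sigma_nm,
                 residual_rms = x$residual_rms,
                 nobs = nrow(x$data))
}

#' @rdname tidy.step_fit
#' @param object a `step_fit`.
#' @export
autoplot.step_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_nm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "distance (nm)", y = "intensity (a.u.)") +
    ggplot2::theme_classic()
}

#' Tidiers for overhang results
#'
#' @param x an `overhang_result` from [aggregate_cell()].
#' @param ... unused.
#' @return `tidy()`: the per-bin table; `glance()`: the per-cell row.
#' @export
tidy.overhang_result <- function(x, ...) attr(x, "bins")

#' @rdname tidy.overhang_result
#' @export
glance.overhang_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.overhang_result
#' @param object an `overhang_result`.
#' @export
autoplot.overhang_result <- function(object, ...) {
  bins <- attr(object, "bins")
  ggplot2::ggplot(dplyr::filter(bins, .data$accepted),
                  ggplot2::aes(.data$arc_center_nm, .data$overhang_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$overhang_pct,
                        linetype = "dashed") +
    ggplot2::labs(x = "position along cortex (nm)",
                  y = "cytoplasmic overhang (%)") +
    ggplot2::theme_classic()
}

#' Tidiers for tension results
#'
#' @param x a `tension_result` from [tension_from_curve()].
#' @param ... unused.
#' @export
tidy.tension_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::where(is.numeric),
                        names_to = "term", values_to = "estimate")
}

#' @rdname tidy.tension_result
#' @export
glance.tension_result <- function(x, ...) tibble::as_tibble(x)

#' Tidier for group comparisons
#'
#' @param x a `group_comparison` from [compare_groups()].
#' @param ... unused.
#' @export
tidy.group_comparison <- function(x, ...) tibble::as_tibble(x)

#' Plot a force curve with its drug-response windows
#'
#' @param curve force-curve tibble.
#' @param t_drug_s optional drug time to mark.
#' @return a ggplot object.
#' @export
plot_force_curve <- function(curve, t_drug_s = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$time_s, .data$force_nN)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "force (nN)") +
    ggplot2::theme_classic()
  if (!is.null(t_drug_s)) {
    p <- p + ggplot2::geom_vline(xintercept = t_drug_s, linetype = "dashed")
  }
  p
}
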