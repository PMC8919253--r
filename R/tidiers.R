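#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a TOF calibration
#'
#' @param x a [tof_calibrate()] result.
#' @param ... unused.
#' @return Tibble with one row per model term (`t0`, `k`), columns
#'   `term`, `estimate`, `std.error`.
#' @export
tidy.tof_calibration <- function(x, ...) {
  # two-reference calibrations fit exactly; summary() warns about that
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("t0", "k"),
                 estimate = c(x$t0, x$k),
                 std.error = unname(sm[, "Std. Error"]))
}

#' One-row summary of a TOF calibration
#'
#' @param x a [tof_calibrate()] result.
#' @param ... unused.
#' @return Tibble: `t0`, `k`, `n_refs`, `r.squared`.
#' @export
glance.tof_calibration <- function(x, ...) {
  tibble::tibble(t0 = x$t0, k = x$k, n_refs = x$n_refs,
                 r.squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' One-row summary of a break-probability table
#'
#' @param x a [break_probability_table()] result.
#' @param ... unused.
#' @return Tibble: ensemble size, counting convention, analysis settings.
#' @export
glance.break_table <- function(x, ...) {
  tibble::tibble(
    n_trajectories = attr(x, "n_trajectories"),
    counting = attr(x, "counting"),
    threshold = attr(x, "threshold"),
    persistence_fs = attr(x, "persistence_fs"),
    n_classes = nrow(x)
  )
}
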