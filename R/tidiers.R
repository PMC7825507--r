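#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the radial profile of an equilibrium run
#'
#' @param x A `rhizo_sim` object.
#' @param ... Unused.
#' @return The per-annulus profile tibble (`r_cm`, `C_umol_cm3`,
#'   `C_nmol_cm3`, `sorbed_umol_cm3`, `mineralized_cum_umol`).
#' @export
tidy.rhizo_sim <- function(x, ...) x$profile

#' One-row equilibrium summary of a run
#'
#' @param x A `rhizo_sim` object.
#' @param ... Unused.
#' @return The summary tibble (see [run_to_equilibrium()]).
#' @export
glance.rhizo_sim <- function(x, ...) x$summary

#' @export
tidy.rhizo_sweep <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rhizo_sweep")
  out
}

#' @export
tidy.rhizo_prcc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rhizo_prcc")
  out
}

#' Plot the radial accumulation gradient of a run
#'
#' Concentration (log scale) against radial distance from the root
#' surface, with the rhizosphere-extent threshold marked.
#'
#' @param object A `rhizo_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rhizo_sim <- function(object, ...) {
  pr <- object$profile
  pr <- pr[pr$C_nmol_cm3 > 0, ]
  thr <- object$settings$threshold_nmol
  ggplot2::ggplot(pr, ggplot2::aes(x = (.data$r_cm - object$root$r0) * 10,
                                   y = .data$C_nmol_cm3)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "distance from rhizoplane (mm)",
      y = expression(concentration ~ (nmol ~ cm^-3)),
      title = sprintf("%s at %g cm depth", object$summary$solute,
                      object$summary$depth)) +
    ggplot2::theme_minimal()
}

#' Plot equilibrium outputs across depths
#'
#' @param object A `rhizo_sweep` tibble.
#' @param vars Summary columns to facet over.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rhizo_sweep <- function(object,
                                 vars = c("rhizoplane_C", "extent_mm",
                                          "influx", "net_exudation"),
                                 ...) {
  long <- tidyr::pivot_longer(tidy(object), cols = dplyr::all_of(vars),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depth, y = .data$value,
                                     colour = .data$solute)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "soil depth (cm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot partial rank correlation coefficients
#'
#' @param object A `rhizo_prcc` tibble (optionally binned).
#' @param ... Unused.
#' @return A ggplot barplot of the coefficients.
#' @export
autoplot.rhizo_prcc <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$parameter, abs(.data$prcc)),
    y = .data$prcc)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "partial rank correlation coefficient") +
    ggplot2::theme_minimal()
  if ("bin" %in% names(d)) p <- p + ggplot2::facet_wrap(~bin)
  p
}

#' @importFrom rlang .data
NULL
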