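#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: the replication kinetics of a trajectory, the six combing
#' observables, a fitted parameter ensemble and a (smoothed, segmented)
#' timing profile.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name replifire-plots
NULL

#' @rdname replifire-plots
#' @export
autoplot.replication_trajectory <- function(object, ...) {
  tr <- object$trajectory %>%
    tidyr::pivot_longer(c("f", "n_forks", "n_initiations"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(.data$minutes, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = sprintf("%s replication kinetics, L = %d kb",
                                  object$params$variant, object$L))
}

#' @rdname replifire-plots
#' @export
autoplot.observable_curves <- function(object, ...) {
  df <- purrr::imap_dfr(unclass(object)[c("i_rate", "fork_density",
                                          "fraction_dist", "eye_length",
                                          "gap_length", "eted")],
                        ~mutate(.x, observable = .y))
  ggplot2::ggplot(df, ggplot2::aes(.data$grid, .data$value)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~observable, scales = "free") +
    ggplot2::labs(x = "f (curves) / length kb (histograms)", y = NULL)
}

#' @rdname replifire-plots
#' @export
autoplot.replication_fit <- function(object, ...) {
  ggplot2::ggplot(object$ensemble,
                  ggplot2::aes(.data$parameter, .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "fitted value (ensemble mean ± sd)")
}

#' @rdname replifire-plots
#' @param segments Optional `timing_segments` overlay.
#' @export
autoplot.timing_profile <- function(object, segments = NULL, ...) {
  prof <- object$profile
  g <- ggplot2::ggplot(prof, ggplot2::aes(.data$position, .data$mean_time)) +
    ggplot2::geom_point(colour = "grey70", size = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "position (kb)", y = "mean replication time (min)")
  if (!is.null(prof$smoothed)) {
    g <- g + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                                colour = "steelblue")
  }
  if (!is.null(segments)) {
    g <- g + ggplot2::geom_rect(
      data = segments, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$class),
      alpha = 0.15)
  }
  g
}
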