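#' Plot a two-channel trace and its FRET efficiency
#'
#' Diagnostic display of one molecule: donor/acceptor intensities (top) and
#' the per-frame FRET efficiency (bottom), the standard way to eyeball
#' transitions, photobleaching steps and noise.
#'
#' @param frames Output of [fret_frames()] (or a raw trace tibble).
#' @param molecule A `molecule_id` present in `frames`.
#' @return A ggplot object.
#' @export
plot_trace <- function(frames, molecule) {
  d <- dplyr::filter(frames, .data$molecule_id == molecule)
  stopifnot(nrow(d) > 0)
  time <- if ("time" %in% names(d)) d$time else d$frame
  long <- dplyr::bind_rows(
    tibble::tibble(time = time, value = d$donor, panel = "intensity",
                   channel = "donor"),
    tibble::tibble(time = time, value = d$acceptor, panel = "intensity",
                   channel = "acceptor"),
    if ("efficiency" %in% names(d)) {
      tibble::tibble(time = time, value = d$efficiency, panel = "FRET",
                     channel = "efficiency")
    }
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_step(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(donor = "#2a9d2a",
                                            acceptor = "#d62728",
                                            efficiency = "#1f77b4")) +
    ggplot2::labs(x = "time (s)", y = NULL, title = molecule) +
    ggplot2::theme_minimal()
}

#' Plot an idealized trace over its efficiency data
#'
#' @param object An `hmm_fit`.
#' @param efficiency The efficiency trace the model was fitted to.
#' @param frame_rate Acquisition rate in Hz (for the time axis).
#' @param ... Unused.
#' @return A ggplot object: the observed efficiency with the Viterbi
#'   idealization overlaid.
#' @method autoplot hmm_fit
#' @export
autoplot.hmm_fit <- function(object, efficiency, frame_rate = 10, ...) {
  e <- efficiency[!is.na(efficiency)]
  t <- (seq_along(e) - 1) / frame_rate
  d <- tibble::tibble(time = t, efficiency = e,
                      idealized = object$means[object$viterbi_path])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$efficiency), colour = "grey40",
                       linewidth = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$idealized), colour = "#d62728",
                       linewidth = 0.6) +
    ggplot2::labs(x = "time (s)", y = "FRET efficiency") +
    ggplot2::theme_minimal()
}

#' Plot dwell-time histograms with the short/long partition
#'
#' Linear- and log-timescale dwell histograms for one state, with the
#' partition threshold marked, mirroring the standard dwell-kinetics
#' display.
#'
#' @param dwells Dwell table filtered to one state.
#' @param threshold Partition threshold in seconds (drawn as a dashed line).
#' @param linear_binwidth,log_binwidth Bin widths (see [dwell_histograms()]).
#' @return A ggplot object faceted into linear and log panels.
#' @export
plot_dwell_histograms <- function(dwells, threshold = NULL,
                                  linear_binwidth = 1, log_binwidth = 0.25) {
  h <- dwell_histograms(dwells, linear_binwidth, log_binwidth)
  d <- dplyr::bind_rows(
    tibble::tibble(x = h$linear$bin_center, count = h$linear$count,
                   scale = "linear (s)"),
    tibble::tibble(x = h$log$log10_center, count = h$log$count,
                   scale = "log10 (s)")
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$scale), scales = "free") +
    ggplot2::labs(x = "dwell time", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    vl <- tibble::tibble(x = c(threshold, log10(threshold)),
                         scale = c("linear (s)", "log10 (s)"))
    p <- p + ggplot2::geom_vline(data = vl, ggplot2::aes(xintercept = .data$x),
                                 colour = "#d62728", linetype = "dashed")
  }
  p
}

#' Plot a FRET histogram with a Gaussian-mixture fit
#'
#' @param object A `fret_mixture`.
#' @param histogram The histogram it was fitted to (`bin_center`, `density`).
#' @param ... Unused.
#' @return A ggplot object: observed density, per-component Gaussians and
#'   their sum.
#' @method autoplot fret_mixture
#' @export
autoplot.fret_mixture <- function(object, histogram, ...) {
  x <- seq(min(histogram$bin_center), max(histogram$bin_center), length.out = 400)
  comp <- purrr::map(seq_len(object$n_components), function(i) {
    a <- object$weights[i] / (object$sigmas[i] * sqrt(2 * pi))
    tibble::tibble(x = x, density = a * exp(-(x - object$means[i])^2 /
                                              (2 * object$sigmas[i]^2)),
                   component = paste0("component ", i))
  }) |>
    dplyr::bind_rows()
  total <- comp |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop") |>
    dplyr::mutate(component = "sum")
  ggplot2::ggplot() +
    ggplot2::geom_col(data = histogram,
                      ggplot2::aes(x = .data$bin_center, y = .data$density),
                      fill = "grey70", width = diff(histogram$bin_center[1:2])) +
    ggplot2::geom_line(data = dplyr::bind_rows(comp, total),
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "FRET efficiency", y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
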