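#' Extract dwell times from idealized state paths
#'
#' A dwell is one contiguous visit to a kinetic state in an idealized
#' (Viterbi) path. The first and last dwell of every trace are excluded:
#' the entry time of the first (section I) and the exit time of the last
#' (section III, possibly ended by photobleaching) are unknown, so only
#' interior (section II) dwells carry usable durations. Setting
#' `drop_boundary = FALSE` keeps the boundary dwells, marked `censored`.
#'
#' @param paths Frame-level idealized paths from [idealized_paths()].
#' @param frame_rate Acquisition rate in Hz.
#' @param drop_boundary Drop the first/last dwell of each trace (default).
#' @return A tibble of dwell records: `molecule_id`, `field_id`,
#'   `state_label`, `duration` (s, an integer multiple of `1/frame_rate`),
#'   `n_frames`, `in_section_II`, `censored`.
#' @export
extract_dwells <- function(paths, frame_rate, drop_boundary = TRUE) {
  per_mol <- split(paths, paths$molecule_id)
  purrr::map(per_mol, function(d) {
    d <- d[order(d$frame_index), ]
    r <- rle(d$state_label)
    n_runs <- length(r$lengths)
    boundary <- seq_len(n_runs) %in% c(1L, n_runs)
    out <- tibble::tibble(
      molecule_id = d$molecule_id[1], field_id = d$field_id[1],
      state_label = r$values,
      n_frames = r$lengths,
      duration = r$lengths / frame_rate,
      in_section_II = !boundary,
      censored = boundary
    )
    if (drop_boundary) out <- out[!boundary, ]
    out
  }) |>
    dplyr::bind_rows()
}

#' Dwell-time histograms on linear and logarithmic timescales
#'
#' @param dwells Dwell table from [extract_dwells()] (one state's dwells;
#'   filter by `state_label` first if several states are present).
#' @param linear_binwidth Linear-axis bin width in seconds.
#' @param log_binwidth Log-axis bin width in log10 seconds.
#' @return A list of tibbles `linear` (`bin_center`, `count`) and `log`
#'   (`log10_center`, `count`); counts, not densities, so the total over
#'   bins equals the number of dwells.
#' @export
dwell_histograms <- function(dwells, linear_binwidth = 1, log_binwidth = 0.25) {
  d <- dwells$duration
  if (length(d) == 0) {
    warning("no dwells; returning empty histograms")
    return(list(
      linear = tibble::tibble(bin_center = numeric(0), count = integer(0)),
      log = tibble::tibble(log10_center = numeric(0), count = integer(0))
    ))
  }
  lin_breaks <- seq(0, (floor(max(d) / linear_binwidth) + 1) * linear_binwidth,
                    by = linear_binwidth)
  hl <- graphics::hist(d, breaks = lin_breaks, plot = FALSE)
  ld <- log10(d)
  lo <- floor(min(ld) / log_binwidth) * log_binwidth
  hi <- (floor(max(ld) / log_binwidth) + 1) * log_binwidth
  log_breaks <- seq(lo - log_binwidth / 2, hi + log_binwidth / 2, by = log_binwidth)
  hg <- graphics::hist(ld, breaks = log_breaks, plot = FALSE)
  list(
    linear = tibble::tibble(bin_center = hl$mids, count = hl$counts),
    log = tibble::tibble(log10_center = hg$mids, count = hg$counts)
  )
}

#' Locate the short/long-lived partition threshold
#'
#' Finds the interior local minimum of the (smoothed) log-timescale dwell
#' histogram between its two largest modes — the point used to partition
#' dwells into short- and long-lived populations. If the histogram has no
#' interior minimum (e.g. a unimodal single-exponential distribution), the
#' supplied default threshold is returned with `fallback = TRUE`. For
#' cross-condition comparisons the assay's defaults (0.56 s for the high
#' state, 0.32 s for the low state) are authoritative.
#'
#' @param log_histogram The `log` tibble from [dwell_histograms()].
#' @param default_threshold Fallback threshold in seconds.
#' @param smooth_bins Moving-average window (bins) applied before the
#'   minimum search.
#' @return A one-row tibble: `threshold` (s), `fallback`.
#' @export
find_partition_threshold <- function(log_histogram, default_threshold,
                                     smooth_bins = 3) {
  cnt <- log_histogram$count
  ctr <- log_histogram$log10_center
  if (length(cnt) >= smooth_bins) {
    sm <- stats::filter(cnt, rep(1 / smooth_bins, smooth_bins), sides = 2)
    sm[is.na(sm)] <- cnt[is.na(sm)]
    sm <- as.numeric(sm)
  } else {
    sm <- cnt
  }
  n <- length(sm)
  fallback <- tibble::tibble(threshold = default_threshold, fallback = TRUE)
  if (n < 3) return(fallback)
  # local maxima (modes) of the smoothed histogram
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) sm[i - 1] else -Inf
    r <- if (i < n) sm[i + 1] else -Inf
    sm[i] >= l && sm[i] >= r && sm[i] > 0
  }, logical(1))
  modes <- which(is_max)
  # collapse plateaus
  if (length(modes) > 1) modes <- modes[c(TRUE, diff(modes) > 1)]
  if (length(modes) < 2) return(fallback)
  top2 <- sort(modes[order(sm[modes], decreasing = TRUE)][1:2])
  between <- (top2[1] + 1):(top2[2] - 1)
  if (length(between) == 0) return(fallback)
  imin <- between[which.min(sm[between])]
  tibble::tibble(threshold = 10^ctr[imin], fallback = FALSE)
}

#' Partition dwells into short- and long-lived populations
#'
#' For each state, dwells shorter than the state's threshold (strictly
#' `< threshold`) are short-lived; the rest (`>= threshold`) long-lived.
#' Population fractions are computed per field of view and summarized as
#' mean +- SD across fields, the assay's headline statistic.
#'
#' @param dwells Dwell table from [extract_dwells()].
#' @param thresholds Named numeric vector of thresholds in seconds, one per
#'   state label present (default: the assay's 0.56 s high-state and
#'   0.32 s low-state partitions).
#' @return A tibble with one row per state: `state_label`, `threshold`,
#'   `short_mean`, `short_sd`, `long_mean`, `long_sd`, `n_dwells`,
#'   `n_fields`. With a single field the SDs are 0 (noted by message).
#' @export
partition_populations <- function(dwells, thresholds = c(high = 0.56, low = 0.32)) {
  stopifnot(nrow(dwells) >= 1)
  states <- intersect(names(thresholds), unique(dwells$state_label))
  out <- purrr::map(states, function(st) {
    d <- dwells[dwells$state_label == st, ]
    if (nrow(d) == 0) return(NULL)
    thr <- thresholds[[st]]
    per_field <- d |>
      dplyr::group_by(.data$field_id) |>
      dplyr::summarise(short = mean(.data$duration < thr), .groups = "drop")
    nf <- nrow(per_field)
    if (nf == 1) message("single field for state '", st, "': SD reported as 0")
    tibble::tibble(
      state_label = st, threshold = thr,
      short_mean = mean(per_field$short),
      short_sd = if (nf > 1) sd(per_field$short) else 0,
      long_mean = 1 - mean(per_field$short),
      long_sd = if (nf > 1) sd(per_field$short) else 0,
      n_dwells = nrow(d), n_fields = nf
    )
  })
  dplyr::bind_rows(out)
}

#' Fit a first-order exponential rate to dwell times
#'
#' Estimates the exit rate of a dwell population restricted to durations
#' beyond `fit_domain_start` (the short/long partition threshold), as used
#' to extract the disassembly rate from the long-lived high-FRET dwells.
#'
#' Two estimators are provided. `"lsq"` (default, mirroring the histogram
#' procedure): unweighted nonlinear least squares of `A * exp(-k * t)` to
#' the linear dwell-time histogram counts over bins with centers at or
#' beyond `fit_domain_start`. `"mle"`: the maximum-likelihood estimator for
#' a left-truncated exponential, `k = 1 / (mean(t[t >= start]) - start)`,
#' which is unbiased under truncation and recommended as a cross-check.
#'
#' @param dwells Dwell table (or any tibble with a `duration` column);
#'   filter to one state first.
#' @param fit_domain_start Lower edge of the fitted domain in seconds.
#' @param method `"lsq"` or `"mle"`.
#' @param binwidth Histogram bin width for the `"lsq"` method (s).
#' @param min_dwells Minimum number of dwells beyond `fit_domain_start`.
#' @return An object of class `rate_fit`: `rate` (s^-1), `mean_dwell`
#'   (`1/rate`, s), `rate_sd`, `method`, `fit_domain_start`, `n_used`,
#'   `converged`.
#' @export
fit_exponential_rate <- function(dwells, fit_domain_start = 0.56,
                                 method = c("lsq", "mle"), binwidth = 1,
                                 min_dwells = 20) {
  method <- match.arg(method)
  d <- if (is.data.frame(dwells)) dwells$duration else as.numeric(dwells)
  d_fit <- d[d >= fit_domain_start]
  n_used <- length(d_fit)
  if (n_used < min_dwells) {
    stop(sprintf("only %d dwells beyond %.2f s (< %d); rate fit refused",
                 n_used, fit_domain_start, min_dwells))
  }
  if (method == "mle") {
    k <- 1 / (mean(d_fit) - fit_domain_start)
    rate_sd <- k / sqrt(n_used)
    converged <- TRUE
  } else {
    breaks <- seq(0, (floor(max(d) / binwidth) + 1) * binwidth, by = binwidth)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    keep <- h$mids >= fit_domain_start
    x <- h$mids[keep]
    y <- h$counts[keep]
    # starting values from a log-linear fit on the positive-count bins
    pos <- y > 0
    sl <- stats::lm(log(y[pos]) ~ x[pos])
    k0 <- max(-stats::coef(sl)[2], 1e-3)
    a0 <- exp(stats::coef(sl)[1])
    fit <- minpack.lm::nlsLM(
      y ~ a * exp(-k * x), start = list(a = a0, k = k0),
      lower = c(0, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    co <- stats::coef(fit)
    k <- unname(co["k"])
    rate_sd <- unname(summary(fit)$coefficients["k", "Std. Error"])
    converged <- TRUE
  }
  structure(list(
    rate = k, mean_dwell = 1 / k, rate_sd = rate_sd, method = method,
    fit_domain_start = fit_domain_start, n_used = n_used,
    converged = converged
  ), class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> %s: rate %.4f s^-1 (mean dwell %.2f s), n = %d beyond %.2f s\n",
              x$method, x$rate, x$mean_dwell, x$n_used, x$fit_domain_start))
  invisible(x)
}

#' @rdname fit_exponential_rate
#' @param x A `rate_fit` object.
#' @param ... Unused.
#' @method tidy rate_fit
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rate", "mean_dwell"),
    estimate = c(x$rate, x$mean_dwell),
    std.error = c(x$rate_sd, x$rate_sd / x$rate^2)
  )
}

#' @rdname fit_exponential_rate
#' @method glance rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    rate = x$rate, mean_dwell = x$mean_dwell, rate_sd = x$rate_sd,
    method = x$method, fit_domain_start = x$fit_domain_start,
    n_used = x$n_used, converged = x$converged
  )
}
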