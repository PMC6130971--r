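#' Channel leakage (cross-talk) matrix
#'
#' Describes the linear mixing of true donor/acceptor emission into the two
#' detection channels: a fraction `l_da` of true donor signal is detected in
#' the acceptor channel and a fraction `l_ad` of true acceptor signal in the
#' donor channel. Defaults are the quad-notch emission pathway values of the
#' assay: 1.7% donor-to-acceptor and 16.5% acceptor-to-donor.
#'
#' The observed counts relate to the true emissions through the mixing
#' matrix `M = [[1 - l_da, l_ad], [l_da, 1 - l_ad]]` applied frame-wise to
#' the (donor, acceptor) vector.
#'
#' @param l_da Fraction of donor emission leaking into the acceptor channel.
#' @param l_ad Fraction of acceptor emission leaking into the donor channel.
#' @return An object of class `leakage_matrix`.
#' @export
leakage_matrix <- function(l_da = 0.017, l_ad = 0.165) {
  stopifnot(l_da >= 0, l_da < 1, l_ad >= 0, l_ad < 1)
  structure(list(l_da = l_da, l_ad = l_ad), class = "leakage_matrix")
}

#' @export
print.leakage_matrix <- function(x, ...) {
  cat(sprintf("<leakage_matrix> donor->acceptor %.3f, acceptor->donor %.3f\n",
              x$l_da, x$l_ad))
  invisible(x)
}

#' Apply channel leakage mixing to true emissions
#'
#' The forward model: computes the observed channel counts from true donor
#' and acceptor emissions. [correct_leakage()] is its exact inverse.
#'
#' @param donor,acceptor True per-frame emissions.
#' @param lm A [leakage_matrix()].
#' @return A list with mixed `donor` and `acceptor` vectors.
#' @export
mix_leakage <- function(donor, acceptor, lm) {
  list(
    donor = (1 - lm$l_da) * donor + lm$l_ad * acceptor,
    acceptor = lm$l_da * donor + (1 - lm$l_ad) * acceptor
  )
}

#' Correct channel leakage by full linear unmixing
#'
#' Solves the 2x2 linear mixing model `observed = M %*% true` frame-wise,
#' with `M = [[1 - l_da, l_ad], [l_da, 1 - l_ad]]`. This is a full
#' unmixing, not a sequential subtraction: the two are identical only when
#' one leakage term is zero.
#'
#' @param donor,acceptor Observed per-frame channel counts.
#' @param lm A [leakage_matrix()].
#' @return A list with unmixed `donor` and `acceptor` vectors.
#' @export
correct_leakage <- function(donor, acceptor, lm) {
  det <- 1 - lm$l_da - lm$l_ad
  if (abs(det) < 1e-12) {
    stop("leakage matrix is singular (l_da + l_ad = 1); cannot unmix")
  }
  list(
    donor = ((1 - lm$l_ad) * donor - lm$l_ad * acceptor) / det,
    acceptor = ((1 - lm$l_da) * acceptor - lm$l_da * donor) / det
  )
}

#' Compute FRET efficiency from corrected intensities
#'
#' `E = I_A / (I_A + I_D)` per frame, using leakage-corrected intensities.
#' Frames whose summed intensity falls below `total_floor` (e.g. after
#' photobleaching of the donor) are returned as `NA` rather than divided.
#'
#' @param donor,acceptor Leakage-corrected per-frame intensities.
#' @param total_floor Minimum summed intensity for a frame to be valid.
#' @return Numeric vector of efficiencies, `NA` for invalid frames.
#' @export
compute_fret <- function(donor, acceptor, total_floor = 0) {
  total <- donor + acceptor
  ifelse(total > total_floor & total > 0, acceptor / total, NA_real_)
}

#' Leakage-correct a trace table and compute per-frame FRET
#'
#' Pipeline step: takes a long trace tibble (`molecule_id`, `field_id`,
#' `frame`, `donor`, `acceptor`), unmixes channel leakage, and computes the
#' per-frame FRET efficiency. The validity floor is set per molecule to
#' `total_floor_frac` of that molecule's robust single-molecule intensity
#' level (the median of its summed intensity over bright frames), so frames
#' after complete photobleaching are flagged invalid.
#'
#' @param traces Long trace tibble.
#' @param leakage A [leakage_matrix()].
#' @param total_floor_frac Validity floor as a fraction of the molecule's
#'   bright-level summed intensity.
#' @return The input tibble with added columns `donor_corr`,
#'   `acceptor_corr`, `efficiency` (`NA` on invalid frames) and `total_corr`.
#' @export
fret_frames <- function(traces, leakage = leakage_matrix(),
                        total_floor_frac = 0.2) {
  corr <- correct_leakage(traces$donor, traces$acceptor, leakage)
  traces$donor_corr <- corr$donor
  traces$acceptor_corr <- corr$acceptor
  traces$total_corr <- corr$donor + corr$acceptor
  traces |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::mutate(
      efficiency = compute_fret(
        .data$donor_corr, .data$acceptor_corr,
        total_floor = total_floor_frac * bright_level(.data$total_corr)
      )
    ) |>
    dplyr::ungroup()
}

# Robust single-molecule intensity level: median of the summed intensity
# over frames in the bright part of the trace.
bright_level <- function(total) {
  ref <- quantile(total, 0.95, names = FALSE, na.rm = TRUE)
  bright <- total[total > 0.5 * ref]
  if (length(bright) == 0) return(max(total, 0))
  median(bright)
}

smooth_trace <- function(x, k = 9) {
  k <- max(1L, as.integer(k) - (1L - as.integer(k) %% 2L)) # force odd
  if (length(x) < k || k < 3) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# First index from which `x` never again shows a *sustained* excursion at
# or above `thresh`. Excursions shorter than `run_len` frames are treated
# as smoothed-noise artifacts, not recovery: a live fluorophore stays
# bright over many frames, while noise excursions that survive a running
# median last about one smoothing window. Returns length(x) + 1 when the
# signal is still recovering at the end of the trace.
first_never_recovers <- function(x, thresh, run_len) {
  above <- x >= thresh
  r <- rle(above)
  r$values[r$values & r$lengths < run_len] <- FALSE
  above <- inverse.rle(r)
  last <- if (any(above)) max(which(above)) else 0L
  if (last >= length(x)) length(x) + 1L else last + 1L
}

# Linear interpolation over NA frames (flat extension at the ends) so the
# running median is defined; callers re-mask originally-NA positions.
fill_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(rep(0, length(x)))
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Detect terminal photobleaching and section one FRET trace
#'
#' Locates the terminal photobleaching event of a single molecule and
#' divides its pre-bleach FRET trace into the three sections used in dwell
#' analysis: section I is the initial dwell (entry time unknown), section
#' III the final dwell (exit unknown — its end may be photobleaching rather
#' than a conformational step), and section II everything in between. The
#' discriminating criterion between an acceptor-bleach step and a genuine
#' conformational transition is recovery: a transition returns to high
#' FRET, a bleach never recovers.
#'
#' Detection operates on running-median smoothed channels: donor bleaching
#' is the first frame after which the summed intensity never again exceeds
#' `bleach_total_frac` of the molecule's bright level in a sustained way;
#' acceptor bleaching is the first frame after which the acceptor channel
#' never again exceeds `bleach_acceptor_frac` of that level (while the
#' donor persists). Recovery must last at least `smooth_k` frames to count:
#' a live fluorophore stays bright over many frames, whereas noise
#' excursions that survive the running median last about one smoothing
#' window.
#'
#' Classification: `without_transitions` if the smoothed efficiency stays
#' above `high_boundary` for the whole pre-bleach trace; `with_transitions`
#' if it contains at least one accepted excursion below the boundary (a run
#' of at least `min_run` frames); `excluded` when there is no co-localized
#' acceptor signal (donor-only molecule), or fewer than `min_frames`
#' analyzable pre-bleach frames.
#'
#' @param donor,acceptor Leakage-corrected channel vectors for one molecule.
#' @param efficiency Per-frame FRET efficiencies (`NA` allowed).
#' @param high_boundary FRET boundary of the high state (default 0.5).
#' @param bleach_total_frac,bleach_acceptor_frac Bleach-detection
#'   thresholds as fractions of the bright level.
#' @param coloc_frac Minimum smoothed acceptor level (fraction of bright
#'   level) for the molecule to count as having co-localized acceptor.
#' @param min_frames Minimum analyzable pre-bleach frames.
#' @param min_run Minimum run length (frames) for an accepted excursion.
#' @param smooth_k Running-median window (frames).
#' @return A one-row tibble: `classification` (`with_transitions`,
#'   `without_transitions`, `excluded`), `reason`, `bleach_frame` (0-based
#'   first bleached frame, `NA` if none), `n_prebleach`, and 0-based section
#'   bounds `sec1_end`, `sec2_start`, `sec2_end`, `sec3_start` (`NA` where a
#'   section is absent).
#' @export
detect_bleach_and_section <- function(donor, acceptor, efficiency,
                                      high_boundary = 0.5,
                                      bleach_total_frac = 0.5,
                                      bleach_acceptor_frac = 0.12,
                                      coloc_frac = 0.3,
                                      min_frames = 20,
                                      min_run = 2,
                                      smooth_k = 9) {
  n <- length(donor)
  total_s <- smooth_trace(donor + acceptor, smooth_k)
  acc_s <- smooth_trace(acceptor, smooth_k)
  ref <- bright_level(donor + acceptor)

  res <- function(classification, reason, bleach_frame, n_prebleach,
                  s1e = NA_integer_, s2s = NA_integer_, s2e = NA_integer_,
                  s3s = NA_integer_) {
    tibble::tibble(
      classification = classification, reason = reason,
      bleach_frame = bleach_frame, n_prebleach = n_prebleach,
      sec1_end = s1e, sec2_start = s2s, sec2_end = s2e, sec3_start = s3s
    )
  }

  # donor bleach: summed intensity never again recovers above threshold in
  # a sustained way (excursions shorter than the smoothing window are noise)
  db <- first_never_recovers(total_s, bleach_total_frac * ref, smooth_k)

  # co-localized acceptor present before donor bleach?
  pre_donor <- seq_len(min(db - 1L, n))
  has_acceptor <- length(pre_donor) > 0 &&
    max(acc_s[pre_donor]) > coloc_frac * ref
  if (!has_acceptor) {
    return(res("excluded", "no_acceptor",
               if (db <= n) db - 1L else NA_integer_,
               length(pre_donor)))
  }

  # acceptor bleach within the donor-alive window: acceptor never recovers
  ab <- n + 1L
  if (length(pre_donor) > 1) {
    hit <- first_never_recovers(acc_s[pre_donor],
                                bleach_acceptor_frac * ref, smooth_k)
    if (hit <= length(pre_donor)) ab <- hit
  }

  bleach <- min(db, ab)
  bleach_frame <- if (bleach <= n) bleach - 1L else NA_integer_
  pre <- seq_len(min(bleach - 1L, n))
  n_pre <- length(pre)
  if (n_pre < min_frames) {
    return(res("excluded", "too_short", bleach_frame, n_pre))
  }

  # accepted excursions below the high boundary on the smoothed efficiency;
  # invalid frames can never count as an excursion
  e_raw <- efficiency[pre]
  e_s <- smooth_trace(fill_na(e_raw), min(smooth_k, 5))
  low <- !is.na(e_raw) & e_s <= high_boundary
  r <- rle(low)
  accepted <- r$values & r$lengths >= min_run
  if (!any(accepted)) {
    return(res("without_transitions", "constant_high", bleach_frame, n_pre,
               s1e = n_pre - 1L))
  }

  # sections from runs of the thresholded (smoothed) efficiency
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  s1e <- ends[1] - 1L
  s3s <- starts[length(starts)] - 1L
  s2s <- if (s1e + 1L <= s3s - 1L) s1e + 1L else NA_integer_
  s2e <- if (!is.na(s2s)) s3s - 1L else NA_integer_
  res("with_transitions", "transitions", bleach_frame, n_pre,
      s1e = as.integer(s1e), s2s = as.integer(s2s),
      s2e = as.integer(s2e), s3s = as.integer(s3s))
}

#' Classify every molecule of a trace table
#'
#' Runs [detect_bleach_and_section()] on each molecule of a
#' [fret_frames()]-annotated table, then applies the field-level
#' multiple-complex exclusion: molecules whose bright-level summed intensity
#' exceeds `multi_factor` times the field median single-molecule level are
#' excluded (several complexes under one spot).
#'
#' @param frames Output of [fret_frames()].
#' @param multi_factor Multiple-complex exclusion threshold (x field median).
#' @inheritParams detect_bleach_and_section
#' @return A classification tibble with one row per molecule:
#'   `molecule_id`, `field_id`, `classification`, `reason`, `bleach_frame`,
#'   `n_prebleach`, section bounds, and `bright` (the molecule's intensity
#'   level).
#' @export
classify_traces <- function(frames, high_boundary = 0.5,
                            bleach_total_frac = 0.5,
                            bleach_acceptor_frac = 0.12,
                            coloc_frac = 0.3, multi_factor = 1.5,
                            min_frames = 20, min_run = 2, smooth_k = 9) {
  cls <- frames |>
    dplyr::group_by(.data$molecule_id, .data$field_id) |>
    dplyr::group_modify(function(d, key) {
      out <- detect_bleach_and_section(
        d$donor_corr, d$acceptor_corr, d$efficiency,
        high_boundary = high_boundary,
        bleach_total_frac = bleach_total_frac,
        bleach_acceptor_frac = bleach_acceptor_frac,
        coloc_frac = coloc_frac, min_frames = min_frames,
        min_run = min_run, smooth_k = smooth_k
      )
      out$bright <- bright_level(d$total_corr)
      out
    }) |>
    dplyr::ungroup()

  # multiple-complex exclusion against the field's single-molecule level,
  # assessed among acceptor-bearing molecules
  cls |>
    dplyr::group_by(.data$field_id) |>
    dplyr::mutate(
      single_level = median(.data$bright[.data$classification != "excluded"]),
      multi = !is.na(.data$single_level) &
        .data$classification != "excluded" &
        .data$bright > multi_factor * .data$single_level,
      classification = ifelse(.data$multi, "excluded", .data$classification),
      reason = ifelse(.data$multi, "multi_complex", .data$reason)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"multi", -"single_level")
}

#' Fraction of molecules without transitions, per field
#'
#' The assay's per-condition activity readout: for each field of view, the
#' number of molecules classified `without_transitions` divided by the
#' total number of donor-visible molecules in the field (the denominator
#' includes donor-only and otherwise excluded spots; the numerator never
#' includes them). The summary is the mean and SD across fields.
#'
#' @param classification Classification tibble from [classify_traces()], or
#'   any tibble with `field_id` and `classification` columns.
#' @return A list with `per_field` (tibble: `field_id`, `n_total`,
#'   `n_without`, `fraction`) and `summary` (tibble: `mean`, `sd`,
#'   `n_fields`).
#' @export
fraction_without_transitions <- function(classification) {
  per_field <- classification |>
    dplyr::group_by(.data$field_id) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_without = sum(.data$classification == "without_transitions"),
      .groups = "drop"
    )
  empty <- per_field$n_total == 0
  if (any(empty)) {
    warning("skipping field(s) with zero molecules: ",
            paste(per_field$field_id[empty], collapse = ", "))
    per_field <- per_field[!empty, ]
  }
  per_field$fraction <- per_field$n_without / per_field$n_total
  list(
    per_field = per_field,
    summary = tibble::tibble(
      mean = mean(per_field$fraction),
      sd = if (nrow(per_field) > 1) sd(per_field$fraction) else 0,
      n_fields = nrow(per_field)
    )
  )
}

#' Point-wise FRET efficiency histogram
#'
#' Pools per-frame efficiencies over the section II frames of the selected
#' molecules and bins them into a unit-area histogram, as used to read off
#' the conformational state populations.
#'
#' @param frames Output of [fret_frames()].
#' @param classification Classification tibble from [classify_traces()].
#' @param which `"with_transitions"` (default; the assay pools only
#'   molecules with transitions) or `"all"` (all non-excluded molecules,
#'   pooling their pre-bleach frames).
#' @param breaks Histogram break points on the efficiency axis.
#' @return A tibble `bin_center`, `count`, `density` (unit total area).
#' @export
pointwise_histogram <- function(frames, classification,
                                which = c("with_transitions", "all"),
                                breaks = seq(-0.2, 1.2, by = 0.02)) {
  which <- match.arg(which)
  sel <- if (which == "with_transitions") {
    dplyr::filter(classification, .data$classification == "with_transitions")
  } else {
    dplyr::filter(classification, .data$classification != "excluded")
  }
  pooled <- frames |>
    dplyr::inner_join(
      dplyr::select(sel, "molecule_id", "sec2_start", "sec2_end", "n_prebleach"),
      by = "molecule_id"
    ) |>
    dplyr::filter(
      !is.na(.data$efficiency),
      if (which == "with_transitions") {
        !is.na(.data$sec2_start) & .data$frame >= .data$sec2_start &
          .data$frame <= .data$sec2_end
      } else {
        .data$frame < .data$n_prebleach
      }
    )
  if (nrow(pooled) == 0) {
    warning("no frames selected; returning empty histogram")
    return(tibble::tibble(bin_center = numeric(0), count = integer(0),
                          density = numeric(0)))
  }
  e <- pmin(pmax(pooled$efficiency, min(breaks)), max(breaks))
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  tibble::tibble(bin_center = h$mids, count = h$counts, density = h$density)
}

#' Fit a sum of Gaussian components to a FRET histogram
#'
#' Nonlinear least-squares fit of a sum of 1-3 Gaussian functions to a
#' binned point-wise FRET density, used to resolve the state populations
#' when intermediate-FRET states overlap. Components are returned sorted by
#' mean. Non-convergence is reported through the `converged` flag rather
#' than an error.
#'
#' @param histogram A tibble with `bin_center` and `density` columns.
#' @param n_components 1, 2 or 3.
#' @param init_means Initial component means (length `n_components`).
#' @param init_sigma Initial component SD (scalar, default 0.05).
#' @return An object of class `fret_mixture`: `weights` (component areas),
#'   `means`, `sigmas`, `rss`, `converged`, `n_components`, `diagnostics`.
#' @export
fit_gaussian_mixture <- function(histogram, n_components, init_means,
                                 init_sigma = 0.05) {
  stopifnot(n_components %in% 1:3, length(init_means) == n_components)
  x <- histogram$bin_center
  y <- histogram$density
  fail <- function(msg) {
    structure(list(weights = rep(NA_real_, n_components),
                   means = rep(NA_real_, n_components),
                   sigmas = rep(NA_real_, n_components),
                   rss = NA_real_, converged = FALSE,
                   n_components = n_components, diagnostics = msg),
              class = "fret_mixture")
  }
  if (length(y) == 0 || all(y == 0) || all(!is.finite(y))) {
    return(fail("degenerate histogram (no mass)"))
  }
  amp0 <- rep(max(y) / n_components, n_components)
  start <- c(
    setNames(amp0, paste0("a", seq_len(n_components))),
    setNames(init_means, paste0("m", seq_len(n_components))),
    setNames(rep(init_sigma, n_components), paste0("s", seq_len(n_components)))
  )
  k <- seq_len(n_components)
  model <- function(p) {
    rowSums(sapply(k, function(i) {
      p[[paste0("a", i)]] * exp(-(x - p[[paste0("m", i)]])^2 /
                                  (2 * p[[paste0("s", i)]]^2))
    }))
  }
  fml <- stats::as.formula(paste(
    "y ~", paste(sprintf("a%d * exp(-(x - m%d)^2 / (2 * s%d^2))", k, k, k),
                 collapse = " + ")
  ))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fml, data = data.frame(x = x, y = y), start = start,
      lower = c(rep(0, n_components), rep(-0.2, n_components),
                rep(1e-4, n_components)),
      upper = c(rep(Inf, n_components), rep(1.2, n_components),
                rep(1, n_components)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail("nonlinear least squares did not converge"))
  p <- as.list(stats::coef(fit))
  ord <- order(unlist(p[paste0("m", k)]))
  a <- unlist(p[paste0("a", k)])[ord]
  m <- unlist(p[paste0("m", k)])[ord]
  s <- unlist(p[paste0("s", k)])[ord]
  structure(list(
    weights = a * s * sqrt(2 * pi), means = unname(m), sigmas = unname(s),
    rss = sum(stats::residuals(fit)^2), converged = TRUE,
    n_components = n_components, diagnostics = "ok"
  ), class = "fret_mixture")
}

#' @export
print.fret_mixture <- function(x, ...) {
  cat(sprintf("<fret_mixture> %d component(s), converged: %s\n",
              x$n_components, x$converged))
  if (x$converged) {
    for (i in seq_len(x$n_components)) {
      cat(sprintf("  E = %.3f, sigma = %.3f, area = %.3f\n",
                  x$means[i], x$sigmas[i], x$weights[i]))
    }
  } else {
    cat("  ", x$diagnostics, "\n")
  }
  invisible(x)
}

#' @rdname fit_gaussian_mixture
#' @param x A `fret_mixture` object.
#' @param ... Unused.
#' @method tidy fret_mixture
#' @export
tidy.fret_mixture <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    mean = x$means, sigma = x$sigmas, weight = x$weights
  )
}

#' @rdname fit_gaussian_mixture
#' @method glance fret_mixture
#' @export
glance.fret_mixture <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, rss = x$rss,
                 converged = x$converged)
}
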