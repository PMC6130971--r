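#' FRET state boundaries
#'
#' Cut points partitioning the efficiency axis `[0, 1]` into labeled
#' states, used to assign kinetic state labels to fitted HMM means. The
#' two-state default splits at E = 0.5 into `low`/`high`; three-state
#' presets for the binary-complex reporters use 0.45/0.8 and 0.35/0.7.
#'
#' @param cutpoints Strictly increasing cut points inside `(0, 1)`.
#' @param labels State labels, `length(cutpoints) + 1`, ordered low to high.
#' @return An object of class `state_boundaries`.
#' @export
state_boundaries <- function(cutpoints = 0.5,
                             labels = if (length(cutpoints) == 1) c("low", "high")
                             else c("low", "mid", "high")) {
  stopifnot(all(diff(c(0, cutpoints, 1)) > 0),
            length(labels) == length(cutpoints) + 1)
  structure(list(cutpoints = cutpoints, labels = labels),
            class = "state_boundaries")
}

#' Assign state labels to fitted FRET values
#'
#' @param e Fitted FRET efficiencies (e.g. HMM state means).
#' @param boundaries A [state_boundaries()].
#' @return Character vector of state labels.
#' @export
label_states <- function(e, boundaries = state_boundaries()) {
  as.character(cut(e, breaks = c(-Inf, boundaries$cutpoints, Inf),
                   labels = boundaries$labels))
}

#' Fit a Gaussian-emission hidden Markov model to one FRET trace
#'
#' Maximum-likelihood idealization of a single molecule's efficiency trace:
#' Baum-Welch expectation-maximization with per-state Gaussian emissions
#' and a discrete per-frame transition matrix. Each molecule is fitted
#' independently. The forward-backward recursions are scaled, so
#' near-noiseless traces do not underflow; the log-likelihood is
#' non-decreasing across iterations by construction and asserted in the
#' returned `loglik_trace`.
#'
#' Initialization follows the assay's protocol: user-supplied initial state
#' means (defaults 0.2/0.8 for two states, 0.2/0.5/0.8 for three), emission
#' SD initialized to the sample SD of the trace, self-transition
#' probability 0.95 with uniform off-diagonal, uniform initial state
#' probabilities. States are reported sorted by fitted mean, so results are
#' invariant to permutations of `init_means`.
#'
#' @param efficiency Numeric efficiency trace (`NA` frames are dropped).
#' @param n_states 2 or 3.
#' @param init_means Initial state means, length `n_states`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sigma_floor Lower bound on emission SDs (prevents collapse on
#'   noiseless traces).
#' @param min_frames Minimum analyzable frames; traces shorter than this
#'   are refused with a classed error (`fretkin_error_too_few_frames`).
#' @return An object of class `hmm_fit`: `means`, `sigmas`, `trans`
#'   (row-stochastic), `init_probs`, `log_likelihood`, `loglik_trace`,
#'   `viterbi_path` (1-based state per analyzable frame), `posterior`
#'   (frame x state matrix), `converged`, `n_iterations`, `degenerate`
#'   (per-state flag for near-empty states), `occupancy`, `n_frames`.
#' @export
fit_hmm <- function(efficiency, n_states = 2,
                    init_means = if (n_states == 2) c(0.2, 0.8) else c(0.2, 0.5, 0.8),
                    tol = 1e-6, max_iter = 500, sigma_floor = 1e-3,
                    min_frames = 20) {
  e <- efficiency[!is.na(efficiency)]
  t_len <- length(e)
  if (t_len < min_frames) {
    stop(structure(
      class = c("fretkin_error_too_few_frames", "error", "condition"),
      list(message = sprintf("trace has %d analyzable frames (< %d); fit refused",
                             t_len, min_frames),
           call = sys.call(-1))
    ))
  }
  stopifnot(n_states >= 2, length(init_means) == n_states)

  means <- as.numeric(init_means)
  sigmas <- rep(max(sd(e), sigma_floor), n_states)
  trans <- matrix((1 - 0.95) / (n_states - 1), n_states, n_states)
  diag(trans) <- 0.95
  init_p <- rep(1 / n_states, n_states)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  gamma <- NULL
  for (it in seq_len(max_iter)) {
    logb <- vapply(seq_len(n_states),
                   function(k) dnorm(e, means[k], sigmas[k], log = TRUE),
                   numeric(t_len))
    fb <- fk_forward_backward(logb, init_p, trans)
    ll <- fb$loglik
    gamma <- fb$gamma
    ll_trace <- c(ll_trace, ll)

    # M-step
    init_p <- pmax(gamma[1, ], 1e-12)
    init_p <- init_p / sum(init_p)
    xi <- fb$xi_sum
    denom <- rowSums(xi)
    for (i in seq_len(n_states)) {
      if (denom[i] > 1e-12) trans[i, ] <- xi[i, ] / denom[i]
    }
    occ <- colSums(gamma)
    for (k in seq_len(n_states)) {
      if (occ[k] > 1e-8) {
        means[k] <- sum(gamma[, k] * e) / occ[k]
        sigmas[k] <- sqrt(sum(gamma[, k] * (e - means[k])^2) / occ[k])
      }
      # near-empty state: parameters retained from previous iteration
    }
    sigmas <- pmax(sigmas, sigma_floor)

    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  # final pass with the updated parameters
  logb <- vapply(seq_len(n_states),
                 function(k) dnorm(e, means[k], sigmas[k], log = TRUE),
                 numeric(t_len))
  fb <- fk_forward_backward(logb, init_p, trans)
  gamma <- fb$gamma
  occupancy <- colSums(gamma) / t_len
  degenerate <- occupancy < 1 / t_len

  # resolve label switching: sort states by fitted mean
  ord <- order(means)
  means <- means[ord]
  sigmas <- sigmas[ord]
  trans <- trans[ord, ord, drop = FALSE]
  init_p <- init_p[ord]
  gamma <- gamma[, ord, drop = FALSE]
  occupancy <- occupancy[ord]
  degenerate <- degenerate[ord]

  fit <- structure(list(
    n_states = as.integer(n_states), means = means, sigmas = sigmas,
    trans = trans, init_probs = init_p, log_likelihood = fb$loglik,
    loglik_trace = ll_trace, posterior = gamma,
    converged = converged, n_iterations = length(ll_trace),
    degenerate = degenerate, occupancy = occupancy, n_frames = t_len
  ), class = "hmm_fit")
  fit$viterbi_path <- viterbi_decode(fit, e)
  fit
}

#' Decode the most probable state path
#'
#' Viterbi decoding of an efficiency trace under a fitted model's
#' parameters (Gaussian emissions, discrete transition matrix).
#'
#' @param fit An `hmm_fit` object (or any list with `means`, `sigmas`,
#'   `trans`, `init_probs`).
#' @param efficiency Efficiency trace to decode (`NA` frames dropped).
#' @return Integer vector of 1-based state indices (states ordered by mean).
#' @export
viterbi_decode <- function(fit, efficiency) {
  e <- efficiency[!is.na(efficiency)]
  k <- length(fit$means)
  logb <- vapply(seq_len(k),
                 function(i) dnorm(e, fit$means[i], fit$sigmas[i], log = TRUE),
                 numeric(length(e)))
  fk_viterbi(logb, log(pmax(fit$init_probs, 1e-300)),
             log(pmax(fit$trans, 1e-300)))
}

#' Convert per-frame self-transition probabilities to exit rates
#'
#' Reporting convenience: `k = -frame_rate * log(p_stay)` per state, the
#' continuous-time exit rate implied by a discrete per-frame transition
#' matrix.
#'
#' @param fit An `hmm_fit`.
#' @param frame_rate Acquisition rate in Hz.
#' @return Numeric vector of per-state exit rates (s^-1).
#' @export
exit_rates <- function(fit, frame_rate) {
  -frame_rate * log(pmax(diag(fit$trans), 1e-300))
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> %d states, %d frames, logL %.2f, %s after %d iterations\n",
              x$n_states, x$n_frames, x$log_likelihood,
              if (x$converged) "converged" else "not converged", x$n_iterations))
  for (k in seq_len(x$n_states)) {
    cat(sprintf("  state %d: E = %.3f, sigma = %.3f, occupancy = %.3f%s\n",
                k, x$means[k], x$sigmas[k], x$occupancy[k],
                if (x$degenerate[k]) " (degenerate)" else ""))
  }
  invisible(x)
}

#' @rdname fit_hmm
#' @param x An `hmm_fit` object.
#' @param ... Unused.
#' @method tidy hmm_fit
#' @export
tidy.hmm_fit <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$n_states), mean = x$means, sigma = x$sigmas,
    occupancy = x$occupancy, self_transition = diag(x$trans),
    degenerate = x$degenerate
  )
}

#' @rdname fit_hmm
#' @method glance hmm_fit
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states, n_frames = x$n_frames,
    log_likelihood = x$log_likelihood, n_iterations = x$n_iterations,
    converged = x$converged, degenerate = any(x$degenerate)
  )
}

#' Fit HMMs to every molecule with transitions
#'
#' Pipeline step: fits a per-molecule HMM to the pre-bleach valid frames of
#' each molecule classified `with_transitions`. Molecules whose fit is
#' refused (too few frames) are logged and skipped, never abort the run.
#'
#' @param frames Output of [fret_frames()].
#' @param classification Classification tibble from [classify_traces()].
#' @inheritParams fit_hmm
#' @return A tibble with one row per attempted molecule: `molecule_id`,
#'   `field_id`, `fit` (list column of `hmm_fit` or `NULL`), `fitted`
#'   (logical), plus the [glance()] diagnostics of successful fits.
#' @export
fit_hmm_all <- function(frames, classification, n_states = 2,
                        init_means = if (n_states == 2) c(0.2, 0.8) else c(0.2, 0.5, 0.8),
                        tol = 1e-6, max_iter = 500, min_frames = 20) {
  sel <- dplyr::filter(classification, .data$classification == "with_transitions")
  frames_sel <- frames |>
    dplyr::inner_join(dplyr::select(sel, "molecule_id", "n_prebleach"),
                      by = "molecule_id") |>
    dplyr::filter(.data$frame < .data$n_prebleach)
  split_frames <- split(frames_sel, frames_sel$molecule_id)
  rows <- purrr::map(split_frames, function(d) {
    fit <- tryCatch(
      fit_hmm(d$efficiency, n_states = n_states, init_means = init_means,
              tol = tol, max_iter = max_iter, min_frames = min_frames),
      fretkin_error_too_few_frames = function(e) NULL
    )
    out <- tibble::tibble(
      molecule_id = d$molecule_id[1], field_id = d$field_id[1],
      fitted = !is.null(fit), fit = list(fit)
    )
    if (!is.null(fit)) out <- dplyr::bind_cols(out, glance(fit))
    out
  })
  dplyr::bind_rows(rows)
}

#' Idealized state path per frame
#'
#' Expands a table of HMM fits into a frame-level tibble of decoded states,
#' with the fitted state mean and the kinetic state label obtained by
#' applying [state_boundaries()] to the fitted means (the label used in
#' dwell analysis, rather than the raw state index).
#'
#' @param fits Output of [fit_hmm_all()].
#' @param boundaries A [state_boundaries()].
#' @return Tibble: `molecule_id`, `field_id`, `frame_index` (0-based index
#'   among that molecule's analyzable frames), `state`, `fitted_mean`,
#'   `state_label`.
#' @export
idealized_paths <- function(fits, boundaries = state_boundaries()) {
  ok <- dplyr::filter(fits, .data$fitted)
  purrr::pmap(
    list(ok$molecule_id, ok$field_id, ok$fit),
    function(mid, fid, fit) {
      labels <- label_states(fit$means, boundaries)
      tibble::tibble(
        molecule_id = mid, field_id = fid,
        frame_index = seq_along(fit$viterbi_path) - 1L,
        state = fit$viterbi_path,
        fitted_mean = fit$means[fit$viterbi_path],
        state_label = labels[fit$viterbi_path]
      )
    }
  ) |>
    dplyr::bind_rows()
}

#' Distribution of fitted FRET efficiencies and their dwell times
#'
#' Pools the fitted state means of converged HMM fits, weighted by the
#' number of frames each state occupies, into a unit-area probability
#' density histogram; and pairs each dwell (contiguous Viterbi run) with
#' its state's fitted efficiency for scatter display.
#'
#' @param fits Output of [fit_hmm_all()].
#' @param frame_rate Acquisition rate in Hz (for dwell durations).
#' @param breaks Histogram breaks on the efficiency axis.
#' @return A list with `histogram` (tibble `bin_center`, `density`) and
#'   `dwells` (tibble `molecule_id`, `fitted_mean`, `duration`).
#' @export
fitted_fret_distribution <- function(fits, frame_rate,
                                     breaks = seq(-0.2, 1.2, by = 0.02)) {
  ok <- dplyr::filter(fits, .data$fitted)
  stopifnot(nrow(ok) > 0)
  vals <- purrr::map(ok$fit, function(fit) fit$means[fit$viterbi_path])
  pooled <- pmin(pmax(unlist(vals), min(breaks)), max(breaks))
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  dwells <- purrr::map2(ok$molecule_id, ok$fit, function(mid, fit) {
    r <- rle(fit$viterbi_path)
    tibble::tibble(
      molecule_id = mid,
      fitted_mean = fit$means[r$values],
      duration = r$lengths / frame_rate
    )
  }) |>
    dplyr::bind_rows()
  list(
    histogram = tibble::tibble(bin_center = h$mids, density = h$density),
    dwells = dwells
  )
}
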