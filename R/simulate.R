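#' Simulation configuration for synthetic smFRET fields of view
#'
#' Bundles every parameter of the trace generator: the conformational
#' Markov model (state FRET efficiencies and per-second rate matrix), the
#' photophysics (total emission intensity, per-channel Gaussian noise,
#' channel leakage, dye photobleaching rates), the stochastic two-site
#' labeling model, and the acquisition geometry (frame rate, trace length,
#' molecules per field, number of fields).
#'
#' Defaults describe a surface-tethered SNARE-complex disassembly assay
#' imaged at 10 Hz for 200 s: two conformational states at FRET efficiencies
#' 0.2 (disassembled) and 0.8 (assembled), disassembly from the assembled
#' state at 0.07 s^-1 (the ~14 s mean lifetime of the long-lived assembled
#' state) and reassembly at 0.1 s^-1, donor-to-acceptor leakage 1.7% and
#' acceptor-to-donor leakage 16.5%.
#'
#' @param n_states Number of conformational states (2 or 3).
#' @param state_fret FRET efficiency of each state, strictly increasing,
#'   in `[0, 1]`. State order is defined by increasing FRET.
#' @param rate_matrix `n_states x n_states` generator matrix of per-second
#'   transition rates: non-negative off-diagonals, rows summing to zero.
#' @param total_intensity Mean summed two-channel counts per frame before
#'   bleaching (arbitrary units).
#' @param noise_sigma Per-channel Gaussian noise SD (same units).
#' @param leakage A [leakage_matrix()].
#' @param frame_rate Acquisition rate in Hz.
#' @param trace_length Trace duration in seconds.
#' @param donor_bleach_rate,acceptor_bleach_rate Per-second rates of the
#'   single irreversible photobleaching event of each dye; `0` disables
#'   bleaching.
#' @param label_efficiency Probability that each of the two labeling sites
#'   carries any dye.
#' @param donor_prob Probability that a labeled site carries the donor
#'   (vs the acceptor) dye.
#' @param initial_state Starting conformational state: `"highest"` (the
#'   assembled, highest-FRET state; the assay's starting condition),
#'   `"stationary"` (drawn from the chain's stationary distribution), or a
#'   state index.
#' @param n_molecules_per_field Molecules per field of view.
#' @param n_fields Number of independent fields of view.
#' @param seed Integer seed controlling all randomness of a run.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_field()], [simulate_experiment()]
#' @export
sim_config <- function(n_states = 2,
                       state_fret = c(0.2, 0.8),
                       rate_matrix = NULL,
                       total_intensity = 1000,
                       noise_sigma = 80,
                       leakage = leakage_matrix(0.017, 0.165),
                       frame_rate = 10,
                       trace_length = 200,
                       donor_bleach_rate = 0.005,
                       acceptor_bleach_rate = 0.01,
                       label_efficiency = 0.9,
                       donor_prob = 0.5,
                       initial_state = "highest",
                       n_molecules_per_field = 500,
                       n_fields = 3,
                       seed = 1L) {
  if (is.null(rate_matrix)) {
    rate_matrix <- if (n_states == 2) {
      # low -> high (reassembly) 0.1 /s; high -> low (disassembly) 0.07 /s
      matrix(c(-0.1, 0.1, 0.07, -0.07), nrow = 2, byrow = TRUE)
    } else {
      k <- 0.1
      m <- matrix(k, n_states, n_states)
      diag(m) <- 0
      diag(m) <- -rowSums(m)
      m
    }
  }
  cfg <- list(
    n_states = as.integer(n_states), state_fret = as.numeric(state_fret),
    rate_matrix = rate_matrix, total_intensity = total_intensity,
    noise_sigma = noise_sigma, leakage = leakage, frame_rate = frame_rate,
    trace_length = trace_length, donor_bleach_rate = donor_bleach_rate,
    acceptor_bleach_rate = acceptor_bleach_rate,
    label_efficiency = label_efficiency, donor_prob = donor_prob,
    initial_state = initial_state,
    n_molecules_per_field = as.integer(n_molecules_per_field),
    n_fields = as.integer(n_fields), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_states %in% c(2L, 3L),
    length(cfg$state_fret) == cfg$n_states,
    all(cfg$state_fret >= 0 & cfg$state_fret <= 1),
    all(diff(cfg$state_fret) > 0),
    is.matrix(cfg$rate_matrix),
    nrow(cfg$rate_matrix) == cfg$n_states,
    ncol(cfg$rate_matrix) == cfg$n_states,
    cfg$total_intensity > 0, cfg$noise_sigma >= 0,
    cfg$frame_rate > 0, cfg$trace_length > 0,
    cfg$donor_bleach_rate >= 0, cfg$acceptor_bleach_rate >= 0,
    cfg$label_efficiency >= 0, cfg$label_efficiency <= 1,
    cfg$donor_prob >= 0, cfg$donor_prob <= 1,
    cfg$n_molecules_per_field >= 1, cfg$n_fields >= 1
  )
  q <- cfg$rate_matrix
  off <- q
  diag(off) <- 0
  if (any(off < 0)) stop("rate_matrix off-diagonals must be non-negative")
  if (any(abs(rowSums(q)) > 1e-8)) stop("rate_matrix rows must sum to zero")
  invisible(cfg)
}

# Deterministic per-molecule substream seed; stable under reordering of
# molecules or fields, always < 2^31.
substream_seed <- function(seed, field, molecule) {
  ((as.numeric(seed) %% 99991) * 20011 +
     as.numeric(field) * 100003 +
     as.numeric(molecule) * 127) %% 2147483647
}

initial_state_index <- function(config) {
  if (identical(config$initial_state, "highest")) return(config$n_states)
  if (identical(config$initial_state, "stationary")) {
    # stationary distribution: left null vector of the generator
    q <- config$rate_matrix
    ns <- nrow(q)
    a <- rbind(t(q), rep(1, ns))
    pi0 <- qr.solve(a, c(rep(0, ns), 1))
    pi0 <- pmax(pi0, 0)
    return(sample.int(ns, 1, prob = pi0 / sum(pi0)))
  }
  as.integer(config$initial_state)
}

#' Simulate a continuous-time conformational state path
#'
#' Draws one exact-event realization of the continuous-time Markov chain
#' defined by `config$rate_matrix` over `[0, trace_length]` (Gillespie
#' algorithm): holding times are exponential with the state's total exit
#' rate, and jumps are drawn proportionally to the off-diagonal rates.
#' States with zero exit rate are absorbing and yield a single segment.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; when supplied the path is reproducible.
#' @param initial_state Optional state index overriding `config$initial_state`.
#' @return A tibble with one row per visited state: `state` (1-based index,
#'   ordered by increasing FRET), `entry_time` and `exit_time` in seconds.
#' @export
simulate_state_path <- function(config, seed = NULL, initial_state = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- config$rate_matrix
  t_end <- config$trace_length
  s <- if (is.null(initial_state)) initial_state_index(config) else as.integer(initial_state)
  state <- integer(0)
  entry <- numeric(0)
  t <- 0
  repeat {
    state <- c(state, s)
    entry <- c(entry, t)
    exit_rate <- -q[s, s]
    if (exit_rate <= 0) break
    t <- t + rexp(1, exit_rate)
    if (t >= t_end) break
    p <- q[s, ]
    p[s] <- 0
    s <- sample.int(length(p), 1, prob = p)
  }
  tibble::tibble(
    state = state,
    entry_time = entry,
    exit_time = c(entry[-1], t_end)
  )
}

# Integrate a piecewise-constant signal over uniform camera frames.
# Segments [start, end) carry constant values; each frame reports the
# time-weighted average over its exposure (camera integration model).
integrate_frames <- function(seg_start, seg_end, seg_value, n_frames, frame_rate) {
  out <- numeric(n_frames)
  dt <- 1 / frame_rate
  for (i in seq_along(seg_value)) {
    s <- seg_start[i]
    e <- min(seg_end[i], n_frames * dt)
    if (e <= s) next
    f0 <- max(0L, as.integer(floor(s / dt + 1e-12)))
    f1 <- min(n_frames - 1L, as.integer(ceiling(e / dt - 1e-12)) - 1L)
    if (f1 < f0) next
    fs <- f0:f1
    ov <- pmin(e, (fs + 1) * dt) - pmax(s, fs * dt)
    out[fs + 1] <- out[fs + 1] + seg_value[i] * ov / dt
  }
  out
}

#' Render a state path into a two-channel intensity trace
#'
#' Converts a conformational path into per-frame donor/acceptor counts:
#' the total emission `total_intensity` is split by the state's FRET
#' efficiency (frames spanning a transition carry the time-weighted
#' average), photobleaching truncates the appropriate channel (acceptor
#' bleach returns the full intensity to the donor channel; donor bleach
#' drops both channels to background zero), channel leakage mixes the two
#' ideal channels, and Gaussian noise is added per channel.
#'
#' @param path A state path from [simulate_state_path()].
#' @param config A [sim_config()].
#' @param donor_bleach_time,acceptor_bleach_time Bleach times in seconds;
#'   `NULL` draws them from the configured exponential bleaching rates,
#'   `Inf` disables bleaching of that dye.
#' @param seed Optional integer seed.
#' @return A tibble with columns `frame` (0-based), `time` (frame start, s),
#'   `donor`, `acceptor` (observed counts) and `ideal_efficiency` (the
#'   noise- and leakage-free frame-averaged FRET efficiency, `NA` after
#'   bleaching); bleach times are attached as attributes
#'   `donor_bleach_time` / `acceptor_bleach_time`.
#' @export
render_intensities <- function(path, config, donor_bleach_time = NULL,
                               acceptor_bleach_time = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw_bleach <- function(rate) {
    if (is.null(rate) || rate <= 0) Inf else rexp(1, rate)
  }
  if (is.null(donor_bleach_time)) donor_bleach_time <- draw_bleach(config$donor_bleach_rate)
  if (is.null(acceptor_bleach_time)) acceptor_bleach_time <- draw_bleach(config$acceptor_bleach_rate)

  n_frames <- as.integer(round(config$trace_length * config$frame_rate))
  segs <- split_segments(path, config, donor_bleach_time, acceptor_bleach_time)

  donor_ideal <- integrate_frames(segs$start, segs$end, segs$donor, n_frames, config$frame_rate)
  acceptor_ideal <- integrate_frames(segs$start, segs$end, segs$acceptor, n_frames, config$frame_rate)
  e_ideal <- integrate_frames(segs$start, segs$end, segs$efficiency * segs$alive,
                              n_frames, config$frame_rate)
  alive <- integrate_frames(segs$start, segs$end, as.numeric(segs$alive),
                            n_frames, config$frame_rate)
  e_ideal <- ifelse(alive > 0, e_ideal / pmax(alive, 1e-12), NA_real_)

  mixed <- mix_leakage(donor_ideal, acceptor_ideal, config$leakage)
  donor <- mixed$donor + rnorm(n_frames, 0, config$noise_sigma)
  acceptor <- mixed$acceptor + rnorm(n_frames, 0, config$noise_sigma)

  out <- tibble::tibble(
    frame = seq_len(n_frames) - 1L,
    time = (seq_len(n_frames) - 1L) / config$frame_rate,
    donor = donor,
    acceptor = acceptor,
    ideal_efficiency = e_ideal
  )
  attr(out, "donor_bleach_time") <- donor_bleach_time
  attr(out, "acceptor_bleach_time") <- acceptor_bleach_time
  out
}

# Split the conformational path at bleach times into segments carrying
# constant ideal (donor, acceptor) emission.
split_segments <- function(path, config, t_d, t_a) {
  t_end <- config$trace_length
  bp <- sort(unique(pmin(pmax(c(0, path$entry_time, t_a, t_d, t_end), 0), t_end)))
  bp <- bp[bp <= t_end]
  if (bp[length(bp)] < t_end) bp <- c(bp, t_end)
  start <- bp[-length(bp)]
  end <- bp[-1]
  keep <- end > start
  start <- start[keep]
  end <- end[keep]
  mid <- (start + end) / 2
  st <- path$state[findInterval(mid, path$entry_time)]
  e <- config$state_fret[st]
  total <- config$total_intensity
  donor <- ifelse(mid >= t_d, 0, ifelse(mid >= t_a, total, total * (1 - e)))
  acceptor <- ifelse(mid >= t_d | mid >= t_a, 0, total * e)
  list(start = start, end = end, donor = donor, acceptor = acceptor,
       efficiency = e, alive = mid < t_d & mid < t_a)
}

draw_labels <- function(config) {
  site <- function() {
    if (runif(1) >= config$label_efficiency) return("none")
    if (runif(1) < config$donor_prob) "donor" else "acceptor"
  }
  s1 <- site()
  s2 <- site()
  n_donor <- sum(c(s1, s2) == "donor")
  n_acceptor <- sum(c(s1, s2) == "acceptor")
  class <- if (n_donor >= 1 && n_acceptor >= 1) "fret"
  else if (n_donor >= 1) "donor_only"
  else if (n_acceptor >= 1) "acceptor_only"
  else "unlabeled"
  list(class = class, n_donor = n_donor, n_acceptor = n_acceptor)
}

#' Simulate one field of view
#'
#' Draws the labeling outcome for each molecule (each of two sites carries a
#' dye with probability `label_efficiency`, donor vs acceptor with
#' probability `donor_prob`), simulates a conformational path and bleach
#' times per molecule, and renders intensity traces. Molecules without any
#' donor dye emit nothing under donor excitation and produce no trace;
#' donor-only molecules produce donor-channel traces (with leakage into the
#' acceptor channel); donor+acceptor molecules produce FRET traces.
#'
#' @param config A [sim_config()].
#' @param field_id Field identifier (string).
#' @param field_index Integer index used to derive the field's RNG substream.
#' @param keep_paths Also return the true conformational paths of the
#'   FRET-capable molecules (for ground-truth comparisons).
#' @return A list with `traces` — a long tibble (`molecule_id`, `field_id`,
#'   `frame`, `time`, `donor`, `acceptor`) of all donor-visible molecules —
#'   and `ledger` — one row per molecule of ground truth: labeling class,
#'   dye counts, bleach times, number of conformational transitions before
#'   bleaching, pre-bleach occupancy of the highest-FRET state, and the
#'   ground-truth classification (`with_transitions`, `without_transitions`,
#'   `donor_only`, or `dark`). With `keep_paths = TRUE` a third tibble
#'   `paths` (`molecule_id`, `state`, `entry_time`, `exit_time`).
#' @export
simulate_field <- function(config, field_id = "F1", field_index = 1L,
                           keep_paths = FALSE) {
  n <- config$n_molecules_per_field
  traces <- vector("list", n)
  ledger <- vector("list", n)
  paths_out <- vector("list", n)
  for (m in seq_len(n)) {
    set.seed(substream_seed(config$seed, field_index, m))
    lab <- draw_labels(config)
    mol_id <- sprintf("%s_m%03d", field_id, m)

    t_d <- if (lab$n_donor > 0 && config$donor_bleach_rate > 0) {
      rexp(1, config$donor_bleach_rate)
    } else Inf
    t_a <- if (lab$n_acceptor > 0 && config$acceptor_bleach_rate > 0) {
      rexp(1, config$acceptor_bleach_rate)
    } else Inf

    path <- simulate_state_path(config)
    window_end <- min(t_d, t_a, config$trace_length)
    n_trans <- sum(path$entry_time > 0 & path$entry_time < window_end)
    occ_high <- if (window_end > 0) {
      hi <- path$state == config$n_states
      sum(pmin(path$exit_time, window_end) * hi - pmin(path$entry_time, window_end) * hi) /
        window_end
    } else NA_real_

    if (lab$class == "fret") {
      tr <- render_intensities(path, config, donor_bleach_time = t_d,
                               acceptor_bleach_time = t_a)
      truth <- if (n_trans >= 1) "with_transitions" else "without_transitions"
      if (keep_paths) {
        paths_out[[m]] <- tibble::tibble(
          molecule_id = mol_id, field_id = field_id,
          state = path$state, entry_time = path$entry_time,
          exit_time = path$exit_time
        )
      }
    } else if (lab$class == "donor_only") {
      flat <- tibble::tibble(state = config$n_states, entry_time = 0,
                             exit_time = config$trace_length)
      cfg_d <- config
      cfg_d$state_fret <- rep(0, config$n_states) # all emission in donor channel
      cfg_d$total_intensity <- config$total_intensity * lab$n_donor
      tr <- render_intensities(flat, cfg_d, donor_bleach_time = t_d,
                               acceptor_bleach_time = Inf)
      truth <- "donor_only"
    } else {
      tr <- NULL
      truth <- "dark"
    }

    if (!is.null(tr)) {
      traces[[m]] <- tibble::tibble(
        molecule_id = mol_id, field_id = field_id,
        frame = tr$frame, time = tr$time, donor = tr$donor, acceptor = tr$acceptor
      )
    }
    ledger[[m]] <- tibble::tibble(
      molecule_id = mol_id, field_id = field_id,
      label_class = lab$class, n_donor = lab$n_donor, n_acceptor = lab$n_acceptor,
      donor_bleach_time = t_d, acceptor_bleach_time = t_a,
      n_transitions_prebleach = n_trans,
      occupancy_high_prebleach = occ_high,
      truth_class = truth
    )
  }
  out <- list(
    traces = dplyr::bind_rows(traces),
    ledger = dplyr::bind_rows(ledger)
  )
  if (keep_paths) out$paths <- dplyr::bind_rows(paths_out)
  out
}

#' Simulate a full experiment (several fields of view)
#'
#' @param config A [sim_config()]; `n_fields` fields are generated, each
#'   from its own RNG substream so fields are reproducible independently.
#' @param keep_paths Also return the true conformational paths.
#' @return A list with `traces` (long tibble over all fields, carrying the
#'   acquisition `frame_rate` as an attribute) and `ledger` (ground truth,
#'   one row per molecule); with `keep_paths = TRUE`, also `paths`.
#' @export
simulate_experiment <- function(config, keep_paths = FALSE) {
  fields <- purrr::map(seq_len(config$n_fields), function(f) {
    simulate_field(config, field_id = sprintf("F%02d", f), field_index = f,
                   keep_paths = keep_paths)
  })
  traces <- dplyr::bind_rows(purrr::map(fields, "traces"))
  attr(traces, "frame_rate") <- config$frame_rate
  out <- list(
    traces = traces,
    ledger = dplyr::bind_rows(purrr::map(fields, "ledger"))
  )
  if (keep_paths) out$paths <- dplyr::bind_rows(purrr::map(fields, "paths"))
  out
}
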