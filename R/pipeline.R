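#' Analysis run configuration
#'
#' Bundles every tunable of the analysis pipeline, with the assay's
#' constants as defaults: 10 Hz acquisition, leakage 1.7%/16.5%, a
#' two-state boundary at E = 0.5, short/long partitions at 0.56 s (high
#' state) and 0.32 s (low state), exponential-fit cutoff 0.56 s, HMM
#' initial means 0.2/0.8. All values are defaults, never hard-coded in the
#' pipeline stages.
#'
#' @param frame_rate Acquisition rate, Hz.
#' @param leakage A [leakage_matrix()].
#' @param boundaries A [state_boundaries()].
#' @param partition_thresholds Named vector of short/long partition
#'   thresholds per state label, seconds.
#' @param fit_domain_start Exponential-fit domain start, seconds.
#' @param fit_state State label whose dwells are rate-fitted.
#' @param n_states,init_means,hmm_tol,hmm_max_iter,min_frames HMM settings.
#' @param rate_method `"lsq"` or `"mle"` (see [fit_exponential_rate()]).
#' @param rate_binwidth Histogram bin width for the lsq rate fit, seconds.
#' @param seed Integer seed for any stochastic stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(frame_rate = 10,
                       leakage = leakage_matrix(0.017, 0.165),
                       boundaries = state_boundaries(0.5),
                       partition_thresholds = c(high = 0.56, low = 0.32),
                       fit_domain_start = 0.56,
                       fit_state = "high",
                       n_states = 2,
                       init_means = if (n_states == 2) c(0.2, 0.8) else c(0.2, 0.5, 0.8),
                       hmm_tol = 1e-6, hmm_max_iter = 500,
                       min_frames = 20,
                       rate_method = "lsq",
                       rate_binwidth = 1,
                       seed = 1L) {
  cfg <- list(
    frame_rate = frame_rate, leakage = leakage, boundaries = boundaries,
    partition_thresholds = partition_thresholds,
    fit_domain_start = fit_domain_start, fit_state = fit_state,
    n_states = as.integer(n_states), init_means = init_means,
    hmm_tol = hmm_tol, hmm_max_iter = as.integer(hmm_max_iter),
    min_frames = as.integer(min_frames), rate_method = rate_method,
    rate_binwidth = rate_binwidth, seed = as.integer(seed)
  )
  stopifnot(
    cfg$frame_rate > 0, inherits(cfg$leakage, "leakage_matrix"),
    inherits(cfg$boundaries, "state_boundaries"),
    all(cfg$partition_thresholds > 0), cfg$fit_domain_start >= 0,
    cfg$n_states %in% 2:3, length(cfg$init_means) == cfg$n_states,
    cfg$hmm_tol > 0, cfg$hmm_max_iter >= 1, cfg$min_frames >= 2,
    cfg$rate_method %in% c("lsq", "mle"), cfg$rate_binwidth > 0
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Only keys present in the file override the [run_config()] defaults.
#' Nested keys `leakage: {l_da, l_ad}` and `boundaries: {cutpoints,
#' labels}` are converted to their parameter objects. Unknown keys raise a
#' validation error listing the offending fields.
#'
#' @param path A `.yml`/`.yaml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  if (!is.null(raw$leakage)) {
    raw$leakage <- leakage_matrix(raw$leakage$l_da, raw$leakage$l_ad)
  }
  if (!is.null(raw$boundaries)) {
    raw$boundaries <- state_boundaries(unlist(raw$boundaries$cutpoints),
                                       unlist(raw$boundaries$labels))
  }
  if (!is.null(raw$partition_thresholds)) {
    raw$partition_thresholds <- unlist(raw$partition_thresholds)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Simulate an experiment and write its trace files and ground-truth ledger
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @param format Trace file format (`"csv"`, `"tsv"` or `"parquet"`).
#' @param overwrite Overwrite existing outputs.
#' @return Invisibly, a list with the written `traces_path`, `ledger_path`
#'   and the in-memory `traces`/`ledger`.
#' @export
run_simulate <- function(sim, out_dir, format = "csv", overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- simulate_experiment(sim)
  ts <- trace_set(res$traces, frame_rate = sim$frame_rate,
                  condition = "simulated")
  traces_path <- file.path(out_dir, paste0("traces.", format))
  write_traces(ts, traces_path, format = format, overwrite = overwrite)
  ledger_path <- file.path(out_dir, "ledger.csv")
  if (file.exists(ledger_path) && !overwrite) {
    stop("file exists and overwrite = FALSE: ", ledger_path)
  }
  write_result_csv(res$ledger, ledger_path, config = unclass(sim))
  invisible(list(traces_path = traces_path, ledger_path = ledger_path,
                 traces = ts, ledger = res$ledger))
}

#' Run the full trace-analysis pipeline
#'
#' Orchestrates every stage on a trace set: leakage correction and FRET
#' computation, photobleach detection and molecule classification, the
#' fraction of molecules without transitions, point-wise FRET histogram,
#' per-molecule HMM idealization, dwell extraction, short/long-lived
#' population partitioning and the exponential rate fit. A molecule whose
#' HMM fit is refused is logged and skipped; a rate fit with too few
#' long-lived dwells is reported as `NULL` rather than aborting.
#'
#' @param traces A [trace_set()] or long trace tibble (then `frame_rate`
#'   is taken from `config`), or a path readable by [read_traces()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, every result table
#'   is written as CSV with a provenance header and the per-stage molecule
#'   counts as JSON-lines (`log.jsonl`).
#' @return A list: `frames`, `classification`, `fraction` (per-field and
#'   summary), `pointwise` histogram, `fits`, `paths`, `dwells`,
#'   `partition`, `rate` (a `rate_fit` or `NULL`), and `counts` — the
#'   per-stage molecule accounting (every molecule lands in exactly one
#'   terminal category).
#' @export
run_analyze <- function(traces, config = run_config(), out_dir = NULL) {
  if (is.character(traces)) traces <- read_traces(traces)
  frame_rate <- attr(traces, "frame_rate") %||% config$frame_rate

  empty_run <- function() {
    warning("no traces to analyze; returning empty results")
    list(frames = tibble::tibble(), classification = tibble::tibble(),
         fraction = NULL, pointwise = tibble::tibble(),
         fits = tibble::tibble(), paths = tibble::tibble(),
         dwells = tibble::tibble(), partition = tibble::tibble(),
         rate = NULL,
         counts = tibble::tibble(stage = "total_molecules", n = 0L))
  }
  if (nrow(traces) == 0) return(empty_run())

  frames <- fret_frames(traces, leakage = config$leakage)
  high_boundary <- max(config$boundaries$cutpoints)
  classification <- classify_traces(frames, high_boundary = high_boundary,
                                    min_frames = config$min_frames)
  fraction <- fraction_without_transitions(classification)
  pointwise <- pointwise_histogram(frames, classification)

  fits <- fit_hmm_all(frames, classification, n_states = config$n_states,
                      init_means = config$init_means, tol = config$hmm_tol,
                      max_iter = config$hmm_max_iter,
                      min_frames = config$min_frames)
  paths <- if (nrow(fits) && any(fits$fitted)) {
    idealized_paths(fits, config$boundaries)
  } else tibble::tibble()
  dwells <- if (nrow(paths)) extract_dwells(paths, frame_rate) else tibble::tibble()
  partition <- if (nrow(dwells)) {
    partition_populations(dwells, config$partition_thresholds)
  } else tibble::tibble()
  rate <- NULL
  if (nrow(dwells)) {
    d_state <- dwells[dwells$state_label == config$fit_state, ]
    rate <- tryCatch(
      fit_exponential_rate(d_state, fit_domain_start = config$fit_domain_start,
                           method = config$rate_method,
                           binwidth = config$rate_binwidth),
      error = function(e) {
        message("rate fit skipped: ", conditionMessage(e))
        NULL
      }
    )
  }

  counts <- tibble::tibble(
    stage = c("total_molecules", "excluded", "without_transitions",
              "with_transitions", "hmm_fitted", "hmm_refused", "dwells"),
    n = c(nrow(classification),
          sum(classification$classification == "excluded"),
          sum(classification$classification == "without_transitions"),
          sum(classification$classification == "with_transitions"),
          sum(fits$fitted %||% logical(0)),
          sum(!(fits$fitted %||% logical(0))),
          nrow(dwells))
  )

  out <- list(frames = frames, classification = classification,
              fraction = fraction, pointwise = pointwise, fits = fits,
              paths = paths, dwells = dwells, partition = partition,
              rate = rate, counts = counts)
  if (!is.null(out_dir)) write_analysis(out, config, out_dir)
  out
}

write_analysis <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(config)
  write_result_csv(res$classification,
                   file.path(out_dir, "classification.csv"), cfg)
  if (!is.null(res$fraction)) {
    write_result_csv(res$fraction$per_field,
                     file.path(out_dir, "fraction_without_transitions.csv"), cfg)
  }
  write_result_csv(res$pointwise, file.path(out_dir, "pointwise_histogram.csv"), cfg)
  if (nrow(res$fits)) {
    write_result_csv(dplyr::select(res$fits, -"fit"),
                     file.path(out_dir, "hmm_fits.csv"), cfg)
  }
  if (nrow(res$dwells)) {
    write_result_csv(res$dwells, file.path(out_dir, "dwells.csv"), cfg)
  }
  if (nrow(res$partition)) {
    write_result_csv(res$partition, file.path(out_dir, "partition.csv"), cfg)
  }
  if (!is.null(res$rate)) {
    write_result_csv(glance(res$rate), file.path(out_dir, "rate_fit.csv"), cfg)
  }
  log_path <- file.path(out_dir, "log.jsonl")
  lines <- vapply(seq_len(nrow(res$counts)), function(i) {
    jsonlite::toJSON(as.list(res$counts[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, log_path)
  invisible(out_dir)
}

#' Binding and competition summaries
#'
#' Computes the equilibrium binding-isotherm table for a set of ligand
#' concentrations and, when observations are supplied, the normalized
#' competition summary.
#'
#' @param ligand_concs Ligand concentrations, uM.
#' @param kd Dissociation constant, uM.
#' @param observations Optional competition observations (see
#'   [normalize_competition()]).
#' @param out_dir Optional output directory for CSV results.
#' @return A list with `isotherm` (tibble `ligand_conc`, `fraction_bound`)
#'   and `competition` (tibble or `NULL`).
#' @export
run_binding <- function(ligand_concs, kd = 1.5, observations = NULL,
                        out_dir = NULL) {
  isotherm <- tibble::tibble(
    ligand_conc = ligand_concs,
    fraction_bound = fraction_bound(ligand_concs, kd)
  )
  competition <- if (!is.null(observations)) {
    normalize_competition(observations)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_csv(isotherm, file.path(out_dir, "isotherm.csv"),
                     list(kd = kd))
    if (!is.null(competition)) {
      write_result_csv(competition, file.path(out_dir, "competition.csv"),
                       list(kd = kd))
    }
  }
  list(isotherm = isotherm, competition = competition)
}
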