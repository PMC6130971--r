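make_paths <- function(states, frame_rate = 10, molecule_id = "m1",
                       fitted_means = c(0.2, 0.8)) {
  tibble::tibble(
    molecule_id = molecule_id, field_id = "F1",
    frame_index = seq_along(states) - 1L,
    state = states, fitted_mean = fitted_means[states],
    state_label = c("low", "high")[states]
  )
}

test_that("boundary dwells are censored and interior dwells timed exactly", {
  # 50 high, 3 low, 40 high frames at 10 frames/s: only the interior
  # 0.3 s low dwell survives (sections I and III have unknown entry/exit)
  paths <- make_paths(c(rep(2L, 50), rep(1L, 3), rep(2L, 40)))
  dw <- extract_dwells(paths, frame_rate = 10)
  expect_equal(nrow(dw), 1L)
  expect_equal(dw$duration, 0.3)
  expect_equal(dw$state_label, "low")

  # with boundary dwells kept, all three runs appear with exact durations
  dw_all <- extract_dwells(paths, frame_rate = 10, drop_boundary = FALSE)
  expect_equal(dw_all$duration, c(5, 0.3, 4))
})

test_that("a trace without transitions contributes no interior dwells", {
  paths <- make_paths(rep(2L, 80))
  expect_equal(nrow(extract_dwells(paths, frame_rate = 10)), 0L)
})

test_that("interior dwell time is conserved per molecule", {
  set.seed(12)
  states <- rle(sample(1:2, 400, replace = TRUE))
  states <- inverse.rle(states)
  paths <- make_paths(states)
  dw <- extract_dwells(paths, frame_rate = 10)
  r <- rle(states)
  interior <- r$lengths[-c(1, length(r$lengths))] / 10
  expect_equal(sum(dw$duration), sum(interior))
  expect_equal(nrow(dw), length(interior))
})

test_that("dwell histograms conserve counts on linear and log axes", {
  set.seed(13)
  dw <- tibble::tibble(
    molecule_id = "m1", field_id = "F1",
    state_label = sample(c("low", "high"), 300, replace = TRUE),
    duration = rexp(300, 0.2)
  )
  for (lab in c("low", "high")) {
    h <- dwell_histograms(dw[dw$state_label == lab, ])
    n_lab <- sum(dw$state_label == lab)
    expect_equal(sum(h$linear$count), n_lab)
    expect_equal(sum(h$log$count), n_lab)
  }
})

test_that("the log-time minimum separates two well-split dwell populations", {
  # mixture of exp(rate 10) and exp(rate 0.1): modes near 0.1 s and 10 s.
  # The density minimum of the log10-duration mixture is computed here
  # numerically from the generative model, independent of the histogram.
  set.seed(14)
  n <- 4000
  dur <- c(rexp(n / 2, 10), rexp(n / 2, 0.1))
  dens <- function(u) {
    # density of log10(T) for the equal mixture
    t <- 10^u
    ln10 <- log(10)
    0.5 * (10 * exp(-10 * t) + 0.1 * exp(-0.1 * t)) * t * ln10
  }
  grid <- seq(-1.5, 1.5, by = 0.01)
  interior <- grid[which.min(dens(grid))]

  dw <- tibble::tibble(molecule_id = "m1", field_id = "F1",
                       state_label = "high", duration = dur)
  h <- dwell_histograms(dw)
  thr <- find_partition_threshold(h$log, default_threshold = 0.56)
  expect_false(thr$fallback)
  expect_lt(abs(log10(thr$threshold) - interior), 0.3)
})

test_that("a unimodal dwell distribution falls back to the default threshold", {
  set.seed(15)
  dw <- tibble::tibble(molecule_id = "m1", field_id = "F1",
                       state_label = "high", duration = rexp(2000, 1))
  h <- dwell_histograms(dw)
  thr <- find_partition_threshold(h$log, default_threshold = 0.56)
  expect_true(thr$fallback)
  expect_equal(thr$threshold, 0.56)
})

test_that("short-dwell fractions match the exponential closed form", {
  # P(T < 0.56) for T ~ exp(1/14.3) is 1 - exp(-0.56/14.3) ~ 0.0384
  set.seed(16)
  n <- 1e4
  dw <- tibble::tibble(molecule_id = "m1", field_id = "F1",
                       state_label = rep(c("high", "low"), each = n / 2),
                       duration = c(rexp(n / 2, 1 / 14.3),
                                    rexp(n / 2, 1 / 14.3)))
  out <- suppressMessages(
    partition_populations(dw, thresholds = c(high = 0.56, low = 0.32))
  )
  p_high <- 1 - exp(-0.56 / 14.3)
  p_low <- 1 - exp(-0.32 / 14.3)
  se_high <- sqrt(p_high * (1 - p_high) / (n / 2))
  se_low <- sqrt(p_low * (1 - p_low) / (n / 2))
  expect_lt(abs(out$short_mean[out$state_label == "high"] - p_high),
            3 * se_high)
  expect_lt(abs(out$short_mean[out$state_label == "low"] - p_low),
            3 * se_low)
  expect_equal(out$short_mean + out$long_mean, rep(1, 2))
})

test_that("partitioning uses a strict threshold and exact boundary counts", {
  dw <- tibble::tibble(molecule_id = "m1", field_id = "F1",
                       state_label = "high",
                       duration = c(0.3, 0.55, 0.56, 0.57, 2))
  out <- suppressMessages(partition_populations(dw))
  # durations strictly below 0.56 are short: 0.3 and 0.55, i.e. 2 of 5
  expect_equal(out$short_mean, 0.4)
  expect_equal(out$n_dwells, 5L)
})

test_that("both rate estimators recover a known exponential time constant", {
  # deterministic quantile grid of exp(mean 5): removes Monte Carlo error,
  # so both estimators must land within 2% of the generative constant
  tau <- 5
  dur <- stats::qexp(stats::ppoints(2000), rate = 1 / tau)
  dw <- tibble::tibble(molecule_id = "m1", field_id = "F1",
                       state_label = "high", duration = dur)
  for (m in c("lsq", "mle")) {
    fit <- fit_exponential_rate(dw, fit_domain_start = 0.56, method = m)
    expect_true(fit$converged)
    expect_lt(abs(1 / fit$rate - tau) / tau, 0.02)
  }
})

test_that("fitting above a start time corrects truncation bias", {
  # estimate from dwells >= start only; memorylessness means the estimator
  # must stay unbiased for the full time constant
  set.seed(17)
  taus <- c(2, 5, 14.3)
  starts <- c(0, 0.32, 0.56)
  for (tau in taus) {
    for (s0 in starts) {
      est <- replicate(20, {
        dw <- tibble::tibble(molecule_id = "m1", field_id = "F1",
                             state_label = "high",
                             duration = rexp(5000, 1 / tau))
        fit <- fit_exponential_rate(dw, fit_domain_start = s0,
                                    method = "mle")
        1 / fit$rate
      })
      expect_lt(abs(mean(est) - tau) / tau, 0.03)
    }
  }
})

test_that("least-squares and maximum-likelihood rates agree", {
  set.seed(18)
  dw <- tibble::tibble(molecule_id = "m1", field_id = "F1",
                       state_label = "high", duration = rexp(3000, 1 / 14.3))
  lsq <- fit_exponential_rate(dw, method = "lsq")
  mle <- fit_exponential_rate(dw, method = "mle")
  expect_lt(abs(lsq$rate - mle$rate) / mle$rate, 0.15)
  expect_equal(glance(lsq)$method, "lsq")
  expect_true(all(c("term", "estimate") %in% names(tidy(mle))))
})

test_that("too few dwells refuse a rate fit", {
  dw <- tibble::tibble(molecule_id = "m1", field_id = "F1",
                       state_label = "high", duration = rexp(5, 1))
  expect_error(fit_exponential_rate(dw, min_dwells = 20), "dwell")
})
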