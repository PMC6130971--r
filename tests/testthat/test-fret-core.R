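test_that("zero leakage correction is the identity", {
  lm0 <- leakage_matrix(0, 0)
  out <- correct_leakage(c(100, 200), c(300, 400), lm0)
  expect_identical(out$donor, c(100, 200))
  expect_identical(out$acceptor, c(300, 400))
})

test_that("unmixing inverts mixing to machine precision", {
  lm <- leakage_matrix(0.017, 0.165)
  mixed <- mix_leakage(200, 800, lm)
  back <- correct_leakage(mixed$donor, mixed$acceptor, lm)
  expect_equal(back$donor, 200, tolerance = 1e-12)
  expect_equal(back$acceptor, 800, tolerance = 1e-12)
})

test_that("unmixing agrees with the hand-solved 2x2 system", {
  # observed (400, 600) under l_da = 0.1, l_ad = 0.3:
  #   0.9 D + 0.3 A = 400
  #   0.1 D + 0.7 A = 600
  # det = 1 - 0.1 - 0.3 = 0.6; D = (0.7*400 - 0.3*600)/0.6 = 500/3,
  # A = (0.9*600 - 0.1*400)/0.6 = 2500/3
  out <- correct_leakage(400, 600, leakage_matrix(0.1, 0.3))
  expect_equal(out$donor, 500 / 3)
  expect_equal(out$acceptor, 2500 / 3)
})

test_that("mix-unmix identity holds over random valid leakage matrices", {
  set.seed(101)
  for (i in 1:50) {
    lm <- leakage_matrix(runif(1, 0, 0.45), runif(1, 0, 0.45))
    d <- runif(20, 0, 2000)
    a <- runif(20, 0, 2000)
    mixed <- mix_leakage(d, a, lm)
    back <- correct_leakage(mixed$donor, mixed$acceptor, lm)
    expect_equal(back$donor, d, tolerance = 1e-10)
    expect_equal(back$acceptor, a, tolerance = 1e-10)
  }
})

test_that("a singular leakage matrix is rejected", {
  expect_error(correct_leakage(1, 1, leakage_matrix(0.4, 0.6)), "singular")
})

test_that("FRET efficiency follows E = A / (A + D) with floor flagging", {
  expect_equal(compute_fret(500, 500), 0.5)
  expect_equal(compute_fret(800, 0), 0)
  expect_equal(compute_fret(0, 800), 1)
  e <- compute_fret(c(500, 10), c(500, 10), total_floor = 100)
  expect_equal(e, c(0.5, NA_real_))
  # non-negative inputs always give E in [0, 1]
  set.seed(2)
  d <- runif(100, 0, 1000)
  a <- runif(100, 0, 1000)
  e <- compute_fret(d, a)
  expect_true(all(e >= 0 & e <= 1, na.rm = TRUE))
})

# Build a synthetic corrected-intensity trace from per-frame efficiencies,
# with the noise of the reference conditions.
intensity_from_e <- function(e, total = 1000, sigma = 40, seed = 1) {
  set.seed(seed)
  donor <- total * (1 - e) + rnorm(length(e), 0, sigma)
  acceptor <- total * e + rnorm(length(e), 0, sigma)
  list(donor = donor, acceptor = acceptor,
       efficiency = compute_fret(donor, acceptor))
}

test_that("acceptor bleach without recovery is classified without_transitions", {
  e_true <- rep(0.8, 300)
  tr <- intensity_from_e(e_true, seed = 3)
  # acceptor bleach at frame 150: donor rises to the full total
  tr$donor[151:300] <- 1000 + rnorm(150, 0, 40)
  tr$acceptor[151:300] <- rnorm(150, 0, 40)
  tr$efficiency <- compute_fret(tr$donor, tr$acceptor)
  out <- detect_bleach_and_section(tr$donor, tr$acceptor, tr$efficiency)
  expect_equal(out$classification, "without_transitions")
  expect_false(is.na(out$bleach_frame))
  expect_lt(abs(out$bleach_frame - 150), 8)
})

test_that("an anti-correlated step that returns to high FRET is a transition", {
  e_true <- c(rep(0.8, 120), rep(0.2, 40), rep(0.8, 140))
  tr <- intensity_from_e(e_true, seed = 4)
  out <- detect_bleach_and_section(tr$donor, tr$acceptor, tr$efficiency)
  expect_equal(out$classification, "with_transitions")
  expect_true(is.na(out$bleach_frame))
  # section I ends at the first step, section III starts at the last return
  expect_lt(abs(out$sec1_end - 119), 4)
  expect_lt(abs(out$sec3_start - 160), 4)
})

test_that("donor-only molecules are excluded for lack of co-localized acceptor", {
  tr <- intensity_from_e(rep(0, 200), seed = 5) # all emission in donor channel
  out <- detect_bleach_and_section(tr$donor, tr$acceptor, tr$efficiency)
  expect_equal(out$classification, "excluded")
  expect_equal(out$reason, "no_acceptor")
})

test_that("short pre-bleach traces are excluded", {
  e_true <- rep(0.8, 200)
  tr <- intensity_from_e(e_true, seed = 6)
  tr$donor[11:200] <- rnorm(190, 0, 40) # donor bleach at frame 10
  tr$acceptor[11:200] <- rnorm(190, 0, 40)
  tr$efficiency <- compute_fret(tr$donor, tr$acceptor)
  out <- detect_bleach_and_section(tr$donor, tr$acceptor, tr$efficiency)
  expect_equal(out$classification, "excluded")
  expect_equal(out$reason, "too_short")
})

test_that("classification on a simulated field matches the ground-truth ledger", {
  cfg <- quiet_config(
    noise_sigma = 80, leakage = leakage_matrix(0.017, 0.165),
    label_efficiency = 0.9, donor_prob = 0.5,
    donor_bleach_rate = 0.005, acceptor_bleach_rate = 0.01,
    n_molecules_per_field = 60, trace_length = 200, seed = 21
  )
  fd <- simulate_field(cfg)
  frames <- fret_frames(fd$traces, cfg$leakage)
  cls <- classify_traces(frames)
  joined <- dplyr::inner_join(cls, fd$ledger, by = c("molecule_id", "field_id"))
  expected <- dplyr::case_when(
    joined$truth_class == "donor_only" ~ "excluded",
    pmin(joined$donor_bleach_time, joined$acceptor_bleach_time) < 2 ~ "excluded",
    joined$truth_class == "with_transitions" ~ "with_transitions",
    TRUE ~ "without_transitions"
  )
  expect_gte(mean(joined$classification == expected), 0.95)
})

test_that("fraction without transitions follows the per-field definition", {
  cls <- tibble::tibble(
    field_id = "F1",
    classification = c(rep("without_transitions", 50),
                       rep("with_transitions", 100), rep("excluded", 50))
  )
  out <- fraction_without_transitions(cls)
  expect_equal(out$per_field$fraction, 0.25) # 50 of 200 donor-visible spots

  cls3 <- tibble::tibble(
    field_id = rep(c("A", "B", "C"), each = 10),
    classification = c(rep("without_transitions", 2), rep("with_transitions", 8),
                       rep("without_transitions", 3), rep("with_transitions", 7),
                       rep("without_transitions", 4), rep("with_transitions", 6))
  )
  out3 <- fraction_without_transitions(cls3)
  expect_equal(out3$summary$mean, 0.3)
  expect_equal(out3$summary$sd, 0.1)

  all_trans <- tibble::tibble(field_id = "F1",
                              classification = rep("with_transitions", 30))
  expect_equal(fraction_without_transitions(all_trans)$summary$mean, 0)
})

test_that("point-wise histogram reflects state occupancy and integrates to 1", {
  cfg <- quiet_config(trace_length = 200, n_molecules_per_field = 20, seed = 31)
  fd <- simulate_field(cfg)
  frames <- fret_frames(fd$traces, cfg$leakage)
  cls <- classify_traces(frames)
  h <- pointwise_histogram(frames, cls, which = "all")
  bw <- diff(h$bin_center[1:2])
  expect_equal(sum(h$density) * bw, 1, tolerance = 1e-9)

  # noiseless two-level traces put essentially all mass at the two state
  # efficiencies; transition-spanning frames carry the small remainder
  near_state <- vapply(h$bin_center, function(x) {
    min(abs(x - cfg$state_fret)) < 0.06
  }, logical(1))
  expect_gte(sum(h$density[near_state]) * bw, 0.95)

  # mass above the boundary tracks the ledger's high-state occupancy
  led <- fd$ledger[fd$ledger$label_class == "fret", ]
  truth_occ <- mean(led$occupancy_high_prebleach)
  mass_high <- sum(h$density[h$bin_center > 0.5]) * bw
  expect_lt(abs(mass_high - truth_occ), 0.05)
})

test_that("empty selections give an empty histogram with a warning", {
  frames <- tibble::tibble(molecule_id = character(0), frame = integer(0),
                           efficiency = numeric(0))
  cls <- tibble::tibble(molecule_id = character(0),
                        classification = character(0),
                        sec2_start = integer(0), sec2_end = integer(0),
                        n_prebleach = integer(0))
  expect_warning(h <- pointwise_histogram(frames, cls), "empty")
  expect_equal(nrow(h), 0L)
})

test_that("Gaussian mixture fits recover generative parameters", {
  x <- seq(-0.2, 1.2, by = 0.01)
  y1 <- dnorm(x, 0.53, 0.08)
  fit1 <- fit_gaussian_mixture(tibble::tibble(bin_center = x, density = y1),
                               1, init_means = 0.4)
  expect_true(fit1$converged)
  expect_lt(abs(fit1$means - 0.53) / 0.53, 0.02)
  expect_lt(abs(fit1$sigmas - 0.08) / 0.08, 0.02)

  y3 <- 0.5 * dnorm(x, 0.2, 0.05) + 0.3 * dnorm(x, 0.5, 0.05) +
    0.2 * dnorm(x, 0.8, 0.05)
  fit3 <- fit_gaussian_mixture(tibble::tibble(bin_center = x, density = y3),
                               3, init_means = c(0.25, 0.45, 0.85))
  expect_true(fit3$converged)
  expect_equal(fit3$means, c(0.2, 0.5, 0.8), tolerance = 0.02)
  expect_equal(unname(fit3$weights), c(0.5, 0.3, 0.2), tolerance = 0.05)
  expect_equal(nrow(tidy(fit3)), 3L)
})

test_that("a degenerate histogram yields a flagged non-convergent fit", {
  h <- tibble::tibble(bin_center = seq(0, 1, 0.1), density = rep(0, 11))
  fit <- fit_gaussian_mixture(h, 2, init_means = c(0.2, 0.8))
  expect_false(fit$converged)
  expect_false(glance(fit)$converged)
})
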