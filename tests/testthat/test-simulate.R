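test_that("absorbing configurations yield a single segment covering the trace", {
  cfg <- quiet_config(rate_matrix = matrix(0, 2, 2), trace_length = 50)
  path <- simulate_state_path(cfg, seed = 7)
  expect_equal(nrow(path), 1L)
  expect_equal(path$entry_time, 0)
  expect_equal(path$exit_time, 50)
  expect_equal(path$state, 2L) # starts in the assembled (highest-FRET) state
})

test_that("holding times follow the configured exponential rates", {
  k <- 0.1
  cfg <- quiet_config(
    rate_matrix = matrix(c(-k, k, k, -k), 2, byrow = TRUE),
    trace_length = 2e4
  )
  path <- simulate_state_path(cfg, seed = 42)
  # interior holding times only (the last is truncated by the trace end)
  hold <- (path$exit_time - path$entry_time)[-nrow(path)]
  expect_gt(length(hold), 1000)
  expect_lt(abs(mean(hold) - 1 / k) / (1 / k), 0.05)

  # empirical per-state exit rates within 3 SE of the configured rates
  for (s in 1:2) {
    time_in <- sum((path$exit_time - path$entry_time)[path$state == s])
    n_exit <- sum(path$state[-nrow(path)] == s)
    k_hat <- n_exit / time_in
    se <- sqrt(n_exit) / time_in
    expect_lt(abs(k_hat - k), 3 * se)
  }
})

test_that("identical config and seed reproduce paths and traces exactly", {
  cfg <- quiet_config(noise_sigma = 50, trace_length = 30,
                      donor_bleach_rate = 0.01, acceptor_bleach_rate = 0.02)
  p1 <- simulate_state_path(cfg, seed = 11)
  p2 <- simulate_state_path(cfg, seed = 11)
  expect_identical(p1, p2)
  t1 <- render_intensities(p1, cfg, seed = 12)
  t2 <- render_intensities(p2, cfg, seed = 12)
  expect_identical(t1, t2)
  f1 <- simulate_field(cfg, field_index = 1L)
  f2 <- simulate_field(cfg, field_index = 1L)
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$ledger, f2$ledger)
})

test_that("noiseless, leakage-free rendering splits intensity by state FRET", {
  cfg <- quiet_config(rate_matrix = matrix(0, 2, 2), trace_length = 10)
  path <- simulate_state_path(cfg, seed = 1) # stays in state 2, E = 0.8
  tr <- render_intensities(path, cfg, donor_bleach_time = Inf,
                           acceptor_bleach_time = Inf, seed = 1)
  expect_equal(tr$acceptor, rep(800, 100))
  expect_equal(tr$donor, rep(200, 100))
  expect_equal(tr$ideal_efficiency, rep(0.8, 100))
})

test_that("leakage mixing matches the 2x2 arithmetic", {
  # true (donor, acceptor) = (200, 800) through l_da = 0.017, l_ad = 0.165:
  # donor_obs = 0.983*200 + 0.165*800 = 328.6
  # acceptor_obs = 0.017*200 + 0.835*800 = 671.4
  cfg <- quiet_config(rate_matrix = matrix(0, 2, 2), trace_length = 2,
                      leakage = leakage_matrix(0.017, 0.165))
  path <- simulate_state_path(cfg, seed = 1)
  tr <- render_intensities(path, cfg, donor_bleach_time = Inf,
                           acceptor_bleach_time = Inf, seed = 1)
  expect_equal(tr$donor, rep(328.6, 20))
  expect_equal(tr$acceptor, rep(671.4, 20))
})

test_that("instant acceptor bleach gives a donor-only trace from frame 0", {
  cfg <- quiet_config(rate_matrix = matrix(0, 2, 2), trace_length = 5)
  path <- simulate_state_path(cfg, seed = 1)
  tr <- render_intensities(path, cfg, donor_bleach_time = Inf,
                           acceptor_bleach_time = 0, seed = 1)
  expect_equal(tr$donor, rep(1000, 50))
  expect_equal(tr$acceptor, rep(0, 50))
  expect_true(all(is.na(tr$ideal_efficiency)))
})

test_that("stochastic labeling yields the expected molecule classes", {
  cfg <- quiet_config(n_molecules_per_field = 800, trace_length = 3)
  fd <- simulate_field(cfg)
  led <- fd$ledger
  expect_equal(nrow(led), 800L) # ledger conservation

  # with both sites always labeled and donor_prob = 1/2 the four dye
  # combinations are equally likely; donor-visible = {DD, DA, AD},
  # FRET-capable = {DA, AD}, so 2/3 of donor-visible molecules are
  # FRET-capable
  visible <- led$label_class %in% c("fret", "donor_only")
  frac <- sum(led$label_class == "fret") / sum(visible)
  p <- 2 / 3
  se <- sqrt(p * (1 - p) / sum(visible))
  expect_lt(abs(frac - p), 3 * se)

  # traces exist exactly for donor-visible molecules
  expect_setequal(unique(fd$traces$molecule_id), led$molecule_id[visible])
})

test_that("donor-only labeling produces no FRET-capable molecules", {
  cfg <- quiet_config(donor_prob = 1, n_molecules_per_field = 50,
                      trace_length = 3)
  fd <- simulate_field(cfg)
  expect_equal(sum(fd$ledger$label_class == "fret"), 0L)
})

test_that("frame-wise E from clean rendering round-trips the configured state FRET", {
  cfg <- quiet_config(trace_length = 100)
  set.seed(3)
  path <- simulate_state_path(cfg)
  tr <- render_intensities(path, cfg, donor_bleach_time = Inf,
                           acceptor_bleach_time = Inf)
  e <- compute_fret(tr$donor, tr$acceptor)
  # frames fully inside a dwell must hit the configured efficiencies exactly
  # (to machine rounding of the frame integration)
  dist <- pmin(abs(e - cfg$state_fret[1]), abs(e - cfg$state_fret[2]))
  expect_gt(sum(dist < 1e-9), 900)
  # and every frame (transition-spanning ones included) stays in range
  tol <- 1e-9
  expect_true(all(e >= min(cfg$state_fret) - tol &
                    e <= max(cfg$state_fret) + tol))
})

test_that("summed intensity before bleaching matches total_intensity", {
  cfg <- quiet_config(noise_sigma = 80, trace_length = 100)
  set.seed(5)
  path <- simulate_state_path(cfg)
  tr <- render_intensities(path, cfg, donor_bleach_time = Inf,
                           acceptor_bleach_time = Inf)
  total <- tr$donor + tr$acceptor
  se <- sqrt(2) * 80 / sqrt(length(total))
  expect_lt(abs(mean(total) - 1000), 3 * se)
})
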