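test_that("instantaneous phase matches the analytic signal of sinusoids", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)[-1]
  n <- length(t)
  edge <- ceiling(0.05 * n)
  core <- (edge + 1):(n - edge)

  phc <- instantaneous_phase(cos(2 * pi * 10 * t))
  # cos(w t) has phase w t (mod 2 pi); at multiples of the period it is 0
  zero_idx <- which(abs((t * 10) %% 1) < 1e-9)
  zero_idx <- intersect(zero_idx, core)
  expect_true(all(abs(phc[zero_idx]) < 0.05))

  phs <- instantaneous_phase(sin(2 * pi * 10 * t))
  dphi <- (phc[core] - phs[core] + pi) %% (2 * pi) - pi
  expect_true(all(abs(dphi - pi / 2) < 0.05))

  set.seed(1)
  x <- apply_analysis_band(recording(matrix(rnorm(4 * fs), 1), fs),
                           c(1, 40))$data[1, ]
  p <- instantaneous_phase(x)
  expect_true(all(p >= -pi & p < pi))

  expect_error(instantaneous_phase(rep(0, 100)), "all-zero")
})

test_that("Scott's rule bin count follows the stated formula", {
  grid <- seq(-pi, pi, length.out = 4000)
  expect_equal(scott_bin_count(grid), 16L)
  # eightfold sample size with the same sd halves h, doubling the count
  grid8 <- seq(-pi, pi, length.out = 32000)
  expect_equal(scott_bin_count(grid8), 32L)
  expect_error(scott_bin_count(rep(1, 10)), "distinct")
})

test_that("PTE matches an independent histogram transfer-entropy oracle", {
  set.seed(42)
  for (i in 1:5) {
    n <- 400
    phx <- runif(n, -pi, pi)
    phy <- runif(n, -pi, pi)
    B <- 5L
    d <- 2L
    got <- phase_transfer_entropy(phx, phy,
                                  pte_params(delay = d, n_bins = B))
    want_xy <- oracle_te(bin_phase_vec(phx, B), bin_phase_vec(phy, B), B, d)
    want_yx <- oracle_te(bin_phase_vec(phy, B), bin_phase_vec(phx, B), B, d)
    expect_equal(got$xy, max(want_xy, 0), tolerance = 1e-12)
    expect_equal(got$yx, max(want_yx, 0), tolerance = 1e-12)
  }
})

test_that("PTE of a series with itself is exactly zero", {
  set.seed(3)
  p <- runif(500, -pi, pi)
  expect_equal(phase_transfer_entropy(p, p, pte_params(delay = 1))$xy, 0)
})

test_that("PTE is directionally symmetric under independence", {
  set.seed(11)
  wins <- 0
  for (i in 1:50) {
    phx <- instantaneous_phase(band_noise(2000, i * 2))
    phy <- instantaneous_phase(band_noise(2000, i * 2 + 1))
    v <- phase_transfer_entropy(phx, phy, pte_params(delay = 2))
    wins <- wins + (v$xy > v$yx)
  }
  expect_gt(wins, 50 * 0.4 - 0.1)
  expect_lt(wins, 50 * 0.6 + 0.1)
})

test_that("PTE is invariant to phase offsets that are multiples of the bin width", {
  set.seed(5)
  phx <- runif(600, -pi, pi)
  phy <- runif(600, -pi, pi)
  B <- 8L
  pars <- pte_params(delay = 2, n_bins = B)
  base <- phase_transfer_entropy(phx, phy, pars)
  off <- 3 * 2 * pi / B
  wrap <- function(p) ((p + off + pi) %% (2 * pi)) - pi
  shifted <- phase_transfer_entropy(wrap(phx), wrap(phy), pars)
  expect_equal(base$xy, shifted$xy, tolerance = 1e-9)
  expect_equal(base$yx, shifted$yx, tolerance = 1e-9)
})

test_that("stronger planted couplings yield non-decreasing source->target PTE", {
  meds <- vapply(c(0.2, 0.5, 0.8), function(s) {
    vals <- vapply(1:20, function(seed) {
      m <- source_model(2, fs = 256,
                        couplings = data.frame(from = 1, to = 2, lag = 4,
                                               strength = s),
                        noise_sd = 0.3, seed = seed)
      rec <- generate_coupled_timeseries(m, 16)
      ph <- instantaneous_phase(rec$data)
      phase_transfer_entropy(ph[1, ], ph[2, ], pte_params(), fs = 256)$xy
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("connectivity matrices are per-segment, non-negative, zero-diagonal", {
  m <- source_model(3, fs = 128,
                    couplings = data.frame(from = 1, to = 2, lag = 2,
                                           strength = 0.7),
                    noise_sd = 0.4, seed = 13)
  rec <- apply_analysis_band(generate_coupled_timeseries(m, 60),
                             c(0.53, 35))
  segs <- epoch_and_select(rec, 4, 15, seed = 2)
  nets <- connectivity_matrix(segs, pte_params())
  expect_length(nets, 15)
  for (w in nets) {
    expect_true(all(w >= 0))
    expect_true(all(diag(w) == 0))
  }
  avg <- average_connectivity(nets)
  expect_gt(avg[1, 2], avg[2, 1])

  # subject_network agrees in direction with the segment-level path
  sn <- subject_network(rec, pte_params(), seed = 2)
  expect_gt(sn[1, 2], sn[2, 1])
})

test_that("average_connectivity is the entrywise mean", {
  a <- matrix(runif(9), 3, 3)
  diag(a) <- 0
  expect_equal(average_connectivity(list(a, a)), a, ignore_attr = TRUE)
  expect_equal(average_connectivity(list(a, 3 * a)), 2 * a,
               ignore_attr = TRUE)
  set.seed(2)
  nets <- lapply(1:15, function(i) matrix(runif(16), 4, 4))
  naive <- matrix(0, 4, 4)
  for (w in nets) naive <- naive + w / 15
  expect_equal(average_connectivity(nets), naive, ignore_attr = TRUE)
  expect_error(average_connectivity(list()), "empty")
  expect_error(average_connectivity(list(a, matrix(0, 2, 2))), "shape")
})

test_that("pte parameter validation and delay derivation behave", {
  expect_error(pte_params(delay = 0), "delay")
  expect_error(pte_params(n_bins = 1), "n_bins")
  p <- pte_params()
  expect_equal(ptenet:::resolve_delay(p, 256), 4L)
  expect_equal(ptenet:::resolve_delay(p, 128), 2L)
  expect_error(phase_transfer_entropy(runif(30), runif(30),
                                      pte_params(delay = 5)), "10")
})
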