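test_that("phase randomization preserves the amplitude spectrum and autocorrelation", {
  set.seed(17)
  for (n in c(1000, 1001)) {            # even and odd lengths
    rec <- recording(matrix(rnorm(2 * n), nrow = 2), fs = 100)
    sur <- phase_randomize(rec, seed = 9)
    for (k in 1:2) {
      a0 <- Mod(fft(rec$data[k, ]))
      a1 <- Mod(fft(sur$data[k, ]))
      expect_lt(max(abs(a1 - a0)) / max(a0), 1e-9)
      ac0 <- Re(fft(Mod(fft(rec$data[k, ]))^2, inverse = TRUE)) / n
      ac1 <- Re(fft(Mod(fft(sur$data[k, ]))^2, inverse = TRUE)) / n
      expect_lt(max(abs(ac1 - ac0)) / max(abs(ac0)), 1e-6)
    }
    expect_false(isTRUE(all.equal(rec$data, sur$data)))
  }

  z <- recording(matrix(0, 1, 500), fs = 100)
  expect_equal(phase_randomize(z, 1)$data, matrix(0, 1, 500))
})

test_that("the fused surrogate-phase path equals randomize-then-Hilbert", {
  m <- source_model(3, fs = 128, noise_sd = 0.4, seed = 31)
  rec <- apply_analysis_band(generate_coupled_timeseries(m, 10),
                             c(0.53, 35))
  p_fused <- ptenet:::surrogate_phases(rec$data, 77L)
  p_two <- instantaneous_phase(phase_randomize(rec, 77L)$data)
  expect_lt(max(abs(p_fused - t(p_two))), 1e-10)
})

test_that("surrogate ensembles are seeded, sized, and null-centred", {
  m <- source_model(3, fs = 128, noise_sd = 0.5, seed = 41)
  rec <- apply_analysis_band(generate_coupled_timeseries(m, 60),
                             c(0.53, 35))
  ens1 <- build_surrogate_ensemble(rec, 20, pte_params(),
                                   segment_seed = 3, seed = 5)
  ens2 <- build_surrogate_ensemble(rec, 20, pte_params(),
                                   segment_seed = 3, seed = 5)
  expect_length(ens1$networks, 20)
  expect_identical(ens1$networks, ens2$networks)

  # independent channels: the real network is itself null-distributed, so
  # its off-diagonal mean lies within 2 sd of the surrogate means
  real <- subject_network(rec, pte_params(), seed = 3)
  off <- row(real) != col(real)
  sur_means <- vapply(ens1$networks, function(w) mean(w[off]), numeric(1))
  expect_lt(abs(mean(real[off]) - mean(sur_means)), 2 * sd(sur_means) + 1e-9)
})

test_that("pruning follows the exceedance-count rule with tolerance", {
  real <- matrix(0, 2, 2)
  real[1, 2] <- 0.5
  real[2, 1] <- 0.4
  # critical count floor(alpha * n): 1,000 surrogates at 5% -> 50
  fake <- replicate(1000, matrix(0, 2, 2), simplify = FALSE)
  pr <- prune_network(real, fake, alpha = 0.05)
  expect_equal(pr$critical_count, 50)
  expect_equal(pr$network, real, ignore_attr = TRUE)  # real beats all

  # exactly 50 exceeding surrogates is not "more than 50": edge kept
  fake50 <- c(replicate(50, matrix(1, 2, 2), simplify = FALSE),
              replicate(950, matrix(0, 2, 2), simplify = FALSE))
  expect_equal(prune_network(real, fake50)$network, real,
               ignore_attr = TRUE)
  # 51 exceeding surrogates removes the edges
  fake51 <- c(replicate(51, matrix(1, 2, 2), simplify = FALSE),
              replicate(949, matrix(0, 2, 2), simplify = FALSE))
  expect_equal(prune_network(real, fake51)$n_retained, 0)

  # a surrogate exceeding by less than the tolerance does not count
  near <- replicate(1000, matrix(0.5 + 5e-4, 2, 2), simplify = FALSE)
  expect_equal(prune_network(real, near)$network[1, 2], 0.5)

  expect_error(prune_network(real, list(matrix(0, 3, 3))), "shape")
})

test_that("pruning keeps retained weights exact and is monotone in alpha", {
  set.seed(23)
  n <- 6
  real <- random_digraph(n, 23)
  ens <- lapply(1:100, function(i) {
    w <- matrix(runif(n * n), n, n)
    diag(w) <- 0
    w
  })
  pr1 <- prune_network(real, ens, alpha = 0.02)
  pr2 <- prune_network(real, ens, alpha = 0.2)
  kept1 <- pr1$network != 0
  expect_true(all(pr1$network[kept1] == real[kept1]))
  expect_true(all(kept1 <= (pr2$network != 0)))  # subset relation
})

test_that("a null-distributed real network retains roughly alpha of its edges", {
  set.seed(29)
  n <- 8
  retained <- vapply(1:30, function(i) {
    draw <- function() {
      w <- matrix(runif(n * n), n, n)
      diag(w) <- 0
      w
    }
    real <- draw()
    ens <- replicate(200, draw(), simplify = FALSE)
    pr <- prune_network(real, ens, alpha = 0.05, tolerance = 0)
    pr$n_retained / (n * (n - 1))
  }, numeric(1))
  p_hat <- mean(retained)
  se <- sqrt(0.05 * 0.95 / (30 * n * (n - 1)))
  expect_lt(abs(p_hat - 0.05), 2 * se + 0.01)
})
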