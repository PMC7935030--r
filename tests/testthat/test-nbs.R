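make_pair <- function(n_sub, n, f) {
  pre <- lapply(seq_len(n_sub), function(s) {
    w <- matrix(0.5, n, n)
    diag(w) <- 0
    w
  })
  post <- lapply(seq_len(n_sub), function(s) f(pre[[s]], s))
  list(pre = pre, post = post)
}

test_that("edgewise paired t matches the closed form and its symmetries", {
  # no change -> all zero
  pp <- make_pair(4, 3, function(w, s) w)
  expect_true(all(edgewise_paired_t(pp$pre, pp$post, quiet = TRUE) == 0))

  # constant shift d with known jitter at one edge: hand-computed t
  jit <- c(-0.02, 0.01, 0.02, -0.01)
  pp <- make_pair(4, 3, function(w, s) {
    w[1, 2] <- w[1, 2] + 0.3 + jit[s]
    w
  })
  tm <- edgewise_paired_t(pp$pre, pp$post, quiet = TRUE)
  d <- 0.3 + jit
  expect_equal(tm[1, 2], mean(d) / (sd(d) / 2), tolerance = 1e-12)

  # swapping pre and post negates every t
  tm_sw <- edgewise_paired_t(pp$post, pp$pre, quiet = TRUE)
  expect_equal(tm_sw, -tm)

  expect_error(edgewise_paired_t(pp$pre[1], pp$post[1]), "2 subjects")
})

test_that("suprathreshold components use undirected connectivity of directed edges", {
  tm <- matrix(0, 4, 4)
  expect_length(suprathreshold_components(tm, 3), 0)

  tm[1, 2] <- 4; tm[2, 3] <- 5            # A->B, B->C
  comps <- suprathreshold_components(tm, 3)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, 2)
  expect_equal(comps[[1]]$nodes, c(1, 2, 3))

  tm2 <- matrix(0, 5, 5)
  tm2[1, 2] <- 4; tm2[4, 5] <- 4          # two disjoint pairs
  comps2 <- suprathreshold_components(tm2, 3)
  expect_length(comps2, 2)
  expect_true(all(vapply(comps2, `[[`, integer(1), "n_edges") == 1))

  # negative tail picks up the mirrored effect
  expect_length(suprathreshold_components(-tm, 3, tail = "negative"), 1)
  expect_length(suprathreshold_components(-tm, 3, tail = "positive"), 0)

  # component roots agree with igraph's components on random graphs
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    tm3 <- matrix(rnorm(n * n, sd = 2), n, n)
    diag(tm3) <- 0
    comps3 <- suprathreshold_components(tm3, 3, tail = "two_sided")
    pass <- abs(tm3) > 3
    g <- igraph::graph_from_adjacency_matrix((pass | t(pass)) * 1,
                                             mode = "undirected")
    memb <- igraph::components(g)$membership
    for (cp in comps3) {
      expect_length(unique(memb[cp$nodes]), 1)
      expect_equal(cp$n_edges, sum(pass[memb == memb[cp$nodes[1]],
                                        memb == memb[cp$nodes[1]]]))
    }
  }
})

test_that("raising the threshold never enlarges components", {
  set.seed(33)
  tm <- matrix(rnorm(64, sd = 2.5), 8, 8)
  diag(tm) <- 0
  sizes <- vapply(c(1, 2, 3), function(thr) {
    comps <- suprathreshold_components(tm, thr, tail = "two_sided")
    if (length(comps)) comps[[1]]$n_edges else 0L
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the permutation test controls and detects as expected", {
  set.seed(44)
  n_sub <- 10
  n <- 12
  # planted effect on a 3-edge chain
  pre <- lapply(1:n_sub, function(s) {
    w <- matrix(runif(n * n, 0.4, 0.6), n, n)
    diag(w) <- 0
    w
  })
  post <- lapply(1:n_sub, function(s) {
    w <- pre[[s]] + matrix(rnorm(n * n, 0, 0.02), n, n)
    for (e in list(c(1, 2), c(2, 3), c(3, 4)))
      w[e[1], e[2]] <- w[e[1], e[2]] + 0.15
    diag(w) <- 0
    w
  })
  res <- nbs_permutation_test(pre, post, t_threshold = 3,
                              n_permutations = 200, seed = 7)
  expect_s3_class(res, "nbs_result")
  expect_gte(length(res$components), 1)
  expect_lt(res$p[1], 0.05)
  expect_true(all(res$p >= 1 / 201))
  big <- res$components[[1]]
  expect_true(all(c(1, 2, 3, 4) %in% big$nodes))

  # determinism
  res2 <- nbs_permutation_test(pre, post, t_threshold = 3,
                               n_permutations = 200, seed = 7)
  expect_identical(res$p, res2$p)
  expect_identical(res$null_max_size, res2$null_max_size)

  # full pre/post swap: |t| identical, two-sided null unchanged
  res_sw <- nbs_permutation_test(post, pre, t_threshold = 3,
                                 n_permutations = 200, seed = 7,
                                 tail = "two_sided")
  res_2s <- nbs_permutation_test(pre, post, t_threshold = 3,
                                 n_permutations = 200, seed = 7,
                                 tail = "two_sided")
  expect_equal(abs(res_sw$t), abs(res_2s$t))
  expect_identical(res_sw$null_max_size, res_2s$null_max_size)

  expect_error(nbs_permutation_test(pre, post, n_permutations = 10),
               "n_permutations")
})

test_that("summary tabulates components", {
  set.seed(1)
  pre <- lapply(1:6, function(s) random_digraph(5, s, p = 1))
  post <- lapply(1:6, function(s) pre[[s]] + 0.2)
  res <- nbs_permutation_test(pre, post, t_threshold = 3,
                              n_permutations = 100, seed = 2)
  tab <- summary(res)
  expect_true(all(c("id", "n_edges", "n_nodes", "p") %in% names(tab)))
  expect_equal(nrow(tab), length(res$components))
})
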