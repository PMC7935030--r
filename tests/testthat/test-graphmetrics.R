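test_that("graph density is mean weight times max weight", {
  w <- matrix(0.7, 4, 4)
  diag(w) <- 0
  expect_equal(as.numeric(graph_density(w)), 0.7^2)

  empty <- matrix(0, 3, 3)
  expect_equal(as.numeric(graph_density(empty)), 0)

  toy <- matrix(0, 3, 3)
  toy[1, 2] <- 0.2
  toy[2, 3] <- 0.4
  expect_equal(as.numeric(graph_density(toy)), 0.1 * 0.4)
  expect_equal(attr(graph_density(toy), "connection_density"), 2 / 6)
})

test_that("length graph inverts weights", {
  w <- matrix(c(0, 2, 0.5, 0), 2, 2)
  len <- to_length_graph(w)
  expect_equal(len[2, 1], 0.5)
  expect_equal(len[1, 2], 2)
  bin <- complete_graph(3)
  expect_true(all(to_length_graph(bin)[row(bin) != col(bin)] == 1))
  expect_error(to_length_graph(-bin), "non-negative")
})

test_that("global efficiency and path length match hand values", {
  expect_equal(global_efficiency(complete_graph(5)), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(global_efficiency(toy_path_graph()), 5 / 6)

  expect_equal(as.numeric(characteristic_path_length(complete_graph(4))), 1)
  # binary 4-cycle (undirected): distances 1, 1, 2 from each node
  cyc <- matrix(0, 4, 4)
  for (i in 1:4) {
    j <- i %% 4 + 1
    cyc[i, j] <- cyc[j, i] <- 1
  }
  expect_equal(as.numeric(characteristic_path_length(cyc)), 4 / 3)
  # two isolated dyads: only adjacent pairs reachable
  dy <- matrix(0, 4, 4)
  dy[1, 2] <- dy[2, 1] <- dy[3, 4] <- dy[4, 3] <- 1
  cpl <- characteristic_path_length(dy)
  expect_equal(as.numeric(cpl), 1)
  expect_equal(attr(cpl, "n_unreachable"), 8)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no finite")
})

test_that("transitivity and clustering match their definitions", {
  tri <- complete_graph(3)
  expect_equal(graph_transitivity(tri), 1)
  expect_equal(local_clustering(tri), rep(1, 3), ignore_attr = TRUE)

  path <- toy_path_graph()
  expect_equal(graph_transitivity(path), 0)
  expect_equal(local_clustering(path)[2], 0, ignore_attr = TRUE)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(graph_transitivity(star), 0)

  # weighted triangle (1, 1, 0.125): geometric mean pattern
  wt <- matrix(0, 3, 3)
  wt[1, 2] <- wt[2, 1] <- 1
  wt[1, 3] <- wt[3, 1] <- 1
  wt[2, 3] <- wt[3, 2] <- 0.125
  expect_equal(unname(local_clustering(wt)[1]), (1 * 1 * 0.125)^(1 / 3))
})

test_that("betweenness matches path enumeration on known graphs", {
  bc <- betweenness_centrality(toy_path_graph())
  expect_equal(unname(bc[2]), 2)
  expect_equal(unname(attr(bc, "normalized")[2]), 1)

  expect_true(all(betweenness_centrality(complete_graph(4)) == 0))

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(attr(betweenness_centrality(star), "normalized")[1]),
               1)
})

test_that("degree centrality counts nonzero incident edges", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.5
  w[1, 3] <- 0.2
  dc <- degree_centrality(w)
  expect_equal(dc$out_degree, c(2, 0, 0), ignore_attr = TRUE)
  expect_equal(dc$in_degree, c(0, 1, 1), ignore_attr = TRUE)
  expect_equal(dc$total, c(2, 1, 1), ignore_attr = TRUE)
  expect_equal(degree_centrality(complete_graph(4))$out_degree,
               rep(3, 4), ignore_attr = TRUE)
})

test_that("metrics agree with brute-force oracles on random digraphs", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    w <- random_digraph(n, i + 1000, p = 0.6)
    if (all(w == 0)) next
    expect_equal(global_efficiency(w), oracle_global_efficiency(w),
                 tolerance = 1e-9)
    d <- fw_distances(w)
    if (any(is.finite(d[row(d) != col(d)])))
      expect_equal(as.numeric(characteristic_path_length(w)), oracle_cpl(w),
                   tolerance = 1e-9)
    expect_equal(graph_transitivity(w), oracle_transitivity(w),
                 tolerance = 1e-9)
    expect_equal(unname(local_clustering(w)), oracle_clustering(w),
                 tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(w)), oracle_betweenness(w),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("adding binary edges never decreases GE nor increases CPL", {
  set.seed(7)
  for (i in 1:10) {
    n <- 6
    w <- (random_digraph(n, i + 77, p = 0.4) > 0) * 1
    zero <- which(w == 0 & row(w) != col(w))
    if (!length(zero)) next
    w2 <- w
    w2[sample(zero, 1)] <- 1
    expect_gte(global_efficiency(w2), global_efficiency(w) - 1e-12)
    fin1 <- is.finite(fw_distances(w)[row(w) != col(w)])
    if (any(fin1)) {
      # CPL comparison only meaningful on the common reachable set; adding
      # an edge to a connected binary graph cannot lengthen paths
      g_conn <- all(fin1)
      if (g_conn)
        expect_lte(as.numeric(characteristic_path_length(w2)),
                   as.numeric(characteristic_path_length(w)) + 1e-12)
    }
  }
})

test_that("degree-preserving randomization preserves degrees and moves edges", {
  er <- generate_reference_graph("erdos_renyi", list(n = 100, p = 0.1),
                                 seed = 12)
  r <- degree_preserving_randomize(er, swaps_per_edge = 100, seed = 5)
  expect_equal(rowSums(r > 0), rowSums(er > 0), ignore_attr = TRUE)
  expect_equal(colSums(r > 0), colSums(er > 0), ignore_attr = TRUE)
  expect_equal(sort(r[r > 0]), sort(er[er > 0]))  # weights carried
  overlap <- sum(r > 0 & er > 0) / sum(er > 0)
  expect_lt(overlap, 0.7)
  expect_gt(attr(r, "swaps_done"), 0)
  expect_error(degree_preserving_randomize(matrix(0, 3, 3)), "2 edges")
})

test_that("sigma is scale-invariant and ER graphs are not small-world", {
  er <- generate_reference_graph("erdos_renyi", list(n = 60, p = 0.2),
                                 seed = 3)
  s1 <- small_worldness_sigma(er, n_random = 10, swaps_per_edge = 20,
                              seed = 11)
  s2 <- small_worldness_sigma(er * 7.3, n_random = 10, swaps_per_edge = 20,
                              seed = 11)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-9)

  sig <- vapply(1:5, function(seed) {
    g <- generate_reference_graph("erdos_renyi", list(n = 100, p = 0.3),
                                  seed = seed)
    as.numeric(small_worldness_sigma(g, n_random = 10, swaps_per_edge = 20,
                                     seed = seed))
  }, numeric(1))
  expect_true(all(sig > 0.8 & sig < 1.2))
})

test_that("a ring lattice has high clustering and long paths versus nulls", {
  lat <- generate_reference_graph("lattice", list(n = 100, k = 6))
  s <- small_worldness_sigma(lat, n_random = 10, swaps_per_edge = 20,
                             seed = 2)
  expect_gt(attr(s, "c_ratio"), 2)
  expect_gt(attr(s, "l_ratio"), 1.5)
})
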