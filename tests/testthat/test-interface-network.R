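make_scores <- function(adj) {
  # score matrix whose threshold-0.5 digraph has adjacency `adj`
  # (edge template t -> query q drawn from score[q, t])
  n <- nrow(adj)
  m <- matrix(0.1, n, n)
  m[t(adj) > 0] <- 0.9
  diag(m) <- NA_real_
  dimnames(m) <- list(paste0("n", 1:n), paste0("n", 1:n))
  m
}

test_that("threshold digraph edges follow score direction and threshold", {
  s <- matrix(c(NA, 0.30, 0.10,
                0.20, NA, 0.26,
                0.40, 0.25, NA), 3, byrow = TRUE,
              dimnames = list(paste0("i", 1:3), paste0("i", 1:3)))
  g <- build_digraph(s, 0.26)
  el <- igraph::as_edgelist(g)
  # inclusive edges: score[q,t] >= 0.26 gives t -> q
  want <- rbind(c("i2", "i1"), c("i3", "i2"), c("i1", "i3"))
  expect_equal(el[order(el[, 1]), ], want[order(want[, 1]), ])
  # strict variant drops the boundary edge score = 0.26
  g2 <- build_digraph(s, 0.26, ddi_params(edge_inclusive = FALSE))
  expect_equal(igraph::ecount(g2), 2)

  # extreme thresholds
  expect_equal(igraph::ecount(build_digraph(s, 0.95)), 0)
  expect_equal(igraph::ecount(build_digraph(s, 0.05)), 6)

  # missing scores never create edges
  s[1, 2] <- NA
  expect_equal(igraph::ecount(build_digraph(s, 0.05)), 5)
})

test_that("k-th neighbour fractions match closed forms on cycles", {
  n <- 7
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) adj[i, i %% n + 1] <- 1
  g <- build_digraph(make_scores(adj), 0.5)
  expect_equal(kth_neighbor_fraction(g, 1), 1 / (n - 1))
  expect_equal(kth_neighbor_fraction(g, n - 1), 1)
  # complete digraph at k = 1
  full <- matrix(1, 4, 4); diag(full) <- 0
  gf <- build_digraph(make_scores(full), 0.5)
  expect_equal(kth_neighbor_fraction(gf, 1), 1)
})

test_that("k-closure adds exactly the within-k reachable pairs", {
  # path a -> b -> c: closure at k = 2 adds a -> c
  adj <- matrix(0, 3, 3); adj[1, 2] <- 1; adj[2, 3] <- 1
  g <- build_digraph(make_scores(adj), 0.5)
  g1 <- k_closure(g, 1)
  expect_equal(igraph::ecount(g1), 2)
  g2 <- k_closure(g, 2)
  el <- igraph::as_edgelist(g2)
  expect_equal(nrow(el), 3)
  expect_true(any(el[, 1] == "n1" & el[, 2] == "n3"))
})

test_that("graph metrics equal matrix-power and mutual-reachability oracles", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    adj <- matrix(rbinom(n * n, 1, 0.15), n); diag(adj) <- 0
    g <- build_digraph(make_scores(adj), 0.5)
    for (k in c(1, 2, 3, n - 1)) {
      want <- sum(reach_oracle(adj, k)) / (n * (n - 1))
      expect_equal(kth_neighbor_fraction(g, k), want)
      # closure edges equal the oracle's reachable pairs
      expect_equal(igraph::ecount(k_closure(g, k)),
                   sum(reach_oracle(adj, k)))
    }
    # LSCC of the 1-closure equals brute-force mutual reachability
    expect_equal(largest_scc_fraction(g, n),
                 max(scc_oracle(adj)) / n)
  }
})

test_that("LSCC fractions on designed graphs", {
  # directed cycle: everything strongly connected at any k
  n <- 6
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) adj[i, i %% n + 1] <- 1
  g <- build_digraph(make_scores(adj), 0.5)
  expect_equal(largest_scc_fraction(g, 1), 1)

  # two disconnected cycles of sizes 6 and 4 -> 0.6
  adj2 <- matrix(0, 10, 10)
  for (i in 1:6) adj2[i, i %% 6 + 1] <- 1
  for (i in 7:10) adj2[i, (i - 6) %% 4 + 7] <- 1
  g2 <- build_digraph(make_scores(adj2), 0.5)
  expect_equal(largest_scc_fraction(g2, 1), 0.6)
})

test_that("sweep is monotone in threshold and k and matches an exhaustive oracle", {
  set.seed(93)
  n <- 8
  s <- matrix(runif(n * n, 0.1, 0.9), n)
  diag(s) <- NA
  dimnames(s) <- list(paste0("x", 1:n), paste0("x", 1:n))
  sw <- sweep_connectivity(s, thresholds = c(0.2, 0.4, 0.6, 0.95),
                           ks = c(1, 2, 4))
  for (k in unique(sw$k)) {
    sub <- sw[sw$k == k, ]
    expect_true(all(diff(sub$pair_fraction[order(sub$threshold)]) <= 1e-12))
  }
  for (th in unique(sw$threshold)) {
    sub <- sw[sw$threshold == th, ]
    expect_true(all(diff(sub$pair_fraction[order(sub$k)]) >= -1e-12))
    expect_true(all(diff(sub$lscc_fraction[order(sub$k)]) >= -1e-12))
  }
  # emptying threshold yields zero fractions
  top <- sw[sw$threshold == 0.95 & sw$k == 4, ]
  expect_equal(top$pair_fraction, 0)

  # exhaustive check against the matrix-power oracle on the full grid
  for (r in seq_len(nrow(sw))) {
    adj <- (t(s) >= sw$threshold[r]) * 1
    adj[is.na(adj)] <- 0
    want <- sum(reach_oracle(adj, sw$k[r])) / (n * (n - 1))
    expect_equal(sw$pair_fraction[r], want)
  }
})
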