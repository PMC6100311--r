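# independent oracles ------------------------------------------------------

# subgraph centrality by truncated power series sum_k (A^k)_vv / k!
sc_series_oracle <- function(net, kmax = 30) {
  a <- as.matrix(igraph::as_adjacency_matrix(net$graph))
  n <- nrow(a)
  p <- diag(n)
  s <- diag(n)
  for (k in seq_len(kmax)) {
    p <- p %*% a / k
    s <- s + p
  }
  setNames(diag(s), net$nodes)
}

# information centrality by the literal pairwise construction
ic_literal_oracle <- function(net) {
  out <- setNames(numeric(length(net$nodes)), net$nodes)
  comp <- igraph::components(net$graph)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    nc <- length(members)
    if (nc < 2) next
    a <- as.matrix(igraph::as_adjacency_matrix(
      igraph::induced_subgraph(net$graph, members)))
    b <- solve(diag(rowSums(a)) - a + 1)
    for (ui in seq_len(nc)) {
      s <- 0
      for (vi in seq_len(nc)) {
        s <- s + if (ui == vi) b[ui, ui] else b[ui, ui] + b[vi, vi] - 2 * b[ui, vi]
      }
      out[net$nodes[members[ui]]] <- nc / s
    }
  }
  out
}

test_that("degree centrality matches neighbour counts", {
  expect_equal(unname(degree_centrality(complete_net(3))), rep(2, 3))
  expect_equal(degree_centrality(path_net()), c(A = 1, B = 2, C = 1))
  net <- net_from_edges(data.frame(from = "A", to = "B"), isolated = "Z")
  expect_equal(degree_centrality(net)[["Z"]], 0)
})

test_that("eigenvector centrality is the principal eigenvector per component", {
  expect_equal(unname(eigenvector_centrality(complete_net(3))),
               rep(1 / sqrt(3), 3), tolerance = 1e-10)
  ec <- eigenvector_centrality(star_net(4))
  expect_gt(ec[["hub"]], max(ec[paste0("leaf", 1:4)]))
  two_k2 <- net_from_edges(data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_equal(unname(eigenvector_centrality(two_k2)), rep(1 / sqrt(2), 4),
               tolerance = 1e-10)
  # eigen-equation residual on random graphs, per component
  for (s in 1:5) {
    net <- random_net(25, 0.15, seed = s)
    x <- eigenvector_centrality(net)
    comp <- igraph::components(net$graph)
    a <- as.matrix(igraph::as_adjacency_matrix(net$graph))
    for (ci in seq_len(comp$no)) {
      idx <- which(comp$membership == ci)
      if (length(idx) < 2) next
      xc <- x[net$nodes[idx]]
      ax <- a[idx, idx, drop = FALSE] %*% xc
      lam <- sum(xc * ax)
      expect_lt(max(abs(ax - lam * xc)), 1e-6)
    }
  }
})

test_that("subgraph centrality equals the closed-walk series", {
  iso <- net_from_edges(data.frame(from = "A", to = "B"), isolated = "Z")
  expect_equal(subgraph_centrality(iso)[["Z"]], 1.0)
  k2 <- complete_net(2)
  expect_equal(unname(subgraph_centrality(k2)), rep(cosh(1), 2), tolerance = 1e-10)
  k3 <- complete_net(3)
  expect_equal(unname(subgraph_centrality(k3)),
               rep(exp(2) / 3 + 2 * exp(-1) / 3, 3), tolerance = 1e-10)
  for (s in 1:5) {
    net <- random_net(20, 0.2, seed = 10 + s)
    expect_equal(subgraph_centrality(net), sc_series_oracle(net), tolerance = 1e-8)
  }
})

test_that("information centrality matches the current-flow construction", {
  expect_equal(diff(unname(information_centrality(complete_net(2)))), 0)
  expect_equal(diff(range(information_centrality(complete_net(3)))), 0)
  ic <- information_centrality(path_net())
  expect_gt(ic[["B"]], ic[["A"]])
  expect_equal(ic[["A"]], ic[["C"]])
  for (s in 1:5) {
    net <- random_net(20, 0.15, seed = 20 + s)
    expect_equal(information_centrality(net), ic_literal_oracle(net),
                 tolerance = 1e-8)
  }
})

test_that("local average connectivity counts induced neighbour degrees", {
  expect_equal(local_average_connectivity(star_net(4))[["hub"]], 0)
  expect_equal(unname(local_average_connectivity(complete_net(3))), rep(1, 3))
  expect_equal(unname(local_average_connectivity(complete_net(4))), rep(2, 4))
})

test_that("neighborhood centrality sums edge clustering coefficients", {
  expect_equal(unname(neighborhood_centrality(complete_net(3))), rep(2, 3))
  expect_equal(unname(neighborhood_centrality(star_net(4))), rep(0, 5))
  expect_equal(unname(neighborhood_centrality(complete_net(4))), rep(3, 4))
})

test_that("centralities are equivariant under node relabelling", {
  fns <- list(degree_centrality, eigenvector_centrality, subgraph_centrality,
              information_centrality, local_average_connectivity,
              neighborhood_centrality)
  for (s in 1:3) {
    net <- random_net(15, 0.25, seed = 30 + s)
    set.seed(s)
    perm <- sample(net$nodes)
    el <- igraph::as_edgelist(net$graph)
    relabel <- setNames(perm, net$nodes)
    net_p <- net_from_edges(data.frame(from = relabel[el[, 1]],
                                       to = relabel[el[, 2]]),
                            isolated = perm)
    for (fn in fns) {
      v <- fn(net)
      vp <- fn(net_p)
      expect_equal(unname(vp[relabel[net$nodes]]), unname(v), tolerance = 1e-9)
    }
  }
})

test_that("centrality columns are finite and non-negative", {
  net <- random_net(30, 0.1, seed = 99)
  for (fn in list(degree_centrality, eigenvector_centrality, subgraph_centrality,
                  information_centrality, local_average_connectivity,
                  neighborhood_centrality)) {
    v <- fn(net)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0))
  }
  expect_true(all(subgraph_centrality(net) >= 1))
})
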