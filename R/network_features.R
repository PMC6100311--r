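#' Topological centralities for protein interaction networks
#'
#' Six node-level centralities used as topological essentiality features:
#' degree (DC), eigenvector (EC), subgraph (SC), information (IC), local
#' average connectivity (LAC) and neighbourhood centrality (NC). All return
#' a named numeric vector following the network's node order.
#'
#' @details
#' * `degree_centrality()` counts neighbours.
#' * `eigenvector_centrality()` returns the entrywise non-negative principal
#'   eigenvector of the adjacency matrix, computed per connected component
#'   and L2-normalised within each component; isolated nodes score 0. The
#'   power iteration runs on the shifted matrix `A + I` so it also converges
#'   on bipartite components (trees, stars, paths).
#' * `subgraph_centrality()` is the diagonal of the adjacency matrix
#'   exponential, `SC(v) = sum_k (A^k)_vv / k!`, i.e. a count of closed
#'   walks weighted down factorially; every value is at least 1.
#' * `information_centrality()` follows the current-flow construction of
#'   Stephenson and Zelen: per component, invert `L + J` (Laplacian plus
#'   all-ones), set `1/I_uv = B_uu + B_vv - 2 B_uv` for `u != v` and
#'   `1/I_uu = B_uu`, and return the harmonic-type mean
#'   `IC(u) = n / sum_v (1/I_uv)`. Isolated and singleton-component nodes
#'   score 0.
#' * `local_average_connectivity()` averages, over the neighbours of `v`,
#'   their degree inside the subgraph induced by those neighbours.
#' * `neighborhood_centrality()` sums the edge clustering coefficient
#'   `ECC(u,v) = triangles(u,v) / (min(deg(u), deg(v)) - 1)` over edges
#'   incident to `v`, with `ECC = 0` when the denominator is 0.
#'
#' @param net A [ppi_network()].
#' @return Named numeric vector over `net$nodes`.
#' @name centralities
NULL

#' @rdname centralities
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  d <- igraph::degree(net$graph)
  setNames(as.numeric(d), net$nodes)[net$nodes]
}

#' @rdname centralities
#' @export
eigenvector_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (n_proteins(net) == 0) return(setNames(numeric(0), character(0)))
  comp <- igraph::components(net$graph)
  out <- setNames(numeric(n_proteins(net)), net$nodes)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2) next  # isolated node: 0
    a <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(net$graph, members), sparse = TRUE)
    x <- rep(1 / sqrt(length(members)), length(members))
    # power iteration on A + I: same eigenvector, strictly dominant eigenvalue
    for (it in seq_len(20000L)) {
      y <- as.numeric(a %*% x) + x
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < 1e-13) { x <- y; break }
      x <- y
    }
    out[net$nodes[members]] <- abs(x)
  }
  out[net$nodes]
}

#' @rdname centralities
#' @export
subgraph_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_proteins(net)
  if (n == 0) return(setNames(numeric(0), character(0)))
  a <- as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = TRUE))
  es <- eigen(a, symmetric = TRUE)
  sc <- as.numeric((es$vectors^2) %*% exp(es$values))
  setNames(sc, net$nodes)
}

#' @rdname centralities
#' @export
information_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_proteins(net)
  out <- setNames(numeric(n), net$nodes)
  if (n == 0) return(out)
  comp <- igraph::components(net$graph)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    nc <- length(members)
    if (nc < 2) next  # singleton components score 0
    a <- as.matrix(igraph::as_adjacency_matrix(
      igraph::induced_subgraph(net$graph, members), sparse = TRUE))
    lap <- diag(rowSums(a)) - a
    b <- solve(lap + 1)
    tr <- sum(diag(b))
    rs <- rowSums(b)
    # sum_v 1/I_uv with the self term B_uu: (nc + 1) B_uu + tr - 2 R_u
    denom <- (nc + 1) * diag(b) + tr - 2 * rs
    out[net$nodes[members]] <- nc / denom
  }
  out[net$nodes]
}

# 1-indexed neighbour lists in node order
adjacency_list <- function(net) {
  lapply(igraph::as_adj_list(net$graph, mode = "all"), as.integer)
}

#' @rdname centralities
#' @export
local_average_connectivity <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_proteins(net)
  adj <- adjacency_list(net)
  out <- numeric(n)
  member <- logical(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (!length(nb)) next
    member[nb] <- TRUE
    s <- 0L
    for (u in nb) s <- s + sum(member[adj[[u]]])
    member[nb] <- FALSE
    out[v] <- s / length(nb)
  }
  setNames(out, net$nodes)
}

#' @rdname centralities
#' @export
neighborhood_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_proteins(net)
  adj <- adjacency_list(net)
  deg <- lengths(adj)
  out <- numeric(n)
  member <- logical(n)
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      u <- el[e, 1]; v <- el[e, 2]
      denom <- min(deg[u], deg[v]) - 1
      if (denom <= 0) next
      member[adj[[u]]] <- TRUE
      tri <- sum(member[adj[[v]]])
      member[adj[[u]]] <- FALSE
      ecc <- tri / denom
      out[u] <- out[u] + ecc
      out[v] <- out[v] + ecc
    }
  }
  setNames(out, net$nodes)
}
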