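# in-code fixture builders shared across test files

# network from a two-column matrix/data.frame of endpoint names
net_from_edges <- function(edges, isolated = character(0)) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  nodes <- unique(c(edges[[1]], edges[[2]], isolated))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  ppi_network(g)
}

complete_net <- function(k) {
  pairs <- t(utils::combn(paste0("v", seq_len(k)), 2))
  net_from_edges(pairs)
}

star_net <- function(leaves = 4) {
  net_from_edges(data.frame(from = "hub", to = paste0("leaf", seq_len(leaves))))
}

path_net <- function() net_from_edges(data.frame(from = c("A", "B"), to = c("B", "C")))

# Erdos-Renyi graph over n named nodes (always includes all n nodes)
random_net <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  pairs <- t(utils::combn(seq_len(n), 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = paste0("n", pairs[keep, 1]),
                      to = paste0("n", pairs[keep, 2]))
  net_from_edges(edges, isolated = paste0("n", seq_len(n)))
}

# random feature table: n proteins x fn iid normal columns
random_table <- function(n, fn, seed = 1) {
  set.seed(seed)
  cols <- setNames(lapply(seq_len(fn), function(i) rnorm(n)), paste0("f", seq_len(fn)))
  feature_table(sprintf("P%03d", seq_len(n)), cols)
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# gold standard object with prescribed dimension and gold size, built
# directly (cv values are arbitrary but ascending, as the contract requires)
synthetic_gold <- function(fn, gold_size, seed = 1) {
  set.seed(seed)
  structure(list(feature_names = paste0("f", seq_len(fn)),
                 cv = sort(runif(fn)),
                 gold_mask = seq_len(fn) <= gold_size,
                 gold_size = as.integer(gold_size),
                 original_order = seq_len(fn)),
            class = "gold_standard")
}
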