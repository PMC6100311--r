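#' Protein-protein interaction network container
#'
#' A thin wrapper around an undirected simple [igraph][igraph::igraph-package]
#' graph that fixes a stable node order (order of first appearance in the
#' input) and records how many redundant records were dropped during
#' loading. All feature vectors produced by the package follow this node
#' order.
#'
#' @param graph An undirected igraph object; multi-edges and self-loops are
#'   removed (and counted) if present.
#' @param removed_duplicates,removed_self_loops Counts carried over from
#'   parsing, if the graph was built from a file.
#' @return An object of class `ppi_network` with elements `graph`, `nodes`,
#'   `removed_duplicates`, `removed_self_loops`.
#' @export
ppi_network <- function(graph, removed_duplicates = 0L, removed_self_loops = 0L) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  simplified <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::vertex_attr(simplified, "name")) && igraph::vcount(simplified) > 0)
    igraph::V(simplified)$name <- as.character(seq_len(igraph::vcount(simplified)))
  structure(
    list(graph = simplified,
         nodes = igraph::V(simplified)$name,
         removed_duplicates = as.integer(removed_duplicates),
         removed_self_loops = as.integer(removed_self_loops)),
    class = "ppi_network")
}

#' @method print ppi_network
#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions\n",
              length(x$nodes), igraph::ecount(x$graph)))
  if (x$removed_duplicates || x$removed_self_loops)
    cat(sprintf("  (loading removed %d duplicate pairs, %d self-loops)\n",
                x$removed_duplicates, x$removed_self_loops))
  invisible(x)
}

n_proteins <- function(net) length(net$nodes)

# split non-comment lines into whitespace-separated tokens, keeping original
# line numbers for error reporting
parse_token_lines <- function(path, min_tokens) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  tokens <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(tokens, length, 0L) < min_tokens)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected at least %d fields",
                 idx[bad[1]], path, min_tokens), call. = FALSE)
  tokens
}

#' Read a protein interaction edge list
#'
#' Reads a two-column whitespace/tab-separated edge list (`#` starts a
#' comment line; columns beyond the second are ignored), removes
#' self-interactions and duplicate undirected pairs, and returns a simple
#' undirected [ppi_network()]. Proteins appearing only in removed
#' self-interactions are kept as isolated nodes, so the node set is every
#' identifier seen in the file.
#'
#' @param path Path to the edge-list file.
#' @return A [ppi_network()]; `removed_duplicates` and `removed_self_loops`
#'   record how many records were dropped.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B A", "C C"), f)
#' net <- read_edge_list(f)
#' net$removed_duplicates   # 1
#' net$removed_self_loops   # 1
read_edge_list <- function(path) {
  tokens <- parse_token_lines(path, min_tokens = 2L)
  if (!length(tokens)) {
    return(ppi_network(igraph::make_empty_graph(0, directed = FALSE)))
  }
  a <- vapply(tokens, `[[`, "", 1L)
  b <- vapply(tokens, `[[`, "", 2L)
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty protein identifier in ", path)
  nodes <- unique(c(rbind(a, b)))
  self <- a == b
  key <- ifelse(a < b, paste(a, b), paste(b, a))
  dup <- duplicated(key) & !self
  keep <- !self & !dup
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  ppi_network(g,
              removed_duplicates = sum(dup),
              removed_self_loops = sum(self))
}

#' Write a network back to the edge-list dialect
#'
#' @param net A [ppi_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  writeLines(if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t") else character(0), path)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Two-column whitespace/tab-separated file mapping proteins to opaque term
#' identifiers (GO terms, subcellular compartments, ...). Duplicate
#' (protein, term) pairs are collapsed. Proteins absent from the file simply
#' have no terms.
#'
#' @param path Path to the annotation file.
#' @param namespace One of `"GO"`, `"compartment"`, `"complex-member"`;
#'   recorded on the returned object so downstream scorers can check they
#'   were handed the right table.
#' @return A data.frame of class `annotation_table` with columns
#'   `protein_id` and `term_id` and attribute `namespace`.
#' @export
read_annotations <- function(path, namespace = c("GO", "compartment", "complex-member")) {
  namespace <- match.arg(namespace)
  tokens <- parse_token_lines(path, min_tokens = 2L)
  tab <- if (length(tokens)) {
    data.frame(protein_id = vapply(tokens, `[[`, "", 1L),
               term_id = vapply(tokens, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = character(0), term_id = character(0))
  }
  annotation_table(tab, namespace)
}

#' @rdname read_annotations
#' @param tab A data.frame with columns `protein_id` and `term_id`.
#' @export
annotation_table <- function(tab, namespace = c("GO", "compartment", "complex-member")) {
  namespace <- match.arg(namespace)
  stopifnot(all(c("protein_id", "term_id") %in% names(tab)))
  if (any(!nzchar(tab$term_id))) stop("empty term identifier in annotation table")
  tab <- unique(tab[c("protein_id", "term_id")])
  rownames(tab) <- NULL
  structure(tab, namespace = namespace, class = c("annotation_table", "data.frame"))
}

#' Read protein complex membership
#'
#' One complex per line, member identifiers whitespace-separated; duplicate
#' members within a line are collapsed and empty lines skipped.
#'
#' @param path Path to the complex file.
#' @return A list of character vectors, one per complex.
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(strsplit(trimws(lines), "\\s+"), unique)
}

#' Read a plain protein-identifier list (one per line)
#'
#' @param path Path to the list file.
#' @return Character vector of unique identifiers.
#' @export
read_protein_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Protein feature table
#'
#' Rectangular table of named, complete (no missing values) real-valued
#' feature columns over an ordered set of proteins, with per-column
#' provenance (`"computed"` by this package or `"external"`).
#'
#' @param protein_ids Character vector of protein identifiers.
#' @param columns Named list of numeric vectors, one value per protein.
#' @param provenance Named character vector mapping column names to
#'   `"computed"` or `"external"`; defaults to `"computed"` for all.
#' @return A data.frame of class `feature_table` whose first column is
#'   `protein_id`, with a `provenance` attribute.
#' @export
feature_table <- function(protein_ids, columns, provenance = NULL) {
  protein_ids <- as.character(protein_ids)
  if (!length(columns) || is.null(names(columns)) || any(!nzchar(names(columns))))
    stop("feature columns must be a non-empty named list")
  if (anyDuplicated(names(columns)))
    stop("duplicate feature column names: ",
         paste(unique(names(columns)[duplicated(names(columns))]), collapse = ", "))
  len_ok <- vapply(columns, length, 0L) == length(protein_ids)
  if (!all(len_ok)) stop("all feature columns must have one value per protein")
  if (any(vapply(columns, function(x) any(!is.finite(x)), TRUE)))
    stop("feature table must be complete: non-finite values found")
  if (is.null(provenance)) provenance <- setNames(rep("computed", length(columns)), names(columns))
  stopifnot(setequal(names(provenance), names(columns)))
  tab <- data.frame(protein_id = protein_ids, columns,
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(tab, provenance = provenance[names(columns)],
            class = c("feature_table", "data.frame"))
}

feature_names <- function(table) setdiff(names(table), "protein_id")

#' @rdname feature_table
#' @param table A `feature_table`.
#' @return `feature_matrix()` returns the numeric matrix of features with
#'   protein identifiers as row names.
#' @export
feature_matrix <- function(table) {
  m <- as.matrix(table[feature_names(table)])
  rownames(m) <- table$protein_id
  m
}

#' Read and write feature tables as CSV
#'
#' The on-disk format is a plain CSV with header
#' `protein_id,<feature names...>`. Reading a written table reproduces it up
#' to float formatting (values agree to at least 1e-12).
#'
#' @param table A [feature_table()].
#' @param path File path.
#' @return `read_feature_table()` returns a `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (anyDuplicated(names(table))) stop("duplicate feature column names")
  if (any(vapply(table[feature_names(table)], function(x) any(!is.finite(x)), TRUE)))
    stop("feature table must be complete: non-finite values found")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "protein_id") stop("feature table CSV must start with protein_id column")
  if (ncol(tab) < 2) stop("feature table CSV has no feature columns")
  cols <- as.list(tab[-1])
  feature_table(tab$protein_id, cols)
}
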