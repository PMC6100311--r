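#' Specification for synthetic pipeline inputs
#'
#' Describes a desk-scale synthetic study: a scale-free interaction network
#' with triadic closure, a planted essentiality model, and annotation
#' sources (GO terms, subcellular compartments, complexes, external hybrid
#' feature stand-ins) whose enrichment in essential proteins is
#' parameterised explicitly. Everything downstream is reproducible from
#' `(spec, seed)`.
#'
#' @param n_proteins Number of proteins.
#' @param attachment_m Edges added per node by preferential attachment.
#' @param clustering_p Per-neighbour probability of closing a triangle
#'   around each node after attachment (real interaction networks are far
#'   more clustered than plain preferential attachment).
#' @param essential_fraction Expected fraction of essential proteins, in
#'   `(0, 1)`.
#' @param degree_effect Weight of standardised log-degree in the
#'   essentiality log-odds (hubs tend to be essential).
#' @param latent_sd Standard deviation of the latent per-protein
#'   essentiality propensity that annotation enrichments and external
#'   columns later express.
#' @param label_noise Probability of flipping each label, in `[0, 0.5)`.
#' @param compartment_base Named base localization rates for every
#'   compartment.
#' @param compartment_enrichment Named rate ratios applied to essential
#'   proteins (the planted informative compartments).
#' @param n_go_terms,go_base_terms,go_edge_share,go_edge_share_essential
#'   GO generator: vocabulary size, mean number of random terms per
#'   protein, probability that an interaction contributes a shared term,
#'   and the same probability when both partners are essential.
#' @param n_complexes,complex_size_mean,complex_essential_boost Complex
#'   generator: number of complexes, mean size above the minimum of 3, and
#'   sampling-weight multiplier for essential proteins (membership is also
#'   degree-weighted, so module score tracks the topological cluster).
#' @param external_names Names of external hybrid-feature stand-in columns
#'   (synthetic analogues of orthology/expression/domain predictors).
#' @param external_topo_mix,external_label_signal,external_noise_sd Mixing
#'   weights of standardised log-degree, the latent propensity, and fresh
#'   Gaussian noise in each external column.
#' @param informative_features Names of the planted informative feature
#'   columns (defaults to the enriched compartments).
#' @param seed Master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 800L,
                           attachment_m = 3L,
                           clustering_p = 0.15,
                           essential_fraction = 0.23,
                           degree_effect = 0.6,
                           latent_sd = 1,
                           label_noise = 0.05,
                           compartment_base = c(
                             nucleus = 0.12, cytosol = 0.12,
                             mitochondrion = 0.10, endoplasmic_reticulum = 0.08,
                             plasma_membrane = 0.06, cytoskeleton = 0.06,
                             golgi_apparatus = 0.05, vacuole = 0.05,
                             peroxisome = 0.03, endosome = 0.03,
                             extracellular_space = 0.02),
                           compartment_enrichment = c(
                             nucleus = 3.0, cytosol = 2.2,
                             mitochondrion = 2.0, endoplasmic_reticulum = 2.0,
                             cytoskeleton = 1.8, golgi_apparatus = 1.8),
                           n_go_terms = 150L,
                           go_base_terms = 3,
                           go_edge_share = 0.25,
                           go_edge_share_essential = 0.4,
                           n_complexes = max(10L, round(n_proteins / 20)),
                           complex_size_mean = 3,
                           complex_essential_boost = 1.5,
                           external_names = c("ION", "PeC", "WDC", "UDoNC"),
                           external_topo_mix = 0.8,
                           external_label_signal = 0.5,
                           external_noise_sd = 1,
                           informative_features = names(compartment_enrichment),
                           seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               attachment_m = as.integer(attachment_m),
               clustering_p = clustering_p,
               essential_fraction = essential_fraction,
               degree_effect = degree_effect,
               latent_sd = latent_sd,
               label_noise = label_noise,
               compartment_base = compartment_base,
               compartment_enrichment = compartment_enrichment,
               n_go_terms = as.integer(n_go_terms),
               go_base_terms = go_base_terms,
               go_edge_share = go_edge_share,
               go_edge_share_essential = go_edge_share_essential,
               n_complexes = as.integer(n_complexes),
               complex_size_mean = complex_size_mean,
               complex_essential_boost = complex_essential_boost,
               external_names = external_names,
               external_topo_mix = external_topo_mix,
               external_label_signal = external_label_signal,
               external_noise_sd = external_noise_sd,
               informative_features = informative_features,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  if (spec$n_proteins < spec$attachment_m + 1)
    stop("n_proteins must exceed attachment_m")
  if (spec$essential_fraction <= 0 || spec$essential_fraction >= 1)
    stop("essential_fraction must lie in (0, 1)")
  if (spec$label_noise < 0 || spec$label_noise >= 0.5)
    stop("label_noise must lie in [0, 0.5)")
  if (spec$clustering_p < 0 || spec$clustering_p > 1)
    stop("clustering_p must lie in [0, 1]")
  if (!all(names(spec$compartment_enrichment) %in% names(spec$compartment_base)))
    stop("enriched compartments must be among the base compartments")
  spec
}

#' Generate a synthetic interaction network
#'
#' Preferential attachment (guaranteeing a connected, heavy-tailed graph)
#' followed by triadic closure: around every node, random neighbour pairs
#' are connected with probability `clustering_p` per neighbour, giving the
#' high local clustering seen in real interaction data (and making the
#' triangle-based centralities LAC and NC informative rather than
#' degenerate).
#'
#' @param spec A [synthetic_spec()].
#' @return A [ppi_network()].
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  g <- igraph::sample_pa(spec$n_proteins, m = spec$attachment_m,
                         directed = FALSE)
  igraph::V(g)$name <- sprintf("P%04d", seq_len(spec$n_proteins))
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  extra <- vector("list", spec$n_proteins)
  for (v in seq_len(spec$n_proteins)) {
    nb <- adj[[v]]
    if (length(nb) < 2) next
    k <- rbinom(1, length(nb), spec$clustering_p)
    if (k == 0) next
    pairs <- replicate(k, sample(nb, 2L))
    extra[[v]] <- as.vector(pairs)
  }
  extra <- unlist(extra)
  if (length(extra)) g <- igraph::add_edges(g, extra)
  ppi_network(g)
}

#' Plant essentiality labels on a network
#'
#' The essentiality log-odds of protein `i` is
#' `a + degree_effect * z(log degree_i) + latent_i`, with the intercept `a`
#' calibrated so the expected essential fraction matches the spec; labels
#' are drawn from the resulting probabilities and then flipped with
#' probability `label_noise`. The latent propensity is returned so the
#' annotation generator can express it through enriched annotations and
#' external columns.
#'
#' @param net A [ppi_network()].
#' @param spec A [synthetic_spec()].
#' @return An object of class `planted_labels`: list with `labels` (named
#'   logical), `propensity` (the latent + degree log-odds part) and `prob`.
#' @export
plant_labels <- function(net, spec) {
  stopifnot(inherits(net, "ppi_network"), inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n <- n_proteins(net)
  ldeg <- log(igraph::degree(net$graph) + 1)
  z <- if (sd(ldeg) > 0) (ldeg - mean(ldeg)) / sd(ldeg) else rep(0, n)
  eta <- spec$degree_effect * z + spec$latent_sd * rnorm(n)
  a <- uniroot(function(a) mean(plogis(a + eta)) - spec$essential_fraction,
               c(-40, 40), tol = 1e-12)$root
  p <- plogis(a + eta)
  y <- runif(n) < p
  flip <- runif(n) < spec$label_noise
  y <- xor(y, flip)
  structure(list(labels = setNames(y, net$nodes),
                 propensity = setNames(eta, net$nodes),
                 prob = setNames(p, net$nodes)),
            class = "planted_labels")
}

#' Generate annotations and external feature stand-ins
#'
#' Produces, conditional on the planted labels: a compartment table whose
#' enriched compartments have `compartment_enrichment`-fold localization
#' rates in essential proteins; a GO table where interacting proteins share
#' terms (more often between essential partners), so the GO neighbour score
#' tracks degree; degree- and essentiality-weighted complex memberships;
#' and external columns mixing standardised log-degree, the latent
#' propensity and Gaussian noise. All outputs round-trip through the
#' package's file readers.
#'
#' @param net A [ppi_network()].
#' @param labels A [plant_labels()] result.
#' @param spec A [synthetic_spec()].
#' @return List with `go` and `compartments` ([annotation_table()]s),
#'   `complexes` (list of character vectors) and `external`
#'   (a [feature_table()] with external provenance).
#' @export
make_annotations <- function(net, labels, spec) {
  stopifnot(inherits(net, "ppi_network"), inherits(labels, "planted_labels"),
            inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  n <- n_proteins(net)
  ids <- net$nodes
  ess <- labels$labels[ids]

  comp_rows <- lapply(names(spec$compartment_base), function(cmp) {
    p <- rep(spec$compartment_base[[cmp]], n)
    ratio <- spec$compartment_enrichment[cmp]
    if (!is.na(ratio)) p[ess] <- pmin(p[ess] * ratio, 0.95)
    ids[runif(n) < p]
  })
  comp_tab <- data.frame(
    protein_id = unlist(comp_rows),
    term_id = rep(names(spec$compartment_base), lengths(comp_rows)),
    stringsAsFactors = FALSE)
  comp_tab <- comp_tab[order(comp_tab$protein_id, comp_tab$term_id), ]
  compartments <- annotation_table(comp_tab, "compartment")

  term_pool <- sprintf("GO:%06d", seq_len(spec$n_go_terms))
  base_counts <- rpois(n, spec$go_base_terms)
  go_rows <- data.frame(
    protein_id = rep(ids, base_counts),
    term_id = term_pool[sample.int(spec$n_go_terms, sum(base_counts),
                                   replace = TRUE)],
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el)) {
    p_share <- ifelse(ess[el[, 1]] & ess[el[, 2]],
                      spec$go_edge_share_essential, spec$go_edge_share)
    shared <- which(runif(nrow(el)) < p_share)
    if (length(shared)) {
      terms <- term_pool[sample.int(spec$n_go_terms, length(shared),
                                    replace = TRUE)]
      go_rows <- rbind(go_rows,
                       data.frame(protein_id = c(el[shared, 1], el[shared, 2]),
                                  term_id = c(terms, terms),
                                  stringsAsFactors = FALSE))
    }
  }
  go <- annotation_table(go_rows, "GO")

  deg <- igraph::degree(net$graph)
  w <- deg * ifelse(ess, spec$complex_essential_boost, 1)
  complexes <- lapply(seq_len(spec$n_complexes), function(i) {
    size <- min(n, 3L + rpois(1, spec$complex_size_mean))
    sample(ids, size, prob = w)
  })

  ldeg <- log(deg + 1)
  z <- if (sd(ldeg) > 0) (ldeg - mean(ldeg)) / sd(ldeg) else rep(0, n)
  eta <- labels$propensity[ids]
  eta_z <- if (sd(eta) > 0) (eta - mean(eta)) / sd(eta) else rep(0, n)
  ext_cols <- lapply(seq_along(spec$external_names), function(j) {
    spec$external_topo_mix * z + spec$external_label_signal * eta_z +
      rnorm(n, sd = spec$external_noise_sd)
  })
  names(ext_cols) <- spec$external_names
  external <- feature_table(ids, ext_cols,
                            provenance = setNames(rep("external",
                                                      length(ext_cols)),
                                                  names(ext_cols)))
  list(go = go, compartments = compartments, complexes = complexes,
       external = external)
}

#' Generate a complete in-memory synthetic study
#'
#' Runs [make_network()], [plant_labels()], [make_annotations()] and
#' [assemble_feature_table()] in sequence.
#'
#' @param spec A [synthetic_spec()].
#' @param k_compartments Compartments kept by preprocessing (default 6).
#' @return List with `spec`, `network`, `labels`, `essential_ids`,
#'   `annotations` and `features` (the assembled [feature_table()]).
#' @export
synthetic_dataset <- function(spec = synthetic_spec(), k_compartments = 6L) {
  net <- make_network(spec)
  labels <- plant_labels(net, spec)
  ann <- make_annotations(net, labels, spec)
  essential_ids <- names(labels$labels)[labels$labels]
  features <- assemble_feature_table(net, ann$go, ann$compartments,
                                     ann$complexes, essential_ids,
                                     external = ann$external,
                                     k_compartments = k_compartments)
  list(spec = spec, network = net, labels = labels,
       essential_ids = essential_ids, annotations = ann, features = features)
}

#' Write a synthetic study to disk as a pipeline fixture
#'
#' Writes every input file the pipeline consumes, in the package's file
#' dialects: `network.tsv`, `go.tsv`, `compartments.tsv`, `complexes.txt`,
#' `essential.txt`, `external.csv`, plus the generating `spec.json`. The
#' same spec (and seed) produces byte-identical fixtures.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Writable output directory (created if absent).
#' @return Invisibly, a named character vector of file paths, with the
#'   generated study attached as attribute `"study"`.
#' @export
make_fixture <- function(spec = synthetic_spec(), out_dir) {
  study <- synthetic_dataset(spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  write_edge_list(study$network, path("network.tsv"))
  write_annotation_file <- function(tab, f)
    writeLines(paste(tab$protein_id, tab$term_id, sep = "\t"), path(f))
  write_annotation_file(study$annotations$go, "go.tsv")
  write_annotation_file(study$annotations$compartments, "compartments.tsv")
  writeLines(vapply(study$annotations$complexes, paste, "", collapse = " "),
             path("complexes.txt"))
  writeLines(study$essential_ids, path("essential.txt"))
  write_feature_table(study$annotations$external, path("external.csv"))
  jsonlite::write_json(unclass(spec), path("spec.json"),
                       auto_unbox = TRUE, digits = I(17))
  files <- c(network = path("network.tsv"), go = path("go.tsv"),
             compartments = path("compartments.tsv"),
             complexes = path("complexes.txt"),
             essential = path("essential.txt"),
             external = path("external.csv"), spec = path("spec.json"))
  invisible(structure(files, study = study))
}
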