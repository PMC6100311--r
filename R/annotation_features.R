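#' Gene Ontology neighbour-similarity score
#'
#' Functional similarity between two interacting proteins is the size of
#' the intersection of their GO term sets; a protein's GO score is the sum
#' of this similarity over its network neighbours. Unannotated proteins
#' contribute (and receive) 0.
#'
#' @param net A [ppi_network()].
#' @param go An [annotation_table()] with namespace `"GO"`.
#' @return Named numeric vector over `net$nodes`.
#' @export
go_score <- function(net, go) {
  stopifnot(inherits(net, "ppi_network"), inherits(go, "annotation_table"))
  if (!identical(attr(go, "namespace"), "GO"))
    stop("annotation table namespace must be 'GO'")
  terms <- split(go$term_id, go$protein_id)
  out <- setNames(numeric(n_proteins(net)), net$nodes)
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      u <- el[e, 1]; v <- el[e, 2]
      tu <- terms[[u]]; tv <- terms[[v]]
      if (is.null(tu) || is.null(tv)) next
      ov <- length(intersect(tu, tv))
      out[u] <- out[u] + ov
      out[v] <- out[v] + ov
    }
  }
  out
}

# localization weight of each observed compartment: share of all
# localization assignments of standard essential proteins falling in it
compartment_weights <- function(loc, essential_ids) {
  stopifnot(inherits(loc, "annotation_table"))
  if (!identical(attr(loc, "namespace"), "compartment"))
    stop("annotation table namespace must be 'compartment'")
  ess <- loc[loc$protein_id %in% essential_ids, ]
  if (nrow(ess) == 0)
    stop("standard essential proteins have no localization assignments")
  tab <- table(ess$term_id)
  w <- as.numeric(tab) / sum(tab)
  setNames(w, names(tab))
}

#' Subcellular compartment scores
#'
#' Each kept compartment `c` gets a weight `w_c`: the proportion of all
#' localization assignments of standard essential proteins that fall in
#' `c`. A protein scores `w_c` in compartment `c` if it is annotated there
#' and 0 otherwise, giving one feature column per kept compartment.
#'
#' @param loc An [annotation_table()] with namespace `"compartment"`.
#' @param essential_ids Character vector of standard essential proteins.
#' @param kept_compartments Compartment names to emit (see
#'   [select_compartments()]).
#' @param protein_ids Protein order for the returned columns.
#' @return Named list of numeric vectors, one per kept compartment.
#' @export
subcellular_scores <- function(loc, essential_ids, kept_compartments, protein_ids) {
  w <- compartment_weights(loc, essential_ids)
  missing <- setdiff(kept_compartments, names(w))
  if (length(missing))
    stop("compartments never seen among essential localizations: ",
         paste(missing, collapse = ", "))
  membership <- split(loc$protein_id, loc$term_id)
  cols <- lapply(kept_compartments, function(cmp) {
    v <- numeric(length(protein_ids))
    v[protein_ids %in% membership[[cmp]]] <- w[[cmp]]
    setNames(v, protein_ids)
  })
  setNames(cols, kept_compartments)
}

#' Select the most essentiality-enriched compartments
#'
#' Ranks compartments by their essential-localization weight `w_c`
#' (descending, ties broken by compartment name) and keeps the top `k`.
#' This is the preprocessing step that discards the less predictive
#' compartment columns before feature selection.
#'
#' @inheritParams subcellular_scores
#' @param k Number of compartments to keep; at most the number observed.
#' @return Character vector of `k` compartment names.
#' @export
select_compartments <- function(loc, essential_ids, k) {
  w <- compartment_weights(loc, essential_ids)
  if (k > length(w))
    stop(sprintf("k = %d exceeds the %d observed compartments", k, length(w)))
  names(w)[order(-w, names(w))][seq_len(k)]
}

#' Protein-complex membership score
#'
#' The module score of a protein is the number of complexes it belongs to.
#'
#' @param complexes List of character vectors (one complex each), as from
#'   [read_complexes()].
#' @param protein_ids Protein order for the returned vector.
#' @return Named numeric vector.
#' @export
module_score <- function(complexes, protein_ids) {
  counts <- table(unlist(lapply(complexes, unique)))
  v <- numeric(length(protein_ids))
  hit <- protein_ids %in% names(counts)
  v[hit] <- as.numeric(counts[protein_ids[hit]])
  setNames(v, protein_ids)
}

#' Assemble the full protein feature table
#'
#' Computes the six topological centralities, the GO score, the module
#' score and the kept subcellular compartment columns, then appends any
#' externally supplied feature columns (for example precomputed hybrid
#' predictors such as orthology-, expression- or domain-based scores).
#' Column order is: topological, GO, module, compartments, external.
#'
#' @param net A [ppi_network()].
#' @param go GO [annotation_table()].
#' @param loc Compartment [annotation_table()].
#' @param complexes List of complexes.
#' @param essential_ids Standard essential protein identifiers (used only to
#'   weight compartments).
#' @param external Optional [feature_table()] of external columns indexed by
#'   the same protein identifiers; every network protein must be present.
#' @param k_compartments How many compartments to keep (default 6).
#' @return A [feature_table()] over `net$nodes`.
#' @export
assemble_feature_table <- function(net, go, loc, complexes, essential_ids,
                                   external = NULL, k_compartments = 6L) {
  stopifnot(inherits(net, "ppi_network"))
  ids <- net$nodes
  kept <- select_compartments(loc, essential_ids, k_compartments)
  cols <- c(
    list(DC = degree_centrality(net),
         EC = eigenvector_centrality(net),
         SC = subgraph_centrality(net),
         IC = information_centrality(net),
         LAC = local_average_connectivity(net),
         NC = neighborhood_centrality(net),
         GO = go_score(net, go),
         module = module_score(complexes, ids)),
    subcellular_scores(loc, essential_ids, kept, ids))
  provenance <- setNames(rep("computed", length(cols)), names(cols))
  if (!is.null(external)) {
    stopifnot(inherits(external, "feature_table"))
    miss <- setdiff(ids, external$protein_id)
    if (length(miss))
      stop("external feature table is missing proteins: ",
           paste(utils::head(miss, 10), collapse = ", "),
           if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10))
    clash <- intersect(names(cols), feature_names(external))
    if (length(clash))
      stop("external columns clash with computed ones: ", paste(clash, collapse = ", "))
    idx <- match(ids, external$protein_id)
    for (nm in feature_names(external)) {
      cols[[nm]] <- setNames(external[[nm]][idx], ids)
      provenance[[nm]] <- "external"
    }
  }
  feature_table(ids, cols, provenance)
}
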