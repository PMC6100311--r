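#' Run the full essentiality prediction pipeline
#'
#' Assembles the feature table, derives the correlation gold standard,
#' selects features with the elite-search flower pollination optimizer,
#' builds balanced datasets by undersampling, and evaluates the
#' seven-learner voting classifier on the selected features with repeated
#' stratified cross-validation. Following the single-dataset protocol, the
#' report is computed on the first balanced dataset; set
#' `evaluate_all_repeats = TRUE` to get one report per balanced dataset.
#'
#' @param net A [ppi_network()].
#' @param go,loc [annotation_table()]s (GO and compartment namespaces).
#' @param complexes List of complexes.
#' @param essential_ids Character vector of essential proteins.
#' @param external Optional external [feature_table()].
#' @param config An [esfpa_config()].
#' @param k_compartments Compartments kept by preprocessing.
#' @param evaluate_all_repeats Evaluate every balanced dataset instead of
#'   the first only.
#' @return List with `features`, `gold`, `selection` (an `esfpa_result`),
#'   `balanced` (list of datasets), and `report` (an `evaluation_report`,
#'   or a list of them when `evaluate_all_repeats`).
#' @export
run_pipeline <- function(net, go, loc, complexes, essential_ids,
                         external = NULL, config = esfpa_config(),
                         k_compartments = 6L, evaluate_all_repeats = FALSE) {
  validate_config(config)
  features <- assemble_feature_table(net, go, loc, complexes, essential_ids,
                                     external = external,
                                     k_compartments = k_compartments)
  gold <- gold_standard(features, config$gold_fraction)
  selection <- esfpa_run(features, config, gold = gold)
  dataset <- labeled_dataset(features, essential_ids,
                             features = selection$selected_features)
  balanced <- build_balanced_datasets(dataset, config$n_balanced_repeats,
                                      seed = config$seed)
  clf <- make_hybrid_classifier()
  evaluate <- function(ds) cross_validate(clf, ds, k = config$cv_folds,
                                          n_runs = config$cv_runs,
                                          seed = config$seed)
  report <- if (evaluate_all_repeats) lapply(balanced, evaluate)
            else evaluate(balanced[[1]])
  list(features = features, gold = gold, selection = selection,
       balanced = balanced, report = report)
}

#' Run the pipeline from files on disk
#'
#' Thin wrapper over [run_pipeline()] reading the package's file dialects
#' (see [make_fixture()] for the layout).
#'
#' @param network_file Edge-list TSV.
#' @param go_file,compartment_file Annotation TSVs.
#' @param complex_file Line-per-complex file.
#' @param essential_file Line-per-identifier essential protein list.
#' @param external_file Optional external feature CSV.
#' @param config An [esfpa_config()].
#' @param ... Passed on to [run_pipeline()].
#' @return See [run_pipeline()].
#' @export
run_pipeline_files <- function(network_file, go_file, compartment_file,
                               complex_file, essential_file,
                               external_file = NULL,
                               config = esfpa_config(), ...) {
  run_pipeline(read_edge_list(network_file),
               read_annotations(go_file, "GO"),
               read_annotations(compartment_file, "compartment"),
               read_complexes(complex_file),
               read_protein_list(essential_file),
               external = if (!is.null(external_file))
                 read_feature_table(external_file),
               config = config, ...)
}
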