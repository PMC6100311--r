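#' Run configuration for the feature-selection pipeline
#'
#' Collects every tunable parameter of the pipeline in one validated object.
#' All stochastic steps (optimizer, undersampling, cross-validation) draw
#' their randomness from `seed`, so a run is fully reproducible from its
#' configuration.
#'
#' @param seed Integer master seed.
#' @param population_size Number of pollens (candidate feature subsets) in
#'   the swarm; must be at least 2 so local pollination can pick two
#'   distinct partners.
#' @param max_iterations Number of optimizer iterations.
#' @param switch_probability Probability of taking the global (Levy-flight)
#'   pollination branch rather than the local branch, in `[0, 1]`.
#' @param levy_lambda Tail index of the Levy step distribution, in `(1, 2]`.
#' @param levy_s0 Lower truncation of Levy step magnitudes, positive.
#' @param alpha Weight of the accuracy term in the fitness score, in
#'   `[0, 1]`; the remaining weight `1 - alpha` rewards small subsets.
#' @param cons Fraction of the (correlation-ranked) bit positions covered by
#'   the elite search window, in `(0, 1]`.
#' @param sigmoid_orientation `"printed"` uses the decreasing transfer
#'   function `S(x) = 1/(1 + exp(x))`; `"standard"` uses the usual
#'   increasing `S(x) = 1/(1 + exp(-x))`.
#' @param elite_mode `"position"` (default) assigns `cons * G*` to the
#'   continuous position at window bits that disagree with the global best
#'   and re-binarizes them, so pollens are pulled toward the global best
#'   while the window keeps exploring; `"bitcopy"` deterministically
#'   replaces disagreeing window bits with the global-best bits.
#' @param gold_fraction Fraction of features flagged as the gold standard,
#'   in `(0, 1]`.
#' @param n_balanced_repeats Number of balanced datasets drawn by
#'   undersampling.
#' @param cv_folds Number of cross-validation folds, at least 2.
#' @param cv_runs Number of repeated cross-validation runs to average.
#'
#' @return An object of class `esfpa_config` (a validated named list).
#' @export
#' @examples
#' cfg <- esfpa_config(seed = 7, population_size = 20)
#' cfg$gold_fraction
esfpa_config <- function(seed = 1L,
                         population_size = 20L,
                         max_iterations = 100L,
                         switch_probability = 0.8,
                         levy_lambda = 1.5,
                         levy_s0 = 0.01,
                         alpha = 0.8,
                         cons = 2 / 3,
                         sigmoid_orientation = c("printed", "standard"),
                         elite_mode = c("position", "bitcopy"),
                         gold_fraction = 2 / 3,
                         n_balanced_repeats = 10L,
                         cv_folds = 10L,
                         cv_runs = 10L) {
  cfg <- list(
    seed = as.integer(seed),
    population_size = as.integer(population_size),
    max_iterations = as.integer(max_iterations),
    switch_probability = switch_probability,
    levy_lambda = levy_lambda,
    levy_s0 = levy_s0,
    alpha = alpha,
    cons = cons,
    sigmoid_orientation = match.arg(sigmoid_orientation),
    elite_mode = match.arg(elite_mode),
    gold_fraction = gold_fraction,
    n_balanced_repeats = as.integer(n_balanced_repeats),
    cv_folds = as.integer(cv_folds),
    cv_runs = as.integer(cv_runs)
  )
  class(cfg) <- "esfpa_config"
  validate_config(cfg)
  cfg
}

#' @rdname esfpa_config
#' @param cfg An `esfpa_config` object to validate.
#' @return `validate_config()` returns `cfg` invisibly, or stops with an
#'   informative message on the first violated constraint.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "esfpa_config"))
  check <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg, call. = FALSE)
  check(length(cfg$seed) == 1L && is.finite(cfg$seed), "seed must be a single integer")
  check(cfg$population_size >= 2L, "population_size must be >= 2")
  check(cfg$max_iterations >= 0L, "max_iterations must be >= 0")
  check(cfg$switch_probability >= 0 && cfg$switch_probability <= 1,
        "switch_probability must lie in [0, 1]")
  check(cfg$levy_lambda > 1 && cfg$levy_lambda <= 2, "levy_lambda must lie in (1, 2]")
  check(cfg$levy_s0 > 0, "levy_s0 must be positive")
  check(cfg$alpha >= 0 && cfg$alpha <= 1, "alpha must lie in [0, 1]")
  check(cfg$cons > 0 && cfg$cons <= 1, "cons must lie in (0, 1]")
  check(cfg$sigmoid_orientation %in% c("printed", "standard"), "unknown sigmoid_orientation")
  check(cfg$elite_mode %in% c("position", "bitcopy"), "unknown elite_mode")
  check(cfg$gold_fraction > 0 && cfg$gold_fraction <= 1, "gold_fraction must lie in (0, 1]")
  check(cfg$n_balanced_repeats >= 1L, "n_balanced_repeats must be >= 1")
  check(cfg$cv_folds >= 2L, "cv_folds must be >= 2")
  check(cfg$cv_runs >= 1L, "cv_runs must be >= 1")
  invisible(cfg)
}

#' Read and write run configurations
#'
#' Configurations are stored as flat JSON documents at full numeric
#' precision, so `read_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param cfg An [esfpa_config()] object.
#' @param path File path.
#' @return `read_config()` returns an `esfpa_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(esfpa_config, raw)
}

#' @method print esfpa_config
#' @export
print.esfpa_config <- function(x, ...) {
  cat("<esfpa_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]], digits = 15)))
  invisible(x)
}
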