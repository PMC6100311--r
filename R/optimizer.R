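#' Levy-flight step magnitudes
#'
#' Heavy-tailed positive step sizes for global pollination, generated with
#' the Mantegna algorithm for stability index `lambda` (the survival
#' function decays like `s^-lambda`) and truncated below at `s0`. Draws
#' from the current R random number stream.
#'
#' @param lambda Tail index, in `(1, 2]`.
#' @param size Number of steps.
#' @param s0 Lower truncation, positive.
#' @return Numeric vector of `size` values, all `>= s0`.
#' @export
levy_step <- function(lambda, size, s0 = 0.01) {
  if (lambda <= 1 || lambda > 2) stop("lambda must lie in (1, 2]")
  if (s0 <= 0) stop("s0 must be positive")
  sigma_u <- (gamma(1 + lambda) * sin(pi * lambda / 2) /
                (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2)))^(1 / lambda)
  u <- rnorm(size, 0, sigma_u)
  v <- rnorm(size)
  pmax(abs(u) / abs(v)^(1 / lambda), s0)
}

#' Pollination moves on continuous positions
#'
#' `global_pollination()` applies the Levy-flight move
#' `x + L * (x - g_star)` componentwise; `local_pollination()` applies the
#' peer-difference move `x + mu * (xj - xk)`.
#'
#' @param x Current position vector.
#' @param g_star Global-best position (same length).
#' @param L Step magnitudes (same length, recycled if scalar).
#' @return Updated position vector.
#' @export
global_pollination <- function(x, g_star, L) {
  if (length(x) != length(g_star)) stop("position vectors must have equal length")
  x + L * (x - g_star)
}

#' @rdname global_pollination
#' @param xj,xk Positions of two other pollens.
#' @param mu Scalar in `[0, 1]`, drawn uniformly by the caller.
#' @export
local_pollination <- function(x, xj, xk, mu) {
  if (length(xj) != length(x) || length(xk) != length(x))
    stop("position vectors must have equal length")
  x + mu * (xj - xk)
}

#' Binarize a continuous position into a selection mask
#'
#' Applies a sigmoid transfer function and thresholds against per-bit
#' uniform random values `delta`. The `"printed"` orientation uses the
#' decreasing sigmoid `S(x) = 1/(1 + exp(x))` (the package default); the
#' `"standard"` orientation uses the usual increasing
#' `S(x) = 1/(1 + exp(-x))`. A bit is set iff `S(x) > delta`.
#'
#' @param position Numeric vector.
#' @param delta Uniform `[0, 1]` thresholds, one per bit (fresh each call).
#' @param orientation `"printed"` or `"standard"`.
#' @return Logical mask of the same length.
#' @export
binarize <- function(position, delta, orientation = c("printed", "standard")) {
  orientation <- match.arg(orientation)
  stopifnot(length(delta) == length(position))
  s <- if (orientation == "printed") 1 / (1 + exp(position)) else 1 / (1 + exp(-position))
  s > delta
}

# position sign consistent with a mask bit, so the bit tends to survive
# the next binarization
sync_sign <- function(position, mask, orientation) {
  want_negative <- if (orientation == "printed") mask else !mask
  ifelse(want_negative, -abs(position), abs(position))
}

#' Elite search: copy global-best bits over the informative window
#'
#' Over the first `ceil(cons * D)` bit positions (features are encoded in
#' ascending correlation-value order, so the window covers the most
#' distinct features), any bit that disagrees with the global-best mask is
#' replaced by the global-best bit; positions outside the window are left
#' untouched. This pulls every pollen toward the global optimum and
#' accelerates convergence.
#'
#' @param mask Logical mask of length `D`.
#' @param g_mask Global-best mask, same length.
#' @param cons Window fraction, in `(0, 1]` (default two-thirds).
#' @return Updated logical mask.
#' @export
elite_search <- function(mask, g_mask, cons = 2 / 3) {
  if (length(mask) != length(g_mask)) stop("masks must have equal length")
  if (cons <= 0 || cons > 1) stop("cons must lie in (0, 1]")
  window <- seq_len(ceiling(cons * length(mask)))
  mask[window] <- g_mask[window]
  mask
}

#' Fitness of a selection mask against the gold standard
#'
#' Classifies each feature of the mask against the gold standard as TD
#' (true distinct), FD (false distinct), TI (true indistinct) or FI (false
#' indistinct), computes the accuracy
#' `Fperformance = (TD + TI) / fn` and returns the weighted score
#' `alpha * Fperformance + (1 - alpha) / |N|`, where `|N|` is the number of
#' selected features. The empty mask is invalid and scores the sentinel
#' `-1`; it is never accepted as a global best.
#'
#' @param mask Logical selection mask in the gold standard's (ascending
#'   `cv`) feature order.
#' @param gold A [gold_standard()].
#' @param alpha Accuracy weight in `[0, 1]` (default 0.8).
#' @return List with `fitness` and `counts` (named TD/FD/TI/FI vector).
#' @export
mask_fitness <- function(mask, gold, alpha = 0.8) {
  stopifnot(inherits(gold, "gold_standard"))
  g <- gold$gold_mask
  if (length(mask) != length(g)) stop("mask length must equal the number of features")
  counts <- c(TD = sum(mask & g), FD = sum(mask & !g),
              TI = sum(!mask & !g), FI = sum(!mask & g))
  n_sel <- sum(mask)
  if (n_sel == 0) return(list(fitness = -1, counts = counts))
  fperf <- (counts[["TD"]] + counts[["TI"]]) / length(g)
  list(fitness = alpha * fperf + (1 - alpha) / n_sel, counts = counts)
}

#' A plain fitness closure for plugging other optimizers in
#'
#' Returns `function(mask) -> numeric fitness`, so alternative search
#' strategies can be benchmarked against the same objective.
#'
#' @inheritParams mask_fitness
#' @return A function of one logical-mask argument.
#' @export
make_fitness <- function(gold, alpha = 0.8) {
  force(gold); force(alpha)
  function(mask) mask_fitness(mask, gold, alpha)$fitness
}

new_pollen <- function(position, gold, config) {
  mask <- binarize(position, runif(length(position)), config$sigmoid_orientation)
  fit <- mask_fitness(mask, gold, config$alpha)
  list(position = position, mask = mask, fitness = fit$fitness)
}

#' Initialize the pollen population
#'
#' Positions are drawn i.i.d. uniform on `[-1, 1]^D` (`D` = number of
#' features), masks derived by [binarize()], fitness evaluated, and the
#' global best set to the fittest pollen. Fully deterministic given the
#' configuration seed.
#'
#' @param gold A [gold_standard()]; defines the dimension and the fitness.
#' @param config An [esfpa_config()].
#' @return An optimizer state: list with `population`, `global_best`,
#'   `iteration`, `trace`.
#' @export
initialize_population <- function(gold, config) {
  validate_config(config)
  d <- length(gold$gold_mask)
  if (d < 1) stop("need at least one feature")
  set.seed(config$seed)
  population <- lapply(seq_len(config$population_size), function(i)
    new_pollen(runif(d, -1, 1), gold, config))
  best <- population[[which.max(vapply(population, `[[`, 0, "fitness"))]]
  list(population = population, global_best = best,
       iteration = 0L, trace = numeric(0))
}

#' Run the elite-search flower pollination feature selection
#'
#' Each iteration, every pollen takes the global Levy-flight branch with
#' probability `switch_probability` or the local peer-difference branch
#' otherwise; the new position is binarized, the elite search copies
#' global-best bits over the informative window, and the pollen is replaced
#' only if its fitness improves (greedy acceptance). The global best is
#' therefore monotone and the best-fitness trace non-decreasing. Features
#' are encoded internally in ascending correlation-value order; results are
#' reported in both orders.
#'
#' @param table A [feature_table()] (used to build `gold` when not given).
#' @param config An [esfpa_config()].
#' @param gold Optional precomputed [gold_standard()]; when supplied,
#'   `table` may be `NULL`.
#' @return An object of class `esfpa_result`: list with `selected_features`
#'   (character, in the table's column order), `mask` (named logical in
#'   ascending-`cv` order), `fitness`, `counts` (TD/FD/TI/FI), `trace`,
#'   `state` (final optimizer state), `gold`, and `config`.
#' @export
esfpa_run <- function(table = NULL, config = esfpa_config(), gold = NULL) {
  validate_config(config)
  if (is.null(gold)) {
    if (is.null(table)) stop("supply a feature table or a gold standard")
    gold <- gold_standard(table, config$gold_fraction)
  }
  d <- length(gold$gold_mask)
  state <- initialize_population(gold, config)
  pop <- state$population
  best <- state$global_best
  n <- length(pop)
  trace <- numeric(config$max_iterations)
  g <- gold$gold_mask
  alpha <- config$alpha
  n_indistinct <- sum(!g)
  sgn <- if (config$sigmoid_orientation == "printed") 1 else -1
  window <- seq_len(ceiling(config$cons * d))
  for (t in seq_len(config$max_iterations)) {
    for (i in seq_len(n)) {
      x <- pop[[i]]$position
      if (runif(1) < config$switch_probability) {
        L <- levy_step(config$levy_lambda, d, config$levy_s0)
        xnew <- global_pollination(x, best$position, L)
      } else {
        jk <- sample(seq_len(n), 2L)
        xnew <- local_pollination(x, pop[[jk[1]]]$position, pop[[jk[2]]]$position,
                                  runif(1))
      }
      mask <- 1 / (1 + exp(sgn * xnew)) > runif(d)
      if (config$elite_mode == "position") {
        # literal update rule: assign cons * G* to the continuous position at
        # disagreeing window bits, then re-binarize (keeps exploring)
        disagree <- window[mask[window] != best$mask[window]]
        if (length(disagree)) {
          xnew[disagree] <- config$cons * best$position[disagree]
          mask[disagree] <- 1 / (1 + exp(sgn * xnew[disagree])) >
            runif(length(disagree))
        }
      } else {
        mask <- elite_search(mask, best$mask, config$cons)
      }
      want_neg <- if (sgn == 1) mask else !mask
      xnew <- abs(xnew)
      xnew[want_neg] <- -xnew[want_neg]
      # inline mask_fitness (hot loop)
      n_sel <- sum(mask)
      fit <- if (n_sel == 0) -1 else {
        td <- sum(mask & g)
        alpha * ((td + n_indistinct - (n_sel - td)) / d) + (1 - alpha) / n_sel
      }
      if (fit > pop[[i]]$fitness)
        pop[[i]] <- list(position = xnew, mask = mask, fitness = fit)
      if (fit > best$fitness && fit > -1)
        best <- pop[[i]]
    }
    trace[t] <- best$fitness
  }
  mask <- setNames(best$mask, gold$feature_names)
  selected_sorted <- gold$feature_names[mask]
  # report in the original table column order
  original_names <- character(length(gold$feature_names))
  original_names[gold$original_order] <- gold$feature_names
  fit <- mask_fitness(best$mask, gold, config$alpha)
  structure(
    list(selected_features = original_names[original_names %in% selected_sorted],
         mask = mask,
         fitness = fit$fitness,
         counts = fit$counts,
         trace = trace,
         state = list(population = pop, global_best = best,
                      iteration = config$max_iterations, trace = trace),
         gold = gold,
         config = config),
    class = "esfpa_result")
}

#' @method print esfpa_result
#' @export
print.esfpa_result <- function(x, ...) {
  cat(sprintf("<esfpa_result> %d of %d features selected, fitness %.5f\n",
              length(x$selected_features), length(x$mask), x$fitness))
  cat("  ", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive search over all selection masks
#'
#' Brute-force oracle: evaluates the fitness of every non-empty mask over
#' `fn <= 20` features and returns the maximizer (ties resolved by
#' enumeration order, i.e. the lexicographically smallest mask with the
#' first feature varying fastest).
#'
#' @inheritParams mask_fitness
#' @return List with `mask` (logical, gold feature order), `fitness`.
#' @export
exhaustive_oracle <- function(gold, alpha = 0.8) {
  stopifnot(inherits(gold, "gold_standard"))
  fn <- length(gold$gold_mask)
  if (fn > 20) stop("refusing exhaustive search beyond 20 features")
  g <- as.numeric(gold$gold_mask)
  m <- gold$gold_size
  best_fit <- -Inf; best_i <- NA_integer_
  block <- 65536L
  total <- 2^fn - 1
  start <- 1
  while (start <= total) {
    ints <- start:min(start + block - 1, total)
    bits <- matrix(0, length(ints), fn)
    rem <- ints
    for (j in seq_len(fn)) {
      bits[, j] <- rem %% 2
      rem <- rem %/% 2
    }
    td <- as.vector(bits %*% g)
    nsel <- rowSums(bits)
    fperf <- (td + (fn - m - (nsel - td))) / fn
    fit <- alpha * fperf + (1 - alpha) / nsel
    k <- which.max(fit)
    if (fit[k] > best_fit) { best_fit <- fit[k]; best_i <- ints[k] }
    start <- start + block
  }
  mask <- as.logical(intToBits(best_i)[seq_len(fn)])
  list(mask = setNames(mask, gold$feature_names), fitness = best_fit)
}
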