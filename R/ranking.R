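#' Pearson correlation between two feature vectors
#'
#' Plain Pearson correlation with one convention: if either vector has zero
#' variance the correlation is defined as 0 (a constant column carries no
#' redundancy information).
#'
#' @param x,y Numeric vectors of equal length, at least 2.
#' @return A number in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("feature vectors must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  as.numeric(cor(x, y))
}

# full pairwise correlation matrix with the zero-variance convention
correlation_matrix <- function(X) {
  sds <- apply(X, 2, sd)
  C <- suppressWarnings(cor(X))
  C[!is.finite(C)] <- 0
  C[sds == 0, ] <- 0
  C[, sds == 0] <- 0
  diag(C) <- 1
  C
}

#' Per-feature correlation values
#'
#' The correlation value of feature `i` is the mean absolute Pearson
#' correlation with every other feature,
#' `cv_i = sum_{j != i} |cc_ij| / (fn - 1)`. Low values mark distinct
#' (non-redundant) features; high values mark redundant ones.
#'
#' @param table A [feature_table()] with at least two feature columns.
#' @return Named numeric vector of `cv` values in `[0, 1]`, in column order.
#' @export
correlation_values <- function(table) {
  X <- feature_matrix(table)
  fn <- ncol(X)
  if (fn < 2) stop("correlation values need at least two features")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    message("zero-variance feature column(s) treated as uncorrelated: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  C <- correlation_matrix(X)
  cv <- (rowSums(abs(C)) - 1) / (fn - 1)
  setNames(as.numeric(cv), colnames(X))
}

#' Gold standard of distinct features
#'
#' Sorts features by ascending correlation value (ties broken by original
#' column order) and flags the first `floor(gold_fraction * fn)` as the
#' gold standard of "distinct" features. The optimizer's fitness rewards
#' selection masks that reproduce this flagging.
#'
#' @param table A [feature_table()].
#' @param gold_fraction Fraction of features flagged gold, in `(0, 1]`
#'   (default two-thirds).
#' @return An object of class `gold_standard`: list with `feature_names`
#'   (ascending `cv` order), `cv` (same order), `gold_mask`, `gold_size`,
#'   and `original_order` (positions of the sorted features in the input
#'   table).
#' @export
gold_standard <- function(table, gold_fraction = 2 / 3) {
  if (gold_fraction <= 0 || gold_fraction > 1)
    stop("gold_fraction must lie in (0, 1]")
  cv <- correlation_values(table)
  fn <- length(cv)
  ord <- order(cv, seq_along(cv))
  gold_size <- floor(gold_fraction * fn)
  structure(
    list(feature_names = names(cv)[ord],
         cv = as.numeric(cv[ord]),
         gold_mask = seq_len(fn) <= gold_size,
         gold_size = as.integer(gold_size),
         original_order = ord),
    class = "gold_standard")
}

#' @method print gold_standard
#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> %d features, %d gold\n",
              length(x$feature_names), x$gold_size))
  flag <- ifelse(x$gold_mask, "*", " ")
  cat(sprintf("  %s %-20s cv = %.4f\n", flag, x$feature_names, x$cv), sep = "")
  invisible(x)
}

#' Rank features and export the gold standard
#'
#' Convenience wrapper producing a data.frame (one row per feature, in
#' ascending `cv` order) suitable for writing to CSV.
#'
#' @inheritParams gold_standard
#' @return data.frame with columns `feature`, `cv`, `gold`.
#' @export
rank_features <- function(table, gold_fraction = 2 / 3) {
  gs <- gold_standard(table, gold_fraction)
  data.frame(feature = gs$feature_names, cv = gs$cv, gold = gs$gold_mask)
}
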