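#' Labeled protein dataset
#'
#' Features restricted to a selected subset plus binary essentiality
#' labels, aligned row by row.
#'
#' @param table A [feature_table()].
#' @param essential_ids Character vector of essential protein identifiers;
#'   every other protein in `table` is labelled non-essential.
#' @param features Optional character vector of feature columns to keep
#'   (default: all).
#' @return An object of class `labeled_dataset`: list with `protein_ids`,
#'   `X` (numeric matrix) and `y` (logical, `TRUE` = essential).
#' @export
labeled_dataset <- function(table, essential_ids, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(features)) features <- feature_names(table)
  missing <- setdiff(features, feature_names(table))
  if (length(missing))
    stop("unknown feature columns: ", paste(missing, collapse = ", "))
  X <- feature_matrix(table)[, features, drop = FALSE]
  y <- table$protein_id %in% essential_ids
  structure(list(protein_ids = table$protein_id, X = X, y = y),
            class = "labeled_dataset")
}

subset_dataset <- function(ds, rows) {
  structure(list(protein_ids = ds$protein_ids[rows],
                 X = ds$X[rows, , drop = FALSE],
                 y = ds$y[rows]),
            class = "labeled_dataset")
}

#' Balanced datasets by random undersampling
#'
#' Each balanced dataset keeps every essential (positive) protein and a
#' uniformly sampled subset of non-essential proteins of equal size.
#' Repeats share all positives and differ only in the sampled negatives;
#' per-repeat seeds are derived deterministically from the master seed.
#'
#' @param dataset A [labeled_dataset()] with at least as many negatives as
#'   positives.
#' @param n_repeats Number of balanced datasets.
#' @param seed Master seed.
#' @return List of `labeled_dataset` objects, each with equal class counts.
#' @export
build_balanced_datasets <- function(dataset, n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"), n_repeats >= 1)
  pos <- which(dataset$y)
  neg <- which(!dataset$y)
  if (length(pos) == 0) stop("dataset has no positive (essential) proteins")
  if (length(neg) < length(pos))
    stop(sprintf(paste0("only %d negatives for %d positives; undersampling ",
                        "the majority class requires at least as many ",
                        "negatives as positives"),
                 length(neg), length(pos)))
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  lapply(subseeds, function(s) {
    set.seed(s)
    keep <- c(pos, sort(sample(neg, length(pos))))
    subset_dataset(dataset, keep)
  })
}

#' The seven-learner voting classifier
#'
#' An ensemble of seven probabilistic base learners combined by an
#' unweighted average of predicted class probabilities (threshold 0.5):
#' naive Bayes; a linear support vector machine with Platt-calibrated
#' probabilities; an information-gain decision tree; a ridge-regularised
#' logistic regression; a random forest; a single fully randomised
#' (extra-trees) tree; and a cost-complexity-pruned decision tree. The
#' last four members are the package's nearest standard equivalents of
#' tree learners from the original ensemble design (logistic model trees,
#' random tree, reduced-error-pruning tree); see the methods vignette.
#'
#' @param members Character subset of
#'   `c("naive_bayes", "svm_linear", "tree_info", "logistic_ridge",
#'   "random_forest", "random_tree", "pruned_tree")`; a single-member
#'   ensemble is identical to that member.
#' @param num_trees Trees in the random forest member.
#' @return An object of class `hybrid_classifier` (an unfitted
#'   specification; see [fit_classifier()]).
#' @export
make_hybrid_classifier <- function(members = c("naive_bayes", "svm_linear",
                                               "tree_info", "logistic_ridge",
                                               "random_forest", "random_tree",
                                               "pruned_tree"),
                                   num_trees = 100L) {
  known <- c("naive_bayes", "svm_linear", "tree_info", "logistic_ridge",
             "random_forest", "random_tree", "pruned_tree")
  bad <- setdiff(members, known)
  if (length(bad)) stop("unknown ensemble members: ", paste(bad, collapse = ", "))
  structure(list(members = members, num_trees = as.integer(num_trees)),
            class = "hybrid_classifier")
}

# --- base learner fit/predict -------------------------------------------
# each fitter returns an object; each predictor returns P(essential)

fit_member <- function(member, X, y, num_trees) {
  df <- as.data.frame(X)
  yf <- factor(ifelse(y, "essential", "nonessential"),
               levels = c("nonessential", "essential"))
  switch(member,
    naive_bayes = {
      m <- e1071::naiveBayes(df, yf)
      # floor within-class standard deviations so near-constant columns
      # cannot produce degenerate densities
      m$tables <- lapply(m$tables, function(tb) {
        if (is.matrix(tb) && ncol(tb) == 2) tb[, 2] <- pmax(tb[, 2], 1e-6)
        tb
      })
      m
    },
    svm_linear = suppressWarnings(
      e1071::svm(x = X, y = yf, kernel = "linear", probability = TRUE,
                 cost = 1, scale = TRUE)),
    tree_info = rpart::rpart(y ~ ., data = cbind(df, y = yf), method = "class",
                             parms = list(split = "information")),
    logistic_ridge = {
      if (ncol(X) >= 2) {
        glmnet::glmnet(X, yf, family = "binomial", alpha = 0, lambda = 0.01)
      } else {
        suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = yf),
                                    family = stats::binomial()))
      }
    },
    random_forest = ranger::ranger(x = df, y = yf, probability = TRUE,
                                   num.trees = num_trees,
                                   seed = sample.int(1e9, 1)),
    random_tree = ranger::ranger(x = df, y = yf, probability = TRUE,
                                 num.trees = 1L, splitrule = "extratrees",
                                 num.random.splits = 1L, replace = FALSE,
                                 sample.fraction = 1,
                                 mtry = max(1L, floor(sqrt(ncol(X)))),
                                 seed = sample.int(1e9, 1)),
    pruned_tree = {
      m <- rpart::rpart(y ~ ., data = cbind(df, y = yf), method = "class",
                        control = rpart::rpart.control(cp = 0, xval = 10))
      cp <- m$cptable
      best <- cp[which.min(cp[, "xerror"]), "CP"]
      rpart::prune(m, cp = best)
    })
}

predict_member <- function(member, model, X) {
  df <- as.data.frame(X)
  switch(member,
    naive_bayes = predict(model, df, type = "raw")[, "essential"],
    svm_linear = {
      p <- predict(model, X, probability = TRUE)
      attr(p, "probabilities")[, "essential"]
    },
    tree_info = predict(model, df, type = "prob")[, "essential"],
    logistic_ridge = {
      if (inherits(model, "glmnet")) {
        as.numeric(predict(model, X, type = "response"))
      } else {
        as.numeric(predict(model, df, type = "response"))
      }
    },
    random_forest = predict(model, data = df)$predictions[, "essential"],
    random_tree = predict(model, data = df)$predictions[, "essential"],
    pruned_tree = predict(model, df, type = "prob")[, "essential"])
}

#' Fit and apply the voting classifier
#'
#' `fit_classifier()` trains every ensemble member; `predict_classifier()`
#' returns the unweighted average of the members' predicted probabilities
#' of the positive (essential) class. Class is called at probability 0.5.
#'
#' @param clf A [make_hybrid_classifier()] specification.
#' @param X Numeric feature matrix.
#' @param y Logical labels (`TRUE` = essential).
#' @param seed Seed controlling the stochastic members.
#' @return `fit_classifier()` returns a fitted ensemble; applying
#'   `predict_classifier()` to it yields a numeric probability vector.
#' @export
fit_classifier <- function(clf, X, y, seed = 1L) {
  stopifnot(inherits(clf, "hybrid_classifier"))
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  set.seed(seed)
  models <- lapply(clf$members, function(m) fit_member(m, X, y, clf$num_trees))
  structure(list(spec = clf, models = setNames(models, clf$members),
                 features = colnames(X)),
            class = "fitted_hybrid_classifier")
}

#' @rdname fit_classifier
#' @param fit A fitted ensemble from `fit_classifier()`.
#' @export
predict_classifier <- function(fit, X) {
  stopifnot(inherits(fit, "fitted_hybrid_classifier"))
  X <- X[, fit$features, drop = FALSE]
  probs <- vapply(names(fit$models),
                  function(m) as.numeric(predict_member(m, fit$models[[m]], X)),
                  numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' Repeated stratified cross-validation of the voting classifier
#'
#' Splits the dataset into `k` stratified folds (fold sizes differ by at
#' most one within each class), trains on `k - 1` folds and scores the
#' held-out fold, pools the held-out predictions over folds (micro
#' averaging), and repeats the whole procedure `n_runs` times with fresh
#' fold assignments; reported metrics are the average over runs.
#'
#' @param clf A [make_hybrid_classifier()].
#' @param dataset A [labeled_dataset()] containing both classes, with at
#'   least `k` members per class.
#' @param k Number of folds (default 10).
#' @param n_runs Number of repeated runs (default 10).
#' @param seed Master seed.
#' @return An `evaluation_report` (see [compute_metrics()]) with metrics
#'   averaged over runs and the confusion counts summed over runs.
#' @export
cross_validate <- function(clf, dataset, k = 10L, n_runs = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"), k >= 2, n_runs >= 1)
  n_pos <- sum(dataset$y); n_neg <- sum(!dataset$y)
  if (min(n_pos, n_neg) < k)
    stop(sprintf("need at least k = %d members per class for stratified %d-fold CV", k, k))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs * 2L)
  reports <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[2 * r - 1])
    folds <- integer(length(dataset$y))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(dataset$y == cls)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    scores <- numeric(length(dataset$y))
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- fit_classifier(clf, dataset$X[!test, , drop = FALSE],
                            dataset$y[!test],
                            seed = run_seeds[2 * r])
      scores[test] <- predict_classifier(fit, dataset$X[test, , drop = FALSE])
    }
    pred <- scores >= 0.5
    confusion <- c(TP = sum(pred & dataset$y), FP = sum(pred & !dataset$y),
                   FN = sum(!pred & dataset$y), TN = sum(!pred & !dataset$y))
    reports[[r]] <- compute_metrics(confusion, scores, dataset$y)
  }
  avg <- function(field) mean(vapply(reports, `[[`, 0, field))
  p <- avg("precision"); rc <- avg("recall")
  structure(
    list(tp_rate = avg("tp_rate"), precision = p,
         recall = rc,
         # harmonic mean of the report's own averaged precision and recall,
         # keeping the report internally consistent
         f_measure = if (p + rc == 0) 0 else 2 * p * rc / (p + rc),
         mcc = avg("mcc"), auc = avg("auc"),
         confusion = Reduce(`+`, lapply(reports, `[[`, "confusion")),
         n_runs = n_runs,
         degenerate = any(vapply(reports, `[[`, TRUE, "degenerate"))),
    class = "evaluation_report")
}
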