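# Incremental classifier evaluation of ranked feature subsets:
# stratified 5-fold cross-validation, KNN (k = 3) and linear SVM,
# macro-averaged multi-class metrics pooled over folds.

#' Macro-averaged multi-class metrics from a confusion matrix
#'
#' Treats each class in turn as positive and the rest as negative and
#' averages uniformly over classes:
#' accuracy `= (1/M) sum (TPi + TNi) / (TPi + TNi + FPi + FNi)`,
#' precision `= (1/M) sum TPi / (TPi + FPi)`,
#' recall `= (1/M) sum TPi / (TPi + FNi)`,
#' `F = 2 P R / (P + R)`. Per-class terms with a zero denominator
#' contribute 0. The standard overall accuracy (`trace / total`) is
#' reported alongside, since published tables may use either convention.
#'
#' @param cm square confusion matrix, rows = true classes,
#'   columns = predicted classes.
#' @return Named list `accuracy_macro`, `accuracy_overall`, `precision`,
#'   `recall`, `f_measure`, all in `[0, 1]`.
#' @export
multiclass_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2)
    stop("cm must be a square matrix with at least 2 classes")
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix")
  M <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  acc_macro <- mean(safe(tp + tn, tp + tn + fp + fn))
  precision <- mean(safe(tp, tp + fp))
  recall <- mean(safe(tp, tp + fn))
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(accuracy_macro = acc_macro, accuracy_overall = sum(tp) / total,
       precision = precision, recall = recall, f_measure = f)
}

# Stratified fold assignment: within each class, windows are shuffled
# and dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  labels <- factor(labels)
  counts <- table(labels)
  short <- names(counts)[counts < folds]
  if (length(short))
    stop("class(es) with fewer windows than folds: ",
         paste(short, collapse = ", "))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Cross-validated evaluation of incrementally grown feature subsets
#'
#' For each subset size `s`, trains each classifier on the top-`s`
#' ranked features of the training folds and predicts the held-out fold;
#' predictions are pooled over the `folds` folds into one confusion
#' matrix per (size, classifier), from which the macro metrics are
#' computed. Folds are stratified by class and fully determined by
#' `seed`. Classifiers: `"knn"` (k-nearest neighbours, `k = 3`) and
#' `"svm"` (support vector machine, linear kernel, cost 1, one-vs-one
#' multi-class). Classifiers consume the continuous (normalized)
#' features; discretised features are only used by the selector.
#'
#' @param features numeric feature matrix (windows x features),
#'   typically normalized; a `har_features` object supplies its own
#'   labels.
#' @param ranking a `har_ranking` from [jmim_select()].
#' @param subset_sizes integer vector of subset sizes to evaluate
#'   (default `c(1, 10, 30, 60, 120, 193)` capped at the feature count).
#' @param classifiers character subset of `c("svm", "knn")`.
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param labels class labels per window; defaults to
#'   `attr(features, "labels")`.
#' @return An object of class `har_curve`: a data.frame with columns
#'   `size`, `classifier`, `accuracy_macro`, `accuracy_overall`,
#'   `precision`, `recall`, `f_measure`; pooled confusion matrices are
#'   kept in the `confusions` attribute.
#' @export
cross_validate <- function(features, ranking, subset_sizes = NULL,
                           classifiers = c("svm", "knn"), folds = 5,
                           seed = 42, labels = NULL) {
  labels <- labels %||% attr(features, "labels")
  if (is.null(labels)) stop("labels are required")
  labels <- factor(labels)
  X <- unclass(features)
  attr(X, "labels") <- NULL; attr(X, "groups") <- NULL
  p <- ncol(X)
  subset_sizes <- sort(unique(pmin(subset_sizes %||%
                                     c(1, 10, 30, 60, 120, 193), p)))
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  fold_of <- stratified_folds(labels, folds, seed)
  res <- list()
  confusions <- list()
  for (s in subset_sizes) {
    cols <- ranking$order[seq_len(s)]
    Xs <- X[, cols, drop = FALSE]
    for (clf in classifiers) {
      pred <- factor(rep(NA_character_, nrow(Xs)), levels = levels(labels))
      for (f in seq_len(folds)) {
        tr <- fold_of != f
        pred[!tr] <- fit_predict(clf, Xs[tr, , drop = FALSE], labels[tr],
                                 Xs[!tr, , drop = FALSE])
      }
      cm <- table(true = labels, predicted = pred)
      met <- multiclass_metrics(cm)
      res[[length(res) + 1L]] <- data.frame(
        size = s, classifier = clf,
        accuracy_macro = met$accuracy_macro,
        accuracy_overall = met$accuracy_overall,
        precision = met$precision, recall = met$recall,
        f_measure = met$f_measure, stringsAsFactors = FALSE)
      confusions[[paste(clf, s, sep = "_")]] <- cm
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("har_curve", class(out))
  attr(out, "confusions") <- confusions
  out
}

fit_predict <- function(classifier, Xtr, ytr, Xte, knn_k = 3, svm_cost = 1) {
  if (classifier == "knn") {
    class::knn(Xtr, Xte, cl = ytr, k = knn_k)
  } else {
    fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = svm_cost,
                      scale = FALSE)
    predict(fit, Xte)
  }
}

#' Ablation of the regularity-sensitive ("uncommon") feature group
#'
#' Evaluates the full feature matrix against the matrix with the
#' uncommon features (RQA, permutation entropy, Lyapunov exponent, THD;
#' see [uncommon_features()]) removed, re-ranking each set with JMIM,
#' and reports the accuracy difference (with minus without). A positive
#' gain means regularity information adds discriminative power.
#'
#' @param features a `har_features` matrix (normalized recommended).
#' @param discretised matching `har_discretised` object for the
#'   selector; defaults to `discretise_ewd(features, n_bins)`.
#' @param classifier `"svm"` (default) or `"knn"`.
#' @param subset_size number of top-ranked features to evaluate per set;
#'   default: all features of the set.
#' @param folds,seed cross-validation controls.
#' @param n_bins bins for the default discretisation.
#' @param labels class labels; default from `features`.
#' @return List with `with` and `without` (each a `har_curve` row),
#'   `gain_accuracy_macro`, `gain_accuracy_overall`, `gain_f_measure`.
#' @export
ablate_uncommon <- function(features, discretised = NULL,
                            classifier = "svm", subset_size = NULL,
                            folds = 5, seed = 42, n_bins = 10,
                            labels = NULL) {
  labels <- labels %||% attr(features, "labels")
  uncommon <- intersect(uncommon_features(), colnames(features))
  keep <- setdiff(colnames(features), uncommon)
  run_one <- function(cols) {
    Xs <- features[, cols, drop = FALSE]
    D <- discretise_ewd(Xs, n_bins)
    rk <- jmim_select(D, labels)
    s <- min(subset_size %||% length(cols), length(cols))
    cross_validate(Xs, rk, subset_sizes = s, classifiers = classifier,
                   folds = folds, seed = seed, labels = labels)
  }
  with_all <- run_one(colnames(features))
  without <- run_one(keep)
  list(with = with_all, without = without,
       gain_accuracy_macro = with_all$accuracy_macro - without$accuracy_macro,
       gain_accuracy_overall = with_all$accuracy_overall -
         without$accuracy_overall,
       gain_f_measure = with_all$f_measure - without$f_measure)
}
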