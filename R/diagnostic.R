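# Two-gene diagnostic classifier: a least-squares support vector machine
# (LS-SVM) over (anchor, candidate) expression, evaluated by stratified
# cross-validated ROC AUC, plus the empirical anchor-expression threshold
# below which every sample is a case.

kernel_matrix <- function(x, z, kernel, sigma) {
  if (kernel == "linear") return(x %*% t(z))
  # RBF: exp(-||x - z||^2 / (2 sigma^2))
  d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * x %*% t(z)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

median_heuristic <- function(x) {
  d <- as.numeric(stats::dist(x))
  s <- median(d[d > 0])
  if (!is.finite(s) || s == 0) 1 else s
}

#' Fit the two-gene margin classifier
#'
#' Trains a least-squares SVM (Suykens' LS-SVM: equality-constrained SVM
#' solved as one linear system) on a two-column feature matrix. The decision
#' function maps a 2-vector of expression values to a real score, higher =
#' more case-like. Features are used on the log2 scale without
#' re-standardization so thresholds stay in expression units. The RBF
#' bandwidth defaults to the median pairwise distance heuristic.
#'
#' @param features Numeric matrix, samples x 2 (anchor, candidate).
#' @param labels Character/factor of `case`/`control` (aliases accepted).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C Regularization constant (> 0); larger fits the training data
#'   harder.
#' @param sigma RBF bandwidth; `NULL` = median heuristic.
#' @return An object of class `diagnostic_model` with a `predict` method
#'   returning decision scores.
#' @export
fit_classifier <- function(features, labels, kernel = c("rbf", "linear"),
                           C = 1, sigma = NULL) {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  if (ncol(features) != 2) stop_invalid("exactly 2 feature genes required")
  if (any(!is.finite(features))) stop_invalid("non-finite feature values")
  labels <- normalize_group(labels)
  if (length(labels) != nrow(features)) stop_invalid("labels/features mismatch")
  if (nrow(features) < 4) stop_invalid("need >= 4 training samples")
  if (length(unique(labels)) < 2) {
    stop_invalid("training data contains a single class")
  }
  y <- ifelse(labels == "case", 1, -1)
  n <- nrow(features)
  if (kernel == "rbf" && is.null(sigma)) sigma <- median_heuristic(features)
  K <- kernel_matrix(features, features, kernel, sigma)
  # LS-SVM dual system with bias:  [0 1'; 1 K + I/C] [b; a] = [0; y]
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- solve(A, c(0, y))
  model <- structure(list(kernel = kernel, C = C, sigma = sigma,
                          alpha = sol[-1L], b = sol[1L],
                          x_train = features,
                          feature_genes = colnames(features),
                          n = n, n_case = sum(y == 1),
                          n_control = sum(y == -1)),
                     class = "diagnostic_model")
  model$train_accuracy <- mean((predict(model, features) > 0) == (y > 0))
  model
}

#' @param object A `diagnostic_model`.
#' @param newdata Matrix (or 2-vector) of feature values.
#' @param ... Unused.
#' @return Numeric decision scores, higher = more case-like.
#' @rdname fit_classifier
#' @export
predict.diagnostic_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 2)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != 2) stop_invalid("newdata must have 2 columns")
  K <- kernel_matrix(newdata, object$x_train, object$kernel, object$sigma)
  as.numeric(K %*% object$alpha + object$b)
}

#' @export
print.diagnostic_model <- function(x, ...) {
  cat("diagnostic_model (LS-SVM, ", x$kernel, " kernel): ", x$n,
      " samples (", x$n_case, " case / ", x$n_control, " control), ",
      "training accuracy ", format(x$train_accuracy, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: the probability that a random case scores above
#' a random control, with ties counting one half. Invariant under strictly
#' increasing transforms of the scores; constant scores give 0.5.
#'
#' @param scores Numeric decision scores.
#' @param labels `case`/`control` labels (aliases accepted).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- normalize_group(labels)
  pos <- scores[labels == "case"]
  neg <- scores[labels == "control"]
  if (!length(pos) || !length(neg)) stop_invalid("need both classes for AUC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Stratified train/test split
#'
#' Randomly assigns samples to a training and a test set, stratified by
#' class, with per-class training sizes `round(train_fraction * n_class)`.
#'
#' @param labels `case`/`control` labels (aliases accepted), optionally named
#'   by sample id.
#' @param train_fraction Fraction assigned to training (default 0.6).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(labels, train_fraction = 0.6, seed = 1) {
  labels <- normalize_group(labels)
  check_scalar_number(train_fraction, "train_fraction", 0, 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  if (length(labels) < 5) stop_invalid("need >= 5 samples to split")
  if (min(table(labels)) < 2) stop_invalid("each class needs >= 2 samples")
  with_seed(seed, {
    train <- integer(0)
    for (cl in c("control", "case")) {
      idx <- which(labels == cl)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Cross-validated ROC AUC of the two-gene classifier
#'
#' Stratified k-fold cross-validation: for each fold the classifier is
#' trained on the remaining folds and its decision scores on the held-out
#' fold are summarized as a rank-based AUC. The mean of the k AUC values is
#' the headline performance figure.
#'
#' @param features Samples x 2 expression matrix.
#' @param labels `case`/`control` labels.
#' @param k Number of folds (default 10); each class must have >= k samples.
#' @param seed Integer seed for the fold assignment.
#' @inheritParams fit_classifier
#' @return A list of class `cv_report`: `auc_values` (length k), `mean_auc`,
#'   `scheme`, `seed`.
#' @export
cv_auc <- function(features, labels, k = 10, seed = 1,
                   kernel = c("rbf", "linear"), C = 1) {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  labels <- normalize_group(labels)
  check_count(k, "k", min = 2L)
  tab <- table(labels)
  if (length(tab) < 2) stop_invalid("need both classes")
  if (min(tab) < k) {
    stop_invalid("smallest class has ", min(tab), " samples < k = ", k,
                 "; use a smaller k")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  aucs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    model <- fit_classifier(features[tr, , drop = FALSE], labels[tr],
                            kernel = kernel, C = C)
    roc_auc(predict(model, features[!tr, , drop = FALSE]), labels[!tr])
  }, numeric(1))
  structure(list(auc_values = aucs, mean_auc = mean(aucs),
                 scheme = sprintf("stratified %d-fold CV (%s kernel, C=%g)",
                                  k, kernel, C),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report: ", x$scheme, "\n  AUC per fold: ",
      paste(sprintf("%.3f", x$auc_values), collapse = " "),
      "\n  mean AUC: ", sprintf("%.3f", x$mean_auc), "\n", sep = "")
  invisible(x)
}

#' Empirical anchor-expression threshold
#'
#' Returns the largest value `t` such that every sample whose anchor
#' expression lies strictly below `t` is a case - that is, the minimum anchor
#' expression observed among controls. If the global minimum on the anchor
#' axis belongs to a control (no case-only region exists), returns `NA`.
#'
#' @param features Samples x 2 matrix whose first column (by default) is the
#'   anchor gene.
#' @param labels `case`/`control` labels.
#' @param axis Column of `features` holding the anchor (default 1).
#' @return The threshold in expression units, or `NA_real_`.
#' @export
anchor_threshold <- function(features, labels, axis = 1) {
  features <- as.matrix(features)
  labels <- normalize_group(labels)
  v <- features[, axis]
  v_ctrl <- v[labels == "control"]
  v_case <- v[labels == "case"]
  if (!length(v_ctrl) || !length(v_case)) stop_invalid("need both classes")
  if (min(v_ctrl) <= min(v_case)) return(NA_real_)
  min(v_ctrl)
}
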