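# Hybrid classification head: per-feature max-abs scaling to [-1, 1], PCA
# (or LDA) dimensionality reduction, then an SVM replacing the dense
# layers of the network.

#' Fit the hybrid PCA/SVM head on extracted features
#'
#' Scaling factors (per-feature maximum absolute value; zero-variance
#' features get factor 1) are fitted on the training features only. PCA is
#' fitted on the scaled features; its axes are ordered by decreasing
#' explained variance and its component vectors are orthonormal. The SVM
#' (one-vs-one multiclass, as in libsvm) is fitted on the projected
#' coordinates. With `projector = "lda"` the projection dimension is capped
#' at `n_classes - 1`.
#'
#' @param features numeric matrix, samples x features (e.g. 32,768-dim
#'   flatten activations from [predict.mst_extractor()]).
#' @param labels class labels over [cell_classes()]; at least two classes
#'   with two samples each.
#' @param k target projection dimension (default 512); silently capped at
#'   `min(n_samples, n_features)` with a warning when the data cannot
#'   support it.
#' @param projector "pca" (default) or "lda".
#' @param kernel SVM kernel, "radial" (default) or "linear".
#' @param cost SVM regularization parameter C, default 1.
#' @return object of class `hybrid_head`.
#' @importFrom e1071 svm
#' @export
fit_head <- function(features, labels, k = 512L,
                     projector = c("pca", "lda"),
                     kernel = c("radial", "linear"), cost = 1) {
  projector <- match.arg(projector)
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  if (k <= 0) stopf("k must be positive, got %d", k)
  if (any(!is.finite(features))) stopf("features contain non-finite values")
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stopf("features rows (%d) and labels (%d) differ", nrow(features), length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stopf("need at least 2 classes, got %d", length(tab))
  if (any(tab < 2L))
    stopf("every class needs >= 2 samples; short: %s",
          paste(names(tab)[tab < 2L], collapse = ", "))
  if (!all(names(tab) %in% cell_classes()))
    stopf("unknown label(s): %s",
          paste(setdiff(names(tab), cell_classes()), collapse = ", "))
  classes <- intersect(cell_classes(), names(tab))
  n <- nrow(features); p <- ncol(features)

  scale_factors <- apply(abs(features), 2L, max)
  scale_factors[scale_factors == 0] <- 1
  xs <- sweep(features, 2L, scale_factors, "/")
  center <- colMeans(xs)

  if (projector == "pca") {
    k_eff <- min(k, n, p)
    if (k_eff < k)
      warnf("k = %d exceeds the data rank bound; using k = %d (min of %d samples, %d features)",
            k, k_eff, n, p)
    xc <- sweep(xs, 2L, center, "-")
    sv <- svd(xc, nu = 0, nv = k_eff)
    components <- sv$v                       # p x k, orthonormal columns
    sdev <- sv$d / sqrt(max(1, n - 1))
  } else {
    k_eff <- min(k, length(classes) - 1L)
    ld <- MASS::lda(xs, grouping = factor(labels, levels = classes))
    components <- ld$scaling[, seq_len(min(k_eff, ncol(ld$scaling))), drop = FALSE]
    k_eff <- ncol(components)
    sdev <- rep(NA_real_, k_eff)
  }

  z <- sweep(xs, 2L, center, "-") %*% components
  fit <- e1071::svm(x = z, y = factor(labels, levels = classes),
                    kernel = kernel, cost = cost, scale = FALSE)
  structure(list(scale_factors = scale_factors, center = center,
                 components = components, projector = projector,
                 sdev = sdev, k = ncol(components), n_features = p,
                 svm = fit, kernel = kernel, cost = cost,
                 classes = classes,
                 train_abs_max = max(abs(features))),
            class = "hybrid_head")
}

#' @export
print.hybrid_head <- function(x, ...) {
  cat(sprintf("<hybrid_head> %s(%d) + %s SVM over %d features; classes: %s\n",
              toupper(x$projector), x$k, x$kernel, x$n_features,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

check_features <- function(head, f) {
  f <- if (is.null(dim(f))) matrix(f, nrow = 1L) else as.matrix(f)
  if (ncol(f) != head$n_features)
    stopf("feature length %d does not match the head's %d", ncol(f), head$n_features)
  # domain check: flatten activations live on the raw feature scale; input
  # that already sits wholly inside [-1, 1] while training features did not
  # has most likely been max-abs scaled twice
  if (head$train_abs_max > 1.5 && max(abs(f)) <= 1)
    stopf("features appear to be already scaled to [-1, 1]; pass raw extractor features")
  f
}

#' Project features into the fitted PCA/LDA space
#'
#' coords = t(components) (scaled(f) - center); deterministic for a fitted
#' head.
#'
#' @param head a `hybrid_head`.
#' @param features vector (one sample) or matrix (samples x features) of raw
#'   extractor features.
#' @return matrix of projected coordinates (samples x k), or a vector for a
#'   single sample.
#' @export
project <- function(head, features) {
  stopifnot(inherits(head, "hybrid_head"))
  single <- is.null(dim(features))
  f <- check_features(head, features)
  xs <- sweep(f, 2L, head$scale_factors, "/")
  z <- sweep(xs, 2L, head$center, "-") %*% head$components
  if (single) drop(z) else z
}

#' Classify features with the hybrid head
#'
#' @param head a `hybrid_head`.
#' @param features vector or matrix of raw extractor features.
#' @return character labels in the fixed class order's vocabulary.
#' @export
classify <- function(head, features) {
  stopifnot(inherits(head, "hybrid_head"))
  single <- is.null(dim(features))
  f <- check_features(head, features)
  z <- project(head, f)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  out <- as.character(predict(head$svm, z))
  if (single) out[[1]] else out
}

#' @export
predict.hybrid_head <- function(object, newdata,
                                type = c("class", "projection"), ...) {
  type <- match.arg(type)
  if (type == "class") classify(object, newdata) else project(object, newdata)
}

#' Confusion-matrix evaluation report
#'
#' Builds the 4x4 confusion matrix (rows = true class, columns = recognized
#' class) and derives per-class recall, precision and F score plus the
#' overall accuracy (trace / total). Percentages are printed half-up to one
#' decimal; full-precision values are stored alongside.
#'
#' @param pred_labels predicted labels.
#' @param true_labels true labels (same length, both over [cell_classes()]).
#' @param classes class order for the matrix; defaults to the fixed order.
#' @return object of class `eval_report` with fields `confusion`,
#'   `recall`, `precision`, `f_score`, `accuracy` (percent, 1 decimal) and
#'   `full` (full-precision proportions).
#' @export
evaluate <- function(pred_labels, true_labels, classes = cell_classes()) {
  pred <- as.character(pred_labels); truth <- as.character(true_labels)
  if (length(pred) != length(truth) || length(pred) == 0L)
    stopf("pred and truth must be nonempty and of equal length")
  bad <- setdiff(unique(c(pred, truth)), classes)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "recognized")
  diagv <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  recall <- ifelse(rs > 0, diagv / rs, NA_real_)
  precision <- ifelse(cs > 0, diagv / cs, NA_real_)
  f <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
              2 * precision * recall / (precision + recall), NA_real_)
  acc <- sum(diagv) / sum(cm)
  structure(list(
    confusion = cm,
    accuracy = round_half_up(100 * acc, 1),
    recall = round_half_up(100 * recall, 1),
    precision = round_half_up(100 * precision, 1),
    f_score = round_half_up(100 * f, 1),
    full = list(accuracy = acc, recall = recall, precision = precision,
                f_score = f),
    n = length(pred)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%%  (n = %d)\n", x$accuracy, x$n))
  cat("Confusion matrix (rows = true, cols = recognized):\n")
  print(x$confusion)
  tab <- data.frame(recall = x$recall, precision = x$precision,
                    f_score = x$f_score)
  print(tab)
  invisible(x)
}

#' Write an evaluation report as CSV files plus a text summary
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$confusion, file.path(dir, "confusion_matrix.csv"))
  mets <- data.frame(class = rownames(report$confusion),
                     recall = report$recall, precision = report$precision,
                     f_score = report$f_score)
  utils::write.csv(mets, file.path(dir, "metrics.csv"), row.names = FALSE)
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}
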