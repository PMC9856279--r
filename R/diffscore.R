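# Differentiation-degree scoring for iPSC-RPEs: the oriented coordinate
# along the single PCA axis that best separates the RPE cluster from the
# iPSC cluster (the clusters fall on opposite sides of zero on that axis),
# with larger oriented coordinates meaning further from the iPSC cluster,
# i.e. a higher differentiation degree.

#' Find the PCA axis separating two classes
#'
#' Searches the leading axes (default 8) for the one maximizing the
#' absolute standardized mean difference |mu_target - mu_ref| / pooled sd
#' between the two classes, and orients it so the target-class centroid is
#' positive and the reference (iPSC) centroid negative. Also reports the
#' fraction of samples correctly sided by the sign-at-zero rule.
#'
#' @param projections matrix of projected coordinates (samples x k) from
#'   [project()].
#' @param labels class labels for the rows.
#' @param ref_class reference class (default "IPSC").
#' @param target_class target class (default "RPE").
#' @param n_axes number of leading axes searched, default 8.
#' @return object of class `separating_axis`: `axis_index` (0-based, axes
#'   ordered by explained variance), `orientation` (+1/-1), `threshold`
#'   (0), `separation` (the standardized mean difference), `sided_fraction`,
#'   `class_pair`.
#' @export
find_separating_axis <- function(projections, labels, ref_class = "IPSC",
                                 target_class = "RPE", n_axes = 8L) {
  projections <- as.matrix(projections)
  labels <- as.character(labels)
  stopifnot(nrow(projections) == length(labels))
  for (cl in c(ref_class, target_class))
    if (sum(labels == cl) < 2L)
      stopf("class '%s' needs >= 2 samples in the projections", cl)
  a <- projections[labels == ref_class, , drop = FALSE]
  b <- projections[labels == target_class, , drop = FALSE]
  kk <- min(n_axes, ncol(projections))
  sep <- numeric(kk)
  for (j in seq_len(kk)) {
    pooled <- sqrt((stats::var(a[, j]) * (nrow(a) - 1) +
                    stats::var(b[, j]) * (nrow(b) - 1)) /
                   (nrow(a) + nrow(b) - 2))
    sep[j] <- abs(mean(b[, j]) - mean(a[, j])) / max(pooled, 1e-12)
  }
  jbest <- which.max(sep)
  orientation <- if (mean(b[, jbest]) >= mean(a[, jbest])) 1 else -1
  sided <- mean(c(orientation * a[, jbest] < 0, orientation * b[, jbest] > 0))
  if (sided < 0.75)
    warnf("low separation on axis %d: only %.0f%% of samples sided correctly",
          jbest - 1L, 100 * sided)
  structure(list(axis_index = jbest - 1L, orientation = orientation,
                 threshold = 0, separation = sep[jbest],
                 sided_fraction = sided,
                 class_pair = c(ref = ref_class, target = target_class)),
            class = "separating_axis")
}

#' @export
print.separating_axis <- function(x, ...) {
  cat(sprintf("<separating_axis> dim %d (0-based), orientation %+d, SMD %.2f, sided %.1f%% (%s vs %s)\n",
              x$axis_index, x$orientation, x$separation,
              100 * x$sided_fraction, x$class_pair["ref"], x$class_pair["target"]))
  invisible(x)
}

#' Score samples by their oriented separating-axis coordinate
#'
#' The continuous oriented coordinate is the differentiation-degree score:
#' larger = further from the iPSC cluster = more differentiated. Samples
#' are ranked by descending score with a deterministic tie-break on
#' `sample_id`.
#'
#' @param axis a `separating_axis` from [find_separating_axis()].
#' @param projections matrix (samples x k) of target-class projections.
#' @param sample_ids character ids for the rows; defaults to rownames or
#'   "sample_1"...
#' @return data.frame (sample_id, coordinate, rank), sorted by rank.
#' @export
score_samples <- function(axis, projections, sample_ids = NULL) {
  stopifnot(inherits(axis, "separating_axis"))
  projections <- as.matrix(projections)
  if (axis$axis_index + 1L > ncol(projections))
    stopf("projections have only %d dims; axis %d requested",
          ncol(projections), axis$axis_index)
  n <- nrow(projections)
  if (is.null(sample_ids))
    sample_ids <- rownames(projections) %||% sprintf("sample_%d", seq_len(n))
  coord <- axis$orientation * projections[, axis$axis_index + 1L]
  ord <- order(-coord, sample_ids)
  out <- data.frame(sample_id = sample_ids[ord], coordinate = coord[ord],
                    rank = seq_len(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach scores and rank-prefixed names to a manifest
#'
#' Emits a copy of the manifest's target-class rows with a `score` column
#' and a `ranked_name` column whose zero-padded rank prefix makes
#' lexicographic order equal differentiation order. Original files are
#' untouched.
#'
#' @param scores data.frame from [score_samples()].
#' @param manifest data.frame with at least `id` and `label` columns
#'   (as written by [write_dataset()]).
#' @param target_class rows to rename, default "RPE".
#' @return the renamed manifest rows (possibly empty), ordered by rank.
#' @export
rename_manifest <- function(scores, manifest, target_class = "RPE") {
  rows <- manifest[manifest$label == target_class, , drop = FALSE]
  if (nrow(rows) == 0L) {
    rows$score <- numeric(0)
    rows$rank <- integer(0)
    rows$ranked_name <- character(0)
    return(rows)
  }
  m <- match(rows$id, scores$sample_id)
  if (anyNA(m))
    stopf("scores missing for manifest id(s): %s",
          paste(rows$id[is.na(m)], collapse = ", "))
  rows$score <- scores$coordinate[m]
  rows$rank <- scores$rank[m]
  width <- nchar(as.character(nrow(scores)))
  rows$ranked_name <- sprintf("%0*d_%s", width, rows$rank, rows$id)
  rows[order(rows$rank), , drop = FALSE]
}
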