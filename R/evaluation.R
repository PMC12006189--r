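# Evaluation: confusion-derived metrics, cross-validation fold plans,
# bootstrap confidence intervals, Mann-Whitney U validation of the fused
# connectivity, and group-average connectivity maps.

#' Confusion counts from predictions and labels
#'
#' Class 1 is the positive class.
#'
#' @param predictions,labels Integer vectors of 0/1 of equal length.
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (any(!predictions %in% c(0, 1)) || any(!labels %in% c(0, 1)))
    stop("predictions and labels must be 0/1")
  list(TP = sum(predictions == 1 & labels == 1),
       TN = sum(predictions == 0 & labels == 0),
       FP = sum(predictions == 1 & labels == 0),
       FN = sum(predictions == 0 & labels == 1))
}

#' Accuracy, recall and precision from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`. A metric with a zero denominator is
#' reported as `NA` (undefined), not as 0.
#'
#' @param counts List with non-negative `TP`, `TN`, `FP`, `FN` summing to
#'   more than 0.
#' @return List with `accuracy`, `recall`, `precision`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
    total <- TP + TN + FP + FN
    if (total == 0) stop("confusion counts sum to zero")
    list(accuracy = (TP + TN) / total,
         recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
         precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_)
  })
}

#' Cross-validation fold plan
#'
#' Near-equal-size folds, seeded. In subject mode all samples of one
#' subject land in the same fold, which avoids leaking subject identity
#' across the split; the default segment mode treats every segment as an
#' independent sample.
#'
#' @param labels Per-sample class labels (only used for sizing).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param subjects Optional per-sample subject ids; when given, folds are
#'   assigned per subject.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
make_folds <- function(labels, k = 5, seed = 1L, subjects = NULL) {
  n <- length(labels)
  if (n < k) stop("need at least k samples")
  if (is.null(subjects)) {
    with_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    if (length(subjects) != n) stop("subjects must match labels in length")
    us <- unique(subjects)
    if (length(us) < k) stop("need at least k subjects for subject folds")
    sf <- with_seed(seed, sample(rep_len(seq_len(k), length(us))))
    sf[match(subjects, us)]
  }
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples (prediction, label) pairs with replacement `n_boot` times and
#' reports the percentile interval of the metric.
#'
#' @param predictions,labels 0/1 vectors (at least 2 samples).
#' @param metric One of "accuracy", "recall", "precision".
#' @param n_boot Number of resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List with `point`, `lo`, `hi`, `n_boot`, `level`.
#' @export
bootstrap_ci <- function(predictions, labels, metric = "accuracy",
                         n_boot = 1000, level = 0.95, seed = 1L) {
  if (length(predictions) < 2L) stop("need at least 2 samples")
  metric <- match.arg(metric, c("accuracy", "recall", "precision"))
  point <- classification_metrics(confusion(predictions, labels))[[metric]]
  n <- length(predictions)
  vals <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    classification_metrics(confusion(predictions[idx], labels[idx]))[[metric]]
  }, numeric(1)))
  if (mean(is.na(vals)) > 0.5)
    stop("metric undefined in more than half of the resamples")
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(point = point, lo = qs[1], hi = qs[2], n_boot = n_boot, level = level)
}

#' Mann-Whitney U test on pooled fused-connectivity entries
#'
#' Flattens the upper triangle of every segment's fused connectivity
#' matrix, pools the entries per group, and runs a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test with tie correction and the normal
#' approximation for large samples. A small p-value indicates that the
#' fused connectivity distributions of the two groups differ.
#'
#' @param group_a,group_b Lists of [connectivity_matrix()]s (or plain
#'   matrices), one group each, both non-empty.
#' @return List with `U` (statistic for the first group), `p` (two-sided)
#'   and the pooled sample sizes.
#' @export
mann_whitney_connectivity <- function(group_a, group_b) {
  pool <- function(ms) {
    if (length(ms) == 0L) stop("both groups must be non-empty")
    unlist(lapply(ms, function(m) {
      v <- if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)
      v[upper.tri(v)]
    }))
  }
  x <- pool(group_a)
  y <- pool(group_b)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1,
                n1 = length(x), n2 = length(y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Group-average connectivity matrices
#'
#' Elementwise mean of the connectivity matrices of each group, e.g. for
#' rendering group-level brain-network maps.
#'
#' @param matrices_by_group Named list of non-empty lists of
#'   [connectivity_matrix()]s.
#' @return Named list of [connectivity_matrix()]s.
#' @export
group_average_connectivity <- function(matrices_by_group) {
  lapply(matrices_by_group, function(ms) {
    if (length(ms) == 0L) stop("empty group")
    kind <- if (inherits(ms[[1]], "connectivity_matrix")) ms[[1]]$kind else "PCOH"
    vals <- Reduce(`+`, lapply(ms, function(m)
      if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)))
    connectivity_matrix(vals / length(ms), kind = kind)
  })
}
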