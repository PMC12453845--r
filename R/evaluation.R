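# Confusion-matrix metrics and grouped stratified cross-validation.
#
# The positive class is cancer throughout. Five scores are derived from the
# confusion matrix: accuracy, sensitivity (recall), specificity, precision
# and F1 (the harmonic mean of precision and sensitivity). Degenerate 0/0
# ratios yield 0 with a flag instead of an error, so fold aggregation never
# crashes on an empty cell.

#' Confusion matrix of cancer/normal predictions
#'
#' @param y_true,y_pred Character vectors of labels (`cancer` / `normal`,
#'   case-insensitive), equal length.
#' @return A list of class `confusion_matrix` with counts `tp`, `tn`, `fp`,
#'   `fn` (positive class = cancer).
#' @export
confusion <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred),
              "y_true and y_pred must have equal length", "cxrcad_validation_error")
  y_true <- canonical_label(y_true)
  y_pred <- canonical_label(y_pred)
  structure(
    list(
      tp = sum(y_true == "cancer" & y_pred == "cancer"),
      tn = sum(y_true == "normal" & y_pred == "normal"),
      fp = sum(y_true == "normal" & y_pred == "cancer"),
      fn = sum(y_true == "cancer" & y_pred == "normal")
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Derived classification metrics
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1
#' `2 * precision * sensitivity / (precision + sensitivity)`. A 0/0 ratio
#' returns the 0 sentinel and sets `degenerate = TRUE`.
#'
#' @param cm A [confusion()] object, or a list/vector with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, `degenerate`.
#' @examples
#' compute_metrics(list(tp = 80, fn = 20, tn = 70, fp = 30))
#' @export
compute_metrics <- function(cm) {
  cm <- as.list(cm)
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  total <- tp + tn + fp + fn
  assert_that(total >= 1, "confusion matrix must contain at least one case")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  degenerate <- anyNA(c(sens, spec, prec, f1))
  tibble::tibble(
    accuracy = (tp + tn) / total,
    sensitivity = sens %|0|% 0,
    specificity = spec %|0|% 0,
    precision = prec %|0|% 0,
    f1 = f1 %|0|% 0,
    degenerate = degenerate
  )
}

# NA -> 0 sentinel
#' @noRd
`%|0|%` <- function(x, y) if (is.na(x)) y else x

#' Grouped, label-stratified k-fold assignment
#'
#' Partitions image ids into `k` validation folds so that (a) every id
#' appears in exactly one fold, (b) per-fold class proportions match the
#' global proportions to within one image, and (c) all patches of an image
#' follow their image (split on ids, never on patches). Within each label
#' the shuffled ids are dealt round-robin, with the dealing position
#' carried across labels so fold sizes stay balanced.
#'
#' @param manifest Manifest tibble (or any data frame with `id` and
#'   `label`).
#' @param k Number of folds (>= 2).
#' @param seed Shuffle seed; folds are deterministic given the seed.
#' @return A tibble of class `cv_folds` with columns `id`, `label`, `fold`.
#' @export
grouped_stratified_kfold <- function(manifest, k = 10L, seed = 1L) {
  assert_that(k >= 2, "k must be >= 2", "cxrcad_validation_error")
  ids <- as.character(manifest$id)
  labels <- canonical_label(manifest$label)
  assert_that(length(ids) >= k, sprintf("need at least k = %d images, have %d", k, length(ids)),
              "cxrcad_validation_error")
  for (lab in unique(labels)) {
    assert_that(sum(labels == lab) >= 1, sprintf("label %s absent", lab))
  }
  out <- with_seed(seed, {
    fold <- integer(length(ids))
    pos <- 0L
    for (lab in sort(unique(labels))) {
      where <- which(labels == lab)
      shuffled <- where[sample.int(length(where))]
      fold[shuffled] <- ((pos + seq_along(shuffled) - 1L) %% k) + 1L
      pos <- pos + length(shuffled)
    }
    tibble::tibble(id = ids, label = labels, fold = fold)
  })
  class(out) <- c("cv_folds", class(out))
  out
}

#' Train/validation id pairs of a fold assignment
#'
#' @param folds A `cv_folds` tibble from [grouped_stratified_kfold()].
#' @return A list of length `k`; element `i` is
#'   `list(train = ids, val = ids)` for fold `i` as the validation fold.
#' @export
fold_splits <- function(folds) {
  purrr::map(sort(unique(folds$fold)), function(f) {
    list(train = folds$id[folds$fold != f], val = folds$id[folds$fold == f])
  })
}

#' Aggregate patch predictions into one image-level diagnosis
#'
#' The mean rule averages patch cancer probabilities and diagnoses cancer
#' when the mean is at least 0.5; the majority rule counts patch votes.
#' Ties resolve to cancer (screening errs toward the positive class).
#'
#' @param patch_probs Numeric vector of per-patch cancer probabilities.
#' @param rule `"mean"` (default) or `"majority"`.
#' @return A list with `probability` (mean cancer probability) and `label`.
#' @examples
#' aggregate_image(c(0.4, 0.45, 0.8)) # mean 0.55 -> cancer
#' @export
aggregate_image <- function(patch_probs, rule = c("mean", "majority")) {
  rule <- match.arg(rule)
  if (length(patch_probs) == 0) {
    abort("no patch probabilities to aggregate (image lost all patches)",
          class = "cxrcad_aggregation_error")
  }
  p <- mean(patch_probs)
  label <- if (rule == "mean") {
    if (p >= 0.5) "cancer" else "normal"
  } else {
    votes_cancer <- sum(patch_probs >= 0.5)
    if (votes_cancer >= length(patch_probs) - votes_cancer) "cancer" else "normal"
  }
  list(probability = p, label = label)
}
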