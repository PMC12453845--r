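# End-to-end cross-validated evaluation of the pipeline.
#
# Folds partition images (never patches): every patch follows its parent
# image, so overlapping patches of one radiograph can never appear on both
# sides of a split. Patch extraction and t-test selection depend only on
# the patch itself, so they are computed once; training and prediction run
# per fold.

#' Cross-validate the patch pipeline
#'
#' For each fold: train the classifier on the (selected) patches of the
#' training images, predict the validation patches, and score both at the
#' patch level and — after aggregating each validation image's patch
#' probabilities — at the full-image level. If selection removes every
#' patch of some image, that image is scored over its pre-selection patches
#' with a warning (no image is silently dropped).
#'
#' @param images Named list of [chest_image] objects, or a manifest tibble
#'   (loaded via [load_cohort()]).
#' @param patch_cfg A [patch_config].
#' @param selection `"ttest"` (default), `"threshold"` or `"none"`.
#' @param selection_cfg A [selection_config] (t-test selector).
#' @param model_cfg A [model_config].
#' @param hyper A [train_config]; its `seed` is re-derived per fold.
#' @param k Number of folds.
#' @param seed Master seed for fold assignment and per-fold training.
#' @param aggregation Image-level rule, `"mean"` or `"majority"`.
#' @param quiet Suppress progress messages.
#' @return A `cv_report`: per-fold metrics at both levels, mean and sample
#'   standard deviation across folds, the full configuration, and the
#'   selection statistics. See [tidy.cv_report()], [glance.cv_report()],
#'   [autoplot.cv_report()].
#' @export
cross_validate <- function(images,
                           patch_cfg = patch_config(),
                           selection = c("ttest", "threshold", "none"),
                           selection_cfg = selection_config(),
                           model_cfg = model_config(),
                           hyper = train_config(),
                           k = 10L, seed = 1L,
                           aggregation = c("mean", "majority"),
                           quiet = TRUE) {
  selection <- match.arg(selection)
  aggregation <- match.arg(aggregation)
  if (is.data.frame(images)) images <- load_cohort(images)
  manifest <- tibble::tibble(
    id = purrr::map_chr(images, "id"),
    label = purrr::map_chr(images, "label")
  )
  folds <- grouped_stratified_kfold(manifest, k = k, seed = seed)

  patches <- extract_cohort_patches(images, patch_cfg)
  sel_stats <- NULL
  selected <- switch(selection,
    ttest = {
      sel <- select_patches(patches, selection_cfg, quiet = quiet)
      # keep the numeric stats only: the pixel crops would dominate the
      # report's memory footprint
      sel_stats <- sel$stats[setdiff(names(sel$stats), c("pixels", "mask"))]
      sel$retained
    },
    threshold = threshold_select(patches),
    none = patches
  )

  fold_rows <- list()
  for (f in sort(unique(folds$fold))) {
    train_ids <- folds$id[folds$fold != f]
    val_ids <- folds$id[folds$fold == f]
    train_patches <- selected[selected$parent_id %in% train_ids, ]
    fold_hyper <- hyper
    fold_hyper$seed <- derive_seed(seed, 1000L + f)
    model <- build_custom_cnn(model_cfg, init_seed = fold_hyper$seed)
    model <- train_classifier(model, train_patches, fold_hyper)

    # patch level: the selected validation patches
    val_patches <- selected[selected$parent_id %in% val_ids, ]
    patch_pred <- predict(model, val_patches)
    patch_metrics <- compute_metrics(confusion(patch_pred$label, patch_pred$pred_label))

    # image level: aggregate each validation image's patch probabilities,
    # falling back to the pre-selection patches when none survived
    image_rows <- purrr::map(val_ids, function(vid) {
      probs <- patch_pred$p_cancer[patch_pred$parent_id == vid]
      if (length(probs) == 0) {
        warn(sprintf("image '%s' lost all patches to selection; scoring pre-selection patches", vid))
        fallback <- patches[patches$parent_id == vid, ]
        probs <- predict(model, fallback)$p_cancer
      }
      agg <- aggregate_image(probs, aggregation)
      tibble::tibble(id = vid, truth = manifest$label[manifest$id == vid],
                     probability = agg$probability, pred = agg$label)
    }) |> dplyr::bind_rows()
    image_metrics <- compute_metrics(confusion(image_rows$truth, image_rows$pred))

    fold_rows[[length(fold_rows) + 1]] <- dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(fold = f, level = "patch"), patch_metrics),
      dplyr::bind_cols(tibble::tibble(fold = f, level = "image"), image_metrics)
    )
    if (!quiet) {
      message(sprintf("fold %d/%d: patch acc %.3f, image acc %.3f", f, k,
                      patch_metrics$accuracy, image_metrics$accuracy))
    }
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  summary <- fold_metrics |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity", "precision", "f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$level, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")

  structure(
    list(
      fold_metrics = fold_metrics,
      summary = summary,
      selection = selection,
      n_images = length(images),
      n_patches = nrow(patches),
      n_selected = nrow(selected),
      selection_stats = sel_stats,
      config = list(
        patch = unclass(patch_cfg), selection_cfg = unclass(selection_cfg),
        model = unclass(model_cfg), hyper = unclass(hyper),
        k = as.integer(k), seed = as.integer(seed),
        selection = selection, aggregation = aggregation
      ),
      folds = folds
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold CV on %d images, selection = %s (%d/%d patches kept)\n",
    x$config$k, x$n_images, x$selection, x$n_selected, x$n_patches
  ))
  img <- x$summary[x$summary$level == "image", ]
  for (i in seq_len(nrow(img))) {
    cat(sprintf("  image %-12s %.3f ± %.3f\n", img$metric[i], img$mean[i], img$sd[i]))
  }
  invisible(x)
}

#' Tidy per-fold CV metrics
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with one row per fold x level: `fold`, `level`,
#'   `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`,
#'   `degenerate`.
#' @export
tidy.cv_report <- function(x, ...) x$fold_metrics

#' One-row CV summary
#'
#' @param x A `cv_report`.
#' @param level `"image"` (default) or `"patch"`.
#' @param ... Unused.
#' @return One-row tibble of `<metric>_mean` / `<metric>_sd` columns plus
#'   run descriptors.
#' @export
glance.cv_report <- function(x, level = "image", ...) {
  s <- x$summary[x$summary$level == level, ]
  wide <- tidyr::pivot_wider(
    s[c("metric", "mean", "sd")],
    names_from = "metric", values_from = c("mean", "sd"), names_glue = "{metric}_{.value}"
  )
  dplyr::bind_cols(
    tibble::tibble(level = level, k = x$config$k, selection = x$selection,
                   n_images = x$n_images),
    wide
  )
}

#' Plot cross-validated metrics
#'
#' Per-fold values (points) with the across-fold mean and one sample
#' standard deviation (ranges), faceted by evaluation level.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$fold_metrics,
    c("accuracy", "sensitivity", "specificity", "precision", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red", size = 2) +
    ggplot2::stat_summary(
      fun.data = function(v) {
        data.frame(y = mean(v), ymin = mean(v) - sd(v), ymax = mean(v) + sd(v))
      },
      geom = "errorbar", colour = "red", width = 0.25
    ) +
    ggplot2::facet_wrap(~level) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score",
                  title = sprintf("%d-fold CV, selection = %s",
                                  object$config$k, object$selection)) +
    ggplot2::theme_bw()
}

#' Write a CV report to disk
#'
#' Serialises the report as JSON plus a metrics CSV
#' (`fold,level,accuracy,sensitivity,specificity,precision,f1`).
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      summary = report$summary, fold_metrics = report$fold_metrics,
      selection = report$selection, n_images = report$n_images,
      n_patches = report$n_patches, n_selected = report$n_selected,
      config = report$config
    ),
    file.path(dir, "cv_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(
    report$fold_metrics[c("fold", "level", "accuracy", "sensitivity",
                          "specificity", "precision", "f1")],
    file.path(dir, "metrics.csv")
  )
  invisible(dir)
}
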