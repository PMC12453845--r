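# End-to-end pipeline driver: one reproducible configuration in, a full set
# of artifacts out. A thin command-line wrapper around these functions is
# installed at `system.file("scripts", "cxrcad.R", package = "cxrcad")`.

#' Assemble a reproducible run configuration
#'
#' Collects every sub-configuration plus the input manifest and output
#' directory into one serialisable object; a run can be re-executed
#' bit-compatibly from its saved configuration and seed.
#'
#' @param manifest Path to a manifest CSV (see [load_manifest()]).
#' @param out_dir Output directory for all artifacts.
#' @param patch A [patch_config].
#' @param selection `"ttest"`, `"threshold"` or `"none"`.
#' @param selection_cfg A [selection_config].
#' @param model A [model_config].
#' @param hyper A [train_config].
#' @param k Number of CV folds.
#' @param seed Master seed; all stage seeds derive from it.
#' @param aggregation Image-level aggregation rule.
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest, out_dir,
                       patch = patch_config(),
                       selection = c("ttest", "threshold", "none"),
                       selection_cfg = selection_config(),
                       model = model_config(),
                       hyper = train_config(),
                       k = 10L, seed = 1L,
                       aggregation = c("mean", "majority")) {
  structure(
    list(
      manifest = manifest, out_dir = out_dir, patch = patch,
      selection = match.arg(selection), selection_cfg = selection_cfg,
      model = model, hyper = hyper, k = as.integer(k), seed = as.integer(seed),
      aggregation = match.arg(aggregation)
    ),
    class = "run_config"
  )
}

#' Run the full pipeline from a configuration
#'
#' Loads the manifest, extracts and selects patches, trains and evaluates
#' by grouped stratified k-fold CV, and writes all artifacts — the CV
#' report (JSON + CSV), the per-patch selection report, and the exact
#' effective configuration — into `out_dir`.
#'
#' @param config A [run_config].
#' @param quiet Suppress progress messages.
#' @return The `cv_report`, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "cxrcad_pipeline_error", parent = e)
    })
  }
  manifest <- stage("load", load_manifest(config$manifest))
  images <- stage("load", load_cohort(manifest))
  report <- stage("evaluate", cross_validate(
    images,
    patch_cfg = config$patch,
    selection = config$selection,
    selection_cfg = config$selection_cfg,
    model_cfg = config$model,
    hyper = config$hyper,
    k = config$k, seed = config$seed,
    aggregation = config$aggregation,
    quiet = quiet
  ))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cv_report(report, config$out_dir)
  if (!is.null(report$selection_stats)) {
    write_selection_report(report$selection_stats,
                           file.path(config$out_dir, "selection.csv"))
  }
  strip_classes <- function(x) if (is.list(x)) lapply(unclass(x), strip_classes) else x
  jsonlite::write_json(
    strip_classes(config),
    file.path(config$out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  if (!quiet) print(report)
  invisible(report)
}

#' Compare patch-selection strategies under paired seeds
#'
#' Runs the cross-validated pipeline once per selection strategy on the
#' same images with the same master seed, so fold assignments and training
#' initialisation are paired and differences are attributable to the
#' selection stage alone.
#'
#' @param images Named list of [chest_image] objects (or a manifest
#'   tibble).
#' @param selections Character vector of strategies to compare.
#' @param ... Passed to [cross_validate()] (configs, `k`, `seed`, ...).
#' @return A named list of `cv_report`s, one per strategy, with a
#'   `comparison` attribute: a tibble of image-level mean metrics per
#'   strategy.
#' @export
compare_selections <- function(images,
                               selections = c("ttest", "threshold", "none"),
                               ...) {
  reports <- purrr::map(selections, function(s) {
    cross_validate(images, selection = s, ...)
  })
  names(reports) <- selections
  comparison <- dplyr::bind_rows(purrr::imap(reports, function(r, s) {
    g <- glance(r, level = "image")
    g$selection <- s
    g
  }))
  attr(reports, "comparison") <- comparison
  reports
}
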