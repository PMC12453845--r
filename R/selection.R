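# Patch selection.
#
# A patch is informative when it actually contains lung/non-lung contrast.
# The primary selector runs a two-sample t-test between the patch's lung
# pixels (group 1) and non-lung pixels (group 2) and retains the patch when
# the two-sided p-value falls below 0.003. Patches almost entirely outside
# the lung are discarded without testing; patches almost entirely inside are
# retained without testing (there is no second group to contrast, and fully
# lung tissue is exactly the diagnostically relevant region). A mask-free
# Otsu-thresholding selector is provided as the simpler baseline.

#' Patch selection configuration
#'
#' @param p_threshold Two-sided significance level below which a tested
#'   patch is retained. Default 0.003.
#' @param min_group_fraction Lung-fraction bounds for running the test: a
#'   patch below this fraction is force-discarded, above `1 -` this fraction
#'   force-retained. Default 0.05.
#' @param test_flavor `"welch"` (unequal variances, Welch-Satterthwaite
#'   degrees of freedom; default) or `"pooled"` (classic equal-variance
#'   statistic, df `n1 + n2 - 2`).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 0.003, min_group_fraction = 0.05,
                             test_flavor = c("welch", "pooled")) {
  assert_that(p_threshold > 0 && p_threshold < 1, "p_threshold must be in (0, 1)")
  assert_that(min_group_fraction >= 0 && min_group_fraction < 0.5,
              "min_group_fraction must be in [0, 0.5)")
  structure(
    list(
      p_threshold = p_threshold, min_group_fraction = min_group_fraction,
      test_flavor = match.arg(test_flavor)
    ),
    class = "selection_config"
  )
}

#' Two-sample t-test of equal means
#'
#' Two-sided test. The Welch flavour uses the unequal-variance statistic
#' with Welch-Satterthwaite degrees of freedom; the pooled flavour uses the
#' classic equal-variance statistic with `n1 + n2 - 2` degrees of freedom.
#' Degenerate inputs follow explicit rules: both groups constant with equal
#' means gives `t = 0, p = 1`; constant with unequal means gives an infinite
#' t sentinel and `p = 0`.
#'
#' @param group1,group2 Numeric vectors with at least 2 values each.
#' @param flavor `"welch"` or `"pooled"`.
#' @return A one-row tibble with `t`, `dof`, `p`, `mean1`, `mean2`, `n1`,
#'   `n2`.
#' @examples
#' two_sample_t(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7)) # t = -2, dof = 8
#' @export
two_sample_t <- function(group1, group2, flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) {
    abort("each group needs at least 2 values for a t-test",
          class = "cxrcad_insufficient_data_error")
  }
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (flavor == "welch") {
    se2 <- v1 / n1 + v2 / n2
    dof <- if (se2 > 0) {
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
      n1 + n2 - 2
    }
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    dof <- n1 + n2 - 2
  }
  if (se2 == 0) {
    if (m1 == m2) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(m1 - m2) * Inf; p <- 0
    }
  } else {
    t_stat <- (m1 - m2) / sqrt(se2)
    p <- 2 * pt(-abs(t_stat), df = dof)
  }
  tibble::tibble(t = t_stat, dof = dof, p = p, mean1 = m1, mean2 = m2,
                 n1 = n1, n2 = n2)
}

#' Score one patch by lung / non-lung intensity contrast
#'
#' Splits the patch's pixels by its mask crop into lung (group 1) and
#' non-lung (group 2) and applies [two_sample_t()]. Patches with a lung
#' fraction below `min_group_fraction` are force-discarded without testing;
#' above `1 - min_group_fraction`, force-retained. Otherwise the decision is
#' `retain` iff `p < p_threshold`.
#'
#' @param pixels Patch intensity matrix.
#' @param mask Binary mask crop aligned to the patch.
#' @param config A [selection_config].
#' @return A one-row tibble (`PatchStats`): `t`, `dof`, `p`, `mean_lung`,
#'   `mean_nonlung`, `n_lung`, `n_nonlung`, `lung_fraction`, `decision`
#'   (one of retain / discard / forced_retain / forced_discard).
#' @export
score_patch <- function(pixels, mask, config = selection_config()) {
  assert_that(identical(dim(pixels), dim(mask)),
              "patch and mask crops must be aligned", "cxrcad_alignment_error")
  lf <- mean(mask)
  n <- length(pixels)
  n_lung <- sum(mask == 1)
  base <- tibble::tibble(
    t = NA_real_, dof = NA_real_, p = NA_real_,
    mean_lung = if (n_lung > 0) mean(pixels[mask == 1]) else NA_real_,
    mean_nonlung = if (n_lung < n) mean(pixels[mask == 0]) else NA_real_,
    n_lung = n_lung, n_nonlung = n - n_lung, lung_fraction = lf
  )
  if (lf < config$min_group_fraction) {
    base$decision <- "forced_discard"
  } else if (lf > 1 - config$min_group_fraction) {
    base$decision <- "forced_retain"
  } else {
    tt <- two_sample_t(pixels[mask == 1], pixels[mask == 0], config$test_flavor)
    base$t <- tt$t; base$dof <- tt$dof; base$p <- tt$p
    base$decision <- if (tt$p < config$p_threshold) "retain" else "discard"
  }
  base
}

#' Select informative patches by t-test
#'
#' Applies [score_patch()] to every row of a patch tibble (as produced by
#' [extract_patches()]) and splits retained from discarded patches.
#'
#' @param patches Patch tibble with list-columns `pixels` and `mask`.
#' @param config A [selection_config].
#' @param quiet Suppress the retention-rate message.
#' @return A list with `retained` (patch tibble rows whose decision is
#'   retain/forced_retain, in input order) and `stats` (the patch tibble
#'   with the `PatchStats` columns appended).
#' @export
select_patches <- function(patches, config = selection_config(), quiet = FALSE) {
  if (nrow(patches) == 0) {
    return(list(retained = patches, stats = patches))
  }
  stats <- dplyr::bind_rows(
    purrr::map2(patches$pixels, patches$mask, score_patch, config = config)
  )
  out <- dplyr::bind_cols(
    patches[setdiff(names(patches), c("pixels", "mask"))],
    stats[setdiff(names(stats), "lung_fraction")],
    patches[c("pixels", "mask")]
  )
  kept <- out$decision %in% c("retain", "forced_retain")
  if (!quiet) {
    message(sprintf("retained %d / %d patches (%.1f%%)",
                    sum(kept), nrow(out), 100 * mean(kept)))
  }
  list(retained = out[kept, ], stats = out)
}

#' Otsu's threshold of a grayscale sample
#'
#' Maximises between-class variance over a 256-bin histogram on `[0, 1]`.
#'
#' @param x Numeric vector or matrix of intensities in `[0, 1]`.
#' @param levels Number of histogram bins.
#' @return The threshold intensity, or `NA` if `x` is constant.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.vector(x)
  if (max(x) == min(x)) return(NA_real_)
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1), levels),
                nbins = levels)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  # threshold sits at the upper edge of the chosen bin (midpoint convention)
  breaks[which.max(sb) + 1]
}

#' Baseline patch selector: adaptive intensity thresholding
#'
#' Mask-free alternative to the t-test selector: a patch is retained when
#' the fraction of its pixels darker than a cutoff is at least
#' `min_dark_fraction`. By default the cutoff is each patch's own Otsu
#' threshold; dark pixels stand in for lung tissue, which is radiolucent.
#' Constant patches (Otsu undefined) are discarded with a warning.
#'
#' @param patches Patch tibble with a list-column `pixels`.
#' @param dark_cutoff Fixed intensity cutoff; `NULL` (default) uses the
#'   per-patch Otsu threshold.
#' @param min_dark_fraction Minimum fraction of below-cutoff pixels for
#'   retention. Default 0.3.
#' @return The retained rows of `patches`, in input order, with a
#'   `dark_fraction` column appended.
#' @export
threshold_select <- function(patches, dark_cutoff = NULL, min_dark_fraction = 0.3) {
  if (nrow(patches) == 0) {
    patches$dark_fraction <- numeric(0)
    return(patches)
  }
  dark <- purrr::map_dbl(patches$pixels, function(px) {
    cutoff <- dark_cutoff %||% otsu_threshold(px)
    if (is.na(cutoff)) {
      warn("constant patch: Otsu threshold undefined, patch discarded")
      return(NA_real_)
    }
    mean(px < cutoff)
  })
  patches$dark_fraction <- dark
  patches[!is.na(dark) & dark >= min_dark_fraction, ]
}

#' Write a per-patch selection report
#'
#' @param stats The `stats` tibble from [select_patches()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(stats, path) {
  cols <- intersect(
    c("parent_id", "r0", "c0", "r1", "c1", "lung_fraction",
      "n_lung", "n_nonlung", "t", "dof", "p", "decision", "label"),
    names(stats)
  )
  readr::write_csv(stats[cols], path)
  invisible(path)
}
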