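# Shared fixtures, all generated in code.

# Reduced classifier used throughout the tests: same architecture, small
# enough to train in seconds.
reduced_model_config <- function(input_size = 64L) {
  model_config(input_size = input_size, block_filters = c(8L, 16L, 16L, 16L, 16L))
}

# A small phantom with deterministic nodule placement.
tiny_phantom <- function(seed = 1, with_nodule = FALSE, size = c(128, 128), ...) {
  generate_phantom(phantom_spec(seed = seed, size = size,
                                with_nodule = with_nodule, ...))
}

# A clean, separable labelled patch cohort: for each phantom pair (same
# seed with/without nodule) take the grid patch best covering the nodule
# from the nodule image and the same box from its nodule-free twin, so the
# two classes differ only by the nodule disk.
separable_patch_cohort <- function(n_pairs = 30, seed = 100,
                                   config = patch_config()) {
  rows <- lapply(seq_len(n_pairs), function(i) {
    sp <- phantom_spec(seed = seed + i, noise_sigma = 0.02,
                       nodule_contrast = 0.3, with_nodule = TRUE)
    img_c <- generate_phantom(sp, id = sprintf("pair%03d_cancer", i))
    sp$with_nodule <- FALSE
    img_n <- generate_phantom(sp, id = sprintf("pair%03d_normal", i))
    pc <- extract_patches(img_c, config)
    pn <- extract_patches(img_n, config)
    # the patch with the brightest content contains the nodule
    j <- which.max(vapply(pc$pixels, max, numeric(1)))
    box <- pc[j, c("r0", "c0")]
    jn <- which(pn$r0 == box$r0 & pn$c0 == box$c0)
    if (length(jn) == 0) jn <- j
    rbind(pc[j, ], pn[jn[1], ])
  })
  dplyr::bind_rows(rows)
}

# Random confusion matrices for property tests.
random_confusions <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        cm <- as.list(stats::setNames(sample(0:40, 4, replace = TRUE),
                                      c("tp", "tn", "fp", "fn")))
        if (cm$tp + cm$tn + cm$fp + cm$fn >= 1) return(cm)
      }
    })
  })
}
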