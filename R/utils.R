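# Internal helpers shared across modules.

#' @noRd
assert_that <- function(ok, msg, class = "cxrcad_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# Derive a child seed from a parent seed and an index; stays inside the
# 32-bit integer range R requires for set.seed().
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# Run `expr` under a seeded, restored RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Nearest-neighbour index map from `n_out` positions onto `n_in` source
# positions (pixel-centre convention).
#' @noRd
nn_index <- function(n_in, n_out) {
  pmin(pmax(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1, 1), n_in)
}

# Nearest-neighbour resample of a matrix to `shape` = c(rows, cols).
#' @noRd
resize_nearest <- function(x, shape) {
  x[nn_index(nrow(x), shape[1]), nn_index(ncol(x), shape[2]), drop = FALSE]
}

# Bilinear resample of a matrix to `shape` = c(rows, cols), pixel-centre
# aligned, edge-clamped.
#' @noRd
resize_bilinear <- function(x, shape) {
  h_in <- nrow(x); w_in <- ncol(x)
  h_out <- shape[1]; w_out <- shape[2]
  if (h_in == h_out && w_in == w_out) return(x)
  rf <- (seq_len(h_out) - 0.5) * h_in / h_out - 0.5
  cf <- (seq_len(w_out) - 0.5) * w_in / w_out - 0.5
  r0 <- pmin(pmax(floor(rf), 0), h_in - 1); r1 <- pmin(r0 + 1, h_in - 1)
  c0 <- pmin(pmax(floor(cf), 0), w_in - 1); c1 <- pmin(c0 + 1, w_in - 1)
  wr <- pmin(pmax(rf - r0, 0), 1); wc <- pmin(pmax(cf - c0, 0), 1)
  a <- x[r0 + 1, c0 + 1, drop = FALSE]; b <- x[r0 + 1, c1 + 1, drop = FALSE]
  d <- x[r1 + 1, c0 + 1, drop = FALSE]; e <- x[r1 + 1, c1 + 1, drop = FALSE]
  top <- a + sweep(b - a, 2, wc, "*")
  bot <- d + sweep(e - d, 2, wc, "*")
  top + (bot - top) * wr
}

#' @noRd
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
canonical_label <- function(x) {
  out <- tolower(trimws(as.character(x)))
  bad <- !out %in% c("cancer", "normal", "unknown")
  if (any(bad)) {
    abort(
      paste0(
        "labels must be 'cancer' or 'normal' (case-insensitive); offending: ",
        paste(unique(x[bad]), collapse = ", ")
      ),
      class = "cxrcad_validation_error"
    )
  }
  out
}
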