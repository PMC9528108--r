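# Shared helpers: seeded RNG scoping, image IO, affine resampling.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All stochastic package functions route
# through this so a user-level seed gives full reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Deterministic sub-seed derived from a base seed and a stage label, kept
# within the 32-bit signed range.
derive_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- as.numeric(seed) %% 2147483647
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h %% 2000000000 + 1)
}

#' Read and write 8-bit grayscale PNG images
#'
#' Images are plain numeric matrices in `[0, 1]`, rows = y (downward),
#' columns = x (rightward). Writing quantizes to 8 bits.
#'
#' @param path File path.
#' @param img Numeric matrix in `[0, 1]`.
#' @return `read_image()` returns a matrix; `write_image()` returns `path`
#'   invisibly.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# Affine resampling helpers. Coordinates are 0-based pixel centers
# (x = column, y = row). cpp_warp_affine maps output coords -> input coords.

# Halve both image dimensions by 2x2 block averaging (odd trailing
# row/column dropped).
halve_image <- function(img) {
  h <- nrow(img) %/% 2L
  w <- ncol(img) %/% 2L
  i <- seq_len(h) * 2L
  j <- seq_len(w) * 2L
  (img[i - 1L, j - 1L, drop = FALSE] + img[i, j - 1L, drop = FALSE] +
     img[i - 1L, j, drop = FALSE] + img[i, j, drop = FALSE]) / 4
}

# Resize a matrix to out_h x out_w (center-aligned sampling). Strong
# downscaling is pre-reduced by block averaging so thin structures are
# integrated rather than skipped; the final step is bilinear.
resize_image <- function(img, out_h, out_w) {
  while (nrow(img) >= 2 * out_h && ncol(img) >= 2 * out_w &&
         nrow(img) > 2 && ncol(img) > 2) {
    img <- halve_image(img)
  }
  sy <- nrow(img) / out_h
  sx <- ncol(img) / out_w
  # output pixel center (x+0.5, y+0.5) maps to input center scaled
  a <- c(sx, 0, 0.5 * sx - 0.5, 0, sy, 0.5 * sy - 0.5)
  cpp_warp_affine(img, a, as.integer(out_h), as.integer(out_w))
}

# Map 0-based coordinates between resolutions (center-aligned).
rescale_coords <- function(xy, from_size, to_size) {
  s <- to_size / from_size
  (xy + 0.5) * s - 0.5
}

# Mirror an image horizontally (left <-> right hand orientation).
mirror_image <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

# Mirror x coordinates on a width-W image.
mirror_x <- function(x, width) (width - 1) - x

clip01 <- function(x) pmin(pmax(x, 0), 1)
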