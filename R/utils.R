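# Shared internal utilities.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so every generator is a pure function of (config, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Min-max rescale to [0, 1]; constant input maps to 0 (avoids 0/0).
rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(array(0, dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a finite numeric scalar", call. = FALSE)
  }
}

#' Read a grayscale image from a PNG file
#'
#' Returns a numeric matrix with intensities in `[0, 1]`. Colour PNGs are
#' reduced to their first channel.
#'
#' @param path Path to a PNG file.
#' @return A numeric matrix in `[0, 1]`.
#' @export
load_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a grayscale image to a PNG file
#'
#' Intensities are clipped to `[0, 1]` and stored as 8-bit grayscale.
#' Logical masks are written as 0/255.
#'
#' @param image Numeric matrix in `[0, 1]`, or a logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  if (is.logical(image)) image <- image * 1
  png::writePNG(clip01(image), path)
  invisible(path)
}
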