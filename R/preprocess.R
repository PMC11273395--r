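# Standardisation and Hessian-eigenvalue vessel enhancement for en face
# angiography images.
#
# Bright curvilinear vessels are ridges of the intensity surface: at a
# vessel pixel the second derivative across the vessel is strongly
# negative while the derivative along it is near zero. The enhancement
# filter therefore computes the Hessian of the Gaussian-smoothed image at
# several scales, takes its eigenvalues sorted by absolute value, and
# applies a Frangi-style ridge response (anisotropy ratio + structureness)
# wherever the dominant eigenvalue is negative.

#' Preprocessing configuration
#'
#' @param resize_to Side length after resizing (bilinear). The
#'   full-resolution setting is 512.
#' @param crop_to Side length after the center crop (must not exceed
#'   `resize_to`); full-resolution setting 480, which removes border
#'   artifacts of en face projections.
#' @param vesselness_scales Gaussian smoothing scales (pixels) of the
#'   multiscale ridge filter.
#' @param enhance Logical; apply vesselness enhancement. Enhancement
#'   helps the pixel-wise segmentation path but not scan-wise
#'   classification, so it is off by default and enabled on the
#'   segmentation path.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(resize_to = 512L, crop_to = 480L,
                              vesselness_scales = c(1, 2, 4),
                              enhance = FALSE) {
  if (crop_to > resize_to) stop("crop_to must not exceed resize_to",
                                call. = FALSE)
  if (any(vesselness_scales <= 0)) stop("scales must be positive",
                                        call. = FALSE)
  structure(list(resize_to = as.integer(resize_to),
                 crop_to = as.integer(crop_to),
                 vesselness_scales = as.numeric(vesselness_scales),
                 enhance = isTRUE(enhance)),
            class = "preprocess_config")
}

#' Standardize an en face image
#'
#' Resizes to `resize_to` (bilinear), center-crops to `crop_to` (equal
#' margins; odd remainders leave the smaller margin toward the top-left)
#' and min-max rescales intensities to `[0, 1]` (constant images map
#' to 0).
#'
#' @param image 2-D numeric matrix, any size.
#' @param cfg A [preprocess_config()].
#' @return A `crop_to` x `crop_to` numeric matrix in `[0, 1]`.
#' @export
standardize <- function(image, cfg) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix", call. = FALSE)
  # idempotence: an already-standardized image is only rescaled
  if (nrow(image) == cfg$crop_to && ncol(image) == cfg$crop_to) {
    return(rescale01(image))
  }
  r <- cfg$resize_to
  if (nrow(image) != r || ncol(image) != r) {
    image <- EBImage::resize(image, w = r, h = r)
    image <- matrix(as.numeric(image), r, r)
  }
  off <- (r - cfg$crop_to) %/% 2L
  idx <- seq_len(cfg$crop_to) + off
  rescale01(image[idx, idx])
}

# Separable Gaussian smoothing with replicate padding; kernel radius
# ceiling(3*sigma).
gaussian_smooth <- function(image, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_rows <- function(m, r) rbind(m[rep(1, r), , drop = FALSE], m,
                                   m[rep(nrow(m), r), , drop = FALSE])
  sm <- function(m) {  # smooth along rows (dimension 1)
    mp <- pad_rows(m, r)
    out <- 0
    for (t in seq_along(k)) {
      out <- out + k[t] * mp[t:(t + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(sm(t(sm(image))))
}

#' Per-pixel Hessian of the Gaussian-smoothed image
#'
#' Smooths the image at the given scale and computes the symmetric 2x2
#' matrix of second derivatives by central finite differences (replicate
#' boundary), with x along rows and y along columns.
#'
#' @param image 2-D numeric matrix.
#' @param scale Gaussian smoothing scale in pixels (> 0).
#' @return A list with matrices `hxx`, `hxy`, `hyy`.
#' @export
hessian_matrix <- function(image, scale) {
  stopifnot(scale > 0)
  f <- gaussian_smooth(image, scale)
  nr <- nrow(f); nc <- ncol(f)
  up <- f[c(1, seq_len(nr - 1)), ]          # shift down: f[i-1, j]
  dn <- f[c(seq_len(nr - 1) + 1, nr), ]     # f[i+1, j]
  lf <- f[, c(1, seq_len(nc - 1))]          # f[i, j-1]
  rt <- f[, c(seq_len(nc - 1) + 1, nc)]     # f[i, j+1]
  hxx <- dn - 2 * f + up
  hyy <- rt - 2 * f + lf
  fx <- (dn - up) / 2
  hxy <- (fx[, c(seq_len(nc - 1) + 1, nc)] - fx[, c(1, seq_len(nc - 1))]) / 2
  list(hxx = hxx, hxy = hxy, hyy = hyy)
}

#' Eigenvalues of a per-pixel symmetric 2x2 Hessian field
#'
#' Closed-form eigenvalues of `[[hxx, hxy], [hxy, hyy]]`, sorted per
#' pixel by absolute value (`|lambda1| <= |lambda2|`); absolute-value
#' ties are broken by signed value ascending.
#'
#' @param H A list with matrices `hxx`, `hxy`, `hyy` as returned by
#'   [hessian_matrix()].
#' @return A list with matrices `lambda1`, `lambda2`.
#' @export
hessian_eigenvalues <- function(H) {
  tr <- H$hxx + H$hyy
  disc <- sqrt(pmax(0, (H$hxx - H$hyy)^2 + 4 * H$hxy^2))
  lo <- (tr - disc) / 2   # signed smaller
  hi <- (tr + disc) / 2   # signed larger
  swap <- abs(lo) > abs(hi)   # on |.|-ties keep signed ascending order
  lambda1 <- ifelse(swap, hi, lo)
  lambda2 <- ifelse(swap, lo, hi)
  dm <- dim(H$hxx)
  list(lambda1 = matrix(lambda1, dm[1], dm[2]),
       lambda2 = matrix(lambda2, dm[1], dm[2]))
}

#' Multiscale Hessian vesselness enhancement
#'
#' Frangi-style bright-ridge response from the Hessian eigenvalues: with
#' `|lambda1| <= |lambda2|` and scale-normalised derivatives
#' (`scale^2 H`), pixels respond where `lambda2 < 0` with
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`, where
#' `Rb = lambda1/lambda2` penalises blobs and the structureness
#' `S = sqrt(lambda1^2 + lambda2^2)` suppresses flat noise (`beta = 0.5`,
#' `c` = half the maximum structureness per scale). The response is
#' maximised over scales and min-max rescaled to `[0, 1]`.
#'
#' @param image 2-D numeric matrix.
#' @param cfg A [preprocess_config()]; uses `vesselness_scales`.
#' @return Numeric matrix in `[0, 1]` of the same size.
#' @export
vesselness_enhance <- function(image, cfg) {
  scales <- cfg$vesselness_scales
  stopifnot(length(scales) >= 1)
  beta <- 0.5
  best <- matrix(0, nrow(image), ncol(image))
  for (s in scales) {
    H <- hessian_matrix(image, s)
    H <- lapply(H, function(m) s^2 * m)   # gamma = 2 scale normalisation
    ev <- hessian_eigenvalues(list(hxx = H$hxx, hxy = H$hxy, hyy = H$hyy))
    S2 <- ev$lambda1^2 + ev$lambda2^2
    smax <- max(sqrt(S2))
    if (smax <= 0) next
    cc <- smax / 2
    rb2 <- ifelse(ev$lambda2 != 0, (ev$lambda1 / ev$lambda2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    v[ev$lambda2 >= 0] <- 0
    best <- pmax(best, v)
  }
  if (max(best) <= 0) return(best)
  rescale01(best)
}
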