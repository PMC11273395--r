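# Segmentation post-processing: thresholding, morphology and small-
# component removal.
#
# Score maps (upscaled ALM or epistemic uncertainty) become binary
# anomaly segmentations by strict thresholding (so a threshold of 0
# flags any nonzero uncertainty), followed by morphological opening
# (noise removal), dilation (region consolidation) and removal of
# connected components smaller than an area s.

#' Post-processing configuration
#'
#' Default structuring-element radii and minimum area are stated for the
#' 480-px full-resolution scale and scaled proportionally (by area for
#' `min_area`) to the working resolution.
#'
#' @param threshold Score threshold (strict `>`): 0.05 for the ALM path,
#'   0 for the uncertainty path, or any custom value.
#' @param opening_radius Disk radius (pixels) of the opening, at 480-px
#'   scale.
#' @param dilation_radius Disk radius of the subsequent dilation, at
#'   480-px scale.
#' @param min_area Minimum connected-component area s (pixels^2), at
#'   480-px scale.
#' @param reference_size Scale at which the radii/area are expressed.
#' @return An object of class `postprocess_config`.
#' @export
postprocess_config <- function(threshold = 0.05, opening_radius = 1,
                               dilation_radius = 2, min_area = 64,
                               reference_size = 480L) {
  stopifnot(opening_radius >= 0, dilation_radius >= 0, min_area >= 0)
  structure(list(threshold = threshold, opening_radius = opening_radius,
                 dilation_radius = dilation_radius, min_area = min_area,
                 reference_size = as.integer(reference_size)),
            class = "postprocess_config")
}

#' Threshold a score map
#'
#' Strict comparison: a pixel is anomalous iff its value exceeds the
#' threshold, so threshold 0 marks any strictly positive score.
#'
#' @param map Numeric score-map matrix (finite values).
#' @param threshold Single numeric threshold.
#' @return Binary (0/1) integer matrix.
#' @export
binarize <- function(map, threshold) {
  stopifnot(all(is.finite(map)))
  (map > threshold) * 1L
}

# 8-connected component labelling via the pixel adjacency graph.
label_components <- function(binary) {
  idx <- which(binary > 0)
  lab <- matrix(0L, nrow(binary), ncol(binary))
  if (length(idx) == 0) return(lab)
  nr <- nrow(binary)
  pos <- arrayInd(idx, dim(binary))
  inside <- function(i, j) i >= 1 & i <= nr & j >= 1 & j <= ncol(binary)
  edges <- list()
  # half the 8-neighbourhood suffices for an undirected graph
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    ni <- pos[, 1] + off[1]; nj <- pos[, 2] + off[2]
    ok <- inside(ni, nj)
    nidx <- (nj - 1L) * nr + ni
    ok[ok] <- binary[nidx[ok]] > 0
    edges[[length(edges) + 1L]] <- cbind(idx[ok], nidx[ok])
  }
  edges <- do.call(rbind, edges)
  vids <- match(seq_len(length(binary)), idx)   # pixel -> vertex id
  g <- igraph::graph_from_edgelist(
    cbind(vids[edges[, 1]], vids[edges[, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# Binary morphology with a disk structuring element (EBImage).
disk_kernel <- function(radius) {
  size <- 2L * ceiling(radius) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

#' Refine a binary segmentation
#'
#' Morphological opening with a disk of `opening_radius`, dilation with
#' a disk of `dilation_radius`, then removal of 8-connected components
#' with area below `min_area`. Radii and area are rescaled from
#' `reference_size` to the map's actual resolution.
#'
#' @param binary Binary (0/1) matrix.
#' @param cfg A [postprocess_config()].
#' @return Binary (0/1) integer matrix, the anomaly segmentation B.
#' @export
refine <- function(binary, cfg) {
  stopifnot(all(binary %in% c(0, 1)))
  scale <- nrow(binary) / cfg$reference_size
  b <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  orad <- round(cfg$opening_radius * scale)
  drad <- round(cfg$dilation_radius * scale)
  s <- cfg$min_area * scale^2
  if (orad > 0 && any(b > 0)) {
    b <- EBImage::opening(b, disk_kernel(orad))
  }
  if (drad > 0 && any(b > 0)) {
    b <- EBImage::dilate(b, disk_kernel(drad))
  }
  b <- matrix(as.numeric(b > 0.5), nrow(binary), ncol(binary))
  if (s > 0 && any(b > 0)) {
    lab <- label_components(b)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= s)
    b <- matrix(as.numeric(lab %in% keep & lab > 0), nrow(b), ncol(b))
  }
  matrix(as.integer(b), nrow(binary), ncol(binary))
}

#' Scan-wise score from a score map
#'
#' Sum of map values strictly above the threshold (the same aggregation
#' used for NLL maps in [scan_score()]).
#'
#' @param map Numeric score-map matrix.
#' @param threshold Threshold (t_ar for NLL maps, t_un for uncertainty
#'   maps).
#' @return Single nonnegative number.
#' @export
scanwise_from_map <- function(map, threshold) {
  stopifnot(all(is.finite(map)))
  sum(map[map > threshold])
}
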