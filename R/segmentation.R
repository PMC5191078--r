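# Pixel classification sweep and binary-mask noise elimination:
# relative-size region filtering, disc opening/closing, hole filling.

#' Classify every pixel of an image with a strong classifier
#'
#' For each pixel, the features are the means of the required component
#' planes over the `window x window` neighborhood (sliding window, stride 1,
#' reflective border padding); the pixel is foreground (1, grape) iff the
#' strong classifier votes `+1`.
#'
#' @param image RGB array (`height x width x 3`, values in \[0,1\]), at
#'   least `window` pixels in each dimension.
#' @param object A fitted [grape_boost()] model.
#' @param window Odd sub-window side length (default 7).
#' @param bstar_limits Passed to [extract_components()].
#' @return Integer 0/1 matrix of the image's dimensions.
#' @export
classify_pixels <- function(image, object, window = 7L,
                            bstar_limits = c(-128, 127)) {
  stopifnot(inherits(object, "grape_boost"))
  image <- as_rgb_array(image)
  needed <- unique(unlist(lapply(object$rounds,
                                 function(r) r$model$components)))
  planes <- extract_components(image, needed, bstar_limits)
  planes <- lapply(planes, window_mean, window = window)
  features <- as.data.frame(lapply(planes, as.vector))
  lab <- strong_classify(object, features)
  matrix(as.integer(lab == 1L), dim(image)[1], dim(image)[2])
}

#' Label connected components of a binary mask
#'
#' @param mask Integer/numeric 0/1 matrix.
#' @param connectivity 8 (default; diagonal contacts join) or 4.
#' @return Integer matrix of component labels, 0 for background. Label
#'   numbering is arbitrary but deterministic.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask > 0),
                                                    nrow(mask), ncol(mask))))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 4L || nlab <= 1L) return(lab)
  # bwlabel is 4-connected; merge labels that touch diagonally
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- lab
  out[lab > 0] <- memb[lab[lab > 0]]
  out
}

#' Remove regions small relative to the largest region
#'
#' Connected components with area below `fraction` times the largest
#' component's area are erased; the largest region always survives. An
#' empty mask is returned unchanged.
#'
#' @param mask Integer/numeric 0/1 matrix.
#' @param fraction Relative area cutoff in (0,1); default 1/10.
#' @param connectivity Passed to [label_components()].
#' @return Integer 0/1 matrix.
#' @export
filter_small_regions <- function(mask, fraction = 1 / 10,
                                 connectivity = 8L) {
  stopifnot(fraction > 0, fraction < 1)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= fraction * max(areas))
  matrix(as.integer(lab %in% keep & lab > 0L), nrow(mask), ncol(mask))
}

# Disc structuring element {(dx,dy): dx^2 + dy^2 <= r^2}.
disc_kernel <- function(radius) {
  stopifnot(radius >= 1)
  d <- seq(-radius, radius)
  outer(d, d, function(x, y) as.numeric(x^2 + y^2 <= radius^2))
}

#' Morphological opening then closing with a disc element
#'
#' Opening (erode-dilate) removes foreground specks smaller than the disc;
#' the subsequent closing (dilate-erode) seals cracks and recovers the
#' cluster contour. The disc is \eqn{\{(dx,dy): dx^2+dy^2 \le r^2\}}.
#'
#' @param mask Integer/numeric 0/1 matrix.
#' @param radius Disc radius in pixels (default 5).
#' @return Integer 0/1 matrix.
#' @export
morphological_clean <- function(mask, radius = 5L) {
  stopifnot(is.matrix(mask), radius >= 1)
  kern <- disc_kernel(radius)
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  m <- EBImage::imageData(EBImage::opening(m, kern))
  m <- EBImage::imageData(EBImage::closing(m, kern))
  matrix(as.integer(m > 0.5), nrow(mask), ncol(mask))
}

#' Fill holes in a binary mask
#'
#' Background components not connected to the image border become
#' foreground; holes opening to the border through a channel are kept.
#' Never removes foreground.
#'
#' @param mask Integer/numeric 0/1 matrix.
#' @return Integer 0/1 matrix.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- EBImage::imageData(EBImage::fillHull(matrix(as.numeric(mask > 0),
                                                   nrow(mask), ncol(mask))))
  matrix(as.integer(m > 0.5), nrow(mask), ncol(mask))
}
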