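# Color-component transforms and image preprocessing.
#
# All transforms take RGB intensities in [0,1] and return values normalized to
# [0,1], so thresholds learned by the weak classifiers live on a single scale.

#' Component identifiers understood by the pipeline
#'
#' `"H"` (HSI hue), `"Cb"` (YCbCr blue-difference chroma), `"bstar"`
#' (CIELab yellow--blue axis), and the raw `"R"`, `"G"`, `"B"` channels.
#'
#' @return Character vector of the supported component ids.
#' @export
component_ids <- function() c("H", "Cb", "bstar", "R", "G", "B")

#' HSI hue of an RGB pixel, normalized to \[0,1\]
#'
#' Computes the angular hue
#' \deqn{\theta = \arccos\frac{0.5[(R-G)+(R-B)]}{\sqrt{(R-G)^2+(R-B)(G-B)}}}
#' with \eqn{H = \theta} when \eqn{B \le G} and \eqn{360^\circ - \theta}
#' otherwise, returned as \eqn{H/360}. Achromatic pixels (zero denominator,
#' i.e. R = G = B) return 0 by convention. The arccos argument is clamped to
#' \[-1,1\] to absorb floating-point drift.
#'
#' @param r,g,b Numeric vectors of intensities in \[0,1\] (recycled together).
#' @return Numeric vector of normalized hues in \[0,1\].
#' @examples
#' rgb_to_hue(1, 0, 0)   # pure red: 0
#' rgb_to_hue(0, 0, 1)   # pure blue: 240/360
#' @export
rgb_to_hue <- function(r, g, b) {
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  arg <- ifelse(den > 0, num / den, 1)   # den == 0 only when R = G = B
  theta <- acos(pmin(pmax(arg, -1), 1)) * 180 / pi
  h <- ifelse(b <= g, theta, 360 - theta)
  h / 360
}

#' YCbCr Cb component of an RGB pixel, normalized to \[0,1\]
#'
#' Evaluates \eqn{Cb = (-0.1687 R - 0.3313 G + 0.500 B) + 128} on the 0--255
#' scale, clips to \[0,255\] and divides by 255. The coefficients cancel
#' exactly for gray pixels, which therefore map to 128/255.
#'
#' @inheritParams rgb_to_hue
#' @return Numeric vector of normalized Cb values in \[0,1\].
#' @export
rgb_to_cb <- function(r, g, b) {
  cb <- (-0.1687 * r - 0.3313 * g + 0.500 * b) * 255 + 128
  pmin(pmax(cb, 0), 255) / 255
}

#' CIELab b* component of an RGB pixel, normalized to \[0,1\]
#'
#' Computes \eqn{[X\,Y\,Z]^T = \frac{1}{0.17697} M [R\,G\,B]^T} with the CIE
#' RGB matrix
#' \deqn{M = \begin{pmatrix} 0.49 & 0.31 & 0.20 \\ 0.17697 & 0.81240 &
#'   0.01063 \\ 0.00 & 0.01 & 0.99 \end{pmatrix}}
#' then \eqn{b^* = 200[f(Y) - f(Z/1.192)]} with \eqn{f(t) = t^{1/3}} for
#' \eqn{t > 0.008856} and \eqn{7.787t + 0.138} otherwise. The raw value is
#' mapped to \[0,1\] by the fixed affine transform
#' `(braw - limits[1]) / (limits[2] - limits[1])` and clipped; the default
#' limits (-128, 127) span the conventional b* range. Only the relative
#' ordering matters downstream since thresholds are learned on the same scale.
#'
#' @inheritParams rgb_to_hue
#' @param limits Length-2 numeric, the raw b* values mapped to 0 and 1.
#' @return Numeric vector of normalized b* values in \[0,1\].
#' @export
rgb_to_bstar <- function(r, g, b, limits = c(-128, 127)) {
  stopifnot(length(limits) == 2L, limits[2] > limits[1])
  y <- (0.17697 * r + 0.81240 * g + 0.01063 * b) / 0.17697
  z <- (0.00 * r + 0.01 * g + 0.99 * b) / 0.17697
  braw <- 200 * (lab_f(y) - lab_f(z / 1.192))
  pmin(pmax((braw - limits[1]) / (limits[2] - limits[1]), 0), 1)
}

# CIELab companding function as printed: cube root above 0.008856, else the
# linear branch 7.787 t + 0.138.
lab_f <- function(t) {
  ifelse(t > 0.008856, t^(1 / 3), 7.787 * t + 0.138)
}

#' Extract normalized color-component planes from an RGB image
#'
#' @param image An RGB image: numeric `height x width x 3` array with values
#'   in \[0,1\].
#' @param ids Character vector of component ids, a subset of
#'   [component_ids()].
#' @param bstar_limits Passed to [rgb_to_bstar()].
#' @return Named list of `height x width` matrices, one per id, all in
#'   \[0,1\].
#' @export
extract_components <- function(image, ids = component_ids(),
                               bstar_limits = c(-128, 127)) {
  image <- as_rgb_array(image)
  bad <- setdiff(ids, component_ids())
  if (length(bad)) {
    stop("unknown component id(s): ", paste(bad, collapse = ", "))
  }
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  out <- lapply(ids, function(id) {
    switch(id,
      H = matrix(rgb_to_hue(r, g, b), nrow(r), ncol(r)),
      Cb = matrix(rgb_to_cb(r, g, b), nrow(r), ncol(r)),
      bstar = matrix(rgb_to_bstar(r, g, b, bstar_limits), nrow(r), ncol(r)),
      R = r, G = g, B = b)
  })
  names(out) <- ids
  out
}

# Box mean of a matrix with symmetric (reflective, edge-included) padding,
# computed with running sums; k = 1 is the identity.
box_mean <- function(m, k) {
  stopifnot(is.matrix(m))
  if (k == 1L) return(m)
  p <- (k - 1L) %/% 2L
  if (nrow(m) < 1L || ncol(m) < 1L) stop("empty matrix")
  ri <- reflect_index(nrow(m), p)
  ci <- reflect_index(ncol(m), p)
  pm <- m[ri, ci, drop = FALSE]
  run <- function(x, k) {  # column-wise sums of k consecutive rows
    cs <- apply(x, 2, cumsum)
    cs <- rbind(matrix(0, 1, ncol(x)), cs)
    cs[(k + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - k), , drop = FALSE]
  }
  s <- run(pm, k)
  s <- t(run(t(s), k))
  s / (k * k)
}

# Symmetric padding index: 2 1 | 1 2 3 ... n | n n-1 for p = 2.
reflect_index <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  if (p > n) stop("padding wider than the image")
  c(rev(seq_len(p)), seq_len(n), n + 1L - seq_len(p))
}

#' Per-channel box mean filter
#'
#' Smooths an RGB image with a `kernel x kernel` box mean using reflective
#' border padding, the preprocessing step applied before component
#' extraction to suppress illumination noise. `kernel = 1` is the identity.
#'
#' @inheritParams extract_components
#' @param kernel Odd positive integer side length (default 3).
#' @return The filtered image, same dimensions.
#' @export
mean_filter <- function(image, kernel = 3L) {
  check_odd(kernel, "kernel")
  image <- as_rgb_array(image)
  if (kernel == 1L) return(image)
  for (ch in 1:3) image[, , ch] <- box_mean(image[, , ch], kernel)
  image
}

#' Sliding-window mean of a component plane
#'
#' Mean over the `window x window` neighborhood centered on each pixel
#' (stride 1, reflective padding). This is the feature fed to the
#' classifiers, both when building training samples and during the
#' sliding-window sweep over a full image.
#'
#' @param plane Numeric matrix.
#' @param window Odd positive integer side length (default 7).
#' @return Matrix of window means, same dimensions as `plane`.
#' @export
window_mean <- function(plane, window = 7L) {
  check_odd(window, "window")
  stopifnot(is.matrix(plane))
  if (nrow(plane) < window || ncol(plane) < window) {
    stop("plane (", nrow(plane), "x", ncol(plane),
         ") is smaller than the window (", window, ")")
  }
  box_mean(plane, window)
}

check_odd <- function(k, what) {
  if (length(k) != 1L || is.na(k) || k < 1 || k %% 2 != 1) {
    stop(what, " must be an odd positive integer, got ", k)
  }
  invisible(as.integer(k))
}

#' Bicubic image resize
#'
#' Separable bicubic resampling with the Keys kernel (a = -0.5), the
#' conventional bicubic interpolator. Output values are clipped to \[0,1\].
#'
#' @inheritParams extract_components
#' @param target Length-2 integer `(height, width)`; default `c(600, 800)`,
#'   the working resolution of the detection pipeline.
#' @return The resized image.
#' @export
resize_bicubic <- function(image, target = c(600L, 800L)) {
  stopifnot(length(target) == 2L, all(target >= 1))
  image <- as_rgb_array(image)
  wr <- cubic_weights(dim(image)[1], target[1])
  wc <- cubic_weights(dim(image)[2], target[2])
  out <- array(0, c(target[1], target[2], 3))
  for (ch in 1:3) {
    out[, , ch] <- pmin(pmax(wr %*% image[, , ch] %*% t(wc), 0), 1)
  }
  out
}

# Dense interpolation matrix (n_out x n_in) for the Keys a = -0.5 cubic
# kernel; source coordinates follow the center-aligned convention
# u = (i + 0.5) * n_in/n_out - 0.5 (0-based), neighbors clamped at borders.
cubic_weights <- function(n_in, n_out) {
  kern <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
           ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
  }
  scale <- n_in / n_out
  u <- (seq_len(n_out) - 0.5) * scale - 0.5       # 0-based source position
  i0 <- floor(u)
  w <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    idx <- pmin(pmax(i0 + k, 0), n_in - 1)        # clamp at the border
    wt <- kern(u - (i0 + k))
    w[cbind(seq_len(n_out), idx + 1)] <-
      w[cbind(seq_len(n_out), idx + 1)] + wt
  }
  w / rowSums(w)
}

# Coerce to an h x w x 3 numeric array in [0,1]; grayscale matrices are
# replicated across channels, alpha channels dropped.
as_rgb_array <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  if (length(dim(image)) != 3L) stop("expected an RGB array")
  if (dim(image)[3] > 3L) image <- image[, , 1:3, drop = FALSE]
  if (dim(image)[3] == 1L) image <- array(rep(image, 3), c(dim(image)[1:2], 3))
  if (dim(image)[3] != 3L) stop("expected 3 channels, got ", dim(image)[3])
  if (anyNA(image) || min(image) < -1e-8 || max(image) > 1 + 1e-8) {
    stop("image values must be in [0,1]")
  }
  pmin(pmax(image, 0), 1)  # absorb floating-point drift from filtering
}

#' Read an RGB image from PNG or JPEG
#'
#' 8-bit (or 16-bit PNG) files are converted to intensities in \[0,1\];
#' grayscale images are replicated to three channels and alpha is dropped.
#'
#' @param path File path ending in `.png`, `.jpg` or `.jpeg`.
#' @return `height x width x 3` numeric array in \[0,1\].
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (use PNG or JPEG)"))
  as_rgb_array(img)
}

#' Write a component plane as a grayscale image
#'
#' For inspection of intermediate planes. A `.tif`/`.tiff` path stores
#' 16-bit grayscale (value x 65535); a `.png` path stores 8-bit
#' (value x 255), the PNG writer's maximum depth.
#'
#' @param plane Numeric matrix in \[0,1\].
#' @param path Output file path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_component_image <- function(plane, path) {
  stopifnot(is.matrix(plane), min(plane) >= 0, max(plane) <= 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(plane, path, bits.per.sample = 16L),
    png = png::writePNG(plane, path),
    stop("unsupported component-image format: .", ext))
  invisible(path)
}

#' Read and write binary masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNGs with foreground = 255.
#'
#' @param mask Integer/numeric matrix of 0s and 1s.
#' @param path File path.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns an integer 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}
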