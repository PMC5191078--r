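# Region extraction, the barycenter split for adjoining cluster pairs, and
# the full detect pipeline producing enclosing rectangles.

#' Extract connected regions from a binary mask
#'
#' One region per connected component, in deterministic order (row-major by
#' each region's first pixel). Coordinates are 1-based `(row, col)` — R's
#' native indexing — and bounding boxes are `(top, left, height, width)`
#' with `top`/`left` the first foreground pixel of the tightest enclosing
#' rectangle.
#'
#' @param mask Integer/numeric 0/1 matrix.
#' @param connectivity Passed to [label_components()].
#' @return List of `grape_region` objects, each with elements `area`,
#'   `centroid` (the barycenter, `c(row, col)`), `bbox`
#'   (`c(top, left, height, width)`) and `pixels` (two-column matrix of
#'   row/col indices).
#' @export
extract_regions <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(list())
  idx <- which(lab > 0L, arr.ind = TRUE)
  regions <- lapply(split.data.frame(idx, lab[lab > 0L]), region_from_pixels)
  # row-major order of each region's first pixel
  keys <- vapply(regions, function(r) {
    min((r$pixels[, 1] - 1) * ncol(mask) + r$pixels[, 2])
  }, numeric(1))
  regions <- regions[order(keys)]
  for (i in seq_along(regions)) regions[[i]]$id <- i
  unname(regions)
}

region_from_pixels <- function(px) {
  px <- as.matrix(px)
  colnames(px) <- c("row", "col")
  top <- min(px[, 1]); left <- min(px[, 2])
  structure(list(
    id = NA_integer_,
    area = nrow(px),
    centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
    bbox = c(top = top, left = left,
             height = max(px[, 1]) - top + 1L,
             width = max(px[, 2]) - left + 1L),
    pixels = px), class = "grape_region")
}

#' @export
print.grape_region <- function(x, ...) {
  cat(sprintf(
    "Region %s: area %d, barycenter (%.1f, %.1f), bbox [%d,%d %dx%d]\n",
    x$id, x$area, x$centroid[1], x$centroid[2],
    x$bbox["top"], x$bbox["left"], x$bbox["height"], x$bbox["width"]))
  invisible(x)
}

#' Heuristic test for a region holding two adjoining clusters
#'
#' The criterion is a bounding-box aspect test: width / height strictly
#' greater than `ratio_threshold`. A single hanging cluster is taller than
#' wide, so a markedly wide region suggests two clusters side by side.
#' This trigger is a heuristic of this package, not a prescribed rule.
#'
#' @param region A `grape_region`.
#' @param ratio_threshold Aspect cutoff (default 1.4).
#' @return Logical flag.
#' @export
is_adjoining_pair <- function(region, ratio_threshold = 1.4) {
  stopifnot(ratio_threshold > 0)
  unname(region$bbox["width"] / region$bbox["height"]) > ratio_threshold
}

#' Split a region by a vertical line through its barycenter
#'
#' Pixels with column strictly less than the barycenter column form the
#' left part; pixels on or right of it form the right part (deterministic
#' tie rule). Each part's enclosing rectangle is recomputed. The two parts
#' partition the original region.
#'
#' @param region A `grape_region` spanning at least two columns.
#' @return List of two `grape_region` objects (left, right).
#' @export
split_at_barycenter <- function(region) {
  px <- region$pixels
  if (length(unique(px[, 2])) < 2L) {
    stop("cannot split a region spanning a single column")
  }
  cc <- region$centroid["col"]
  left <- px[px[, 2] < cc, , drop = FALSE]
  right <- px[px[, 2] >= cc, , drop = FALSE]
  stopifnot(nrow(left) > 0L, nrow(right) > 0L)
  list(region_from_pixels(left), region_from_pixels(right))
}

#' Pipeline configuration for cluster detection
#'
#' Collects the tunable constants of the whole pipeline with the method's
#' published values as defaults.
#'
#' @param window Sliding sub-window side for pixel features (7).
#' @param mean_kernel Preprocessing box-mean kernel (3); 1 disables.
#' @param region_fraction Relative-area cutoff of
#'   [filter_small_regions()] (1/10).
#' @param connectivity Component connectivity (8).
#' @param disc_radius Disc radius of [morphological_clean()] (5).
#' @param split_ratio Aspect threshold of [is_adjoining_pair()] (1.4).
#' @param resize Optional `(height, width)` to resize inputs with
#'   [resize_bicubic()] before processing (e.g. `c(600, 800)`); NULL keeps
#'   the input size.
#' @param bstar_limits Passed to [extract_components()].
#' @return A named list of class `detect_config`.
#' @export
detect_config <- function(window = 7L, mean_kernel = 3L,
                          region_fraction = 1 / 10, connectivity = 8L,
                          disc_radius = 5L, split_ratio = 1.4,
                          resize = NULL, bstar_limits = c(-128, 127)) {
  check_odd(window, "window")
  check_odd(mean_kernel, "mean_kernel")
  stopifnot(region_fraction > 0, region_fraction < 1,
            connectivity %in% c(4L, 8L), disc_radius >= 1, split_ratio > 0)
  structure(list(window = window, mean_kernel = mean_kernel,
                 region_fraction = region_fraction,
                 connectivity = connectivity, disc_radius = disc_radius,
                 split_ratio = split_ratio, resize = resize,
                 bstar_limits = bstar_limits),
            class = "detect_config")
}

#' Detect grape clusters in an image
#'
#' Runs the full chain: optional bicubic resize, mean filter, per-pixel
#' strong classification, relative-size region filtering, disc
#' opening/closing, hole filling, region extraction, and a barycenter
#' split of regions judged to hold two adjoining clusters. Detections are
#' the enclosing rectangles of the resulting regions.
#'
#' @param image RGB array (`height x width x 3`).
#' @param object A fitted [grape_boost()] model.
#' @param config A [detect_config()].
#' @return Object of class `grape_detections`: list with `boxes` (data
#'   frame with columns `id`, `top`, `left`, `height`, `width`, `split`,
#'   `region`; 1-based inclusive coordinates), `mask` (the final binary
#'   mask), and `regions` (the pre-split region list).
#' @export
detect_clusters <- function(image, object, config = detect_config()) {
  stopifnot(inherits(config, "detect_config"))
  image <- as_rgb_array(image)
  if (!is.null(config$resize)) image <- resize_bicubic(image, config$resize)
  if (config$mean_kernel > 1L) image <- mean_filter(image, config$mean_kernel)
  mask <- classify_pixels(image, object, config$window, config$bstar_limits)
  mask <- filter_small_regions(mask, config$region_fraction,
                               config$connectivity)
  mask <- morphological_clean(mask, config$disc_radius)
  mask <- fill_holes(mask)
  regions <- extract_regions(mask, config$connectivity)

  rows <- list()
  for (r in regions) {
    if (is_adjoining_pair(r, config$split_ratio) &&
        length(unique(r$pixels[, 2])) >= 2L) {
      parts <- split_at_barycenter(r)
      for (p in parts) rows[[length(rows) + 1L]] <- c(p$bbox, split = 1,
                                                      region = r$id)
    } else {
      rows[[length(rows) + 1L]] <- c(r$bbox, split = 0, region = r$id)
    }
  }
  boxes <- if (length(rows)) {
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- c("top", "left", "height", "width", "split", "region")
    df$split <- df$split == 1
    cbind(id = seq_len(nrow(df)), df)
  } else {
    data.frame(id = integer(), top = integer(), left = integer(),
               height = integer(), width = integer(), split = logical(),
               region = integer())
  }
  structure(list(boxes = boxes, mask = mask, regions = regions),
            class = "grape_detections")
}

#' @export
print.grape_detections <- function(x, ...) {
  cat(sprintf("Grape cluster detections: %d rectangle(s)\n", nrow(x$boxes)))
  if (nrow(x$boxes)) print(x$boxes, row.names = FALSE)
  invisible(x)
}

#' Convert detection boxes to a binary mask
#'
#' Marks the rectangle interiors; useful for rectangle-level overlap
#' metrics against a ground-truth mask.
#'
#' @param boxes Data frame with `top`, `left`, `height`, `width` columns.
#' @param dim Length-2 integer `(height, width)` of the target mask.
#' @return Integer 0/1 matrix.
#' @export
boxes_to_mask <- function(boxes, dim) {
  m <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(boxes))) {
    rr <- boxes$top[i]:(boxes$top[i] + boxes$height[i] - 1L)
    cc <- boxes$left[i]:(boxes$left[i] + boxes$width[i] - 1L)
    m[rr, cc] <- 1L
  }
  m
}

#' Draw detection rectangles into an image
#'
#' Returns a copy of the image with 2-pixel rectangle borders drawn in the
#' given color, for visual inspection of detections.
#'
#' @param image RGB array.
#' @param boxes Data frame with `top`, `left`, `height`, `width`.
#' @param color Length-3 RGB border color (default red).
#' @return The annotated RGB array.
#' @export
draw_boxes <- function(image, boxes, color = c(1, 0, 0)) {
  image <- as_rgb_array(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  for (i in seq_len(nrow(boxes))) {
    r1 <- max(1L, boxes$top[i]); c1 <- max(1L, boxes$left[i])
    r2 <- min(h, boxes$top[i] + boxes$height[i] - 1L)
    c2 <- min(w, boxes$left[i] + boxes$width[i] - 1L)
    for (ch in 1:3) {
      image[unique(pmin(c(r1, r1 + 1L, r2 - 1L, r2), h)), c1:c2, ch] <-
        color[ch]
      image[r1:r2, unique(pmin(c(c1, c1 + 1L, c2 - 1L, c2), w)), ch] <-
        color[ch]
    }
  }
  image
}
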