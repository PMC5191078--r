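# Synthetic vineyard scenes and labeled pixel-sample tables with
# ground-truth masks, for training and end-to-end testing without
# photographs.
#
# The generator emulates the structure of the field dataset: dark purple
# berry clusters against green leaves, brown branches, sky and soil, under
# three illumination regimes. Colors are Gaussians in RGB clipped to [0,1],
# chosen so each of the four color components is individually informative
# but none perfect (sky pixels confuse Cb and the B&R line).

#' Specification of a synthetic vineyard scene
#'
#' @param height,width Image size in pixels (default 220 x 300; clusters
#'   span roughly a third of the image height, the relative scale of
#'   typical working-distance vineyard photographs).
#' @param clusters Number of grape clusters (default 2).
#' @param cluster_rx,cluster_ry Horizontal / vertical semi-axes of the
#'   elliptical footprint berries are scattered in (default 32 x 41 px,
#'   taller than wide, as hanging clusters are).
#' @param berries Berries per cluster (default 110, giving a dense,
#'   nearly solid cluster body).
#' @param berry_radius Length-2 range of berry disc radii (default
#'   7--10, comfortably above the radius-5 cleanup disc, as real berries
#'   are at working distance).
#' @param adjoining If TRUE, place exactly two clusters close enough that
#'   their masks merge into one wide region (to exercise the barycenter
#'   split); requires `clusters = 2`.
#' @param grape_color Mean RGB of ripe berries (dark purple: low G,
#'   B slightly above R).
#' @param grape_sd Per-pixel RGB noise s.d.
#' @param berry_jitter_sd Per-berry mean color jitter s.d.
#' @param background Named list of background layers (`leaf`, `branch`,
#'   `sky`, `soil`), each `list(mean, sd, weight)`; weights are the class
#'   mix used when sampling background windows.
#' @param illumination One of `"frontlight"`, `"overshadow"`, `"overcast"`:
#'   a global gain/offset applied to the rendered image (an affine stand-in
#'   for lighting conditions, not physical rendering).
#' @param highlight_prob Probability that a berry carries a small specular
#'   highlight.
#' @param pepper_density Fraction of background pixels replaced by isolated
#'   grape-colored single-pixel noise (default 0).
#' @param seed Integer RNG seed; identical spec + seed gives an identical
#'   scene.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(height = 220L, width = 300L, clusters = 2L,
                       cluster_rx = 32, cluster_ry = 41, berries = 110L,
                       berry_radius = c(7, 10), adjoining = FALSE,
                       grape_color = c(0.30, 0.10, 0.36), grape_sd = 0.05,
                       berry_jitter_sd = 0.055,
                       background = default_background(),
                       illumination = c("overcast", "frontlight",
                                        "overshadow"),
                       highlight_prob = 0.02, pepper_density = 0,
                       seed = 0L) {
  illumination <- match.arg(illumination)
  stopifnot(height >= 7, width >= 7, clusters >= 0, berries >= 1,
            length(berry_radius) == 2L, berry_radius[1] <= berry_radius[2],
            length(grape_color) == 3L, pepper_density >= 0,
            pepper_density <= 0.05)
  if (adjoining && clusters != 2L) {
    stop("adjoining placement requires exactly 2 clusters")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 clusters = as.integer(clusters), cluster_rx = cluster_rx,
                 cluster_ry = cluster_ry, berries = as.integer(berries),
                 berry_radius = berry_radius, adjoining = adjoining,
                 grape_color = grape_color, grape_sd = grape_sd,
                 berry_jitter_sd = berry_jitter_sd, background = background,
                 illumination = illumination,
                 highlight_prob = highlight_prob,
                 pepper_density = pepper_density, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_background <- function() {
  # leaf/branch/sky/soil plus two confuser layers: purple-brown dead
  # leaves overlap grape in hue, bluish shaded foliage overlaps it in Cb,
  # b* and B-R, so no single component separates the classes perfectly
  list(leaf = list(mean = c(0.22, 0.45, 0.16), sd = 0.05, weight = 0.34),
       branch = list(mean = c(0.38, 0.26, 0.13), sd = 0.04, weight = 0.14),
       sky = list(mean = c(0.62, 0.74, 0.90), sd = 0.03, weight = 0.13),
       soil = list(mean = c(0.46, 0.36, 0.24), sd = 0.04, weight = 0.14),
       dead_leaf = list(mean = c(0.30, 0.20, 0.28), sd = 0.04, weight = 0.13),
       shade = list(mean = c(0.20, 0.22, 0.40), sd = 0.05, weight = 0.12))
}

# Global gain/offset per illumination regime.
illumination_params <- function(regime) {
  switch(regime,
         frontlight = c(gain = 1.15, offset = 0.03),
         overshadow = c(gain = 0.70, offset = -0.03),
         overcast = c(gain = 0.95, offset = 0.00),
         stop("unknown illumination regime: ", regime))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a labeled pixel-sample table
#'
#' Draws `window x window` RGB pixel windows from the class color
#' distributions (grape, or a background layer chosen by the layer
#' weights), applies a per-sample illumination regime, computes the color
#' components per pixel and averages them over the window — exactly the
#' feature computation used at inference time. The default sizes mirror a
#' manually cropped field dataset (400 grape / 800 background for
#' training).
#'
#' @param n_grape,n_background Sample counts per class.
#' @param spec A [scene_spec()] supplying colors and noise levels.
#' @param seed RNG seed (defaults to the scene specification's seed).
#' @param window Window side (default 7).
#' @param regimes Illumination regimes sampled uniformly per sample;
#'   default all three, as in a mixed-conditions field dataset.
#' @return Data frame with columns `H`, `Cb`, `bstar`, `R`, `G`, `B` and
#'   `label` (+1 grape, -1 background).
#' @export
generate_samples <- function(n_grape = 400L, n_background = 800L,
                             spec = scene_spec(), seed = spec$seed,
                             window = 7L,
                             regimes = c("frontlight", "overshadow",
                                         "overcast")) {
  stopifnot(n_grape >= 1L, n_background >= 1L)
  set.seed(seed)
  npx <- window * window

  draw_class <- function(n, mean_fun) {
    out <- vector("list", n)
    regime <- sample(regimes, n, replace = TRUE)
    for (i in seq_len(n)) {
      mu <- mean_fun()
      px <- matrix(stats::rnorm(npx * 3, rep(mu, each = npx),
                                spec$grape_sd), npx, 3)
      il <- illumination_params(regime[i])
      px <- clip01(px * il["gain"] + il["offset"])
      out[[i]] <- c(mean(rgb_to_hue(px[, 1], px[, 2], px[, 3])),
                    mean(rgb_to_cb(px[, 1], px[, 2], px[, 3])),
                    mean(rgb_to_bstar(px[, 1], px[, 2], px[, 3])),
                    colMeans(px))
    }
    do.call(rbind, out)
  }

  grape <- draw_class(n_grape, function() {
    clip01(spec$grape_color + stats::rnorm(3, 0, spec$berry_jitter_sd))
  })
  layers <- spec$background
  wts <- vapply(layers, `[[`, numeric(1), "weight")
  bg <- draw_class(n_background, function() {
    ly <- layers[[sample(length(layers), 1, prob = wts)]]
    clip01(ly$mean + stats::rnorm(3, 0, ly$sd / 2))
  })

  df <- as.data.frame(rbind(grape, bg))
  names(df) <- c("H", "Cb", "bstar", "R", "G", "B")
  df$label <- rep(c(1L, -1L), c(n_grape, n_background))
  df
}

#' Render a synthetic vineyard scene with ground truth
#'
#' Background layers (sky band on top, soil band at the bottom, leaf
#' texture in between crossed by branch strips) are rendered first, then
#' each cluster as a union of overlapping berry discs with per-berry color
#' jitter and optional specular highlights. The ground-truth mask is the
#' union of the berry discs; optional isolated pepper noise and the global
#' illumination transform are applied last.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (RGB array), `mask` (0/1 matrix), `boxes`
#'   (data frame of true per-cluster enclosing rectangles: `cluster`,
#'   `top`, `left`, `height`, `width`) and `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  npx <- h * w

  # background layer map
  layer <- matrix("leaf", h, w)
  sky_rows <- seq_len(max(1L, round(0.15 * h)))
  soil_rows <- seq(h - max(1L, round(0.15 * h)) + 1L, h)
  layer[sky_rows, ] <- "sky"
  layer[soil_rows, ] <- "soil"
  mid_rows <- setdiff(seq_len(h), c(sky_rows, soil_rows))
  for (bc in sort(sample.int(w - 6L, 2L) + 3L)) {
    cols <- pmin(pmax(bc + seq(-2L, 2L), 1L), w)
    layer[mid_rows, cols] <- "branch"
  }
  # scattered elliptical patches of the confuser layers, if present
  for (nm in intersect(c("dead_leaf", "shade"), names(spec$background))) {
    for (p in 1:3) {
      pc <- stats::runif(1, 10, w - 10); pr <- stats::runif(1, 0.2, 0.8) * h
      prx <- stats::runif(1, 4, 9); pry <- stats::runif(1, 4, 9)
      sel <- (matrix(seq_len(h), h, w) - pr)^2 / pry^2 +
        (matrix(seq_len(w), h, w, byrow = TRUE) - pc)^2 / prx^2 <= 1
      layer[sel] <- nm
    }
  }
  img <- array(0, c(h, w, 3))
  for (nm in names(spec$background)) {
    ly <- spec$background[[nm]]
    sel <- layer == nm
    n <- sum(sel)
    if (!n) next
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- stats::rnorm(n, ly$mean[ch], ly$sd)
      img[, , ch] <- plane
    }
  }

  # cluster placement
  margin <- spec$cluster_rx + spec$berry_radius[2] + 1
  vmargin <- spec$cluster_ry + spec$berry_radius[2] + 1
  k <- spec$clusters
  if (k > 0L) {
    if (spec$adjoining) {
      gap <- 1.5 * spec$cluster_rx
      cx <- w / 2 + c(-gap / 2, gap / 2)
      cy <- rep(h / 2, 2)
    } else {
      cx <- w * seq_len(k) / (k + 1) + stats::runif(k, -3, 3)
      cy <- rep(h * 0.52, k) + stats::runif(k, -4, 4)
    }
    if (any(cx < margin | cx > w - margin | cy < vmargin | cy > h - vmargin)) {
      stop("cluster placement impossible within image bounds; ",
           "enlarge the image or shrink the clusters")
    }
  }

  mask <- matrix(0L, h, w)
  boxes <- NULL
  rowm <- matrix(seq_len(h), h, w)
  colm <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(k)) {
    cmask <- matrix(FALSE, h, w)
    ang <- stats::runif(spec$berries, 0, 2 * pi)
    rad <- sqrt(stats::runif(spec$berries))
    bx <- cx[i] + spec$cluster_rx * rad * cos(ang)
    by <- cy[i] + spec$cluster_ry * rad * sin(ang)
    br <- stats::runif(spec$berries, spec$berry_radius[1],
                       spec$berry_radius[2])
    for (j in seq_len(spec$berries)) {
      rr <- max(1L, floor(by[j] - br[j])):min(h, ceiling(by[j] + br[j]))
      cc <- max(1L, floor(bx[j] - br[j])):min(w, ceiling(bx[j] + br[j]))
      sub <- (rowm[rr, cc] - by[j])^2 + (colm[rr, cc] - bx[j])^2 <= br[j]^2
      bcol <- clip01(spec$grape_color +
                       stats::rnorm(3, 0, spec$berry_jitter_sd))
      idx <- which(sub)
      if (!length(idx)) next
      for (ch in 1:3) {
        plane <- img[rr, cc, ch]
        plane[idx] <- stats::rnorm(length(idx), bcol[ch], spec$grape_sd)
        img[rr, cc, ch] <- plane
      }
      cmask[rr, cc][idx] <- TRUE
      if (stats::runif(1) < spec$highlight_prob) {
        hr <- round(by[j] - br[j] / 3); hc <- round(bx[j] - br[j] / 3)
        if (hr >= 1 && hr < h && hc >= 1 && hc < w) {
          img[hr:(hr + 1L), hc:(hc + 1L), ] <- 0.95
        }
      }
    }
    mask[cmask] <- 1L
    px <- which(cmask, arr.ind = TRUE)
    boxes <- rbind(boxes, data.frame(
      cluster = i, top = min(px[, 1]), left = min(px[, 2]),
      height = diff(range(px[, 1])) + 1L,
      width = diff(range(px[, 2])) + 1L))
  }

  # isolated pepper noise on the background
  if (spec$pepper_density > 0) {
    n_pepper <- round(spec$pepper_density * npx)
    far <- which(mask == 0L)
    if (length(far) && n_pepper > 0) {
      pick <- sample(far, min(n_pepper, length(far)))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[pick] <- spec$grape_color[ch]
        img[, , ch] <- plane
      }
    }
  }

  il <- illumination_params(spec$illumination)
  img <- clip01(img * il["gain"] + il["offset"])
  list(image = img, mask = mask, boxes = boxes, spec = spec)
}

#' Write a corpus of synthetic scenes and sample tables to disk
#'
#' For every seed and illumination regime, writes the scene image (PNG),
#' its ground-truth mask (PNG) and true boxes (CSV), plus one training
#' sample table (CSV) per seed, and a JSON manifest listing every file
#' with its seed, regime and MD5 hash. Regeneration with the same seeds
#' yields identical hashes.
#'
#' @param dir Output directory (created if missing).
#' @param seeds Integer vector of scene seeds.
#' @param regimes Illumination regimes to render per seed.
#' @param spec Base [scene_spec()]; its seed/illumination are overridden.
#' @param n_grape,n_background Sizes of the per-seed sample tables.
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
generate_suite <- function(dir, seeds = 0:4,
                           regimes = c("frontlight", "overshadow",
                                       "overcast"),
                           spec = scene_spec(), n_grape = 400L,
                           n_background = 800L) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  entries <- list()
  add <- function(path, seed, regime, kind) {
    entries[[length(entries) + 1L]] <<- list(
      file = basename(path), seed = seed, regime = regime, kind = kind,
      md5 = unname(tools::md5sum(path)))
  }
  for (seed in seeds) {
    for (ri in seq_along(regimes)) {
      sp <- spec
      sp$seed <- as.integer(seed * 8L + ri)
      sp$illumination <- regimes[ri]
      scene <- generate_scene(sp)
      base <- file.path(dir, sprintf("scene_s%03d_%s", seed, regimes[ri]))
      png::writePNG(scene$image, paste0(base, ".png"))
      write_mask_png(scene$mask, paste0(base, "_mask.png"))
      utils::write.csv(scene$boxes, paste0(base, "_boxes.csv"),
                       row.names = FALSE)
      add(paste0(base, ".png"), seed, regimes[ri], "image")
      add(paste0(base, "_mask.png"), seed, regimes[ri], "mask")
      add(paste0(base, "_boxes.csv"), seed, regimes[ri], "boxes")
    }
    samples <- generate_samples(n_grape, n_background, spec,
                                seed = as.integer(seed * 8L + 7L))
    spath <- file.path(dir, sprintf("samples_s%03d.csv", seed))
    write_samples_csv(samples, spath)
    add(spath, seed, "all", "samples")
  }
  manifest <- list(seeds = as.integer(seeds), regimes = regimes,
                   files = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read and write pixel-sample tables as CSV
#'
#' One row per sample; a header row names the component columns, and the
#' `label` column holds +1 (grape) or -1 (background).
#'
#' @param samples Data frame as from [generate_samples()].
#' @param path CSV file path.
#' @return `write_samples_csv()` returns `path` invisibly;
#'   `read_samples_csv()` the data frame.
#' @export
write_samples_csv <- function(samples, path) {
  stopifnot("label" %in% names(samples))
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) {
    stop("sample CSV is missing required column: label")
  }
  if (!all(df$label %in% c(-1L, 1L))) {
    stop("sample labels must be +1 or -1")
  }
  df
}
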