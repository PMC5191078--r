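# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# Default training samples and strong classifier (deterministic).
fixture_samples <- function() {
  if (is.null(.fixture_env$samples)) {
    .fixture_env$samples <- generate_samples(400, 800, seed = 1)
  }
  .fixture_env$samples
}

fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- grape_boost(fixture_samples())
  }
  .fixture_env$fit
}

# Binary mask with rectangular components of the given areas (height 10),
# spaced so they never touch.
mask_with_areas <- function(areas, height = 10L) {
  widths <- as.integer(areas / height)
  stopifnot(all(widths * height == areas))
  w <- sum(widths) + 5L * (length(areas) + 1L)
  m <- matrix(0L, height + 10L, w)
  left <- 5L
  for (wd in widths) {
    m[6:(5L + height), left:(left + wd - 1L)] <- 1L
    left <- left + wd + 5L
  }
  m
}

# Dumbbell: two squares joined by a thin bridge.
dumbbell_mask <- function(side = 20L, bridge = 8L, bridge_h = 2L) {
  h <- side + 10L
  w <- 2L * side + bridge + 10L
  m <- matrix(0L, h, w)
  m[6:(5L + side), 6:(5L + side)] <- 1L
  m[6:(5L + side), (6L + side + bridge):(5L + 2L * side + bridge)] <- 1L
  mid <- 5L + side %/% 2L
  m[mid:(mid + bridge_h - 1L), (6L + side):(5L + side + bridge)] <- 1L
  m
}

# Uniform-color image of the given size.
uniform_image <- function(rgb, h = 20L, w = 20L) {
  array(rep(rgb, each = h * w), c(h, w, 3))
}
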