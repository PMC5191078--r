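# Independent oracles: straightforward scalar evaluations of the printed
# formulas and brute-force searches, kept deliberately separate from the
# package's vectorized implementations.

oracle_hue <- function(r, g, b) {
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  if (den == 0) return(0)
  theta <- acos(max(-1, min(1, num / den))) * 180 / pi
  if (b <= g) theta / 360 else (360 - theta) / 360
}

oracle_cb <- function(r, g, b) {
  cb <- (-0.1687 * (r * 255) - 0.3313 * (g * 255) + 0.500 * (b * 255)) + 128
  max(0, min(255, cb)) / 255
}

oracle_bstar <- function(r, g, b, lo = -128, hi = 127) {
  m <- rbind(c(0.49, 0.31, 0.20),
             c(0.17697, 0.81240, 0.01063),
             c(0.00, 0.01, 0.99))
  xyz <- (m %*% c(r, g, b)) / 0.17697
  f <- function(t) if (t > 0.008856) t^(1 / 3) else 7.787 * t + 0.138
  braw <- 200 * (f(xyz[2]) - f(xyz[3] / 1.192))
  max(0, min(1, (braw - lo) / (hi - lo)))
}

# Brute-force weighted threshold search: evaluates the error at every
# sample value +/- eps and well outside the range, for both decision kinds.
oracle_lce_threshold <- function(x, y, w = rep(1 / length(x), length(x)),
                                 kind = "above", eps = 1e-7) {
  w <- w / sum(w)
  cands <- sort(unique(c(x - eps, x + eps, min(x) - 1, max(x) + 1)))
  errs <- vapply(cands, function(th) {
    pred <- if (kind == "above") ifelse(x >= th, 1, -1) else
      ifelse(th - x >= 0, 1, -1)
    sum(w[pred != y])
  }, numeric(1))
  list(threshold = cands[which.min(errs)], error = min(errs))
}

# Classification error of an arbitrary mask pair restricted to a pixel set.
mask_agreement <- function(a, b) mean((a > 0) == (b > 0))

# Disc structuring element built independently of the package internals.
disc_kernel_oracle <- function(radius) {
  d <- seq(-radius, radius)
  outer(d, d, function(x, y) as.numeric(x^2 + y^2 <= radius^2))
}
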