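# Linear weak classifiers over color components and their
# lowest-classification-error (LCE) training.
#
# Three model kinds are supported:
#   threshold_above : margin = value - threshold   (hue / Cb style)
#   threshold_below : margin = threshold - value   (b* style)
#   line            : margin = a*v1 + b*v2 + c     (two-channel style)
# A positive margin votes grape (+1); the decision rule h(x) = +1 iff
# margin >= 0 includes the boundary.

#' Construct a weak classification model
#'
#' @param kind One of `"threshold_above"`, `"threshold_below"`, `"line"`.
#' @param components Component id(s): one id for the threshold kinds, two for
#'   the line kind (see [component_ids()]).
#' @param params Named list: `threshold` for the threshold kinds; `a`, `b`,
#'   `c` for the line kind (margin `a*v1 + b*v2 + c`, positive = grape side).
#' @return An object of class `weak_model`.
#' @export
weak_model <- function(kind = c("threshold_above", "threshold_below", "line"),
                       components, params) {
  kind <- match.arg(kind)
  components <- as.character(components)
  if (kind == "line") {
    stopifnot(length(components) == 2L,
              all(c("a", "b", "c") %in% names(params)))
  } else {
    stopifnot(length(components) == 1L, "threshold" %in% names(params))
  }
  structure(list(kind = kind, components = components,
                 params = lapply(params, as.numeric)),
            class = "weak_model")
}

#' @export
print.weak_model <- function(x, ...) {
  cat("Weak classifier:", equation_string(x), "\n")
  invisible(x)
}

# Human-readable dividing-line equation, Table-1 style.
equation_string <- function(model) {
  p <- model$params
  switch(model$kind,
    threshold_above = sprintf("%s(x) - %.4g = 0", model$components[1],
                              p$threshold),
    threshold_below = sprintf("%.4g - %s(x) = 0", p$threshold,
                              model$components[1]),
    line = sprintf("%.4g*%s(x) %s %.4g*%s(x) %s %.4g = 0",
                   p$a, model$components[1],
                   if (p$b < 0) "-" else "+", abs(p$b), model$components[2],
                   if (p$c < 0) "-" else "+", abs(p$c)))
}

#' Signed decision margin of a weak model
#'
#' @param model A [weak_model()].
#' @param features Data frame (or named list of equal-length numeric
#'   vectors) containing the model's component(s) as columns.
#' @return Numeric vector of signed margins; positive values are on the
#'   grape side of the dividing line.
#' @export
decision_value <- function(model, features) {
  stopifnot(inherits(model, "weak_model"))
  missing <- setdiff(model$components, names(features))
  if (length(missing)) {
    stop("feature(s) missing from sample: ", paste(missing, collapse = ", "))
  }
  p <- model$params
  switch(model$kind,
    threshold_above = features[[model$components[1]]] - p$threshold,
    threshold_below = p$threshold - features[[model$components[1]]],
    line = p$a * features[[model$components[1]]] +
           p$b * features[[model$components[2]]] + p$c)
}

#' Classify samples with a weak model
#'
#' Returns `+1` (grape) when the decision margin is `>= 0` — the boundary
#' belongs to the grape class — and `-1` (background) otherwise.
#'
#' @inheritParams decision_value
#' @return Integer vector of labels in `{-1, +1}`.
#' @export
weak_classify <- function(model, features) {
  ifelse(decision_value(model, features) >= 0, 1L, -1L)
}

#' Train a single-component threshold classifier by exhaustive LCE search
#'
#' Minimizes the weighted misclassification rate over all candidate
#' thresholds: the midpoints between consecutive sorted distinct feature
#' values plus one sentinel below the minimum and one above the maximum
#' (so a constant classifier is always attainable). With uniform weights
#' this is the plain lowest-classification-error criterion. Ties among
#' equally optimal thresholds are broken toward the candidate with the
#' largest margin to the nearest sample value, then toward the smallest
#' threshold, making the search deterministic.
#'
#' @param data Data frame of features (or numeric vector of the component's
#'   values).
#' @param labels Integer vector of class labels in `{-1, +1}`.
#' @param component Component id naming the feature column.
#' @param kind `"above"` (grape when value >= threshold) or `"below"`.
#' @param weights Nonnegative per-sample weights (normalized internally);
#'   default uniform.
#' @return List with elements `model` (a [weak_model()]) and `error` (the
#'   achieved weighted misclassification rate).
#' @export
train_lce_threshold <- function(data, labels, component,
                                kind = c("above", "below"), weights = NULL) {
  kind <- match.arg(kind)
  x <- if (is.numeric(data)) data else data[[component]]
  if (is.null(x)) stop("feature(s) missing from sample: ", component)
  check_training_input(x, labels)
  w <- normalize_weights(weights, length(x))

  ord <- order(x)
  xs <- x[ord]; ys <- labels[ord]; ws <- w[ord]
  n <- length(xs)
  cum_pos <- cumsum(ws * (ys == 1))
  cum_neg <- cumsum(ws * (ys == -1))
  tot_pos <- cum_pos[n]; tot_neg <- cum_neg[n]

  # boundaries: after sorted position i, for i in {0, change points, n}
  cuts <- c(0L, which(diff(xs) > 0), n)
  cp <- c(0, cum_pos)[cuts + 1L]
  cn <- c(0, cum_neg)[cuts + 1L]
  err <- if (kind == "above") cp + (tot_neg - cn) else cn + (tot_pos - cp)

  thr <- numeric(length(cuts))
  gap <- numeric(length(cuts))
  inner <- cuts > 0L & cuts < n
  thr[cuts == 0L] <- xs[1] - 1
  thr[cuts == n] <- xs[n] + 1
  thr[inner] <- (xs[cuts[inner]] + xs[cuts[inner] + 1L]) / 2
  gap[cuts == 0L | cuts == n] <- 1
  gap[inner] <- (xs[cuts[inner] + 1L] - xs[cuts[inner]]) / 2

  best <- which(err == min(err))
  best <- best[order(-gap[best], thr[best])][1]
  model <- weak_model(paste0("threshold_", kind), component,
                      list(threshold = thr[best]))
  list(model = model, error = as.numeric(err[best]))
}

#' Train a two-component line classifier by direction-and-intercept search
#'
#' Scans `n_directions` unit directions \eqn{(a,b) = (\cos\theta,
#' \sin\theta)} over the half circle, projects samples onto
#' \eqn{a v_1 + b v_2}, and optimizes the intercept exactly with the 1-D
#' threshold search of [train_lce_threshold()]; both orientations of each
#' direction are considered, so the grape side may lie on either side of the
#' line. The search is exact in the intercept and dense in angle.
#'
#' @inheritParams train_lce_threshold
#' @param components Length-2 character vector of component ids.
#' @param n_directions Number of directions over the half circle
#'   (default 180, i.e. 1 degree resolution).
#' @return List with elements `model` (a line [weak_model()] with params
#'   `a`, `b`, `c`) and `error`.
#' @export
train_lce_line <- function(data, labels, components, weights = NULL,
                           n_directions = 180L) {
  stopifnot(length(components) == 2L, n_directions >= 1L)
  missing <- setdiff(components, names(data))
  if (length(missing)) {
    stop("feature(s) missing from sample: ", paste(missing, collapse = ", "))
  }
  v1 <- data[[components[1]]]; v2 <- data[[components[2]]]
  check_training_input(v1, labels)
  w <- normalize_weights(weights, length(v1))

  best <- NULL
  for (theta in (seq_len(n_directions) - 1L) * pi / n_directions) {
    a <- cos(theta); b <- sin(theta)
    p <- a * v1 + b * v2
    for (kind in c("above", "below")) {
      fit <- train_lce_threshold(p, labels, "proj", kind, w)
      if (is.null(best) || fit$error < best$error) {
        th <- fit$model$params$threshold
        coefs <- if (kind == "above") c(a, b, -th) else c(-a, -b, th)
        best <- list(coefs = coefs, error = fit$error)
      }
    }
  }
  model <- weak_model("line", components,
                      list(a = best$coefs[1], b = best$coefs[2],
                           c = best$coefs[3]))
  list(model = model, error = best$error)
}

check_training_input <- function(x, labels) {
  stopifnot(length(x) == length(labels), all(labels %in% c(-1, 1)))
  if (!any(labels == 1) || !any(labels == -1)) {
    stop("training data must contain at least one sample of each class")
  }
  invisible(TRUE)
}

normalize_weights <- function(weights, n) {
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  s <- sum(weights)
  if (s <= 0) stop("weights must sum to a positive number")
  weights / s
}
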