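# Detection and classification metrics.
#
# Naming caveat: the rates follow the source method's idiosyncratic usage.
# Its "FNR" is a false-discovery-style rate over detections (spurious /
# (spurious + correct)), and its "FPR" is the miss rate over true clusters.
# They are implemented exactly as defined, warts and all.

#' Detection tallies for a test set
#'
#' @param total Number of true grape clusters.
#' @param correctly_done Number detected correctly.
#' @param false_negative Number of background regions misreported as
#'   clusters (the method's "false negatives", i.e. spurious detections).
#' @return Object of class `detection_counts`; `missed_done` is derived as
#'   `total - correctly_done`.
#' @export
detection_counts <- function(total, correctly_done, false_negative) {
  stopifnot(total >= 0, correctly_done >= 0, false_negative >= 0,
            correctly_done <= total)
  structure(list(total = total, correctly_done = correctly_done,
                 false_negative = false_negative,
                 missed_done = total - correctly_done),
            class = "detection_counts")
}

#' Detection rates (method's definitions)
#'
#' `fnr()` = 100 * FN / (FN + correct): spurious detections over all
#' detections. `fpr()` = 100 * missed / total: the miss rate. `tpr()` =
#' 100 * correct / total: the detection rate. Note `tpr + fpr = 100` by
#' construction. The names are the method's own, nonstandard usage (see
#' the package vignette).
#'
#' @param counts A [detection_counts()] object.
#' @return Percentage in \[0,100\].
#' @export
fnr <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  den <- counts$false_negative + counts$correctly_done
  if (den <= 0) stop("no detections: FNR undefined")
  100 * counts$false_negative / den
}

#' @rdname fnr
#' @export
fpr <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  if (counts$total <= 0) stop("no true clusters: FPR undefined")
  100 * counts$missed_done / counts$total
}

#' @rdname fnr
#' @export
tpr <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  if (counts$total <= 0) stop("no true clusters: TPR undefined")
  100 * counts$correctly_done / counts$total
}

#' Two-class confusion tallies for pixel-sample classification
#'
#' @param grape_as_grape,grape_as_background Counts for true grape samples.
#' @param background_as_grape,background_as_background Counts for true
#'   background samples.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(grape_as_grape, grape_as_background,
                             background_as_grape, background_as_background) {
  counts <- c(grape_as_grape, grape_as_background,
              background_as_grape, background_as_background)
  stopifnot(all(counts >= 0))
  structure(list(grape_as_grape = grape_as_grape,
                 grape_as_background = grape_as_background,
                 background_as_grape = background_as_grape,
                 background_as_background = background_as_background),
            class = "confusion_counts")
}

#' Overall sample-classification accuracy
#'
#' 100 * (correct grape + correct background) / all samples.
#'
#' @param conf A [confusion_counts()] object.
#' @return Percentage in \[0,100\].
#' @export
accuracy <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  total <- conf$grape_as_grape + conf$grape_as_background +
    conf$background_as_grape + conf$background_as_background
  if (total <= 0) stop("no samples: accuracy undefined")
  100 * (conf$grape_as_grape + conf$background_as_background) / total
}

#' Pixel recognition accuracy (PRA)
#'
#' \eqn{PRA = 100\,|manual \cap algorithm| / |manual|}: the fraction of the
#' hand-labeled cluster pixels recovered by the algorithm. 75% or more is
#' the usability bar for a harvesting robot.
#'
#' @param manual Ground-truth binary mask (matrix) or logical vector.
#' @param algorithm Predicted binary mask of the same shape.
#' @return Percentage in \[0,100\].
#' @export
pra <- function(manual, algorithm) {
  stopifnot(length(manual) == length(algorithm))
  m <- manual > 0; a <- algorithm > 0
  if (!any(m)) stop("manual region is empty: PRA undefined")
  100 * sum(m & a) / sum(m)
}

#' Mean of PRA percentages
#'
#' @param values Nonempty numeric vector of percentages.
#' @return Their arithmetic mean.
#' @export
mean_pra <- function(values) {
  if (!length(values)) stop("no PRA values")
  mean(values)
}

#' Round half-up for percentage display
#'
#' Display rounding used by the reporting tables (half-up, unlike base R's
#' round-half-even); raw values are carried at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}
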