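# Discrete AdaBoost over the pool of color-component weak-classifier
# families, and the S3 modelling interface around it.

#' Default weak-classifier family pool
#'
#' The four families used for dark-grape detection: hue above a threshold,
#' Cb above a threshold, b* below a threshold, and a two-channel dividing
#' line (default channels B and R).
#'
#' @param line_components Length-2 character vector for the line family.
#' @return List of family specifications accepted by [grape_boost()].
#' @export
default_pool <- function(line_components = c("B", "R")) {
  list(list(kind = "threshold_above", components = "H"),
       list(kind = "threshold_above", components = "Cb"),
       list(kind = "threshold_below", components = "bstar"),
       list(kind = "line", components = line_components))
}

#' Uniform initial sample weights
#'
#' @param n Positive sample count.
#' @return Numeric vector of `n` weights, each `1/n`.
#' @export
init_weights <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive count")
  rep(1 / n, n)
}

#' Weighted misclassification rate of a weak model
#'
#' \eqn{\epsilon = \sum_i D(x_i)\,[y_i \ne h(x_i)]}, the sum of the weights
#' of misclassified samples.
#'
#' @inheritParams decision_value
#' @param labels Labels in `{-1, +1}`.
#' @param weights Normalized sample weights.
#' @return The weighted error in \[0,1\].
#' @export
weighted_error <- function(model, features, labels, weights) {
  sum(weights[weak_classify(model, features) != labels])
}

#' Weak-classifier weight from its round error
#'
#' \eqn{\alpha = \tfrac12 \ln\frac{1-\epsilon}{\epsilon}} (natural
#' logarithm). Defined for \eqn{\epsilon \in (0, 0.5)}; a perfect or
#' worse-than-chance learner must be handled by the caller (see
#' [grape_boost()], which floors \eqn{\epsilon} at `1/(2N)` and rejects
#' \eqn{\epsilon \ge 0.5}).
#'
#' @param epsilon Weighted error, strictly between 0 and 0.5.
#' @return The round weight \eqn{\alpha > 0}.
#' @examples
#' alpha_from_error(0.119)  # 1.001 to 3 decimals
#' @export
alpha_from_error <- function(epsilon) {
  stopifnot(length(epsilon) == 1L, is.finite(epsilon))
  if (epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must lie strictly between 0 and 0.5, got ", epsilon)
  }
  0.5 * log((1 - epsilon) / epsilon)
}

#' AdaBoost sample-weight update
#'
#' Correctly classified samples are scaled by \eqn{e^{-\alpha}},
#' misclassified ones by \eqn{e^{+\alpha}}, and the result is renormalized
#' to sum to 1 so the next round's weights form a distribution.
#'
#' @inheritParams weighted_error
#' @param alpha The round weight.
#' @return Normalized weight vector.
#' @export
update_weights <- function(weights, model, features, labels, alpha) {
  correct <- weak_classify(model, features) == labels
  w <- weights * exp(ifelse(correct, -alpha, alpha))
  w / sum(w)
}

#' Fit a boosted color-component grape classifier
#'
#' Discrete AdaBoost over a pool of weak-classifier families. Each round,
#' every available family is trained under the current sample weights by
#' the exhaustive LCE search ([train_lce_threshold()],
#' [train_lce_line()]); the family with the lowest weighted error is
#' retained with weight \eqn{\alpha_t = \tfrac12\ln((1-\epsilon_t)/
#' \epsilon_t)} and the sample weights are re-focused on its mistakes.
#' Boosting stops when a round's best error reaches 0.5 (round discarded),
#' when the strong classifier's training error drops below `target_error`,
#' when the pool is exhausted (`without_replacement = TRUE`, the default,
#' which uses each family at most once), or after `max_rounds` rounds.
#' A perfect round (\eqn{\epsilon_t = 0}) has its error floored at
#' `1/(2N)` so its weight stays finite while still dominating.
#'
#' @param data Data frame whose columns include the component features
#'   named by the pool (and, for the default method with `labels = NULL`,
#'   a `label` column), or a formula (see
#'   `grape_boost(formula, data, ...)`).
#' @param labels Integer vector of class labels, `+1` grape, `-1`
#'   background.
#' @param pool List of family specifications, each
#'   `list(kind =, components =)` as produced by [default_pool()]; when
#'   `refit = FALSE` the entries must instead be fitted [weak_model()]
#'   objects, which are only weighted, never re-trained.
#' @param max_rounds Maximum boosting rounds (capped at 5000).
#' @param target_error Stop once the strong classifier's unweighted
#'   training error falls below this (default 0.05).
#' @param without_replacement Use each family at most once (default TRUE);
#'   set FALSE for classical boosting with repeatable families.
#' @param refit Re-train family parameters each round under the current
#'   weights (default TRUE).
#' @param n_directions Angular resolution of the line-family search.
#' @param ... Passed between methods.
#' @return An object of class `grape_boost` with components `rounds`
#'   (list of `list(model, alpha, epsilon)`), `trace` (per-round data
#'   frame), `weight_history` (list of post-update weight vectors),
#'   `training_error`, `config` and `call`. Methods: [predict.grape_boost()],
#'   `print`, `summary`, `coef`, `plot`.
#' @examples
#' samples <- generate_samples(60, 120, seed = 1)
#' fit <- grape_boost(samples)
#' summary(fit)
#' @export
grape_boost <- function(data, ...) UseMethod("grape_boost")

#' @rdname grape_boost
#' @export
grape_boost.default <- function(data, labels = NULL, pool = default_pool(),
                                max_rounds = length(pool),
                                target_error = 0.05,
                                without_replacement = TRUE, refit = TRUE,
                                n_directions = 180L, ...) {
  data <- as.data.frame(data)
  if (is.null(labels)) {
    if (!"label" %in% names(data)) {
      stop("labels not given and no 'label' column in data")
    }
    labels <- data$label
    data <- data[setdiff(names(data), "label")]
  }
  labels <- as.integer(labels)
  stopifnot(length(pool) >= 1L, max_rounds >= 1L,
            target_error > 0, target_error < 0.5)
  max_rounds <- min(max_rounds, 5000L)
  check_training_input(data[[1]], labels)

  n <- length(labels)
  eps_floor <- 1 / (2 * n)
  d <- init_weights(n)
  available <- seq_along(pool)
  rounds <- list()
  weight_history <- list()
  trace <- NULL
  score <- numeric(n)

  for (t in seq_len(max_rounds)) {
    fits <- lapply(available, function(j) {
      fam <- pool[[j]]
      if (!refit) {
        stopifnot(inherits(fam, "weak_model"))
        return(list(model = fam,
                    error = weighted_error(fam, data, labels, d)))
      }
      switch(fam$kind,
        threshold_above = train_lce_threshold(data, labels, fam$components,
                                              "above", d),
        threshold_below = train_lce_threshold(data, labels, fam$components,
                                              "below", d),
        line = train_lce_line(data, labels, fam$components, d, n_directions),
        stop("unknown weak-model kind: ", fam$kind))
    })
    errs <- vapply(fits, `[[`, numeric(1), "error")
    j <- which.min(errs)
    eps <- errs[j]
    if (eps >= 0.5) {
      if (t == 1L) stop("no weak learner better than chance")
      break
    }
    model <- fits[[j]]$model
    alpha <- alpha_from_error(max(eps, eps_floor))
    d <- update_weights(d, model, data, labels, alpha)
    score <- score + alpha * weak_classify(model, data)
    strong_err <- mean(ifelse(score > 0, 1L, -1L) != labels)

    rounds[[t]] <- list(model = model, alpha = alpha, epsilon = eps)
    weight_history[[t]] <- d
    trace <- rbind(trace, data.frame(
      round = t, family = available[j], kind = model$kind,
      components = paste(model$components, collapse = "&"),
      epsilon = eps, alpha = alpha, train_error = strong_err))
    if (without_replacement) available <- setdiff(available, available[j])
    if (strong_err < target_error || length(available) == 0L) break
  }

  structure(list(
    rounds = rounds, trace = trace, weight_history = weight_history,
    training_error = trace$train_error[nrow(trace)],
    config = list(max_rounds = max_rounds, target_error = target_error,
                  without_replacement = without_replacement, refit = refit,
                  n_directions = n_directions),
    call = match.call()), class = "grape_boost")
}

#' @rdname grape_boost
#' @param formula A formula such as `label ~ .` naming the label column;
#'   the right-hand side selects feature columns.
#' @export
grape_boost.formula <- function(data, ...) {
  # 'data' is the formula by positional dispatch; the data frame arrives in ...
  formula <- data
  dots <- list(...)
  df <- as.data.frame(dots[[1]])
  dots <- dots[-1]
  mf <- stats::model.frame(formula, df)
  y <- stats::model.response(mf)
  x <- mf[setdiff(names(mf), all.vars(formula[[2]]))]
  do.call(grape_boost.default, c(list(data = x, labels = y), dots))
}

#' Classify samples with a strong classifier
#'
#' \eqn{H(x) = \mathrm{sign}(\sum_t \alpha_t h_t(x))} with the strict-`>`
#' convention: an exact zero score is background (-1).
#'
#' @param object A `grape_boost` model.
#' @param features Data frame of component features.
#' @return Integer labels in `{-1, +1}`.
#' @export
strong_classify <- function(object, features) {
  ifelse(strong_score(object, features) > 0, 1L, -1L)
}

#' @rdname strong_classify
#' @return `strong_score()` returns the real-valued vote sum
#'   \eqn{\sum_t \alpha_t h_t(x)}.
#' @export
strong_score <- function(object, features) {
  stopifnot(inherits(object, "grape_boost"), length(object$rounds) >= 1L)
  Reduce(`+`, lapply(object$rounds, function(r) {
    r$alpha * weak_classify(r$model, features)
  }))
}

#' Predict method for grape_boost models
#'
#' @param object A fitted `grape_boost` model.
#' @param newdata Data frame of component features.
#' @param type `"class"` for labels in `{-1, +1}` or `"score"` for the raw
#'   weighted vote sum.
#' @param ... Ignored.
#' @return Numeric or integer vector, one value per row of `newdata`.
#' @export
predict.grape_boost <- function(object, newdata,
                                type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") strong_score(object, newdata)
  else strong_classify(object, newdata)
}

#' @export
print.grape_boost <- function(x, ...) {
  cat("Boosted color-component grape classifier\n")
  cat(sprintf("  rounds: %d, training error: %.4f\n",
              length(x$rounds), x$training_error))
  invisible(x)
}

#' @export
summary.grape_boost <- function(object, ...) {
  tab <- data.frame(
    round = object$trace$round,
    equation = vapply(object$rounds, function(r) equation_string(r$model), ""),
    epsilon = object$trace$epsilon,
    alpha = object$trace$alpha,
    train_error = object$trace$train_error)
  structure(list(table = tab, training_error = object$training_error,
                 config = object$config),
            class = "summary.grape_boost")
}

#' @export
print.summary.grape_boost <- function(x, ...) {
  cat("Boosted grape classifier: per-round weak classifiers\n\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("\nFinal training error: %.4f\n", x$training_error))
  invisible(x)
}

#' @export
coef.grape_boost <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$rounds), function(t) {
    r <- object$rounds[[t]]
    p <- r$model$params
    data.frame(round = t, kind = r$model$kind,
               components = paste(r$model$components, collapse = "&"),
               threshold = if (is.null(p$threshold)) NA_real_ else p$threshold,
               a = if (is.null(p$a)) NA_real_ else p$a,
               b = if (is.null(p$b)) NA_real_ else p$b,
               c = if (is.null(p$c)) NA_real_ else p$c,
               epsilon = r$epsilon, alpha = r$alpha)
  }))
}

#' @export
plot.grape_boost <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$round, tr$train_error, type = "b", pch = 16,
                 ylim = c(0, max(tr$epsilon, tr$train_error)),
                 xlab = "boosting round", ylab = "error",
                 main = "Boosting progress", ...)
  graphics::lines(tr$round, tr$epsilon, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", legend = c("strong training error",
                                          "round weighted error"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Serialize a strong classifier to JSON
#'
#' The JSON schema stores each round's kind, components, parameters at full
#' precision, alpha and round error, plus the fitting configuration, and
#' [load_model()] restores an equivalent `grape_boost` object.
#'
#' @param object A `grape_boost` model.
#' @param path Output JSON path.
#' @return `path` invisibly (`save_model`); the restored model
#'   (`load_model`).
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "grape_boost"))
  payload <- list(
    rounds = lapply(object$rounds, function(r) {
      list(kind = r$model$kind, components = as.list(r$model$components),
           params = r$model$params, alpha = r$alpha, epsilon = r$epsilon)
    }),
    training_error = object$training_error,
    config = object$config,
    metadata = list(package = "grapeboost",
                    version = as.character(utils::packageVersion("grapeboost"))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$rounds) || !length(payload$rounds)) {
    stop("not a grapeboost model file (no rounds): ", path)
  }
  rounds <- lapply(payload$rounds, function(r) {
    list(model = weak_model(r$kind, unlist(r$components),
                            lapply(r$params, as.numeric)),
         alpha = as.numeric(r$alpha), epsilon = as.numeric(r$epsilon))
  })
  trace <- data.frame(
    round = seq_along(rounds),
    family = NA_integer_,
    kind = vapply(rounds, function(r) r$model$kind, ""),
    components = vapply(rounds, function(r) {
      paste(r$model$components, collapse = "&")
    }, ""),
    epsilon = vapply(rounds, `[[`, numeric(1), "epsilon"),
    alpha = vapply(rounds, `[[`, numeric(1), "alpha"),
    train_error = NA_real_)
  structure(list(rounds = rounds, trace = trace, weight_history = list(),
                 training_error = as.numeric(payload$training_error),
                 config = payload$config, call = NULL),
            class = "grape_boost")
}
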