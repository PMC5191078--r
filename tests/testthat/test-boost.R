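# AdaBoost training, the strong classifier, and model serialization.

test_that("weight initialization and the error/alpha/update arithmetic", {
  expect_equal(init_weights(4), rep(0.25, 4))
  expect_equal(init_weights(1), 1)
  expect_equal(sum(init_weights(97)), 1)
  expect_error(init_weights(0))

  m <- weak_model("threshold_above", "v", list(threshold = 0.5))
  d <- data.frame(v = c(0.1, 0.9, 0.8, 0.2))
  y <- c(-1, 1, 1, -1)
  w <- rep(0.25, 4)
  expect_equal(weighted_error(m, d, y, w), 0)
  expect_equal(weighted_error(m, d, c(-1, -1, 1, -1), w), 0.25)
  expect_equal(weighted_error(m, d, -y, w), 1)
})

test_that("alpha uses the natural log and rejects out-of-range errors", {
  expect_equal(round(alpha_from_error(0.119), 3), 1.001)
  expect_equal(round(alpha_from_error(0.225), 3), 0.618)
  expect_lt(alpha_from_error(0.4999), 1e-3)
  expect_error(alpha_from_error(0))
  expect_error(alpha_from_error(0.5))
  expect_error(alpha_from_error(0.7))
})

test_that("weight update renormalizes and emphasizes mistakes", {
  m <- weak_model("threshold_above", "v", list(threshold = 0.5))
  d <- data.frame(v = c(0.9, 0.1))
  y <- c(1, 1)                       # second sample misclassified
  w2 <- update_weights(c(0.5, 0.5), m, d, y, 0.5 * log(3))
  expect_equal(w2, c(0.25, 0.75), tolerance = 1e-12)
  set.seed(31)
  dd <- data.frame(v = runif(10)); yy <- sample(c(-1, 1), 10, TRUE)
  a <- 0.8
  w <- runif(10); w <- w / sum(w)
  wn <- update_weights(w, m, dd, yy, a)
  expect_equal(sum(wn), 1, tolerance = 1e-12)
  wrong <- weak_classify(m, dd) != yy
  if (any(wrong) && any(!wrong)) {
    expect_true(all((wn / w)[wrong] > max((wn / w)[!wrong])))
  }
})

test_that("separable one-component data trains in a single round", {
  d <- data.frame(H = c(0.1, 0.2, 0.8, 0.9))
  fit <- grape_boost(d, c(-1, -1, 1, 1),
                     pool = list(list(kind = "threshold_above",
                                      components = "H")))
  expect_equal(length(fit$rounds), 1L)
  expect_equal(fit$training_error, 0)
  expect_identical(predict(fit, d), c(-1L, -1L, 1L, 1L))
})

test_that("boosting combines individually imperfect thresholds to error 0", {
  # positive iff either channel is high: no single threshold separates
  d <- data.frame(A = c(0.8, 0.2, 0.8, 0.2, 0.3, 0.1),
                  B = c(0.2, 0.8, 0.8, 0.2, 0.1, 0.3))
  y <- c(1, 1, 1, -1, -1, -1)
  pool <- list(list(kind = "threshold_above", components = "A"),
               list(kind = "threshold_above", components = "B"))
  fit <- grape_boost(d, y, pool = pool, without_replacement = FALSE,
                     max_rounds = 6, target_error = 0.01)
  expect_equal(fit$training_error, 0)
  expect_true(all(fit$trace$epsilon > 0))
  expect_identical(strong_classify(fit, d), as.integer(y))
})

test_that("boosting on the default fixture satisfies the AdaBoost contracts", {
  samples <- fixture_samples()
  fit <- fixture_fit()
  feats <- samples[setdiff(names(samples), "label")]
  y <- samples$label

  # every retained round is better than chance with positive weight
  expect_true(all(fit$trace$epsilon < 0.5))
  expect_true(all(fit$trace$alpha > 0))
  # weights remain a distribution after every round
  for (w in fit$weight_history) {
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  # classical AdaBoost training-error bound
  bound <- prod(2 * sqrt(fit$trace$epsilon * (1 - fit$trace$epsilon)))
  expect_lte(fit$training_error, bound + 1e-12)
  # strong accuracy at least matches every individual weak accuracy
  for (r in fit$rounds) {
    weak_acc <- mean(weak_classify(r$model, feats) == y)
    expect_gte(mean(strong_classify(fit, feats) == y), weak_acc)
  }
  # each family used at most once without replacement
  expect_lte(length(fit$rounds), 4L)
  expect_false(any(duplicated(fit$trace$family)))
})

test_that("training is deterministic for identical inputs", {
  s <- generate_samples(60, 120, seed = 5)
  f1 <- grape_boost(s)
  f2 <- grape_boost(s)
  expect_equal(f1$trace, f2$trace)
  expect_equal(coef(f1), coef(f2))
})

test_that("first round recovers a planted separating threshold", {
  set.seed(33)
  hits <- 0L
  for (rep in 1:20) {
    n <- 60
    h <- c(runif(n / 2, 0.62, 0.95), runif(n / 2, 0.05, 0.40))
    d <- data.frame(H = h + rnorm(n, 0, 0.01))
    y <- rep(c(1, -1), each = n / 2)
    fit <- grape_boost(d, y, pool = list(list(kind = "threshold_above",
                                              components = "H")))
    th <- fit$rounds[[1]]$model$params$threshold
    if (th > max(d$H[y == -1]) && th < min(d$H[y == 1])) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("worse-than-chance first rounds are rejected outright", {
  d <- data.frame(v = c(0.1, 0.9, 0.1, 0.9))
  y <- c(1, -1, -1, 1)  # no threshold beats 0.5
  expect_error(grape_boost(d, y, pool = list(list(
    kind = "threshold_above", components = "v"))), "chance")
})

test_that("frozen pools are weighted without re-fitting", {
  s <- fixture_samples()
  pool <- lapply(fixture_fit()$rounds, `[[`, "model")
  fit <- grape_boost(s, pool = pool, refit = FALSE)
  fitted_params <- lapply(fit$rounds, function(r) r$model$params)
  expect_true(all(vapply(fitted_params, function(p) {
    any(vapply(pool, function(m) identical(m$params, p), logical(1)))
  }, logical(1))))
})

test_that("strong classification follows Table-1-style weighted voting", {
  mk <- function(comp, th) weak_model("threshold_above", comp,
                                      list(threshold = th))
  clf <- structure(list(rounds = list(
    list(model = mk("a", 0.5), alpha = 1.537, epsilon = 0.044),
    list(model = mk("b", 0.5), alpha = 1.001, epsilon = 0.119),
    list(model = mk("c", 0.5), alpha = 0.620, epsilon = 0.225),
    list(model = mk("d", 0.5), alpha = 0.331, epsilon = 0.341))),
    class = "grape_boost")
  # votes (+1, +1, -1, -1): 1.537 + 1.001 - 0.620 - 0.331 = +1.587
  x <- data.frame(a = 1, b = 1, c = 0, d = 0)
  expect_equal(strong_score(clf, x), 1.587, tolerance = 1e-12)
  expect_identical(strong_classify(clf, x), 1L)
  # all votes against
  x2 <- data.frame(a = 0, b = 0, c = 0, d = 0)
  expect_identical(strong_classify(clf, x2), -1L)
  # an exact zero vote sum is background (strict >)
  clf0 <- structure(list(rounds = list(
    list(model = mk("a", 0.5), alpha = 1, epsilon = 0.2),
    list(model = mk("b", 0.5), alpha = 1, epsilon = 0.2))),
    class = "grape_boost")
  expect_identical(strong_classify(clf0, data.frame(a = 1, b = 0)), -1L)
})

test_that("models survive a JSON round-trip at full precision", {
  fit <- fixture_fit()
  tf <- tempfile(fileext = ".json")
  save_model(fit, tf)
  back <- load_model(tf)
  expect_equal(length(back$rounds), length(fit$rounds))
  for (i in seq_along(fit$rounds)) {
    expect_identical(back$rounds[[i]]$model$kind, fit$rounds[[i]]$model$kind)
    expect_identical(back$rounds[[i]]$model$components,
                     fit$rounds[[i]]$model$components)
    expect_equal(back$rounds[[i]]$model$params, fit$rounds[[i]]$model$params,
                 tolerance = 1e-15)
    expect_equal(back$rounds[[i]]$alpha, fit$rounds[[i]]$alpha,
                 tolerance = 1e-15)
  }
  s <- fixture_samples()[1:50, ]
  feats <- s[setdiff(names(s), "label")]
  expect_identical(strong_classify(back, feats), strong_classify(fit, feats))

  # malformed/truncated files fail loudly
  tf2 <- tempfile(fileext = ".json")
  full <- readChar(tf, file.size(tf))
  writeChar(substr(full, 1, nchar(full) %/% 2), tf2, eos = NULL)
  expect_error(load_model(tf2))
  tf3 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(foo = 1), tf3)
  expect_error(load_model(tf3), "rounds")
})

test_that("summary and coef expose the per-round table", {
  fit <- fixture_fit()
  cf <- coef(fit)
  expect_equal(nrow(cf), length(fit$rounds))
  expect_true(all(c("kind", "components", "epsilon", "alpha") %in% names(cf)))
  s <- summary(fit)
  expect_s3_class(s, "summary.grape_boost")
  expect_output(print(s), "weak classifiers")
  expect_output(print(fit), "rounds")
})

test_that("the formula interface matches the default interface", {
  s <- generate_samples(40, 80, seed = 9)
  f1 <- grape_boost(label ~ ., s)
  f2 <- grape_boost(s)
  expect_equal(f1$trace$epsilon, f2$trace$epsilon)
  expect_equal(f1$trace$alpha, f2$trace$alpha)
})
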