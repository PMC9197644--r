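test_that("hidden layers are reproducible and compute the closed form", {
  h1 <- elm_hidden_layer(3, 10, seed = 7)
  h2 <- elm_hidden_layer(3, 10, seed = 7)
  expect_identical(h1$W, h2$W)
  expect_identical(h1$b, h2$b)

  x0 <- matrix(0, nrow = 1, ncol = 3)
  expect_equal(as.numeric(hidden_activations(h1, x0)),
               1 / (1 + exp(-h1$b)))

  h <- elm_hidden_layer(1, 1, seed = 1)
  x <- matrix(2.5)
  expect_equal(as.numeric(hidden_activations(h, x)),
               1 / (1 + exp(-(h$W[1, 1] * 2.5 + h$b[1]))))
})

test_that("label-weighted targets inflate minority positives", {
  y <- rep(c("a", "b", "c"), c(6, 3, 1))
  T1 <- label_weighted_targets(y, "ratio")
  expect_equal(unname(T1["a", y == "a"][1]), 1)
  expect_equal(unname(T1["b", y == "b"][1]), 2)
  expect_equal(unname(T1["c", y == "c"][1]), 6)
  expect_true(all(T1[cbind(match(y, rownames(T1)), seq_along(y))] > 0))
  expect_equal(sum(T1 > 0), length(y))

  T2 <- label_weighted_targets(y, "ratio_squared")
  expect_equal(unname(T2["b", y == "b"][1]), 4)
  expect_equal(unname(T2["c", y == "c"][1]), 36)

  yb <- rep(c("a", "b"), each = 5)
  expect_identical(label_weighted_targets(yb), plain_targets(yb))
  expect_error(label_weighted_targets(factor("a", levels = c("a", "b"))),
               "zero samples")
})

test_that("the ridge solve matches explicit normal equations", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(10 * 3), 10, 3)
    y <- sample(c("p", "q"), 10, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    hid <- elm_hidden_layer(3, 5, seed = s)
    tg <- plain_targets(y)
    m <- train_elm(X, tg, hid, penalty = 2)
    H <- hidden_activations(hid, X)
    expect_equal(m$beta, ridge_oracle(H, t(tg), 2), tolerance = 1e-10,
                 ignore_attr = TRUE)

    w <- runif(10, 0.1, 3)
    mw <- train_weighted_elm(X, tg, w, hid, penalty = 2)
    expect_equal(mw$beta, ridge_oracle(H, t(tg), 2, w), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("unit weights reduce the weighted solve to the plain one", {
  set.seed(3)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rep(c("a", "b", "c"), 4)
  hid <- elm_hidden_layer(4, 6, seed = 3)
  tg <- label_weighted_targets(y)
  expect_equal(train_weighted_elm(X, tg, rep(1, 12), hid)$beta,
               train_elm(X, tg, hid)$beta, tolerance = 1e-12)
  expect_error(train_weighted_elm(X, tg, c(-1, rep(1, 11)), hid), "negative")
  expect_error(train_weighted_elm(X, tg, rep(0, 12), hid), "all sample weights")
})

test_that("a zero weight is equivalent to dropping the sample", {
  set.seed(8)
  X <- matrix(rnorm(6 * 2), 6, 2)
  y <- c("a", "a", "a", "b", "b", "b")
  hid <- elm_hidden_layer(2, 4, seed = 8)
  tg <- plain_targets(y)
  w <- c(1, 1, 1, 1, 1, 0)
  m_w <- train_weighted_elm(X, tg, w, hid, penalty = 5)
  m_drop <- train_elm(X[1:5, ], tg[, 1:5], hid, penalty = 5)
  expect_equal(m_w$beta, m_drop$beta, tolerance = 1e-10)
})

test_that("duplicating samples is undone by rescaling the penalty", {
  set.seed(10)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- rep(c("a", "b"), 4)
  hid <- elm_hidden_layer(3, 5, seed = 10)
  tg <- plain_targets(y)
  m1 <- train_elm(X, tg, hid, penalty = 4)
  X2 <- rbind(X, X)
  tg2 <- cbind(tg, tg); attr(tg2, "classes") <- attr(tg, "classes")
  m2 <- train_elm(X2, tg2, hid, penalty = 2)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-8)
})

test_that("prediction decodes argmax scores with a stable tie-break", {
  hid <- elm_hidden_layer(2, 3, seed = 1)
  model <- structure(list(hidden = hid,
                          beta = matrix(0, 3, 3), penalty = 1,
                          classes = c("c1", "c2", "c3")),
                     class = "elm_model")
  p <- predict(model, matrix(rnorm(4 * 2), 4, 2))
  expect_true(all(p$class == "c1"))        # exact three-way ties
  expect_equal(dim(p$scores), c(3, 4))
  expect_error(predict(model, matrix(0, 2, 5)), "5 columns")
})

test_that("the interpolation limit fits separable training data exactly", {
  cl <- make_clusters(list(a = 15, b = 15, c = 15),
                      list(a = c(4, 0), b = c(0, 4), c = c(-4, -4)), seed = 2)
  m <- lw_elm(cl$X, cl$y, L = 45, penalty = 1e8, seed = 5, scheme = NULL)
  p <- predict(m, cl$X)
  expect_equal(mean(p$class == cl$y), 1)
})

test_that("squaring the label weights never hurts minority training recall", {
  recs <- vapply(1:10, function(s) {
    d <- generate_feature_dataset(120, proportions = c(maj = 0.875, min = 0.125),
                                  separation = 1.5, seed = 100 + s)
    X <- as.matrix(d[, 3:22]); y <- d$label
    rec <- function(scheme) {
      m <- lw_elm(X, y, L = 40, penalty = 1, seed = s, scheme = scheme)
      mean(predict(m, X)$class[y == "min"] == "min")
    }
    bal <- lw_elm(X, y, L = 40, penalty = 1, seed = s, scheme = NULL)
    bal_rec <- mean(predict(bal, X)$class[y == "min"] == "min")
    c(ratio = rec("ratio"), sq = rec("ratio_squared"), bal = bal_rec)
  }, numeric(3))
  # the balanced model errs on the minority in this fixture ...
  expect_true(any(recs["bal", ] < 1))
  # ... and the stronger weighting never lowers minority training recall
  expect_true(all(recs["sq", ] >= recs["ratio", ] - 1e-12))
})

test_that("models round-trip bit-exactly through serialization", {
  set.seed(12)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(c("a", "b", "c"), 10)
  m <- lw_elm(X, y, L = 10, seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$beta, m$beta)
  expect_identical(m2$hidden$W, m$hidden$W)
  expect_identical(predict(m2, X), predict(m, X))
})
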