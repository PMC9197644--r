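# helper: one-hot label matrix for small fixtures (mirrors the coding
# train_ielm applies internally)
onehot <- function(y, classes = sort(unique(y))) {
  Y <- matrix(0L, length(y), length(classes),
              dimnames = list(NULL, classes))
  for (j in seq_along(classes)) Y[y == classes[j], j] <- 1L
  Y
}

test_that("imbalance ratios are symmetric majority/minority quotients", {
  Y <- cbind(l1 = c(rep(1, 5), rep(0, 5)))
  expect_equal(imbalance_ratio(Y, 1), 1)
  expect_equal(imbalance_ratio(cbind(c(rep(1, 9), 0)), 1), 9)
  expect_equal(imbalance_ratio(cbind(c(rep(1, 2), rep(0, 8))), 1), 4)
  expect_error(imbalance_ratio(cbind(rep(1, 4)), 1), "empty class")
})

test_that("initial weights spread each block over mass 1/(2q)", {
  # q = 1, balanced 4 + 4: uniform 1/8 everywhere
  Yb <- cbind(c(rep(1, 4), rep(0, 4)))
  Wb <- initial_weight_distribution(Yb)
  expect_equal(as.numeric(Wb), rep(0.125, 8))

  # q = 1, 2 positive / 8 negative: positives 1/4 each, negatives 1/16
  Yi <- cbind(c(rep(1, 2), rep(0, 8)))
  Wi <- initial_weight_distribution(Yi)
  expect_equal(as.numeric(Wi[1:2]), rep(0.25, 2))
  expect_equal(as.numeric(Wi[3:10]), rep(1 / 16, 8))
  expect_equal(sum(Wi), 1, tolerance = 1e-12)

  # 3-label one-hot: grand total 1, each block mass 1/6
  set.seed(1)
  y <- sample(c("a", "b", "c"), 60, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  Y <- onehot(y)
  W <- initial_weight_distribution(Y)
  expect_equal(sum(W), 1, tolerance = 1e-12)
  for (l in 1:3) {
    expect_equal(sum(W[Y[, l] == 1, l]), 1 / 6, tolerance = 1e-12)
    expect_equal(sum(W[Y[, l] == 0, l]), 1 / 6, tolerance = 1e-12)
  }
})

test_that("block errors and coefficients follow the clipped half-log law", {
  Y <- cbind(c(1, 1, 0, 0, 0, 0))
  W <- initial_weight_distribution(Y)
  truth_sign <- 2 * Y - 1

  all_right <- truth_sign
  expect_equal(label_class_error(all_right, Y, W, 1, "pos"), 0)
  all_wrong <- -truth_sign
  expect_equal(label_class_error(all_wrong, Y, W, 1, "neg"), 0.5,
               tolerance = 1e-12)

  # brute-force mass summation on a mixed prediction
  pred <- truth_sign; pred[c(3, 4), 1] <- -pred[c(3, 4), 1]
  expect_equal(label_class_error(pred, Y, W, 1, "neg"),
               sum(W[c(3, 4), 1]), tolerance = 1e-14)

  # equal correct and wrong block mass -> coefficient 0
  pred2 <- truth_sign; pred2[c(3, 4), 1] <- -pred2[c(3, 4), 1]
  expect_equal(label_class_coefficient(pred2, Y, W, 1, "neg"), 0)
  # perfect block hits the clip ceiling
  expect_equal(label_class_coefficient(all_right, Y, W, 1, "pos"),
               0.5 * log(0.5 / 1e-10))
  # correct : wrong = e^2 : 1 -> coefficient exactly 1
  Wx <- W
  Wx[3:6, 1] <- c(exp(2), 1, 0, 0) / (exp(2) + 1) / 2
  predx <- truth_sign; predx[4, 1] <- -predx[4, 1]
  expect_equal(label_class_coefficient(predx, Y, Wx, 1, "neg"), 1)
})

test_that("weight updates conserve every block's mass", {
  set.seed(2)
  y <- sample(c("a", "b", "c"), 40, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  Y <- onehot(y)
  W <- initial_weight_distribution(Y)
  truth_sign <- 2 * Y - 1
  pred <- truth_sign * ifelse(matrix(runif(length(Y)), nrow(Y)) < 0.25, -1, 1)
  cf <- matrix(rnorm(6), 3, 2, dimnames = list(colnames(Y), c("pos", "neg")))

  W0 <- update_weight_distribution(W, matrix(0, 3, 2,
          dimnames = list(colnames(Y), c("pos", "neg"))), pred, Y)
  expect_equal(W0, W, tolerance = 1e-14)

  W1 <- update_weight_distribution(W, cf, pred, Y)
  q <- 3
  for (l in 1:q) for (j in c(1, 0)) {
    expect_equal(sum(W1[Y[, l] == j, l]), 1 / (2 * q), tolerance = 1e-12)
  }
  expect_equal(sum(W1), 1, tolerance = 1e-12)
})

test_that("q = 1 updates reproduce classic AdaBoost ratios within blocks", {
  Y <- cbind(c(1, 1, 1, 0, 0, 0))
  W <- initial_weight_distribution(Y)
  truth_sign <- 2 * Y - 1
  pred <- truth_sign; pred[c(2, 5), 1] <- -pred[c(2, 5), 1]
  cf <- matrix(0.7, 1, 2, dimnames = list(NULL, c("pos", "neg")))
  W1 <- update_weight_distribution(W, cf, pred, Y)

  # same multiplicative rule as the classic update, renormalised per block
  y_lab <- c("p", "p", "p", "n", "n", "n")
  p_lab <- c("p", "x", "p", "n", "x", "n")
  up <- as.numeric(update_sample_weights(rep(1 / 6, 6), 0.7, p_lab, y_lab))
  pos_ref <- up[1:3] / sum(up[1:3]) / 2
  neg_ref <- up[4:6] / sum(up[4:6]) / 2
  expect_equal(as.numeric(W1[1:3, 1]), pos_ref, tolerance = 1e-12)
  expect_equal(as.numeric(W1[4:6, 1]), neg_ref, tolerance = 1e-12)
})

test_that("the round coefficient reduces to the classic one when q = 1", {
  set.seed(3)
  Y <- cbind(sample(c(1, 0), 30, replace = TRUE, prob = c(0.3, 0.7)))
  W <- initial_weight_distribution(Y)
  truth_sign <- 2 * Y - 1
  pred <- truth_sign * ifelse(runif(30) < 0.3, -1, 1)
  eps <- sum(W[pred != truth_sign])
  expect_equal(ensemble_coefficient(pred, Y, W),
               round_coefficient(eps), tolerance = 1e-12)
})

test_that("training conserves the weight distribution every round", {
  d <- generate_feature_dataset(150, separation = 1.5, seed = 7)
  X <- as.matrix(d[, 3:22])
  m <- train_ielm(X, d$label, rounds = 6, L = 30, seed = 7)
  q <- m$q
  Y <- onehot(d$label, m$classes)
  for (W in m$weight_history) {
    expect_equal(sum(W), 1, tolerance = 1e-10)
    for (l in 1:q) for (j in c(1, 0))
      expect_equal(sum(W[Y[, l] == j, l]), 1 / (2 * q), tolerance = 1e-10)
  }
})

test_that("balanced data and one round degenerate to the plain ELM", {
  cl <- make_clusters(list(a = 30, b = 30),
                      list(a = rep(1.5, 4), b = rep(-1.5, 4)), seed = 11)
  mi <- suppressMessages(
    train_ielm(cl$X, cl$y, rounds = 1, L = 25, penalty = 10, seed = 11))
  me <- train_elm(cl$X, plain_targets(cl$y),
                  elm_hidden_layer(4, 25, seed = 11 + 1), penalty = 10)
  # identical solve (exact count balance makes R = 1 and targets +/-1) ...
  expect_equal(mi$rounds[[1]]$model$beta, me$beta, tolerance = 1e-10,
               ignore_attr = TRUE)
  # ... and identical decisions
  expect_identical(predict(mi, cl$X)$class, predict(me, cl$X)$class)
})

test_that("a separable three-class problem is fit perfectly", {
  cl <- make_clusters(list(a = 20, b = 20, c = 20),
                      list(a = c(4, 0, 0), b = c(0, 4, 0), c = c(0, 0, 4)),
                      seed = 13)
  m <- suppressMessages(train_ielm(cl$X, cl$y, rounds = 5, L = 60,
                                   penalty = 100, seed = 13))
  expect_equal(mean(predict(m, cl$X)$class == cl$y), 1)
})

test_that("predictions are equivariant under class relabelling", {
  d <- generate_feature_dataset(200, separation = 2, seed = 17)
  X <- as.matrix(d[, 3:22])
  y <- d$label
  swap <- c(high = "zz_high", moderate = "aa_moderate", low = "mm_low")
  m1 <- train_ielm(X, y, rounds = 4, L = 40, seed = 17)
  m2 <- train_ielm(X, unname(swap[y]), rounds = 4, L = 40, seed = 17)
  p1 <- predict(m1, X)
  p2 <- predict(m2, X)
  # the score matrices are exactly permutation-equivariant ...
  expect_equal(unname(p1$scores[m1$classes, ]),
               unname(p2$scores[swap[m1$classes], ]), tolerance = 1e-12)
  # ... and so are the decisions wherever the vote is untied (the
  # tie-break goes to the lowest class index, which relabelling permutes)
  untied <- apply(p1$scores, 2, function(s) sum(s == max(s)) == 1)
  expect_gt(mean(untied), 0.8)
  expect_identical(unname(swap[p1$class[untied]]), p2$class[untied])
})

test_that("zero-coefficient rounds contribute nothing to prediction", {
  d <- generate_feature_dataset(80, separation = 2, seed = 19)
  X <- as.matrix(d[, 3:22])
  m <- train_ielm(X, d$label, rounds = 2, L = 20, seed = 19)
  stopifnot(length(m$rounds) == 2)
  single <- m; single$rounds <- m$rounds[1]
  zeroed <- m; zeroed$rounds[[2]]$coefficient <- 0
  expect_identical(predict(zeroed, X)$class, predict(single, X)$class)
  # and a lone round decodes the argmax of its signed outputs
  S <- predict(single, X)$scores
  expect_equal(unname(S) / single$rounds[[1]]$coefficient,
               unname(ifelse(S >= 0, 1, -1)), tolerance = 1e-12)
})

test_that("minority recall is boosted on the imbalanced stress mix", {
  wins <- vapply(1:10, function(s) {
    d <- generate_feature_dataset(500, separation = 2, seed = 200 + s)
    X0 <- as.matrix(d[, 3:22]); y <- d$label
    tr <- stratified_split(y, 0.7, seed = s)
    sc <- minmax_scale(X0[tr, ], X0[!tr, ])
    mi <- train_ielm(sc[[1]], y[tr], rounds = 10, L = 100, seed = s)
    me <- lw_elm(sc[[1]], y[tr], L = 100, seed = s + 1, scheme = NULL)
    ri <- mean(predict(mi, sc[[2]])$class[y[!tr] == "high"] == "high")
    re <- mean(predict(me, sc[[2]])$class[y[!tr] == "high"] == "high")
    c(ielm = ri, elm = re)
  }, numeric(2))
  expect_gte(sum(wins["ielm", ] >= wins["elm", ]), 8)
  expect_gt(mean(wins["ielm", ]), mean(wins["elm", ]))
})

test_that("ensembles round-trip through serialization", {
  d <- generate_feature_dataset(60, separation = 3, seed = 23)
  X <- as.matrix(d[, 3:22])
  m <- suppressMessages(train_ielm(X, d$label, rounds = 3, L = 15, seed = 23))
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(predict(m2, X), predict(m, X))
  expect_identical(m2$weight_history, m$weight_history)
})
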