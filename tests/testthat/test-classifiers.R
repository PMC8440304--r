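# Weighted logistic regression, labelling rules, multiclass ensembles and
# the external-method adapters.

test_that("class weight solves the effective-balance relation", {
  expect_equal(class_weight(1000, 1000, 1), 1)
  expect_equal(class_weight(1000, 5000, 1), 5)
  expect_equal(class_weight(1000, 1000, 2), 2)
  expect_error(class_weight(0, 10, 1), "positive")
})

test_that("weighted log loss reduces to the plain log loss at w = 1", {
  set.seed(5)
  X <- cbind(1, matrix(rnorm(60), ncol = 3))
  tau <- rbinom(20, 1, 0.5)
  theta <- rnorm(4)
  h <- 1 / (1 + exp(-drop(X %*% theta)))
  plain <- -mean(tau * log(h) + (1 - tau) * log(1 - h))
  expect_equal(weighted_log_loss(theta, X, tau, w = 1), plain)
  # all-0.5 predictions give log 2
  expect_equal(weighted_log_loss(rep(0, 4), X, tau, w = 1), log(2))
  # perfectly confident correct predictions drive the loss to zero
  X2 <- cbind(1, c(-2, -1, 1, 2))
  expect_lt(weighted_log_loss(c(0, 50), X2, c(0, 0, 1, 1), w = 1), 1e-3)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(9)
  for (w in c(1, 3.7)) {
    X <- cbind(1, matrix(rnorm(80), ncol = 4))
    tau <- rbinom(nrow(X), 1, 0.4)
    theta <- rnorm(5) * 0.5
    g <- weighted_log_loss_grad(theta, X, tau, w)
    eps <- 1e-6
    g_fd <- vapply(seq_along(theta), function(j) {
      e <- rep(0, length(theta))
      e[j] <- eps
      (weighted_log_loss(theta + e, X, tau, w) -
         weighted_log_loss(theta - e, X, tau, w)) / (2 * eps)
    }, numeric(1))
    expect_equal(g, g_fd, tolerance = 1e-6)
  }
})

test_that("logistic training separates separable data and is duplication-invariant", {
  set.seed(21)
  toy <- toy_separable(80)
  m <- train_logistic(toy$X, toy$tau)
  expect_true(all(predict_binary(m, toy$X) == toy$tau))
  # duplicating every sample leaves the optimum unchanged (the loss is a
  # mean); checked on overlapping classes so the optimum is finite
  n <- 200
  Xo <- matrix(rnorm(2 * n), ncol = 2)
  tau_o <- rbinom(n, 1, 1 / (1 + exp(-Xo[, 1])))
  mo <- train_logistic(Xo, tau_o)
  mo2 <- train_logistic(rbind(Xo, Xo), c(tau_o, tau_o))
  expect_equal(mo2$theta, mo$theta, tolerance = 1e-5)
})

test_that("larger positive-class weight never hurts positive recall", {
  set.seed(77)
  n <- 300
  X <- matrix(rnorm(2 * n), ncol = 2)
  tau <- rbinom(n, 1, 1 / (1 + exp(-(1.2 * X[, 1] - 1.5))))  # minority 1s
  recalls <- vapply(c(0.5, 1, 3, 10), function(w) {
    m <- train_logistic(X, tau, w = w)
    pred <- predict_binary(m, X)
    sum(pred == 1 & tau == 1) / sum(tau == 1)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("decision boundary is inclusive and degenerate at the extremes", {
  m <- identity_prob_model()
  x <- matrix(logit(c(0.2, 0.5, 0.7)), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(predict_prob(m, x), c(0.2, 0.5, 0.7), tolerance = 1e-12)
  expect_equal(predict_binary(m, x, B = 0.5), c(0L, 1L, 1L))  # p = B is C1
  expect_equal(predict_binary(m, x, B = 0), c(1L, 1L, 1L))
})

test_that("labelling rules implement the four configurations", {
  y <- c("healthy", "aorta", "iliac_1", "iliac_2")
  expect_equal(label_for(list(type = "enbc"), y), c(1, 0, 0, 0))
  expect_equal(label_for(list(type = "ivbc", vessel = "aorta"), y),
               c(0, 1, 0, 0))
  expect_equal(label_for(list(type = "ova", class = "iliac_2"), y),
               c(0, 0, 0, 1))
  ovo <- label_for(list(type = "ovo", class1 = "aorta",
                        class0 = "iliac_2"), y)
  expect_equal(ovo, c(NA, 1, NA, 0))
  expect_error(label_for(list(type = "nope"), y), "unknown")
})

test_that("one-vs-all picks the argmax with class-order tie-break", {
  members <- setNames(rep(list(identity_prob_model()), 4), class_levels())
  x <- matrix(logit(0.5), 1, 1)  # every member returns 0.5: tie
  expect_identical(predict_ova(members, x), "healthy")
  # dial one member up
  members2 <- members
  members2$iliac_1 <- structure(
    list(theta = c(`(intercept)` = 2, x = 0), B = 0.5),
    class = c("logistic_model", "stn_binary"))
  expect_identical(predict_ova(members2, x), "iliac_1")
})

test_that("one-vs-one majority vote with documented tie-breaks", {
  set.seed(64)
  vpd <- surrogate_fixture()
  feats <- features_from_vpd(vpd)
  y <- vpd_labels(vpd)
  tr <- seq_len(200)
  std <- fit_standardiser(feats[tr, ])
  ens <- train_multiclass(predict(std, feats[tr, ]), y[tr],
                          strategy = "ovo", method = "lr")
  expect_length(ens$members, 6)
  pred <- predict(ens, predict(std, feats[-tr, ]))
  expect_true(all(pred %in% class_levels()))
  # vote mechanics with hand-built members: when every pairwise member
  # outputs probability 0.9 the first class of each pair gets the vote,
  # so `healthy` (first class of three pairs) must win
  prs <- combn(class_levels(), 2, simplify = FALSE)
  mock <- lapply(prs, function(p) {
    m <- identity_prob_model()
    m$class1 <- p[1]
    m$class0 <- p[2]
    m
  })
  names(mock) <- vapply(prs, paste, character(1), collapse = "|")
  x <- matrix(logit(0.9), 1, 1, dimnames = list(NULL, "x"))
  expect_identical(predict_ovo(mock, x), "healthy")
})

test_that("CPC defaults to healthy and is monotone in the boundary", {
  members <- setNames(rep(list(identity_prob_model()), 3),
                      c("aorta", "iliac_1", "iliac_2"))
  # one feature drives all members identically; craft per-member probs
  # via separate calls instead: use matrix rows
  x <- matrix(logit(c(0.3, 0.7)), ncol = 1, dimnames = list(NULL, "x"))
  pred <- predict_cpc(members, x, B = 0.5)
  expect_identical(pred, c("healthy", "aorta"))
  expect_identical(predict_cpc(members, x, B = 0.8),
                   c("healthy", "healthy"))
  expect_identical(predict_cpc(members, x, B = 0),
                   c("aorta", "aorta"))
  # healthy count non-decreasing over a boundary sweep (random probs)
  set.seed(12)
  xr <- matrix(logit(runif(200, 0.01, 0.99)), ncol = 1,
               dimnames = list(NULL, "x"))
  healthy_n <- vapply(seq(0, 1, by = 0.05), function(B) {
    sum(predict_cpc(members, xr, B) == "healthy")
  }, numeric(1))
  expect_true(all(diff(healthy_n) >= 0))
})

test_that("external adapters fit separable and Gaussian-blob data", {
  set.seed(42)
  toy <- toy_separable(80)
  sv <- fit_binary("svm_linear", toy$X, toy$tau)
  expect_true(all(stenoscreen:::predict_class01(sv, toy$X) == toy$tau))
  # two well-separated Gaussian blobs: NB test accuracy > 0.95
  n <- 400
  X <- rbind(matrix(rnorm(n, -2, 1), ncol = 2),
             matrix(rnorm(n, 2, 1), ncol = 2))
  tau <- rep(c(0, 1), each = n / 2)
  tr <- sample(n, n / 2)
  nb <- fit_binary("gaussian_nb", X[tr, ], tau[tr])
  acc <- mean(stenoscreen:::predict_class01(nb, X[-tr, ]) == tau[-tr])
  expect_gt(acc, 0.95)
  pr <- predict_prob(nb, X[-tr, ])
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(fit_binary("deep_net", toy$X, toy$tau), "unsupported")
})

test_that("random-forest grid search freezes a scored hyperparameter pair", {
  set.seed(11)
  toy <- toy_separable(120)
  gs <- rf_grid_search(toy$X, toy$tau, ntree_grid = c(50, 100),
                       maxnodes_grid = c(8, 32))
  expect_true(gs$ntree %in% c(50, 100))
  expect_true(gs$maxnodes %in% c(8, 32))
  expect_equal(nrow(gs$grid), 4)
  expect_true(all(is.finite(gs$grid$f1)))
})

test_that("training is invariant to feature permutation", {
  set.seed(3)
  toy <- toy_separable(60)
  X <- cbind(toy$X, matrix(rnorm(120), ncol = 2))
  colnames(X) <- paste0("f", 1:4)
  m1 <- train_logistic(X, toy$tau)
  perm <- c(3, 1, 4, 2)
  m2 <- train_logistic(X[, perm], toy$tau)
  expect_equal(unname(m2$theta[-1][order(perm)]), unname(m1$theta[-1]),
               tolerance = 1e-4)
  expect_equal(predict_prob(m2, X[, perm]), predict_prob(m1, X),
               tolerance = 1e-5)
})

test_that("CPC rejects non-probabilistic methods", {
  set.seed(10)
  vpd <- surrogate_fixture()
  feats <- features_from_vpd(vpd)[1:80, 1:11]
  y <- vpd_labels(vpd)[1:80]
  expect_error(train_multiclass(scale(feats), y, strategy = "cpc",
                                method = "svm_rbf"), "probabilistic")
})
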