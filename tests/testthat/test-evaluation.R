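# Metrics, the reporting convention, experiment drivers and ROC/AUC.

test_that("F score combines precision and recall as prescribed", {
  expect_equal(f_score(0.5, 0.8), 8 / 13)
  expect_equal(f_score(0.7, 0.7), 0.7)  # harmonic mean of equals
  expect_equal(f_score(0, 0), 0)        # degenerate case defined as 0
  # delta > 1 prefers recall
  expect_gt(f_score(0.4, 0.9, delta = 2), f_score(0.4, 0.9, delta = 1))
  expect_error(f_score(1.2, 0.5))
})

test_that("the balanced screening worked examples reproduce", {
  # equal healthy/unhealthy counts; healthy recall 0.8, unhealthy correct
  # rate 0.2: healthy-class F score 8/13 (prints as 0.61); the reversed
  # case gives 2/7 (prints as 0.28)
  n <- 1000
  truth <- rep(c(1, 0), each = n)
  pred_a <- c(rep(1, 800), rep(0, 200), rep(1, 800), rep(0, 200))
  rep_a <- binary_report(pred_a, truth, "enbc")
  expect_equal(rep_a$f, 8 / 13)
  expect_equal(trunc(rep_a$f * 100) / 100, 0.61)
  pred_b <- c(rep(1, 200), rep(0, 800), rep(1, 200), rep(0, 800))
  rep_b <- binary_report(pred_b, truth, "enbc")
  expect_equal(rep_b$f, 2 / 7)
  expect_equal(trunc(rep_b$f * 100) / 100, 0.28)
  # reported sensitivity is the disease-detection recall
  expect_equal(rep_a$sensitivity, 0.2)
  expect_equal(rep_a$specificity, 0.8)
})

test_that("reporting convention reproduces both table-derived checks", {
  # entire-network configuration, balanced classes:
  # disease recall 0.7994, healthy recall 0.5688 -> healthy F score 0.6429
  n <- 10000
  truth <- rep(c(1, 0), each = n)
  pred <- c(rep(1, 5688), rep(0, 4312), rep(0, 7994), rep(1, 2006))
  rep_e <- binary_report(pred, truth, "enbc")
  expect_equal(rep_e$sensitivity, 0.7994)
  expect_equal(rep_e$specificity, 0.5688)
  expect_equal(round(rep_e$f, 4), 0.6429)
  # individual-vessel configuration at 1:5 imbalance, weighted-balanced:
  # vessel recall 0.8893, rest recall 0.7814 -> weighted F score 0.8437
  m1 <- 10000
  m2 <- 50000
  truth_i <- rep(c(1, 0), c(m1, m2))
  pred_i <- c(rep(1, 8893), rep(0, 1107), rep(0, 39070), rep(1, 10930))
  w <- class_weight(m1, m2, r = 1)
  rep_i <- binary_report(pred_i, truth_i, "ivbc", w = w)
  expect_equal(rep_i$sensitivity, 0.8893)
  expect_equal(rep_i$specificity, 0.7814)
  expect_lt(abs(rep_i$f - 0.8437), 5e-4)
  # perfect predictions
  rep_p <- binary_report(truth, truth, "enbc")
  expect_equal(c(rep_p$sensitivity, rep_p$specificity, rep_p$f),
               c(1, 1, 1))
})

test_that("events-per-variable sizing yields the study cohort", {
  sz <- epv_requirements(12, 66, 2 / 3)
  expect_equal(sz$diseased_per_vessel, 1188)
  expect_equal(sz$healthy, 3564)
  expect_equal(sz$total, 7128)
  expect_equal(sz$healthy_epv, 36)
  expect_equal(sz$max_dims, 66)
})

test_that("five-fold splits are disjoint, exhaustive and reproducible", {
  vpd <- surrogate_fixture()
  feats <- features_from_vpd(vpd)
  y <- vpd_labels(vpd)
  set.seed(404)
  res <- five_fold(feats, y, rule = list(type = "enbc"), method = "lr",
                   folds = 5, keep_models = TRUE)
  expect_equal(nrow(res$folds), 5)
  for (m in res$models) {
    tr <- m$train
    expect_length(intersect(tr, setdiff(seq_along(y), tr)), 0)
    expect_setequal(c(tr, setdiff(seq_along(y), tr)), seq_along(y))
    expect_equal(length(tr), round(2 / 3 * length(y)))
  }
  set.seed(404)
  res2 <- five_fold(feats, y, rule = list(type = "enbc"), method = "lr",
                    folds = 5)
  expect_equal(res2$folds$f, res$folds$f)
  # averaging five identical folds returns the single-fold value
  df <- res$folds
  expect_equal(unname(res$mean[["f"]]), mean(df$f))
})

test_that("combination search finds the informative measurement", {
  set.seed(909)
  vpd <- surrogate_vpd(targets = c(healthy = 120, aorta = 40,
                                   iliac_1 = 40, iliac_2 = 40),
                       informative = "P1")
  res <- combination_search(vpd, methods = "lr",
                            rule = list(type = "enbc"), folds = 3)
  expect_equal(nrow(res), 63)
  has_p1 <- grepl("P1", res$combination)
  expect_gt(mean(res$f[has_p1]), mean(res$f[!has_p1]))
  # the top-ranked combinations all contain the informative site
  expect_true(all(has_p1[order(-res$f)][1:5]))
})

test_that("more measurements raise the average score on the surrogate", {
  set.seed(910)
  vpd <- surrogate_fixture()
  res <- cached("enbc_search_lr",
                combination_search(vpd, methods = "lr",
                                   rule = list(type = "enbc"), folds = 3))
  expect_equal(nrow(res), 63)
  mean_by_size <- tapply(res$f, res$size, mean)
  expect_true(all(diff(mean_by_size) > -0.02))
  expect_gt(mean_by_size[["6"]], mean_by_size[["1"]])
})

test_that("like-for-like audit pairs 24 symmetric searches", {
  set.seed(910)
  vpd <- surrogate_fixture()
  res <- cached("enbc_search_lr",
                combination_search(vpd, methods = "lr",
                                   rule = list(type = "enbc"), folds = 3))
  audit <- like_for_like_audit(res)
  expect_equal(nrow(audit), 24)
  expect_true(all(audit$discrepancy >= 0))
  # exactly symmetric (constructed) scores give zero discrepancies
  sym <- res
  lut <- setNames(sym$f, sym$combination)
  sym$f <- vapply(strsplit(sym$combination, ","), function(cmb) {
    k2 <- paste(iliac_swap(cmb), collapse = ",")
    (lut[[sym$combination[1]]] * 0) + mean(c(lut[[paste(cmb, collapse = ",")]],
                                             lut[[k2]]))
  }, numeric(1))
  audit0 <- like_for_like_audit(sym)
  expect_lt(max(audit0$discrepancy), 1e-12)
})

test_that("ROC endpoints and AUC behave for perfect and random scorers", {
  # random scores vs random labels give AUC near one half
  set.seed(2001)
  auc_r <- auc_from_scores(runif(2000), rbinom(2000, 1, 0.5))
  expect_gt(auc_r, 0.45)
  expect_lt(auc_r, 0.55)
  # perfectly separating scores give AUC one
  lab <- rbinom(500, 1, 0.4)
  expect_equal(auc_from_scores(lab + runif(500) * 0.5, lab), 1)
  # CPC healthy-class curve spans (0,0) to (1,1)
  vpd <- surrogate_fixture()
  feats <- features_from_vpd(vpd)
  y <- vpd_labels(vpd)
  set.seed(303)
  tr <- stenoscreen:::split_two_thirds(y)
  std <- fit_standardiser(feats[tr, ])
  ens <- train_multiclass(predict(std, feats[tr, ]), y[tr],
                          strategy = "cpc", method = "lr")
  roc <- roc_and_auc(ens, predict(std, feats[-tr, ]), y[-tr],
                     boundaries = seq(0, 1, length.out = 21))
  hp <- roc$points[roc$points$class == "healthy", ]
  expect_equal(hp$tpr[hp$boundary == 1], 1)
  expect_equal(hp$fpr[hp$boundary == 1], 1)
  expect_equal(hp$tpr[hp$boundary == 0], 0)
  expect_equal(hp$fpr[hp$boundary == 0], 0)
  expect_true(is.finite(roc$auc[["healthy"]]))
  expect_gte(roc$auc[["healthy"]], 0)
  expect_lte(roc$auc[["healthy"]], 1)
})

test_that("learning curve improves with more patients and reproduces", {
  vpd <- surrogate_fixture()
  set.seed(515)
  lc <- learning_curve(vpd, vessel = "aorta", sizes = c(90, 300),
                       method = "lr", folds = 3)
  expect_equal(nrow(lc), 2)
  expect_gte(lc$test_f[2], lc$test_f[1])
  set.seed(515)
  lc2 <- learning_curve(vpd, vessel = "aorta", sizes = c(90, 300),
                        method = "lr", folds = 3)
  expect_equal(lc2$test_f, lc$test_f)
})

test_that("severity analysis partitions the test set", {
  vpd <- surrogate_fixture()
  feats <- features_from_vpd(vpd)
  y <- vpd_labels(vpd)
  tau <- label_for(list(type = "enbc"), y)
  sev <- vpd_severities(vpd)
  set.seed(606)
  tr <- stenoscreen:::split_two_thirds(tau)
  std <- fit_standardiser(feats[tr, ])
  m <- train_logistic(predict(std, feats[tr, ]), tau[tr])
  sa <- severity_analysis(m, predict(std, feats[-tr, ]), tau[-tr],
                          sev[-tr])
  expect_equal(nrow(sa), length(y) - length(tr))
  expect_true(all(sa$outcome %in% c("TP", "FN", "FP", "TN")))
  expect_equal(sum(table(sa$outcome)), nrow(sa))
  # healthy patients carry severity zero; diseased appear exactly once
  expect_true(all(sa$severity[sa$truth == 1] == 0))  # truth 1 = healthy here
  expect_equal(sum(sa$severity > 0), sum(y[-tr] != "healthy"))
  # a probability strictly increasing in severity yields a rising
  # true-positive fraction across severity bins (constructed monotone
  # model; the physical classifiers need not show this)
  mono <- identity_prob_model()
  xs <- matrix(logit(pmin(pmax(0.1 + sev[-tr], 0.01), 0.99)), ncol = 1,
               dimnames = list(NULL, "x"))
  # ivbc-style truth: diseased = positive
  sa2 <- severity_analysis(mono, xs, as.numeric(sev[-tr] > 0), sev[-tr])
  dis <- sa2[sa2$truth == 1, ]
  bins <- cut(dis$severity, c(0.5, 0.633, 0.767, 0.9),
              include.lowest = TRUE)
  tp_frac <- tapply(dis$outcome == "TP", bins, mean)
  expect_true(all(diff(tp_frac) >= 0))
})
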