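# Evaluation: confusion counting, F score, EPV sizing, five-fold driver,
# combination searches, symmetry audit, ROC/AUC, learning curve and
# severity analysis.

#' F score
#'
#' \deqn{F = \frac{(\delta^2+1)\,\mathcal{P}\mathcal{R}}
#'                {\delta^2\mathcal{P} + \mathcal{R}}}
#' combining precision and recall; delta = 1 gives their harmonic mean
#' (the F1 score).  The degenerate case precision = recall = 0 is defined
#' as 0.
#'
#' @param precision,recall rates in \[0,1\].
#' @param delta recall-preference hyperparameter.
#' @return the F score.
#' @export
f_score <- function(precision, recall, delta = 1) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  (delta^2 + 1) * precision * recall / (delta^2 * precision + recall)
}

#' Confusion counts for a binary outcome
#'
#' @param pred,truth 0/1 vectors (1 = positive class C1).
#' @param w weight applied to positive-class counts (TP and FN); used to
#'   report effectively class-balanced scores for imbalanced
#'   configurations.
#' @return list of TP, FP, FN, TN (weighted where applicable).
#' @export
confusion_counts <- function(pred, truth, w = 1) {
  stopifnot(length(pred) == length(truth))
  list(TP = w * sum(pred == 1 & truth == 1),
       FP = sum(pred == 1 & truth == 0),
       FN = w * sum(pred == 0 & truth == 1),
       TN = sum(pred == 0 & truth == 0))
}

#' Binary classification report
#'
#' Computes the reporting convention used for binary screening
#' configurations: the reported sensitivity is the recall of the
#' disease-present outcome and the reported specificity the recall of the
#' disease-absent outcome, while the F score is computed for the
#' configuration's positive class C1 (healthy for the entire-network
#' configuration, the target vessel for individual-vessel configurations)
#' on w-weighted counts.  With w equal to the training imbalance the
#' individual-vessel F score is effectively class-balanced.
#'
#' @param pred,truth 0/1 vectors (1 = configuration class C1).
#' @param config_type `"enbc"` (C1 = healthy) or `"ivbc"` (C1 = diseased
#'   vessel).
#' @param w weight for C1 counts (see [class_weight()]).
#' @param delta F-score hyperparameter.
#' @return list with `sensitivity`, `specificity`, `precision`, `recall`,
#'   `f`, and the raw `counts`.
#' @export
binary_report <- function(pred, truth, config_type = c("enbc", "ivbc"),
                          w = 1, delta = 1) {
  config_type <- match.arg(config_type)
  cc <- confusion_counts(pred, truth, w = w)
  recall1 <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_
  recall0 <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA_real_
  precision1 <- if (cc$TP + cc$FP > 0) cc$TP / (cc$TP + cc$FP) else NA_real_
  f <- if (is.na(precision1) || is.na(recall1)) NA_real_ else
    f_score(precision1, recall1, delta)
  if (config_type == "enbc") {
    se <- recall0  # disease present = class 0 of the ENBC
    sp <- recall1
  } else {
    se <- recall1
    sp <- recall0
  }
  list(sensitivity = se, specificity = sp, precision = precision1,
       recall = recall1, f = f, counts = cc)
}

#' Events-per-variable VPD sizing
#'
#' Applies the EPV rule-of-thumb: with a minimum of `epv_min` training
#' examples of the rarest classification per input dimension, at most
#' `max_dims` input dimensions and a training fraction of the database,
#' the required number of diseased patients per vessel is
#' epv_min * max_dims / train_fraction; the healthy class (balanced
#' design) needs three times that, giving it a proportionally larger EPV.
#'
#' @param epv_min minimum events per variable (default 12).
#' @param max_dims maximum input dimensionality (default 66 = 6
#'   measurements x 11 Fourier coefficients).
#' @param train_fraction fraction of the VPD used for training.
#' @return list with `diseased_per_vessel`, `healthy`, `total`,
#'   `healthy_epv`, `max_dims`.
#' @export
epv_requirements <- function(epv_min = 12, max_dims = 66,
                             train_fraction = 2 / 3) {
  stopifnot(epv_min > 0, max_dims > 0, train_fraction > 0,
            train_fraction < 1)
  dis <- epv_min * max_dims / train_fraction
  healthy <- 3 * dis
  list(diseased_per_vessel = dis, healthy = healthy,
       total = healthy + 3 * dis,
       healthy_epv = healthy * train_fraction / max_dims,
       max_dims = max_dims)
}

# Stratification-free random 2/3 split; regenerated (new draw) if a class
# is missing from either side.
split_two_thirds <- function(y, train_fraction = 2 / 3, max_tries = 50) {
  n <- length(y)
  for (k in seq_len(max_tries)) {
    tr <- sample(n, round(train_fraction * n))
    if (length(unique(y[tr])) == length(unique(y)) &&
        length(unique(y[-tr])) == length(unique(y))) {
      return(tr)
    }
  }
  stop("split_two_thirds: could not produce a split with all classes",
       call. = FALSE)
}

#' Five-fold validation of a binary configuration
#'
#' Five independent random 2/3-train / 1/3-test splits; for each fold the
#' standardiser is fitted on the training rows only, a binary classifier
#' is trained with the weight from [class_weight()] at ratio r, and a
#' [binary_report()] is computed on the test rows.  Metrics are averaged
#' over folds.
#'
#' @param features feature matrix (unstandardised).
#' @param y multiclass labels.
#' @param rule labelling rule for [label_for()] (`enbc` or `ivbc`).
#' @param method binary method for [fit_binary()].
#' @param r effective balance ratio.
#' @param B decision boundary for probabilistic methods.
#' @param folds number of random splits (default 5).
#' @param config method settings for [fit_binary()].
#' @param keep_models return the per-fold fitted models.
#' @return list with `folds` (data frame of per-fold metrics incl. train
#'   F score) and `mean` (averaged metrics).
#' @export
five_fold <- function(features, y, rule, method = "lr", r = 1, B = 0.5,
                      folds = 5, config = list(), keep_models = FALSE) {
  tau <- label_for(rule, y)
  stopifnot(!anyNA(tau))
  config_type <- if (rule$type == "enbc") "enbc" else "ivbc"
  rows <- vector("list", folds)
  models <- vector("list", folds)
  for (fd in seq_len(folds)) {
    tr <- split_two_thirds(tau)
    std <- fit_standardiser(features[tr, , drop = FALSE])
    Xtr <- predict(std, features[tr, , drop = FALSE])
    Xte <- predict(std, features[-tr, , drop = FALSE])
    w <- class_weight(sum(tau[tr] == 1), sum(tau[tr] == 0), r)
    model <- fit_binary(method, Xtr, tau[tr], w, config)
    pred_te <- predict_class01(model, Xte, B)
    pred_tr <- predict_class01(model, Xtr, B)
    rep_te <- binary_report(pred_te, tau[-tr], config_type, w = w)
    rep_tr <- binary_report(pred_tr, tau[tr], config_type, w = w)
    rows[[fd]] <- data.frame(fold = fd, f = rep_te$f,
                             sensitivity = rep_te$sensitivity,
                             specificity = rep_te$specificity,
                             train_f = rep_tr$f, w = w)
    if (keep_models) models[[fd]] <- list(model = model, std = std,
                                          train = tr)
  }
  df <- do.call(rbind, rows)
  out <- list(folds = df,
              mean = colMeans(df[, c("f", "sensitivity", "specificity",
                                     "train_f")]))
  if (keep_models) out$models <- models
  out
}

#' Combination search over measurement subsets
#'
#' Trains and tests a binary configuration for every one of the 63
#' measurement combinations and every requested method, five-fold
#' averaged.
#'
#' @param vpd a `vpd` (solver-built or surrogate).
#' @param methods character vector of methods for [fit_binary()].
#' @param rule labelling rule (`list(type = "enbc")` or
#'   `list(type = "ivbc", vessel = ...)`).
#' @param r,B,folds see [five_fold()].
#' @param combinations optionally restrict the searched combinations.
#' @return data frame with one row per (combination, method):
#'   `combination` (comma-separated), `size`, `method`, `f`,
#'   `sensitivity`, `specificity`.
#' @export
combination_search <- function(vpd, methods = "lr",
                               rule = list(type = "enbc"), r = 1, B = 0.5,
                               folds = 5, combinations = NULL) {
  feats <- features_from_vpd(vpd)
  y <- vpd_labels(vpd)
  combos <- combinations %||% enumerate_combinations()
  rows <- list()
  for (cmb in combos) {
    fc <- features_for_combination(feats, cmb)
    for (mth in methods) {
      res <- five_fold(fc, y, rule, method = mth, r = r, B = B,
                       folds = folds)
      rows[[length(rows) + 1]] <- data.frame(
        combination = paste(cmb, collapse = ","), size = length(cmb),
        method = mth, f = res$mean[["f"]],
        sensitivity = res$mean[["sensitivity"]],
        specificity = res$mean[["specificity"]])
    }
  }
  do.call(rbind, rows)
}

#' Like-for-like symmetry audit
#'
#' For each of the 24 pairs of combinations exchanged by the iliac swap,
#' the absolute difference of F scores between the two members.  Because
#' the two classifiers see statistically identical problems, these
#' discrepancies estimate the training/statistical noise floor of the
#' combination search.
#'
#' @param search_results output of [combination_search()].
#' @return data frame with `method`, `first`, `second`, `f_first`,
#'   `f_second`, `discrepancy`.
#' @export
like_for_like_audit <- function(search_results) {
  pairs <- like_for_like_pairs()
  rows <- list()
  for (mth in unique(search_results$method)) {
    sub <- search_results[search_results$method == mth, ]
    lut <- setNames(sub$f, sub$combination)
    for (p in pairs) {
      k1 <- paste(p$first, collapse = ",")
      k2 <- paste(p$second, collapse = ",")
      if (!(k1 %in% names(lut)) || !(k2 %in% names(lut))) next
      rows[[length(rows) + 1]] <- data.frame(
        method = mth, first = k1, second = k2,
        f_first = unname(lut[k1]), f_second = unname(lut[k2]),
        discrepancy = abs(unname(lut[k1]) - unname(lut[k2])))
    }
  }
  do.call(rbind, rows)
}

#' Per-class multiclass accuracy table
#'
#' One-vs-rest sensitivity and specificity for each of the four classes.
#'
#' @param pred,truth character vectors of class labels.
#' @return data frame with `class`, `sensitivity`, `specificity`.
#' @export
multiclass_report <- function(pred, truth) {
  do.call(rbind, lapply(class_levels(), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fn <- sum(pred != cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    tn <- sum(pred != cl & truth != cl)
    data.frame(class = cl, sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp))
  }))
}

#' ROC curves and AUC for a CPC ensemble
#'
#' Sweeps the decision boundary over a grid including the exact endpoints
#' 0 and 1 and records one-vs-rest true/false positive rates per class.
#' At B = 1 every patient is classified healthy, so the healthy-class
#' curve reaches (1,1) there and (0,0) at B = 0: its ROC curve is
#' complete and its AUC is computed by the trapezoidal rule on
#' FPR-sorted points.  The disease-class curves are returned without
#' forcing completeness (they cannot reach (1,1) under the CPC rule).
#'
#' @param ensemble a CPC `stn_multiclass` (from [train_multiclass()]).
#' @param X test features (standardised as in training).
#' @param y test labels.
#' @param boundaries boundary grid (0 and 1 are appended if missing).
#' @return list with `points` (data frame: class, boundary, tpr, fpr)
#'   and `auc` (named vector; NA where the curve is incomplete).
#' @export
roc_and_auc <- function(ensemble, X, y,
                        boundaries = seq(0, 1, length.out = 101)) {
  stopifnot(identical(ensemble$strategy, "cpc"))
  boundaries <- sort(unique(c(0, boundaries, 1)))
  y <- as.character(y)
  rows <- list()
  for (B in boundaries) {
    pred <- predict(ensemble, X, B = B)
    for (cl in class_levels()) {
      tp <- sum(pred == cl & y == cl)
      fn <- sum(pred != cl & y == cl)
      fp <- sum(pred == cl & y != cl)
      tn <- sum(pred != cl & y != cl)
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, boundary = B, tpr = tp / (tp + fn),
        fpr = fp / (fp + tn))
    }
  }
  pts <- do.call(rbind, rows)
  auc <- setNames(rep(NA_real_, 4), class_levels())
  for (cl in class_levels()) {
    sub <- pts[pts$class == cl, ]
    sub <- sub[order(sub$fpr, sub$tpr), ]
    complete <- min(sub$fpr) == 0 && max(sub$fpr) == 1 &&
      min(sub$tpr) == 0 && max(sub$tpr) == 1
    if (complete) {
      auc[cl] <- sum(diff(sub$fpr) * (head(sub$tpr, -1) +
                                        diff(sub$tpr) / 2))
    }
  }
  list(points = pts, auc = auc)
}

#' Trapezoidal AUC of scores against binary labels
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 truth.
#' @return area under the ROC curve.
#' @export
auc_from_scores <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tpr <- c(0, cumsum(lab == 1) / sum(lab == 1))
  fpr <- c(0, cumsum(lab == 0) / sum(lab == 0))
  sum(diff(fpr) * (head(tpr, -1) + diff(tpr) / 2))
}

#' Learning curve for an individual-vessel classifier
#'
#' Five-fold train and test F scores using all six measurements at
#' successively increasing numbers of available patients (sampled as a
#' class-stratified subset of the VPD), with the member weight from the
#' class imbalance at r = 1.
#'
#' @param vpd a `vpd`.
#' @param vessel vessel of the individual-vessel configuration.
#' @param sizes increasing patient counts (each <= VPD size).
#' @param method binary method.
#' @param folds folds per size.
#' @param r effective balance ratio.
#' @return data frame with `n`, `train_f`, `test_f`, `sensitivity`,
#'   `specificity`.
#' @export
learning_curve <- function(vpd, vessel = "aorta", sizes, method = "lr",
                           folds = 5, r = 1) {
  feats <- features_from_vpd(vpd)
  y <- vpd_labels(vpd)
  n <- length(y)
  stopifnot(all(sizes <= n), all(sizes >= 30))
  rows <- list()
  for (sz in sizes) {
    idx <- unlist(lapply(split(seq_len(n), y), function(ii) {
      sample(ii, round(length(ii) * sz / n))
    }))
    res <- five_fold(feats[idx, , drop = FALSE], y[idx],
                     rule = list(type = "ivbc", vessel = vessel),
                     method = method, r = r, folds = folds)
    rows[[length(rows) + 1]] <- data.frame(
      n = length(idx), train_f = res$mean[["train_f"]],
      test_f = res$mean[["f"]],
      sensitivity = res$mean[["sensitivity"]],
      specificity = res$mean[["specificity"]])
  }
  do.call(rbind, rows)
}

#' Severity analysis of a binary classifier
#'
#' Per-patient table of stenosis severity (0 for healthy patients),
#' predicted probability (where the model is probabilistic), predicted
#' and true binary outcome, and the confusion outcome TP/FN/FP/TN; used
#' to examine whether detection accuracy depends on severity.
#'
#' @param model fitted `stn_binary`.
#' @param X test features (standardised as in training).
#' @param tau 0/1 truth for the binary configuration.
#' @param severity per-patient severities.
#' @param B decision boundary.
#' @return data frame with one row per test patient.
#' @export
severity_analysis <- function(model, X, tau, severity, B = 0.5) {
  stopifnot(length(tau) == nrow(as.matrix(X)),
            length(severity) == length(tau))
  prob <- tryCatch(predict_prob(model, X), error = function(e)
    rep(NA_real_, length(tau)))
  pred <- predict_class01(model, X, B)
  outcome <- ifelse(pred == 1 & tau == 1, "TP",
                    ifelse(pred == 0 & tau == 1, "FN",
                           ifelse(pred == 1 & tau == 0, "FP", "TN")))
  data.frame(severity = severity, probability = prob, predicted = pred,
             truth = tau, outcome = outcome)
}
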