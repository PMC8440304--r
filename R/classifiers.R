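# Classifiers: cost-weighted logistic regression (authored here), binary
# labelling rules, multiclass ensembles (OVA / OVO / CPC), and adapters to
# established SVM / naive Bayes / random forest implementations.

#' Class weight from the effective-balance ratio
#'
#' Solves \eqn{r = w\,m^{(1)}/m^{(2)}} for the weight w applied to the
#' positive-class cost, where m1 and m2 are the training counts of the
#' two classes.  r = 1 balances the potential contribution of the two
#' classes to the loss.
#'
#' @param m1,m2 positive class / negative class training counts.
#' @param r desired effective ratio (default 1).
#' @return weight w > 0.
#' @export
class_weight <- function(m1, m2, r = 1) {
  if (m1 <= 0 || m2 <= 0 || r <= 0) {
    stop("class_weight: counts and r must be positive", call. = FALSE)
  }
  r * m2 / m1
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Predicted probabilities are kept strictly inside (0, 1): saturated
# activations would otherwise report exactly 1 and defeat boundary rules
# that compare p >= B at B = 1 (every patient must default to healthy
# there).
clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Cost-weighted logistic log loss and gradient
#'
#' Mean weighted cross-entropy
#' \deqn{L = -\frac1m \sum_i \big(w\,\tau_i \log h_i +
#'        (1-\tau_i)\log(1-h_i)\big),\qquad
#'       h_i = \sigma(\theta^\top x_i),}
#' which reduces to the ordinary logistic loss at w = 1.  Probabilities
#' are clipped away from 0/1 by machine-epsilon to keep the loss finite.
#'
#' @param theta coefficient vector (matching the columns of `X`).
#' @param X design matrix, intercept column included if desired.
#' @param tau 0/1 response vector.
#' @param w positive-class cost weight.
#' @return `weighted_log_loss`: scalar loss;
#'   `weighted_log_loss_grad`: gradient vector.
#' @export
weighted_log_loss <- function(theta, X, tau, w = 1) {
  stopifnot(all(tau %in% c(0, 1)))
  h <- sigmoid(drop(X %*% theta))
  eps <- .Machine$double.eps
  h <- pmin(pmax(h, eps), 1 - eps)
  -mean(w * tau * log(h) + (1 - tau) * log(1 - h))
}

#' @rdname weighted_log_loss
#' @export
weighted_log_loss_grad <- function(theta, X, tau, w = 1) {
  h <- sigmoid(drop(X %*% theta))
  # dL/dtheta = (1/m) sum_i [ h_i (w tau_i + 1 - tau_i) - w tau_i ] x_i
  coef <- h * (w * tau + 1 - tau) - w * tau
  drop(crossprod(X, coef)) / nrow(X)
}

add_intercept <- function(X) {
  cbind(`(intercept)` = 1, X)
}

#' Train a cost-weighted logistic regression
#'
#' Minimises the weighted log loss with deterministic full-batch BFGS
#' (analytic gradient, zero initialisation, no regularisation by default).
#' An intercept is handled as an appended constant feature.
#'
#' @param X feature matrix (standardised features expected).
#' @param tau 0/1 response.
#' @param w positive-class cost weight (see [class_weight()]).
#' @param B decision boundary used by [predict_binary()] (default 0.5).
#' @param lambda optional L2 penalty (0 = none; excluded from intercept).
#' @param maxit optimiser iteration cap.
#' @param reltol optimiser relative-loss tolerance.
#' @return object of class `logistic_model` with `theta`, diagnostics
#'   `loss`, `converged`, and the decision boundary `B`.
#' @export
train_logistic <- function(X, tau, w = 1, B = 0.5, lambda = 0,
                           maxit = 2000, reltol = 1e-8) {
  stopifnot(length(unique(tau)) == 2)
  Xi <- add_intercept(as.matrix(X))
  pen <- c(0, rep(lambda, ncol(Xi) - 1))
  fn <- function(th) weighted_log_loss(th, Xi, tau, w) + sum(pen * th^2)
  gr <- function(th) weighted_log_loss_grad(th, Xi, tau, w) + 2 * pen * th
  opt <- optim(rep(0, ncol(Xi)), fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  gnorm <- sqrt(mean(gr(opt$par)^2))
  converged <- opt$convergence == 0 || gnorm < 1e-3
  if (!converged) {
    # on separable data the loss surface is flat and the iteration cap is
    # benign; warn only when the gradient shows a genuine failure
    warning(sprintf(
      "train_logistic: optimiser code %d after %d evals (RMS gradient %.2g)",
      opt$convergence, opt$counts[["function"]], gnorm))
  }
  structure(list(theta = setNames(opt$par, colnames(Xi)), B = B, w = w,
                 loss = opt$value, converged = converged,
                 grad_norm = gnorm,
                 feature_names = colnames(X)),
            class = c("logistic_model", "stn_binary"))
}

#' Predicted positive-class probability
#' @param model a fitted binary model.
#' @param X feature matrix.
#' @return probabilities in (0,1), or decision scores for
#'   non-probabilistic models.
#' @export
predict_prob <- function(model, X) UseMethod("predict_prob")

#' @export
predict_prob.logistic_model <- function(model, X) {
  clip01(sigmoid(drop(add_intercept(as.matrix(X)) %*% model$theta)))
}

#' Binary class prediction via the decision boundary
#'
#' Assigns the positive class C1 whenever the predicted probability is
#' greater than or equal to the boundary B (boundary inclusive).
#'
#' @param model a fitted probabilistic binary model.
#' @param X feature matrix.
#' @param B decision boundary in \[0,1\] (defaults to the model's).
#' @return integer vector: 1 for C1, 0 for C2.
#' @export
predict_binary <- function(model, X, B = NULL) {
  if (is.null(B)) B <- if (!is.null(model$B)) model$B else 0.5
  as.integer(predict_prob(model, X) >= B)
}

#' Binary labelling rules
#'
#' Maps the four-class ground truth onto the 0/1 response of a binary
#' configuration:
#' * `enbc`: 1 if no disease anywhere (healthy is the positive class C1);
#' * `ivbc`: 1 if disease lies in the designated vessel;
#' * `ova`: 1 if the label equals the designated class;
#' * `ovo`: 1 / 0 for the two designated classes, `NA` (excluded)
#'   otherwise.
#'
#' @param rule list with `type` (`"enbc"`, `"ivbc"`, `"ova"`, `"ovo"`) and
#'   the class fields it needs: `vessel` for ivbc, `class` for ova,
#'   `class1`/`class0` for ovo.
#' @param y character/factor vector of multiclass labels (see
#'   [class_levels()]).
#' @return numeric vector of 0/1 (NA for OVO exclusions).
#' @export
label_for <- function(rule, y) {
  y <- as.character(y)
  stopifnot(all(y %in% class_levels()))
  switch(rule$type,
    enbc = as.numeric(y == "healthy"),
    ivbc = as.numeric(y == rule$vessel),
    ova = as.numeric(y == rule$class),
    ovo = ifelse(y == rule$class1, 1,
                 ifelse(y == rule$class0, 0, NA_real_)),
    stop("label_for: unknown rule type", call. = FALSE))
}

# ---- adapters to established implementations --------------------------------

#' Fit a binary classifier with an established method
#'
#' Thin adapters wrapping `e1071::svm` (RBF or linear kernel, cost weight
#' passed through `class.weights`), `e1071::naiveBayes` (Gaussian
#' likelihoods) and `randomForest::randomForest`.  Features are expected
#' already standardised, so internal scaling is disabled.
#'
#' @param method one of `"lr"`, `"svm_rbf"`, `"svm_linear"`,
#'   `"gaussian_nb"`, `"random_forest"`.
#' @param X standardised feature matrix.
#' @param tau 0/1 response.
#' @param w positive-class cost weight (ignored by NB).
#' @param config optional list of method settings (`ntree`, `maxnodes`
#'   for random forest; `cost` for SVM; `B`, `lambda` for lr).
#' @return fitted object of class `stn_binary`.
#' @export
fit_binary <- function(method, X, tau, w = 1, config = list()) {
  X <- as.matrix(X)
  yf <- factor(tau, levels = c(0, 1))
  fit <- switch(method,
    lr = return(train_logistic(X, tau, w = w,
                               B = config$B %||% 0.5,
                               lambda = config$lambda %||% 0)),
    svm_rbf = e1071::svm(X, yf, kernel = "radial", scale = FALSE,
                         cost = config$cost %||% 1,
                         class.weights = c(`0` = 1, `1` = w)),
    svm_linear = e1071::svm(X, yf, kernel = "linear", scale = FALSE,
                            cost = config$cost %||% 1,
                            class.weights = c(`0` = 1, `1` = w)),
    gaussian_nb = e1071::naiveBayes(as.data.frame(X), yf),
    random_forest = randomForest::randomForest(
      X, yf, ntree = config$ntree %||% 200,
      maxnodes = config$maxnodes,
      classwt = c(`0` = 1, `1` = w)),
    stop(sprintf("fit_binary: unsupported method '%s'", method),
         call. = FALSE))
  structure(list(method = method, fit = fit,
                 probabilistic = method %in% c("gaussian_nb",
                                               "random_forest"),
                 feature_names = colnames(X)),
            class = c(paste0("stn_", method), "stn_binary"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict_prob.stn_gaussian_nb <- function(model, X) {
  pr <- predict(model$fit, as.data.frame(as.matrix(X)), type = "raw")
  clip01(unname(pr[, "1"]))
}

#' @export
predict_prob.stn_random_forest <- function(model, X) {
  pr <- predict(model$fit, as.matrix(X), type = "prob")
  clip01(unname(pr[, "1"]))
}

#' @export
predict_prob.stn_svm_rbf <- function(model, X) {
  # decision score, not a probability; used only for ranking/tie-breaks
  d <- attr(predict(model$fit, as.matrix(X), decision.values = TRUE),
            "decision.values")
  s <- drop(d)
  if (grepl("^0/", colnames(d)[1])) s <- -s
  unname(s)
}

#' @export
predict_prob.stn_svm_linear <- function(model, X) {
  predict_prob.stn_svm_rbf(model, X)
}

predict_class01 <- function(model, X, B = 0.5) {
  if (inherits(model, "logistic_model") ||
      model$method %in% c("gaussian_nb", "random_forest")) {
    as.integer(predict_prob(model, X) >= B)
  } else {
    as.integer(as.character(predict(model$fit, as.matrix(X))) == "1")
  }
}

#' Frozen random-forest hyperparameter search
#'
#' One-off grid search over tree count and tree size maximising the
#' F score on a held-out third of the supplied data; the winning pair is
#' returned and is meant to be frozen for all subsequent runs.
#'
#' @param X standardised features; @param tau 0/1 response.
#' @param ntree_grid,maxnodes_grid candidate values.
#' @return list with `ntree`, `maxnodes` and the scored `grid`.
#' @export
rf_grid_search <- function(X, tau, ntree_grid = c(100, 300),
                           maxnodes_grid = c(16, 64, 256)) {
  n <- nrow(X)
  tr <- sample(n, round(2 / 3 * n))
  grid <- expand.grid(ntree = ntree_grid, maxnodes = maxnodes_grid)
  grid$f1 <- NA_real_
  for (g in seq_len(nrow(grid))) {
    m <- fit_binary("random_forest", X[tr, , drop = FALSE], tau[tr],
                    config = list(ntree = grid$ntree[g],
                                  maxnodes = grid$maxnodes[g]))
    pred <- predict_class01(m, X[-tr, , drop = FALSE])
    cc <- confusion_counts(pred, tau[-tr])
    pr <- cc$TP / max(cc$TP + cc$FP, 1)
    rc <- cc$TP / max(cc$TP + cc$FN, 1)
    grid$f1[g] <- if (pr + rc == 0) 0 else f_score(pr, rc)
  }
  best <- grid[which.max(grid$f1), ]
  list(ntree = best$ntree, maxnodes = best$maxnodes, grid = grid)
}

# ---- multiclass ensembles ---------------------------------------------------

#' Train a multiclass ensemble
#'
#' Builds the member binary classifiers of the chosen strategy:
#' * `ova` -- four one-vs-all members (one per class);
#' * `ovo` -- six pairwise members;
#' * `cpc` -- three disease-vs-rest members (aorta, iliac 1, iliac 2);
#'   the healthy class is the default and has no member.
#'
#' Each member's cost weight is derived from its own class imbalance via
#' [class_weight()] at the given ratio r.
#'
#' @param X standardised training features.
#' @param y multiclass labels (levels of [class_levels()]).
#' @param strategy `"ova"`, `"ovo"` or `"cpc"`.
#' @param method binary method passed to [fit_binary()] (CPC requires a
#'   probabilistic method).
#' @param r effective balance ratio for member weights.
#' @param B decision boundary (used by CPC prediction).
#' @param config per-member settings for [fit_binary()].
#' @return object of class `stn_multiclass`.
#' @export
train_multiclass <- function(X, y, strategy = c("ova", "ovo", "cpc"),
                             method = "lr", r = 1, B = 0.5,
                             config = list()) {
  strategy <- match.arg(strategy)
  y <- as.character(y)
  lv <- class_levels()
  if (strategy == "cpc" && method %in% c("svm_rbf", "svm_linear")) {
    stop("CPC requires a probabilistic binary method", call. = FALSE)
  }
  members <- list()
  if (strategy == "ova") {
    for (cl in lv) {
      tau <- label_for(list(type = "ova", class = cl), y)
      w <- class_weight(sum(tau == 1), sum(tau == 0), r)
      members[[cl]] <- fit_binary(method, X, tau, w, config)
    }
  } else if (strategy == "ovo") {
    prs <- combn(lv, 2, simplify = FALSE)
    for (p in prs) {
      rule <- list(type = "ovo", class1 = p[1], class0 = p[2])
      tau <- label_for(rule, y)
      keep <- !is.na(tau)
      w <- class_weight(sum(tau[keep] == 1), sum(tau[keep] == 0), r)
      m <- fit_binary(method, X[keep, , drop = FALSE], tau[keep], w, config)
      m$class1 <- p[1]
      m$class0 <- p[2]
      members[[paste(p, collapse = "|")]] <- m
    }
  } else {
    for (cl in lv[-1]) {
      tau <- label_for(list(type = "ova", class = cl), y)
      w <- class_weight(sum(tau == 1), sum(tau == 0), r)
      members[[cl]] <- fit_binary(method, X, tau, w, config)
    }
  }
  structure(list(strategy = strategy, method = method, members = members,
                 B = B, r = r),
            class = "stn_multiclass")
}

#' One-vs-all prediction
#'
#' The class with the highest member probability wins; exact ties break
#' by class order C1 < C2 < C3 < C4.
#'
#' @param members named list of fitted probabilistic members (one per
#'   class, in class order).
#' @param X feature matrix.
#' @return character vector of class labels.
#' @export
predict_ova <- function(members, X) {
  probs <- vapply(members, function(m) predict_prob(m, X),
                  numeric(nrow(as.matrix(X))))
  probs <- matrix(probs, ncol = length(members),
                  dimnames = list(NULL, names(members)))
  names(members)[max.col(probs, ties.method = "first")]
}

#' One-vs-one prediction
#'
#' Majority vote over the pairwise members; ties break first by summed
#' member probabilities/scores, then by class order.
#'
#' @param members named list of pairwise members with `class1`/`class0`.
#' @param X feature matrix.
#' @return character vector of class labels.
#' @export
predict_ovo <- function(members, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  lv <- class_levels()
  votes <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
  score <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
  for (m in members) {
    cls <- predict_class01(m, X)
    sc <- tryCatch(predict_prob(m, X), error = function(e) rep(0, n))
    votes[, m$class1] <- votes[, m$class1] + (cls == 1)
    votes[, m$class0] <- votes[, m$class0] + (cls == 0)
    score[, m$class1] <- score[, m$class1] + sc
    score[, m$class0] <- score[, m$class0] - sc
  }
  out <- character(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      top <- top[score[i, top] == max(score[i, top])]
    }
    out[i] <- lv[top[1]]
  }
  out
}

#' Custom probabilistic configuration prediction
#'
#' Every patient defaults to healthy; the default is overridden only when
#' the largest of the three disease probabilities reaches the decision
#' boundary B, in which case the corresponding vessel class is assigned.
#' The set of patients classified healthy is non-shrinking in B.
#'
#' @param members named list of three probabilistic members
#'   (aorta, iliac_1, iliac_2).
#' @param X feature matrix.
#' @param B decision boundary in \[0,1\].
#' @return character vector of class labels.
#' @export
predict_cpc <- function(members, X, B = 0.5) {
  probs <- vapply(members, function(m) predict_prob(m, X),
                  numeric(nrow(as.matrix(X))))
  probs <- matrix(probs, ncol = length(members),
                  dimnames = list(NULL, names(members)))
  best <- max.col(probs, ties.method = "first")
  pmax_ <- probs[cbind(seq_len(nrow(probs)), best)]
  ifelse(pmax_ >= B, colnames(probs)[best], "healthy")
}

#' Predict from a multiclass ensemble
#' @param object an `stn_multiclass` from [train_multiclass()].
#' @param newdata feature matrix.
#' @param B decision boundary override (CPC only).
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.stn_multiclass <- function(object, newdata, B = NULL, ...) {
  switch(object$strategy,
         ova = predict_ova(object$members, newdata),
         ovo = predict_ovo(object$members, newdata),
         cpc = predict_cpc(object$members, newdata, B %||% object$B))
}
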