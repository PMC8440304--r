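# Waveform features: Fourier-series coefficients, Z-score standardisation,
# and measurement-combination combinatorics.

measurement_names <- function() c("Q1", "Q2", "Q3", "P1", "P2", "P3")

#' Fit a truncated Fourier series to one periodic waveform
#'
#' Linear least squares of uniformly sampled data on the basis
#' \eqn{\{1, \sin(n\omega t), \cos(n\omega t)\}_{n=1..N}}; at uniform
#' sampling this is equivalent to a discrete Fourier transform, so a
#' band-limited input (at most N harmonics) is reconstructed exactly.
#'
#' @param series numeric vector: samples uniform over one period
#'   (endpoint excluded), length at least 2*order + 1.
#' @param period period T in s.
#' @param order truncation order N (default 5).
#' @return named numeric vector of the 2N+1 coefficients
#'   `b0, a1..aN, b1..bN`.
#' @export
fit_fourier <- function(series, period = 1, order = 5) {
  m <- length(series)
  if (m < 2 * order + 1) {
    stop("fit_fourier: need at least 2*order+1 samples", call. = FALSE)
  }
  X <- fourier_design(m, period, order)
  cf <- qr.coef(qr(X), series)
  setNames(as.numeric(cf), colnames(X))
}

# Design matrix on the uniform grid t_k = k T / m, k = 0..m-1, with columns
# ordered b0, a1..aN, b1..bN.
fourier_design <- function(m, period, order) {
  t <- seq(0, period, length.out = m + 1)[-(m + 1)]
  om <- 2 * pi / period
  X <- matrix(0, m, 2 * order + 1)
  X[, 1] <- 1
  for (n in seq_len(order)) {
    X[, 1 + n] <- sin(n * om * t)
    X[, 1 + order + n] <- cos(n * om * t)
  }
  colnames(X) <- c("b0", paste0("a", seq_len(order)),
                   paste0("b", seq_len(order)))
  X
}

#' Evaluate a fitted Fourier series
#' @param coefs coefficients as returned by [fit_fourier()].
#' @param t times in s.
#' @param period period T in s.
#' @return reconstructed values.
#' @export
eval_fourier <- function(coefs, t, period = 1) {
  order <- (length(coefs) - 1) / 2
  om <- 2 * pi / period
  out <- rep(coefs[["b0"]], length(t))
  for (n in seq_len(order)) {
    out <- out + coefs[[paste0("a", n)]] * sin(n * om * t) +
      coefs[[paste0("b", n)]] * cos(n * om * t)
  }
  out
}

#' Full feature matrix of a VPD
#'
#' 11 Fourier coefficients per measurement site for all six measurements:
#' a 66-column matrix with columns named like `P1_b0`, `P1_a1`, ...,
#' `Q3_b5`.
#'
#' @param vpd a `vpd` object (solver-built or surrogate).
#' @param order Fourier truncation order.
#' @return numeric matrix, one row per patient.
#' @export
features_from_vpd <- function(vpd, order = 5) {
  stopifnot(length(vpd$patients) > 0)
  w1 <- vpd$patients[[1]]$waveforms
  m <- nrow(w1$series)
  X <- fourier_design(m, w1$period, order)
  proj <- solve(crossprod(X), t(X))  # (11 x m) least-squares projector
  meas <- measurement_names()
  out <- matrix(0, length(vpd$patients), length(meas) * (2 * order + 1))
  colnames(out) <- as.vector(vapply(
    meas, function(s) paste(s, colnames(X), sep = "_"),
    character(2 * order + 1)))
  for (i in seq_along(vpd$patients)) {
    ser <- vpd$patients[[i]]$waveforms$series
    out[i, ] <- as.vector(proj %*% ser[, meas])
  }
  out
}

#' Restrict a feature matrix to a measurement combination
#' @param features full feature matrix from [features_from_vpd()].
#' @param combination character vector: subset of
#'   `c("Q1","Q2","Q3","P1","P2","P3")`.
#' @return the 11*|combination| column subset.
#' @export
features_for_combination <- function(features, combination) {
  stopifnot(length(combination) > 0,
            all(combination %in% measurement_names()))
  keep <- unlist(lapply(combination, function(s) {
    grep(paste0("^", s, "_"), colnames(features))
  }))
  features[, keep, drop = FALSE]
}

#' Z-score standardiser
#'
#' Learns per-coordinate mean and standard deviation on training data;
#' the same statistics are applied to any later data (test rows are never
#' used to fit).  Coordinates with zero variance get SD 1 (with a
#' warning) so that degenerate inputs pass through unchanged.
#'
#' @param X training feature matrix (>= 2 rows).
#' @return object of class `standardiser` with `center` and `scale`.
#' @export
fit_standardiser <- function(X) {
  stopifnot(nrow(X) >= 2)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero <- !is.finite(scl) | scl == 0
  if (any(zero)) {
    warning(sprintf("standardiser: %d zero-variance coordinate(s), SD set to 1",
                    sum(zero)))
    scl[zero] <- 1
  }
  structure(list(center = ctr, scale = scl), class = "standardiser")
}

#' @param object a `standardiser`.
#' @param newdata matrix to transform.
#' @param ... unused.
#' @rdname fit_standardiser
#' @export
predict.standardiser <- function(object, newdata, ...) {
  sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
}

#' Invert a standardisation
#' @param object a `standardiser`.
#' @param Z standardised matrix.
#' @return matrix on the original scale.
#' @export
unstandardise <- function(object, Z) {
  sweep(sweep(Z, 2, object$scale, "*"), 2, object$center, "+")
}

#' Enumerate the measurement combinations
#'
#' All 63 non-empty subsets of the six measurements, in a deterministic
#' order (by subset size, then by position).
#'
#' @return list of character vectors.
#' @export
enumerate_combinations <- function() {
  meas <- measurement_names()
  out <- list()
  for (k in 1:6) {
    cmb <- combn(meas, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Iliac-swap image of a measurement combination
#'
#' The left/right iliac relabelling maps P2 <-> P3 and Q2 <-> Q3 and
#' leaves the inlet measurements fixed; it is an involution on the 63
#' combinations.
#'
#' @param combination character vector of measurements.
#' @return the swapped combination (sorted in canonical order).
#' @export
iliac_swap <- function(combination) {
  map <- c(Q1 = "Q1", Q2 = "Q3", Q3 = "Q2", P1 = "P1", P2 = "P3", P3 = "P2")
  out <- unname(map[combination])
  out[order(match(out, measurement_names()))]
}

#' Like-for-like combination pairs
#'
#' The unordered pairs \{S, sigma(S)\} of combinations exchanged by the
#' iliac swap with sigma(S) != S.  Classifiers trained on the two members
#' of a pair should perform identically up to training noise; there are
#' 24 such pairs (and 15 swap-invariant combinations).
#'
#' @return list of two-element lists `first`/`second`.
#' @export
like_for_like_pairs <- function() {
  combos <- enumerate_combinations()
  key <- vapply(combos, paste, character(1), collapse = ",")
  seen <- character(0)
  pairs <- list()
  for (cmb in combos) {
    sw <- iliac_swap(cmb)
    k1 <- paste(cmb, collapse = ",")
    k2 <- paste(sw, collapse = ",")
    if (k1 == k2 || k1 %in% seen || k2 %in% seen) next
    seen <- c(seen, k1, k2)
    pairs[[length(pairs) + 1]] <- list(first = cmb, second = sw)
  }
  stopifnot(all(c(key) %in% key))
  pairs
}
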