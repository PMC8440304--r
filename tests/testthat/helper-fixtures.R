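# Shared fixtures, built in code.  Expensive objects are cached across
# test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# Small surrogate cohort exercising the full ML layer.
surrogate_fixture <- function() {
  cached("surrogate", {
    set.seed(7741)
    surrogate_vpd(targets = c(healthy = 150, aorta = 50, iliac_1 = 50,
                              iliac_2 = 50))
  })
}

# Mean-parameter healthy patient solved once at defaults.
mean_patient_waveforms <- function() {
  cached("mean_wave", {
    ref <- reference_parameters()
    solve_network(apply_disease(ref$means, list(site = "none")),
                  blood_model(), default_inlet_series(), solver_config())
  })
}

# A logistic model whose predicted probability equals sigmoid(x) for a
# single feature; lets tests dial in exact probabilities.
identity_prob_model <- function() {
  structure(list(theta = c(`(intercept)` = 0, x = 1), B = 0.5, w = 1,
                 feature_names = "x"),
            class = c("logistic_model", "stn_binary"))
}

logit <- function(p) log(p / (1 - p))

# Linearly separable two-class toy set in 2D.
toy_separable <- function(n = 60) {
  x <- matrix(rnorm(2 * n), ncol = 2)
  tau <- as.numeric(x[, 1] + x[, 2] > 0)
  x[tau == 1, ] <- x[tau == 1, , drop = FALSE] + 1.5
  x[tau == 0, ] <- x[tau == 0, , drop = FALSE] - 1.5
  list(X = x, tau = tau)
}
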