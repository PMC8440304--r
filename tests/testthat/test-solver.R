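# Elementary closures and the 1D solver's physical invariants.

test_that("wall stiffness follows the elastic closure and rejects bad input", {
  expect_equal(compute_beta(500e3, 1.03e-3), (4 / 3) * 500e3 * 1.03e-3 * sqrt(pi))
  expect_equal(compute_beta(500e3, 1.03e-3), 1217.15, tolerance = 1e-4)
  expect_equal(compute_beta(700e3, 0.72e-3), 1191.09, tolerance = 1e-4)
  # vanishing wall thickness drives beta to zero
  expect_lt(compute_beta(500e3, 1e-15), 1e-8)
  expect_error(compute_beta(-1, 1e-3), "positive")
  expect_error(compute_beta(500e3, 0), "positive")
})

test_that("tube law recovers the diastolic reference and is monotone in area", {
  bl <- blood_model()
  Ad <- 2e-4
  beta <- compute_beta(500e3, 1e-3)
  p_ref <- bl$external_pressure + bl$diastolic_pressure
  expect_equal(tube_law_pressure(Ad, Ad, beta, bl), p_ref)
  # sqrt(4 Ad) = 2 sqrt(Ad) gives an exact closed form
  expect_equal(tube_law_pressure(4 * Ad, Ad, beta, bl),
               p_ref + beta / sqrt(Ad))
  a_grid <- seq(0.5, 2, length.out = 20) * Ad
  p_grid <- tube_law_pressure(a_grid, Ad, beta, bl)
  expect_true(all(diff(p_grid) > 0))
  expect_error(tube_law_pressure(-1e-4, Ad, beta, bl), "positive")
})

test_that("wall friction is linear and opposes the flow", {
  bl <- blood_model(viscosity = 4e-3, zeta = 9)
  expect_equal(friction_force(0, bl), 0)
  expect_equal(friction_force(0.1, bl), -2 * 11 * 4e-3 * pi * 0.1)
  expect_equal(friction_force(0.1, bl), -2.7646e-2, tolerance = 1e-4)
  u <- rnorm(5)
  expect_equal(friction_force(-u, bl), -friction_force(u, bl))
})

test_that("inlet Fourier series evaluates and is periodic", {
  s <- inlet_series(a = c(0, 0, 0, 0, 0, 0), b = c(3e-5, 0, 0, 0, 0, 0))
  expect_equal(inlet_flow_at(c(0, 0.3, 0.9), s), rep(3e-5, 3))
  s2 <- inlet_series(a = c(0, 2e-5, 0, 0, 0, 0), b = rep(0, 6), period = 2)
  expect_equal(inlet_flow_at(0.5, s2), 2e-5)  # sin(omega T/4) = 1
  s3 <- inlet_series(a = c(0, rnorm(5) * 1e-5), b = rnorm(6) * 1e-5)
  t <- runif(10)
  expect_equal(inlet_flow_at(t, s3), inlet_flow_at(t + 1, s3))
  expect_error(inlet_series(a = c(1e-6, rep(0, 5)), b = rep(0, 6)), "a0")
})

test_that("Windkessel model matches its closed-form RC behaviour", {
  o <- windkessel_outlet(R1 = 5e7, R2 = 3e9, C = 4e-10,
                         outflow_pressure = 600)
  q <- 1e-5
  dt <- 1e-3
  p <- windkessel_pressure(rep(q, 50000), o, dt, Pc0 = 0)
  expect_equal(tail(p, 1), o$outflow_pressure + q * (o$R1 + o$R2),
               tolerance = 1e-6)
  # vanishing compliance: purely resistive response at every step
  o0 <- windkessel_outlet(5e7, 3e9, 1e-25)
  qs <- abs(rnorm(10)) * 1e-5
  expect_equal(windkessel_pressure(qs, o0, dt), qs * (o0$R1 + o0$R2),
               tolerance = 1e-8)
  # step change relaxes with time constant R2 C (closed-form oracle)
  tau <- o$R2 * o$C
  n <- 2000
  p2 <- windkessel_pressure(rep(q, n), o, dt, Pc0 = 0)
  pc <- p2 - q * o$R1  # compliance pressure
  pinf <- o$outflow_pressure + q * o$R2
  t_grid <- (1:n) * dt
  oracle <- pinf * (1 - exp(-t_grid / tau))
  expect_equal(pc, oracle, tolerance = 2e-3)
})

test_that("constant inflow relaxes to the 0D series-resistance state", {
  ref <- reference_parameters()
  p <- ref$means
  q0 <- 1.1e-5
  inlet0 <- inlet_series(a = rep(0, 6), b = c(q0, rep(0, 5)))
  w <- solve_network(apply_disease(p, list(site = "none")), blood_model(),
                     inlet0, solver_config())
  r_eff <- 1 / (1 / (p[["wk1_R1"]] + p[["wk1_R2"]]) +
                  1 / (p[["wk2_R1"]] + p[["wk2_R2"]]))
  expect_equal(mean(w$series[, "P1"]), q0 * r_eff, tolerance = 0.01)
  # flat waveforms at the steady state
  expect_lt(diff(range(w$series[, "P1"])) / mean(w$series[, "P1"]), 1e-3)
})

test_that("pulsatile solution conserves mass and stays physiological", {
  w <- mean_patient_waveforms()
  q1 <- mean(w$series[, "Q1"])
  q23 <- mean(w$series[, "Q2"]) + mean(w$series[, "Q3"])
  expect_equal(q23 / q1, 1, tolerance = 0.005)
  expect_lt(w$residual, solver_config()$periodic_tolerance)
  expect_true(all(is.finite(w$series)))
  expect_true(all(w$series[, c("P1", "P2", "P3")] > 0))
})

test_that("mirrored patients swap the iliac waveforms exactly", {
  set.seed(311)
  ref <- reference_parameters()
  p <- sample_healthy(1, ref)[1, ]
  pm <- p
  pm[c("wk1_R1", "wk1_R2", "wk1_C")] <- p[c("wk2_R1", "wk2_R2", "wk2_C")]
  pm[c("wk2_R1", "wk2_R2", "wk2_C")] <- p[c("wk1_R1", "wk1_R2", "wk1_C")]
  d <- list(site = "iliac_1", severity = 0.7, start = 0.25, end = 0.6,
            reference_location = 0.4)
  dm <- d
  dm$site <- "iliac_2"
  inlet <- patient_inlet_series(p)
  w1 <- solve_network(apply_disease(p, d), blood_model(), inlet,
                      solver_config())
  w2 <- solve_network(apply_disease(pm, dm), blood_model(), inlet,
                      solver_config())
  scale <- matrix(apply(abs(w1$series[, c("P2", "Q2", "P3", "Q3")]), 2,
                        max), nrow(w1$series), 4, byrow = TRUE)
  err <- max(abs(w1$series[, c("P2", "Q2", "P3", "Q3")] -
                   w2$series[, c("P3", "Q3", "P2", "Q2")]) / scale)
  expect_lt(err, 1e-8)
})

test_that("grid refinement converges monotonically on a healthy case", {
  ref <- reference_parameters()
  inlet <- default_inlet_series()
  solve_at <- function(el) {
    solve_network(apply_disease(ref$means, list(site = "none"),
                                elements = el),
                  blood_model(), inlet, solver_config())$series[, "P1"]
  }
  fine <- solve_at(96)
  errs <- vapply(c(12, 24, 48), function(el) mean(abs(solve_at(el) - fine)),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  order_est <- log2(errs[1] / errs[2])
  expect_gte(order_est, 1)
})

test_that("deepening a mid-vessel stenosis never reduces the mean pressure drop", {
  ref <- reference_parameters()
  inlet <- default_inlet_series()
  drop_at <- function(S) {
    d <- list(site = "aorta", severity = S, start = 0.35, end = 0.65,
              reference_location = 0.5)
    w <- solve_network(apply_disease(ref$means, d), blood_model(), inlet,
                       solver_config())
    mean(w$series[, "P1"]) - mean(w$series[, "P2"])
  }
  d1 <- drop_at(0.4)
  d2 <- drop_at(0.8)
  expect_gte(d2, d1)
})

test_that("junction rule and non-convergence are surfaced", {
  ref <- reference_parameters()
  inlet <- default_inlet_series()
  net <- apply_disease(ref$means, list(site = "none"))
  w_static <- solve_network(net, blood_model(), inlet,
                            solver_config(junction_rule = "static_pressure"))
  expect_s3_class(w_static, "waveform_set")
  expect_error(
    solve_network(net, blood_model(), inlet,
                  solver_config(max_cycles = 2,
                                periodic_tolerance = 1e-12)),
    class = "stn_nonconvergence")
})
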