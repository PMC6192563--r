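test_that("the shifted sigmoid is zero at zero, increasing, and bounded", {
  for (par in list(c(1.3, 4), c(2, 3.7), c(0.5, 1))) {
    a <- par[1]; th <- par[2]
    expect_identical(wc_sigmoid(0, a, th), 0)
    x <- seq(-10, 10, length.out = 201)
    expect_true(all(diff(wc_sigmoid(x, a, th)) > 0))
    smax <- 1 - 1 / (1 + exp(a * th))
    expect_lt(abs(wc_sigmoid(th + 30 / a, a, th) - smax), 1e-12)
  }
  expect_lt(abs(wc_sigmoid(50, 1.3, 4) - (1 - 1 / (1 + exp(5.2)))), 1e-12)
  # frozen value at the excitatory threshold: 0.5 - 1/(1 + e^5.2)
  expect_equal(wc_sigmoid(4, 1.3, 4), 0.4945137, tolerance = 1e-6)
})

test_that("parameter defaults expose the derived sigmoid ceilings", {
  p <- wc_params()
  expect_equal(p$S_E_max, 1 - 1 / (1 + exp(1.3 * 4)))
  expect_equal(p$S_I_max, 1 - 1 / (1 + exp(2 * 3.7)))
  expect_error(wc_params(tau = -1))
  expect_error(wc_params(step_h = 0))
})

test_that("the drift matches an independent scalar implementation", {
  p <- wc_params()
  n <- 2
  zero <- matrix(0, n, n)

  # origin is an equilibrium of the uncoupled, undriven system
  d0 <- wc_derivatives(rep(0, n), rep(0, n), zero, zero, zero, 0.2, p)
  expect_equal(d0$dE, rep(0, n))
  expect_equal(d0$dI, rep(0, n))

  # uncoupled regions follow the isolated single-region formula
  E <- c(0.15, 0.4); I <- c(0.1, 0.2); P <- c(0, 1.15)
  d <- wc_derivatives(E, I, zero, zero, zero, 0.2, p, P)
  for (i in 1:2) {
    ref <- wc_drift_scalar(E[i], I[i], p, P[i])
    expect_equal(d$dE[i], unname(ref["dE"]))
    expect_equal(d$dI[i], unname(ref["dI"]))
  }

  # coupling term is linear in c5: recomputed through the closed form
  A <- matrix(c(0, 2, 2, 0), 2, 2)
  Edel <- matrix(0.3, 2, 2); Idel <- matrix(0.25, 2, 2)
  d1 <- wc_derivatives(E, I, Edel, Idel, A, 0.1, p)
  arg <- p$c1 * E - p$c2 * I + 0.1 * rowSums(A * Edel)
  d2 <- wc_derivatives(E, I, 2 * Edel, 2 * Idel, A, 0.05, p)
  expect_equal(d2$dE,
               (-E + (p$S_E_max - E) * wc_sigmoid(arg, p$a_E, p$theta_E)) / p$tau)
  expect_equal(d1$dE, d2$dE)  # c5 * delayed activity enters as a product
})

test_that("an isolated noiseless unit relaxes to the deSolve fixed point", {
  skip_if_not_installed("deSolve")
  p <- wc_params(sigma = 0)
  ref <- deSolve::ode(
    y = c(E = 0.1, I = 0.1), times = seq(0, 2000, by = 10),
    func = function(t, y, parms) list(wc_drift_scalar(y[1], y[2], p)),
    parms = NULL, rtol = 1e-12, atol = 1e-14)
  Estar <- ref[nrow(ref), "E"]

  conn <- toy_connectome(matrix(0, 1, 1))
  tr <- simulate_network(conn, p, c5 = 0, duration_ms = 1000,
                         stabilize_ms = 0)
  late <- tr$E[1, tr$time_ms > 800]
  expect_true(all(abs(late - Estar) < 1e-6))
})

test_that("constant drive P = 1.15 sustains a limit cycle", {
  p <- wc_params(sigma = 0)
  conn <- toy_connectome(matrix(0, 1, 1))
  sch <- stim_schedule("V1", 1.15, 0, 2000)
  tr <- simulate_network(conn, p, 0, schedule = sch, duration_ms = 2000,
                         stabilize_ms = 0)
  e <- tr$E[1, ]; t <- tr$time_ms
  ptp <- vapply(seq(1000, 1750, by = 250), function(w)
    diff(range(e[t >= w & t < w + 250])), numeric(1))
  expect_true(all(ptp > 0.1))
  expect_lt(diff(range(ptp)), 0.01)  # non-decaying across windows
})

test_that("zero coupling decouples regions and noise streams are seeded", {
  det <- wc_params(sigma = 0)
  conn2 <- toy_connectome(matrix(0, 2, 2))
  conn1 <- connectome(matrix(0, 1, 1), "V1",
                      conn2$centroids[1, , drop = FALSE], 1000)
  sch2 <- stim_schedule("V2", 1.15, 0, 200)
  sch1 <- stim_schedule("V1", 1.15, 0, 200)
  tr2 <- simulate_network(conn2, det, 0.3, schedule = sch2,
                          duration_ms = 200, stabilize_ms = 0)
  # without noise each region reproduces the isolated single-region run
  expect_identical(tr2$E[1, ],
                   simulate_network(conn1, det, 0.3, duration_ms = 200,
                                    stabilize_ms = 0)$E[1, ])
  expect_identical(tr2$E[2, ],
                   simulate_network(conn1, det, 0.3, schedule = sch1,
                                    duration_ms = 200,
                                    stabilize_ms = 0)$E[1, ])

  p <- wc_params()
  tr2 <- simulate_network(conn2, p, 0.3, duration_ms = 200, seed = 11,
                          stabilize_ms = 0)
  rerun <- simulate_network(conn2, p, 0.3, duration_ms = 200, seed = 11,
                            stabilize_ms = 0)
  expect_identical(rerun$E, tr2$E)
  other <- simulate_network(conn2, p, 0.3, duration_ms = 200, seed = 12,
                            stabilize_ms = 0)
  expect_false(identical(other$E, tr2$E))
})

test_that("the deterministic integrator converges at second order", {
  conn <- toy_connectome(matrix(0, 1, 1))
  sch <- stim_schedule("V1", 1.15, 0, 50)
  end_state <- function(h) {
    p <- wc_params(sigma = 0, step_h = h)
    tr <- simulate_network(conn, p, 0, schedule = sch, duration_ms = 50,
                           stabilize_ms = 0)
    tr$E[1, length(tr$time_ms)]
  }
  ref <- end_state(0.003125)
  e1 <- abs(end_state(0.1) - ref)
  e2 <- abs(end_state(0.05) - ref)
  expect_gt(log2(e1 / e2), 1.8)
})

test_that("traces stay within the sigmoid-bounded band", {
  p <- wc_params()
  conn <- generate_connectome(cohort_spec(n_subjects = 1, n_regions = 16,
                                          seed = 9), 1)
  tr <- simulate_network(conn, p, 0.2, duration_ms = 500, seed = 2,
                         stabilize_ms = 500)
  expect_true(all(tr$E > -1e-3 & tr$E < p$S_E_max + 1e-3))
  expect_true(all(tr$I > -1e-3 & tr$I < p$S_I_max + 1e-3))
})

test_that("divergence is reported with the offending step", {
  p <- wc_params(sigma = 3)  # absurd noise forces the blow-up guard
  conn <- toy_connectome(matrix(0, 1, 1))
  expect_error(simulate_network(conn, p, 0, duration_ms = 100, seed = 1,
                                stabilize_ms = 0),
               "diverged at step")
})

test_that("stimulus schedules validate their intervals and targets", {
  expect_error(stim_schedule("V1", 1.15, 100, 100))
  conn <- toy_connectome(matrix(0, 2, 2))
  sch <- stim_schedule("V9", 1.15, 0, 100)
  expect_error(simulate_network(conn, wc_params(), 0, schedule = sch,
                                duration_ms = 200, seed = 1), "V9")
  both <- c(stim_schedule("V1", 1, 0, 50), stim_schedule("V2", 2, 50, 100))
  expect_s3_class(both, "stim_schedule")
  expect_length(unclass(both), 2)
})
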