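make_trace <- function(X, step_h = 1) {
  # wrap a samples x regions matrix as a trace segment (1 ms grid)
  structure(
    list(time_ms = (seq_len(nrow(X)) - 1) * step_h, E = t(X),
         I = t(X) * 0, labels = paste0("V", seq_len(ncol(X))),
         step_h = step_h, c5 = 0, seed = NULL, schedule = NULL),
    class = "sim_trace"
  )
}

test_that("maximum-lag FC recovers identical and lag-shifted signals", {
  t <- seq(0, 0.999, by = 0.001)
  x <- sin(2 * pi * 5 * t)                 # 5 Hz, 1 ms sampling
  X <- cbind(x, x)
  fc <- functional_connectivity(make_trace(X), window_ms = 999,
                                max_lag_ms = 250)
  expect_equal(fc[1, 2], 1)

  y <- sin(2 * pi * 5 * (t - 0.1))         # 100 ms lag, within range
  fc2 <- functional_connectivity(make_trace(cbind(x, y)), window_ms = 999,
                                 max_lag_ms = 250)
  expect_gt(fc2[1, 2], 1 - 1e-6)
})

test_that("FC equals the exhaustive-lag brute-force oracle", {
  set.seed(8)
  X <- matrix(rnorm(300 * 3), 300, 3)
  X[, 3] <- 0.4                            # constant signal: undefined pairs
  fc <- functional_connectivity(make_trace(X), window_ms = 300,
                                max_lag_ms = 50)
  ref <- fc_brute(X, 50)
  expect_equal(unclass(fc), ref, ignore_attr = TRUE)
  expect_true(all(is.na(fc[3, ])))
  # the max over lags is positively biased above the lag-0 correlation
  expect_gte(fc[1, 2], cor(X[, 1], X[, 2]))
  # symmetry and bounds on defined entries
  expect_identical(fc[1, 2], fc[2, 1])
  expect_true(all(abs(fc[1:2, 1:2]) <= 1))
})

test_that("FC complains when the window exceeds the segment", {
  X <- matrix(rnorm(100 * 2), 100, 2)
  expect_error(functional_connectivity(make_trace(X), window_ms = 500,
                                       max_lag_ms = 10), "longer than")
})

test_that("functional effects average the requested pair scopes", {
  z <- matrix(0, 4, 4)
  rownames(z) <- colnames(z) <- paste0("V", 1:4)
  circ <- region_set("c", c("V1", "V2"))
  expect_equal(functional_effect(z, "global"), 0)
  expect_equal(functional_effect(z, circ), 0)
  o <- z + 1; diag(o) <- 0
  expect_equal(functional_effect(o, "global"), 1)
  expect_equal(functional_effect(o, circ), 1)
  expect_equal(functional_effect(o, "outside", circuit = circ), 1)

  set.seed(3)
  m <- matrix(rnorm(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("V", 1:6)
  c3 <- region_set("c", c("V1", "V2", "V3"))
  expect_equal(functional_effect(m, c3),
               mean(c(m[1, 2], m[1, 3], m[2, 3])))
  expect_equal(functional_effect(m, "outside", circuit = c3),
               mean(c(m[4, 5], m[4, 6], m[5, 6])))
  # cross pairs belong to neither restricted scope: perturbing them only
  # moves the global average
  m2 <- m; m2[1, 4] <- m2[4, 1] <- 99
  expect_equal(functional_effect(m2, c3), functional_effect(m, c3))
  expect_equal(functional_effect(m2, "outside", circuit = c3),
               functional_effect(m, "outside", circuit = c3))
  expect_false(functional_effect(m2, "global") ==
                 functional_effect(m, "global"))

  expect_error(functional_effect(m, region_set("s", "V1")), "2 regions")
})

test_that("regional variability maps normalize sd by the mean", {
  mk_fc <- function(v) {
    # 3-region FC with region 1's off-diagonal mean equal to v
    m <- matrix(c(1, v, v, v, 1, v, v, v, 1), 3, 3)
    rownames(m) <- colnames(m) <- paste0("V", 1:3)
    m
  }
  fcv <- fc_variability(list(mk_fc(0.2), mk_fc(0.4)))
  expect_equal(unname(fcv[1]), sd(c(0.2, 0.4)) / 0.3, tolerance = 1e-12)
  expect_true(all(fc_variability(list(mk_fc(0.3), mk_fc(0.3))) == 0))
  expect_error(fc_variability(list(mk_fc(0.2))), "2 subjects")

  tr1 <- make_trace(matrix(rep(c(0.1, 0.5, 0), each = 10), 10, 3))
  tr2 <- make_trace(matrix(rep(c(0.3, 0.5, 0), each = 10), 10, 3))
  fv <- functional_variability(list(tr1, tr2))
  expect_equal(unname(fv[1]), sqrt(2) / 2)   # sd({0.1,0.3})/0.2
  expect_equal(unname(fv[2]), 0)
  expect_true(is.na(fv[3]))                  # silent region is flagged
})

test_that("stimulation drives the target into a limit cycle", {
  spec <- cohort_spec(n_subjects = 1, n_regions = 16, seed = 31)
  conn <- generate_connectome(spec, 1)
  tgt <- region_set("seed", conn$labels[1], conn)
  ex <- run_stimulation_experiment(conn, wc_params(), c5T = 0.1, tgt,
                                   seed = 4, grid_step = 0.005)
  expect_equal(ex$c5, 0.095)
  ptp <- function(tr, i) diff(range(tr$E[i, ]))
  expect_gt(ptp(ex$during, 1), ptp(ex$pre, 1))
  expect_error(run_stimulation_experiment(conn, wc_params(), 0.1,
                                          region_set("x", "Z9"), 1),
               "Z9")
})

test_that("null stimulation and causally unreachable regions show no effect", {
  p <- wc_params()
  conn <- two_block_connectome(k = 5, w = 20)
  all_regions <- region_set("all", conn$labels, conn)
  effects <- vapply(1:5, function(s) {
    ex <- run_stimulation_experiment(conn, p, c5T = 0.1, all_regions,
                                     seed = s, amplitude = 0,
                                     grid_step = 0.005)
    functional_effect(delta_fc(ex), "global")
  }, numeric(1))
  expect_true(all(abs(effects) < 0.05))

  # stimulate only component 1; component 2 pairs must stay at null level
  comp1 <- region_set("c1", conn$labels[1:5], conn)
  comp2 <- region_set("c2", conn$labels[6:10], conn)
  d2 <- vapply(1:3, function(s) {
    ex <- run_stimulation_experiment(conn, p, c5T = 0.1, comp1,
                                     seed = 10 + s, grid_step = 0.005)
    functional_effect(delta_fc(ex), comp2)
  }, numeric(1))
  expect_true(all(abs(d2) < 0.05))
})
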