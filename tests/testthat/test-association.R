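test_that("bootstrapped Pearson reproduces exact correlations", {
  res <- pearson_bootstrap(c(1, 2, 3), c(2, 4, 6), n_boot = 200, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)

  neg <- pearson_bootstrap(1:4, -(1:4), n_boot = 200, seed = 1)
  expect_equal(neg$r, -1)

  mid <- pearson_bootstrap(c(1, 2, 3, 4), c(1, 3, 2, 4), n_boot = 500,
                           seed = 2)
  expect_equal(mid$r, 0.8)
  expect_true(mid$ci_low <= mid$r && mid$r <= mid$ci_high)

  expect_error(pearson_bootstrap(rep(1, 5), rnorm(5)), "zero-variance")
  expect_identical(pearson_bootstrap(1:5, c(2, 1, 4, 3, 5), seed = 7,
                                     n_boot = 100),
                   pearson_bootstrap(1:5, c(2, 1, 4, 3, 5), seed = 7,
                                     n_boot = 100))
})

test_that("the p-value comes from the standard Pearson t reference", {
  set.seed(21)
  x <- rnorm(10); y <- rnorm(10)
  res <- pearson_bootstrap(x, y, n_boot = 50, seed = 1)
  expect_equal(res$p, cor.test(x, y)$p.value)
})

test_that("FDR across tasks follows Benjamini-Hochberg", {
  all3 <- fdr_across_tasks(c(0.001, 0.02, 0.04))
  expect_true(all(all3$significant))
  none <- fdr_across_tasks(c(0.5, 0.6, 0.7))
  expect_false(any(none$significant))
  one <- fdr_across_tasks(c(0.01, 0.5, 0.9))
  expect_equal(one$p_adjusted, c(0.03, 0.75, 0.9))
  expect_equal(one$significant, c(TRUE, FALSE, FALSE))

  set.seed(9)
  for (k in 1:1000) {
    p <- runif(sample(2:8, 1))
    got <- fdr_across_tasks(p)
    # agreement to machine rounding (the two implementations order the
    # multiplications differently), and identical discovery sets
    expect_equal(got$p_adjusted, bh_brute(p), tolerance = 1e-14)
    expect_identical(got$significant, bh_brute(p) < 0.05)
  }
})

test_that("grouped FDR corrects each feature/condition family separately", {
  res <- data.frame(
    feature = rep(c("c5T", "degree"), each = 3),
    task = rep(c("VG", "SC", "NR"), 2),
    condition = "before",
    p = c(0.01, 0.5, 0.9, 0.001, 0.02, 0.04))
  out <- fdr_across_tasks(res)
  expect_equal(out$p_adjusted[out$feature == "c5T"], c(0.03, 0.75, 0.9))
  expect_true(all(out$fdr_significant[out$feature == "degree"]))
})

test_that("the random-subnetwork null is calibrated under independence", {
  set.seed(14)
  n_sub <- 10; n_reg <- 20
  deltas <- lapply(1:n_sub, function(i) {
    m <- matrix(rnorm(n_reg^2, 0, 0.2), n_reg, n_reg)
    m <- (m + t(m)) / 2; diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("V", 1:n_reg)
    m
  })
  rt <- rnorm(n_sub, 600, 20)  # independent of the matrices
  null <- random_subnetwork_null(deltas, rt, circuit_size = 6, n_draws = 500,
                                 seed = 3)
  expect_lt(null$fraction_significant, 0.10)
  expect_equal(nrow(null$draws), 500)

  # full-size draws collapse to the global scope: no sampling variability
  g <- random_subnetwork_null(deltas, rt, circuit_size = n_reg, n_draws = 20,
                              seed = 3)
  expect_equal(length(unique(round(g$draws$r, 12))), 1)
  glob <- mean(sapply(deltas, function(d) mean(d[upper.tri(d)])))
  ct <- cor.test(sapply(deltas, function(d) mean(d[upper.tri(d)])), rt)
  expect_equal(g$fraction_significant,
               as.numeric(ct$estimate > 0.5 && ct$p.value < 0.05))

  expect_error(random_subnetwork_null(deltas, rt, circuit_size = 6,
                                      n_draws = 0), "n_draws")
  expect_error(random_subnetwork_null(deltas, rt, circuit_size = 1,
                                      n_draws = 5), "circuit_size")

  # overlap bookkeeping against a known circuit
  circ <- region_set("c", paste0("V", 1:5))
  o <- random_subnetwork_null(deltas, rt, circuit_size = 10, n_draws = 50,
                              true_circuit = circ, seed = 1)
  expect_true(all(o$draws$overlap >= 0 & o$draws$overlap <= 1))
})

test_that("contiguous site enumeration matches brute force", {
  # five collinear regions with nearest-neighbour adjacency form a chain
  cents <- cbind(seq(0, 80, by = 20), 0, 0)
  A <- matrix(1, 5, 5); diag(A) <- 0
  conn <- connectome(A, paste0("V", 1:5), cents, rep(1000, 5))
  circ <- region_set("c", conn$labels, conn)
  sites2 <- enumerate_sites(conn, circ, site_size = 2, k = 1)
  expect_length(sites2, 4)
  expect_setequal(vapply(sites2, function(s) paste(sort(s$labels),
                                                   collapse = "-"),
                         character(1)),
                  c("V1-V2", "V2-V3", "V3-V4", "V4-V5"))

  ones <- enumerate_sites(conn, circ, site_size = 1, k = 1)
  expect_length(ones, 5)
  expect_error(enumerate_sites(conn, circ, site_size = 6), "exceeds")

  # random geometry: compare against igraph-verified exhaustive enumeration
  set.seed(33)
  cents2 <- matrix(runif(30, 0, 100), 10, 3)
  conn2 <- connectome(matrix(1, 10, 10) - diag(10), paste0("V", 1:10),
                      cents2, rep(1000, 10))
  circ2 <- region_set("c", conn2$labels, conn2)
  adj <- conndyn:::knn_adjacency(cents2, 3)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  combos <- utils::combn(10, 4)
  ref <- apply(combos, 2, function(idx)
    igraph::is_connected(igraph::induced_subgraph(g, idx)))
  got <- enumerate_sites(conn2, circ2, site_size = 4, k = 3,
                         max_sites = 10000)
  expect_length(got, sum(ref))
  got_keys <- sort(vapply(got, function(s) paste(sort(s$labels),
                                                 collapse = "-"),
                          character(1)))
  ref_keys <- sort(apply(combos[, ref, drop = FALSE], 2, function(idx)
    paste(sort(paste0("V", idx)), collapse = "-")))
  expect_identical(got_keys, ref_keys)
})
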