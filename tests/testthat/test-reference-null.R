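test_that("bucket assignment follows the absolute degree-difference rule", {
  # seeds with degree 4 ("hub") and 1 ("leaf"); v with degree 2 is forced
  # to the leaf's bucket (|2-1| < |2-4|)
  ed <- data.frame(a = c("H", "H", "H", "H", "V", "L"),
                   b = c("x1", "x2", "x3", "V", "x4", "x1"))
  net <- ppi_network(ed)
  expect_equal(unname(igraph::degree(net)[c("H", "L", "V")]), c(4, 1, 2))
  set.seed(1)
  part <- partition_buckets(net, seed_set(c("H", "L")))
  expect_true("V" %in% part$L)

  # single seed: one bucket holding all of V
  part1 <- partition_buckets(net, seed_set("H"))
  expect_setequal(part1$H, igraph::V(net)$name)

  # exact tie |6-10| = |6-2|: assignment is a fair coin
  ed2 <- data.frame(
    a = c(rep("A", 10), rep("B", 2), rep("V", 6)),
    b = c(sprintf("a%d", 1:10), sprintf("b%d", 1:2), sprintf("a%d", 1:6)))
  net2 <- ppi_network(ed2)
  expect_equal(unname(igraph::degree(net2)[c("A", "B", "V")]), c(10, 2, 6))
  set.seed(2)
  inA <- replicate(1000, "V" %in% partition_buckets(net2, seed_set(c("A", "B")))$A)
  expect_gt(mean(inA), 0.44)   # ~3.8 sigma band around 0.5 at 1000 draws
  expect_lt(mean(inA), 0.56)
})

test_that("bucket partitions cover all nodes with disjoint buckets", {
  set.seed(11)
  for (i in 1:5) {
    net <- random_network(60, 100)
    seeds <- seed_set(sample(igraph::V(net)$name, 6))
    part <- partition_buckets(net, seeds)
    members <- unlist(part, use.names = FALSE)
    expect_equal(sort(members), sort(igraph::V(net)$name))  # cover, disjoint
    expect_true(all(lengths(part) >= 1))
    # each seed sits in its own bucket under the anchored default
    for (u in seeds$ids) expect_true(u %in% part[[u]])
  }
})

test_that("null seed sets draw one member per bucket, uniformly", {
  part <- structure(list(u1 = "a", u2 = "b"), class = "bucket_partition")
  expect_equal(sample_null_seed_set(part), c("a", "b"))

  part4 <- structure(list(u1 = c("a", "b", "c", "d"), u2 = "z"),
                     class = "bucket_partition")
  expect_length(sample_null_seed_set(part4), 2)
  set.seed(3)
  draws <- replicate(10000, sample_null_seed_set(part4)[1])
  tab <- table(factor(draws, levels = c("a", "b", "c", "d")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)  # uniform within bucket

  empty <- structure(list(u1 = character(0)), class = "bucket_partition")
  expect_error(sample_null_seed_set(empty), "empty bucket")
})

test_that("calibration is reproducible and degenerates to zero variance with singleton buckets", {
  net <- path_network(c("A", "B", "C"))
  # seeds = all nodes: every bucket is a singleton, so every null seed set
  # is identical and sigma must vanish everywhere
  cal <- calibrate_null(net, seed_set(c("A", "B", "C")), n = 2, rng_seed = 1)
  expect_equal(unname(cal$sigma), c(0, 0, 0))
  expect_equal(cal$n_effective, 2)

  bench <- generate_benchmark(tiny_config())
  c1 <- calibrate_null(bench$network, bench$seeds, n = 50, rng_seed = 77)
  c2 <- calibrate_null(bench$network, bench$seeds, n = 50, rng_seed = 77)
  expect_identical(c1$mu, c2$mu)
  expect_identical(c1$sigma, c2$sigma)
})

test_that("bucket null reduces to uniform seed sampling on a regular graph", {
  # On a cycle all degrees are equal, so (marginally over tie-break
  # partitions) drawing one node per bucket is uniform sampling of seed
  # sets; compare Monte Carlo means against an independent uniform oracle.
  n <- 12
  cyc <- ppi_network(data.frame(a = sprintf("n%02d", 1:n),
                                b = sprintf("n%02d", c(2:n, 1))))
  seeds <- seed_set(c("n01", "n05", "n09"))
  draw_marginal <- function() {
    repeat {
      p <- partition_buckets(cyc, seeds, anchor_seeds = FALSE)
      if (all(lengths(p) > 0)) return(sample_null_seed_set(p))
    }
  }
  set.seed(2)
  mu_bucket <- rowMeans(replicate(4000,
    compute_crosstalk(cyc, seed_set(draw_marginal()))$alpha))
  set.seed(3)
  nodes <- igraph::V(cyc)$name
  mu_unif <- rowMeans(replicate(4000,
    compute_crosstalk(cyc, seed_set(sample(nodes, 3)))$alpha))
  expect_lt(max(abs(mu_bucket - mu_unif[names(mu_bucket)])), 0.012)
  expect_equal(mean(mu_bucket), 1 / n, tolerance = 1e-9)
})

test_that("score adjustment standardizes against the null", {
  fake_cal <- structure(list(mu = c(A = 0.3, B = 0.2, C = 0.1),
                             sigma = c(A = 0.1, B = 0, C = 0),
                             n = 10L, n_effective = 10L, rng_seed = 1L),
                        class = "null_calibration")
  sc <- adjust_scores(c(A = 0.5, B = 0.4, C = 0.1), fake_cal)
  expect_equal(unname(sc$z["A"]), 2.0)
  expect_equal(unname(sc$z["B"]), Inf)     # sigma 0, alpha > mu
  expect_equal(unname(sc$z["C"]), 0)       # sigma 0, alpha == mu
  expect_equal(sc$n_degenerate, 2)

  sc0 <- adjust_scores(c(A = 0.3, B = 0.1, C = 0.1), fake_cal)
  expect_equal(unname(sc0$z["A"]), 0)      # alpha == mu
  expect_equal(unname(sc0$z["B"]), -Inf)

  expect_error(adjust_scores(c(A = 1, Q = 0), fake_cal), "different node sets")
})

test_that("protein labels follow the crosstalker/interactor rules", {
  # star: S = {A}; D is two hops away (via B) so not a seed neighbor
  ed <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "D"))
  net <- ppi_network(ed)
  seeds <- seed_set("A")
  mk <- function(z, z_star = 3.45) {
    structure(list(z = z, alpha = z, mu = z * 0, sigma = z * 0 + 1,
                   z_star = z_star, n_degenerate = 0L),
              class = "adjusted_scores")
  }
  z <- c(A = 0.5, B = 1.0, C = 0.2, D = 4.0)
  lab <- label_proteins(mk(z), net, seeds)
  expect_equal(unname(lab["D"]), "crosstalker")  # significant without adjacency
  expect_equal(unname(lab["B"]), "interactor")
  expect_equal(unname(lab["C"]), "interactor")
  expect_equal(unname(lab["A"]), "other")        # seed itself, not significant

  # z* = +Inf: nobody is a crosstalker; z* = -Inf: everyone scored is
  lab_hi <- label_proteins(mk(z, z_star = Inf), net, seeds)
  expect_false(any(lab_hi == "crosstalker"))
  lab_lo <- label_proteins(mk(z, z_star = -Inf), net, seeds)
  expect_true(all(lab_lo == "crosstalker"))
})

test_that("null seed sets match the real seed set's total degree", {
  bench <- generate_benchmark(tiny_config(rng_seed = 5))
  deg <- igraph::degree(bench$network)
  true_total <- sum(deg[bench$seeds$ids])
  set.seed(9)
  part <- partition_buckets(bench$network, bench$seeds)
  totals <- replicate(1000, sum(deg[sample_null_seed_set(part)]))
  expect_lt(abs(mean(totals) - true_total) / true_total, 0.10)
})
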