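mk_data <- function(mat, labels) {
  expression_dataset(mat, labels)
}

test_that("row normalization centers and scales with the sample convention", {
  m <- matrix(c(1, 3), nrow = 1, dimnames = list("g1", NULL))
  norm <- normalize_expression(m)
  expect_equal(as.numeric(norm), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  m2 <- rbind(g1 = c(1, 3, 5), g2 = c(2, 2, 2))
  expect_warning(n2 <- normalize_expression(m2), "constant")
  expect_equal(rownames(n2), "g1")

  # idempotence
  expect_equal(normalize_expression(norm), norm, tolerance = 1e-12)
  expect_error(normalize_expression(matrix(1, 1, 1)), "2 samples")
})

test_that("aggregate profiles follow the sqrt-size scaling", {
  mat <- rbind(g1 = c(1, -1), g2 = c(1, -1), g3 = c(-1, 1))
  d <- mk_data(mat, c(0, 1))
  expect_equal(as.numeric(aggregate_profile(c("g1", "g2"), d)),
               c(sqrt(2), -sqrt(2)))
  # singleton passthrough
  expect_equal(as.numeric(aggregate_profile("g1", d)), c(1, -1))
  # anti-correlated members cancel
  expect_equal(as.numeric(aggregate_profile(c("g1", "g3"), d)), c(0, 0))
  # unmeasured members dropped with warning; effective set attached
  expect_warning(p <- aggregate_profile(c("g1", "gX"), d), "not measured")
  expect_equal(attr(p, "members_used"), "g1")
  expect_error(aggregate_profile("gX", d), "no member")
})

test_that("equal-width quantization spans the observed range", {
  expect_equal(quantize_profile(0:5, k = 6), 1:6)
  expect_equal(suppressWarnings(quantize_profile(rep(2.5, 4), k = 6)), rep(1L, 4))
  expect_equal(quantize_profile(c(0, 0.49, 0.51, 1), k = 2), c(1L, 1L, 2L, 2L))
  # the maximum lands in the last (closed) bin
  expect_equal(max(quantize_profile(runif(50), k = 6)), 6L)
  expect_warning(quantize_profile(c(0, 1), k = 6), "coarse")
})

test_that("plug-in mutual information matches brute-force joint counting", {
  expect_equal(mutual_information(c(1, 1, 2, 2), c(0, 0, 1, 1)), 1.0)
  expect_equal(mutual_information(c(1, 2, 1, 2), c(0, 0, 1, 1)), 0.0)
  expect_equal(mutual_information(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.0)
  expect_error(mutual_information(1:3, 1:4), "equal length")

  # exhaustive cross-check against the independent oracle at small m
  for (m in 2:4) {
    xs <- as.matrix(expand.grid(rep(list(1:2), m)))
    cs <- as.matrix(expand.grid(rep(list(0:1), m)))
    for (i in seq_len(nrow(xs))) {
      for (j in seq_len(nrow(cs))) {
        expect_equal(mutual_information(xs[i, ], cs[j, ]),
                     mi_oracle(xs[i, ], cs[j, ]), tolerance = 1e-12)
      }
    }
  }
})

test_that("synergy score is invariant to relabeling and joint permutation", {
  set.seed(21)
  x <- sample(1:4, 30, replace = TRUE)
  y <- rbinom(30, 1, 0.5)
  base <- mutual_information(x, y)
  expect_equal(mutual_information(5 - x, y), base)      # bin relabeling
  expect_equal(mutual_information(x, 1 - y), base)      # class relabeling
  perm <- sample(30)
  expect_equal(mutual_information(x[perm], y[perm]), base)

  # phi(Q) invariance under joint sample permutation
  bench <- generate_benchmark(tiny_config(rng_seed = 8))
  d <- suppressWarnings(normalize_expression(bench$data))
  Q <- bench$truth[1:4]
  phi0 <- as.numeric(synergy_score(Q, d))
  perm <- sample(ncol(d$expr))
  d2 <- d
  d2$expr <- d$expr[, perm]
  d2$labels <- d$labels[perm]
  expect_equal(as.numeric(synergy_score(Q, d2)), phi0)

  # adding a pure-noise gene can never push phi above H(c)
  hc <- mutual_information(d$labels, d$labels)
  for (extra in setdiff(rownames(d$expr), bench$truth)[1:5]) {
    expect_lte(as.numeric(synergy_score(c(bench$truth[1], extra), d)), hc)
  }
})

test_that("star null drops infeasible sizes, is reproducible, and its bias shrinks with sample size", {
  # network with max degree 3: size 4 must be dropped
  net <- ppi_network(data.frame(p = c("h", "h", "h"), q = c("a", "b", "c")))
  mat <- matrix(rnorm(4 * 12), 4, 12, dimnames = list(c("h", "a", "b", "c"), NULL))
  d <- normalize_expression(mk_data(mat, rep(c(0, 1), each = 6)))
  expect_warning(nl <- star_null_distribution(net, d, sizes = c(2, 4), n = 50,
                                              rng_seed = 1),
                 "degree >= 4")
  expect_equal(nl$table$size, 2)

  bench <- generate_benchmark(tiny_config(rng_seed = 13))
  dn <- suppressWarnings(normalize_expression(bench$data))
  n1 <- suppressWarnings(star_null_distribution(bench$network, dn, n = 100, rng_seed = 5))
  n2 <- suppressWarnings(star_null_distribution(bench$network, dn, n = 100, rng_seed = 5))
  expect_identical(n1$table, n2$table)

  # label-independent expression: the null mean reflects plug-in MI bias,
  # which decreases with the number of samples
  null_bench <- function(m_per_class, seed) {
    cfg <- synthetic_config(n_nodes = 150, module_size = 10, n_seeds = 10,
                            effect_delta = 0, n_per_class = m_per_class,
                            rng_seed = seed)
    b <- generate_benchmark(cfg)
    dd <- suppressWarnings(normalize_expression(b$data))
    suppressWarnings(star_null_distribution(b$network, dd, sizes = c(2, 4),
                                            n = 300, rng_seed = seed))
  }
  small_m <- null_bench(10, 31)   # 20 samples
  large_m <- null_bench(100, 32)  # 200 samples
  expect_gt(mean(small_m$table$mean), mean(large_m$table$mean))
  expect_gt(min(small_m$table$mean), 0)
})

test_that("null interpolation is piecewise linear with flagged extrapolation", {
  nl <- structure(list(table = data.frame(size = c(2, 4, 8),
                                          mean = c(0.10, 0.20, 0.30),
                                          sd = c(0.05, 0.10, 0.20),
                                          n_used = 100),
                       k = 6L, n = 100L, rng_seed = 1L),
                  class = "size_null")
  expect_equal(interpolated_null(nl, 3)$mean, 0.15)
  expect_equal(interpolated_null(nl, 8)$mean, 0.30)  # sampled size: exact
  expect_false(interpolated_null(nl, 8)$extrapolated)
  ext <- interpolated_null(nl, 16)
  expect_true(ext$extrapolated)
  expect_equal(ext$mean, 0.30 + (0.30 - 0.20) / 4 * 8)  # last segment slope
  expect_error(interpolated_null(nl, 1), "at least 2")
})

test_that("synergy assessment applies the one-sigma rule and skips tiny candidates", {
  nl <- structure(list(table = data.frame(size = c(2, 4), mean = c(0.2, 0.2),
                                          sd = c(0.1, 0.1), n_used = 100),
                       k = 6L, n = 100L, rng_seed = 1L),
                  class = "size_null")
  mat <- rbind(g1 = c(rep(-1, 6), rep(1, 6)) + rnorm(12, sd = 0.05),
               g2 = c(rep(-1, 6), rep(1, 6)) + rnorm(12, sd = 0.05),
               g3 = rnorm(12))
  d <- normalize_expression(mk_data(mat, rep(c(0, 1), each = 6)))

  strong <- structure(list(seed = "u", kind = "crosstalker",
                           members = c("g1", "g2"), size = 2L, scorable = TRUE),
                      class = "candidate_subnetwork")
  a <- assess_synergy(strong, d, nl)
  expect_false(a$skipped)
  expect_equal(a$phi >= a$null_mean + a$null_sd, a$significant)
  expect_true(a$significant)   # two clean separators: phi ~ H(c) = 1

  # members unmeasured in the dataset: skip record with reason
  ghost <- structure(list(seed = "u", kind = "crosstalker",
                          members = c("zz", "g1"), size = 2L, scorable = TRUE),
                     class = "candidate_subnetwork")
  s <- assess_synergy(ghost, d, nl)
  expect_true(s$skipped)
  expect_match(s$reason, "need >= 2")
  expect_true(is.na(s$significant))

  tab <- synergy_table(list(a, s))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$skipped, c(FALSE, TRUE))
})

test_that("individual gene scores behave at the extremes", {
  set.seed(17)
  m <- 500
  labels <- rep(c(0L, 1L), each = m / 2)
  mat <- rbind(sep = ifelse(labels == 1, 1, -1),          # perfect separator
               noise = rnorm(m))                          # independent of class
  d <- normalize_expression(mk_data(mat, labels))
  mi <- score_individual_genes(d)
  expect_equal(unname(mi["sep"]), 1.0)                    # H(c) = 1 bit
  expect_lt(unname(mi["noise"]), 0.05)
})
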