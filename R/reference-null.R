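# Degree-matched Monte Carlo reference model for crosstalk scores.
#
# Proteomic seed sets are biased toward well-connected, well-studied
# proteins, and raw RWR scores are inflated for network hubs.  The
# reference model corrects for both: null seed sets are drawn to match
# the real seed set in size and degree distribution, the walk is re-run
# for each, and every protein's raw score is standardized against its
# own null mean and standard deviation.

#' Partition network nodes into degree-matched buckets
#'
#' Every node `v` is assigned to the bucket of the seed `u` minimizing
#' the absolute degree difference `|deg(v) - deg(u)|`; ties are broken
#' uniformly at random.  Buckets are disjoint and cover all of `V`, so
#' drawing one node per bucket produces a random seed set matching the
#' real one in size and (approximately) total degree.
#'
#' @param network a `ppi_network`.
#' @param seeds a mapped [seed_set()].
#' @param anchor_seeds keep each seed in its own bucket instead of
#'   letting a random tie-break move it elsewhere.  A seed always
#'   attains the minimal degree difference (0) to itself, so anchoring
#'   only resolves ties - but it guarantees every bucket is nonempty
#'   even when several seeds share a degree that few other nodes have.
#'   Set to `FALSE` for the fully exchangeable tie-breaking rule (under
#'   which buckets can come out empty).
#' @return object of class `bucket_partition`: a named list, one
#'   character vector of member node IDs per seed.  Uses the R random
#'   number generator for tie-breaking; call `set.seed()` beforehand for
#'   reproducibility.
#' @export
partition_buckets <- function(network, seeds, anchor_seeds = TRUE) {
  network <- as_ppi_network(network)
  if (!length(seeds$ids)) stop("empty seed set", call. = FALSE)
  deg <- igraph::degree(network)
  if (!all(seeds$ids %in% names(deg))) {
    stop("seed set contains IDs absent from the network", call. = FALSE)
  }
  # |V| x |S| absolute degree differences; random argmin per row
  D <- abs(outer(as.numeric(deg), as.numeric(deg[seeds$ids]), "-"))
  pick <- max.col(-D, ties.method = "random")
  if (anchor_seeds) {
    pick[match(seeds$ids, names(deg))] <- seq_along(seeds$ids)
  }
  buckets <- split(names(deg), factor(seeds$ids[pick], levels = seeds$ids))
  structure(buckets, class = "bucket_partition")
}

#' @export
print.bucket_partition <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("Bucket partition: %d buckets covering %d nodes (sizes %d-%d)\n",
              length(x), sum(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' Draw one degree-matched null seed set
#'
#' Chooses exactly one node uniformly at random from each bucket, so the
#' null set has the same cardinality as the real seed set and each real
#' seed is represented by a node of similar degree.
#'
#' @param partition a [partition_buckets()] result.
#' @return character vector of node IDs, one per bucket.
#' @export
sample_null_seed_set <- function(partition) {
  stopifnot(inherits(partition, "bucket_partition"))
  if (any(lengths(partition) == 0L)) {
    stop("empty bucket: a seed cannot be represented in the null", call. = FALSE)
  }
  vapply(partition, function(b) b[[sample.int(length(b), 1L)]], character(1L),
         USE.NAMES = FALSE)
}

#' Calibrate the null distribution of crosstalk scores
#'
#' Draws `n` degree-matched null seed sets, reruns the random walk for
#' each (with a uniform restart vector over the null set, regardless of
#' how the real run weights its seeds), and records the per-protein mean
#' `mu_S(v)` and standard deviation `sigma_S(v)` (n-1 denominator) of
#' the null score distribution.  All `n` walks share one transition
#' matrix and are iterated as a single batched fixed-point computation.
#'
#' @param network a `ppi_network`.
#' @param seeds a mapped [seed_set()].
#' @param cfg an [rwr_config()]; `use_seed_weights` is ignored for the
#'   null (null restarts are always uniform).
#' @param n number of Monte Carlo replicates (default 1000).
#' @param rng_seed optional integer; when given, `set.seed()` is called
#'   so bucket tie-breaks and null draws are reproducible.
#' @return object of class `null_calibration`: list with `mu`, `sigma`
#'   (named numeric over nodes), `n`, `n_effective` (replicates that
#'   converged), `rng_seed`, and the `bucket_partition` used.
#' @export
calibrate_null <- function(network, seeds, cfg = rwr_config(), n = 1000L,
                           rng_seed = NULL) {
  network <- as_ppi_network(network)
  stopifnot(inherits(cfg, "rwr_config"), n >= 2L)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  partition <- partition_buckets(network, seeds)

  nodes <- igraph::V(network)$name
  nv <- length(nodes)
  ns <- length(seeds$ids)
  Rho <- matrix(0, nrow = nv, ncol = n, dimnames = list(nodes, NULL))
  for (i in seq_len(n)) {
    s_i <- sample_null_seed_set(partition)
    Rho[match(s_i, nodes), i] <- 1 / ns
  }

  P <- build_transition_matrix(network, cfg$use_edge_weights)
  dangling <- attr(P, "dangling")
  fit <- rwr_iterate(P, Rho, cfg$restart, cfg$tol, cfg$max_iter, dangling)
  keep <- fit$converged
  if (!all(keep)) {
    warning(sprintf("%d of %d null replicates did not converge and were excluded",
                    sum(!keep), n), call. = FALSE)
  }
  A <- fit$X[, keep, drop = FALSE]
  ne <- ncol(A)
  if (ne < 2L) stop("fewer than 2 converged null replicates", call. = FALSE)
  mu <- rowMeans(A)
  sigma <- sqrt(rowSums((A - mu)^2) / (ne - 1L))
  structure(list(mu = stats::setNames(mu, nodes),
                 sigma = stats::setNames(sigma, nodes),
                 n = as.integer(n), n_effective = as.integer(ne),
                 rng_seed = rng_seed, partition = partition),
            class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf("Null calibration: %d/%d converged replicates over %d proteins\n",
              x$n_effective, x$n, length(x$mu)))
  invisible(x)
}

#' Adjust crosstalk scores against the null calibration
#'
#' Standardizes each protein's raw score: `z_S(v) = (alpha(v) -
#' mu_S(v)) / sigma_S(v)`.  Where `sigma_S(v) = 0` the z-score is set to
#' `+Inf` if `alpha(v) > mu_S(v)`, `-Inf` if below, and 0 if equal; the
#' number of such degenerate nodes is reported in `n_degenerate`.
#'
#' @param alpha a `crosstalk_result` (or named numeric score vector).
#' @param calibration a [calibrate_null()] result over the same node set.
#' @param z_star significance cutoff for crosstalkers; the default 3.45
#'   corresponds to a p-value of 0.001 under a normal approximation of
#'   the null score distribution.
#' @return object of class `adjusted_scores`: list with named vectors
#'   `z`, `alpha`, `mu`, `sigma`, plus `z_star` and `n_degenerate`.
#' @export
adjust_scores <- function(alpha, calibration, z_star = 3.45) {
  if (inherits(alpha, "crosstalk_result")) alpha <- alpha$alpha
  stopifnot(inherits(calibration, "null_calibration"), is.numeric(z_star))
  if (is.null(names(alpha)) || !setequal(names(alpha), names(calibration$mu))) {
    stop("score vector and calibration cover different node sets", call. = FALSE)
  }
  alpha <- alpha[names(calibration$mu)]
  mu <- calibration$mu
  sigma <- calibration$sigma
  z <- (alpha - mu) / sigma
  deg <- sigma == 0
  if (any(deg)) {
    z[deg] <- sign(alpha[deg] - mu[deg]) * Inf
    z[deg & alpha == mu] <- 0
  }
  structure(list(z = z, alpha = alpha, mu = mu, sigma = sigma,
                 z_star = z_star, n_degenerate = sum(deg)),
            class = "adjusted_scores")
}

#' @export
print.adjusted_scores <- function(x, ...) {
  cat(sprintf("Adjusted crosstalk scores over %d proteins (z* = %.3g): %d above cutoff\n",
              length(x$z), x$z_star, sum(x$z > x$z_star)))
  invisible(x)
}

#' @export
as.data.frame.adjusted_scores <- function(x, ...) {
  data.frame(protein = names(x$z), alpha = as.numeric(x$alpha),
             mu = as.numeric(x$mu), sigma = as.numeric(x$sigma),
             z = as.numeric(x$z), row.names = NULL)
}

#' Label proteins as crosstalkers, interactors, or other
#'
#' A *crosstalker* is any protein whose adjusted score exceeds the
#' cutoff (`z_S(v) > z*`), whether or not it touches a seed.  An
#' *interactor* is a non-significant protein directly interacting with
#' at least one seed.  Everything else is labeled `other`.  Seeds are
#' labeled by the same rules as any other protein.
#'
#' @param scores an [adjust_scores()] result.
#' @param network a `ppi_network`.
#' @param seeds a mapped [seed_set()].
#' @return named character vector over network nodes with values
#'   `"crosstalker"`, `"interactor"`, or `"other"`.
#' @export
label_proteins <- function(scores, network, seeds) {
  network <- as_ppi_network(network)
  stopifnot(inherits(scores, "adjusted_scores"))
  nodes <- igraph::V(network)$name
  seed_nb <- unique(unlist(lapply(seeds$ids, function(u) {
    igraph::neighbors(network, u)$name
  })))
  lab <- stats::setNames(rep("other", length(nodes)), nodes)
  lab[intersect(seed_nb, nodes)] <- "interactor"
  lab[names(scores$z)[scores$z > scores$z_star]] <- "crosstalker"
  lab
}

#' Write adjusted scores and labels to TSV
#'
#' Columns: `protein  alpha  mu  sigma  z  label`.
#'
#' @param scores an [adjust_scores()] result.
#' @param labels a [label_proteins()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjusted_scores <- function(scores, labels, path) {
  df <- as.data.frame(scores)
  df$label <- as.character(labels[df$protein])
  df <- df[order(-df$z, df$protein), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
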