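# Network crosstalk via random walk with restart (RWR).
#
# The walk starts at a seed protein; at each step it moves to a random
# interacting partner with probability 1 - r, or restarts at a seed with
# probability r.  The stationary distribution alpha(v) measures each
# protein's proximity and connectivity to the seed set; r = 0 reduces to
# PageRank of the network, r = 1 to the restart distribution itself.

#' Random-walk-with-restart configuration
#'
#' @param restart restart probability `r` in `[0, 1]`.  Default 0.5:
#'   a fairly local walk in which half the probability mass restarts at
#'   the seeds on every step.
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter iteration budget.
#' @param use_edge_weights if `TRUE`, move probabilities are proportional
#'   to interaction reliability weights `w(u, v)` instead of uniform over
#'   neighbors.
#' @param use_seed_weights if `TRUE`, the restart distribution is
#'   proportional to the seeds' fold-change z-scores `z_P(u)` instead of
#'   uniform over the seed set.
#' @return list of class `rwr_config`.
#' @export
rwr_config <- function(restart = 0.5, tol = 1e-10, max_iter = 10000L,
                       use_edge_weights = FALSE, use_seed_weights = FALSE) {
  stopifnot(is.numeric(restart), length(restart) == 1L,
            restart >= 0, restart <= 1,
            is.numeric(tol), tol > 0, max_iter >= 1L)
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter),
                 use_edge_weights = isTRUE(use_edge_weights),
                 use_seed_weights = isTRUE(use_seed_weights)),
            class = "rwr_config")
}

#' Build the restart vector over network nodes
#'
#' Unweighted: `rho(u) = 1/|S|` for seeds, 0 elsewhere.  Weighted:
#' `rho(u) = z_P(u) / sum(z_P)` over the seed set, so seeds with more
#' significant proteomic fold change attract more restarts.
#'
#' @param seeds a [seed_set()]; all seeds must be in the network.
#' @param network a `ppi_network`.
#' @param use_seed_weights use fold-change z-scores as restart weights.
#' @return named numeric vector over all network nodes, summing to 1.
#' @export
build_restart_vector <- function(seeds, network, use_seed_weights = FALSE) {
  network <- as_ppi_network(network)
  nodes <- igraph::V(network)$name
  if (!all(seeds$ids %in% nodes)) {
    stop("seed set contains IDs absent from the network; run map_seed_set() first",
         call. = FALSE)
  }
  rho <- stats::setNames(numeric(length(nodes)), nodes)
  if (use_seed_weights) {
    z <- seeds$fold_z
    if (is.null(z) || !all(seeds$ids %in% names(z))) {
      stop("weighted restart requested but fold-change z-scores are missing for some seeds",
           call. = FALSE)
    }
    z <- z[seeds$ids]
    if (sum(z) <= 0) {
      stop("fold-change z-scores sum to zero; weighted restart undefined", call. = FALSE)
    }
    rho[seeds$ids] <- z / sum(z)
  } else {
    rho[seeds$ids] <- 1 / length(seeds$ids)
  }
  rho
}

#' Build the column-stochastic transition operator
#'
#' `P[u, v]` is the probability of moving to `u` given the walk is at
#' `v`: `1/|N(v)|` for a uniform walk, or `w(u,v) / sum_{u' in N(v)}
#' w(u',v)` when edge weights are used.  Columns of degree-0 nodes are
#' all zero; their indices are attached as the `dangling` attribute (the
#' walk teleports back to the restart distribution from such nodes).
#'
#' @param network a `ppi_network`.
#' @param use_edge_weights normalize by interaction reliability weights.
#' @return a sparse `dgCMatrix` with node names on both margins and a
#'   logical `dangling` attribute marking all-zero columns.
#' @export
build_transition_matrix <- function(network, use_edge_weights = FALSE) {
  network <- as_ppi_network(network)
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE,
                                   attr = if (use_edge_weights) "weight" else NULL)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  cs <- Matrix::colSums(A)
  dangling <- cs == 0
  inv <- ifelse(dangling, 0, 1 / cs)
  P <- A %*% Matrix::Diagonal(x = inv)
  dimnames(P) <- dimnames(A)
  attr(P, "dangling") <- stats::setNames(as.logical(dangling), colnames(A))
  P
}

# Internal fixed-point iteration shared by the single and batch solvers.
# X columns are probability vectors; Rho columns the matching restart
# vectors.  Mass sitting on dangling (degree-0) nodes is redirected to
# the restart vector each step, so every column keeps unit L1 norm.
rwr_iterate <- function(P, Rho, r, tol, max_iter, dangling) {
  X <- Rho
  nv <- nrow(Rho)
  d <- rep(Inf, ncol(Rho))
  for (it in seq_len(max_iter)) {
    leak <- if (any(dangling)) {
      if (ncol(X) == 1L) sum(X[dangling, ]) else colSums(X[dangling, , drop = FALSE])
    } else {
      numeric(ncol(X))
    }
    Xn <- (1 - r) * as.matrix(P %*% X) + Rho * rep((1 - r) * leak + r, each = nv)
    d <- colSums(abs(Xn - X))
    X <- Xn
    if (max(d) < tol) {
      return(list(X = X, iterations = it, converged = rep(TRUE, ncol(X)), delta = d))
    }
  }
  list(X = X, iterations = max_iter, converged = d < tol, delta = d)
}

#' Compute crosstalk scores by random walk with restart
#'
#' Iterates `alpha_{t+1} = (1 - r) P alpha_t + r rho` from `alpha_0 =
#' rho` until the L1 change drops below `cfg$tol`.  Probability mass on
#' degree-0 nodes is teleported back to `rho` each step, so the iterate
#' stays a probability vector throughout.  Nodes in components containing
#' no seed end with `alpha = 0`; their count is reported via the
#' `n_unreachable` field.
#'
#' @param network a `ppi_network`.
#' @param seeds a mapped [seed_set()].
#' @param cfg an [rwr_config()].
#' @return object of class `crosstalk_result`: list with `alpha` (named
#'   scores summing to 1), `iterations`, `converged`, `n_unreachable`.
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' res <- compute_crosstalk(net, seed_set("A"))
#' res$alpha  # (7/12, 1/3, 1/12) for A, B, C at r = 0.5
#' @export
compute_crosstalk <- function(network, seeds, cfg = rwr_config()) {
  network <- as_ppi_network(network)
  stopifnot(inherits(cfg, "rwr_config"))
  rho <- build_restart_vector(seeds, network, cfg$use_seed_weights)
  P <- build_transition_matrix(network, cfg$use_edge_weights)
  dangling <- attr(P, "dangling")
  fit <- rwr_iterate(P, matrix(rho, ncol = 1L), cfg$restart, cfg$tol,
                     cfg$max_iter, dangling)
  if (!all(fit$converged)) {
    warning(sprintf("random walk did not converge within %d iterations (L1 change %.3g)",
                    cfg$max_iter, max(fit$delta)), call. = FALSE)
  }
  alpha <- stats::setNames(as.numeric(fit$X), names(rho))
  structure(list(alpha = alpha,
                 iterations = fit$iterations,
                 converged = all(fit$converged),
                 n_unreachable = sum(alpha == 0)),
            class = "crosstalk_result")
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat(sprintf("Crosstalk scores over %d proteins (%d iterations, %sconverged)\n",
              length(x$alpha), x$iterations, if (x$converged) "" else "NOT "))
  top <- sort(x$alpha, decreasing = TRUE)[seq_len(min(5L, length(x$alpha)))]
  cat("  top:", paste(sprintf("%s=%.4g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Exact crosstalk solve (dense linear-system oracle)
#'
#' Solves the fixed point directly: `alpha = r (I - (1 - r) P')^{-1} rho`
#' where `P'` is the transition operator with dangling columns replaced
#' by the restart distribution (the same teleport rule the iterative
#' solver applies).  Intended as an independent check of
#' [compute_crosstalk()] on small networks; guarded to 2000 nodes.
#'
#' @param network a `ppi_network` with at most 2000 nodes.
#' @param seeds a mapped [seed_set()].
#' @param r restart probability in `(0, 1]`; `r = 0` makes the system
#'   singular and is rejected in favor of the iterative path.
#' @param use_edge_weights,use_seed_weights as in [rwr_config()].
#' @return a `crosstalk_result` with `iterations = NA`.
#' @export
solve_crosstalk_exact <- function(network, seeds, r = 0.5,
                                  use_edge_weights = FALSE,
                                  use_seed_weights = FALSE) {
  network <- as_ppi_network(network)
  nv <- igraph::vcount(network)
  if (nv > 2000L) {
    stop("dense solve guarded to networks of at most 2000 nodes", call. = FALSE)
  }
  if (r <= 0 || r > 1) {
    stop("exact solve requires 0 < r <= 1; use compute_crosstalk() for r = 0",
         call. = FALSE)
  }
  rho <- build_restart_vector(seeds, network, use_seed_weights)
  P <- build_transition_matrix(network, use_edge_weights)
  dangling <- attr(P, "dangling")
  Pd <- as.matrix(P)
  if (any(dangling)) Pd[, dangling] <- rho   # teleport from dangling nodes
  alpha <- solve(diag(nv) - (1 - r) * Pd, r * rho)
  alpha <- pmax(alpha, 0)
  alpha <- alpha / sum(alpha)
  structure(list(alpha = stats::setNames(as.numeric(alpha), names(rho)),
                 iterations = NA_integer_, converged = TRUE,
                 n_unreachable = sum(alpha == 0)),
            class = "crosstalk_result")
}

#' Write crosstalk scores to TSV
#'
#' @param result a `crosstalk_result`.
#' @param path output path (`protein  alpha`, sorted by score descending).
#' @return `path`, invisibly.
#' @export
write_crosstalk <- function(result, path) {
  stopifnot(inherits(result, "crosstalk_result"))
  a <- sort(result$alpha, decreasing = TRUE)
  df <- data.frame(protein = names(a), alpha = as.numeric(a))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
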