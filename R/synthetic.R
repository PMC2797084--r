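# Synthetic benchmark generator with known ground truth.
#
# Emulates the shape of the real inputs: a scale-free interactome with a
# planted densely connected "hotspot" module, a seed set drawn from the
# module and its neighborhood (mimicking proteomic hits that sit in or
# near disease hotspots), and class-conditional expression in which the
# planted module's genes carry a mean shift between phenotype classes.

#' Configuration for the synthetic benchmark
#'
#' Defaults define the package's standard benchmark conditions: a
#' 500-node scale-free network (2 edges per new node), a planted module
#' of 20 nodes wired at density 0.5, a class mean shift of 1.5 against
#' unit noise, 20 samples per class, and 30 seeds drawn 70/30 from the
#' module and its direct neighborhood.
#'
#' @param n_nodes network size.
#' @param attach_m edges added per new node during preferential
#'   attachment.
#' @param module_size number of planted-module nodes.
#' @param module_density probability of each within-module edge
#'   (clipped to 1 with a warning if larger).
#' @param effect_delta class mean shift added to planted-module genes in
#'   disease samples (in units of the noise standard deviation when
#'   `noise_sigma = 1`).
#' @param noise_sigma standard deviation of the Gaussian expression
#'   noise (> 0).
#' @param n_per_class samples per phenotype class (>= 2).
#' @param n_seeds number of seed proteins.
#' @param seed_truth_ratio fraction of seeds drawn from the planted
#'   module (the rest come from its direct neighbors).
#' @param rng_seed integer seed fixing the whole benchmark.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 500L, attach_m = 2L, module_size = 20L,
                             module_density = 0.5, effect_delta = 1.5,
                             noise_sigma = 1, n_per_class = 20L, n_seeds = 30L,
                             seed_truth_ratio = 0.7, rng_seed = 1L) {
  stopifnot(n_nodes >= 3L, attach_m >= 1L, module_size >= 2L,
            module_size <= n_nodes, effect_delta >= 0, noise_sigma > 0,
            n_per_class >= 2L, n_seeds >= 1L,
            seed_truth_ratio >= 0, seed_truth_ratio <= 1)
  if (module_density > 1) {
    warning("module_density > 1 clipped to 1 (complete module)", call. = FALSE)
    module_density <- 1
  }
  stopifnot(module_density > 0)
  structure(list(n_nodes = as.integer(n_nodes), attach_m = as.integer(attach_m),
                 module_size = as.integer(module_size),
                 module_density = module_density, effect_delta = effect_delta,
                 noise_sigma = noise_sigma, n_per_class = as.integer(n_per_class),
                 n_seeds = as.integer(n_seeds),
                 seed_truth_ratio = seed_truth_ratio,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

# Internal: preferential-attachment backbone over integer node IDs.
# Starts from 2 unconnected nodes; each new node v attaches min(m, v - 1)
# edges to existing nodes with probability proportional to degree + 1, so
# the edge count is exactly (n - 2) * m whenever m <= 2 (and more
# generally sum_v min(m, v - 1)).
pa_backbone <- function(n, m) {
  deg <- integer(n)
  from <- integer(0)
  to <- integer(0)
  for (v in 3:n) {
    nt <- min(m, v - 1L)
    tgt <- sample.int(v - 1L, nt, prob = deg[seq_len(v - 1L)] + 1)
    from <- c(from, rep.int(v, nt))
    to <- c(to, tgt)
    deg[v] <- deg[v] + nt
    deg[tgt] <- deg[tgt] + 1L
  }
  list(from = from, to = to)
}

#' Generate a scale-free network with a planted dense module
#'
#' Grows a preferential-attachment backbone: two initial nodes, then
#' each new node attaches `attach_m` edges to existing nodes with
#' probability proportional to degree + 1 (so early isolated nodes can
#' still be chosen).  The backbone therefore has exactly
#' `(n_nodes - 2) * attach_m` edges for `attach_m = 2` and a
#' heavy-tailed degree distribution.  A random set of `module_size`
#' nodes is then additionally wired as a dense module: each internal
#' pair is added independently with probability `module_density`.
#'
#' Uses the current RNG state; seed it (or call via
#' [generate_benchmark()]) for reproducibility.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `network` (a `ppi_network`) and `truth` (character
#'   vector of planted-module node IDs).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_nodes
  ids <- sprintf("g%04d", seq_len(n))
  bb <- pa_backbone(n, cfg$attach_m)
  edges <- data.frame(protein_a = ids[bb$from], protein_b = ids[bb$to],
                      stringsAsFactors = FALSE)

  module <- sort(sample.int(n, cfg$module_size))
  pairs <- utils::combn(module, 2L)
  keep <- stats::runif(ncol(pairs)) < cfg$module_density
  if (any(keep)) {
    edges <- rbind(edges,
                   data.frame(protein_a = ids[pairs[1L, keep]],
                              protein_b = ids[pairs[2L, keep]],
                              stringsAsFactors = FALSE))
  }
  list(network = ppi_network(edges), truth = ids[module])
}

#' Generate class-conditional expression for a benchmark network
#'
#' One gene per network node, `2 * n_per_class` samples with balanced
#' 0/1 labels.  Entry for gene `g`, sample `i`:
#' `x = delta * c(i) * [g in truth] + Normal(0, sigma^2)` - i.e. pure
#' Gaussian noise everywhere except the planted-module genes, which gain
#' a mean shift of `effect_delta` in the disease class.
#'
#' @param cfg a [synthetic_config()].
#' @param truth planted-module gene IDs.
#' @param network the benchmark `ppi_network` (defines the gene list).
#' @return an (unnormalized) [expression_dataset()].
#' @export
generate_expression <- function(cfg, truth, network) {
  stopifnot(inherits(cfg, "synthetic_config"))
  network <- as_ppi_network(network)
  genes <- igraph::V(network)$name
  m <- 2L * cfg$n_per_class
  labels <- rep(c(0L, 1L), each = cfg$n_per_class)
  mat <- matrix(stats::rnorm(length(genes) * m, sd = cfg$noise_sigma),
                nrow = length(genes), ncol = m,
                dimnames = list(genes, sprintf("s%03d", seq_len(m))))
  mat[intersect(truth, genes), labels == 1L] <-
    mat[intersect(truth, genes), labels == 1L] + cfg$effect_delta
  expression_dataset(mat, labels)
}

#' Draw a seed set from the planted module's neighborhood
#'
#' Seeds emulate proteomic hits residing in or near the disease hotspot:
#' a `seed_truth_ratio` fraction is drawn from the planted module, the
#' rest from the module's direct neighbors, and every seed receives a
#' synthetic fold-change z-score drawn from `|Normal(3, 1)|` so the
#' weighted-restart code path is exercisable.
#'
#' @param cfg a [synthetic_config()].
#' @param truth planted-module node IDs.
#' @param network the benchmark `ppi_network`.
#' @return a [seed_set()] with fold-change z-scores.
#' @export
generate_seed_set <- function(cfg, truth, network) {
  stopifnot(inherits(cfg, "synthetic_config"))
  network <- as_ppi_network(network)
  nbrs <- setdiff(unique(unlist(lapply(truth, function(u) {
    igraph::neighbors(network, u)$name
  }))), truth)
  n_truth <- min(round(cfg$seed_truth_ratio * cfg$n_seeds), length(truth))
  n_nb <- cfg$n_seeds - n_truth
  if (n_nb > length(nbrs)) {
    stop(sprintf("cannot draw %d seeds from module plus %d neighbors",
                 cfg$n_seeds, length(nbrs)), call. = FALSE)
  }
  ids <- c(sample(truth, n_truth), if (n_nb > 0L) sample(nbrs, n_nb))
  fz <- stats::setNames(abs(stats::rnorm(length(ids), mean = 3, sd = 1)), ids)
  seed_set(ids, fz)
}

#' Generate a full synthetic benchmark
#'
#' Seeds the RNG from `cfg$rng_seed` and produces the network with its
#' planted module, the expression dataset, and the seed set in one
#' reproducible object.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `synthetic_benchmark`: list with `network`,
#'   `data` (unnormalized), `seeds`, `truth`, `config`.
#' @export
generate_benchmark <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$rng_seed)
  net <- generate_network(cfg)
  data <- generate_expression(cfg, net$truth, net$network)
  seeds <- generate_seed_set(cfg, net$truth, net$network)
  structure(list(network = net$network, data = data, seeds = seeds,
                 truth = net$truth, config = cfg),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("Synthetic benchmark: %d-node network, %d-gene planted module, %d seeds, %d samples\n",
              igraph::vcount(x$network), length(x$truth), length(x$seeds$ids),
              ncol(x$data$expr)))
  invisible(x)
}

#' Write a benchmark to canonical TSV files
#'
#' Writes `edges.tsv`, `expr.tsv`, `labels.tsv`, `seeds.txt`,
#' `truth.txt` into a directory, in the dialects the package readers
#' consume.
#'
#' @param benchmark a [generate_benchmark()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "synthetic_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edge_list(benchmark$network, file.path(dir, "edges.tsv"))
  expr <- data.frame(gene = rownames(benchmark$data$expr),
                     benchmark$data$expr, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = benchmark$data$sample_ids,
                                class = benchmark$data$labels),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sdf <- data.frame(id = benchmark$seeds$ids,
                    fold_z = as.numeric(benchmark$seeds$fold_z[benchmark$seeds$ids]))
  utils::write.table(sdf, file.path(dir, "seeds.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(benchmark$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}
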