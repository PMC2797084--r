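# Shared fixtures and independent oracles, all built in code.

# A simple path graph A - B - C (- D ...).
path_network <- function(ids = c("A", "B", "C")) {
  ppi_network(data.frame(protein_a = ids[-length(ids)], protein_b = ids[-1]))
}

# Random G(n, m) network as a ppi_network (isolated nodes dropped by
# construction, which is what the readers guarantee too).
random_network <- function(n, m) {
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  ed <- igraph::as_edgelist(g, names = TRUE)
  ppi_network(data.frame(protein_a = ed[, 1], protein_b = ed[, 2]))
}

# Brute-force mutual information oracle (bits): direct sum over the joint
# cells of p(a, b) * log2(p(a, b) / (p(a) p(b))), independent of the
# entropy-decomposition route used by the package.
mi_oracle <- function(x, y) {
  m <- length(x)
  total <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pab <- sum(x == a & y == b) / m
      if (pab > 0) {
        pa <- sum(x == a) / m
        pb <- sum(y == b) / m
        total <- total + pab * log2(pab / (pa * pb))
      }
    }
  }
  total
}

# Small, fast benchmark configuration for unit tests.
tiny_config <- function(rng_seed = 1L) {
  synthetic_config(n_nodes = 150L, module_size = 10L, n_seeds = 10L,
                   n_per_class = 10L, rng_seed = rng_seed)
}

# Hand-built synergy assessment records for classifier tests.
fake_assessment <- function(seed, phi, significant, members = c("gX"),
                            kind = "crosstalker", size = length(members)) {
  structure(list(seed = seed, kind = kind, members = members, size = size,
                 phi = phi, null_mean = 0.1, null_sd = 0.05,
                 significant = significant, skipped = FALSE,
                 reason = NA_character_),
            class = "synergy_assessment")
}
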