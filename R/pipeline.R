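# End-to-end convenience wrapper over the five pipeline stages.

#' Run the full crosstalk -> synergy pipeline
#'
#' Convenience wrapper: computes crosstalk scores for the seed set,
#' calibrates them against the degree-matched Monte Carlo null, builds
#' the per-seed interactor/crosstalker candidates, estimates the
#' star-topology synergy null on the expression dataset, and assesses
#' every candidate.  Each stage is also available as a standalone
#' function for finer control.
#'
#' @param network a `ppi_network`.
#' @param seeds a mapped [seed_set()].
#' @param data an [expression_dataset()]; row-normalized internally if
#'   it is not already.
#' @param cfg an [rwr_config()].
#' @param n_null Monte Carlo replicates for both nulls (default 1000).
#' @param z_star crosstalker cutoff on the adjusted z-score.
#' @param k quantization bins for the synergy score.
#' @param null_sizes star-null sub-network sizes.
#' @param rng_seed integer seed covering both Monte Carlo stages.
#' @return list with components `alpha` (crosstalk result),
#'   `calibration`, `scores` (adjusted), `labels`, `candidates`,
#'   `star_null`, `assessments`, and `data` (the normalized dataset).
#' @export
discover_subnetworks <- function(network, seeds, data, cfg = rwr_config(),
                                 n_null = 1000L, z_star = 3.45, k = 6L,
                                 null_sizes = c(2L, 4L, 8L, 16L, 32L, 64L),
                                 rng_seed = NULL) {
  network <- as_ppi_network(network)
  if (!data$normalized) data <- suppressWarnings(normalize_expression(data))
  alpha <- compute_crosstalk(network, seeds, cfg)
  calibration <- calibrate_null(network, seeds, cfg, n = n_null,
                                rng_seed = rng_seed)
  scores <- adjust_scores(alpha, calibration, z_star = z_star)
  labels <- label_proteins(scores, network, seeds)
  candidates <- build_candidates(network, seeds, scores)
  star_null <- star_null_distribution(network, data, sizes = null_sizes, k = k,
                                      n = n_null,
                                      rng_seed = if (!is.null(rng_seed)) rng_seed + 1L)
  assessments <- assess_candidates(candidates, data, star_null, k = k)
  list(alpha = alpha, calibration = calibration, scores = scores,
       labels = labels, candidates = candidates, star_null = star_null,
       assessments = assessments, data = data)
}
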