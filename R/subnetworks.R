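# Candidate sub-network construction: for each seed u, the interactor
# sub-network is induced by all interacting partners N(u); the
# crosstalker sub-network keeps only partners whose adjusted crosstalk
# score clears the cutoff, N*(u) = { v in N(u) : z_S(v) > z* }.

#' Build per-seed candidate sub-networks
#'
#' Emits exactly two candidates per degree->=1 seed: the interactor
#' sub-network (all neighbors) and the crosstalker sub-network (the
#' neighbors with significant adjusted crosstalk).  The seed itself is
#' excluded from its own candidate by default (candidates are defined
#' over interacting partners).  Empty crosstalker sets are still emitted
#' but flagged unscorable; candidates with fewer than 2 members are kept
#' for bookkeeping but carry `scorable = FALSE` (the synergy null starts
#' at size 2).  Candidates of different seeds may overlap; no global
#' deduplication is performed.
#'
#' @param network a `ppi_network`.
#' @param seeds a mapped [seed_set()].
#' @param scores an [adjust_scores()] result covering all seed neighbors.
#' @param include_seed also place the seed in its own candidate
#'   (default `FALSE`).
#' @return list of `candidate_subnetwork` objects, each with fields
#'   `seed`, `kind` (`"interactor"` or `"crosstalker"`), `members`,
#'   `size`, `scorable`.
#' @export
build_candidates <- function(network, seeds, scores, include_seed = FALSE) {
  network <- as_ppi_network(network)
  stopifnot(inherits(scores, "adjusted_scores"))
  z <- scores$z
  out <- list()
  for (u in seeds$ids) {
    if (!u %in% igraph::V(network)$name || igraph::degree(network, u) == 0L) {
      warning(sprintf("seed '%s' has no interactions; skipped", u), call. = FALSE)
      next
    }
    nb <- igraph::neighbors(network, u)$name
    if (!include_seed) nb <- setdiff(nb, u)
    missing_z <- setdiff(nb, names(z))
    if (length(missing_z)) {
      stop(sprintf("adjusted scores missing for %d neighbor(s) of seed '%s'",
                   length(missing_z), u), call. = FALSE)
    }
    star <- nb[z[nb] > scores$z_star]
    out[[length(out) + 1L]] <- new_candidate(u, "interactor", nb)
    out[[length(out) + 1L]] <- new_candidate(u, "crosstalker", star)
  }
  out
}

new_candidate <- function(seed, kind, members) {
  structure(list(seed = seed, kind = kind,
                 members = as.character(members),
                 size = length(members),
                 scorable = length(members) >= 2L),
            class = "candidate_subnetwork")
}

#' @export
print.candidate_subnetwork <- function(x, ...) {
  cat(sprintf("%s sub-network of seed %s: %d member(s)%s\n", x$kind, x$seed,
              x$size, if (x$scorable) "" else " [unscorable]"))
  invisible(x)
}

#' Tabulate candidate sub-networks
#'
#' @param candidates a [build_candidates()] result.
#' @return data frame with columns `seed`, `kind`, `size`, `scorable`,
#'   `members` (comma-separated).
#' @export
candidates_table <- function(candidates) {
  data.frame(seed = vapply(candidates, `[[`, "", "seed"),
             kind = vapply(candidates, `[[`, "", "kind"),
             size = vapply(candidates, `[[`, 0L, "size"),
             scorable = vapply(candidates, `[[`, TRUE, "scorable"),
             members = vapply(candidates, function(x) paste(x$members, collapse = ","), ""),
             stringsAsFactors = FALSE)
}

#' Write candidate sub-networks to TSV
#'
#' @param candidates a [build_candidates()] result.
#' @param path output path (`seed  kind  size  scorable  members`).
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates_table(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read candidate sub-networks from TSV
#'
#' Inverse of [write_candidates()].
#'
#' @param path path to a candidates TSV.
#' @return list of `candidate_subnetwork` objects.
#' @export
read_candidates <- function(path) {
  df <- read_tsv_strict(path, min_cols = 5L, max_cols = 5L)
  lapply(seq_len(nrow(df)), function(i) {
    members <- strsplit(df$members[i], ",", fixed = TRUE)[[1L]]
    members <- members[nzchar(members)]
    new_candidate(df$seed[i], df$kind[i], members)
  })
}
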