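# Network data model: undirected weighted PPI graph over protein IDs.
# Protein IDs are opaque, case-sensitive strings; no identifier translation
# is attempted here (cross-namespace mapping is the caller's job).

#' Construct a protein-protein interaction network
#'
#' Builds an undirected, weighted PPI network from a table of binary
#' interactions and, optionally, a table of protein complex memberships.
#' Complexes are merged using the *matrix model*: each complex contributes
#' a clique among its members.  Self-loops are dropped, duplicate edges
#' (in either orientation) are collapsed keeping the maximum weight, and
#' complex-derived edges receive weight 1 unless the protein pair already
#' carries a higher-weight binary edge.
#'
#' @param edges data frame whose first two columns are protein IDs
#'   (`protein_a`, `protein_b`); an optional third numeric column gives
#'   the interaction reliability `weight` in `(0, 1]` (default 1).
#' @param complexes optional data frame with columns `complex_id`,
#'   `member`, one row per complex membership.
#' @return An undirected [igraph][igraph::aaa-igraph-package] graph with a
#'   `weight` edge attribute, classed `ppi_network`.  Node membership is
#'   defined by the kept edges, so the network never contains isolated
#'   nodes on construction.
#' @seealso [load_network()] to read the canonical TSV files,
#'   [expand_complex()] for the clique expansion itself.
#' @examples
#' net <- ppi_network(data.frame(a = "A", b = "B"),
#'                    complexes = data.frame(cx = "C1", member = c("A", "B", "C")))
#' igraph::ecount(net)  # A-B, A-C, B-C
#' @export
ppi_network <- function(edges, complexes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    stop("'edges' must be a data frame with at least two columns", call. = FALSE)
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1.0, length(a))
  if (anyNA(a) || anyNA(b) || anyNA(w)) {
    stop("edge table contains missing protein IDs or non-numeric weights",
         call. = FALSE)
  }
  if (any(w <= 0)) {
    stop("edge weights must be strictly positive", call. = FALSE)
  }

  if (!is.null(complexes)) {
    if (!is.data.frame(complexes) || ncol(complexes) < 2L) {
      stop("'complexes' must be a data frame with columns complex_id, member",
           call. = FALSE)
    }
    members <- split(as.character(complexes[[2L]]), as.character(complexes[[1L]]))
    for (m in members) {
      cl <- expand_complex(m)
      if (nrow(cl)) {
        a <- c(a, cl$protein_a)
        b <- c(b, cl$protein_b)
        w <- c(w, rep(1.0, nrow(cl)))
      }
    }
  }

  keep <- a != b                        # drop self-loops
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  if (!length(a)) stop("network has no edges after filtering", call. = FALSE)

  # collapse duplicates on the unordered pair, keeping the maximum weight
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\t")
  wmax <- tapply(w, key, max)
  pair <- strsplit(names(wmax), "\t", fixed = TRUE)
  df <- data.frame(from   = vapply(pair, `[`, "", 1L),
                   to     = vapply(pair, `[`, "", 2L),
                   weight = as.numeric(wmax),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  class(g) <- unique(c("ppi_network", class(g)))
  g
}

#' Expand a protein complex into clique edges
#'
#' The matrix model represents a complex as a clique: every unordered pair
#' of distinct members becomes an edge.
#'
#' @param members character vector of protein IDs (duplicates are removed).
#' @return data frame with columns `protein_a`, `protein_b`, one row per
#'   pair (`choose(n, 2)` rows for `n` unique members).  A complex with
#'   fewer than 2 unique members yields zero rows with a warning.
#' @export
expand_complex <- function(members) {
  members <- unique(as.character(members))
  if (length(members) < 2L) {
    warning("degenerate complex with fewer than 2 unique members; no edges generated",
            call. = FALSE)
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  }
  pr <- utils::combn(members, 2L)
  data.frame(protein_a = pr[1L, ], protein_b = pr[2L, ], stringsAsFactors = FALSE)
}

# Internal: strict TSV reader for the canonical dialect (UTF-8, '#' comment
# lines skipped, header row required, constant column count).  Reports the
# 1-based file line number of the first malformed row.
read_tsv_strict <- function(path, min_cols, max_cols, header = TRUE) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*#", raw) & nzchar(trimws(raw)))
  if (!length(keep)) stop(sprintf("'%s' contains no content rows", path), call. = FALSE)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nc <- length(fields[[1L]])
  if (nc < min_cols || nc > max_cols) {
    stop(sprintf("'%s': line %d has %d column(s), expected between %d and %d",
                 path, keep[1L], nc, min_cols, max_cols), call. = FALSE)
  }
  bad <- which(lengths(fields) != nc)
  if (length(bad)) {
    stop(sprintf("'%s': malformed row at line %d (%d fields, expected %d)",
                 path, keep[bad[1L]], lengths(fields)[bad[1L]], nc), call. = FALSE)
  }
  hdr <- if (header) trimws(fields[[1L]]) else sprintf("V%d", seq_len(nc))
  body <- if (header) fields[-1L] else fields
  lines <- if (header) keep[-1L] else keep
  if (!length(body)) {
    df <- as.data.frame(stats::setNames(replicate(nc, character(0), simplify = FALSE), hdr),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
    names(df) <- hdr
  }
  attr(df, "line_numbers") <- lines
  df
}

#' Read a PPI edge list
#'
#' Canonical dialect: UTF-8 TSV with a header row, columns
#' `protein_a  protein_b  [weight]`; lines starting with `#` are skipped.
#'
#' @param path path to the edge-list file.
#' @return data frame with columns `protein_a`, `protein_b`, `weight`.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_strict(path, min_cols = 2L, max_cols = 3L)
  lines <- attr(df, "line_numbers")
  out <- data.frame(protein_a = df[[1L]], protein_b = df[[2L]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 3L) {
    w <- suppressWarnings(as.numeric(df[[3L]]))
    if (anyNA(w)) {
      stop(sprintf("'%s': non-numeric weight at line %d", path,
                   lines[which(is.na(w))[1L]]), call. = FALSE)
    }
    if (any(w <= 0)) {
      stop(sprintf("'%s': non-positive weight at line %d", path,
                   lines[which(w <= 0)[1L]]), call. = FALSE)
    }
    out$weight <- w
  } else {
    out$weight <- rep(1.0, nrow(out))
  }
  out
}

#' Read a protein-complex membership table
#'
#' TSV with header, columns `complex_id  member`, one row per membership.
#'
#' @param path path to the complex file.
#' @return data frame with columns `complex_id`, `member`.
#' @export
read_complex_table <- function(path) {
  df <- read_tsv_strict(path, min_cols = 2L, max_cols = 2L)
  data.frame(complex_id = df[[1L]], member = df[[2L]], stringsAsFactors = FALSE)
}

#' Load a PPI network from edge-list and complex files
#'
#' Reads the canonical TSV files and assembles the network via
#' [ppi_network()] (matrix-model complex expansion, self-loop removal,
#' duplicate collapse keeping the maximum weight).
#'
#' @param edge_file path to the binary-interaction TSV
#'   (`protein_a  protein_b  [weight]`).
#' @param complex_file optional path to the complex membership TSV
#'   (`complex_id  member`).
#' @return a `ppi_network` object.
#' @export
load_network <- function(edge_file, complex_file = NULL) {
  edges <- read_edge_list(edge_file)
  complexes <- if (!is.null(complex_file)) read_complex_table(complex_file)
  ppi_network(edges, complexes)
}

#' Write a network as a canonical sorted edge list
#'
#' Emits a UTF-8 TSV with header `protein_a  protein_b  weight`, rows
#' sorted lexicographically on the (normalized) protein pair so repeated
#' exports of the same network are byte-identical, and reloading the file
#' with [load_network()] reproduces an identical network.
#'
#' @param network a `ppi_network` (or any named undirected igraph).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  network <- as_ppi_network(network)
  ends <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::E(network)$weight
  lo <- pmin(ends[, 1L], ends[, 2L])
  hi <- pmax(ends[, 1L], ends[, 2L])
  ord <- order(lo, hi)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("protein_a\tprotein_b\tweight", con)
  writeLines(sprintf("%s\t%s\t%s", lo[ord], hi[ord], format(w[ord], digits = 15)), con)
  invisible(path)
}

#' Export a (sub-)network in Pajek format
#'
#' Convenience plumbing for external graph visualization.  When `members`
#' is given, the induced sub-network on those nodes is exported.
#'
#' @param network a `ppi_network`.
#' @param path output `.net` path.
#' @param members optional character vector of node IDs to induce on.
#' @return `path`, invisibly.
#' @export
export_pajek <- function(network, path, members = NULL) {
  network <- as_ppi_network(network)
  g <- if (is.null(members)) network else {
    igraph::induced_subgraph(network, intersect(members, igraph::V(network)$name))
  }
  igraph::write_graph(g, path, format = "pajek")
  invisible(path)
}

# Internal: accept a ppi_network or any named undirected igraph.
as_ppi_network <- function(x) {
  if (!igraph::is_igraph(x)) {
    stop("expected a ppi_network (or named undirected igraph)", call. = FALSE)
  }
  if (igraph::is_directed(x)) stop("network must be undirected", call. = FALSE)
  if (is.null(igraph::V(x)$name)) stop("network nodes must be named", call. = FALSE)
  if (is.null(igraph::E(x)$weight)) igraph::E(x)$weight <- 1.0
  x
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d proteins, %d interactions\n",
              igraph::vcount(x), igraph::ecount(x)))
  w <- igraph::E(x)$weight
  if (length(w) && any(w != 1)) {
    cat(sprintf("  edge weights in [%.3g, %.3g]\n", min(w), max(w)))
  }
  invisible(x)
}

# Seed sets ----------------------------------------------------------------

#' Construct a seed set
#'
#' A seed set holds the ordered list of seed protein IDs `S` and,
#' optionally, a nonnegative fold-change z-score `z_P(u)` per seed, used
#' by the weighted restart vector of the random walk.
#'
#' @param ids character vector of protein IDs (deduplicated, order kept).
#' @param fold_z optional named numeric vector of fold-change z-scores;
#'   names must be a subset of `ids`, values must be `>= 0`.
#' @return an object of class `seed_set` with elements `ids` and `fold_z`.
#' @export
seed_set <- function(ids, fold_z = NULL) {
  ids <- as.character(ids)
  ids <- ids[!duplicated(ids)]
  if (!length(ids)) stop("seed set is empty", call. = FALSE)
  if (!is.null(fold_z)) {
    if (is.null(names(fold_z)) || !all(names(fold_z) %in% ids)) {
      stop("'fold_z' must be named by seed IDs", call. = FALSE)
    }
    if (anyNA(fold_z) || any(fold_z < 0)) {
      stop("fold-change z-scores must be nonnegative and non-missing", call. = FALSE)
    }
    fold_z <- fold_z[intersect(ids, names(fold_z))]
  }
  structure(list(ids = ids, fold_z = fold_z), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("Seed set: %d proteins%s\n", length(x$ids),
              if (is.null(x$fold_z)) "" else " (with fold-change z-scores)"))
  cat(" ", paste(utils::head(x$ids, 8L), collapse = ", "),
      if (length(x$ids) > 8L) ", ...\n" else "\n")
  invisible(x)
}

#' Map raw seed IDs onto a network
#'
#' Restricts a raw seed list to proteins present in the network with at
#' least one interaction, deduplicates while preserving order, and
#' reports the dropped IDs with a warning (mirroring the usual situation
#' where only part of a proteomic hit list maps onto the interactome).
#'
#' @param raw_ids character vector of candidate seed IDs.
#' @param network a `ppi_network`.
#' @param fold_z optional named fold-change z-scores for the raw IDs.
#' @return list with elements `seeds` (a [seed_set()]) and `dropped`
#'   (character vector of unmapped IDs).  All IDs dropping out is an
#'   error: an empty seed set cannot drive the random walk.
#' @export
map_seed_set <- function(raw_ids, network, fold_z = NULL) {
  network <- as_ppi_network(network)
  raw_ids <- as.character(raw_ids)
  if (!length(raw_ids)) stop("no seed IDs supplied", call. = FALSE)
  ids <- raw_ids[!duplicated(raw_ids)]
  deg <- igraph::degree(network)
  present <- ids[ids %in% names(deg) & deg[ids] >= 1L]
  dropped <- setdiff(ids, present)
  if (!length(present)) {
    stop("none of the seed IDs map to a connected network node", call. = FALSE)
  }
  if (length(dropped)) {
    warning(sprintf("%d seed ID(s) not in the network (or isolated) were dropped: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")),
            call. = FALSE)
  }
  fz <- if (!is.null(fold_z)) fold_z[intersect(present, names(fold_z))]
  if (!is.null(fz) && !length(fz)) fz <- NULL
  list(seeds = seed_set(present, fz), dropped = dropped)
}

#' Read a seed list file
#'
#' One protein ID per line; an optional second tab-separated column gives
#' the fold-change z-score.  `#` comment lines are skipped; no header.
#'
#' @param path path to the seed file.
#' @return a [seed_set()].
#' @export
read_seed_list <- function(path) {
  df <- read_tsv_strict(path, min_cols = 1L, max_cols = 2L, header = FALSE)
  ids <- df[[1L]]
  fz <- NULL
  if (ncol(df) >= 2L) {
    z <- suppressWarnings(as.numeric(df[[2L]]))
    if (anyNA(z)) {
      stop(sprintf("'%s': non-numeric fold-change z-score at line %d", path,
                   attr(df, "line_numbers")[which(is.na(z))[1L]]), call. = FALSE)
    }
    fz <- stats::setNames(z, ids)
    fz <- fz[!duplicated(names(fz))]
  }
  seed_set(ids, fz)
}
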