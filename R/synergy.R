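# Synergistic dysregulation of candidate sub-networks.
#
# A candidate's member genes are summed into one aggregate expression
# profile (Chuang-style 1/sqrt(|Q|) scaling), quantized into k bins, and
# scored by the plug-in mutual information phi(Q) between the discretized
# profile and the binary phenotype.  Significance is judged against a
# null of random star sub-networks (a random hub's neighbors) matched in
# size to the candidate.

#' Construct an expression dataset
#'
#' @param expr numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns; no missing values.
#' @param labels binary phenotype vector of length `ncol(expr)`
#'   (1 = disease, 0 = control); both classes must be present.
#' @param sample_ids optional sample identifiers (defaults to column
#'   names, or `s1..sm`).
#' @return object of class `expression_dataset` with fields `expr`,
#'   `labels`, `sample_ids`, `normalized`.
#' @export
expression_dataset <- function(expr, labels, sample_ids = NULL) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr) || anyNA(expr)) {
    stop("expression matrix must be numeric with no missing values", call. = FALSE)
  }
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != ncol(expr) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be a 0/1 vector with one entry per sample", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both phenotype classes must be present", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(expr)
    if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(expr)))
  }
  colnames(expr) <- sample_ids
  structure(list(expr = expr, labels = labels, sample_ids = sample_ids,
                 normalized = FALSE),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d samples (%d disease / %d control)%s\n",
              nrow(x$expr), ncol(x$expr), sum(x$labels == 1L), sum(x$labels == 0L),
              if (x$normalized) ", row-normalized" else ""))
  invisible(x)
}

#' Read an expression matrix with phenotype labels
#'
#' Expression TSV: header row, first column the gene ID, remaining
#' columns one per sample.  Labels TSV: header row, columns
#' `sample_id  class` with class in \{0, 1\}.  Samples are matched by ID
#' and reordered to the expression columns.
#'
#' @param expr_file path to the expression TSV.
#' @param label_file path to the labels TSV.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(expr_file, label_file) {
  df <- utils::read.delim(expr_file, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  lab <- read_tsv_strict(label_file, min_cols = 2L, max_cols = 2L)
  cls <- suppressWarnings(as.integer(lab[[2L]]))
  names(cls) <- lab[[1L]]
  missing <- setdiff(colnames(mat), names(cls))
  if (length(missing)) {
    stop(sprintf("no phenotype label for sample(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  expression_dataset(mat, cls[colnames(mat)])
}

#' Row-standardize an expression dataset
#'
#' Transforms every gene row to mean 0 and (sample, n-1 denominator)
#' standard deviation 1 across all samples, classes pooled.  Constant
#' rows carry no phenotype information and are dropped with a warning.
#'
#' @param data an [expression_dataset()] (or bare matrix).
#' @return the same type, normalized; idempotent up to floating point.
#' @export
normalize_expression <- function(data) {
  mat <- if (inherits(data, "expression_dataset")) data$expr else as.matrix(data)
  if (ncol(mat) < 2L) stop("need at least 2 samples to standardize", call. = FALSE)
  sds <- apply(mat, 1L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("dropped %d constant gene row(s)", sum(!keep)), call. = FALSE)
    mat <- mat[keep, , drop = FALSE]
    sds <- sds[keep]
  }
  if (!nrow(mat)) stop("all gene rows are constant", call. = FALSE)
  mat <- (mat - rowMeans(mat)) / sds
  if (inherits(data, "expression_dataset")) {
    data$expr <- mat
    data$normalized <- TRUE
    data
  } else {
    mat
  }
}

#' Aggregate expression profile of a gene set
#'
#' `e(Q)(i) = sum_{v in Q} e(v)(i) / sqrt(|Q|)`: the member rows are
#' summed sample-wise and scaled by the square root of the (effective)
#' set size, so coordinate shifts reinforce while independent noise
#' keeps unit variance.  Members absent from the matrix are dropped with
#' a warning; the effective member set is attached as an attribute.
#'
#' @param members character vector of gene IDs (the set `Q`).
#' @param data an [expression_dataset()], normally row-normalized.
#' @return numeric vector of length `m` with attribute `members_used`.
#' @export
aggregate_profile <- function(members, data) {
  stopifnot(inherits(data, "expression_dataset"))
  members <- unique(as.character(members))
  present <- intersect(members, rownames(data$expr))
  if (!length(present)) {
    stop("no member of the gene set is measured in the dataset", call. = FALSE)
  }
  if (length(present) < length(members)) {
    warning(sprintf("%d of %d member gene(s) not measured; aggregated over %d",
                    length(members) - length(present), length(members),
                    length(present)), call. = FALSE)
  }
  prof <- colSums(data$expr[present, , drop = FALSE]) / sqrt(length(present))
  attr(prof, "members_used") <- present
  prof
}

#' Quantize a profile into equal-width bins
#'
#' Bins span `[min(e), max(e)]`, all intervals right-open except the
#' last.  A constant vector maps entirely to bin 1.
#'
#' @param e numeric vector.
#' @param k number of bins (>= 2).  A warning is issued when the vector
#'   is shorter than `k` (too few samples for stable estimates).
#' @return integer vector of bin indices in `1..k`.
#' @export
quantize_profile <- function(e, k = 6L) {
  stopifnot(is.numeric(e), length(e) >= 1L, k >= 2L)
  if (length(e) < k) {
    warning(sprintf("profile has %d values for %d bins; estimates will be coarse",
                    length(e), k), call. = FALSE)
  }
  rng <- range(e)
  if (rng[1L] == rng[2L]) return(rep(1L, length(e)))
  idx <- floor((e - rng[1L]) / (rng[2L] - rng[1L]) * k) + 1L
  pmin(as.integer(idx), as.integer(k))
}

# Internal: entropy (bits) from a count vector; 0 log 0 == 0.
entropy_counts <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p))
}

#' Mutual information between two discrete vectors
#'
#' Plug-in estimate in bits: `MI = H(x) + H(y) - H(x, y)` with empirical
#' cell probabilities `p(a) = |{i : x(i) = a}| / m`.  Always in
#' `[0, min(H(x), H(y))]`.
#'
#' @param x,y equal-length vectors of discrete values.
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (!length(x)) stop("empty vectors", call. = FALSE)
  hx <- entropy_counts(table(x))
  hy <- entropy_counts(table(y))
  hxy <- entropy_counts(table(x, y))
  max(0, hx + hy - hxy)
}

# Internal fast path: x in 1..k, y in 0/1, via a joint tabulate.
mi_binned <- function(x, y01, k) {
  m <- length(x)
  joint <- tabulate((x - 1L) * 2L + y01 + 1L, nbins = 2L * k)
  hx <- entropy_counts(tabulate(x, nbins = k))
  hy <- entropy_counts(tabulate(y01 + 1L, nbins = 2L))
  max(0, hx + hy - entropy_counts(joint))
}

#' Synergy score of a gene set
#'
#' `phi(Q)`: mutual information (bits) between the quantized aggregate
#' expression profile of `Q` and the phenotype vector.
#'
#' @param members gene IDs.
#' @param data a row-normalized [expression_dataset()].
#' @param k number of quantization bins (default 6).
#' @return `phi` in bits, with attribute `members_used`.
#' @export
synergy_score <- function(members, data, k = 6L) {
  prof <- aggregate_profile(members, data)
  q <- suppressWarnings(quantize_profile(prof, k))
  phi <- mi_binned(q, data$labels, as.integer(k))
  attr(phi, "members_used") <- attr(prof, "members_used")
  phi
}

#' Null distribution of synergy scores from random star sub-networks
#'
#' A candidate sub-network is a star: its members all interact with one
#' protein (the seed).  The matched null therefore draws, for each size
#' `s`, a random hub `v` uniformly from the bag `D = { v : |N(v)| >= s }`
#' and then `s` of its neighbors uniformly at random (the hub itself is
#' not a member), and records the synergy score of each such random
#' star.  Per-size means and standard deviations (n-1 denominator) are
#' interpolated at arbitrary candidate sizes by [interpolated_null()].
#'
#' @param network a `ppi_network`.
#' @param data a row-normalized [expression_dataset()].
#' @param sizes sub-network sizes to sample (default 2, 4, 8, 16, 32,
#'   64).  Sizes exceeding the network's maximum degree are dropped with
#'   a warning.
#' @param k quantization bins.
#' @param n Monte Carlo replicates per size (default 1000).
#' @param rng_seed optional integer seed for reproducibility.
#' @return object of class `size_null`: list with `table` (data frame
#'   `size, mean, sd, n_used`), `k`, `n`, `rng_seed`.
#' @export
star_null_distribution <- function(network, data, sizes = c(2L, 4L, 8L, 16L, 32L, 64L),
                                   k = 6L, n = 1000L, rng_seed = NULL) {
  network <- as_ppi_network(network)
  stopifnot(inherits(data, "expression_dataset"), n >= 2L, all(sizes >= 2L))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sizes <- sort(unique(as.integer(sizes)))
  nodes <- igraph::V(network)$name
  deg <- as.integer(igraph::degree(network))
  adj <- lapply(igraph::as_adj_list(network), as.integer)
  row_of <- match(nodes, rownames(data$expr))
  expr <- data$expr
  labels <- data$labels
  k <- as.integer(k)

  rows <- list()
  for (s in sizes) {
    bag <- which(deg >= s)
    if (!length(bag)) {
      warning(sprintf("no node has degree >= %d; size dropped from the null", s),
              call. = FALSE)
      next
    }
    phis <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      v <- bag[[sample.int(length(bag), 1L)]]
      nb <- adj[[v]]
      Q <- nb[sample.int(length(nb), s)]
      r <- row_of[Q]
      r <- r[!is.na(r)]
      if (length(r) < 2L) next
      prof <- colSums(expr[r, , drop = FALSE]) / sqrt(length(r))
      q <- quantize_profile(prof, k)
      phis[i] <- mi_binned(q, labels, k)
    }
    phis <- phis[!is.na(phis)]
    if (length(phis) < 2L) {
      warning(sprintf("size %d: fewer than 2 scorable null draws; size dropped", s),
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(size = s, mean = mean(phis),
                                            sd = stats::sd(phis),
                                            n_used = length(phis))
  }
  if (!length(rows)) stop("all requested null sizes were dropped", call. = FALSE)
  structure(list(table = do.call(rbind, rows), k = k, n = as.integer(n),
                 rng_seed = rng_seed),
            class = "size_null")
}

#' @export
print.size_null <- function(x, ...) {
  cat(sprintf("Star-null synergy distribution (%d replicates/size, k = %d bins):\n",
              x$n, x$k))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Interpolate the star null at an arbitrary sub-network size
#'
#' Piecewise-linear interpolation of the per-size null mean and standard
#' deviation.  Sizes beyond the largest sampled size are extrapolated
#' with the last segment's slope and flagged; sizes below 2 are
#' rejected.
#'
#' @param null a [star_null_distribution()] result.
#' @param size candidate sub-network size (>= 2).
#' @return list with `mean`, `sd`, `extrapolated`.
#' @export
interpolated_null <- function(null, size) {
  stopifnot(inherits(null, "size_null"))
  if (size < 2) stop("sub-network size must be at least 2", call. = FALSE)
  tb <- null$table
  interp <- function(y) {
    if (nrow(tb) == 1L) return(y[1L])
    if (size <= tb$size[1L]) {
      s <- (y[2L] - y[1L]) / (tb$size[2L] - tb$size[1L])
      return(y[1L] + s * (size - tb$size[1L]))
    }
    nlast <- nrow(tb)
    if (size >= tb$size[nlast]) {
      s <- (y[nlast] - y[nlast - 1L]) / (tb$size[nlast] - tb$size[nlast - 1L])
      return(y[nlast] + s * (size - tb$size[nlast]))
    }
    stats::approx(tb$size, y, xout = size)$y
  }
  list(mean = interp(tb$mean), sd = max(0, interp(tb$sd)),
       extrapolated = size > max(tb$size) || size < min(tb$size))
}

#' Assess the synergistic dysregulation of a candidate sub-network
#'
#' Computes `phi(Q)` on the candidate's effective member set (members
#' measured in the dataset) and compares it with the size-interpolated
#' star null: the candidate is *significant* when `phi >= null mean +
#' 1 x null sd`.  Candidates whose effective size is below 2 are
#' returned as skip records with a reason.
#'
#' @param candidate a `candidate_subnetwork`.
#' @param data a row-normalized [expression_dataset()].
#' @param null a [star_null_distribution()] result on the same dataset.
#' @param k quantization bins (should match the null's `k`).
#' @return object of class `synergy_assessment`: list with `seed`,
#'   `kind`, `members`, `size` (effective), `phi`, `null_mean`,
#'   `null_sd`, `significant`, `skipped`, `reason`.
#' @export
assess_synergy <- function(candidate, data, null, k = 6L) {
  stopifnot(inherits(candidate, "candidate_subnetwork"),
            inherits(null, "size_null"))
  skip <- function(reason) {
    structure(list(seed = candidate$seed, kind = candidate$kind,
                   members = character(0), size = 0L, phi = NA_real_,
                   null_mean = NA_real_, null_sd = NA_real_,
                   significant = NA, skipped = TRUE, reason = reason),
              class = "synergy_assessment")
  }
  effective <- intersect(unique(candidate$members), rownames(data$expr))
  if (length(effective) < 2L) {
    return(skip(sprintf("effective member set has %d gene(s); need >= 2",
                        length(effective))))
  }
  phi <- as.numeric(synergy_score(effective, data, k))
  ref <- interpolated_null(null, length(effective))
  structure(list(seed = candidate$seed, kind = candidate$kind,
                 members = effective, size = length(effective), phi = phi,
                 null_mean = ref$mean, null_sd = ref$sd,
                 significant = phi >= ref$mean + ref$sd,
                 skipped = FALSE, reason = NA_character_),
            class = "synergy_assessment")
}

#' Assess every candidate sub-network
#'
#' @param candidates a [build_candidates()] result.
#' @param data a row-normalized [expression_dataset()].
#' @param null a [star_null_distribution()] result.
#' @param k quantization bins.
#' @return list of `synergy_assessment` objects.
#' @export
assess_candidates <- function(candidates, data, null, k = 6L) {
  lapply(candidates, assess_synergy, data = data, null = null, k = k)
}

#' Tabulate synergy assessments
#'
#' @param assessments a list of `synergy_assessment` objects.
#' @return data frame with one row per candidate (`seed`, `kind`,
#'   `size`, `phi`, `null_mean`, `null_sd`, `significant`, `skipped`).
#' @export
synergy_table <- function(assessments) {
  data.frame(seed = vapply(assessments, `[[`, "", "seed"),
             kind = vapply(assessments, `[[`, "", "kind"),
             size = vapply(assessments, `[[`, 0L, "size"),
             phi = vapply(assessments, `[[`, 0, "phi"),
             null_mean = vapply(assessments, `[[`, 0, "null_mean"),
             null_sd = vapply(assessments, `[[`, 0, "null_sd"),
             significant = vapply(assessments, `[[`, NA, "significant"),
             skipped = vapply(assessments, `[[`, TRUE, "skipped"),
             stringsAsFactors = FALSE)
}

#' Score every gene individually by mutual information with phenotype
#'
#' Singleton version of the synergy score: each gene's (normalized)
#' expression row is quantized and scored by plug-in mutual information
#' with the phenotype.  Useful for comparing the individual differential
#' expression of protein groups (e.g. crosstalkers vs. the whole
#' network) via empirical distribution functions.
#'
#' @param data a row-normalized [expression_dataset()].
#' @param k quantization bins.
#' @return named numeric vector of per-gene MI (bits).
#' @export
score_individual_genes <- function(data, k = 6L) {
  stopifnot(inherits(data, "expression_dataset"))
  k <- as.integer(k)
  labels <- data$labels
  out <- apply(data$expr, 1L, function(row) {
    mi_binned(suppressWarnings(quantize_profile(row, k)), labels, k)
  })
  stats::setNames(as.numeric(out), rownames(data$expr))
}
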