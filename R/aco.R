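# Ant-colony seriation of gene expression profiles. A "gene sequence" is a
# permutation of genes minimizing the total consecutive-pair squared-Euclidean
# distance (open path by default). Repeated runs with derived seeds feed the
# neighbour-frequency statistic used to screen anchor-coherent candidates.

#' Hyperparameters for the ant-system gene ordering
#'
#' Canonical ant-system settings; the literature's defaults are used because
#' the procedure being reproduced specifies none. All knobs are exposed.
#'
#' @param n_ants Number of ants per iteration; `NULL` means one ant per gene.
#' @param alpha Pheromone exponent (>= 0).
#' @param beta Heuristic (inverse-distance) exponent (>= 0).
#' @param rho Pheromone evaporation rate in (0, 1).
#' @param q Pheromone deposit constant (> 0); each ant deposits `q / length`.
#' @param tau0 Initial pheromone level (> 0).
#' @param n_iterations Ant-system iterations per run.
#' @param objective `"open_path"` (a linear gene sequence, the default) or
#'   `"cycle"` (closed tour).
#' @param eps Small constant added to distances in the heuristic term so zero
#'   distances do not divide by zero.
#' @param seed Integer seed for the run (and base seed for repeated runs).
#' @return A validated list of class `aco_params`.
#' @export
aco_params <- function(n_ants = NULL, alpha = 1, beta = 2, rho = 0.5,
                       q = 100, tau0 = 1, n_iterations = 200,
                       objective = c("open_path", "cycle"),
                       eps = 1e-12, seed = 1) {
  objective <- match.arg(objective)
  if (!is.null(n_ants)) check_count(n_ants, "n_ants")
  check_scalar_number(alpha, "alpha", 0, Inf)
  check_scalar_number(beta, "beta", 0, Inf)
  check_scalar_number(rho, "rho", 0, 1, strict_lower = TRUE,
                      strict_upper = TRUE)
  check_scalar_number(q, "q", 0, Inf, strict_lower = TRUE)
  check_scalar_number(tau0, "tau0", 0, Inf, strict_lower = TRUE)
  check_count(n_iterations, "n_iterations")
  check_count(seed, "seed", min = 0L)
  structure(list(n_ants = n_ants, alpha = alpha, beta = beta, rho = rho,
                 q = q, tau0 = tau0, n_iterations = as.integer(n_iterations),
                 objective = objective, eps = eps, seed = as.integer(seed)),
            class = "aco_params")
}

#' Squared-Euclidean distance matrix between gene expression profiles
#'
#' `d[i, j] = sum_s (x[i, s] - x[j, s])^2` over the selected samples. By
#' default each gene's profile is z-scored across the selected samples first,
#' so "similar expression" means similar pattern irrespective of absolute
#' level; set `standardize = FALSE` for raw-scale distances. A constant gene
#' (zero variance) standardizes to the all-zero profile.
#'
#' @param expr Expression matrix, genes x samples.
#' @param genes Genes to include (>= 3).
#' @param samples Samples over which to compute distances (typically the case
#'   group).
#' @param standardize Z-score each profile first (default `TRUE`).
#' @return Symmetric numeric matrix with zero diagonal and gene dimnames.
#' @export
distance_matrix <- function(expr, genes = rownames(expr),
                            samples = colnames(expr), standardize = TRUE) {
  validate_expression(expr)
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g)) stop_invalid("gene(s) not in matrix: ",
                                      paste(missing_g, collapse = ", "))
  missing_s <- setdiff(samples, colnames(expr))
  if (length(missing_s)) stop_invalid("sample(s) not in matrix: ",
                                      paste(missing_s, collapse = ", "))
  if (length(genes) < 3) stop_invalid("need >= 3 genes for seriation")
  if (length(samples) < 2) stop_invalid("need >= 2 samples")
  x <- expr[genes, samples, drop = FALSE]
  if (standardize) {
    mu <- rowMeans(x)
    s <- apply(x, 1, sd)
    s[s == 0] <- 1 # constant profile -> all-zero z-scores
    x <- (x - mu) / s
  }
  d <- as.matrix(stats::dist(x, method = "euclidean"))^2
  dimnames(d) <- list(genes, genes)
  d
}

validate_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop_invalid("distance matrix must be square")
  }
  if (is.null(rownames(d))) stop_invalid("distance matrix needs gene dimnames")
  if (any(!is.finite(d))) stop_invalid("distance matrix has non-finite values")
  if (any(d < 0)) stop_invalid("negative distances")
  if (max(abs(d - t(d))) > 1e-8) stop_invalid("distance matrix not symmetric")
  invisible(d)
}

#' Total distance along a gene ordering
#'
#' Pure-R recomputation of a sequence length: the sum of consecutive-pair
#' distances, plus the closing edge for the cycle objective. Used as the
#' independent check on lengths reported by the optimizer.
#'
#' @param order Character (gene ids) or integer permutation.
#' @param dist Distance matrix.
#' @param objective `"open_path"` or `"cycle"`.
#' @return The path length (numeric scalar).
#' @export
path_length <- function(order, dist, objective = c("open_path", "cycle")) {
  objective <- match.arg(objective)
  validate_dist(dist)
  n <- nrow(dist)
  idx <- if (is.character(order)) match(order, rownames(dist)) else as.integer(order)
  if (anyNA(idx) || length(idx) != n || !setequal(idx, seq_len(n))) {
    stop_invalid("order is not a permutation of the distance matrix genes")
  }
  len <- sum(dist[cbind(idx[-n], idx[-1L])])
  if (objective == "cycle") len <- len + dist[idx[n], idx[1L]]
  len
}

#' Order genes by ant-colony optimization
#'
#' Runs the canonical ant system over a squared-Euclidean gene distance
#' matrix and returns the best-so-far ordering after the configured number of
#' iterations. Deterministic for a fixed `params$seed`.
#'
#' @param dist Distance matrix from [distance_matrix()].
#' @param params An [aco_params()] object.
#' @return A list of class `gene_sequence`: `order` (gene ids), `length`,
#'   `objective`, `seed`, and the per-iteration best-length `trajectory`.
#' @export
aco_order <- function(dist, params = aco_params()) {
  validate_dist(dist)
  stopifnot(inherits(params, "aco_params"))
  n <- nrow(dist)
  n_ants <- if (is.null(params$n_ants)) n else params$n_ants
  res <- .aco_run_cpp(dist, as.integer(n_ants), params$alpha, params$beta,
                      params$rho, params$q, params$tau0,
                      params$n_iterations, params$objective == "cycle",
                      params$eps, as.double(params$seed))
  structure(list(order = rownames(dist)[res$order],
                 length = res$length,
                 objective = params$objective,
                 seed = params$seed,
                 trajectory = res$trajectory),
            class = "gene_sequence")
}

#' @export
print.gene_sequence <- function(x, ...) {
  cat("gene_sequence (", x$objective, "): ", length(x$order),
      " genes, length ", format(x$length, digits = 6), ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); recursion is fine at n <= 10
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Exhaustive optimal gene ordering (test oracle)
#'
#' Enumerates every permutation and returns the global minimum-length
#' ordering under the configured objective, breaking ties by the
#' lexicographically smallest order. Refuses instances with more than 10
#' genes.
#'
#' @inheritParams path_length
#' @param dist Distance matrix.
#' @return A `gene_sequence` with the optimal order and length.
#' @export
brute_force_order <- function(dist, objective = c("open_path", "cycle")) {
  objective <- match.arg(objective)
  validate_dist(dist)
  n <- nrow(dist)
  if (n > 10) stop_invalid("brute force refuses n > 10 (got ", n, ")")
  perms <- all_permutations(n)
  lens <- numeric(nrow(perms))
  for (k in seq_len(n - 1L)) {
    lens <- lens + dist[cbind(perms[, k], perms[, k + 1L])]
  }
  if (objective == "cycle") lens <- lens + dist[cbind(perms[, n], perms[, 1L])]
  best <- which(lens == min(lens))
  if (length(best) > 1) { # lexicographically smallest among ties
    ord <- do.call(order, as.data.frame(perms[best, , drop = FALSE]))
    best <- best[ord[1L]]
  }
  structure(list(order = rownames(dist)[perms[best, ]],
                 length = min(lens),
                 objective = objective,
                 seed = NA_integer_,
                 trajectory = NULL),
            class = "gene_sequence")
}

#' Repeat the ant-colony ordering with derived seeds
#'
#' Runs [aco_order()] `n_runs` times; run `r` uses seed `params$seed + r`, so
#' the whole list is reproducible from one base seed while the runs are
#' independent draws.
#'
#' @param dist Distance matrix.
#' @param params Base [aco_params()].
#' @param n_runs Number of repeated runs (default 10).
#' @return List of `gene_sequence` objects, length `n_runs`.
#' @export
repeated_ordering <- function(dist, params = aco_params(), n_runs = 10) {
  check_count(n_runs, "n_runs")
  lapply(seq_len(n_runs), function(r) {
    p <- params
    p$seed <- params$seed + r
    aco_order(dist, p)
  })
}

#' Count, per gene, the runs in which it lies near the anchor
#'
#' For each gene `g != anchor`, the count is the number of sequences in which
#' `|position(g) - position(anchor)| <= window`. The definition is symmetric
#' in position, hence invariant to reversing any sequence.
#'
#' @param seqs List of `gene_sequence` objects (or bare orderings).
#' @param anchor Anchor gene id; must appear in every sequence.
#' @param window Positional window on each side of the anchor (default 5).
#' @return A data.frame of class `frequency_table`: `gene_id`, `count`; with
#'   attributes `n_runs`, `window`, `anchor`.
#' @export
neighbor_frequency <- function(seqs, anchor, window = 5) {
  check_count(window, "window")
  orders <- lapply(seqs, function(s) if (inherits(s, "gene_sequence")) s$order else s)
  genes <- orders[[1L]]
  counts <- setNames(integer(length(genes)), genes)
  for (ord in orders) {
    a <- match(anchor, ord)
    if (is.na(a)) stop_invalid("anchor '", anchor, "' absent from a sequence")
    pos <- match(names(counts), ord)
    if (anyNA(pos)) stop_invalid("sequences do not share a gene universe")
    counts <- counts + (abs(pos - a) <= window)
  }
  counts <- counts[names(counts) != anchor]
  counts <- counts[order(names(counts))] # canonical row order
  out <- data.frame(gene_id = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_runs") <- length(orders)
  attr(out, "window") <- as.integer(window)
  attr(out, "anchor") <- anchor
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Screen candidate genes by neighbour frequency
#'
#' Retains genes whose count reaches `min_count` (default: at least 5 of 10
#' runs; `strict = TRUE` switches to strictly more than `min_count`), ranked
#' by count descending then gene id.
#'
#' @param freq A `frequency_table` from [neighbor_frequency()].
#' @param min_count Retention threshold.
#' @param strict If `TRUE`, require `count > min_count` instead of `>=`.
#' @return A data.frame (`gene_id`, `count`) of retained genes, ranked.
#' @export
screen_candidates <- function(freq, min_count = 5, strict = FALSE) {
  check_count(min_count, "min_count")
  n_runs <- attr(freq, "n_runs")
  if (!is.null(n_runs) && min_count > n_runs) {
    stop_invalid("min_count = ", min_count, " exceeds n_runs = ", n_runs)
  }
  keep <- if (strict) freq$count > min_count else freq$count >= min_count
  out <- freq[keep, c("gene_id", "count"), drop = FALSE]
  out <- out[order(-out$count, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
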