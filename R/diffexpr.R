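# Dual differential-expression screen: case-vs-control DEGs, anchor-median
# split DEGs within cases, strict-threshold filtering, and set intersection.

#' Per-gene two-group differential expression test
#'
#' Computes, for every gene, the log2 fold change `mean(numerator) -
#' mean(denominator)` and a two-sided p-value. The default test is Welch's
#' unequal-variance t; `method = "moderated"` applies an empirical-Bayes
#' variance shrink towards the median gene-wise pooled variance with
#' `prior_df` prior degrees of freedom, a self-contained approximation of the
#' limma moderated t.
#'
#' Degenerate genes never produce NaN: when both groups are constant and
#' equal the p-value is 1; a zero-variance gene with a nonzero fold change
#' gets the machine-epsilon p-value floor.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param group Character vector over `colnames(expr)` (or a named vector for
#'   a subset of samples) with exactly two distinct labels.
#' @param numerator,denominator The two group labels; log2fc is
#'   numerator minus denominator.
#' @param method `"welch"` (default) or `"moderated"`.
#' @param prior_df Prior degrees of freedom for the moderated mode.
#' @param adjust If `TRUE`, adds a `p_adj` column (Benjamini-Hochberg); the
#'   filtering step still uses raw p-values unless told otherwise.
#' @return A data.frame of class `deg_table`: `gene_id`, `log2fc`, `p_value`,
#'   `direction` (`up`/`down`/`none`), in input gene order.
#' @export
two_group_test <- function(expr, group, numerator = "case",
                           denominator = "control",
                           method = c("welch", "moderated"),
                           prior_df = 4, adjust = FALSE) {
  method <- match.arg(method)
  validate_expression(expr)
  if (!is.null(names(group))) {
    missing_s <- setdiff(names(group), colnames(expr))
    if (length(missing_s)) stop_invalid("unknown sample(s) in group: ",
                                        paste(missing_s, collapse = ", "))
    expr <- expr[, names(group), drop = FALSE]
  } else if (length(group) != ncol(expr)) {
    stop_invalid("group must label every sample (or be a named vector)")
  }
  group <- as.character(group)
  i1 <- which(group == numerator)
  i2 <- which(group == denominator)
  if (length(i1) + length(i2) != length(group)) {
    stop_invalid("group contains labels other than '", numerator, "'/'",
                 denominator, "'")
  }
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) {
    stop_invalid("each group needs >= 2 samples (got ", n1, " '", numerator,
                 "', ", n2, " '", denominator, "')")
  }
  x1 <- expr[, i1, drop = FALSE]
  x2 <- expr[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  lfc <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (pmax(v1 / n1, 0)^2 / (n1 - 1) + pmax(v2 / n2, 0)^2 / (n2 - 1))
    tt <- lfc / sqrt(se2)
    p <- 2 * pt(-abs(tt), df)
  } else {
    d <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    s02 <- median(sp2[sp2 > 0])
    if (!is.finite(s02)) s02 <- 1
    post <- (prior_df * s02 + d * sp2) / (prior_df + d)
    tt <- lfc / sqrt(post * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tt), prior_df + d)
  }
  # degenerate genes: zero pooled variability
  degen <- !is.finite(p)
  if (any(degen)) {
    p[degen] <- ifelse(lfc[degen] == 0, 1, .Machine$double.eps)
  }
  p <- pmin(pmax(p, .Machine$double.eps), 1)

  out <- data.frame(gene_id = rownames(expr), log2fc = unname(lfc),
                    p_value = unname(p),
                    direction = ifelse(lfc > 0, "up",
                                       ifelse(lfc < 0, "down", "none")),
                    stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Filter a DEG table at effect-size and significance thresholds
#'
#' Retains genes with `|log2fc| > lfc_min` and `p < p_max`, both strict
#' inequalities, and partitions them by direction.
#'
#' @param records A `deg_table` from [two_group_test()].
#' @param lfc_min,p_max Strict thresholds (> 0).
#' @param use_adjusted If `TRUE` and a `p_adj` column exists, filter on it.
#' @return A list of class `deg_gene_set` with `genes`, `up`, `down`
#'   (character vectors, input order) and the thresholds used.
#' @export
filter_degs <- function(records, lfc_min = 0.3, p_max = 0.05,
                        use_adjusted = FALSE) {
  check_scalar_number(lfc_min, "lfc_min", 0, Inf, strict_lower = TRUE)
  check_scalar_number(p_max, "p_max", 0, 1, strict_lower = TRUE)
  p <- if (use_adjusted && "p_adj" %in% colnames(records)) {
    records$p_adj
  } else records$p_value
  keep <- abs(records$log2fc) > lfc_min & p < p_max
  out <- list(genes = records$gene_id[keep],
              up = records$gene_id[keep & records$log2fc > 0],
              down = records$gene_id[keep & records$log2fc < 0],
              lfc_min = lfc_min, p_max = p_max)
  class(out) <- "deg_gene_set"
  out
}

#' @export
print.deg_gene_set <- function(x, ...) {
  cat("DEG set: ", length(x$genes), " genes (", length(x$up), " up, ",
      length(x$down), " down) at |log2FC| > ", x$lfc_min, ", p < ", x$p_max,
      "\n", sep = "")
  invisible(x)
}

#' Split samples into high/low groups at the anchor gene's median expression
#'
#' Samples strictly above the median are `high`; samples at or below the
#' median (including exact ties) are `low`, which keeps the rule
#' deterministic.
#'
#' @param expr Expression matrix.
#' @param anchor Anchor gene identifier.
#' @param samples Sample identifiers to split (e.g. the case group).
#' @return Named character vector (`"high"`/`"low"`) over `samples`.
#' @export
median_split <- function(expr, anchor, samples = colnames(expr)) {
  validate_expression(expr)
  if (!anchor %in% rownames(expr)) {
    stop_invalid("anchor gene '", anchor, "' not present in the matrix")
  }
  missing_s <- setdiff(samples, colnames(expr))
  if (length(missing_s)) stop_invalid("unknown sample(s): ",
                                      paste(missing_s, collapse = ", "))
  if (length(samples) < 4) stop_invalid("median split needs >= 4 samples")
  v <- expr[anchor, samples]
  if (max(v) == min(v)) {
    stop_invalid("all anchor values identical; median split undefined")
  }
  med <- median(v)
  out <- ifelse(v > med, "high", "low")
  names(out) <- samples
  out
}

#' Intersect two gene sets, keeping the first set's order
#'
#' @param a,b Character vectors (or `deg_gene_set` objects, whose `genes`
#'   component is used).
#' @return Character vector: elements of `a` also present in `b`.
#' @export
intersect_gene_sets <- function(a, b) {
  if (inherits(a, "deg_gene_set")) a <- a$genes
  if (inherits(b, "deg_gene_set")) b <- b$genes
  a <- unique(as.character(a))
  a[a %in% b]
}

#' Render a DEG table with its filter verdict for writing to disk
#'
#' @param records A `deg_table`.
#' @param gene_set The matching [filter_degs()] result.
#' @return A data.frame with a logical `passed_filter` column appended.
#' @export
deg_report_table <- function(records, gene_set) {
  records$passed_filter <- records$gene_id %in% gene_set$genes
  records
}
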