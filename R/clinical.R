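# Linear association of candidate-gene expression with clinical endpoints
# (MMSE, NFT) and ranking of candidates by fit quality.

#' Simple ordinary-least-squares fit of a clinical score on expression
#'
#' Closed-form OLS of `y ~ x`: slope, intercept, R-squared and the two-sided
#' t-test p-value of the slope with n - 2 degrees of freedom. Pairs with a
#' missing score are dropped (with a message).
#'
#' @param x Expression values.
#' @param y Clinical scores, same length.
#' @param gene_id,endpoint Optional labels carried into the result.
#' @return A list of class `linear_fit`: `gene_id`, `endpoint`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_fit <- function(x, y, gene_id = NA_character_,
                       endpoint = NA_character_) {
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  keep <- is.finite(x) & !is.na(y)
  if (sum(!keep)) message("dropping ", sum(!keep), " pair(s) with missing values")
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_invalid("need >= 3 complete pairs (got ", n, ")")
  if (max(x) == min(x)) stop_invalid("x is constant; slope undefined")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  r2 <- min(max(r2, 0), 1)
  se <- sqrt(sse / (n - 2) / sxx)
  p <- if (se == 0) .Machine$double.eps else 2 * pt(-abs(slope / se), n - 2)
  structure(list(gene_id = gene_id, endpoint = endpoint, slope = slope,
                 intercept = intercept, r_squared = r2,
                 p_value = max(p, .Machine$double.eps), n = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear_fit %s ~ %s: slope %.4g, intercept %.4g, R2 %.3f, p %.3g, n %d\n",
              x$endpoint, x$gene_id, x$slope, x$intercept, x$r_squared,
              x$p_value, x$n))
  invisible(x)
}

#' Rank candidate genes by the quality of their clinical fits
#'
#' Fits each candidate's expression against MMSE and NFT over the selected
#' samples (case samples by default, where the clinical scores are
#' meaningful) and sorts by MMSE R-squared descending, then NFT R-squared,
#' then gene id. The top gene is the candidate "best associated" with the
#' clinical course.
#'
#' @param candidates Character vector of gene ids (non-empty).
#' @param expr Expression matrix.
#' @param phenotype Phenotype data.frame with `sample_id`, `group`, `mmse`
#'   and optionally `nft`.
#' @param samples `"case"` (default) or `"all"`.
#' @return A data.frame of class `fit_ranking`, one row per candidate in rank
#'   order, with slope/R2/p columns per endpoint.
#' @export
rank_by_fit <- function(candidates, expr, phenotype,
                        samples = c("case", "all")) {
  samples <- match.arg(samples)
  if (!length(candidates)) stop_invalid("no candidate genes supplied")
  phenotype <- validate_phenotype(phenotype)
  if (!"mmse" %in% colnames(phenotype)) {
    stop_invalid("phenotype has no MMSE column; clinical ranking impossible")
  }
  ph <- if (samples == "case") phenotype[phenotype$group == "case", ] else phenotype
  ids <- intersect(ph$sample_id, colnames(expr))
  ph <- ph[match(ids, ph$sample_id), ]
  if (sum(!is.na(ph$mmse)) < 3) stop_invalid("fewer than 3 samples with MMSE")
  missing_g <- setdiff(candidates, rownames(expr))
  if (length(missing_g)) stop_invalid("candidate(s) not in matrix: ",
                                      paste(missing_g, collapse = ", "))
  has_nft <- "nft" %in% colnames(ph) && sum(!is.na(ph$nft)) >= 3

  rows <- lapply(candidates, function(g) {
    fm <- linear_fit(expr[g, ids], ph$mmse, gene_id = g, endpoint = "mmse")
    fn <- if (has_nft) {
      linear_fit(expr[g, ids], ph$nft, gene_id = g, endpoint = "nft")
    } else NULL
    data.frame(gene_id = g,
               slope_mmse = fm$slope, r2_mmse = fm$r_squared,
               p_mmse = fm$p_value,
               slope_nft = if (has_nft) fn$slope else NA_real_,
               r2_nft = if (has_nft) fn$r_squared else NA_real_,
               p_nft = if (has_nft) fn$p_value else NA_real_,
               n = fm$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  r2n <- ifelse(is.na(out$r2_nft), -Inf, out$r2_nft)
  out <- out[order(-out$r2_mmse, -r2n, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fit_ranking", "data.frame")
  out
}
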