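# End-to-end orchestration: simulate-or-load, dual DEG screen, ACO
# neighbour-frequency screen, clinical ranking, diagnostic model, report.

#' Configuration of a full screening run
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or the pair
#' `expression_path`/`phenotype_path` must be supplied.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when loading from disk.
#' @param expression_path,phenotype_path TSV inputs, or `NULL` when
#'   simulating.
#' @param anchor Anchor gene identifier.
#' @param lfc_min,p_max DEG filter thresholds (strict inequalities).
#' @param deg_method `"welch"` or `"moderated"`.
#' @param aco Base [aco_params()] for the seriation runs.
#' @param n_runs Number of repeated ACO runs (default 10).
#' @param window Neighbour window around the anchor (default 5 positions each
#'   side).
#' @param min_count Retention threshold on the neighbour frequency (default
#'   5).
#' @param strict_count If `TRUE`, retain only counts strictly above
#'   `min_count`.
#' @param standardize Z-score profiles before the distance computation.
#' @param aco_samples `"case"` (default) or `"all"`: sample scope of the
#'   distance matrix.
#' @param kernel,C Diagnostic classifier settings.
#' @param folds CV folds for the headline AUC (default 10).
#' @param train_fraction Train share of the auxiliary single-split
#'   evaluation (default 0.6).
#' @param outdir Output directory for tables and the JSON report, or `NULL`
#'   to skip writing.
#' @param seed Global seed; per-stage seeds are derived at fixed offsets.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            expression_path = NULL,
                            phenotype_path = NULL,
                            anchor = "METTL3",
                            lfc_min = 0.3, p_max = 0.05,
                            deg_method = c("welch", "moderated"),
                            aco = aco_params(),
                            n_runs = 10, window = 5, min_count = 5,
                            strict_count = FALSE,
                            standardize = TRUE,
                            aco_samples = c("case", "all"),
                            kernel = c("rbf", "linear"), C = 1,
                            folds = 10, train_fraction = 0.6,
                            outdir = NULL, seed = 1) {
  cfg <- list(synthetic = synthetic,
              expression_path = expression_path,
              phenotype_path = phenotype_path,
              anchor = as.character(anchor),
              lfc_min = lfc_min, p_max = p_max,
              deg_method = match.arg(deg_method),
              aco = aco, n_runs = n_runs, window = window,
              min_count = min_count, strict_count = isTRUE(strict_count),
              standardize = isTRUE(standardize),
              aco_samples = match.arg(aco_samples),
              kernel = match.arg(kernel), C = C,
              folds = folds, train_fraction = train_fraction,
              outdir = outdir, seed = check_count(seed, "seed", min = 0L))
  class(cfg) <- "pipeline_config"
  findings <- validate_config(cfg)
  if (length(findings)) {
    stop_invalid("invalid pipeline config:\n  - ",
                 paste(findings, collapse = "\n  - "))
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or plain list with the same fields).
#' @return Character vector of findings; empty when the config is valid.
#' @export
validate_config <- function(config) {
  findings <- character(0)
  has_syn <- !is.null(config$synthetic)
  has_paths <- !is.null(config$expression_path) ||
    !is.null(config$phenotype_path)
  if (has_syn && has_paths) {
    findings <- c(findings,
                  "supply either a synthetic config or input paths, not both")
  }
  if (!has_syn && !has_paths) {
    findings <- c(findings, "no input: synthetic config and paths both absent")
  }
  if (has_paths && (is.null(config$expression_path) ||
                    is.null(config$phenotype_path))) {
    findings <- c(findings,
                  "both expression_path and phenotype_path are required")
  }
  if (has_syn) {
    ok <- tryCatch({validate_synthetic_config(config$synthetic); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) findings <- c(findings, ok)
    if (isTRUE(ok) && config$synthetic$anchor_name != config$anchor) {
      findings <- c(findings, "synthetic anchor_name differs from anchor")
    }
  }
  if (!inherits(config$aco, "aco_params")) {
    findings <- c(findings, "aco must be an aco_params() object")
  }
  for (nm in c("n_runs", "window", "min_count", "folds")) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != as.integer(v)) {
      findings <- c(findings, paste0(nm, " must be a positive integer"))
    }
  }
  if (is.numeric(config$min_count) && is.numeric(config$n_runs) &&
      length(config$min_count) == 1 && length(config$n_runs) == 1 &&
      config$min_count > config$n_runs) {
    findings <- c(findings, "min_count cannot exceed n_runs")
  }
  findings
}

#' Run the full anchor-coherence screening pipeline
#'
#' Stages: (1) simulate or load the expression matrix and phenotype; (2)
#' case-vs-control DEGs; (3) anchor-median-split DEGs within cases; (4)
#' filter both at `|log2fc| > lfc_min`, `p < p_max` and intersect; (5) ACO
#' seriation of the intersection genes (plus the anchor) over case samples,
#' repeated `n_runs` times, neighbour-frequency screen at `min_count`; (6)
#' rank the screened candidates by clinical fit (when MMSE is available) and
#' choose the top gene; (7) train/evaluate the two-gene diagnostic classifier
#' (stratified k-fold CV AUC, 60/40 split AUC, empirical anchor threshold).
#' An empty intersection or candidate set completes the run with explicit
#' empty-result flags instead of failing.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`; see [write_report()] for the on-disk
#'   layout.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # stage 1: data
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- syn$seed + seed # fan the global seed into the generator
    sim <- synthetic_dataset(syn)
    expr <- sim$expression
    pheno <- sim$phenotype
    truth <- sim$truth
  } else {
    expr <- read_expression(config$expression_path)
    pheno <- read_phenotype(config$phenotype_path)
    truth <- NULL
  }
  expr <- expr[, pheno$sample_id, drop = FALSE]
  if (!config$anchor %in% rownames(expr)) {
    stop_invalid("stage diffexpr: anchor '", config$anchor,
                 "' absent from the expression matrix")
  }
  case_ids <- pheno$sample_id[pheno$group == "case"]

  # stage 2-3: dual DEG screen
  grp <- setNames(pheno$group, pheno$sample_id)
  deg_all <- two_group_test(expr, grp, method = config$deg_method)
  split_lab <- median_split(expr, config$anchor, case_ids)
  deg_split <- two_group_test(expr, split_lab, numerator = "high",
                              denominator = "low",
                              method = config$deg_method)
  set_all <- filter_degs(deg_all, config$lfc_min, config$p_max)
  set_split <- filter_degs(deg_split, config$lfc_min, config$p_max)
  intersection <- intersect_gene_sets(set_all, set_split)

  # stage 4-5: ACO neighbour-frequency screen on the intersection + anchor
  aco_genes <- union(config$anchor, intersection)
  empty_intersection <- length(setdiff(aco_genes, config$anchor)) == 0
  freq <- NULL; screened <- NULL; sequences <- NULL
  if (length(aco_genes) >= 3) {
    dist_samples <- if (config$aco_samples == "case") case_ids else
      pheno$sample_id
    d <- distance_matrix(expr, genes = aco_genes, samples = dist_samples,
                         standardize = config$standardize)
    p <- config$aco
    p$seed <- seed + 100L
    sequences <- repeated_ordering(d, p, n_runs = config$n_runs)
    freq <- neighbor_frequency(sequences, config$anchor,
                               window = config$window)
    screened <- screen_candidates(freq, config$min_count,
                                  strict = config$strict_count)
  }
  empty_candidates <- is.null(screened) || nrow(screened) == 0

  # stage 6: clinical ranking
  fits <- NULL
  candidate <- NA_character_
  if (!empty_candidates) {
    if ("mmse" %in% colnames(pheno) &&
        sum(!is.na(pheno$mmse[pheno$group == "case"])) >= 3) {
      fits <- rank_by_fit(screened$gene_id, expr, pheno, samples = "case")
      candidate <- fits$gene_id[1L]
    } else {
      candidate <- screened$gene_id[1L] # fall back to frequency rank
    }
  }

  # stage 7: diagnostic model on (anchor, candidate)
  cv <- NULL; split_auc <- NA_real_; threshold <- NA_real_
  if (!is.na(candidate)) {
    feat <- t(expr[c(config$anchor, candidate), , drop = FALSE])
    labels <- pheno$group
    cv <- tryCatch(cv_auc(feat, labels, k = config$folds, seed = seed + 200L,
                          kernel = config$kernel, C = config$C),
                   error = function(e) {
                     warning("CV skipped: ", conditionMessage(e))
                     NULL
                   })
    sp <- split_train_test(labels, config$train_fraction, seed = seed + 300L)
    model <- fit_classifier(feat[sp$train, , drop = FALSE], labels[sp$train],
                            kernel = config$kernel, C = config$C)
    split_auc <- roc_auc(predict(model, feat[sp$test, , drop = FALSE]),
                         labels[sp$test])
    threshold <- anchor_threshold(feat, labels)
  }

  report <- structure(list(
    version = as.character(packageVersion("anchorScreen")),
    seed = seed,
    anchor = config$anchor,
    counts = list(
      n_genes = nrow(expr),
      n_samples = ncol(expr),
      n_case = length(case_ids),
      n_control = ncol(expr) - length(case_ids),
      degs_case_control = length(set_all$genes),
      degs_case_control_up = length(set_all$up),
      degs_case_control_down = length(set_all$down),
      degs_anchor_split = length(set_split$genes),
      intersection = length(intersection),
      candidates_screened = if (empty_candidates) 0L else nrow(screened)),
    empty_intersection = empty_intersection,
    empty_candidates = empty_candidates,
    candidate = candidate,
    deg_all = deg_report_table(deg_all, set_all),
    deg_split = deg_report_table(deg_split, set_split),
    intersection = intersection,
    frequency = freq,
    screened = screened,
    sequences = sequences,
    fits = fits,
    cv = cv,
    split_auc = split_auc,
    anchor_threshold = threshold,
    truth = truth), class = "run_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  c <- x$counts
  cat("anchorScreen run report (seed ", x$seed, ")\n", sep = "")
  cat("  data: ", c$n_genes, " genes, ", c$n_control, " controls / ",
      c$n_case, " cases\n", sep = "")
  cat("  DEGs case-vs-control: ", c$degs_case_control, " (",
      c$degs_case_control_up, " up / ", c$degs_case_control_down,
      " down); anchor split: ", c$degs_anchor_split,
      "; intersection: ", c$intersection, "\n", sep = "")
  cat("  candidates past frequency screen: ", c$candidates_screened,
      "; chosen candidate: ", x$candidate, "\n", sep = "")
  if (!is.null(x$cv)) {
    cat("  mean ", length(x$cv$auc_values), "-fold CV AUC: ",
        sprintf("%.3f", x$cv$mean_auc), "; split AUC: ",
        sprintf("%.3f", x$split_auc), "; anchor threshold: ",
        if (is.na(x$anchor_threshold)) "none" else
          sprintf("%.3f", x$anchor_threshold), "\n", sep = "")
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Serializes every intermediate table as TSV plus a machine-readable
#' `report.json`; the written files are sufficient to re-run any later stage
#' in isolation.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    write_table(df, p, seed = report$seed)
    paths <<- c(paths, p)
  }
  wt(report$deg_all, "deg_case_control.tsv")
  wt(report$deg_split, "deg_anchor_split.tsv")
  if (!is.null(report$frequency)) {
    freq <- report$frequency
    freq$passed <- freq$gene_id %in% report$screened$gene_id
    wt(freq, "neighbor_frequency.tsv")
    seq_df <- do.call(rbind, lapply(seq_along(report$sequences), function(r) {
      data.frame(run = r, position = seq_along(report$sequences[[r]]$order),
                 gene_id = report$sequences[[r]]$order)
    }))
    wt(seq_df, "gene_sequences.tsv")
  }
  if (!is.null(report$fits)) wt(as.data.frame(report$fits), "clinical_fits.tsv")
  if (!is.null(report$cv)) {
    wt(data.frame(fold = seq_along(report$cv$auc_values),
                  auc = report$cv$auc_values), "cv_auc.tsv")
  }
  json <- list(version = report$version, seed = report$seed,
               anchor = report$anchor, counts = report$counts,
               empty_intersection = report$empty_intersection,
               empty_candidates = report$empty_candidates,
               candidate = report$candidate,
               intersection = report$intersection,
               mean_cv_auc = if (is.null(report$cv)) NULL else
                 report$cv$mean_auc,
               split_auc = report$split_auc,
               anchor_threshold = report$anchor_threshold)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
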