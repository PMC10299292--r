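#' The 20 m6A regulator gene symbols used as a default gene-name fixture
#'
#' A convenience vector of human m6A writer/eraser/reader gene symbols
#' (METTL3, METTL14, ..., IGF2BP3). The synthetic generator and examples use
#' these purely as realistic gene identifiers; no biology is attached to them
#' anywhere in the package.
#'
#' @return Character vector of 20 gene symbols.
#' @export
m6a_regulators <- function() {
  c("METTL3", "METTL14", "METTL16", "RBM15", "RBM15B", "WTAP", "VIRMA",
    "ZC3H13", "FTO", "ALKBH5", "HNRNPC", "HNRNPA2B1", "YTHDF1", "YTHDF2",
    "YTHDF3", "YTHDC1", "YTHDC2", "IGF2BP1", "IGF2BP2", "IGF2BP3")
}

#' Configuration for the synthetic expression-data generator
#'
#' Describes a case/control log2 expression matrix with an anchor gene, a set
#' of planted genes whose case-group profiles are correlated with the anchor,
#' and clinical scores (MMSE, NFT) linearly coupled to one designated planted
#' gene. Defaults emulate the structure of a 74-control / 87-case brain
#' expression cohort with METTL3 as the anchor.
#'
#' @param n_genes Total number of genes (rows).
#' @param n_control,n_case Sample counts per group (each >= 2).
#' @param anchor_name Identifier of the anchor gene.
#' @param planted_genes Identifiers of the planted coherent genes; must not
#'   include `anchor_name`.
#' @param planted_corr Target population correlation in `[0, 1]` between each
#'   planted gene and the anchor within the case group.
#' @param case_shift Per-gene log2 mean difference (case minus control) applied
#'   to the anchor and every planted gene; negative values emulate
#'   downregulation in cases.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise on the log2
#'   scale (> 0).
#' @param base_mean,anchor_mean Control-group log2 means for ordinary genes and
#'   for the anchor.
#' @param clinical_gene The planted gene that drives the clinical scores
#'   (defaults to the first planted gene).
#' @param clinical_slope_mmse,clinical_slope_nft Linear coupling of MMSE / NFT
#'   to the designated gene's expression in cases. Default signs follow the
#'   convention that lower candidate expression means lower MMSE and higher
#'   NFT.
#' @param clinical_intercept_mmse,clinical_intercept_nft Intercepts of the two
#'   clinical couplings.
#' @param clinical_noise_sd Standard deviation of the clinical score noise
#'   (>= 0).
#' @param mmse_healthy MMSE level of controls (near the healthy ceiling).
#' @param severity_strata Optional integer vector
#'   `c(n_mild, n_moderate, n_severe)` summing to `n_case`; severity is
#'   assigned from MMSE rank (lowest MMSE = severe).
#' @param seed Integer RNG seed; all generator randomness derives from it.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_genes = 100,
                             n_control = 74,
                             n_case = 87,
                             anchor_name = "METTL3",
                             planted_genes = c("SDHA", "NDUFA10", "GPI",
                                               "YTHDC1", "HNRNPC", "YTHDF2",
                                               "NDUFC2"),
                             planted_corr = 0.9,
                             case_shift = -1,
                             noise_sd = 1,
                             base_mean = 8,
                             anchor_mean = 10,
                             clinical_gene = if ("NDUFA10" %in% planted_genes)
                               "NDUFA10" else planted_genes[[1L]],
                             clinical_slope_mmse = 2,
                             clinical_slope_nft = -1,
                             clinical_intercept_mmse = 0,
                             clinical_intercept_nft = 12,
                             clinical_noise_sd = 1,
                             mmse_healthy = 29,
                             severity_strata = NULL,
                             seed = 1) {
  cfg <- list(n_genes = check_count(n_genes, "n_genes"),
              n_control = check_count(n_control, "n_control", min = 2L),
              n_case = check_count(n_case, "n_case", min = 2L),
              anchor_name = as.character(anchor_name),
              planted_genes = as.character(planted_genes),
              planted_corr = planted_corr,
              case_shift = case_shift,
              noise_sd = noise_sd,
              base_mean = base_mean,
              anchor_mean = anchor_mean,
              clinical_gene = as.character(clinical_gene),
              clinical_slope_mmse = clinical_slope_mmse,
              clinical_slope_nft = clinical_slope_nft,
              clinical_intercept_mmse = clinical_intercept_mmse,
              clinical_intercept_nft = clinical_intercept_nft,
              clinical_noise_sd = clinical_noise_sd,
              mmse_healthy = mmse_healthy,
              severity_strata = severity_strata,
              seed = check_count(seed, "seed", min = 0L))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  check_scalar_number(cfg$planted_corr, "planted_corr", 0, 1)
  check_scalar_number(cfg$noise_sd, "noise_sd", 0, Inf, strict_lower = TRUE)
  check_scalar_number(cfg$case_shift, "case_shift")
  check_scalar_number(cfg$clinical_noise_sd, "clinical_noise_sd", 0, Inf)
  if (anyDuplicated(cfg$planted_genes)) {
    stop_invalid("planted_genes contains duplicates")
  }
  if (cfg$anchor_name %in% cfg$planted_genes) {
    stop_invalid("planted_genes must exclude the anchor gene '",
                 cfg$anchor_name, "'")
  }
  if (length(cfg$planted_genes) + 1L > cfg$n_genes) {
    stop_invalid("n_genes = ", cfg$n_genes, " too small for anchor plus ",
                 length(cfg$planted_genes), " planted genes")
  }
  if (!cfg$clinical_gene %in% cfg$planted_genes) {
    stop_invalid("clinical_gene '", cfg$clinical_gene,
                 "' is not one of the planted genes")
  }
  if (!is.null(cfg$severity_strata)) {
    ss <- cfg$severity_strata
    if (length(ss) != 3L || any(ss < 0) || any(ss != as.integer(ss))) {
      stop_invalid("severity_strata must be 3 non-negative integers ",
                   "(n_mild, n_moderate, n_severe)")
    }
    if (sum(ss) != cfg$n_case) {
      stop_invalid("severity_strata parts sum to ", sum(ss),
                   " but n_case = ", cfg$n_case)
    }
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:", x$n_genes, "genes,", x$n_control, "controls,",
      x$n_case, "cases\n")
  cat("  anchor:", x$anchor_name, " planted:",
      length(x$planted_genes), "genes at corr", x$planted_corr,
      " shift", x$case_shift, "\n")
  invisible(x)
}

synthetic_gene_universe <- function(cfg) {
  named <- c(cfg$anchor_name, cfg$planted_genes)
  n_fill <- cfg$n_genes - length(named)
  fillers <- setdiff(c(m6a_regulators(),
                       sprintf("G%04d", seq_len(cfg$n_genes))),
                     named)
  c(named, fillers[seq_len(n_fill)])
}

#' Generate a synthetic log2 expression matrix with planted coherent genes
#'
#' Draws a genes-by-samples matrix on the log2 scale. Control samples of every
#' gene are independent Gaussians around the gene's control mean. Within the
#' case group the anchor gene is shifted by `case_shift`, and each planted gene
#' is an affine function of the anchor's case profile plus calibrated Gaussian
#' noise so that its population correlation with the anchor equals
#' `planted_corr`; all other genes are independent noise. The correlation
#' structure is imposed in the case group only, matching a screen that orders
#' genes on case samples.
#'
#' @param config A [synthetic_config()].
#' @return A list with components `expression` (numeric matrix, genes x
#'   samples), `phenotype` (data.frame with `sample_id` and `group`), and
#'   `truth` (planted gene set, realized case-group correlations with the
#'   anchor, and the true clinical slopes).
#' @export
generate_expression <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  genes <- synthetic_gene_universe(cfg)
  samples <- c(sprintf("CTRL_%03d", seq_len(cfg$n_control)),
               sprintf("AD_%03d", seq_len(cfg$n_case)))
  group <- rep(c("control", "case"), c(cfg$n_control, cfg$n_case))

  with_seed(cfg$seed, {
    n_s <- cfg$n_control + cfg$n_case
    x <- matrix(rnorm(cfg$n_genes * n_s, mean = cfg$base_mean,
                      sd = cfg$noise_sd),
                nrow = cfg$n_genes, ncol = n_s,
                dimnames = list(genes, samples))
    ctrl <- which(group == "control")
    cas <- which(group == "case")

    # anchor: control around anchor_mean, cases shifted by case_shift
    z_anchor <- rnorm(cfg$n_case)
    x[cfg$anchor_name, ctrl] <- rnorm(cfg$n_control, cfg$anchor_mean,
                                      cfg$noise_sd)
    x[cfg$anchor_name, cas] <- cfg$anchor_mean + cfg$case_shift +
      cfg$noise_sd * z_anchor

    # planted genes share the anchor's latent case-group factor z_anchor with
    # weight rho, giving population correlation exactly planted_corr
    rho <- cfg$planted_corr
    for (g in cfg$planted_genes) {
      eps <- rnorm(cfg$n_case)
      x[g, cas] <- cfg$base_mean + cfg$case_shift +
        cfg$noise_sd * (rho * z_anchor + sqrt(1 - rho^2) * eps)
    }

    realized <- vapply(cfg$planted_genes, function(g) {
      cor(x[g, cas], x[cfg$anchor_name, cas])
    }, numeric(1))

    phenotype <- data.frame(sample_id = samples, group = group,
                            stringsAsFactors = FALSE)
    truth <- list(planted_genes = cfg$planted_genes,
                  anchor = cfg$anchor_name,
                  realized_corr = realized,
                  clinical_gene = cfg$clinical_gene,
                  clinical_slopes = c(mmse = cfg$clinical_slope_mmse,
                                      nft = cfg$clinical_slope_nft))
    list(expression = x, phenotype = phenotype, truth = truth)
  })
}

#' Attach synthetic clinical scores (MMSE, NFT) to a phenotype table
#'
#' Case samples receive MMSE and NFT values affine in the designated planted
#' gene's expression plus Gaussian noise; controls sit near the healthy MMSE
#' ceiling with NFT near zero. MMSE is clamped into `[0, 30]` (inactive at the
#' default parameter scales) and NFT floored at 0. If `severity_strata` is
#' configured, case samples are labelled mild/moderate/severe from MMSE rank,
#' lowest MMSE first into `severe`, with exact stratum sizes.
#'
#' @param config The [synthetic_config()] used to generate `expr`.
#' @param expr The expression matrix from [generate_expression()].
#' @param phenotype The matching phenotype data.frame.
#' @return The phenotype data.frame with `mmse`, `nft` and (optionally)
#'   `severity` columns added.
#' @export
generate_clinical <- function(config, expr, phenotype) {
  validate_synthetic_config(config)
  cfg <- config
  if (!cfg$clinical_gene %in% rownames(expr)) {
    stop_invalid("expression matrix does not contain the clinical gene '",
                 cfg$clinical_gene, "' - was it generated with this config?")
  }
  if (!identical(sort(phenotype$sample_id), sort(colnames(expr)))) {
    stop_invalid("phenotype sample_ids do not match the expression columns")
  }
  is_case <- phenotype$group == "case"
  if (sum(is_case) != cfg$n_case || sum(!is_case) != cfg$n_control) {
    stop_invalid("phenotype group sizes do not match the config")
  }
  g <- expr[cfg$clinical_gene, phenotype$sample_id]

  with_seed(cfg$seed + 1000L, {
    mmse <- nft <- numeric(nrow(phenotype))
    n_case <- sum(is_case)
    mmse[is_case] <- cfg$clinical_intercept_mmse +
      cfg$clinical_slope_mmse * g[is_case] +
      rnorm(n_case, sd = cfg$clinical_noise_sd)
    nft[is_case] <- cfg$clinical_intercept_nft +
      cfg$clinical_slope_nft * g[is_case] +
      rnorm(n_case, sd = cfg$clinical_noise_sd)
    mmse[!is_case] <- cfg$mmse_healthy +
      rnorm(sum(!is_case), sd = min(cfg$clinical_noise_sd, 0.5))
    nft[!is_case] <- abs(rnorm(sum(!is_case), sd = 0.1))
    mmse <- pmin(30, pmax(0, mmse))
    nft <- pmax(0, nft)
    out <- phenotype
    out$mmse <- unname(mmse)
    out$nft <- unname(nft)
    if (!is.null(cfg$severity_strata)) {
      ss <- cfg$severity_strata # (mild, moderate, severe)
      sev <- rep(NA_character_, nrow(out))
      ord <- order(out$mmse[is_case], out$sample_id[is_case]) # low MMSE first
      lab <- rep(c("severe", "moderate", "mild"), c(ss[3], ss[2], ss[1]))
      sev[which(is_case)[ord]] <- lab
      out$severity <- sev
    }
    out
  })
}

#' Generate a complete synthetic dataset (expression + clinical phenotype)
#'
#' Convenience wrapper around [generate_expression()] and
#' [generate_clinical()].
#'
#' @inheritParams generate_expression
#' @return A list with `expression`, `phenotype` (including clinical scores)
#'   and `truth`.
#' @export
synthetic_dataset <- function(config = synthetic_config()) {
  sim <- generate_expression(config)
  sim$phenotype <- generate_clinical(config, sim$expression, sim$phenotype)
  sim
}
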