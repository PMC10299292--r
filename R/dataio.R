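# Plain tab-delimited readers/writers with validation on ingest. All formats
# are TSV, UTF-8, '.' decimal; output tables carry a '#' provenance header.

#' Read a log2 expression matrix from a tab-delimited file
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Lines starting with `#` are ignored. Ingest is strict:
#' duplicate identifiers, non-numeric cells and (by default) missing values
#' are errors, never silently dropped.
#'
#' @param path Path to the TSV file.
#' @param impute_missing If `TRUE`, missing values are imputed with the row
#'   median (a message reports how many); the default `FALSE` rejects them.
#' @return A numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path, impute_missing = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) <= 1) stop_invalid("empty expression file: ",
                                                   path)
  gene_ids <- as.character(df[[1L]])
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop_invalid("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop_invalid("duplicate sample identifier(s): ",
                 paste(dup_s, collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) &
                     !toupper(trimws(col)) %in% c("NA", ""))
      if (length(bad)) {
        stop_invalid("non-numeric value '", col[bad[1L]], "' at gene '",
                     gene_ids[bad[1L]], "', sample '", sample_ids[j], "'")
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(gene_ids, sample_ids)
  if (anyNA(m)) {
    if (!impute_missing) {
      stop_invalid("expression matrix contains ", sum(is.na(m)),
                   " missing value(s); re-run with impute_missing = TRUE ",
                   "to impute row medians")
    }
    n_miss <- sum(is.na(m))
    for (i in which(rowSums(is.na(m)) > 0)) {
      med <- median(m[i, ], na.rm = TRUE)
      if (is.na(med)) stop_invalid("gene '", rownames(m)[i],
                                   "' is entirely missing")
      m[i, is.na(m[i, ])] <- med
    }
    message("imputed ", n_miss, " missing value(s) with row medians")
  }
  validate_expression(m)
  m
}

validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_invalid("expression must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_invalid("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) stop_invalid("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop_invalid("duplicate sample identifiers")
  if (anyNA(m)) stop_invalid("expression matrix contains missing values")
  invisible(m)
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param seed Optional seed recorded in the provenance header line.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, seed = NULL) {
  validate_expression(m)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  # %.17g keeps doubles exact over a write/read round trip
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read and validate a phenotype table
#'
#' Expects columns `sample_id` and `group` plus optional `severity`, `mmse`,
#' `nft`. Group labels are normalized through a case-insensitive alias table
#' ("AD", "patient" -> case; "normal", "ctrl" -> control); unknown labels are
#' errors, as are MMSE values outside `[0, 30]` and negative NFT.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with normalized columns.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  validate_phenotype(df)
}

validate_phenotype <- function(df) {
  if (!all(c("sample_id", "group") %in% colnames(df))) {
    stop_invalid("phenotype table needs 'sample_id' and 'group' columns")
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop_invalid("duplicate sample_id(s): ",
                                paste(dup, collapse = ", "))
  df$group <- normalize_group(df$group)
  if ("severity" %in% colnames(df)) {
    df$severity <- normalize_severity(df$severity)
  }
  if ("mmse" %in% colnames(df)) {
    mm <- df$mmse[!is.na(df$mmse)]
    if (length(mm) && (any(mm < 0) || any(mm > 30))) {
      stop_invalid("MMSE values outside [0, 30]: ",
                   paste(head(mm[mm < 0 | mm > 30], 3), collapse = ", "))
    }
  }
  if ("nft" %in% colnames(df)) {
    if (any(df$nft < 0, na.rm = TRUE)) stop_invalid("negative NFT values")
  }
  df
}

#' Write a phenotype or result table as TSV with a provenance header
#'
#' Serializes any data.frame (phenotype tables, DEG tables, frequency tables,
#' fit tables, CV-AUC tables) with stable column order and a `#` header line.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_table
#' @export
write_phenotype <- function(df, path, seed = NULL) {
  write_table(validate_phenotype(df), path, seed = seed)
}
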