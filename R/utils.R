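# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a single finite number")
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_invalid(name, " = ", x, " is outside the allowed range ",
                 if (strict_lower) "(" else "[", lower, ", ", upper,
                 if (strict_upper) ")" else "]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    stop_invalid(name, " must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

# Normalize free-text group labels to the canonical control/case pair.
# GEO-style phenotype tables use many spellings; unknown labels are an error.
normalize_group <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  case_alias <- c("case", "ad", "patient", "patients", "alzheimer",
                  "disease", "affected")
  control_alias <- c("control", "normal", "ctrl", "healthy", "unaffected")
  out <- ifelse(lx %in% case_alias, "case",
                ifelse(lx %in% control_alias, "control", NA_character_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop_invalid("unknown group label(s): ", paste(bad, collapse = ", "),
                 " (expected case/control or a known alias)")
  }
  out
}

normalize_severity <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  lx[lx %in% c("", "na")] <- NA_character_
  map <- c(mild = "mild", incipient = "mild", moderate = "moderate",
           severe = "severe")
  out <- unname(map[lx])
  bad <- !is.na(lx) & is.na(out)
  if (any(bad)) {
    stop_invalid("unknown severity label(s): ",
                 paste(unique(lx[bad]), collapse = ", "))
  }
  out
}

provenance_header <- function(seed = NULL) {
  paste0("# anchorScreen ", as.character(packageVersion("anchorScreen")),
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}
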