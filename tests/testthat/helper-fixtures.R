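# Fixture builders shared across the test files. Everything is generated in
# code; no data files are read.

# small labelled expression matrix from a vector spec
make_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  make_expr(rnorm(n_genes * n_samples, mean = 8),
            sprintf("g%03d", seq_len(n_genes)),
            sprintf("s%03d", seq_len(n_samples)))
}

# symmetric squared-distance matrix from random profiles
random_dist <- function(n, seed = 1, n_dim = 10) {
  set.seed(seed)
  x <- matrix(runif(n * n_dim), n, n_dim)
  d <- as.matrix(dist(x))^2
  dimnames(d) <- list(sprintf("g%d", seq_len(n)), sprintf("g%d", seq_len(n)))
  d
}

# independent brute-force path length (never calls path_length)
naive_path_length <- function(idx, d, cycle = FALSE) {
  tot <- 0
  for (k in seq_len(length(idx) - 1)) tot <- tot + d[idx[k], idx[k + 1]]
  if (cycle) tot <- tot + d[idx[length(idx)], idx[1]]
  tot
}

two_class_labels <- function(n_control, n_case) {
  rep(c("control", "case"), c(n_control, n_case))
}
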