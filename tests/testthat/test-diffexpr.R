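test_that("two_group_test recovers exact shifts and the identity case", {
  x <- random_expr(10, 6, seed = 1)
  g <- setNames(two_class_labels(3, 3), colnames(x))

  # identical groups: copy control columns into the case slots
  x_id <- x
  x_id[, 4:6] <- x[, 1:3]
  res <- two_group_test(x_id, g)
  expect_equal(res$log2fc, rep(0, 10), tolerance = 1e-12)
  expect_identical(res$direction, rep("none", 10))

  # exact +1 shift with nonzero variance
  x_sh <- x
  x_sh[, 4:6] <- x[, 1:3] + 1
  res <- two_group_test(x_sh, g)
  expect_equal(res$log2fc, rep(1, 10), tolerance = 1e-12)
  expect_identical(res$direction, rep("up", 10))
})

test_that("label swap negates log2fc and preserves p-values", {
  x <- random_expr(50, 20, seed = 2)
  g <- setNames(two_class_labels(10, 10), colnames(x))
  for (m in c("welch", "moderated")) {
    a <- two_group_test(x, g, method = m)
    b <- two_group_test(x, g, numerator = "control", denominator = "case",
                        method = m)
    expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate genes never yield NaN", {
  x <- make_expr(c(rep(5, 8),
                   rep(c(5, 6), each = 4)),
                 c("flat", "shifted"), sprintf("s%d", 1:8))
  g <- setNames(two_class_labels(4, 4), colnames(x))
  res <- two_group_test(x, g)
  expect_false(anyNA(res$p_value))
  expect_equal(res[res$gene_id == "flat", "p_value"], 1)
  expect_equal(res[res$gene_id == "shifted", "p_value"], .Machine$double.eps)
})

test_that("null p-values are approximately uniform (KS, both methods)", {
  x <- random_expr(2000, 60, seed = 3)
  g <- setNames(two_class_labels(30, 30), colnames(x))
  for (m in c("welch", "moderated")) {
    p <- two_group_test(x, g, method = m)$p_value
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("moderated mode tracks the limma moderated t ordering", {
  # limma (pre-installed) is the independent oracle for the shrinkage route
  x <- random_expr(300, 24, seed = 4)
  x[1:30, 13:24] <- x[1:30, 13:24] + 0.8
  g <- setNames(two_class_labels(12, 12), colnames(x))
  mine <- two_group_test(x, g, method = "moderated")
  design <- cbind(1, as.integer(g == "case"))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(mine$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-9)
  expect_gt(cor(-log10(mine$p_value), -log10(fit$p.value[, 2]),
                method = "spearman"), 0.98)
})

test_that("filter_degs applies strict thresholds and partitions by sign", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(0.3, -0.5, 0.8, 0.4),
                    p_value = c(0.01, 0.04, 0.05, 0.004),
                    direction = c("up", "down", "up", "up"))
  fs <- filter_degs(rec, lfc_min = 0.3, p_max = 0.05)
  expect_setequal(fs$genes, c("b", "d")) # a fails strict lfc, c fails strict p
  expect_identical(fs$down, "b")
  expect_identical(fs$up, "d")
})

test_that("filter_degs is monotone in both thresholds", {
  set.seed(5)
  rec <- data.frame(gene_id = sprintf("g%d", 1:200),
                    log2fc = rnorm(200), p_value = runif(200),
                    direction = "up")
  base <- filter_degs(rec, 0.3, 0.05)$genes
  for (i in 1:10) {
    lfc <- runif(1, 0.05, 0.3)
    pm <- runif(1, 0.05, 0.5)
    relaxed <- filter_degs(rec, lfc, pm)$genes
    expect_true(all(base %in% relaxed))
  }
})

test_that("median_split follows the tie rule and stays balanced", {
  x <- make_expr(c(1, 2, 3, 4), "METTL3", sprintf("s%d", 1:4))
  sp <- median_split(x, "METTL3")
  expect_identical(unname(sp), c("low", "low", "high", "high"))

  x5 <- make_expr(c(1, 2, 3, 2.5, 0.5), "METTL3", sprintf("s%d", 1:5))
  sp5 <- median_split(x5, "METTL3")
  expect_identical(unname(sp5[c("s1", "s2", "s3")]), c("low", "low", "high"))

  for (seed in 1:5) {
    set.seed(seed)
    xr <- make_expr(rnorm(87), "METTL3", sprintf("s%d", 1:87))
    spl <- median_split(xr, "METTL3")
    expect_lte(abs(sum(spl == "high") - sum(spl == "low")), 1)
  }

  expect_error(median_split(x, "ABSENT"), "ABSENT")
  flat <- make_expr(rep(2, 4), "METTL3", sprintf("s%d", 1:4))
  expect_error(median_split(flat, "METTL3"), "identical")
})

test_that("intersect_gene_sets is an exact, order-stable intersection", {
  expect_identical(intersect_gene_sets(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
  x <- c("q", "a", "z")
  expect_identical(intersect_gene_sets(x, x), x)
  expect_identical(intersect_gene_sets(x, character(0)), character(0))
  for (seed in 1:10) {
    set.seed(seed)
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    expect_equal(length(intersect_gene_sets(a, b)) + length(union(a, b)),
                 length(a) + length(b))
  }
})

test_that("group validation catches small and mislabelled groups", {
  x <- random_expr(5, 4, seed = 6)
  expect_error(two_group_test(x, setNames(c("case", "control", "control",
                                            "control"), colnames(x))),
               ">= 2 samples")
  expect_error(two_group_test(x, setNames(rep("weird", 4), colnames(x))),
               "labels other than")
})
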