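# Loading, filtering, normalization, adjacent profiles, variable genes,
# profile clustering.

test_that("dense CSV round-trips and transposed input matches", {
  d <- withr::local_tempdir()
  m <- matrix(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11), 3, 4,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  f <- file.path(d, "expr.csv")
  write.csv(data.frame(cell = rownames(m), m), f, row.names = FALSE)
  e <- load_expression(f, format = "csv")
  expect_equal(dim(e), c(3, 4))
  expect_equal(unname(e$values), unname(m))
  expect_equal(e$gene_ids, colnames(m))
  expect_equal(e$cell_ids, rownames(m))
  # genes x cells file with the orientation flag gives the same matrix
  ft <- file.path(d, "exprT.csv")
  write.csv(data.frame(gene = colnames(m), t(m)), ft, row.names = FALSE)
  et <- load_expression(ft, format = "csv", orientation = "genes_by_cells")
  expect_equal(et$values, e$values)
})

test_that("MTX with 10x companions round-trips bit-exactly", {
  d <- withr::local_tempdir()
  set.seed(1)
  m <- matrix(rpois(20 * 12, 1), 20, 12,
              dimnames = list(sprintf("bc%02d", 1:20), sprintf("g%02d", 1:12)))
  m[, 3] <- 0  # all-zero gene column survives loading (filtering is separate)
  e0 <- expression_matrix(m)
  write_expression_mtx(e0, d)
  e1 <- load_expression(file.path(d, "matrix.mtx"))
  expect_identical(e1$values, e0$values)
  expect_true("g03" %in% e1$gene_ids)
  # missing companion file is a format error
  file.remove(file.path(d, "barcodes.tsv"))
  expect_error(load_expression(file.path(d, "matrix.mtx")), "companion")
})

test_that("duplicate gene ids and unsupported formats are rejected", {
  m <- matrix(1, 2, 2)
  expect_error(expression_matrix(m, gene_ids = c("a", "a")), "duplicate.*a")
  expect_error(load_expression("x.h5", format = "h5"), "not supported")
})

test_that("zero-gene filtering matches a brute-force scan and is idempotent", {
  set.seed(2)
  m <- matrix(rbinom(10 * 20, 5, 0.1), 10, 20)
  m[, c(4, 17)] <- 0
  e <- expression_matrix(m)
  f <- filter_zero_genes(e)
  keep_oracle <- which(apply(m, 2, function(col) any(col != 0)))
  expect_equal(f$gene_ids, e$gene_ids[keep_oracle])
  expect_equal(unname(f$values), unname(m[, keep_oracle]))
  expect_equal(filter_zero_genes(f)$values, f$values)  # idempotent
  expect_equal(f$cell_ids, e$cell_ids)
  expect_error(filter_zero_genes(expression_matrix(matrix(0, 3, 2))),
               "all genes")
})

test_that("log2(TPM+1) normalization maps known values and guards rescaling", {
  e <- expression_matrix(matrix(c(0, 1, 7, 3), 2, 2), normalization_tag = "tpm")
  n <- normalize_log2_tpm1(e)
  expect_equal(unname(n$values), matrix(c(0, 1, 3, 2), 2, 2))
  expect_equal(n$normalization_tag, "log2_tpm1")
  expect_error(normalize_log2_tpm1(n), "already")
  # strictly monotone per entry
  x <- sort(runif(50, 0, 100))
  v <- normalize_log2_tpm1(expression_matrix(matrix(x, 1),
                                             normalization_tag = "tpm"))$values
  expect_true(all(diff(as.numeric(v)) > 0))
  # raw counts go through the counts-per-million surrogate
  e2 <- expression_matrix(matrix(c(10, 30, 90, 70), 2, 2))
  expect_message(n2 <- normalize_log2_tpm1(e2), "counts-per-million")
  expect_equal(unname(n2$values[1, ]), log2(c(10, 90) / 100 * 1e6 + 1))
})

test_that("adjacent profiles are simplex vectors matching the ratio oracle", {
  ch <- IGH_CHANNELS
  v <- matrix(0, 2, 10,
              dimnames = list(NULL, c(ch, "other1", "other2")))
  v[1, "Ighm"] <- 5
  v[2, c("Ighm", "Ighg1")] <- 3
  v[, "other1"] <- 7  # non-channel expression must not matter
  e <- expression_matrix(v, normalization_tag = "log2_tpm1")
  p <- compute_adjacent_profiles(e, ch)
  expect_equal(unname(p[1, ]), c(1, rep(0, 7)))
  expect_equal(unname(p[2, ]), c(0.5, 0.5, rep(0, 6)))
  # random matrix against an elementwise division oracle
  set.seed(3)
  v2 <- matrix(rexp(50 * 12), 50, 12,
               dimnames = list(NULL, c(ch, paste0("x", 1:4))))
  e2 <- expression_matrix(v2, normalization_tag = "log2_tpm1")
  p2 <- compute_adjacent_profiles(e2, ch)
  oracle <- v2[, ch] / rowSums(v2[, ch])
  expect_equal(unname(p2), unname(oracle), tolerance = 1e-12)
  expect_true(all(abs(rowSums(p2) - 1) <= 1e-9))
  expect_true(all(p2 >= 0 & p2 <= 1))
  # profiles do not depend on non-channel genes
  v3 <- v2; v3[, "x1"] <- 99
  p3 <- compute_adjacent_profiles(
    expression_matrix(v3, normalization_tag = "log2_tpm1"), ch)
  expect_equal(p3, p2)
})

test_that("zero-channel cells get the uniform profile with a warning", {
  v <- matrix(0, 2, 8, dimnames = list(c("a", "b"), IGH_CHANNELS))
  v[1, 1] <- 4
  e <- expression_matrix(v, normalization_tag = "log2_tpm1")
  expect_warning(p <- compute_adjacent_profiles(e), "uniform.*b")
  expect_equal(unname(p[2, ]), rep(1 / 8, 8))
  expect_false(anyNA(p))
})

test_that("profiles require the log scale and present channel genes", {
  e <- expression_matrix(matrix(1, 2, 8, dimnames = list(NULL, IGH_CHANNELS)))
  expect_error(compute_adjacent_profiles(e), "log2")
  e2 <- expression_matrix(matrix(1, 2, 3, dimnames = list(NULL, c("a", "b", "c"))),
                          normalization_tag = "log2_tpm1")
  expect_error(compute_adjacent_profiles(e2), "not found.*Ighm")
  # case-insensitive fallback
  e3 <- expression_matrix(matrix(1, 2, 8,
                                 dimnames = list(NULL, toupper(IGH_CHANNELS))),
                          normalization_tag = "log2_tpm1")
  expect_error(compute_adjacent_profiles(e3), "not found")
  expect_silent(compute_adjacent_profiles(e3, case_insensitive = TRUE))
})

test_that("variable-gene selection matches exhaustive ranking and nests", {
  set.seed(4)
  v <- matrix(rnorm(30 * 100, sd = rep(runif(100, 0.1, 3), each = 30)),
              30, 100)
  e <- expression_matrix(abs(v), normalization_tag = "log2_tpm1")
  s10 <- select_variable_genes(e, 10)
  oracle <- names(sort(apply(e$values, 2, var), decreasing = TRUE))[1:10]
  expect_setequal(s10$gene_ids, oracle)
  # original order preserved among selected
  expect_equal(s10$gene_ids, intersect(e$gene_ids, s10$gene_ids))
  # nesting: top-k1 within top-k2
  s25 <- select_variable_genes(e, 25)
  expect_true(all(s10$gene_ids %in% s25$gene_ids))
  expect_equal(select_variable_genes(e, 100)$values, e$values)  # identity
  expect_error(select_variable_genes(e, 101), "exceeds")
})

test_that("hierarchical clustering recovers planted simplex blobs", {
  set.seed(5)
  centers <- diag(8)[c(1, 2, 5), ]
  p <- do.call(rbind, lapply(1:3, function(k) {
    raw <- pmax(centers[rep(k, 30), ] + matrix(rnorm(30 * 8, sd = 0.03),
                                               30, 8), 0)
    raw / rowSums(raw)
  }))
  rownames(p) <- paste0("c", seq_len(nrow(p)))
  cl <- cluster_adjacent_profiles(p, k = 3)
  planted <- rep(1:3, each = 30)
  expect_equal(length(unique(cl$labels)), 3)
  # perfect agreement up to label permutation
  tab <- table(cl$labels, planted)
  expect_equal(sum(apply(tab, 1, max)), 90)
  # identical profiles always co-cluster
  dup <- rbind(p[1, ], p[1, ], p[31, ], p[61, ])
  rownames(dup) <- paste0("d", 1:4)
  for (k in 2:3) {
    lab <- cluster_adjacent_profiles(dup, k = k)$labels
    expect_equal(lab[[1]], lab[[2]])
  }
  expect_error(cluster_adjacent_profiles(p[1, , drop = FALSE]), "at least 2")
})
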