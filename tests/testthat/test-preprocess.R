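make_tbl <- function(...) {
  cols <- list(...)
  dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", seq_along(cols[[1]]))),
                   tibble::as_tibble(cols))
}

test_that("correlation filter drops the later column of a high-r pair", {
  x <- rnorm(30)
  tbl <- make_tbl(a = x, b = x, c = rnorm(30))
  out <- filter_correlated(tbl, 0.8)
  expect_equal(setdiff(names(out), "gene"), c("a", "c"))
  expect_equal(attr(out, "dropped_features")$feature, "b")

  set.seed(1)
  y <- x * 0.5 + rnorm(30) * sqrt(1 - 0.25)
  stopifnot(abs(cor(x, y)) < 0.8)
  out2 <- filter_correlated(make_tbl(a = x, b = y), 0.8)
  expect_equal(setdiff(names(out2), "gene"), c("a", "b"))
})

test_that("after the correlation filter no surviving pair exceeds the threshold", {
  set.seed(11)
  base <- rnorm(50)
  tbl <- make_tbl(a = base + rnorm(50, sd = 0.2),
                  b = base + rnorm(50, sd = 0.2),
                  c = base + rnorm(50, sd = 0.2),
                  d = rnorm(50))
  out <- filter_correlated(tbl, 0.8)
  m <- as.matrix(out[setdiff(names(out), "gene")])
  r <- cor(m)
  expect_true(all(abs(r[upper.tri(r)]) <= 0.8))
  # the three mutually ~0.9-correlated columns collapse to one survivor
  expect_equal(sum(c("a", "b", "c") %in% colnames(m)), 1L)
})

test_that("missingness filter uses a strict inequality", {
  n <- 20
  col25 <- c(rep(NA, 5), rnorm(15))   # exactly 25%
  col30 <- c(rep(NA, 6), rnorm(14))   # 30%
  tbl <- make_tbl(ok = rnorm(n), boundary = col25, bad = col30)
  out <- filter_missing(tbl, 0.25)
  expect_equal(setdiff(names(out), "gene"), c("ok", "boundary"))
  expect_equal(attr(out, "dropped_features")$feature, "bad")
  expect_error(filter_missing(make_tbl(x = rep(NA_real_, 5)), 0.25),
               "no features survive")
})

test_that("imputation follows the zero/median policy split", {
  tbl <- make_tbl(flag = c(0, 1, NA, 1), expr = c(1, 2, 3, NA))
  out <- impute_features(tbl)
  expect_equal(out$flag[3], 0)
  expect_equal(out$expr[4], 2)  # median of {1,2,3}
  expect_false(anyNA(out))
  # explicit policy override wins over kind
  out2 <- impute_features(tbl, policies = c(expr = "zero"))
  expect_equal(out2$expr[4], 0)
  expect_error(impute_features(make_tbl(x = c(NA_real_, NA_real_))),
               "fully missing")
})

test_that("standardization hits exact z-scores and is idempotent", {
  tbl <- make_tbl(x = c(1, 2, 3), y = c(5, 5, 5))
  expect_warning(standardize_features(tbl), "constant")
  out <- suppressWarnings(standardize_features(tbl))
  expect_equal(out$x, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_false("y" %in% names(out))
  again <- standardize_features(out)
  expect_equal(again$x, out$x, tolerance = 1e-9)
})

test_that("the full pipeline is idempotent and leaves clean columns", {
  fx <- generate_table(n_genes = 120, n_features = 15, n_informative = 4,
                       n_seeds = 12, missing_fraction = 0.15,
                       n_corr_pairs = 2, seed = 9)
  pt <- suppressWarnings(preprocess_features(fx$table))
  m <- as.matrix(pt[setdiff(names(pt), "gene")])
  expect_false(anyNA(m))
  expect_true(all(abs(colMeans(m)) < 1e-9))
  expect_true(all(abs(colMeans(m^2) - 1) < 1e-6))
  pt2 <- preprocess_features(pt)
  expect_equal(as.data.frame(pt2), as.data.frame(pt), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("eda summaries give a symmetric unit-diagonal correlation matrix", {
  x <- rnorm(25)
  tbl <- make_tbl(a = x, b = x, c = c(NA, rnorm(24)))
  eda <- eda_summaries(tbl)
  expect_equal(eda$corr_matrix["a", "b"], 1)
  expect_equal(eda$corr_matrix, t(eda$corr_matrix))
  expect_equal(unname(diag(eda$corr_matrix)), rep(1, 3))
  expect_equal(eda$missing_ratios$missing_fraction, c(0, 0, 1 / 25))
})

test_that("PCA projection matches a covariance eigendecomposition", {
  fx <- generate_table(n_genes = 80, n_features = 10, n_informative = 3,
                       n_seeds = 10, missing_fraction = 0, seed = 13)
  pt <- suppressWarnings(preprocess_features(fx$table))
  pr <- project_2d(pt, "pca")
  m <- as.matrix(pt[setdiff(names(pt), "gene")])
  mc <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(cov(mc))
  oracle <- mc %*% eig$vectors[, 1:2]
  # eigenvectors are sign-ambiguous
  for (j in 1:2) {
    got <- pr$coordinates[[paste0("dim", j)]]
    expect_true(min(sum((got - oracle[, j])^2),
                    sum((got + oracle[, j])^2)) < 1e-12)
  }
  expect_true(all(diff(pr$scree) >= -1e-12))
  expect_true(all(pr$scree >= 0 & pr$scree <= 1 + 1e-12))
})

test_that("rank-2 data saturates the scree by the second component", {
  set.seed(21)
  basis <- matrix(rnorm(20), 10, 2)
  scores <- matrix(rnorm(120), 60, 2)
  tbl <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", 1:60)),
                          tibble::as_tibble(as.data.frame(scores %*% t(basis))))
  pr <- project_2d(tbl, "pca")
  expect_gte(pr$scree[2], 0.999)
})

test_that("t-SNE is deterministic under a fixed seed", {
  fx <- generate_table(n_genes = 100, n_features = 8, n_informative = 3,
                       n_seeds = 10, missing_fraction = 0, seed = 17)
  pt <- suppressWarnings(preprocess_features(fx$table))
  a <- project_2d(pt, "tsne", seed = 5, perplexity = 15)
  b <- project_2d(pt, "tsne", seed = 5, perplexity = 15)
  expect_identical(a$coordinates, b$coordinates)
  expect_equal(nrow(a$coordinates), nrow(pt))
})

test_that("UMAP guards its neighbour requirement and reproduces with a seed", {
  fx <- generate_table(n_genes = 4, n_features = 5, n_informative = 2,
                       n_seeds = 2, missing_fraction = 0, seed = 1)
  expect_error(project_2d(impute_features(fx$table), "umap", n_neighbors = 5),
               "n_neighbors")
  fx2 <- generate_table(n_genes = 60, n_features = 8, n_informative = 3,
                        n_seeds = 8, missing_fraction = 0, seed = 2)
  pt <- suppressWarnings(preprocess_features(fx2$table))
  u <- project_2d(pt, "umap", seed = 4)
  expect_equal(nrow(u$coordinates), 60L)
  expect_true(all(is.finite(u$coordinates$dim1)))
})
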