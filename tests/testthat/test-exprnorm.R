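make_counts <- function(n_genes = 100, n_samples = 6, seed = 1, base = 50) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = base, size = 10),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, gene_lengths = rep(1000, n_genes), scale = "counts")
}

test_that("TMM factors are 1 for identical or proportional columns", {
  set.seed(2)
  col <- rnbinom(200, mu = 100, size = 5) + 1
  m <- cbind(s1 = col, s2 = col)
  rownames(m) <- sprintf("g%03d", 1:200)
  f <- tmm_factors(expression_matrix(m, scale = "rpk"))
  expect_equal(unname(f), c(1, 1), tolerance = 1e-10)

  m2 <- cbind(s1 = col, s2 = 3 * col)
  rownames(m2) <- rownames(m)
  f2 <- tmm_factors(expression_matrix(m2, scale = "rpk"))
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-10)
})

test_that("TMM factors equal a from-scratch trimmed weighted mean oracle", {
  set.seed(7)
  m <- matrix(rnbinom(200 * 4, mu = 80, size = 8) + 1, 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:4)))
  m[1:10, 2] <- m[1:10, 2] * 8   # 10 genes 8-fold up in sample 2
  em <- expression_matrix(m, scale = "rpk")
  f <- tmm_factors(em)
  f_oracle <- tmm_oracle(m)
  expect_equal(unname(f), unname(f_oracle), tolerance = 1e-10)
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
})

test_that("TMM rejects all-zero samples by name", {
  m <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("ok", "empty")))
  expect_error(tmm_factors(expression_matrix(m, scale = "rpk")),
               regexp = "empty", class = "famendo_normalization_error")
})

test_that("geTMM matches its definition and is library-scale invariant", {
  # RPK definition
  m <- matrix(100, 1, 1, dimnames = list("g1", "s1"))
  em <- expression_matrix(m, gene_lengths = c(g1 = 2000), scale = "counts")
  norm <- getmm_normalize(em)
  expect_equal(unname(norm$values[1, 1]), log2(1e6 + 0.5))  # single gene: RPK 50 of 50 total

  cm <- make_counts(n_genes = 300, seed = 11)
  # rescaling every library together changes nothing at all
  n1 <- getmm_normalize(cm)
  cm_all <- cm; cm_all$values <- cm_all$values * 2
  n_all <- getmm_normalize(cm_all)
  expect_lt(max(abs(n1$values - n_all$values)), 1e-9)
  # doubling one sample's library: exactly invariant for the unweighted
  # trimmed mean (M, A and the trims are depth-free)
  n1u <- getmm_normalize(cm, weighted = FALSE)
  cm2 <- cm
  cm2$values[, 3] <- cm2$values[, 3] * 2
  n2u <- getmm_normalize(cm2, weighted = FALSE)
  big <- cm$values[, 3] > 100
  expect_lt(max(abs(n1u$values[big, 3] - n2u$values[big, 3])), 1e-9)
  # the precision-weighted factors are only approximately depth-invariant
  n2w <- getmm_normalize(cm2)
  expect_lt(max(abs(n1$values[big, 3] - n2w$values[big, 3])), 0.02)

  expect_error(getmm_normalize(expression_matrix(
    cm$values, gene_lengths = rep(0, 300), scale = "counts")),
    class = "famendo_argument_error")
})

test_that("geTMM is invariant to sample reordering", {
  cm <- make_counts(n_genes = 200, seed = 12)
  n1 <- getmm_normalize(cm)
  perm <- c(4, 2, 6, 1, 3, 5)
  cmp <- expression_matrix(cm$values[, perm], cm$gene_lengths,
                           scale = "counts")
  n2 <- getmm_normalize(cmp)
  expect_equal(n2$values, n1$values[, perm], tolerance = 1e-12)
})

test_that("batch removal is exact on additive shifts and idempotent", {
  set.seed(21)
  x <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  batch <- rep(c("b1", "b2"), each = 10)
  x[, batch == "b2"] <- x[, batch == "b2"] + 1
  em <- expression_matrix(x, scale = "getmm_log")
  corr <- remove_batch(em, batch)
  bm1 <- rowMeans(corr$values[, batch == "b1"])
  bm2 <- rowMeans(corr$values[, batch == "b2"])
  expect_lt(max(abs(bm1 - bm2)), 1e-10)
  expect_equal(corr$scale, "batch_corrected")

  # idempotent
  corr2 <- remove_batch(corr, batch)
  expect_lt(max(abs(corr2$values - corr$values)), 1e-10)

  # single batch: identity
  same <- remove_batch(em, rep("b1", 20))
  expect_equal(same$values, em$values)
})

test_that("batch removal preserves protected covariate effects", {
  set.seed(22)
  n <- 40
  covar <- rnorm(n)
  batch <- rep(c("b1", "b2"), each = n / 2)
  y <- 2 * covar + (batch == "b2") * 1    # noiseless construction
  x <- rbind(gene1 = y)
  colnames(x) <- sprintf("s%02d", 1:n)
  em <- expression_matrix(x, scale = "getmm_log")
  corr <- remove_batch(em, batch, protect = cbind(covar))
  refit <- lm(corr$values[1, ] ~ covar + batch)
  expect_lt(abs(coef(refit)["covar"] - 2), 1e-6)
  expect_lt(abs(coef(refit)["batchb2"]), 1e-6)

  # confounded design errors out
  expect_error(remove_batch(em, batch, protect = cbind(as.numeric(batch == "b2"))),
               class = "famendo_design_error")
})

test_that("PCA scores behave like an SVD and flag degenerate input", {
  set.seed(31)
  x <- matrix(rnorm(30 * 10, sd = 1e-8), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  x[1, ] <- seq_len(10)  # exactly one gene varies appreciably
  x[2:30, ] <- 0
  p <- pca_scores(x, k = 2)
  expect_gte(attr(p, "var_explained")[1], 0.999)
  expect_lt(abs(sum(p$PC1 * p$PC2)), 1e-8)
  expect_true(all(diff(attr(p, "var_explained")) <= 1e-12))

  expect_error(pca_scores(matrix(1, 5, 5,
                                 dimnames = list(letters[1:5], letters[1:5])), 2),
               class = "famendo_degenerate_error")
})

test_that("PCA separates batches before removal and not after", {
  set.seed(32)
  G <- 200; n <- 100
  x <- matrix(rnorm(G * n), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%03d", 1:n)))
  batch <- rep(c("hiseq", "novaseq"), each = n / 2)
  shift <- rnorm(G, mean = 1, sd = 0.3)   # gene-specific instrument effect
  x[, batch == "novaseq"] <- x[, batch == "novaseq"] + shift
  em <- expression_matrix(x, scale = "getmm_log")
  t_of <- function(p) abs(t.test(p$PC1 ~ rep(c(0, 1), each = n / 2))$statistic)
  expect_gt(t_of(pca_scores(em, k = 2)), 5)
  corr <- remove_batch(em, batch)
  expect_lt(t_of(pca_scores(corr, k = 2)), 2)
})
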