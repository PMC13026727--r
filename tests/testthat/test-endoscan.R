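test_that("Fisher combination has its closed-form identities", {
  # single p inverts the transform exactly
  expect_equal(fisher_combine(0.2)$p_combined, 0.2, tolerance = 1e-12)
  r <- fisher_combine(c(1, 1, 1))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_combined, 1)
  expect_equal(r$df, 6L)
  expect_error(fisher_combine(c(0.5, 0)), class = "famendo_argument_error")
  expect_error(fisher_combine(c(0.5, 1.2)), class = "famendo_argument_error")
  expect_error(fisher_combine(numeric(0)), class = "famendo_argument_error")
})

test_that("Fisher combination matches a log-sum / incomplete-gamma oracle", {
  for (r in 1:100) {
    set.seed(r)
    p <- runif(sample(2:8, 1))
    got <- fisher_combine(p)
    s <- -sum(log(p))
    # chi-square upper tail via the regularized incomplete gamma
    p_oracle <- pgamma(s, shape = length(p), lower.tail = FALSE)
    expect_lt(abs(got$p_combined - p_oracle), 1e-10)
    expect_lt(abs(got$chi2 - 2 * s), 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up on random inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  for (r in 1:8) {
    set.seed(200 + r)
    p <- runif(sample(3:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    # monotone non-decreasing in sorted order of p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(numeric(0)), class = "famendo_argument_error")
})

test_that("a self-associated endophenotype is detected with beta near 1", {
  sh <- shared_study_A()
  d <- draw_trait(sh$eig, h2 = 0.5, seed = 71)
  n <- length(d$y)
  endo <- matrix(d$y - mean(d$y), n, 1,
                 dimnames = list(sh$ped$id, "G1"))
  phen <- tibble::tibble(id = sh$ped$id, trait = d$y)
  scan <- assoc_scan(endo, phen, sh$A, traits = "trait")
  expect_lt(scan$p, 1e-10)
  expect_lt(abs(scan$beta - 1), 0.05)
})

test_that("scan effects are antisymmetric under endophenotype negation", {
  sh <- shared_study_A()
  d <- draw_trait(sh$eig, h2 = 0.4, seed = 72)
  set.seed(73)
  e <- matrix(rnorm(2 * length(d$y)), ncol = 2,
              dimnames = list(sh$ped$id, c("Gp", "Gq")))
  phen <- tibble::tibble(id = sh$ped$id, trait = d$y)
  s1 <- assoc_scan(e, phen, sh$A, traits = "trait")
  s2 <- assoc_scan(-e, phen, sh$A, traits = "trait")
  expect_lt(max(abs(s1$beta + s2$beta)), 1e-10)
  expect_lt(max(abs(s1$p - s2$p)), 1e-10)
})

test_that("an injected causal endophenotype is found at small p", {
  sh <- shared_study_A()
  hits <- 0L
  for (r in 1:5) {
    d <- draw_trait(sh$eig, h2 = 0.3, seed = 80 + r)
    set.seed(90 + r)
    e_causal <- rnorm(length(d$y))
    y <- d$y + 0.5 * e_causal     # 0.5 SD effect
    endo <- cbind(Gc = e_causal)
    rownames(endo) <- sh$ped$id
    phen <- tibble::tibble(id = sh$ped$id, trait = y)
    s <- assoc_scan(endo, phen, sh$A, traits = "trait")
    if (s$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("zero-variance endophenotype columns are skipped, not fatal", {
  sh <- shared_study_A()
  d <- draw_trait(sh$eig, h2 = 0.4, seed = 74)
  endo <- cbind(Gflat = rep(1, length(d$y)), Gok = rnorm(length(d$y)))
  rownames(endo) <- sh$ped$id
  phen <- tibble::tibble(id = sh$ped$id, trait = d$y)
  expect_warning(s <- assoc_scan(endo, phen, sh$A, traits = "trait"),
                 "zero variance")
  expect_true(is.na(s$p[s$gene == "Gflat"]))
  expect_false(is.na(s$p[s$gene == "Gok"]))
})

test_that("multivariate fit reduces exactly to the univariate model at T = 1", {
  sh <- shared_study_A()
  d <- draw_trait(sh$eig, h2 = 0.5, seed = 75)
  Y <- matrix(d$y, ncol = 1, dimnames = list(sh$ped$id, "t1"))
  mf <- fit_multivariate(Y, A = sh$A)
  uf <- fit_polygenic(d$y, A = sh$A, eig = sh$eig)
  expect_lt(abs(mf$loglik - uf$loglik), 1e-6)
  expect_lt(abs(mf$Sigma_g[1, 1] - uf$sigma2_g), 1e-5)
  expect_lt(abs(mf$Sigma_e[1, 1] - uf$sigma2_e), 1e-5)
})

test_that("diagonal-constrained multivariate loglik sums the univariate ones", {
  sh <- shared_study_A()
  d1 <- draw_trait(sh$eig, h2 = 0.5, seed = 76)
  d2 <- draw_trait(sh$eig, h2 = 0.3, seed = 77)
  Y <- cbind(t1 = d1$y, t2 = d2$y)
  rownames(Y) <- sh$ped$id
  mf <- fit_multivariate(Y, A = sh$A, constrain_diag = TRUE)
  u1 <- fit_polygenic(d1$y, A = sh$A, eig = sh$eig, se = FALSE)
  u2 <- fit_polygenic(d2$y, A = sh$A, eig = sh$eig, se = FALSE)
  expect_lt(abs(mf$loglik - (u1$loglik + u2$loglik)), 1e-4)
})

test_that("the multivariate loglik agrees with a dense Kronecker oracle", {
  ped <- simulate_pedigree(3, 3, 3, seed = 78)
  A <- kinship_from_pedigree(ped)
  n <- nrow(A)
  set.seed(79)
  Y <- matrix(rnorm(2 * n), n, 2, dimnames = list(ped$id, c("a", "b")))
  X <- matrix(1, n, 1)
  mf <- fit_multivariate(Y, X, A)
  ll_dense <- dense_mvn_loglik(Y, X, A, mf$Sigma_g, mf$Sigma_e)
  expect_lt(abs(mf$loglik - ll_dense), 1e-5)
})

test_that("a simulated genetic correlation is recovered", {
  sh <- shared_study_A()
  n <- nrow(sh$A)
  fac <- sh$eig$vectors %*% diag(sqrt(pmax(sh$eig$values, 0)))
  rg_truth <- 0.6
  Sg <- matrix(c(0.5, rg_truth * 0.5, rg_truth * 0.5, 0.5), 2)
  Lg <- chol(Sg)
  est <- numeric(10)
  for (r in 1:10) {
    set.seed(300 + r)
    G <- fac %*% matrix(rnorm(2 * n), n, 2) %*% Lg
    E <- matrix(rnorm(2 * n, sd = sqrt(0.5)), n, 2)
    Y <- G + E
    dimnames(Y) <- list(sh$ped$id, c("a", "b"))
    mf <- fit_multivariate(Y, A = sh$A, seed = r)
    est[r] <- mf$Sigma_g[1, 2] / sqrt(mf$Sigma_g[1, 1] * mf$Sigma_g[2, 2])
  }
  expect_lt(abs(mean(est) - rg_truth), 0.15)
})

test_that("joint endophenotype test is calibrated under the null and guarded", {
  ped <- simulate_pedigree(5, 3, 4, seed = 81)
  A <- kinship_from_pedigree(ped)
  n <- nrow(A)
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  fac <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
  ps <- numeric(200)
  for (r in 1:200) {
    set.seed(400 + r)
    G <- fac %*% matrix(rnorm(2 * n), n, 2) * sqrt(0.4)
    Y <- G + matrix(rnorm(2 * n, sd = sqrt(0.6)), n, 2)
    dimnames(Y) <- list(ped$id, c("a", "b"))
    endo <- rnorm(n)   # independent of the traits
    ps[r] <- joint_endophenotype_test(Y, endo, A, n_starts = 1, seed = r)$p
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # power: endophenotype affecting one of the traits
  hits <- 0L
  for (r in 1:10) {
    set.seed(600 + r)
    G <- fac %*% matrix(rnorm(2 * n), n, 2) * sqrt(0.4)
    Y <- G + matrix(rnorm(2 * n, sd = sqrt(0.6)), n, 2)
    endo <- rnorm(n)
    Y[, 1] <- Y[, 1] + 0.5 * endo
    dimnames(Y) <- list(ped$id, c("a", "b"))
    if (joint_endophenotype_test(Y, endo, A, n_starts = 1, seed = r)$p < 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits, 7L)

  # trait-count guard and zero-variance guard
  Yg <- matrix(rnorm(7 * n), n, 7, dimnames = list(ped$id, paste0("t", 1:7)))
  expect_error(fit_multivariate(Yg, A = A), class = "famendo_resource_error")
  Yz <- cbind(a = rnorm(n), b = rep(0, n))
  rownames(Yz) <- ped$id
  expect_error(joint_endophenotype_test(Yz, rnorm(n), A),
               class = "famendo_argument_error")
})

test_that("combine_scan aggregates per-gene evidence across traits", {
  sh <- shared_study_A()
  d1 <- draw_trait(sh$eig, h2 = 0.4, seed = 85)
  d2 <- draw_trait(sh$eig, h2 = 0.4, seed = 86)
  set.seed(87)
  e_causal <- rnorm(length(d1$y))
  endo <- cbind(Gc = e_causal, Gn = rnorm(length(d1$y)))
  rownames(endo) <- sh$ped$id
  phen <- tibble::tibble(id = sh$ped$id,
                         t1 = d1$y + 0.4 * e_causal,
                         t2 = d2$y + 0.4 * e_causal)
  scan <- assoc_scan(endo, phen, sh$A, traits = c("t1", "t2"))
  comb <- combine_scan(scan)
  expect_equal(sort(comb$gene), c("Gc", "Gn"))
  expect_equal(unique(comb$df), 4L)
  expect_lt(comb$p_combined[comb$gene == "Gc"],
            comb$p_combined[comb$gene == "Gn"])
  # combined p equals the direct Fisher computation from the scan rows
  pc <- fisher_combine(scan$p[scan$gene == "Gc"])$p_combined
  expect_equal(comb$p_combined[comb$gene == "Gc"], pc, tolerance = 1e-12)
})
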