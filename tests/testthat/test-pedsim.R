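test_that("single-generation pedigrees contain only founders", {
  ped <- simulate_pedigree(1, 1, 3, seed = 1)
  expect_true(all(is.na(ped$father)))
  expect_true(all(is.na(ped$mother)))
  expect_true(all(ped$generation == 0))
})

test_that("pedigree simulation is seed-deterministic and structurally valid", {
  p1 <- simulate_pedigree(3, 3, 2.5, seed = 7)
  p2 <- simulate_pedigree(3, 3, 2.5, seed = 7)
  expect_identical(p1, p2)
  p3 <- simulate_pedigree(3, 3, 2.5, seed = 8)
  expect_false(identical(p1, p3))

  ped <- simulate_pedigree(20, 3, 3, seed = 11)
  expect_gte(nrow(ped), 20 * 2)      # at least the founding couples
  expect_equal(length(unique(sub("_.*", "", ped$id))), 20)
  # explicit ancestor-set traversal: nobody is their own ancestor
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    anc <- character(); frontier <- c(ped$father[i], ped$mother[i])
    frontier <- frontier[!is.na(frontier)]
    while (length(frontier)) {
      expect_false(ped$id[i] %in% frontier)
      anc <- union(anc, frontier)
      j <- idx[frontier]
      frontier <- setdiff(c(ped$father[j], ped$mother[j]), c(anc, NA))
    }
  }
  # parents exist and have the right sex
  expect_silent(validate_pedigree(ped))
})

test_that("pedigree simulation rejects non-positive arguments", {
  expect_error(simulate_pedigree(0, 3, 2, seed = 1), class = "famendo_argument_error")
  expect_error(simulate_pedigree(2, 0, 2, seed = 1), class = "famendo_argument_error")
  expect_error(simulate_pedigree(2, 3, -1, seed = 1), class = "famendo_argument_error")
})

test_that("expression simulation honours per-gene heritability", {
  ped <- simulate_pedigree(4, 3, 3, seed = 2)
  A <- kinship_from_pedigree(ped)
  sim <- simulate_expression(ped, A, n_genes = 3, h2 = c(0, 0.5, 1), seed = 3)
  expect_equal(unname(sim$truth$true_genetic_values[, 1]), rep(0, nrow(ped)))
  # determinism
  sim2 <- simulate_expression(ped, A, n_genes = 3, h2 = c(0, 0.5, 1), seed = 3)
  expect_identical(sim$expr, sim2$expr)
  expect_error(simulate_expression(ped, A, 2, h2 = c(0.5, 1.2), seed = 1),
               class = "famendo_argument_error")
})

test_that("parent-offspring covariance matches the closed form at h2 = 1", {
  # one parent-offspring pair, many replicate genes: cov of the simulated
  # values across genes estimates h2 * total_var * A_ij = 0.5
  ped <- ped_trio()
  A <- kinship_from_pedigree(ped)
  sim <- simulate_expression(ped, A, n_genes = 2000, h2 = 1, seed = 9)
  vals_dad <- sim$expr["dad", ]
  vals_kid <- sim$expr["kid", ]
  cv <- cov(vals_dad, vals_kid)
  # Monte-Carlo SE of a covariance of bivariate normals, var 1, cov 0.5
  mc_se <- sqrt((1 * 1 + 0.5^2) / 2000)
  expect_lt(abs(cv - 0.5), 3 * mc_se)
})

test_that("empirical genetic variance fraction matches the target h2", {
  sh <- shared_study_A()
  sim <- simulate_expression(sh$ped, sh$A, n_genes = 1000, h2 = 0.4, seed = 13)
  ratios <- apply(sim$truth$true_genetic_values, 2, var) /
    apply(sim$expr, 2, var)
  expect_lt(abs(mean(ratios) - 0.4), 0.02)
})

test_that("count simulation has the stated negative-binomial mean structure", {
  set.seed(1)
  n <- 500; G <- 50
  latent <- matrix(rnorm(n * G, sd = 0.5), n, G,
                   dimnames = list(sprintf("s%03d", 1:n), sprintf("g%02d", 1:G)))
  len <- rep(2000, G); lib <- rep(300, n)
  cnt <- simulate_counts(latent, len, lib, batch = rep("b1", n),
                         batch_offsets = c(b1 = 0), dispersion = 1e-8, seed = 4)
  mu_expected <- t(exp(latent)) * (len / 1000) * rep(lib, each = G)
  rel_err <- abs(rowMeans(cnt) - rowMeans(mu_expected)) / rowMeans(mu_expected)
  expect_lt(max(rel_err), 0.01)

  # batch offset enters the log mean additively
  batch <- rep(c("b1", "b2"), each = n / 2)
  cnt2 <- simulate_counts(latent, len, lib, batch,
                          batch_offsets = c(b1 = 0, b2 = 1),
                          dispersion = 0.05, seed = 5)
  lm1 <- mean(log(cnt2[, batch == "b1"] + 0.5))
  lm2 <- mean(log(cnt2[, batch == "b2"] + 0.5))
  expect_lt(abs((lm2 - lm1) - 1), 0.1)

  # all-zero latent, equal libraries: expected counts equal up to length
  latent0 <- matrix(0, n, 2, dimnames = list(rownames(latent), c("gA", "gB")))
  cnt3 <- simulate_counts(latent0, c(1000, 4000), lib, rep("b1", n),
                          c(b1 = 0), dispersion = 1e-8, seed = 6)
  expect_lt(abs(mean(cnt3["gB", ]) / mean(cnt3["gA", ]) - 4), 0.1)

  expect_error(simulate_counts(latent, -len, lib, rep("b1", n), c(b1 = 0)),
               class = "famendo_argument_error")
})

test_that("phenotype simulation wires causal genes and covariates as designed", {
  sh <- shared_study_A()
  sim <- simulate_expression(sh$ped, sh$A, n_genes = 5, h2 = 0.8, seed = 31)
  # a causal gene with effect 1 correlates positively with its phenotype
  causal <- tibble::tibble(gene = "G00001", phenotype = "AST", effect = 1)
  hits <- 0L
  for (r in 1:100) {
    ph <- simulate_phenotypes(sh$ped, sh$A, sim$truth, causal_genes = causal,
                              pheno_h2 = 0.3, seed = 500 + r)
    if (cor(ph$phenotypes$AST,
            sim$truth$true_genetic_values[, "G00001"]) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95)

  # null construction: no causal effect, no polygenic term, no covariates
  ph0 <- simulate_phenotypes(sh$ped, sh$A, sim$truth, pheno_h2 = 0,
                             covariate_effects = c(), seed = 77)
  f <- fit_polygenic(ph0$phenotypes$AST, A = sh$A, eig = sh$eig, se = FALSE)
  expect_lt(f$h2, 0.1)

  # determinism and unknown-gene error
  ph1 <- simulate_phenotypes(sh$ped, sh$A, sim$truth, causal_genes = causal,
                             seed = 42)
  ph2 <- simulate_phenotypes(sh$ped, sh$A, sim$truth, causal_genes = causal,
                             seed = 42)
  expect_identical(ph1$phenotypes, ph2$phenotypes)
  bad <- tibble::tibble(gene = "NOPE", phenotype = "AST", effect = 1)
  expect_error(simulate_phenotypes(sh$ped, sh$A, sim$truth, causal_genes = bad),
               class = "famendo_argument_error")
})
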