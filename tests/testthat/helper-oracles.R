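# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they verify: dense-matrix algebra
# instead of the eigen rotation, explicit enumeration instead of closed
# forms, direct recomputation of the TMM trim/weight formulas.

# dense-Cholesky (restricted) log-likelihood of y ~ N(Xb, sg*A + se*I),
# with b profiled by GLS
dense_loglik <- function(y, X, A, sg, se, method = "ML") {
  n <- length(y)
  V <- sg * A + se * diag(n)
  R <- chol(V)
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  quad <- sum(r * Vi_r)
  p <- ncol(X)
  if (method == "ML") {
    -0.5 * (n * log(2 * pi) + logdetV + quad)
  } else {
    -0.5 * ((n - p) * log(2 * pi) + logdetV +
            determinant(XtViX)$modulus[1] + quad)
  }
}

# dense BLUP: g = sg * A * V^-1 * (y - X beta)
dense_blup <- function(y, X, A, sg, se, beta) {
  n <- length(y)
  V <- sg * A + se * diag(n)
  drop(sg * A %*% solve(V, y - X %*% beta))
}

# dense Kronecker-covariance log-likelihood of the multivariate model,
# vec(Y) ~ N((I_T x X) vec(B), Sg x A + Se x I), B profiled by GLS
dense_mvn_loglik <- function(Y, X, A, Sg, Se) {
  n <- nrow(Y); T_ <- ncol(Y); p <- ncol(X)
  V <- kronecker(Sg, A) + kronecker(Se, diag(n))
  Xbig <- kronecker(diag(T_), X)
  yv <- as.vector(Y)
  R <- chol(V)
  Vi_y <- backsolve(R, forwardsolve(t(R), yv))
  Vi_X <- backsolve(R, forwardsolve(t(R), Xbig))
  XtViX <- crossprod(Xbig, Vi_X)
  b <- solve(XtViX, crossprod(Xbig, Vi_y))
  r <- yv - Xbig %*% b
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  -0.5 * (n * T_ * log(2 * pi) + 2 * sum(log(diag(R))) + sum(r * Vi_r))
}

# gene-dropping Monte Carlo estimate of the additive relationship matrix:
# founders get unique allele labels, children inherit one random allele from
# each parent; kinship is the identity-by-descent probability of two alleles
# drawn at random, averaged over drops. A = 2 * phi.
gene_drop_A <- function(ped, n_drops, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- ifelse(is.na(ped$father), 0L, idx[ped$father])
  mo <- ifelse(is.na(ped$mother), 0L, idx[ped$mother])
  # iterate until parents precede children
  placed <- logical(n); ord <- integer(0)
  while (length(ord) < n) {
    ready <- !placed & (fa == 0L | placed[pmax(fa, 1L)]) &
      (mo == 0L | placed[pmax(mo, 1L)])
    ord <- c(ord, which(ready)); placed[ready] <- TRUE
  }
  phi_sum <- matrix(0, n, n)
  phi_sq <- matrix(0, n, n)
  a1 <- integer(n); a2 <- integer(n)
  for (d in seq_len(n_drops)) {
    lab <- 0L
    for (i in ord) {
      if (fa[i] == 0L) {
        a1[i] <- lab + 1L; a2[i] <- lab + 2L; lab <- lab + 2L
      } else {
        a1[i] <- if (runif(1) < 0.5) a1[fa[i]] else a2[fa[i]]
        a2[i] <- if (runif(1) < 0.5) a1[mo[i]] else a2[mo[i]]
      }
    }
    ibd <- (outer(a1, a1, "==") + outer(a1, a2, "==") +
            outer(a2, a1, "==") + outer(a2, a2, "==")) / 4
    phi_sum <- phi_sum + ibd
    phi_sq <- phi_sq + ibd^2
  }
  A <- 2 * phi_sum / n_drops
  v <- phi_sq / n_drops - (phi_sum / n_drops)^2
  se <- 2 * sqrt(pmax(v, 0) / n_drops)     # per-entry MC standard error of A
  dimnames(A) <- list(ped$id, ped$id)
  attr(A, "mc_se") <- se
  A
}

# direct recomputation of TMM factors from the trim/weight definitions
tmm_oracle <- function(rpk, trim_M = 0.30, trim_A = 0.05) {
  x <- rpk[rowSums(rpk) > 0, , drop = FALSE]
  lib <- colSums(x)
  f75 <- apply(x, 2, function(col) quantile(col, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  nr <- x[, ref]; Nr <- lib[ref]
  f <- numeric(ncol(x))
  for (s in seq_len(ncol(x))) {
    ns <- x[, s]; Ns <- lib[s]
    ok <- ns > 0 & nr > 0
    M <- log2((ns[ok] / Ns) / (nr[ok] / Nr))
    A <- 0.5 * log2((ns[ok] / Ns) * (nr[ok] / Nr))
    w <- (Ns - ns[ok]) / (Ns * ns[ok]) + (Nr - nr[ok]) / (Nr * nr[ok])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    nG <- length(M)
    loM <- floor(nG * trim_M) + 1; hiM <- nG + 1 - loM
    loA <- floor(nG * trim_A) + 1; hiA <- nG + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    fval <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
    if (!is.finite(fval) || abs(fval) < 1e-6) fval <- 0
    f[s] <- 2^fval
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(x))
}

# brute-force Benjamini-Hochberg step-up
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exhaustive hypergeometric upper tail: P(overlap >= k) over all C(N, n)
# query draws from a universe of size N containing a term of size K
hyper_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  term <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% term) >= k))
}

# small deterministic pedigree builders
ped_trio <- function() {
  tibble::tibble(id = c("dad", "mom", "kid"),
                 father = c(NA, NA, "dad"),
                 mother = c(NA, NA, "mom"),
                 sex = c("male", "female", "female"))
}

ped_sibs <- function() {
  tibble::tibble(id = c("dad", "mom", "s1", "s2"),
                 father = c(NA, NA, "dad", "dad"),
                 mother = c(NA, NA, "mom", "mom"),
                 sex = c("male", "female", "male", "female"))
}

# half-sib mating: f1 with m1 and m2; child of (c1 male, c2 female) who share
# father f1 -> inbred grandchild
ped_halfsib_mating <- function() {
  tibble::tibble(
    id = c("f1", "m1", "m2", "c1", "c2", "gc"),
    father = c(NA, NA, NA, "f1", "f1", "c1"),
    mother = c(NA, NA, NA, "m1", "m2", "c2"),
    sex = c("male", "female", "female", "male", "female", "male"))
}

# shared medium pedigree + eigendecomposition for the heavier model tests
shared_study_A <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- famendo::simulate_pedigree(20, 3, 4.5, seed = 21)
      A <- famendo::kinship_from_pedigree(ped)
      cache <<- list(ped = ped, A = A,
                     eig = eigen((A + t(A)) / 2, symmetric = TRUE))
    }
    cache
  }
})

# draw a trait with given h2 on a relationship matrix using the cached eigen
draw_trait <- function(eig, h2, seed) {
  set.seed(seed)
  n <- length(eig$values)
  fac_z <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * rnorm(n))
  g <- sqrt(h2) * drop(fac_z)
  list(y = g + rnorm(n, sd = sqrt(1 - h2)), g = g)
}
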