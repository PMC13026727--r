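#' Fisher's combined probability test
#'
#' Combines k p-values into one joint test: `chi2 = -2 * sum(log(p))` is
#' referred to chi-square with `2k` degrees of freedom. Valid under
#' independence of the component tests; with positively correlated traits the
#' combined p is anti-conservative and should be read as a lower bound.
#'
#' @param pvalues numeric p-values in `(0, 1]`.
#' @param gene_id optional id carried into the result.
#' @param trait_set optional label for the set of traits combined.
#' @return a tibble with `gene_id`, `trait_set`, `chi2`, `df`, `p_combined`.
#' @examples
#' fisher_combine(c(0.01, 0.04, 0.3))
#' @export
fisher_combine <- function(pvalues, gene_id = NA_character_,
                           trait_set = NA_character_) {
  if (!length(pvalues))
    abort("At least one p-value is required.", class = "famendo_argument_error")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    abort("All p-values must lie in (0, 1].", class = "famendo_argument_error")
  chi2 <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  tibble(gene_id = gene_id, trait_set = trait_set, chi2 = chi2, df = df,
         p_combined = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment:
#' `q_(i) = min over j >= i of m * p_(j) / j`, capped at 1, returned in the
#' original order.
#'
#' @param pvalues numeric p-values in `(0, 1]`.
#' @return numeric q-values aligned to the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues))
    abort("Empty p-value vector.", class = "famendo_argument_error")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    abort("All p-values must lie in (0, 1].", class = "famendo_argument_error")
  p.adjust(pvalues, method = "BH")
}

#' Kinship-aware endophenotype association scan
#'
#' For every (gene, phenotype) pair, fits the polygenic mixed model of the
#' prepared phenotype with fixed effects `[intercept, covariates,
#' endophenotype]` and reports the Wald test of the endophenotype
#' coefficient (`p = 2 * pnorm(-|beta / se|)`). Within each phenotype,
#' q-values are Benjamini-Hochberg over all genes. Missing phenotype values
#' are dropped per phenotype (the relationship matrix is subset and
#' re-eigendecomposed once per phenotype, then shared across genes).
#'
#' @param endo samples x genes endophenotype matrix (rownames = sample ids).
#' @param phenos prepared phenotype tibble (`id` plus trait columns; see
#'   [prepare_phenotypes()]).
#' @param A relationship matrix.
#' @param covariates optional samples x covariates numeric matrix.
#' @param traits trait columns to scan (default: all non-id/age/sex columns).
#' @param method `"ML"` or `"REML"`.
#' @return tibble of class `endo_scan`: `gene`, `phenotype`, `n`, `beta`,
#'   `se`, `p`, `q` (genes with zero-variance endophenotype columns get `NA`
#'   records and a warning count).
#' @export
assoc_scan <- function(endo, phenos, A, covariates = NULL, traits = NULL,
                       method = "ML") {
  if (is.null(traits))
    traits <- setdiff(names(phenos), c("id", "age", "sex", "batch"))
  ids <- phenos$id
  if (!all(ids %in% rownames(endo)))
    abort("Phenotype ids missing from the endophenotype matrix.",
          class = "famendo_argument_error")
  endo <- endo[ids, , drop = FALSE]
  A <- align_matrix(A, ids)
  genes <- colnames(endo)
  zero_var <- apply(endo, 2, function(v) sd(v) == 0 || anyNA(v))
  if (any(zero_var))
    warn(sprintf("%d endophenotype column(s) with zero variance or NA skipped.",
                 sum(zero_var)))
  res <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    y <- phenos[[tr]]
    keep <- which(!is.na(y))
    ys <- y[keep]
    As <- A[keep, keep]
    eig <- relationship_eigen(As)
    covs <- if (!is.null(covariates)) covariates[keep, , drop = FALSE]
    rows <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
      if (zero_var[gi]) {
        rows[[gi]] <- tibble(gene = genes[gi], phenotype = tr,
                             n = NA_integer_, beta = NA_real_,
                             se = NA_real_, p = NA_real_)
        next
      }
      X <- cbind(`(Intercept)` = 1, covs, endo = endo[keep, gi])
      fit <- fit_polygenic(ys, X, As, method = method, eig = eig, se = FALSE)
      b <- unname(fit$beta["endo"])
      s <- sqrt(fit$beta_cov[ncol(X), ncol(X)])
      rows[[gi]] <- tibble(gene = genes[gi], phenotype = tr, n = fit$n,
                           beta = b, se = s,
                           p = 2 * pnorm(-abs(b / s)))
    }
    tab <- dplyr::bind_rows(rows)
    ok <- !is.na(tab$p)
    tab$q <- NA_real_
    if (any(ok)) tab$q[ok] <- bh_adjust(pmax(tab$p[ok], 1e-300))
    res[[ti]] <- tab
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("endo_scan", class(out))
  out
}

#' Combine scan p-values per gene across a trait set
#'
#' Fisher's combined test per gene over the chosen traits, with Bonferroni
#' (default report column) and Benjamini-Hochberg multiplicity control across
#' genes.
#'
#' @param scan an `endo_scan` tibble from [assoc_scan()].
#' @param traits traits to combine (default: all present).
#' @return tibble: `gene`, `trait_set`, `chi2`, `df`, `p_combined`,
#'   `p_bonferroni`, `p_bh`.
#' @export
combine_scan <- function(scan, traits = NULL) {
  if (is.null(traits)) traits <- unique(scan$phenotype)
  sub <- scan[scan$phenotype %in% traits & !is.na(scan$p), , drop = FALSE]
  set_label <- paste(traits, collapse = "+")
  out <- sub |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(fisher_combine(.data$p, gene_id = .data$gene[1],
                                    trait_set = set_label),
                     .groups = "drop") |>
    dplyr::select(-"gene_id")
  m <- nrow(out)
  out$p_bonferroni <- pmin(out$p_combined * m, 1)
  out$p_bh <- bh_adjust(pmax(out$p_combined, 1e-300))
  out
}

#' @method autoplot endo_scan
#' @export
autoplot.endo_scan <- function(object, ...) {
  dat <- object[!is.na(object$p), , drop = FALSE]
  ggplot(dat, aes(x = .data$beta, y = -log10(.data$p))) +
    geom_point(alpha = 0.6) +
    facet_wrap(~phenotype, scales = "free_x") +
    labs(x = "endophenotype effect (beta)", y = "-log10 p") +
    theme_minimal()
}

#' Multivariate polygenic mixed model
#'
#' Joint model of T traits: `vec(Y) ~ N((I_T (x) X) vec(B),
#' Sigma_g (x) A + Sigma_e (x) I)`. Rotating by the eigenvectors of `A`
#' decouples the observations; simultaneously diagonalizing `Sigma_g` against
#' `Sigma_e` then decouples the traits, so each likelihood evaluation costs
#' O(nT) after the one-off eigendecomposition. `Sigma_g` and `Sigma_e` are
#' parameterized through Cholesky factors (log-diagonal) and maximized by
#' quasi-Newton with multiple seeded starts; fixed effects are profiled
#' exactly at every step.
#'
#' @param Y samples x traits numeric matrix (complete cases kept listwise).
#' @param X fixed-effect design (default intercept).
#' @param A relationship matrix (rownames matching `Y`'s).
#' @param constrain_diag force `Sigma_g` and `Sigma_e` diagonal (no genetic
#'   or environmental cross-covariance).
#' @param n_starts number of optimizer starts (first start at the univariate
#'   fits, the rest jittered).
#' @param seed seed for the jittered starts.
#' @return a `multivar_fit`: `Sigma_g`, `Sigma_e`, `B`, `loglik`,
#'   `converged`, `n`, `T`.
#' @export
fit_multivariate <- function(Y, X = NULL, A, constrain_diag = FALSE,
                             n_starts = 3, seed = 1) {
  Y <- as.matrix(Y)
  T_ <- ncol(Y)
  if (T_ > 6)
    abort("At most 6 traits are supported (parameter count guard).",
          class = "famendo_resource_error")
  keep <- which(complete.cases(Y))
  Ys <- Y[keep, , drop = FALSE]
  n <- nrow(Ys)
  if (is.null(X)) X <- matrix(1, nrow(Y), 1)
  Xs <- X[keep, , drop = FALSE]
  p <- ncol(Xs)
  As <- if (!is.null(rownames(Y))) align_matrix(A, rownames(Y)[keep])
        else A[keep, keep]
  eig <- relationship_eigen(As)
  lambda <- eig$values
  tY <- crossprod(eig$vectors, Ys)
  tX <- crossprod(eig$vectors, Xs)

  k <- if (constrain_diag) T_ else T_ * (T_ + 1) / 2
  build_chol <- function(par) {
    L <- matrix(0, T_, T_)
    if (constrain_diag) {
      diag(L) <- exp(par)
    } else {
      diag(L) <- exp(par[seq_len(T_)])
      if (T_ > 1) L[lower.tri(L)] <- par[-seq_len(T_)]
    }
    L
  }
  # profiled negative log-likelihood over the two Cholesky factors
  negll <- function(theta) {
    Lg <- build_chol(theta[seq_len(k)])
    Le <- build_chol(theta[k + seq_len(k)])
    Sg <- tcrossprod(Lg); Se <- tcrossprod(Le)
    Le_inv <- forwardsolve(Le, diag(T_))  # Le^-1 (lower triangular)
    M <- Le_inv %*% Sg %*% t(Le_inv)
    em <- eigen((M + t(M)) / 2, symmetric = TRUE)
    d <- pmax(em$values, 0)
    Tr <- t(Le_inv) %*% em$vectors            # y* = Tr' y  (T x T transform)
    Ystar <- tY %*% Tr
    ll <- -0.5 * n * T_ * log(2 * pi) - n * sum(log(diag(Le)))
    for (t in seq_len(T_)) {
      v <- lambda * d[t] + 1
      w <- 1 / v
      XtWX <- crossprod(tX, tX * w)
      bt <- solve(XtWX, crossprod(tX, Ystar[, t] * w))
      r <- Ystar[, t] - drop(tX %*% bt)
      ll <- ll - 0.5 * (sum(log(v)) + sum(w * r^2))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # starts: univariate fits give the diagonal; jitter the rest
  uni <- vapply(seq_len(T_), function(t) {
    f <- fit_polygenic(Ys[, t], Xs, As, eig = eig, se = FALSE)
    c(f$sigma2_g, f$sigma2_e)
  }, numeric(2))
  start0 <- c(
    if (constrain_diag) 0.5 * log(pmax(uni[1, ], 1e-4))
    else c(0.5 * log(pmax(uni[1, ], 1e-4)), rep(0, k - T_)),
    if (constrain_diag) 0.5 * log(pmax(uni[2, ], 1e-4))
    else c(0.5 * log(pmax(uni[2, ], 1e-4)), rep(0, k - T_))
  )
  withr_seed(seed)
  starts <- list(start0)
  if (n_starts > 1)
    for (s in seq_len(n_starts - 1))
      starts[[s + 1]] <- start0 + rnorm(length(start0), sd = 0.3)
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(st, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) tryCatch(
        optim(st, negll, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e2) NULL))
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    abort("Multivariate fit failed to converge from any start.",
          class = "famendo_fit_error")
  theta <- best$par
  Lg <- build_chol(theta[seq_len(k)]); Le <- build_chol(theta[k + seq_len(k)])
  Sg <- tcrossprod(Lg); Se <- tcrossprod(Le)
  # recover profiled B at the optimum
  Le_inv <- forwardsolve(Le, diag(T_))
  M <- Le_inv %*% Sg %*% t(Le_inv)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(em$values, 0)
  Tr <- t(Le_inv) %*% em$vectors
  Ystar <- tY %*% Tr
  Bstar <- matrix(0, p, T_)
  for (t in seq_len(T_)) {
    w <- 1 / (lambda * d[t] + 1)
    Bstar[, t] <- solve(crossprod(tX, tX * w), crossprod(tX, Ystar[, t] * w))
  }
  B <- Bstar %*% solve(Tr)  # mean(Ystar) = X B Tr  =>  B = Bstar Tr^-1
  dimnames(Sg) <- dimnames(Se) <- list(colnames(Y), colnames(Y))
  structure(list(Sigma_g = Sg, Sigma_e = Se, B = B, loglik = -best$value,
                 converged = best$convergence == 0, n = n, T = T_,
                 constrain_diag = constrain_diag),
            class = "multivar_fit")
}

#' @export
print.multivar_fit <- function(x, ...) {
  cat(sprintf("<multivar_fit> %d traits, n = %d, loglik = %.3f\n",
              x$T, x$n, x$loglik))
  invisible(x)
}

#' @method glance multivar_fit
#' @export
glance.multivar_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_traits = x$T, nobs = x$n,
         converged = x$converged)
}

#' Joint multivariate test of an endophenotype
#'
#' Likelihood-ratio test between multivariate polygenic fits with and without
#' the endophenotype as a fixed effect for every trait; the statistic is
#' referred to chi-square with T degrees of freedom (one endophenotype
#' coefficient per trait). Provides a phenotype-level joint test of
#' association for one transcript.
#'
#' @param Y samples x traits matrix of prepared phenotypes.
#' @param endo_gene numeric endophenotype values aligned to `Y`'s rows.
#' @param A relationship matrix.
#' @param covariates optional numeric covariate matrix.
#' @param ... passed to [fit_multivariate()].
#' @return tibble with `lrt`, `df`, `p`.
#' @export
joint_endophenotype_test <- function(Y, endo_gene, A, covariates = NULL, ...) {
  Y <- as.matrix(Y)
  if (any(apply(Y, 2, function(col) {
        v <- col[!is.na(col)]
        length(v) == 0 || sd(v) == 0
      })))
    abort("Zero-variance trait column in Y.", class = "famendo_argument_error")
  X0 <- cbind(`(Intercept)` = rep(1, nrow(Y)), covariates)
  X1 <- cbind(X0, endo = endo_gene)
  f0 <- fit_multivariate(Y, X0, A, ...)
  f1 <- fit_multivariate(Y, X1, A, ...)
  lrt <- max(0, 2 * (f1$loglik - f0$loglik))
  tibble(lrt = lrt, df = ncol(Y),
         p = pchisq(lrt, df = ncol(Y), lower.tail = FALSE))
}
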