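#' Fit a univariate polygenic mixed model
#'
#' Model: `y = X beta + g + e` with `Cov(y) = sigma2_g * A + sigma2_e * I`,
#' where `A` is the additive relationship matrix. The relationship matrix is
#' eigendecomposed once (`A = U L U'`); rotating `y` and `X` by `U'`
#' diagonalizes the covariance, so for any candidate heritability
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` the fixed effects and the total
#' variance have closed-form (weighted least squares) profiles. The profiled
#' (restricted) log-likelihood is maximized over `h2` in `[0, 1]` by bounded
#' scalar optimization; the endpoints are evaluated explicitly so boundary
#' optima are found exactly.
#'
#' @param y numeric trait vector aligned to `A`'s roster (`NA` allowed;
#'   rows are dropped and the eigendecomposition recomputed on the subset).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param A additive relationship matrix with id dimnames.
#' @param method `"ML"` (default) or `"REML"`.
#' @param h2_fixed optionally fix `h2` (e.g. 0 for the null model of a
#'   heritability test) instead of estimating it.
#' @param eig optional precomputed `relationship_eigen(A)`; only used when
#'   `y` has no missing values.
#' @param se compute a standard error for `h2` by central finite difference
#'   of the profiled log-likelihood (step 1e-4; one-sided at boundaries).
#' @return a `polygenic_fit` object: `sigma2_g`, `sigma2_e`, `h2`, `se_h2`,
#'   `beta`, `loglik`, `method`, `converged`, `boundary`, `n`, and the index
#'   of retained rows (`keep`).
#' @examples
#' ped <- simulate_pedigree(5, 3, 3, seed = 2)
#' A <- kinship_from_pedigree(ped)
#' sim <- simulate_expression(ped, A, n_genes = 1, h2 = 0.6, seed = 3)
#' fit <- fit_polygenic(sim$expr[, 1], A = A)
#' glance(fit)
#' @export
fit_polygenic <- function(y, X = NULL, A, method = c("ML", "REML"),
                          h2_fixed = NULL, eig = NULL, se = TRUE) {
  method <- match.arg(method)
  n_all <- nrow(A)
  if (length(y) != n_all)
    abort("`y` must align with the relationship matrix roster.",
          class = "famendo_argument_error")
  if (is.null(X)) X <- matrix(1, n_all, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- which(!is.na(y) & stats::complete.cases(X))
  n <- length(keep)
  if (n <= ncol(X) + 1)
    abort("Too few non-missing observations for the design.",
          class = "famendo_argument_error")
  ys <- y[keep]; Xs <- X[keep, , drop = FALSE]
  if (qr(Xs)$rank < ncol(Xs))
    abort("Fixed-effect design is rank deficient.", class = "famendo_design_error")
  if (n < n_all || is.null(eig)) eig <- relationship_eigen(A[keep, keep])
  lambda <- eig$values
  ty <- drop(crossprod(eig$vectors, ys))
  tX <- crossprod(eig$vectors, Xs)

  # with all eigenvalues equal (e.g. A = I) the likelihood depends on the
  # variance components only through their sum: h2 is unidentifiable
  identifiable <- (max(lambda) - min(lambda)) > 1e-8
  core <- polygenic_profile(ty, tX, lambda, method)
  if (is.null(h2_fixed)) {
    opt <- optimize(core$negll, interval = c(0, 1), tol = 1e-8)
    cand_h2 <- c(opt$minimum, 0, 1)
    cand_ll <- -vapply(cand_h2, core$negll, numeric(1))
    best <- which.max(cand_ll)
    h2_hat <- cand_h2[best]; ll <- cand_ll[best]
  } else {
    if (h2_fixed < 0 || h2_fixed > 1)
      abort("`h2_fixed` must lie in [0, 1].", class = "famendo_argument_error")
    h2_hat <- h2_fixed; ll <- -core$negll(h2_fixed)
  }
  at <- core$at(h2_hat)
  converged <- is.finite(ll)
  boundary <- is.null(h2_fixed) && (h2_hat < 1e-6 || h2_hat > 1 - 1e-6)

  se_h2 <- NA_real_
  if (se && is.null(h2_fixed) && converged) {
    step <- 1e-4
    pts <- if (h2_hat < step) c(0, step, 2 * step)
           else if (h2_hat > 1 - step) c(1 - 2 * step, 1 - step, 1)
           else h2_hat + c(-step, 0, step)
    f <- -vapply(pts, core$negll, numeric(1))
    d2 <- (f[1] - 2 * f[2] + f[3]) / step^2
    if (is.finite(d2) && d2 < 0) se_h2 <- sqrt(-1 / d2)
  }
  structure(list(
    sigma2_g = h2_hat * at$s2p, sigma2_e = (1 - h2_hat) * at$s2p,
    h2 = h2_hat, se_h2 = se_h2,
    beta = setNames(at$beta, colnames(Xs)),
    beta_cov = at$beta_cov,
    loglik = ll, method = method, converged = converged,
    boundary = boundary, identifiable = identifiable, n = n, keep = keep,
    roster = rownames(A)[keep]
  ), class = "polygenic_fit")
}

# Profiled likelihood machinery in the rotated basis. For candidate h2 the
# per-observation variance is s2p * (h2*lambda_i + 1 - h2); beta by WLS and
# s2p in closed form; returns the negative profiled log-likelihood and the
# profile quantities at a point.
polygenic_profile <- function(ty, tX, lambda, method) {
  n <- length(ty); p <- ncol(tX)
  at <- function(h2) {
    v0 <- h2 * lambda + (1 - h2)
    if (any(v0 <= 1e-12))
      return(list(s2p = NA_real_, beta = rep(NA_real_, p), ll = -Inf,
                  beta_cov = matrix(NA_real_, p, p)))
    w <- 1 / v0
    XtWX <- crossprod(tX, tX * w)
    XtWy <- crossprod(tX, ty * w)
    beta <- drop(solve(XtWX, XtWy))
    r <- ty - drop(tX %*% beta)
    rss <- sum(w * r^2)
    if (method == "ML") {
      s2p <- rss / n
      ll <- -0.5 * (n * log(2 * pi) + n * log(s2p) + sum(log(v0)) + n)
    } else {
      s2p <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2p) +
                    sum(log(v0)) + determinant(XtWX)$modulus[1] + (n - p))
    }
    list(s2p = s2p, beta = beta, ll = ll, beta_cov = s2p * solve(XtWX))
  }
  list(at = at, negll = function(h2) -at(h2)$ll)
}

#' Log-likelihood of the polygenic model at a parameter point
#'
#' Evaluates the (restricted) log-likelihood at given variance components,
#' with fixed effects profiled by generalized least squares, using the
#' eigen-rotated representation. Useful for cross-checking against a dense
#' Cholesky evaluation.
#'
#' @inheritParams fit_polygenic
#' @param sigma2_g,sigma2_e variance components (non-negative, not both 0).
#' @return log-likelihood (scalar).
#' @export
loglik_polygenic <- function(y, X = NULL, A, sigma2_g, sigma2_e,
                             method = c("ML", "REML"), eig = NULL) {
  method <- match.arg(method)
  n <- nrow(A)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(eig)) eig <- relationship_eigen(A)
  ty <- drop(crossprod(eig$vectors, y))
  tX <- crossprod(eig$vectors, X)
  v <- sigma2_g * eig$values + sigma2_e
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  XtWX <- crossprod(tX, tX * w)
  beta <- drop(solve(XtWX, crossprod(tX, ty * w)))
  r <- ty - drop(tX %*% beta)
  quad <- sum(w * r^2)
  p <- ncol(tX)
  if (method == "ML") {
    -0.5 * (n * log(2 * pi) + sum(log(v)) + quad)
  } else {
    -0.5 * ((n - p) * log(2 * pi) + sum(log(v)) +
            determinant(XtWX)$modulus[1] + quad)
  }
}

#' Likelihood-ratio test for heritability
#'
#' Compares a fitted polygenic model against the null with the genetic
#' variance constrained to zero. Because the null pins a variance component
#' to its boundary, the statistic is referred to an equal mixture of a point
#' mass at zero and chi-square with 1 df: `p = 0.5 * P(chisq_1 >= LRT)`.
#'
#' @param fit_full fit with `h2` free.
#' @param fit_null fit of the same data/design with `h2_fixed = 0`.
#' @return a tibble with `lrt`, `df`, `p`.
#' @export
h2_test <- function(fit_full, fit_null) {
  if (fit_full$n != fit_null$n ||
      !identical(fit_full$roster, fit_null$roster))
    abort("Full and null fits must use the same samples.",
          class = "famendo_argument_error")
  if (fit_full$method != fit_null$method)
    abort("Full and null fits must use the same likelihood method.",
          class = "famendo_argument_error")
  lrt <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  p <- 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  tibble(lrt = lrt, df = 1, p = p)
}

#' BLUP genetic values (endophenotypes)
#'
#' Best linear unbiased prediction of the additive genetic values:
#' `g_hat = sigma2_g * A * V^-1 * (y - X beta_hat)` with
#' `V = sigma2_g * A + sigma2_e * I`, computed in the rotated basis where the
#' multiplier is the diagonal shrinkage `sigma2_g * lambda / (sigma2_g *
#' lambda + sigma2_e)` — no explicit matrix inverse.
#'
#' @param fit a converged `polygenic_fit`.
#' @param y,X,A the data the fit was computed on.
#' @param eig optional precomputed eigendecomposition of the retained
#'   submatrix of `A`.
#' @return named numeric vector of genetic values aligned to the retained
#'   roster (samples dropped for missingness get `NA`).
#' @export
blup <- function(fit, y, X = NULL, A, eig = NULL) {
  if (!fit$converged)
    abort("Fit did not converge; BLUP is undefined.", class = "famendo_fit_error")
  n_all <- nrow(A)
  if (is.null(X)) X <- matrix(1, n_all, 1)
  keep <- fit$keep
  out <- setNames(rep(NA_real_, n_all), rownames(A))
  if (fit$sigma2_g == 0 && fit$sigma2_e == 0)
    abort("Both variance components are zero: V is singular.",
          class = "famendo_fit_error")
  if (fit$sigma2_g == 0) {
    out[keep] <- 0
    return(out)
  }
  ys <- y[keep]; Xs <- X[keep, , drop = FALSE]
  if (is.null(eig)) eig <- relationship_eigen(A[keep, keep])
  r <- ys - drop(Xs %*% fit$beta)
  tr <- drop(crossprod(eig$vectors, r))
  shrink <- fit$sigma2_g * eig$values /
    (fit$sigma2_g * eig$values + fit$sigma2_e)
  out[keep] <- drop(eig$vectors %*% (shrink * tr))
  out
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("<polygenic_fit> %s: h2 = %.3f (SE %.3f), loglik = %.3f, n = %d%s\n",
              x$method, x$h2, x$se_h2, x$loglik, x$n,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @method tidy polygenic_fit
#' @export
tidy.polygenic_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = sqrt(diag(x$beta_cov)))
}

#' @method glance polygenic_fit
#' @export
glance.polygenic_fit <- function(x, ...) {
  tibble(h2 = x$h2, se_h2 = x$se_h2, sigma2_g = x$sigma2_g,
         sigma2_e = x$sigma2_e, logLik = x$loglik, method = x$method,
         converged = x$converged, boundary = x$boundary, nobs = x$n)
}

#' Heritability fits for every column of an expression matrix
#'
#' Fits the polygenic model to each (prepared) expression trait, reusing one
#' eigendecomposition of the relationship matrix, and predicts the BLUP
#' genetic values — the endophenotype matrix.
#'
#' @param expr samples x genes numeric matrix (prepared traits; no missing).
#' @param A relationship matrix over the samples.
#' @param X fixed-effect design (default intercept).
#' @param method `"ML"` or `"REML"`.
#' @param test also fit the null model and report the boundary-corrected
#'   likelihood-ratio p-value per gene (default TRUE).
#' @return list with `fits` (tibble: gene, h2, se_h2, sigma2_g, sigma2_e,
#'   loglik, p, converged, boundary, n) and `endo` (samples x genes BLUP
#'   matrix; a gene whose fitted genetic variance is zero yields a zero
#'   column).
#' @export
endophenotypes <- function(expr, A, X = NULL, method = "ML", test = TRUE) {
  if (is.null(rownames(expr)))
    abort("`expr` needs sample rownames.", class = "famendo_argument_error")
  A <- align_matrix(A, rownames(expr))
  eig <- relationship_eigen(A)
  genes <- colnames(expr)
  endo <- matrix(NA_real_, nrow(expr), length(genes),
                 dimnames = dimnames(expr))
  rows <- vector("list", length(genes))
  for (j in seq_along(genes)) {
    yj <- expr[, j]
    fit <- fit_polygenic(yj, X, A, method = method, eig = eig)
    p <- NA_real_
    if (test) {
      fit0 <- fit_polygenic(yj, X, A, method = method, h2_fixed = 0,
                            eig = eig, se = FALSE)
      p <- h2_test(fit, fit0)$p
    }
    endo[, j] <- blup(fit, yj, X, A, eig = eig)
    rows[[j]] <- tibble(gene = genes[j], h2 = fit$h2, se_h2 = fit$se_h2,
                        sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                        loglik = fit$loglik, p = p,
                        converged = fit$converged, boundary = fit$boundary,
                        n = fit$n)
  }
  list(fits = dplyr::bind_rows(rows), endo = endo)
}
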