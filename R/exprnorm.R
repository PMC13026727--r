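#' Expression matrix container
#'
#' A light container for genes x samples expression values plus per-gene
#' lengths and a scale tag tracking what the values currently are:
#' `counts` (raw), `rpk` (reads per kilobase), `getmm_log` (log2 geTMM) or
#' `batch_corrected`.
#'
#' @param values genes x samples numeric matrix with dimnames.
#' @param gene_lengths per-gene lengths in bp (named or in row order).
#' @param scale one of `"counts"`, `"rpk"`, `"getmm_log"`, `"batch_corrected"`.
#' @return an `expr_matrix` object.
#' @export
expression_matrix <- function(values, gene_lengths = NULL,
                              scale = c("counts", "rpk", "getmm_log",
                                        "batch_corrected")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    abort("`values` must be a matrix with gene and sample dimnames.",
          class = "famendo_argument_error")
  if (anyDuplicated(rownames(values)))
    abort("Gene ids must be unique.", class = "famendo_argument_error")
  if (scale %in% c("counts", "rpk") && any(values < 0))
    abort(sprintf("Negative entries are not allowed on the %s scale.", scale),
          class = "famendo_argument_error")
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths))) names(gene_lengths) <- rownames(values)
    gene_lengths <- gene_lengths[rownames(values)]
    if (anyNA(gene_lengths))
      abort("`gene_lengths` must cover every gene.", class = "famendo_argument_error")
  }
  structure(list(values = values, gene_lengths = gene_lengths, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Trimmed mean of M-values scaling factors
#'
#' Computes TMM scaling factors on a reads-per-kilobase matrix (the geTMM
#' recipe): the reference sample is the one whose upper-quartile fraction is
#' closest to the mean of those fractions; per-sample factors are
#' `2^(weighted mean of M)` over genes surviving the M and A trims, with
#' inverse asymptotic-variance weights, rescaled to geometric mean 1.
#' The computation is delegated to the canonical TMM implementation in edgeR;
#' genes that are zero in every sample are dropped first (with a message).
#'
#' @param rpk an `expr_matrix` on the `rpk` scale (or a bare matrix).
#' @param trim_M fraction of extreme M-values trimmed from each tail (default 0.30).
#' @param trim_A fraction of extreme A-values trimmed from each tail (default 0.05).
#' @param weighted use inverse asymptotic-variance weights for the trimmed
#'   mean (default TRUE, the canonical definition). With `weighted = FALSE`
#'   the factors are exactly invariant to rescaling a single sample's
#'   library; the weighted version is only approximately so, because the
#'   precision weights depend on sequencing depth.
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(rpk, trim_M = 0.30, trim_A = 0.05, weighted = TRUE) {
  x <- if (inherits(rpk, "expr_matrix")) rpk$values else rpk
  if (inherits(rpk, "expr_matrix") && rpk$scale != "rpk")
    abort("`tmm_factors` expects values on the rpk scale.",
          class = "famendo_argument_error")
  if (ncol(x) < 2)
    return(setNames(rep(1, ncol(x)), colnames(x)))
  zero_sample <- colSums(x) == 0
  if (any(zero_sample))
    abort(sprintf("Sample(s) with all-zero values: %s",
                  paste(colnames(x)[zero_sample], collapse = ", ")),
          class = "famendo_normalization_error")
  all_zero <- rowSums(x) == 0
  if (any(all_zero)) {
    message(sprintf("Dropping %d genes with zero values in every sample.",
                    sum(all_zero)))
    x <- x[!all_zero, , drop = FALSE]
  }
  f <- edgeR::calcNormFactors(x, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A,
                              doWeighting = weighted)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}

#' Gene-length-corrected TMM (geTMM) normalization
#'
#' Converts counts to reads per kilobase (`count / (length_bp / 1000)`),
#' computes TMM factors on the RPK matrix, scales each sample to per-million
#' by its RPK column sum times its TMM factor, and returns
#' `log2(x + offset)`.
#'
#' @param counts an `expr_matrix` on the `counts` scale with gene lengths.
#' @param trim_M,trim_A trim fractions passed to [tmm_factors()].
#' @param log_offset added before the log to keep zeros finite (default 0.5).
#' @param weighted passed to [tmm_factors()].
#' @return an `expr_matrix` on the `getmm_log` scale.
#' @export
getmm_normalize <- function(counts, trim_M = 0.30, trim_A = 0.05,
                            log_offset = 0.5, weighted = TRUE) {
  if (!inherits(counts, "expr_matrix") || counts$scale != "counts")
    abort("`getmm_normalize` expects an expr_matrix on the counts scale.",
          class = "famendo_argument_error")
  len <- counts$gene_lengths
  if (is.null(len))
    abort("Gene lengths are required for geTMM.", class = "famendo_argument_error")
  if (any(len <= 0))
    abort(sprintf("Non-positive gene length for: %s",
                  paste(names(len)[len <= 0], collapse = ", ")),
          class = "famendo_argument_error")
  rpk <- counts$values / (len / 1000)
  f <- if (ncol(rpk) >= 2) {
    tmm_factors(expression_matrix(rpk, len, scale = "rpk"),
                trim_M = trim_M, trim_A = trim_A, weighted = weighted)
  } else {
    setNames(1, colnames(rpk))
  }
  denom <- colSums(rpk) * f[colnames(rpk)]
  norm <- sweep(rpk, 2, denom / 1e6, "/")
  out <- expression_matrix(log2(norm + log_offset), len, scale = "getmm_log")
  out$scale <- "getmm_log"
  out
}

#' Remove batch effects by linear adjustment
#'
#' Per gene, fits least squares on intercept, optional protected covariates
#' and sum-to-zero batch contrasts, then subtracts only the fitted batch
#' terms, leaving protected-covariate contributions untouched (the standard
#' linear batch-removal used for log-scale expression). Delegated to
#' limma's removeBatchEffect after an explicit design-rank check.
#'
#' @param expr an `expr_matrix` on the `getmm_log` scale.
#' @param batch per-sample batch labels.
#' @param protect optional numeric matrix of covariates to protect
#'   (samples x covariates).
#' @return an `expr_matrix` on the `batch_corrected` scale.
#' @export
remove_batch <- function(expr, batch, protect = NULL) {
  if (!inherits(expr, "expr_matrix") ||
      !expr$scale %in% c("getmm_log", "batch_corrected"))
    abort("`remove_batch` expects log-scale normalized values.",
          class = "famendo_argument_error")
  x <- expr$values
  if (length(batch) != ncol(x))
    abort("`batch` must have one label per sample.", class = "famendo_argument_error")
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    out <- expr
    out$scale <- "batch_corrected"
    return(out)
  }
  design <- cbind(Intercept = rep(1, ncol(x)), protect)
  contr <- stats::contr.sum(nlevels(batch))
  bmat <- contr[as.integer(batch), , drop = FALSE]
  full <- cbind(design, bmat)
  if (qr(full)$rank < ncol(full))
    abort("Batch is confounded with a protected covariate (rank-deficient design).",
          class = "famendo_design_error")
  corrected <- limma::removeBatchEffect(x, batch = batch, design = design)
  out <- expression_matrix(corrected, expr$gene_lengths, scale = "getmm_log")
  out$scale <- "batch_corrected"
  out
}

#' PCA scores for expression diagnostics
#'
#' Centers every gene across samples and computes sample scores on the first
#' `k` principal components by singular value decomposition, with the
#' fraction of variance each component explains. Used before/after batch
#' removal to check that instrument clustering disappears.
#'
#' @param expr an `expr_matrix` (any log scale) or genes x samples matrix.
#' @param k number of components (at most `min(genes, samples) - 1`).
#' @param batch optional per-sample labels carried into the result for plotting.
#' @return a tibble (class `expr_pca`) with `sample_id`, `PC1..PCk` and, if
#'   given, `batch`; attribute `var_explained` holds the fractions.
#' @export
pca_scores <- function(expr, k = 2, batch = NULL) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else expr
  kmax <- min(nrow(x), ncol(x)) - 1L
  if (k > kmax)
    abort(sprintf("`k` must be <= %d for this matrix.", kmax),
          class = "famendo_argument_error")
  xc <- x - rowMeans(x)
  if (max(abs(xc)) == 0)
    abort("Constant matrix: PCA is undefined.", class = "famendo_degenerate_error")
  sv <- svd(t(xc), nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(tibble(sample_id = colnames(x)), as_tibble(scores))
  if (!is.null(batch)) out$batch <- as.character(batch)
  attr(out, "var_explained") <- sv$d^2 / sum(sv$d^2)
  class(out) <- c("expr_pca", class(out))
  out
}

#' @method autoplot expr_pca
#' @export
autoplot.expr_pca <- function(object, ...) {
  ve <- attr(object, "var_explained")
  p <- ggplot(object, aes(x = .data$PC1, y = .data$PC2)) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    theme_minimal()
  if ("batch" %in% names(object))
    p + geom_point(aes(colour = .data$batch))
  else p + geom_point()
}
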