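#' Additive relationship matrix from a pedigree
#'
#' Computes kinship coefficients by the classic recursion — founders have
#' self-kinship 1/2 and zero kinship with other founders; processing parents
#' before children, `phi(i, i) = 0.5 * (1 + phi(father, mother))` and
#' `phi(i, j) = 0.5 * (phi(father, j) + phi(mother, j))` — and returns the
#' additive relationship matrix `A = 2 * phi`, so the polygenic covariance can
#' be written `sigma2_g * A` and heritability keeps its standard meaning.
#'
#' @param ped pedigree tibble (`id`, `father`, `mother`, `sex`); `NA` parents
#'   mark founders.
#' @return symmetric numeric matrix `A` with the pedigree ids as dimnames.
#'   Diagonal entries are 1 for non-inbred individuals, `1 + f` for inbred.
#' @examples
#' trio <- tibble::tibble(id = c("dad", "mom", "kid"),
#'                        father = c(NA, NA, "dad"),
#'                        mother = c(NA, NA, "mom"),
#'                        sex = c("male", "female", "female"))
#' kinship_from_pedigree(trio)["dad", "kid"]  # 0.5
#' @export
kinship_from_pedigree <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  idx <- setNames(seq_len(n), ids)
  fa <- ifelse(is.na(ped$father), 0L, idx[ped$father])
  mo <- ifelse(is.na(ped$mother), 0L, idx[ped$mother])

  # topological order: parents before children
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    fa_ok <- fa == 0L | placed[pmax(fa, 1L)]
    mo_ok <- mo == 0L | placed[pmax(mo, 1L)]
    ready <- !placed & fa_ok & mo_ok
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
    if (all(placed)) break
  }
  if (!all(placed))
    abort("Pedigree parent links do not admit a parents-first ordering.",
          class = "famendo_structure_error")

  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (pos in seq_along(order_out)) {
    i <- order_out[pos]
    f <- fa[i]; m <- mo[i]
    phi[i, i] <- if (f > 0L && m > 0L) 0.5 * (1 + phi[f, m]) else 0.5
    if (pos > 1L) {
      prev <- order_out[seq_len(pos - 1L)]
      val <- 0.5 * ((if (f > 0L) phi[f, prev] else 0) +
                    (if (m > 0L) phi[m, prev] else 0))
      phi[i, prev] <- val
      phi[prev, i] <- val
    }
  }
  2 * phi
}

#' Validate a relationship matrix
#'
#' Checks symmetry (within 1e-10), entries in `[0, 2]`, diagonal at least 1,
#' and positive semidefiniteness within a relative tolerance of
#' `1e-8 * trace`; eigenvalues more negative than that raise an error.
#'
#' @param A square numeric matrix with id dimnames.
#' @return `A` invisibly.
#' @export
validate_relationship_matrix <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    abort("Relationship matrix must be square.", class = "famendo_matrix_error")
  if (is.null(rownames(A)))
    abort("Relationship matrix needs id dimnames.", class = "famendo_matrix_error")
  if (max(abs(A - t(A))) > 1e-10)
    abort("Relationship matrix is not symmetric within 1e-10.",
          class = "famendo_matrix_error")
  if (any(A < -1e-12) || any(A > 2 + 1e-12))
    abort("Relationship entries must lie in [0, 2].", class = "famendo_matrix_error")
  if (any(diag(A) < 1 - 1e-10))
    abort("Relationship diagonal must be >= 1.", class = "famendo_matrix_error")
  relationship_eigen(A)  # errors if too negative
  invisible(A)
}

# Eigendecomposition with PSD guard: eigenvalues in (-1e-8 * trace, 0) are
# clipped to 0 (empirical GRMs are near-PSD but not exactly); anything more
# negative is an error. Symmetrize first to kill round-off skew.
relationship_eigen <- function(A) {
  As <- (A + t(A)) / 2
  eig <- eigen(As, symmetric = TRUE)
  tol <- 1e-8 * sum(diag(As))
  if (min(eig$values) < -tol)
    abort(sprintf(
      "Relationship matrix is not positive semidefinite (min eigenvalue %.3g, tolerance %.3g).",
      min(eig$values), -tol), class = "famendo_matrix_error")
  eig$values <- pmax(eig$values, 0)
  eig
}

# Reorder/subset a relationship matrix to a roster of ids.
align_matrix <- function(A, roster) {
  missing_ids <- setdiff(roster, rownames(A))
  if (length(missing_ids))
    abort(sprintf("Ids absent from the relationship matrix: %s",
                  paste(head(missing_ids, 5), collapse = ", ")),
          class = "famendo_matrix_error")
  A[roster, roster, drop = FALSE]
}

#' Read a relationship matrix from disk
#'
#' Two text conventions are supported: `square_tsv` (header row of ids, one
#' row per id with the id in the first column) and `lower_triplets` (GCTA GRM
#' text convention: row index, column index, marker count (ignored), value;
#' ids supplied in a companion id file, one per line or FID/IID columns).
#' Slightly asymmetric input is symmetrized by averaging with its transpose;
#' asymmetry above 1e-6 logs a warning. Positive semidefiniteness is checked.
#'
#' @param path file path.
#' @param format `"square_tsv"` or `"lower_triplets"`.
#' @param id_file id file path (required for `lower_triplets`).
#' @return symmetric relationship matrix with id dimnames.
#' @export
read_grm <- function(path, format = c("square_tsv", "lower_triplets"),
                     id_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(sprintf("File not found: %s", path), class = "famendo_format_error")
  if (format == "square_tsv") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    ids <- header[-1]
    n <- length(ids)
    if (length(lines) - 1L != n)
      abort(sprintf("Expected %d data rows, found %d.", n, length(lines) - 1L),
            class = "famendo_format_error")
    A <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (r in seq_len(n)) {
      parts <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1]]
      if (length(parts) != n + 1L)
        abort(sprintf("Row %d has %d fields, expected %d.", r,
                      length(parts), n + 1L), class = "famendo_format_error")
      if (parts[1] != ids[r])
        abort(sprintf("Row %d id '%s' does not match header id '%s'.",
                      r, parts[1], ids[r]), class = "famendo_format_error")
      A[r, ] <- as.numeric(parts[-1])
    }
  } else {
    if (is.null(id_file))
      abort("`id_file` is required for lower_triplets format.",
            class = "famendo_format_error")
    id_tab <- utils::read.table(id_file, header = FALSE,
                                stringsAsFactors = FALSE)
    ids <- as.character(id_tab[[ncol(id_tab)]])
    trip <- utils::read.table(path, header = FALSE)
    n <- length(ids)
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    for (r in seq_len(nrow(trip))) {
      i <- trip[r, 1]; j <- trip[r, 2]; v <- trip[r, ncol(trip)]
      A[i, j] <- v; A[j, i] <- v
    }
  }
  if (anyNA(A))
    abort("Relationship matrix contains missing entries.",
          class = "famendo_format_error")
  asym <- max(abs(A - t(A)))
  if (asym > 1e-6)
    warn(sprintf("Relationship matrix asymmetry %.3g; averaging A and t(A).", asym))
  A <- (A + t(A)) / 2
  relationship_eigen(A)  # PSD check, errors loudly
  A
}

#' Write a relationship matrix to disk
#'
#' Text output with 10 significant digits, so entries round-trip to better
#' than 1e-9. See [read_grm()] for the two formats.
#'
#' @param A relationship matrix with id dimnames.
#' @param path output path; for `lower_triplets` the id file is written next
#'   to it with extension `.id`.
#' @param format `"square_tsv"` or `"lower_triplets"`.
#' @return `path` invisibly.
#' @export
write_grm <- function(A, path, format = c("square_tsv", "lower_triplets")) {
  format <- match.arg(format)
  ids <- rownames(A)
  if (format == "square_tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("id", ids), collapse = "\t"), con)
    for (r in seq_len(nrow(A)))
      writeLines(paste(c(ids[r], formatC(A[r, ], digits = 10, format = "g")),
                       collapse = "\t"), con)
  } else {
    n <- nrow(A)
    idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
    out <- sprintf("%d\t%d\t%d\t%s", idx[, 1], idx[, 2], 0L,
                   formatC(A[cbind(idx[, 1], idx[, 2])], digits = 10,
                           format = "g"))
    writeLines(out, path)
    writeLines(ids, paste0(path, ".id"))
  }
  invisible(path)
}
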