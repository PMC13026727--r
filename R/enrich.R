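#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: term id, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: list with `terms` (tibble: term_id,
#'   term_name, members list-column) and `universe` (all annotated genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    abort(sprintf("File not found: %s", path), class = "famendo_format_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad))
    abort("GMT lines need at least term, description and one member.",
          class = "famendo_format_error")
  terms <- tibble(
    term_id = vapply(parts, `[[`, "", 1),
    term_name = vapply(parts, `[[`, "", 2),
    members = lapply(parts, function(x) unique(x[-(1:2)]))
  )
  if (anyDuplicated(terms$term_id))
    abort("Duplicate term ids in GMT.", class = "famendo_format_error")
  gene_set_collection(terms)
}

#' Gene-set collection constructor
#'
#' @param terms tibble with `term_id`, `term_name` and a `members`
#'   list-column of gene ids.
#' @param universe gene universe (default: union of all term members).
#' @return a `gene_set_collection` object.
#' @export
gene_set_collection <- function(terms, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(terms$members))
  terms$members <- lapply(terms$members, intersect, y = universe)
  structure(list(terms = terms, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, tests whether the query gene set overlaps the
#' term more than expected under random draws from the universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` where N is the universe
#' size, K the term size, n the query size and k the overlap. FDR across
#' terms is Benjamini-Hochberg; terms below `min_term_size` are skipped.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query gene ids of interest.
#' @param sets a `gene_set_collection`.
#' @param min_term_size smallest term tested (default 2).
#' @param fdr_threshold significance flag threshold (default 0.05).
#' @return tibble of class `enrich_result`: `term_id`, `term_name`, `k`,
#'   `K`, `n`, `N`, `p`, `fdr`, `significant`, sorted by `fdr`.
#' @export
hypergeom_enrich <- function(query, sets, min_term_size = 2,
                             fdr_threshold = 0.05) {
  if (!inherits(sets, "gene_set_collection"))
    abort("`sets` must be a gene_set_collection.", class = "famendo_argument_error")
  query <- unique(query)
  outside <- setdiff(query, sets$universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe dropped.",
                 length(outside)))
    query <- setdiff(query, outside)
  }
  if (!length(query))
    abort("Query is empty after harmonization with the universe.",
          class = "famendo_argument_error")
  N <- length(sets$universe)
  n <- length(query)
  keep <- vapply(sets$terms$members, length, 1L) >= min_term_size
  terms <- sets$terms[keep, , drop = FALSE]
  k <- vapply(terms$members, function(m) length(intersect(m, query)), 1L)
  K <- vapply(terms$members, length, 1L)
  # P(X >= k) = upper tail at k - 1
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble(term_id = terms$term_id, term_name = terms$term_name,
                k = k, K = K, n = n, N = N, p = p,
                fdr = bh_adjust(pmax(p, 1e-300)))
  out$significant <- out$fdr < fdr_threshold
  out <- dplyr::arrange(out, .data$fdr, .data$p)
  class(out) <- c("enrich_result", class(out))
  out
}

#' @method autoplot enrich_result
#' @export
autoplot.enrich_result <- function(object, top = 15, ...) {
  dat <- head(object, top)
  dat$term_name <- factor(dat$term_name, levels = rev(dat$term_name))
  ggplot(dat, aes(x = -log10(.data$fdr), y = .data$term_name,
                  size = .data$k, colour = .data$fdr)) +
    geom_point() +
    scale_colour_viridis_c(direction = -1) +
    labs(x = "-log10 FDR", y = NULL, size = "genes", colour = "FDR") +
    theme_minimal()
}
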