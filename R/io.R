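# Plain-text I/O. Every writer prepends comment lines ("# key=value") naming
# the tool version and, when run through the pipeline, the config hash and
# seed; every reader skips comment lines.

famendo_header <- function(extra = character()) {
  c(sprintf("# famendo=%s", as.character(packageVersion("famendo"))), extra)
}

write_commented <- function(df, path, extra = character(), sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(famendo_header(extra), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_skip <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a pedigree CSV
#'
#' Columns `id`, `father`, `mother`, `sex` (plus `generation` when present);
#' missing parents are encoded as `0`.
#'
#' @param ped pedigree tibble.
#' @param path file path.
#' @return the path ([write_pedigree()]) or a pedigree tibble
#'   ([read_pedigree()]).
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  write_commented(out, path, sep = ",")
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- read_table_skip(path, sep = ",")
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  df$id <- as.character(df$id)
  df$father[df$father == "0"] <- NA_character_
  df$mother[df$mother == "0"] <- NA_character_
  ped <- as_tibble(df)
  validate_pedigree(ped)
  ped
}

#' Write / read a phenotype table TSV
#'
#' @param pheno phenotype tibble (`id`, `age`, `sex`, trait columns).
#' @param path file path.
#' @param extra extra comment header lines.
#' @return the path, or the phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path, extra = character()) {
  write_commented(as.data.frame(pheno), path, extra = extra)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read_table_skip(path)
  df$id <- as.character(df$id)
  as_tibble(df)
}

#' Write / read a counts TSV
#'
#' Genes as rows; first column the gene id, second the gene length in bp,
#' remaining columns one per sample.
#'
#' @param counts genes x samples count matrix with dimnames.
#' @param gene_lengths per-gene lengths in bp.
#' @param path file path.
#' @param extra extra comment header lines.
#' @return the path, or an `expr_matrix` on the counts scale.
#' @export
write_counts <- function(counts, gene_lengths, path, extra = character()) {
  df <- data.frame(gene_id = rownames(counts),
                   length_bp = unname(gene_lengths[rownames(counts)]),
                   counts, check.names = FALSE)
  write_commented(df, path, extra = extra)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_table_skip(path)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$gene_id
  expression_matrix(m, setNames(df$length_bp, df$gene_id), scale = "counts")
}

#' Write / read a normalized expression matrix TSV
#'
#' The scale tag travels in a comment header line (`# scale=...`).
#'
#' @param expr an `expr_matrix`.
#' @param path file path.
#' @param extra extra comment header lines.
#' @return the path, or the `expr_matrix`.
#' @export
write_expression <- function(expr, path, extra = character()) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write_commented(df, path,
                  extra = c(sprintf("# scale=%s", expr$scale), extra))
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  lines <- readLines(path, n = 20)
  scale_line <- grep("^# scale=", lines, value = TRUE)
  scale <- if (length(scale_line)) sub("^# scale=", "", scale_line[1])
           else "getmm_log"
  df <- read_table_skip(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_matrix(m, scale = scale)
}
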