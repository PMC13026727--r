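#' Published per-trait association statistics for ADAMTS7 and THRAP3
#'
#' The per-trait regression summaries (effect, SE, p, q) reported for the two
#' transcripts whose expression endophenotypes were associated with both
#' liver-injury measures and depressive symptoms in the Mexican American
#' family study this package models. Shipped as plain text under
#' `inst/extdata`; the unparseable q-value printed for the THRAP3 BDI-II row
#' is carried as `NA`. These tables are the input to the Fisher combined
#' joint test reproduced by the acceptance script.
#'
#' @param gene `"ADAMTS7"` or `"THRAP3"`.
#' @return tibble with columns `trait`, `beta`, `se`, `p`, `q`.
#' @examples
#' tab <- reported_associations("ADAMTS7")
#' fisher_combine(tab$p, gene_id = "ADAMTS7")
#' @export
reported_associations <- function(gene = c("ADAMTS7", "THRAP3")) {
  gene <- match.arg(gene)
  path <- system.file("extdata",
                      sprintf("%s_associations.tsv", tolower(gene)),
                      package = "famendo", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_tibble(df)
}
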