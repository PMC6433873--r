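#' Load a packaged printed gene table
#'
#' The package ships, as plain TSV fixtures, three published summary tables of
#' ABA-responsive genes in *P. patens* protonema: differentially regulated
#' cell-wall genes (`table1_cellwall`), ABA biosynthesis and signaling genes
#' (`table2_aba`), and the uniquely identified early ABA-induced genes
#' (`table3_early`). Fold-change cells are signed linear-scale fold changes
#' (never in the open interval (-1, 1)); a dash in the printed table means the
#' gene was not called differentially expressed at that timepoint and is
#' loaded as `NA`.
#'
#' @param name one of `"table1_cellwall"`, `"table2_aba"`, `"table3_early"`.
#' @return a data.frame of class `printed_gene_table` with columns `gene_id`,
#'   `annotation` (absent in `table2_aba`, which carries `section` and
#'   `at_gene` instead), and numeric `fc_30`, `fc_60`, `fc_180` with `NA`
#'   encoding "not called".
#' @export
load_fixture_table <- function(name = c("table1_cellwall", "table2_aba",
                                        "table3_early")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "abatime",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("fc_30", "fc_60", "fc_180")) {
    x <- tab[[col]]
    x[x %in% c("-", "–", "")] <- NA
    tab[[col]] <- as.numeric(x)
  }
  fc <- as.matrix(tab[c("fc_30", "fc_60", "fc_180")])
  if (any(abs(fc) < 1, na.rm = TRUE))
    abort("printed fold changes must never lie in (-1, 1)",
          "abatime_format_error")
  class(tab) <- c("printed_gene_table", "data.frame")
  tab
}
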