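#' Packaged duplication and selection reference tables
#'
#' The package ships transcriptions of three published reference tables for
#' the pear (*Pyrus bretschneideri*) WRKY family: `T1_tandem` (15 tandemly
#' duplicated clusters, 33 genes), `T2_synteny` (61 collinear gene pairs
#' covering 57 genes, with anchor counts, block E-values and mean/SD Ks) and
#' `T3_branchsite` (branch-site model A parameter estimates and
#' log-likelihoods for the alternative and null hypotheses on the Pbr001425
#' foreground branch).
#'
#' @param table_id One of `"T1_tandem"`, `"T2_synteny"`, `"T3_branchsite"`.
#' @return A data.frame with attribute `table_id`. For `T1_tandem` the
#'   `genes` column is comma-separated member ids.
#' @export
load_fixture_table <- function(table_id) {
  files <- c(T1_tandem = "table1_tandem.tsv",
             T2_synteny = "table2_synteny.tsv",
             T3_branchsite = "table3_branchsite.tsv")
  if (length(table_id) != 1L || !table_id %in% names(files)) {
    stop2("unknown table_id: ", paste(table_id, collapse = ", "),
          " (expected one of ", paste(names(files), collapse = ", "), ")")
  }
  path <- system.file("extdata", files[[table_id]], package = "wrkyfamkit",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(tab, "table_id") <- table_id
  tab
}

#' Member gene ids of a fixture tandem cluster table
#' @param tab Data frame from `load_fixture_table("T1_tandem")`.
#' @return Character vector of all member gene ids (with repeats, if any).
#' @export
tandem_table_genes <- function(tab) {
  unlist(strsplit(tab$genes, ",", fixed = TRUE), use.names = FALSE)
}
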