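#' Load a packaged result table of the original study
#'
#' The supplementary tables of the breast-cancer study are shipped as
#' plain-text fixtures: S1 (differentially expressed miRNAs), S2/S3
#' (down-/up-regulated genes), S4 (ROC results), S5 (network size summary)
#' and S6 (per-network enriched GO terms with member genes).
#'
#' @param name One of `"S1"` to `"S6"`.
#' @return A `data.frame`; numeric columns are parsed as printed.
#' @examples
#' s5 <- load_fixture("S5")
#' all(s5$total == s5$l0_count + s5$l1_count)
#' @export
load_fixture <- function(name) {
  files <- c(S1 = "table_s1_mirnas.tsv",
             S2 = "table_s2_down_genes.tsv",
             S3 = "table_s3_up_genes.tsv",
             S4 = "table_s4_roc.tsv",
             S5 = "table_s5_networks.tsv",
             S6 = "table_s6_enrichment.tsv")
  if (length(name) != 1 || !name %in% names(files))
    stop("unknown fixture name: ", paste(name, collapse = ", "),
         " (expected one of ", paste(names(files), collapse = ", "), ")")
  path <- system.file("extdata", files[[name]], package = "mirpin",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  num <- intersect(c("fold_change", "auc", "p_value", "adj_p"), names(tab))
  for (cn in num) tab[[cn]] <- as.numeric(tab[[cn]])
  int <- intersect(c("total", "l0_count", "l1_count"), names(tab))
  for (cn in int) tab[[cn]] <- as.integer(tab[[cn]])
  tab
}
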