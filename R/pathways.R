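# Pathway membership tables for stratified screen analysis.

#' Read a pathway membership table
#'
#' TSV with header columns `gene`, `pathway` (one row per membership).
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `gene`, `pathway`, in file order.
#' @export
load_pathway_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("gene", "pathway") %in% names(df))) {
    stop("pathway map must have columns gene and pathway", call. = FALSE)
  }
  df[, c("gene", "pathway"), drop = FALSE]
}

#' Write a pathway membership table
#' @param pathway_map data.frame with columns `gene`, `pathway`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_map <- function(pathway_map, path) {
  utils::write.table(pathway_map[, c("gene", "pathway"), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
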