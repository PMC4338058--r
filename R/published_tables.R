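# Loaders for the reference sRNA catalogue of B. animalis subsp. lactis
# KLDS 2.0603 shipped under inst/extdata. The catalogue file is kept
# exactly as printed in its source, including two repeated rows, so that
# deduplication and the coordinate arithmetic can be checked against it.

#' Load the reference sRNA catalogue (KLDS 2.0603)
#'
#' Eleven distinct intergenic sRNAs (13 rows as printed; two rows are
#' duplicates) with strand-polarized coordinates: minus-strand rows list
#' start > end, and `abs(end - start)` equals the length column.
#'
#' @param deduplicate Drop repeated sRNA ids (default `FALSE`, the table as
#'   printed).
#' @return A data.frame with columns `srna_id`, `start`, `end`, `strand`,
#'   `length`, `upstream_gene`, `downstream_gene`, `orientation`.
#' @export
load_reference_catalogue <- function(deduplicate = FALSE) {
  path <- system.file("extdata", "klds2_0603_srna_catalogue.tsv",
                      package = "srnaseeker", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (deduplicate) df <- df[!duplicated(df$srna_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load the reference sRNA stress fold changes (KLDS 2.0603)
#'
#' Expression of the 11 reference sRNAs under acid, bile-salt and simulated
#' gastrointestinal treatment, as fold change over the untreated control.
#'
#' @return A data.frame with columns `srna_id`, `acid`, `bile`, `git`.
#' @export
load_reference_srna_folds <- function() {
  path <- system.file("extdata", "klds2_0603_srna_fold_changes.tsv",
                      package = "srnaseeker", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
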