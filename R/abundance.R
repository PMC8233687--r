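#' Read a gene-level abundance table
#'
#' TSV with columns `gene_id`, `condition_id`, `abundance` (mRNA or protein,
#' any consistent nonnegative unit).  Genes without a measurement are simply
#' absent — absence is never coerced to zero, because "not measured" and
#' "not expressed" cannot be distinguished in these inputs.
#'
#' @param path TSV file path.
#' @return data.frame with the three columns above.
#' @export
read_abundance_table <- function(path) {
  d <- read_tsv_strict(path, colClasses = c(gene_id = "character",
                                            condition_id = "character"))
  need <- c("gene_id", "condition_id", "abundance")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop_data("abundance TSV missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(is.na(d$abundance)) || any(d$abundance < 0)) {
    stop_data("negative or missing abundance values in ", path)
  }
  dup <- duplicated(d[, c("gene_id", "condition_id")])
  if (any(dup)) {
    stop_data("duplicate (gene_id, condition_id) pair: ",
              d$gene_id[dup][1], " / ", d$condition_id[dup][1])
  }
  d[, need]
}

#' @rdname read_abundance_table
#' @param abundance abundance data.frame.
#' @export
write_abundance_table <- function(abundance, path) {
  write_tsv(abundance[, c("gene_id", "condition_id", "abundance")], path)
}

#' Extract one condition of an abundance table as a named covariate vector
#'
#' @param abundance abundance data.frame (`gene_id`, `condition_id`,
#'   `abundance`).
#' @param condition the `condition_id` to extract.
#' @return named numeric vector (names are gene ids) with a `covariate_id`
#'   attribute, suitable for [associate()].
#' @export
abundance_vector <- function(abundance, condition) {
  sub <- abundance[abundance$condition_id == condition, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_data("condition '", condition, "' not present in abundance table")
  }
  v <- sub$abundance
  names(v) <- sub$gene_id
  attr(v, "covariate_id") <- condition
  v
}
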