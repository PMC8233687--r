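#' Read an observed-mutation table
#'
#' One row is one ever-observed allele in one population: the allele is
#' counted once, at the first sequenced timepoint where it was seen, and never
#' re-counted at later timepoints.  The CSV dialect has header columns
#' `population_id`, `population_class`, `gene_id`, `mutation_class`,
#' `generation_observed`.
#'
#' Records with `gene_id == "INTERGENIC"` are retained (a message reports how
#' many) but are excluded from all gene-level statistics downstream.
#'
#' @param path CSV file path.
#' @param horizon experiment horizon in generations; records observed later
#'   are rejected.  Use `Inf` to disable the check.
#' @return A `data.frame` of validated mutation records.
#' @export
read_mutation_table <- function(path, horizon = 60000) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population_id", "population_class", "gene_id", "mutation_class",
            "generation_observed")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop_data("mutation table missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(d) == 0) {
    warning("mutation table ", path, " has a header but no records")
    return(validate_mutation_table(d[, need], horizon = horizon))
  }
  d$gene_id <- as.character(d$gene_id)
  d$population_id <- as.character(d$population_id)
  validate_mutation_table(d[, need], horizon = horizon)
}

#' Validate a mutation record table against the record invariants
#'
#' @param records data.frame with the mutation-table columns.
#' @param horizon maximum admissible `generation_observed`.
#' @return the validated records, invisibly classed `mutation_table`.
#' @export
validate_mutation_table <- function(records, horizon = 60000) {
  bad_pc <- which(!records$population_class %in% POPULATION_CLASSES)
  if (length(bad_pc) > 0) {
    stop_data("unknown population_class '", records$population_class[bad_pc[1]],
              "' at row ", bad_pc[1])
  }
  bad_mc <- which(!records$mutation_class %in% MUTATION_CLASSES)
  if (length(bad_mc) > 0) {
    stop_data("unknown mutation_class '", records$mutation_class[bad_mc[1]],
              "' at row ", bad_mc[1])
  }
  gen <- records$generation_observed
  bad_g <- which(!is_whole(gen) | gen < 0)
  if (length(bad_g) > 0) {
    stop_data("non-integer or negative generation_observed at row ", bad_g[1])
  }
  late <- which(gen > horizon)
  if (length(late) > 0) {
    stop_data("generation_observed exceeds horizon (", horizon, ") at row ",
              late[1])
  }
  records$generation_observed <- as.integer(round(gen))
  n_inter <- sum(records$gene_id == INTERGENIC)
  if (n_inter > 0) {
    message(n_inter, " INTERGENIC record(s) retained; they are excluded from ",
            "gene-level statistics")
  }
  class(records) <- c("mutation_table", "data.frame")
  records
}

#' Write a mutation table in the CSV dialect
#'
#' Round-trip safe: `read_mutation_table(write_mutation_table(x, p))` yields
#' an identical collection.
#'
#' @param records mutation record data.frame.
#' @param path output CSV path.
#' @export
write_mutation_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Convert allele-frequency trajectories to first-observation records
#'
#' Convenience converter from trajectory-style input (one row per allele per
#' sequenced timepoint, with a frequency column) to the flat one-row-per-allele
#' dialect used everywhere else: each allele contributes one record at the
#' first generation where its frequency was positive; alleles never observed
#' at positive frequency are dropped.
#'
#' @param traj data.frame with columns `allele_id`, `population_id`,
#'   `population_class`, `gene_id`, `mutation_class`, `generation`,
#'   `frequency`.
#' @return a mutation record data.frame.
#' @export
first_observed <- function(traj) {
  need <- c("allele_id", "population_id", "population_class", "gene_id",
            "mutation_class", "generation", "frequency")
  miss <- setdiff(need, names(traj))
  if (length(miss) > 0) {
    stop_data("trajectory table missing columns: ", paste(miss, collapse = ", "))
  }
  seen <- traj[traj$frequency > 0, , drop = FALSE]
  if (nrow(seen) == 0) {
    out <- data.frame(population_id = character(), population_class = character(),
                      gene_id = character(), mutation_class = character(),
                      generation_observed = integer(),
                      stringsAsFactors = FALSE)
    return(validate_mutation_table(out, horizon = Inf))
  }
  key <- paste(seen$population_id, seen$allele_id, sep = "\r")
  ord <- order(key, seen$generation)
  seen <- seen[ord, , drop = FALSE]
  first <- seen[!duplicated(key[ord]), , drop = FALSE]
  out <- data.frame(population_id = first$population_id,
                    population_class = first$population_class,
                    gene_id = first$gene_id,
                    mutation_class = first$mutation_class,
                    generation_observed = first$generation,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_mutation_table(out, horizon = Inf)
}
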