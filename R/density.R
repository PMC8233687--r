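#' Mutation-class filters
#'
#' Decides which mutation classes enter a count.  The `nonsynonymous` scheme
#' includes exactly missense and nonsense point mutations; `synonymous`
#' includes only synonymous point mutations; `all` includes every class
#' assigned to a gene (indels and structural variants within gene boundaries
#' included); `point` restricts `all` to point mutations
#' (missense, nonsense, synonymous) for the alternative reading of
#' "all mutations".
#'
#' @param mutation_class character vector of mutation classes.
#' @param scheme one of `"all"`, `"nonsynonymous"`, `"synonymous"`, `"point"`.
#' @return logical vector: include this record?
#' @export
classify_mutation <- function(mutation_class,
                              scheme = c("all", "nonsynonymous", "synonymous",
                                         "point")) {
  scheme <- match.arg(scheme)
  bad <- setdiff(unique(mutation_class), MUTATION_CLASSES)
  if (length(bad) > 0) {
    stop_data("unknown mutation_class: ", paste(bad, collapse = ", "))
  }
  included <- switch(scheme,
    all = MUTATION_CLASSES,
    nonsynonymous = c("missense", "nonsense"),
    synonymous = "synonymous",
    point = c("missense", "nonsense", "synonymous"))
  mutation_class %in% included
}

select_populations <- function(records, populations) {
  if (length(populations) == 1 && populations %in% c(POPULATION_CLASSES, "all")) {
    if (populations == "all") records
    else records[records$population_class == populations, , drop = FALSE]
  } else {
    records[records$population_id %in% populations, , drop = FALSE]
  }
}

#' Count ever-observed mutations per gene
#'
#' The core counting step: `m_g` is the number of ever-observed alleles in
#' gene `g` across the selected populations, restricted to the mutation-class
#' scheme, with first observation at or before the generation cutoff
#' (inclusive).  Every annotated gene appears in the result, including genes
#' with `m_g = 0`.  Intergenic records are ignored; a record naming a gene
#' absent from the annotation set is a hard error.
#'
#' @param records mutation record data.frame (see [read_mutation_table()]).
#' @param annotations a `gene_annotation` table defining the gene universe.
#' @param populations `"hypermutator"`, `"nonmutator"`, `"all"`, or a character
#'   vector of explicit population ids.
#' @param scheme mutation-class scheme, see [classify_mutation()].
#' @param cutoff generation cutoff (inclusive).
#' @return data.frame with columns `gene_id`, `count` and a `subset` attribute
#'   describing the selection.
#' @export
count_per_gene <- function(records, annotations, populations = "hypermutator",
                           scheme = "all", cutoff = 60000) {
  r <- select_populations(records, populations)
  r <- r[r$gene_id != INTERGENIC, , drop = FALSE]
  unknown <- setdiff(unique(r$gene_id), annotations$gene_id)
  if (length(unknown) > 0) {
    stop_data("mutation record(s) reference unknown gene_id: ",
              paste(unknown, collapse = ", "))
  }
  keep <- classify_mutation(r$mutation_class, scheme) &
    r$generation_observed <= cutoff
  counts <- tabulate(factor(r$gene_id[keep], levels = annotations$gene_id),
                     nbins = nrow(annotations))
  out <- data.frame(gene_id = annotations$gene_id, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "subset") <- list(populations = populations, scheme = scheme,
                              cutoff = cutoff)
  out
}

#' Length-normalize per-gene counts into mutation densities
#'
#' `d_g = m_g / L_g`, with `L_g` the full annotated nucleotide length of the
#' gene (no per-class site normalization).  The subset descriptor of the
#' count table is carried through unchanged.
#'
#' @param counts output of [count_per_gene()].
#' @param annotations the `gene_annotation` table supplying `length_nt`.
#' @return a `density_table`: data.frame with `gene_id`, `length_nt`, `count`,
#'   `density`, and the `subset` attribute.
#' @export
densify <- function(counts, annotations) {
  idx <- match(counts$gene_id, annotations$gene_id)
  if (anyNA(idx)) {
    stop_data("no annotation (gene length) for: ",
              paste(counts$gene_id[is.na(idx)], collapse = ", "))
  }
  len <- annotations$length_nt[idx]
  out <- data.frame(gene_id = counts$gene_id, length_nt = len,
                    count = counts$count, density = counts$count / len,
                    stringsAsFactors = FALSE)
  attr(out, "subset") <- attr(counts, "subset")
  class(out) <- c("density_table", "data.frame")
  out
}

#' One-call per-gene mutation density
#'
#' Convenience wrapper: [count_per_gene()] followed by [densify()].
#'
#' @inheritParams count_per_gene
#' @return a `density_table`.
#' @export
mutation_density <- function(records, annotations, populations = "hypermutator",
                             scheme = "all", cutoff = 60000) {
  densify(count_per_gene(records, annotations, populations, scheme, cutoff),
          annotations)
}

#' Cumulative density tables at successive generation cutoffs
#'
#' One density table per cutoff, each using only mutations first observed at
#' or before that mark, e.g. the six 10,000-generation marks of a
#' 60,000-generation experiment.  Per-gene counts are nondecreasing along the
#' list, and the final table equals the plain full-horizon table.
#'
#' @inheritParams count_per_gene
#' @param cutoffs strictly ascending numeric vector of generation cutoffs.
#' @return a `density_series`: named list of `density_table`s.
#' @export
cumulative_series <- function(records, annotations, populations = "hypermutator",
                              scheme = "all",
                              cutoffs = seq(10000, 60000, by = 10000)) {
  if (length(cutoffs) == 0 || any(diff(cutoffs) <= 0)) {
    stop_config("cutoffs must be strictly ascending")
  }
  out <- lapply(cutoffs, function(co) {
    mutation_density(records, annotations, populations, scheme, cutoff = co)
  })
  names(out) <- as.character(cutoffs)
  class(out) <- "density_series"
  out
}

#' @export
print.density_table <- function(x, ...) {
  s <- attr(x, "subset")
  cat("Per-gene mutation density: ", nrow(x), " genes, ",
      sum(x$count), " mutations\n", sep = "")
  if (!is.null(s)) {
    cat("  populations: ", paste(s$populations, collapse = ","),
        " | scheme: ", s$scheme, " | cutoff: ", s$cutoff, "\n", sep = "")
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more genes\n", sep = "")
  invisible(x)
}

subset_columns <- function(subset) {
  data.frame(populations = paste(subset$populations %||% NA, collapse = ";"),
             scheme = subset$scheme %||% NA_character_,
             cutoff = subset$cutoff %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Serialize / deserialize a density table
#'
#' TSV columns: `gene_id`, `length_nt`, `count`, `density`, plus the subset
#' descriptor (`populations` semicolon-joined, `scheme`, `cutoff`).  Integer
#' counts are bit-exact through the round trip.
#'
#' @param density a `density_table`.
#' @param path file path.
#' @export
write_density_table <- function(density, path) {
  s <- subset_columns(attr(density, "subset") %||% list())
  write_tsv(cbind(as.data.frame(density), s[rep(1, nrow(density)), ,
                                            drop = FALSE]),
            path)
}

#' @rdname write_density_table
#' @export
read_density_table <- function(path) {
  d <- read_tsv_strict(path, colClasses = c(gene_id = "character"))
  out <- d[, c("gene_id", "length_nt", "count", "density")]
  out$count <- as.integer(out$count)
  attr(out, "subset") <- list(
    populations = strsplit(as.character(d$populations[1]), ";", fixed = TRUE)[[1]],
    scheme = as.character(d$scheme[1]),
    cutoff = d$cutoff[1])
  class(out) <- c("density_table", "data.frame")
  out
}

#' Scatter a density table against a gene-level covariate
#'
#' Diagnostic plot: covariate on a log-ish square-root axis, density on the
#' y axis, one point per gene in the intersection of the two gene sets.
#'
#' @param density a `density_table`.
#' @param covariate named numeric vector (see [associate()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot_density_covariate <- function(density, covariate, ...) {
  common <- intersect(density$gene_id, names(covariate))
  x <- sqrt(as.numeric(covariate[common]))
  y <- density$density[match(common, density$gene_id)]
  graphics::plot(x, y, xlab = "sqrt(covariate)",
                 ylab = "mutation density (per nt)", pch = 16,
                 col = grDevices::rgb(0, 0, 0, 0.3), ...)
  invisible(data.frame(gene_id = common, covariate = covariate[common],
                       density = y))
}
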