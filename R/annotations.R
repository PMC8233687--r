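#' Mutation class and population class vocabularies
#'
#' `MUTATION_CLASSES` enumerates the recognised per-allele mutation classes;
#' `POPULATION_CLASSES` the two population phenotypes of the experiment
#' (hypermutator lineages with broken DNA repair, and nonmutator lineages).
#' `INTERGENIC` is the sentinel gene id for mutations that fall outside any
#' annotated gene; such records are retained on read but excluded from all
#' gene-level statistics.
#'
#' @export
MUTATION_CLASSES <- c("missense", "nonsense", "synonymous", "noncoding",
                      "indel", "sv")

#' @rdname MUTATION_CLASSES
#' @export
POPULATION_CLASSES <- c("hypermutator", "nonmutator")

#' @rdname MUTATION_CLASSES
#' @export
INTERGENIC <- "INTERGENIC"

#' Construct a validated gene annotation table
#'
#' Gene coordinates are stored 0-based half-open, so `length_nt = end - start`
#' with no off-by-one arithmetic anywhere downstream.  The length in
#' nucleotides is the normalizer for per-gene mutation density.
#'
#' @param gene_id character vector of unique locus identifiers.
#' @param start,end integer vectors, 0-based half-open coordinates.
#' @param strand character vector, each `"+"` or `"-"`.
#' @param name optional display names (defaults to `gene_id`).
#' @return A `data.frame` with class `gene_annotation` and columns
#'   `gene_id`, `name`, `start`, `end`, `strand`, `length_nt`.
#' @export
gene_annotation <- function(gene_id, start, end, strand, name = gene_id) {
  gene_id <- as.character(gene_id)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- as.character(strand)
  name <- as.character(name)

  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0) {
    stop_data("duplicate gene_id in annotation set: ",
              paste(dup, collapse = ", "))
  }
  len <- end - start
  bad <- gene_id[is.na(len) | len <= 0]
  if (length(bad) > 0) {
    stop_data("zero or negative gene length for: ", paste(bad, collapse = ", "))
  }
  if (!all(strand %in% c("+", "-"))) {
    stop_data("strand must be '+' or '-'")
  }
  out <- data.frame(gene_id = gene_id, name = name, start = start, end = end,
                    strand = strand, length_nt = len,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Read gene annotations from GFF3 or a simple TSV dialect
#'
#' GFF3 coordinates are 1-based inclusive and are converted to the internal
#' 0-based half-open convention on read, so a GFF3 feature spanning 101..400
#' becomes `start = 100, end = 400, length_nt = 300`.  The TSV dialect has
#' columns `gene_id`, `name`, `start_1based`, `end_1based`, `strand`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"`, or `"tsv"`.
#' @return A `gene_annotation` table, one row per protein-coding gene.
#' @export
read_gene_annotations <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    g <- rtracklayer::readGFF(path)
    g <- as.data.frame(g, stringsAsFactors = FALSE)
    rows <- g[g$type == "gene", , drop = FALSE]
    if (nrow(rows) == 0) rows <- g[g$type == "CDS", , drop = FALSE]
    if (nrow(rows) == 0) stop_data("no gene or CDS features in ", path)
    id <- if ("ID" %in% names(rows)) as.character(rows$ID) else NULL
    if (is.null(id) || anyNA(id)) {
      if ("locus_tag" %in% names(rows)) {
        lt <- as.character(rows$locus_tag)
        id <- if (is.null(id)) lt else ifelse(is.na(id), lt, id)
      }
    }
    if (is.null(id) || anyNA(id)) {
      stop_data("GFF3 gene records without ID or locus_tag in ", path)
    }
    nm <- if ("Name" %in% names(rows)) as.character(rows$Name) else id
    nm[is.na(nm)] <- id[is.na(nm)]
    gene_annotation(gene_id = id, start = rows$start - 1L, end = rows$end,
                    strand = as.character(rows$strand), name = nm)
  } else {
    d <- read_tsv_strict(path, colClasses = c(gene_id = "character",
                                              name = "character"))
    need <- c("gene_id", "name", "start_1based", "end_1based", "strand")
    miss <- setdiff(need, names(d))
    if (length(miss) > 0) {
      stop_data("annotation TSV missing columns: ", paste(miss, collapse = ", "))
    }
    gene_annotation(gene_id = d$gene_id, start = d$start_1based - 1L,
                    end = d$end_1based, strand = d$strand, name = d$name)
  }
}

#' Write gene annotations in the TSV dialect (1-based inclusive coordinates)
#'
#' @param annotations a `gene_annotation` table.
#' @param path output file path.
#' @export
write_gene_annotations <- function(annotations, path) {
  write_tsv(data.frame(gene_id = annotations$gene_id,
                       name = annotations$name,
                       start_1based = annotations$start + 1L,
                       end_1based = annotations$end,
                       strand = annotations$strand,
                       stringsAsFactors = FALSE),
            path)
}
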