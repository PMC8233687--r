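#' Construct a protein-protein interaction network from an edge table
#'
#' Edges are undirected and unweighted: reciprocal duplicates (a,b)/(b,a) are
#' collapsed to a single edge and self-loops are dropped (a message reports
#' how many of each).
#'
#' @param a,b character vectors of gene ids (edge endpoints).
#' @param network_id label for the source edge set.
#' @return an object of class `ppi_network`: a list with `edges` (two-column
#'   data.frame, lexicographically ordered endpoints), `nodes`, `network_id`.
#' @export
ppi_network <- function(a, b, network_id = "ppi") {
  a <- as.character(a)
  b <- as.character(b)
  self <- a == b
  if (any(self)) {
    message("dropped ", sum(self), " self-loop(s)")
    a <- a[!self]
    b <- b[!self]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate edge(s)")
  }
  edges <- data.frame(gene_id_a = lo[!dup], gene_id_b = hi[!dup],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_id_a, edges$gene_id_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_id_a, edges$gene_id_b))),
                 network_id = network_id),
            class = "ppi_network")
}

#' Read a PPI edge list from TSV
#'
#' Two tab-separated gene-id columns, no header by default.  An optional third
#' numeric column (e.g. a STRING-style confidence score) is accepted; when
#' `min_score` is given, edges below it are discarded before network
#' construction, otherwise all edges are kept.
#'
#' @param path TSV file path.
#' @param network_id label for the edge set (defaults to the file name).
#' @param min_score optional confidence threshold applied to a third column.
#' @param header logical; does the file carry a header row?
#' @return a `ppi_network`.
#' @export
read_ppi_edgelist <- function(path, network_id = NULL, min_score = NULL,
                              header = FALSE) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  network_id <- network_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  if (header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(ppi_network(character(), character(), network_id = network_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2 & nf != 3)
  if (length(bad) > 0) {
    stop_data("malformed PPI edge row ", bad[1] + as.integer(header),
              " in ", path, " (expected 2 columns, got ", nf[bad[1]], ")")
  }
  if (any(nf == 2) && any(nf == 3)) {
    stop_data("mixed 2- and 3-column rows in ", path)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (all(nf == 3) && !is.null(min_score)) {
    score <- as.numeric(vapply(fields, `[[`, "", 3L))
    keep <- !is.na(score) & score >= min_score
    a <- a[keep]
    b <- b[keep]
  }
  ppi_network(a, b, network_id = network_id)
}

#' @rdname read_ppi_edgelist
#' @param network a `ppi_network`.
#' @export
write_ppi_edgelist <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-gene interaction degree
#'
#' Degree is the number of distinct interaction partners in an undirected,
#' deduplicated network; the handshake identity `sum(degree) == 2 * n_edges`
#' holds by construction.  Genes absent from the network get no entry (they
#' are omitted, not imputed as zero); [associate()]'s intersection rule then
#' decides the test universe.
#'
#' @param network a `ppi_network`.
#' @return named integer vector of degrees with `covariate_id` and
#'   `network_id` attributes.
#' @export
ppi_degree <- function(network) {
  ends <- c(network$edges$gene_id_a, network$edges$gene_id_b)
  deg <- table(factor(ends, levels = network$nodes))
  out <- as.integer(deg)
  names(out) <- network$nodes
  attr(out, "covariate_id") <- paste0("degree_", network$network_id)
  attr(out, "network_id") <- network$network_id
  out
}

#' Serialize a degree map to TSV (`gene_id`, `degree`, `network_id`)
#'
#' @param degree named vector from [ppi_degree()].
#' @param path output path.
#' @export
write_degree_map <- function(degree, path) {
  write_tsv(data.frame(gene_id = names(degree),
                       degree = as.integer(degree),
                       network_id = attr(degree, "network_id") %||% NA_character_,
                       stringsAsFactors = FALSE),
            path)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network '", x$network_id, "': ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}
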