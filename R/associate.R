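#' Rank association between mutation density and a gene-level covariate
#'
#' Runs a two-sided Spearman test of per-gene mutation density against any
#' gene-level covariate (mRNA abundance, protein abundance, PPI degree).  The
#' test universe is the intersection of the density table's gene set and the
#' covariate's gene set — covariate values are never imputed for missing
#' genes.  With `zeros = "include"` (the default, matching the convention
#' that genes with no observed mutations are kept in the test), zero-count
#' genes enter the ranks; `zeros = "exclude"` drops genes with `m_g = 0`
#' before testing, and the reported `n` is the post-filter size.
#'
#' @param density a `density_table`.
#' @param covariate named numeric vector (names = gene ids), e.g. from
#'   [abundance_vector()] or [ppi_degree()], or a data.frame with a `gene_id`
#'   column and one numeric value column.
#' @param zeros `"include"` or `"exclude"`.
#' @param covariate_id label carried into the result (defaults to the
#'   covariate's `covariate_id` attribute).
#' @return a `density_assoc` object: `rho`, `p_value`, `n`, plus the full
#'   subset descriptor that produced it.
#' @export
associate <- function(density, covariate, zeros = c("include", "exclude"),
                      covariate_id = NULL) {
  zeros <- match.arg(zeros)
  cov <- as_covariate(covariate)
  covariate_id <- covariate_id %||% attr(cov, "covariate_id") %||% "covariate"

  common <- intersect(density$gene_id, names(cov))
  d <- density[match(common, density$gene_id), , drop = FALSE]
  if (zeros == "exclude") {
    keep <- d$count > 0
    d <- d[keep, , drop = FALSE]
    common <- common[keep]
  }
  if (length(common) < 3) {
    stop_data("fewer than 3 genes shared between density table and covariate '",
              covariate_id, "' (", length(common), " after zeros=", zeros, ")")
  }
  xs <- as.numeric(cov[common])
  if (length(unique(xs)) == 1) {
    stop_data("covariate '", covariate_id, "' is constant on the test set")
  }
  st <- spearman_two_sided(xs, d$density)
  sub <- attr(density, "subset") %||% list()
  structure(list(rho = st$rho, p_value = st$p_value, n = st$n,
                 method = st$method,
                 subset = c(sub, list(covariate_id = covariate_id,
                                      zeros = zeros))),
            class = "density_assoc")
}

as_covariate <- function(covariate) {
  if (is.data.frame(covariate)) {
    if (!"gene_id" %in% names(covariate)) {
      stop_config("covariate data.frame needs a gene_id column")
    }
    if ("condition_id" %in% names(covariate) &&
        length(unique(covariate$condition_id)) > 1) {
      stop_config("covariate table has several conditions; extract one with ",
                  "abundance_vector()")
    }
    val_col <- setdiff(names(covariate), c("gene_id", "condition_id",
                                           "network_id"))
    num <- val_col[vapply(covariate[val_col], is.numeric, logical(1))]
    if (length(num) != 1) {
      stop_config("covariate data.frame needs exactly one numeric value column")
    }
    v <- covariate[[num]]
    names(v) <- covariate$gene_id
    attr(v, "covariate_id") <- num
    return(v)
  }
  if (!is.numeric(covariate) || is.null(names(covariate))) {
    stop_config("covariate must be a named numeric vector or a data.frame")
  }
  covariate
}

#' Spearman correlation time course over cumulative density tables
#'
#' One association per generation cutoff of a [cumulative_series()].  The
#' final element equals [associate()] on the full-horizon table.
#'
#' @param series a `density_series`.
#' @inheritParams associate
#' @return an `assoc_series`: list of `density_assoc`, named by cutoff.
#' @export
correlation_time_course <- function(series, covariate,
                                    zeros = c("include", "exclude"),
                                    covariate_id = NULL) {
  zeros <- match.arg(zeros)
  out <- lapply(series, associate, covariate = covariate, zeros = zeros,
                covariate_id = covariate_id)
  names(out) <- names(series)
  class(out) <- "assoc_series"
  out
}

#' @export
print.density_assoc <- function(x, ...) {
  s <- x$subset
  cat("Spearman rank association (two-sided, ", x$method, ")\n", sep = "")
  cat("  covariate: ", s$covariate_id, " | populations: ",
      paste(s$populations, collapse = ","), " | scheme: ", s$scheme %||% NA,
      " | cutoff: ", s$cutoff %||% NA, " | zeros: ", s$zeros, "\n", sep = "")
  cat(sprintf("  rho = %.4g, p = %.3g, n = %d\n", x$rho, x$p_value, x$n))
  invisible(x)
}

#' @export
as.data.frame.density_assoc <- function(x, ...) {
  s <- x$subset
  data.frame(covariate_id = s$covariate_id %||% NA_character_,
             population_class = paste(s$populations %||% NA, collapse = ";"),
             scheme = s$scheme %||% NA_character_,
             cutoff = s$cutoff %||% NA_real_,
             zeros_policy = s$zeros %||% NA_character_,
             n = x$n, rho = x$rho, p_value = x$p_value,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.assoc_series <- function(x, ...) {
  out <- do.call(rbind, lapply(unclass(x), as.data.frame))
  rownames(out) <- NULL
  out
}

#' @export
plot.assoc_series <- function(x, ...) {
  d <- as.data.frame(x)
  graphics::plot(d$cutoff, d$rho, type = "b", pch = 16,
                 xlab = "generation cutoff", ylab = "Spearman rho", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(d)
}

#' Serialize association results to a TSV report
#'
#' One row per test: `covariate_id`, `populations`, `scheme`, `cutoff`,
#' `zeros_policy`, `n`, `rho`, `p_value` — mirroring a panel grid.
#'
#' @param results a `density_assoc`, an `assoc_series`, a list of either, or a
#'   data.frame already in report form.
#' @param path output TSV path.
#' @export
write_association_results <- function(results, path) {
  if (is.data.frame(results)) {
    d <- results
  } else if (inherits(results, c("density_assoc", "assoc_series"))) {
    d <- as.data.frame(results)
  } else {
    d <- do.call(rbind, lapply(results, as.data.frame))
  }
  rownames(d) <- NULL
  write_tsv(d, path)
}
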