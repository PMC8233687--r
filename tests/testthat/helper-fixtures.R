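# Fixtures and independent brute-force oracles used across the suite.

make_ann <- function(ids = c("g1", "g2", "g3"), len = c(300, 600, 900)) {
  start <- cumsum(c(0, utils::head(len, -1) + 50))
  gene_annotation(ids, start = start, end = start + len, strand = "+")
}

make_records <- function(population_id, population_class, gene_id,
                         mutation_class, generation_observed) {
  data.frame(population_id = population_id,
             population_class = population_class,
             gene_id = gene_id,
             mutation_class = mutation_class,
             generation_observed = as.integer(generation_observed),
             stringsAsFactors = FALSE)
}

# Spearman oracle: explicit average ranks, then the explicit Pearson
# product-moment formula on those ranks.
bf_spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Counting oracle: a literal loop over records.
bf_count_per_gene <- function(records, annotations, populations, scheme,
                              cutoff) {
  included <- switch(scheme,
                     all = MUTATION_CLASSES,
                     nonsynonymous = c("missense", "nonsense"),
                     synonymous = "synonymous",
                     point = c("missense", "nonsense", "synonymous"))
  counts <- stats::setNames(integer(nrow(annotations)), annotations$gene_id)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    pop_ok <- if (length(populations) == 1 &&
                  populations %in% c("hypermutator", "nonmutator")) {
      r$population_class == populations
    } else if (identical(populations, "all")) TRUE
    else r$population_id %in% populations
    if (pop_ok && r$gene_id != INTERGENIC &&
        r$mutation_class %in% included && r$generation_observed <= cutoff) {
      counts[r$gene_id] <- counts[r$gene_id] + 1L
    }
  }
  counts
}

# Random small instance generator for the counting oracle.
random_instance <- function(n_genes = 6, n_records = 50) {
  ann <- make_ann(sprintf("rg%02d", seq_len(n_genes)),
                  len = sample(seq(90, 3000, by = 3), n_genes))
  pops <- data.frame(id = c("H1", "H2", "N1", "N2"),
                     class = c("hypermutator", "hypermutator",
                               "nonmutator", "nonmutator"),
                     stringsAsFactors = FALSE)
  k <- sample.int(n_records, 1)
  pick <- sample.int(nrow(pops), k, replace = TRUE)
  rec <- make_records(pops$id[pick], pops$class[pick],
                      sample(c(ann$gene_id, INTERGENIC), k, replace = TRUE),
                      sample(MUTATION_CLASSES, k, replace = TRUE),
                      sample.int(60000, k, replace = TRUE))
  list(ann = ann, rec = rec)
}

tiny_sim_config <- function(...) {
  sim_config(n_genes = 150, n_hypermutator = 3, n_nonmutator = 2,
             mu_h = 2e-3, mu_n = 5e-4, mean_degree = 6, ...)
}
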