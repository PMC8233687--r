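#' Configuration for the synthetic hypermutator-evolution generator
#'
#' The generator emulates a long-term evolution experiment at desk scale: a
#' single circular genome of `n_genes` protein-coding genes with log-normal
#' length spread, log-normal gene abundance measured under several growth
#' conditions, a PPI network whose expected degree can be coupled to
#' abundance, and per-population tables of ever-observed mutations.
#'
#' Mutations are generated by Poisson arrival proportional to gene length and
#' thinned by abundance-coupled purifying selection: each nonsynonymous
#' candidate in gene g is removed (never reaches observable frequency) with
#' probability `pi_g = plogis(beta * z_g)`, where `z_g` is the gene's
#' standardized log-abundance.  With `beta = 0` the removal probability is a
#' constant 0.5 for every gene, decoupling density from abundance.  Synonymous
#' candidates are retained with a rate multiplier `1 + gamma * max(z_g, 0)`,
#' renormalized so the genome-wide expected synonymous total does not depend
#' on `gamma` — the synonymous bias is purely distributional.
#'
#' @param n_genes number of genes (default 4200, the scale of an *E. coli*
#'   protein-coding annotation).
#' @param length_meanlog,length_sdlog log-normal gene-length parameters in
#'   nucleotides; lengths are rounded to positive codon multiples.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters
#'   (arbitrary consistent units).
#' @param conditions labels of the growth conditions to emit.
#' @param condition_cor between-condition coupling in [0, 1]; 1 gives
#'   identical abundance ranks across conditions.
#' @param n_hypermutator,n_nonmutator population counts.
#' @param horizon experiment length in generations.
#' @param mu_h,mu_n observable-candidate arrival rates per nucleotide per
#'   population over the whole horizon (hypermutator and nonmutator).
#' @param frac_syn fraction of arising point mutations that are synonymous.
#' @param missense_frac missense share within surviving nonsynonymous
#'   mutations (remainder are nonsense).
#' @param beta abundance-coupled purifying-selection strength (>= 0).
#' @param gamma expression-coupled synonymous rate bias (>= 0).
#' @param delta abundance-degree coupling of the PPI network (>= 0).
#' @param mean_degree expected mean PPI degree.
#' @param pos_sel_targets,pos_sel_rate optional nonmutator positive-selection
#'   channel: number of target genes and expected extra missense mutations
#'   per target per population (both 0 by default).
#' @param seed integer seed governing all randomness of the generator.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 4200,
                       length_meanlog = log(800), length_sdlog = 0.55,
                       abundance_meanlog = log(100), abundance_sdlog = 1.5,
                       conditions = c("exponential", "stationary"),
                       condition_cor = 0.8,
                       n_hypermutator = 6, n_nonmutator = 6,
                       horizon = 60000,
                       mu_h = 1e-3, mu_n = 1e-5,
                       frac_syn = 0.25, missense_frac = 0.9,
                       beta = 2, gamma = 1, delta = 1,
                       mean_degree = 8,
                       pos_sel_targets = 0, pos_sel_rate = 0,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, length_meanlog = length_meanlog,
              length_sdlog = length_sdlog,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              conditions = as.character(conditions),
              condition_cor = condition_cor,
              n_hypermutator = n_hypermutator, n_nonmutator = n_nonmutator,
              horizon = horizon, mu_h = mu_h, mu_n = mu_n,
              frac_syn = frac_syn, missense_frac = missense_frac,
              beta = beta, gamma = gamma, delta = delta,
              mean_degree = mean_degree,
              pos_sel_targets = pos_sel_targets, pos_sel_rate = pos_sel_rate,
              seed = seed)
  with(cfg, {
    if (n_genes < 1) stop_config("n_genes must be >= 1")
    if (n_hypermutator < 1 || n_nonmutator < 0) {
      stop_config("need n_hypermutator >= 1 and n_nonmutator >= 0")
    }
    if (any(c(mu_h, mu_n, beta, gamma, delta, mean_degree, pos_sel_rate) < 0)) {
      stop_config("rates and couplings must be nonnegative")
    }
    if (frac_syn < 0 || frac_syn > 1 || missense_frac < 0 || missense_frac > 1) {
      stop_config("frac_syn and missense_frac must lie in [0, 1]")
    }
    if (condition_cor < 0 || condition_cor > 1) {
      stop_config("condition_cor must lie in [0, 1]")
    }
    if (!is_whole(seed) || abs(seed) >= 2^31 - 10) {
      stop_config("seed must be a 32-bit integer")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome annotation
#'
#' Lays `n_genes` non-overlapping genes on a single circular reference, with
#' lengths drawn from the configured log-normal and rounded to positive
#' multiples of 3 (whole codons), separated by fixed 50-nt intergenic gaps.
#'
#' @param config a `sim_config`.
#' @return a `gene_annotation` table.
#' @export
generate_genome <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  len <- 3L * pmax(1L, as.integer(round(
    stats::rlnorm(n, config$length_meanlog, config$length_sdlog) / 3)))
  start <- cumsum(c(0L, len[-n] + 50L))
  gene_annotation(gene_id = sprintf("SYNG_%05d", seq_len(n)),
                  start = start, end = start + len,
                  strand = sample(c("+", "-"), n, replace = TRUE))
}

# Latent gene effect u drives both abundance and selection; each condition
# observes z_c = sqrt(r) u + sqrt(1-r) noise, so any two conditions correlate
# at r on the latent (Gaussian copula) scale, and r = 1 reproduces u exactly.
generate_abundance <- function(config, annotations) {
  set.seed(config$seed + 2L)
  n <- nrow(annotations)
  u <- stats::rnorm(n)
  names(u) <- annotations$gene_id
  r <- config$condition_cor
  ab <- do.call(rbind, lapply(config$conditions, function(cond) {
    z <- sqrt(r) * u + sqrt(1 - r) * stats::rnorm(n)
    data.frame(gene_id = annotations$gene_id, condition_id = cond,
               abundance = exp(config$abundance_meanlog +
                                 config$abundance_sdlog * z),
               stringsAsFactors = FALSE)
  }))
  rownames(ab) <- NULL
  list(abundance = ab, z = u)
}

# Degree targets Poisson with mean increasing in abundance (coupling delta),
# realized by an erased configuration model: stubs are paired uniformly and
# self-loops / duplicate pairings are discarded, re-shuffling a few times and
# keeping the realization that loses fewest edges.
generate_ppi <- function(config, annotations, z) {
  set.seed(config$seed + 3L)
  n <- nrow(annotations)
  w <- exp(config$delta * z)
  lambda <- config$mean_degree * w / mean(w)
  target <- stats::rpois(n, lambda)
  if (sum(target) %% 2 == 1) target[which.max(target)] <- target[which.max(target)] + 1L
  stubs <- rep(annotations$gene_id, target)
  best <- NULL
  best_bad <- Inf
  retries <- 0L
  for (attempt in 1:5) {
    s <- sample(stubs)
    a <- s[seq(1, length(s), by = 2)]
    b <- s[seq(2, length(s), by = 2)]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    bad <- sum(lo == hi) + sum(duplicated(paste(lo, hi, sep = "\r")))
    if (bad < best_bad) {
      best <- list(a = a, b = b)
      best_bad <- bad
    }
    if (bad == 0) break
    retries <- attempt
  }
  if (best_bad > 0) {
    message("configuration model: ", retries, " re-pairing attempt(s), ",
            best_bad, " conflicting stub pair(s) erased")
  }
  net <- suppressMessages(ppi_network(best$a, best$b,
                                      network_id = "synthetic_ppi"))
  list(network = net, target_degree = stats::setNames(target,
                                                      annotations$gene_id))
}

#' Generate abundance tables, a PPI network, and the simulation ground truth
#'
#' @param config a `sim_config`.
#' @param annotations genome from [generate_genome()].
#' @param ppi set `FALSE` to skip network generation (abundance-only studies).
#' @return list with `abundance` (long data.frame), `network` (`ppi_network`
#'   or `NULL`), and `truth` (a `sim_truth`: latent standardized
#'   log-abundance `z`, per-gene removal probabilities `pi`, target degrees,
#'   and the config).
#' @export
generate_covariates <- function(config, annotations, ppi = TRUE) {
  ab <- generate_abundance(config, annotations)
  net <- if (ppi) generate_ppi(config, annotations, ab$z) else NULL
  truth <- structure(list(z = ab$z,
                          pi = stats::plogis(config$beta * ab$z),
                          target_degree = if (ppi) net$target_degree else NULL,
                          config = config),
                     class = "sim_truth")
  list(abundance = ab$abundance, network = net$network, truth = truth)
}

#' Simulate per-population tables of ever-observed mutations
#'
#' Hypermutator populations: per gene, nonsynonymous candidates arrive
#' Poisson with mean `mu_h * (1 - frac_syn) * L_g` and survive purifying
#' selection with probability `1 - pi_g`; survivors split missense:nonsense
#' at `missense_frac`.  Synonymous mutations arrive Poisson at the
#' gamma-biased, renormalized rate.  Nonmutator populations use `mu_n` with
#' no selection thinning, plus the optional positive-selection channel that
#' concentrates extra missense mutations in a small random target-gene set
#' shared across nonmutator populations.  First-observation generations are
#' uniform on (0, horizon].
#'
#' @param config a `sim_config`.
#' @param annotations genome annotation.
#' @param truth `sim_truth` from [generate_covariates()].
#' @return a validated mutation record data.frame.
#' @export
simulate_mutation_tables <- function(config, annotations, truth) {
  set.seed(config$seed + 4L)
  n <- nrow(annotations)
  L <- annotations$length_nt
  gid <- annotations$gene_id
  pi_g <- truth$pi
  w <- 1 + config$gamma * pmax(truth$z, 0)
  syn_mult <- w * sum(L) / sum(L * w)

  targets <- if (config$pos_sel_targets > 0) {
    sample(gid, min(config$pos_sel_targets, n))
  } else character()

  one_pop <- function(pop_id, pop_class, mu, thin) {
    ns_cand <- stats::rpois(n, mu * (1 - config$frac_syn) * L)
    surv <- if (thin) stats::rbinom(n, ns_cand, 1 - pi_g) else ns_cand
    mis <- stats::rbinom(n, surv, config$missense_frac)
    non <- surv - mis
    syn <- stats::rpois(n, mu * config$frac_syn * L * syn_mult)
    gene <- c(rep(gid, mis), rep(gid, non), rep(gid, syn))
    cls <- c(rep("missense", sum(mis)), rep("nonsense", sum(non)),
             rep("synonymous", sum(syn)))
    if (pop_class == "nonmutator" && length(targets) > 0 &&
        config$pos_sel_rate > 0) {
      extra <- stats::rpois(length(targets), config$pos_sel_rate)
      gene <- c(gene, rep(targets, extra))
      cls <- c(cls, rep("missense", sum(extra)))
    }
    if (length(gene) == 0) return(NULL)
    data.frame(population_id = pop_id, population_class = pop_class,
               gene_id = gene, mutation_class = cls,
               generation_observed = sample.int(config$horizon, length(gene),
                                                replace = TRUE),
               stringsAsFactors = FALSE)
  }

  parts <- c(
    lapply(seq_len(config$n_hypermutator), function(i) {
      one_pop(sprintf("H%d", i), "hypermutator", config$mu_h, thin = TRUE)
    }),
    lapply(seq_len(config$n_nonmutator), function(i) {
      one_pop(sprintf("N%d", i), "nonmutator", config$mu_n, thin = FALSE)
    }))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- if (length(parts) == 0) {
    data.frame(population_id = character(), population_class = character(),
               gene_id = character(), mutation_class = character(),
               generation_observed = integer(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, parts)
  }
  rownames(out) <- NULL
  validate_mutation_table(out, horizon = config$horizon)
}

#' Run the full synthetic study: genome, covariates, mutation tables
#'
#' @param config a `sim_config`.
#' @param ppi generate the PPI network? (see [generate_covariates()]).
#' @return an `ltee_sim` list: `config`, `annotations`, `abundance`,
#'   `network`, `truth`, `mutations`.
#' @export
simulate_ltee <- function(config = sim_config(), ppi = TRUE) {
  annotations <- generate_genome(config)
  cov <- generate_covariates(config, annotations, ppi = ppi)
  mutations <- simulate_mutation_tables(config, annotations, cov$truth)
  structure(list(config = config, annotations = annotations,
                 abundance = cov$abundance, network = cov$network,
                 truth = cov$truth, mutations = mutations),
            class = "ltee_sim")
}

#' @export
print.ltee_sim <- function(x, ...) {
  cat("Synthetic evolution experiment: ", nrow(x$annotations), " genes, ",
      x$config$n_hypermutator, " hypermutator + ", x$config$n_nonmutator,
      " nonmutator populations, ", nrow(x$mutations),
      " observed mutations over ", x$config$horizon, " generations\n", sep = "")
  invisible(x)
}

#' Write a simulated study in the package's file dialects
#'
#' Emits `annotations.tsv`, `mutations.csv`, `abundance.tsv`, `ppi.tsv`,
#' `truth.tsv` (gene, latent z, removal probability, target degree) and
#' `config.yaml` into `dir`.
#'
#' @param sim an `ltee_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  write_mutation_table(sim$mutations, file.path(dir, "mutations.csv"))
  write_abundance_table(sim$abundance, file.path(dir, "abundance.tsv"))
  if (!is.null(sim$network)) {
    write_ppi_edgelist(sim$network, file.path(dir, "ppi.tsv"))
  }
  truth <- sim$truth
  write_tsv(data.frame(gene_id = names(truth$z), z = as.numeric(truth$z),
                       pi = as.numeric(truth$pi),
                       target_degree =
                         if (is.null(truth$target_degree)) NA_integer_
                         else as.integer(truth$target_degree),
                       stringsAsFactors = FALSE),
            file.path(dir, "truth.tsv"))
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
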