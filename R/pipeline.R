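#' Run the full analysis pipeline from a structured configuration
#'
#' Chains the stages end to end — load or simulate inputs, compute per-gene
#' mutation densities over an analysis grid (population selectors x
#' mutation-class schemes x zeros policies x generation cutoffs), derive PPI
#' degree covariates, run every Spearman association — and writes
#' machine-readable reports into the output directory:
#'
#' * `associations.tsv` — one row per grid cell per covariate
#'   (`covariate_id`, `population_class`, `scheme`, `cutoff`, `zeros_policy`,
#'   `n`, `rho`, `p_value`);
#' * `density_<populations>_<scheme>.tsv` — full-horizon density tables;
#' * `degree_<network>.tsv` — degree maps;
#' * `manifest.yaml` — config echo, config hash, seed and versions, enough to
#'   re-run bit-exactly;
#' * `inputs/` — the emitted simulation inputs, when simulating.
#'
#' The configuration is a list (or a YAML file path) with fields `seed`,
#' `out_dir`, exactly one of `simulate` (a [sim_config()] block) or `inputs`
#' (paths: `annotations`, `mutations`, optional `abundance` and `ppi`, each a
#' path or list of paths), and an optional `grid` block with `populations`,
#' `schemes`, `zeros`, `cutoffs`.  Numeric report files carry full precision.
#'
#' @param config list or YAML file path.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, a list with the association data.frame, the output
#'   directory, and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML path")
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop_config("config must contain exactly one of 'simulate' or 'inputs'")
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_config("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  grid <- config$grid %||% list()
  populations <- grid$populations %||% c("hypermutator", "nonmutator")
  schemes <- grid$schemes %||% c("all", "nonsynonymous", "synonymous")
  zeros <- grid$zeros %||% c("include", "exclude")
  cutoffs <- as.numeric(grid$cutoffs %||% seq(10000, 60000, by = 10000))
  if (length(populations) == 0 || length(schemes) == 0 || length(zeros) == 0 ||
      length(cutoffs) == 0) {
    stop_config("analysis grid must be non-empty")
  }

  message("[stage] inputs")
  if (has_sim) {
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_ltee(scfg)
    annotations <- sim$annotations
    mutations <- sim$mutations
    abundance <- sim$abundance
    networks <- list(sim$network)
    if (isTRUE(config$write_inputs %||% TRUE)) {
      write_simulation(sim, file.path(out_dir, "inputs"))
    }
  } else {
    inp <- config$inputs
    if (is.null(inp$annotations) || is.null(inp$mutations)) {
      stop_config("inputs block needs 'annotations' and 'mutations' paths")
    }
    annotations <- read_gene_annotations(inp$annotations)
    mutations <- read_mutation_table(inp$mutations, horizon = Inf)
    abundance <- if (is.null(inp$abundance)) NULL else {
      do.call(rbind, lapply(unlist(inp$abundance), read_abundance_table))
    }
    networks <- lapply(unlist(inp$ppi), read_ppi_edgelist)
  }

  message("[stage] covariates")
  covariates <- list()
  if (!is.null(abundance)) {
    for (cond in unique(abundance$condition_id)) {
      covariates[[cond]] <- abundance_vector(abundance, cond)
    }
  }
  for (net in networks) {
    if (is.null(net)) next
    deg <- ppi_degree(net)
    covariates[[attr(deg, "covariate_id")]] <- deg
    write_degree_map(deg, file.path(out_dir,
                                    paste0("degree_", net$network_id, ".tsv")))
  }
  if (length(covariates) == 0) {
    stop_config("no covariates: provide abundance tables and/or PPI edge lists")
  }

  message("[stage] density + association grid")
  rows <- list()
  for (pop in populations) {
    for (scheme in schemes) {
      series <- cumulative_series(mutations, annotations, populations = pop,
                                  scheme = scheme, cutoffs = cutoffs)
      write_density_table(series[[length(series)]],
                          file.path(out_dir, sprintf("density_%s_%s.tsv",
                                                     paste(pop, collapse = "-"),
                                                     scheme)))
      for (cov_id in names(covariates)) {
        for (z in zeros) {
          tc <- correlation_time_course(series, covariates[[cov_id]],
                                        zeros = z, covariate_id = cov_id)
          rows[[length(rows) + 1]] <- as.data.frame(tc)
        }
      }
    }
  }
  associations <- do.call(rbind, rows)
  rownames(associations) <- NULL
  write_association_results(associations, file.path(out_dir, "associations.tsv"))

  manifest <- list(
    seed = seed,
    config = config,
    config_md5 = unname(config_md5(config)),
    mutdensity_version = as.character(utils::packageVersion("mutdensity")),
    r_version = R.version.string)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  if (isTRUE(config$plots)) {
    message("[stage] plots")
    grDevices::pdf(file.path(out_dir, "diagnostics.pdf"), width = 6, height = 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (cov_id in names(covariates)) {
      sub <- associations[associations$covariate_id == cov_id &
                            associations$zeros_policy == zeros[1], ]
      for (pop in unique(sub$population_class)) {
        for (scheme in unique(sub$scheme)) {
          d <- sub[sub$population_class == pop & sub$scheme == scheme, ]
          graphics::plot(d$cutoff, d$rho, type = "b", pch = 16,
                         xlab = "generation cutoff", ylab = "Spearman rho",
                         main = paste(cov_id, pop, scheme))
          graphics::abline(h = 0, lty = 3)
        }
      }
    }
  }
  invisible(list(associations = associations, out_dir = out_dir,
                 manifest = manifest))
}

config_md5 <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  tools::md5sum(tmp)
}
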