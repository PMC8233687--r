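test_that("perfect monotone and antitone pairs give rho of 1 and -1", {
  expect_equal(spearman_two_sided(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_two_sided(1:4, c(40, 30, 20, 10))$rho, -1)
})

test_that("rho matches the explicit ranks-then-Pearson oracle, ties included", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    x <- sample(round(rnorm(n), 1))  # rounding induces ties
    y <- round(rnorm(n), 1)
    got <- spearman_two_sided(x, y)
    expect_equal(got$rho, bf_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(got$rho, unname(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
    # t-approximation p agrees with R's standard routine
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("small-sample p-values are exact permutation probabilities", {
  set.seed(5)
  x <- c(2, 9, 1, 5, 7)
  y <- c(3, 8, 2, 9, 1)
  got <- spearman_two_sided(x, y)
  expect_equal(got$method, "exact permutation")
  # independent enumeration: loop over all permutations of y
  perms <- mutdensity:::all_permutations(5)
  rhos <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  expect_equal(got$p_value,
               mean(abs(rhos) >= abs(cor(x, y, method = "spearman")) - 1e-12))
  # and matches cor.test's exact two-sided p for tie-free data
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("spearman test is symmetric and rejects degenerate input", {
  set.seed(2)
  x <- rnorm(20)
  y <- rnorm(20)
  a <- spearman_two_sided(x, y)
  b <- spearman_two_sided(y, x)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_value, b$p_value)

  expect_error(spearman_two_sided(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_two_sided(1:2, 1:2), "at least 3")
  expect_error(spearman_two_sided(1:5, 1:4), "equal length")
  expect_error(spearman_two_sided(c(1, NA, 3), 1:3), "NA")
})

test_that("result is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rexp(40) + 0.1
  y <- rnorm(40)
  base <- spearman_two_sided(x, y)
  for (f in list(sqrt, log, function(v) v^2, function(v) 5 * v + 2)) {
    tr <- spearman_two_sided(f(x), y)
    expect_equal(tr$rho, base$rho, tolerance = 1e-12)
    expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("associate intersects gene sets and applies the zeros policy", {
  ann <- make_ann(sprintf("g%02d", 1:10), len = rep(300, 10))
  rec <- make_records(rep("H1", 9), "hypermutator",
                      rep(sprintf("g%02d", 1:6), c(2, 1, 3, 1, 1, 1)),
                      "missense", rep(100, 9))
  dt <- mutation_density(rec, ann, "hypermutator", "all", 60000)
  covariate <- stats::setNames(seq(1, 10) + 0.1 * rnorm(10), ann$gene_id)

  inc <- associate(dt, covariate, zeros = "include")
  exc <- associate(dt, covariate, zeros = "exclude")
  expect_equal(inc$n, 10)
  expect_equal(exc$n, 6)  # 4 genes have m_g = 0

  # covariate covering only part of the gene universe restricts n
  part <- covariate[1:5]
  expect_equal(associate(dt, part)$n, 5)

  # policies coincide when no gene has m_g = 0
  dt6 <- dt[dt$count > 0, ]
  attr(dt6, "subset") <- attr(dt, "subset")
  class(dt6) <- class(dt)
  i6 <- associate(dt6, covariate, zeros = "include")
  e6 <- associate(dt6, covariate, zeros = "exclude")
  expect_equal(i6$rho, e6$rho)
  expect_equal(i6$p_value, e6$p_value)
  expect_equal(i6$n, e6$n)
})

test_that("associate errors on tiny intersections and constant covariates", {
  ann <- make_ann()
  rec <- make_records("H1", "hypermutator", "g1", "missense", 1)
  dt <- mutation_density(rec, ann, "hypermutator", "all", 60000)
  expect_error(associate(dt, c(g1 = 1, g2 = 2)), "fewer than 3")
  expect_error(associate(dt, stats::setNames(rep(2, 3), ann$gene_id)),
               "constant")
})

test_that("associate accepts data.frame covariates and carries descriptors", {
  set.seed(21)
  inst <- random_instance(n_genes = 12)
  dt <- mutation_density(inst$rec, inst$ann, "all", "all", 60000)
  cov_df <- data.frame(gene_id = inst$ann$gene_id,
                       degree = rpois(12, 5) + 1)
  res <- associate(dt, cov_df, zeros = "include")
  expect_equal(res$subset$covariate_id, "degree")
  expect_equal(res$subset$scheme, "all")
  row <- as.data.frame(res)
  expect_named(row, c("covariate_id", "population_class", "scheme", "cutoff",
                      "zeros_policy", "n", "rho", "p_value"))
  # multi-condition tables must be disambiguated first
  ab2 <- data.frame(gene_id = rep(inst$ann$gene_id, 2),
                    condition_id = rep(c("a", "b"), each = 12),
                    abundance = runif(24))
  expect_error(associate(dt, ab2), "abundance_vector")
})

test_that("correlation time course matches per-cutoff direct tests", {
  set.seed(13)
  inst <- random_instance(n_genes = 15, n_records = 50)
  covariate <- stats::setNames(rexp(15), inst$ann$gene_id)
  cuts <- c(10000, 30000, 60000)
  series <- cumulative_series(inst$rec, inst$ann, "all", "all", cuts)
  tc <- correlation_time_course(series, covariate, zeros = "include")
  expect_length(tc, 3)
  expect_equal(names(tc), as.character(cuts))
  direct <- associate(series[[3]], covariate, zeros = "include")
  expect_equal(tc[[3]]$rho, direct$rho)
  expect_equal(tc[[3]]$p_value, direct$p_value)

  # saturated series gives identical rho at every cutoff
  early <- inst$rec
  early$generation_observed <- 100L
  s2 <- cumulative_series(early, inst$ann, "all", "all", cuts)
  tc2 <- correlation_time_course(s2, covariate)
  expect_equal(tc2[[1]]$rho, tc2[[3]]$rho)

  d <- as.data.frame(tc)
  expect_equal(d$cutoff, cuts)
  p <- tempfile(fileext = ".tsv")
  write_association_results(tc, p)
  expect_equal(nrow(read.delim(p)), 3)
})
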