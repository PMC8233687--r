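test_that("GFF3 coordinates convert to 0-based half-open with correct lengths", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsynth\tgene\t101\t400\t.\t+\t.\tID=g1;Name=geneA",
    "chr1\tsynth\tgene\t501\t800\t.\t-\t.\tID=g2;Name=geneB"), gff)
  ann <- read_gene_annotations(gff)
  expect_s3_class(ann, "gene_annotation")
  expect_equal(ann$start, c(100L, 500L))
  expect_equal(ann$end, c(400L, 800L))
  expect_equal(ann$length_nt, c(300L, 300L))
  expect_equal(ann$strand, c("+", "-"))
})

test_that("GFF3 and its equivalent TSV rendering yield identical annotations", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsynth\tgene\t101\t400\t.\t+\t.\tID=g1;Name=geneA",
    "chr1\tsynth\tgene\t501\t800\t.\t-\t.\tID=g2;Name=geneB",
    "chr1\tsynth\tgene\t1001\t1300\t.\t+\t.\tID=g3;Name=geneC"), gff)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tname\tstart_1based\tend_1based\tstrand",
               "g1\tgeneA\t101\t400\t+",
               "g2\tgeneB\t501\t800\t-",
               "g3\tgeneC\t1001\t1300\t+"), tsv)
  expect_equal(read_gene_annotations(gff), read_gene_annotations(tsv))
})

test_that("annotation invariants are enforced", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tname\tstart_1based\tend_1based\tstrand",
               "ECB_00001\ta\t1\t300\t+",
               "ECB_00002\tb\t400\t900\t+",
               "ECB_00001\tc\t1000\t1200\t+"), tsv)
  expect_error(read_gene_annotations(tsv), "ECB_00001")

  expect_error(gene_annotation("g1", start = 100, end = 100, strand = "+"),
               "length")
  expect_error(read_gene_annotations(tempfile()), "not found")
})

test_that("annotation TSV write/read round-trips", {
  ann <- make_ann(c("a", "b", "c"), len = c(90, 1200, 333))
  p <- tempfile(fileext = ".tsv")
  write_gene_annotations(ann, p)
  expect_equal(read_gene_annotations(p), ann)
})

test_that("mutation table reads validate classes, generations and round-trip", {
  rec <- make_records(c("H1", "H1", "H2", "N1", "N1"),
                      c(rep("hypermutator", 3), rep("nonmutator", 2)),
                      c("g1", "g2", "g1", INTERGENIC, "g3"),
                      c("missense", "synonymous", "indel", "noncoding", "sv"),
                      c(500, 10000, 60000, 25000, 0))
  p <- tempfile(fileext = ".csv")
  write_mutation_table(suppressMessages(validate_mutation_table(rec)), p)
  rt <- suppressMessages(read_mutation_table(p))
  expect_equal(as.data.frame(rt), rec)
  expect_message(read_mutation_table(p), "INTERGENIC")

  bad <- rec
  bad$mutation_class[3] <- "promoter"
  write.csv(bad, p, row.names = FALSE, quote = FALSE)
  expect_error(suppressMessages(read_mutation_table(p)), "row 3")

  bad <- rec
  bad$population_class[2] <- "mutator"
  write.csv(bad, p, row.names = FALSE, quote = FALSE)
  expect_error(suppressMessages(read_mutation_table(p)), "row 2")

  expect_error(validate_mutation_table(transform(rec, generation_observed =
    generation_observed + 0.5)), "non-integer")
  expect_error(validate_mutation_table(rec, horizon = 50000), "horizon")
})

test_that("header-only mutation file yields empty collection with a warning", {
  p <- tempfile(fileext = ".csv")
  writeLines(paste("population_id", "population_class", "gene_id",
                   "mutation_class", "generation_observed", sep = ","), p)
  expect_warning(out <- read_mutation_table(p), "no records")
  expect_equal(nrow(out), 0)
})

test_that("PPI loading collapses reciprocal duplicates and drops self-loops", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta", "b\tc"), p)
  net <- suppressMessages(read_ppi_edgelist(p))
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes, c("a", "b", "c"))

  writeLines("a\ta", p)
  net <- suppressMessages(read_ppi_edgelist(p))
  expect_equal(nrow(net$edges), 0)
  expect_message(read_ppi_edgelist(p), "self-loop")

  writeLines(c("a\tb", "b\tc", "c\ta"), p)
  net <- read_ppi_edgelist(p)
  expect_equal(nrow(net$edges), 3)
  expect_equal(length(net$nodes), 3)
})

test_that("PPI loading is order-independent and rejects malformed rows", {
  edges <- data.frame(a = c("x", "y", "z", "w"), b = c("y", "z", "x", "x"))
  p1 <- tempfile()
  p2 <- tempfile()
  writeLines(paste(edges$a, edges$b, sep = "\t"), p1)
  shuffled <- sample(nrow(edges))
  writeLines(paste(edges$b[shuffled], edges$a[shuffled], sep = "\t"), p2)
  expect_equal(read_ppi_edgelist(p1, network_id = "n"),
               read_ppi_edgelist(p2, network_id = "n"))

  writeLines(c("a\tb", "c"), p1)
  expect_error(read_ppi_edgelist(p1), "row 2")
})

test_that("PPI confidence scores can be thresholded at load time", {
  p <- tempfile()
  writeLines(c("a\tb\t900", "b\tc\t150", "c\td\t400"), p)
  expect_equal(nrow(read_ppi_edgelist(p)$edges), 3)
  expect_equal(nrow(read_ppi_edgelist(p, min_score = 400)$edges), 2)
})

test_that("abundance tables validate and extract per-condition vectors", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcondition_id\tabundance",
               "g1\texp\t10.5", "g2\texp\t0", "g1\tstat\t3"), p)
  ab <- read_abundance_table(p)
  expect_equal(nrow(ab), 3)
  v <- abundance_vector(ab, "exp")
  expect_equal(as.numeric(v), c(10.5, 0))
  expect_equal(names(v), c("g1", "g2"))
  expect_equal(attr(v, "covariate_id"), "exp")
  expect_error(abundance_vector(ab, "missing_cond"), "not present")

  writeLines(c("gene_id\tcondition_id\tabundance", "g1\texp\t-2"), p)
  expect_error(read_abundance_table(p), "negative")
})

test_that("trajectory input converts to first-observation records", {
  traj <- data.frame(
    allele_id = c("m1", "m1", "m1", "m2", "m2"),
    population_id = "H1", population_class = "hypermutator",
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    mutation_class = c(rep("missense", 3), rep("synonymous", 2)),
    generation = c(10000, 20000, 30000, 10000, 20000),
    frequency = c(0, 0.2, 0.8, 0, 0),
    stringsAsFactors = FALSE)
  out <- first_observed(traj)
  expect_equal(nrow(out), 1)  # m2 never reaches positive frequency
  expect_equal(out$generation_observed, 20000L)
  expect_equal(out$gene_id, "g1")
})
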