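# Coverage normalisation formula and the enrichment QC metrics.

test_that("normalisation matches hand evaluation of the formula", {
  counts <- matrix(c(100, 0), nrow = 1, dimnames = list("g1", c("r1", "r2")))
  reg <- as_region_table(tibble::tibble(
    region_id = c("r1", "r2"), chrom = "chrA01",
    start = c(0L, 2000L), end = c(1000L, 3000L),
    is_target = TRUE, annotation_class = "target_gene"))
  p <- coverage_panel(counts, c(g1 = 10000), genome_length = 1e6)
  norm <- normalize_coverage(p, reg)
  # (100 * 1e6) / (1e4 * 1e3) = 10
  expect_equal(norm$norm[1, "r1"], 10)
  expect_equal(norm$norm[1, "r2"], 0)
  # count = total, region length = genome length -> exactly 1
  c_id <- matrix(10000, 1, dimnames = list("g1", "whole"))
  reg_id <- as_region_table(tibble::tibble(
    region_id = "whole", chrom = "chrA01", start = 0L, end = 1000000L,
    is_target = TRUE, annotation_class = "target_gene"))
  p_id <- coverage_panel(c_id, c(g1 = 10000), genome_length = 1e6)
  expect_equal(normalize_coverage(p_id, reg_id)$norm[1, "whole"], 1)
})

test_that("normalisation is invariant to joint library scaling", {
  set.seed(42)
  counts <- matrix(rpois(20, 50), nrow = 4,
                   dimnames = list(paste0("g", 1:4), paste0("r", 1:5)))
  reg <- as_region_table(tibble::tibble(
    region_id = paste0("r", 1:5), chrom = "chrA01",
    start = seq(0L, 8000L, 2000L), end = seq(0L, 8000L, 2000L) + 1000L,
    is_target = TRUE, annotation_class = "target_gene"))
  totals <- setNames(rowSums(counts) + 500, rownames(counts))
  p1 <- coverage_panel(counts, totals, genome_length = 1e7)
  p2 <- coverage_panel(counts * 7, totals * 7, genome_length = 1e7)
  n1 <- normalize_coverage(p1, reg)
  n2 <- normalize_coverage(p2, reg)
  expect_equal(n1$norm, n2$norm)
  expect_equal(target_specificity(p1, reg), target_specificity(p2, reg))
  expect_equal(enrichment_factor(p1, reg), enrichment_factor(p2, reg))
})

test_that("mass identity links normalised coverage to the on-target fraction", {
  sim <- simulate_panel(sim_config(n_genotypes = 12, n_regions = 50,
                                   n_target_regions = 20,
                                   n_homeolog_groups = 5, seed = 2))
  norm <- normalize_coverage(sim$panel, sim$regions)
  lhs <- as.vector((norm$norm %*% norm$region_length) / norm$genome_length)
  rhs <- unname(rowSums(sim$panel$counts) / sim$panel$total_aligned_reads)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("genome-wide and target coverage follow the counting definitions", {
  counts <- matrix(c(100, 0), nrow = 1, dimnames = list("g1", c("t1", "t2")))
  reg <- as_region_table(tibble::tibble(
    region_id = c("t1", "t2"), chrom = "chrA01",
    start = c(0L, 5000L), end = c(1000L, 6000L),
    is_target = TRUE, annotation_class = "target_gene"))
  p <- coverage_panel(counts, c(g1 = 5e6), read_length = 100,
                      genome_length = 8.5e8)
  expect_equal(genome_wide_coverage(p)$genome_wide_coverage,
               5e6 * 100 / 8.5e8)  # 0.588x
  # one covered target of 1000 bp with 100 reads of 100 bp -> 100x over t1,
  # averaged with the empty equal-length t2 -> 5x
  expect_equal(target_coverage(p, reg)$target_coverage, 5)
  expect_equal(enrichment_factor(p, reg)$enrichment_factor,
               5 / (5e6 * 100 / 8.5e8))
  # doubling the library doubles genome-wide coverage
  p2 <- coverage_panel(counts, c(g1 = 1e7), read_length = 100,
                       genome_length = 8.5e8)
  expect_equal(genome_wide_coverage(p2)$genome_wide_coverage,
               2 * genome_wide_coverage(p)$genome_wide_coverage)
})

test_that("target specificity is the on-target read percentage", {
  counts <- matrix(c(68, 10), nrow = 1, dimnames = list("g1", c("t1", "n1")))
  reg <- as_region_table(tibble::tibble(
    region_id = c("t1", "n1"), chrom = "chrA01",
    start = c(0L, 5000L), end = c(1000L, 6000L),
    is_target = c(TRUE, FALSE),
    annotation_class = c("target_gene", "non_target_other")))
  p <- coverage_panel(counts, c(g1 = 100))
  expect_equal(target_specificity(p, reg)$target_specificity, 68)
  p0 <- coverage_panel(matrix(c(0, 10), 1, dimnames = dimnames(counts)),
                       c(g1 = 100))
  expect_equal(target_specificity(p0, reg)$target_specificity, 0)
})

test_that("target sensitivity counts covered bases and is monotone in depth", {
  reg <- as_region_table(tibble::tibble(
    region_id = c("t1", "t2"), chrom = "chrA01",
    start = c(0L, 5000L), end = c(100L, 5100L),
    is_target = TRUE, annotation_class = "target_gene"))
  prof <- tibble::tibble(
    genotype_id = "g1", region_id = c("t1", "t2"),
    depths = list(rep(5L, 100), rep(0L, 100)))
  expect_equal(target_sensitivity(prof, reg, 1)$target_sensitivity, 50)
  expect_equal(target_sensitivity(prof, reg, 6)$target_sensitivity, 0)
  prof11 <- tibble::tibble(
    genotype_id = "g1", region_id = c("t1", "t2"),
    depths = list(rep(11L, 100), rep(11L, 100)))
  expect_equal(target_sensitivity(prof11, reg, 11)$target_sensitivity, 100)
  expect_equal(target_sensitivity(prof11, reg, 12)$target_sensitivity, 0)
  # non-increasing in min_depth on an arbitrary profile
  set.seed(1)
  profr <- tibble::tibble(genotype_id = "g1", region_id = c("t1", "t2"),
                          depths = list(sample(0:20, 100, TRUE),
                                        sample(0:20, 100, TRUE)))
  sens <- vapply(1:20, function(d)
    target_sensitivity(profr, reg, d)$target_sensitivity, 0)
  expect_true(all(diff(sens) <= 0))
  # a missing target profile is an error
  expect_error(target_sensitivity(prof[1, ], reg), "missing depth profile")
})

test_that("qc report aggregates per-genotype metrics and morphotype means", {
  sim <- simulate_panel(sim_config(n_genotypes = 20, n_regions = 40,
                                   n_target_regions = 16,
                                   n_homeolog_groups = 4, seed = 8))
  qc <- qc_report(sim$panel, sim$regions, labels = sim$morphotypes)
  per <- tidy(qc)
  # single-genotype consistency with the individual operations
  expect_equal(per$enrichment_factor,
               enrichment_factor(sim$panel, sim$regions)$enrichment_factor)
  expect_equal(per$target_specificity,
               target_specificity(sim$panel, sim$regions)$target_specificity)
  # panel mean is the arithmetic mean of per-genotype values
  expect_equal(glance(qc)$target_coverage, mean(per$target_coverage))
  # per-morphotype means partition the panel mean (weighted average)
  bym <- qc$by_morphotype
  expect_equal(sum(bym$n * bym$target_coverage) / sum(bym$n),
               glance(qc)$target_coverage)
})
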