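# Synthetic-panel generator: noiseless identities, determinism, Poisson
# behaviour, truth bookkeeping and depth-profile placement.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genotypes = 30, n_regions = 60, n_target_regions = 24,
         n_homeolog_groups = 8, seed = 11),
    list(...))
  do.call(sim_config, args)
}

test_that("config validation rejects impossible demands", {
  expect_error(sim_config(n_regions = 10, n_target_regions = 20),
               "n_target_regions")
  expect_error(sim_config(event_prevalence = 1.2), "0, 1")
  expect_error(sim_config(event_prevalence = 0.6), "exceeds 1")
  expect_error(sim_config(deletion_ratio = -1), ">= 0")
  expect_error(sim_config(n_homeolog_groups = 0, hnrt_prevalence = 0.01),
               "no homeolog pairs")
  expect_error(small_cfg(n_homeolog_groups = 50), "target-gene regions")
})

test_that("noiseless event-free panel has unit copy ratios and empty truth", {
  sim <- simulate_panel(small_cfg(noise = "none", event_prevalence = 0,
                                  hnrt_prevalence = 0))
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(sim$copy_ratio == 1))
  # all-normal panel: every ratio of normalised coverage to panel mean is 1
  calls <- call_cnv(normalize_coverage(sim$panel, sim$regions))
  active <- calls$calls[, colSums(sim$panel$counts) > 0]
  expect_true(all(active == "normal"))
})

test_that("noiseless deletions with ratio zero produce zero counts", {
  sim <- simulate_panel(small_cfg(noise = "none", deletion_ratio = 0))
  del <- sim$truth[sim$truth$event_type == "simple_deletion", ]
  idx <- cbind(match(del$genotype_id, rownames(sim$panel$counts)),
               match(del$region_id, colnames(sim$panel$counts)))
  expect_true(all(sim$panel$counts[idx] == 0))
})

test_that("identical seeds reproduce panels bit-exactly, different seeds differ", {
  a <- simulate_panel(small_cfg())
  b <- simulate_panel(small_cfg())
  expect_identical(a$panel$counts, b$panel$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$morphotypes, b$morphotypes)
  c <- simulate_panel(small_cfg(seed = 12))
  expect_false(identical(a$panel$counts, c$panel$counts))
})

test_that("copy ratios differ from 1 exactly at planted-event cells", {
  sim <- simulate_panel(small_cfg())
  truth_cells <- unique(rbind(
    cbind(sim$truth$genotype_id, sim$truth$region_id),
    cbind(sim$truth$genotype_id[sim$truth$event_type == "hnrt"],
          sim$truth$partner_region_id[sim$truth$event_type == "hnrt"])
  ))
  idx <- cbind(match(truth_cells[, 1], rownames(sim$copy_ratio)),
               match(truth_cells[, 2], colnames(sim$copy_ratio)))
  expect_true(all(sim$copy_ratio[idx] != 1))
  altered <- matrix(FALSE, nrow(sim$copy_ratio), ncol(sim$copy_ratio))
  altered[idx] <- TRUE
  expect_identical(unname(sim$copy_ratio != 1), altered)
})

test_that("planted HNRTs duplicate the donor copy and delete the acceptor", {
  sim <- simulate_panel(small_cfg(hnrt_prevalence = 0.05))
  hn <- sim$truth[sim$truth$event_type == "hnrt", ]
  expect_gt(nrow(hn), 0)
  sub <- setNames(sim$regions$subgenome, sim$regions$region_id)
  src <- ifelse(hn$direction == "A_to_C", "A", "C")
  dst <- ifelse(hn$direction == "A_to_C", "C", "A")
  expect_equal(unname(sub[hn$region_id]), src)
  expect_equal(unname(sub[hn$partner_region_id]), dst)
  gi <- match(hn$genotype_id, rownames(sim$copy_ratio))
  expect_true(all(sim$copy_ratio[cbind(gi, match(hn$region_id,
    colnames(sim$copy_ratio)))] == sim$config$duplication_ratio))
  expect_true(all(sim$copy_ratio[cbind(gi, match(hn$partner_region_id,
    colnames(sim$copy_ratio)))] == sim$config$deletion_ratio))
})

test_that("Poisson counts match the noiseless expectation within sampling error", {
  cfg_none <- small_cfg(n_genotypes = 150, event_prevalence = 0,
                        hnrt_prevalence = 0, library_size_sd = 0,
                        noise = "none")
  cfg_pois <- small_cfg(n_genotypes = 150, event_prevalence = 0,
                        hnrt_prevalence = 0, library_size_sd = 0,
                        noise = "poisson")
  mu <- simulate_panel(cfg_none)$panel$counts  # = expectation (rounded)
  x <- simulate_panel(cfg_pois)$panel$counts
  n <- nrow(mu)
  se <- sqrt(colSums(mu)) / n  # SE of the per-region mean under Poisson
  dev <- abs(colMeans(x) - colMeans(mu))
  expect_gte(mean(dev <= 3 * se), 0.98)
  # law of large numbers: at expectation >= 1e4 the relative deviation is
  # small (2% is 2 sigma there, so a ~95% share) and vanishes on average
  big <- mu >= 1e4
  expect_gt(sum(big), 100)
  expect_gte(mean(abs(x[big] / mu[big] - 1) <= 0.02), 0.93)
  expect_lt(abs(mean(x[big] / mu[big]) - 1), 0.002)
})

test_that("morphotype proportions and prevalence multipliers are honoured", {
  sim <- simulate_panel(small_cfg(n_genotypes = 280))
  tab <- table(sim$morphotypes$morphotype)
  expect_equal(as.integer(tab[c("winter", "spring", "other")]),
               c(137L, 94L, 49L))
  # doubling prevalence in one group raises its event count
  sim2 <- simulate_panel(sim_config(
    n_genotypes = 200, n_regions = 100, n_target_regions = 40,
    n_homeolog_groups = 10, seed = 4, event_prevalence = 0.05,
    morphotype_prevalence_multiplier = c(winter = 3)))
  per <- dplyr::count(dplyr::inner_join(sim2$truth, sim2$morphotypes,
                                        by = "genotype_id"),
                      .data$morphotype)
  lab_n <- table(sim2$morphotypes$morphotype)
  rate <- setNames(per$n / as.integer(lab_n[per$morphotype]), per$morphotype)
  expect_gt(rate[["winter"]], 2 * rate[["spring"]])
})

test_that("depth profiles obey the read-placement counting identity", {
  reg <- as_region_table(tibble::tibble(
    region_id = c("exact", "long"), chrom = "chrA01",
    start = c(0L, 1000L), end = c(100L, 2000L),
    is_target = TRUE, annotation_class = "target_gene"))
  counts <- matrix(c(5, 100), nrow = 1,
                   dimnames = list("g1", c("exact", "long")))
  p <- coverage_panel(counts, c(g1 = 1000), read_length = 100)
  prof <- simulate_depth_profiles(p, reg, seed = 9)
  exact <- prof$depths[[which(prof$region_id == "exact")]]
  expect_equal(exact, rep(5L, 100))  # read length == region length
  long <- prof$depths[[which(prof$region_id == "long")]]
  expect_equal(sum(long), 100 * 100)  # no truncation possible
  # zero count gives an all-zero profile
  p0 <- coverage_panel(matrix(0, 1, 2, dimnames = dimnames(counts)),
                       c(g1 = 1000), read_length = 100)
  prof0 <- simulate_depth_profiles(p0, reg, seed = 9)
  expect_true(all(vapply(prof0$depths, sum, 0) == 0))
})
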