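# Classification of calls into simple events and directional HNRTs,
# subgenome summaries, correlation and landscape.

# call matrix over the tiny_regions() fixture, all-normal unless overridden
tiny_calls <- function(..., genotypes = c("g1", "g2")) {
  reg <- tiny_regions()
  m <- matrix("normal", length(genotypes), nrow(reg),
              dimnames = list(genotypes, reg$region_id))
  edits <- list(...)
  for (e in edits) m[e[[1]], e[[2]]] <- e[[3]]
  calls_from_matrix(m)
}

test_that("a coupled duplication-deletion across subgenomes becomes an HNRT", {
  calls <- tiny_calls(list("g1", "Bna.X.A03", "duplication"),
                      list("g1", "Bna.X.C03", "deletion"))
  ev <- classify_events(calls, tiny_homeologs(), tiny_regions())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "hnrt")
  expect_equal(ev$region_id, "Bna.X.A03")
  expect_equal(ev$partner_region_id, "Bna.X.C03")
  expect_equal(ev$direction, "A_to_C")
  expect_equal(ev$subgenome, "A")
})

test_that("unmatched calls stay simple events, with or without a homeolog", {
  calls <- tiny_calls(list("g1", "Bna.X.A03", "duplication"),
                      list("g2", "gene_solo", "deletion"))
  ev <- classify_events(calls, tiny_homeologs(), tiny_regions())
  expect_equal(ev$event_type[ev$genotype_id == "g1"], "simple_duplication")
  expect_equal(ev$direction[ev$genotype_id == "g1"], "none")
  expect_equal(ev$event_type[ev$genotype_id == "g2"], "simple_deletion")
})

test_that("random-scaffold copies are excluded from pairing but keep simple calls", {
  calls <- tiny_calls(list("g1", "Bna.X.A03", "duplication"),
                      list("g1", "Bna.X.C03", "deletion"),
                      list("g1", "Bna.X.C03_random", "deletion"))
  ev <- classify_events(calls, tiny_homeologs(), tiny_regions(),
                        exclude_random = TRUE)
  hn <- ev[ev$event_type == "hnrt", ]
  expect_equal(hn$partner_region_id, "Bna.X.C03")
  expect_equal(ev$event_type[ev$region_id == "Bna.X.C03_random"],
               "simple_deletion")
  # with exclusion off the random copy is pairable; lexicographic greediness
  # still prefers Bna.X.C03 over Bna.X.C03_random
  ev2 <- classify_events(calls, tiny_homeologs(), tiny_regions(),
                         exclude_random = FALSE)
  expect_equal(ev2$partner_region_id[ev2$event_type == "hnrt"], "Bna.X.C03")
})

test_that("both orientations can coexist within one homeolog group", {
  calls <- tiny_calls(list("g1", "Bna.Y.C02", "duplication"),
                      list("g1", "Bna.Y.A02", "deletion"))
  ev <- classify_events(calls, tiny_homeologs(), tiny_regions())
  expect_equal(ev$direction, "C_to_A")
  expect_equal(ev$region_id, "Bna.Y.C02")
})

test_that("classification rejects a map referencing regions absent from calls", {
  calls <- tiny_calls()
  calls$calls <- calls$calls[, 1:2]
  expect_error(classify_events(calls, tiny_homeologs(), tiny_regions()),
               "absent from calls")
})

test_that("every deletion and duplication call is consumed exactly once", {
  sim <- simulate_panel(sim_config(n_genotypes = 50, n_regions = 120,
                                   n_target_regions = 48,
                                   n_homeolog_groups = 15,
                                   hnrt_prevalence = 0.05, seed = 31))
  calls <- call_cnv(normalize_coverage(sim$panel, sim$regions))
  ev <- classify_events(calls, sim$homeologs, sim$regions)
  n_del_calls <- sum(calls$calls == "deletion")
  n_dup_calls <- sum(calls$calls == "duplication")
  n_hnrt <- sum(ev$event_type == "hnrt")
  expect_equal(sum(ev$event_type == "simple_deletion") + n_hnrt, n_del_calls)
  expect_equal(sum(ev$event_type == "simple_duplication") + n_hnrt, n_dup_calls)
  # direction consistency: donor subgenome = source, acceptor = destination
  hn <- ev[ev$event_type == "hnrt", ]
  sub <- setNames(sim$regions$subgenome, sim$regions$region_id)
  expect_true(all(sub[hn$region_id] ==
                    ifelse(hn$direction == "A_to_C", "A", "C")))
  expect_true(all(sub[hn$partner_region_id] ==
                    ifelse(hn$direction == "A_to_C", "C", "A")))
})

test_that("subgenome summary tallies events at nested scopes", {
  reg <- tiny_regions()
  ev <- tibble::tibble(
    genotype_id = c("g1", "g1", "g2", "g2", "g3"),
    region_id = c("Bna.X.C03", "Bna.Y.C02", "Bna.X.C03", "Bna.Y.A02",
                  "gene_solo"),
    event_type = c("simple_deletion", "simple_deletion", "simple_deletion",
                   "simple_deletion", "simple_deletion"),
    partner_region_id = NA_character_, direction = "none",
    subgenome = c("C", "C", "C", "A", "A"))
  sg <- subgenome_event_counts(ev, reg)
  tab <- sg$simple
  get <- function(scope, sub) {
    tab$n[tab$scope == scope & tab$subgenome == sub &
            tab$event_type == "simple_deletion"]
  }
  expect_equal(get("target", "C"), 3L)
  expect_equal(get("target", "A"), 1L)
  expect_equal(get("genic", "A"), 2L)   # gene_solo counts as genic, not target
  expect_equal(get("all", "A"), 2L)
  # empty event table gives all-zero counts
  sg0 <- subgenome_event_counts(capcnv:::empty_event_table(), reg)
  expect_true(all(sg0$simple$n == 0))
  expect_true(all(sg0$hnrt$n == 0))
})

test_that("HNRT events count toward direction, not simple tallies", {
  reg <- tiny_regions()
  ev <- tibble::tibble(
    genotype_id = "g1", region_id = "Bna.X.A03", event_type = "hnrt",
    partner_region_id = "Bna.X.C03", direction = "A_to_C", subgenome = "A")
  sg <- subgenome_event_counts(ev, reg)
  expect_true(all(sg$simple$n == 0))
  expect_equal(sg$hnrt$n[sg$hnrt$direction == "A_to_C"], 1L)
  expect_equal(sg$hnrt$n[sg$hnrt$direction == "C_to_A"], 0L)
})

test_that("deletion-duplication correlation matches the textbook formula", {
  reg <- as_region_table(tibble::tibble(
    region_id = sprintf("Bna.G%d.C0%d", 1:5, 1:5),
    chrom = sprintf("chrC0%d", 1:5),
    start = 0L, end = 1000L, is_target = TRUE,
    annotation_class = "target_gene"))
  counts <- tibble::tibble(del = c(3L, 1L, 4L, 1L, 5L),
                           dup = c(2L, 7L, 1L, 8L, 2L))
  ev <- dplyr::bind_rows(
    purrr::map2_dfr(reg$region_id, counts$del, function(r, n) {
      tibble::tibble(genotype_id = sprintf("g%02d", seq_len(n)),
                     region_id = r, event_type = "simple_deletion",
                     partner_region_id = NA_character_,
                     direction = "none", subgenome = "C")
    }),
    purrr::map2_dfr(reg$region_id, counts$dup, function(r, n) {
      tibble::tibble(genotype_id = sprintf("h%02d", seq_len(n)),
                     region_id = r, event_type = "simple_duplication",
                     partner_region_id = NA_character_,
                     direction = "none", subgenome = "C")
    }))
  res <- deletion_duplication_correlation(ev, reg, "C")
  # independent oracle: covariance over sd product, coded out by hand
  x <- counts$del; y <- counts$dup
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  expect_equal(res$n_units, 5L)
  # perfect correlation when y = x
  ev_eq <- ev[ev$event_type == "simple_deletion", ]
  ev_eq2 <- ev_eq
  ev_eq2$event_type <- "simple_duplication"
  ev_eq2$genotype_id <- paste0("h", ev_eq2$genotype_id)
  expect_equal(deletion_duplication_correlation(
    dplyr::bind_rows(ev_eq, ev_eq2), reg, "C")$estimate, 1)
  # zero variance is an error
  flat <- dplyr::bind_rows(
    tibble::tibble(genotype_id = "g1", region_id = reg$region_id,
                   event_type = "simple_deletion",
                   partner_region_id = NA_character_,
                   direction = "none", subgenome = "C"))
  expect_error(deletion_duplication_correlation(flat, reg, "C"),
               "zero variance")
})

test_that("landscape pair counts conserve the HNRT total", {
  sim <- simulate_panel(sim_config(n_genotypes = 60, n_regions = 100,
                                   n_target_regions = 40,
                                   n_homeolog_groups = 12,
                                   hnrt_prevalence = 0.06, seed = 13))
  calls <- call_cnv(normalize_coverage(sim$panel, sim$regions))
  ev <- classify_events(calls, sim$homeologs, sim$regions)
  land <- hnrt_landscape(ev, sim$regions)
  expect_equal(sum(land$pairs$n), sum(ev$event_type == "hnrt"))
  # per-region simple counts equal direct tallies of the event table
  tal <- table(ev$region_id[ev$event_type == "simple_deletion"])
  for (r in names(tal)) {
    expect_equal(land$simple$simple_deletions[land$simple$region_id == r],
                 as.integer(tal[[r]]))
  }
})
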