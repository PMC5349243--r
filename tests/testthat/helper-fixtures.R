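# Shared fixtures: a small hand-built region table with homeolog pairs and a
# random-scaffold copy, plus constructors for call matrices and panels.

tiny_regions <- function() {
  as_region_table(tibble::tribble(
    ~region_id,          ~chrom,          ~start, ~end,  ~is_target, ~gene_label,      ~annotation_class,
    "Bna.X.A03",         "chrA03",        1000L,  2000L, TRUE,       "Bna.X.A03",      "target_gene",
    "Bna.X.C03",         "chrC03",        1000L,  2000L, TRUE,       "Bna.X.C03",      "target_gene",
    "Bna.X.C03_random",  "chrCnn_random", 0L,     1000L, TRUE,       "Bna.X.C03_random", "target_gene",
    "Bna.Y.A02",         "chrA02",        500L,   1500L, TRUE,       "Bna.Y.A02",      "target_gene",
    "Bna.Y.C02",         "chrC02",        500L,   1500L, TRUE,       "Bna.Y.C02",      "target_gene",
    "gene_solo",         "chrA07",        0L,     2000L, FALSE,      "gene_solo",      "non_target_gene",
    "reg_other",         "chrC05",        0L,     500L,  FALSE,      "",               "non_target_other"
  ))
}

tiny_homeologs <- function(regions = tiny_regions()) {
  as_homeolog_map(
    tibble::tibble(group_id = c("X", "X", "X", "Y", "Y"),
                   region_id = c("Bna.X.A03", "Bna.X.C03",
                                 "Bna.X.C03_random", "Bna.Y.A02",
                                 "Bna.Y.C02")),
    regions)
}

# cnv_calls object built directly from a character matrix of call states
calls_from_matrix <- function(m, lower = 0.5, upper = 1.5) {
  structure(list(calls = m, ratio = NULL, lower = lower, upper = upper),
            class = "cnv_calls")
}

# small coverage panel with uniform counts unless overridden
tiny_panel <- function(counts, totals = NULL, read_length = 100,
                       genome_length = 1e6) {
  if (is.null(totals)) totals <- rowSums(counts) * 2
  coverage_panel(counts, totals, read_length = read_length,
                 genome_length = genome_length)
}
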