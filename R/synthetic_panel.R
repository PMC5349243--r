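# Synthetic coverage-panel generator with planted CNV and HNRT events and
# known truth. Emulates a targeted sequence-capture experiment on a diversity
# panel of inbred allotetraploid lines; see the methods vignette for the
# read-depth model and the choice of defaults.

#' Simulation configuration for a synthetic capture panel
#'
#' The defaults describe a species-wide diversity panel of 280 inbred
#' *Brassica napus*-like genotypes captured over 1184 regions, 231 of which
#' are intended targets sequenced to a mean depth of 670x with 100 bp
#' single-end reads. Because the lines are inbred (5+ generations selfed),
#' planted deletions are homozygous (expected copy ratio 0) and duplications
#' carry one extra copy pair (ratio 2); heterozygous intermediates (0.5/1.5)
#' can be requested for threshold-sensitivity studies.
#'
#' Expected reads for a region are
#' `mean_target_depth * length / read_length`, multiplied by
#' `off_target_depth_factor` for non-target regions, by a per-region gamma
#' capture efficiency (mean 1, shape `capture_efficiency_shape`), a
#' per-genotype lognormal library factor (sigma `library_size_sd`) and the
#' planted copy ratio. Counts are Poisson around that expectation
#' (`noise = "poisson"`) or its rounded value (`noise = "none"`). The
#' per-genotype total aligned reads are set so that the on-target read
#' fraction equals `on_target_fraction`.
#'
#' @param n_genotypes Number of inbred genotypes in the panel.
#' @param n_regions Total number of captured regions.
#' @param n_target_regions Number of intended target regions (target genes,
#'   promoter hits and pseudogenes); must be `<= n_regions`.
#' @param n_homeolog_groups Number of homeolog pairs (one A-subgenome and one
#'   C-subgenome target-gene copy each) available for HNRT planting.
#' @param mean_target_depth Mean sequencing depth over target regions
#'   (x-fold).
#' @param off_target_depth_factor Depth of captured non-target regions
#'   relative to targets.
#' @param on_target_fraction Fraction of each genotype's aligned reads that
#'   fall in target regions (target specificity / 100).
#' @param read_length Read length in bases.
#' @param genome_length Reference assembly length in bases.
#' @param region_length_range Integer range regions lengths are drawn from.
#' @param deletion_ratio Expected copy ratio of a planted deletion.
#' @param duplication_ratio Expected copy ratio of a planted duplication.
#' @param event_prevalence Per-(genotype, region) probability of a simple
#'   deletion, and likewise of a simple duplication; at most one event is
#'   planted per cell, so `2 * event_prevalence` must be `<= 1`.
#' @param hnrt_prevalence Per-(genotype, homeolog pair) probability of a
#'   planted HNRT (coupled duplication at the donor copy and deletion at the
#'   acceptor copy).
#' @param hnrt_direction_bias Probability a planted HNRT is oriented
#'   A-subgenome to C-subgenome (A copy duplicated, C copy deleted).
#' @param library_size_sd Lognormal sigma of the per-genotype library factor.
#' @param capture_efficiency_shape Gamma shape of the per-region capture
#'   efficiency; the Gamma-Poisson mixture makes counts overdispersed across
#'   regions while staying Poisson within a region.
#' @param n_dropout_targets Number of target regions with zero capture
#'   efficiency, mimicking target copies that failed enrichment; no events
#'   are planted there and downstream calling reports them as `no_call`.
#' @param random_scaffold_fraction Fraction of non-target regions placed on
#'   unassembled `*_random` scaffolds.
#' @param morphotype_proportions Named numeric vector of relative group
#'   sizes for morphotype labels.
#' @param morphotype_prevalence_multiplier Optional named vector scaling
#'   event prevalences per morphotype, to emulate morphotype-enriched CNVs.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   panels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 280,
                       n_regions = 1184,
                       n_target_regions = 231,
                       n_homeolog_groups = 90,
                       mean_target_depth = 670,
                       off_target_depth_factor = 0.05,
                       on_target_fraction = 0.68,
                       read_length = 100,
                       genome_length = 8.5e8,
                       region_length_range = c(500L, 3000L),
                       deletion_ratio = 0,
                       duplication_ratio = 2,
                       event_prevalence = 0.02,
                       hnrt_prevalence = 0.01,
                       hnrt_direction_bias = 0.82,
                       library_size_sd = 0.3,
                       capture_efficiency_shape = 20,
                       n_dropout_targets = 2,
                       random_scaffold_fraction = 0.03,
                       morphotype_proportions = c(winter = 137, spring = 94,
                                                  other = 49),
                       morphotype_prevalence_multiplier = NULL,
                       noise = c("poisson", "none"),
                       seed = 1L) {
  noise <- match.arg(noise)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genotypes >= 1, cfg$n_regions >= 1)
  if (cfg$n_target_regions > cfg$n_regions) {
    abort("n_target_regions exceeds n_regions")
  }
  if (cfg$deletion_ratio < 0 || cfg$duplication_ratio < 0) {
    abort("copy ratios must be >= 0")
  }
  for (p in c("event_prevalence", "hnrt_prevalence", "hnrt_direction_bias",
              "on_target_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(paste0(p, " must lie in [0, 1]"))
    }
  }
  mult <- max(1, cfg$morphotype_prevalence_multiplier %||% 1)
  if (2 * cfg$event_prevalence * mult > 1) {
    abort("2 * event_prevalence (times any morphotype multiplier) exceeds 1")
  }
  if (cfg$hnrt_prevalence > 0 && cfg$n_homeolog_groups < 1) {
    abort("HNRTs requested but no homeolog pairs available")
  }
  n_class <- target_class_sizes(cfg$n_target_regions)
  if (2 * cfg$n_homeolog_groups > n_class[["target_gene"]]) {
    abort(sprintf(
      "n_homeolog_groups = %d needs %d target-gene regions but only %d exist",
      cfg$n_homeolog_groups, 2 * cfg$n_homeolog_groups,
      n_class[["target_gene"]]))
  }
  invisible(cfg)
}

# Split the target count into gene / promoter-hit / pseudogene classes with
# the proportions of the emulated experiment (186 : 33 : 12 of 231).
target_class_sizes <- function(n_target) {
  n_prom <- round(n_target * 33 / 231)
  n_pseudo <- round(n_target * 12 / 231)
  c(target_gene = n_target - n_prom - n_pseudo,
    target_promoter = n_prom, pseudogene = n_pseudo)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d genotypes x %d regions (%d targets, %d homeolog pairs)\n",
    "  depth %gx, noise = %s, seed = %d\n"),
    x$n_genotypes, x$n_regions, x$n_target_regions, x$n_homeolog_groups,
    x$mean_target_depth, x$noise, x$seed))
  invisible(x)
}

# Deterministic region scaffold for a config: region table + homeolog map.
build_sim_regions <- function(cfg) {
  n_class <- target_class_sizes(cfg$n_target_regions)
  n_pairs <- cfg$n_homeolog_groups
  n_single_tg <- n_class[["target_gene"]] - 2 * n_pairs
  pair_chr <- ((seq_len(max(n_pairs, 1)) - 1L) %% 9L) + 1L

  rows <- list()
  homeo <- list()
  if (n_pairs > 0) {
    gene <- sprintf("G%03d", seq_len(n_pairs))
    a_id <- sprintf("Bna.%s.A%02d", gene, pair_chr[seq_len(n_pairs)])
    c_id <- sprintf("Bna.%s.C%02d", gene, pair_chr[seq_len(n_pairs)])
    rows$pair_a <- tibble(region_id = a_id,
                          chrom = sprintf("chrA%02d", pair_chr[seq_len(n_pairs)]),
                          gene_label = a_id, annotation_class = "target_gene")
    rows$pair_c <- tibble(region_id = c_id,
                          chrom = sprintf("chrC%02d", pair_chr[seq_len(n_pairs)]),
                          gene_label = c_id, annotation_class = "target_gene")
    homeo <- tibble(group_id = rep(gene, 2), region_id = c(a_id, c_id))
  } else {
    homeo <- tibble(group_id = character(), region_id = character())
  }
  if (n_single_tg > 0) {
    sub <- rep(c("A", "C"), length.out = n_single_tg)
    chr <- ((seq_len(n_single_tg) - 1L) %% 9L) + 1L
    id <- sprintf("Bna.S%03d.%s%02d", seq_len(n_single_tg), sub, chr)
    rows$single_tg <- tibble(region_id = id,
                             chrom = sprintf("chr%s%02d", sub, chr),
                             gene_label = id, annotation_class = "target_gene")
  }
  n_prom <- n_class[["target_promoter"]]
  if (n_prom > 0) {
    sub <- rep(c("A", "C"), length.out = n_prom)
    chr <- ((seq_len(n_prom) - 1L) %% 9L) + 1L
    rows$prom <- tibble(region_id = sprintf("prom_%03d", seq_len(n_prom)),
                        chrom = sprintf("chr%s%02d", sub, chr),
                        gene_label = "", annotation_class = "target_promoter")
  }
  n_pseudo <- n_class[["pseudogene"]]
  if (n_pseudo > 0) {
    sub <- rep(c("A", "C"), length.out = n_pseudo)
    chr <- ((seq_len(n_pseudo) - 1L) %% 9L) + 1L
    rows$pseudo <- tibble(region_id = sprintf("pseudo_%03d", seq_len(n_pseudo)),
                          chrom = sprintf("chr%s%02d", sub, chr),
                          gene_label = "", annotation_class = "pseudogene")
  }
  n_off <- cfg$n_regions - cfg$n_target_regions
  if (n_off > 0) {
    n_genic <- round(n_off * 453 / 953)
    n_other <- n_off - n_genic
    if (n_genic > 0) {
      sub <- rep(c("A", "C"), length.out = n_genic)
      chr <- ((seq_len(n_genic) - 1L) %% 9L) + 1L
      id <- sprintf("gene_%04d", seq_len(n_genic))
      rows$genic <- tibble(region_id = id,
                           chrom = sprintf("chr%s%02d", sub, chr),
                           gene_label = id, annotation_class = "non_target_gene")
    }
    if (n_other > 0) {
      n_rand <- round(n_other * cfg$random_scaffold_fraction)
      sub <- rep(c("A", "C"), length.out = n_other)
      chr <- ((seq_len(n_other) - 1L) %% 9L) + 1L
      chrom <- sprintf("chr%s%02d", sub, chr)
      if (n_rand > 0) {
        chrom[seq_len(n_rand)] <- sprintf("chr%snn_random",
                                          sub[seq_len(n_rand)])
      }
      rows$other <- tibble(region_id = sprintf("reg_%04d", seq_len(n_other)),
                           chrom = chrom, gene_label = "",
                           annotation_class = "non_target_other")
    }
  }
  df <- dplyr::bind_rows(rows)
  df$is_target <- df$annotation_class %in%
    c("target_gene", "target_promoter", "pseudogene")
  rng <- as.integer(cfg$region_length_range)
  df$length <- sample(seq(rng[1], rng[2]), nrow(df), replace = TRUE)
  # lay regions along each chromosome with fixed spacing
  df <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(start = cumsum(dplyr::lag(.data$length, default = 0L) + 5000L),
                  end = .data$start + .data$length) |>
    dplyr::ungroup()
  regions <- as_region_table(df[, c("region_id", "chrom", "start", "end",
                                    "is_target", "gene_label",
                                    "annotation_class")])
  list(regions = regions, homeologs = homeo)
}

#' Simulate a coverage panel with planted events and known truth
#'
#' Draws a full synthetic capture experiment: region scaffold with homeolog
#' pairs, morphotype labels, planted simple deletions/duplications and
#' coupled HNRT events, and a genotypes-by-regions count matrix under the
#' read-depth model described in [sim_config()]. The returned truth table
#' uses the same schema as [classify_events()] output, so recovery can be
#' scored directly.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_panel` with elements `panel`
#'   ([coverage_panel()]), `regions` (region table), `homeologs` (homeolog
#'   map), `truth` (tibble: `genotype_id`, `region_id`, `event_type`,
#'   `partner_region_id`, `direction`; HNRT rows carry the duplicated donor
#'   copy as `region_id` and the deleted acceptor copy as
#'   `partner_region_id`), `morphotypes` (label tibble), `copy_ratio`
#'   (latent genotypes-by-regions expected copy-ratio matrix) and `config`.
#' @examples
#' sim <- simulate_panel(sim_config(n_genotypes = 8, n_regions = 40,
#'                                  n_target_regions = 20,
#'                                  n_homeolog_groups = 6, seed = 7))
#' sim$truth
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  scaffold <- build_sim_regions(cfg)
  regions <- scaffold$regions
  homeo <- scaffold$homeologs
  n_g <- cfg$n_genotypes
  n_r <- nrow(regions)
  geno <- sprintf("geno_%03d", seq_len(n_g))

  # morphotype labels with fixed overall proportions
  prop <- cfg$morphotype_proportions / sum(cfg$morphotype_proportions)
  n_per <- floor(prop * n_g)
  rest <- n_g - sum(n_per)
  if (rest > 0) {
    top <- order(prop * n_g - n_per, decreasing = TRUE)[seq_len(rest)]
    n_per[top] <- n_per[top] + 1L
  }
  morpho_lab <- sample(rep(names(n_per), times = n_per))
  morphotypes <- tibble(genotype_id = geno, morphotype = morpho_lab)

  mult <- rep(1, n_g)
  if (!is.null(cfg$morphotype_prevalence_multiplier)) {
    m <- cfg$morphotype_prevalence_multiplier
    hit <- morpho_lab %in% names(m)
    mult[hit] <- unname(m[morpho_lab[hit]])
  }

  # per-region capture efficiency and per-genotype library factor
  eff <- rgamma(n_r, shape = cfg$capture_efficiency_shape,
                rate = cfg$capture_efficiency_shape)
  dropout <- character()
  if (cfg$n_dropout_targets > 0) {
    candidates <- regions$region_id[regions$is_target &
                                      !(regions$region_id %in% homeo$region_id)]
    dropout <- head(candidates, cfg$n_dropout_targets)
    eff[match(dropout, regions$region_id)] <- 0
  }
  lib <- rlnorm(n_g, meanlog = -cfg$library_size_sd^2 / 2,
                sdlog = cfg$library_size_sd)

  # plant events into the latent copy-ratio matrix
  ratio <- matrix(1, n_g, n_r, dimnames = list(geno, regions$region_id))
  truth <- list()
  n_pairs <- cfg$n_homeolog_groups
  if (n_pairs > 0 && cfg$hnrt_prevalence > 0) {
    groups <- split(homeo$region_id, homeo$group_id)
    sub <- setNames(regions$subgenome, regions$region_id)
    u <- matrix(runif(n_g * n_pairs), n_g, n_pairs)
    v <- matrix(runif(n_g * n_pairs), n_g, n_pairs)
    hit <- u < cfg$hnrt_prevalence * mult
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      gnames <- names(groups)
      recs <- lapply(seq_len(nrow(idx)), function(i) {
        g <- idx[i, 1]; k <- idx[i, 2]
        members <- groups[[gnames[k]]]
        a_copy <- members[sub[members] == "A"][1]
        c_copy <- members[sub[members] == "C"][1]
        a_to_c <- v[g, k] < cfg$hnrt_direction_bias
        donor <- if (a_to_c) a_copy else c_copy
        acceptor <- if (a_to_c) c_copy else a_copy
        tibble(genotype_id = geno[g], region_id = donor,
               event_type = "hnrt", partner_region_id = acceptor,
               direction = if (a_to_c) "A_to_C" else "C_to_A")
      })
      truth$hnrt <- dplyr::bind_rows(recs)
      ri <- match(truth$hnrt$region_id, regions$region_id)
      pi <- match(truth$hnrt$partner_region_id, regions$region_id)
      gi <- match(truth$hnrt$genotype_id, geno)
      ratio[cbind(gi, ri)] <- cfg$duplication_ratio
      ratio[cbind(gi, pi)] <- cfg$deletion_ratio
    }
  }
  if (cfg$event_prevalence > 0) {
    u <- matrix(runif(n_g * n_r), n_g, n_r)
    eligible <- ratio == 1
    eligible[, regions$region_id %in% dropout] <- FALSE
    p <- cfg$event_prevalence * mult  # per-genotype prevalence
    del <- eligible & (u < p)
    dup <- eligible & (u >= p) & (u < 2 * p)
    # A simple duplication on one copy of a homeolog pair coinciding with a
    # simple deletion on the other copy in the same genotype is, by the
    # coupled-event definition, indistinguishable from an HNRT; suppress the
    # deletion so every planted event has an identifiable classification.
    if (nrow(homeo) > 0) {
      grp <- split(match(homeo$region_id, regions$region_id), homeo$group_id)
      sub_idx <- regions$subgenome
      for (members in grp) {
        a_i <- members[sub_idx[members] == "A"][1]
        c_i <- members[sub_idx[members] == "C"][1]
        if (is.na(a_i) || is.na(c_i)) next
        del[dup[, a_i] & del[, c_i], c_i] <- FALSE
        del[dup[, c_i] & del[, a_i], a_i] <- FALSE
      }
    }
    ratio[del] <- cfg$deletion_ratio
    ratio[dup] <- cfg$duplication_ratio
    di <- which(del, arr.ind = TRUE)
    if (nrow(di) > 0) {
      truth$del <- tibble(genotype_id = geno[di[, 1]],
                          region_id = regions$region_id[di[, 2]],
                          event_type = "simple_deletion",
                          partner_region_id = NA_character_,
                          direction = "none")
    }
    pi <- which(dup, arr.ind = TRUE)
    if (nrow(pi) > 0) {
      truth$dup <- tibble(genotype_id = geno[pi[, 1]],
                          region_id = regions$region_id[pi[, 2]],
                          event_type = "simple_duplication",
                          partner_region_id = NA_character_,
                          direction = "none")
    }
  }
  truth <- dplyr::bind_rows(truth)
  if (nrow(truth) == 0) {
    truth <- tibble(genotype_id = character(), region_id = character(),
                    event_type = character(), partner_region_id = character(),
                    direction = character())
  }
  truth <- dplyr::arrange(truth, .data$genotype_id, .data$region_id)

  # expected reads and observed counts
  base <- cfg$mean_target_depth * regions$length / cfg$read_length
  base <- base * ifelse(regions$is_target, 1, cfg$off_target_depth_factor)
  mu <- (lib %o% (base * eff)) * ratio
  counts <- switch(cfg$noise,
    poisson = matrix(rpois(length(mu), mu), n_g, n_r),
    none = round(mu))
  dimnames(counts) <- dimnames(ratio)

  on_target <- rowSums(counts[, regions$is_target, drop = FALSE])
  totals <- pmax(ceiling(on_target / cfg$on_target_fraction),
                 rowSums(counts), 1)
  panel <- coverage_panel(counts, setNames(totals, geno),
                          read_length = cfg$read_length,
                          genome_length = cfg$genome_length)
  structure(
    list(panel = panel, regions = regions, homeologs = homeo, truth = truth,
         morphotypes = morphotypes, copy_ratio = ratio, config = cfg),
    class = "sim_panel"
  )
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d genotypes x %d regions, %d planted events\n",
              nrow(x$panel$counts), ncol(x$panel$counts), nrow(x$truth)))
  print(dplyr::count(x$truth, .data$event_type))
  invisible(x)
}

#' Simulate per-base depth profiles for target regions
#'
#' Places each counted read of a target region at a start position drawn
#' uniformly among the positions where the read fits; regions shorter than
#' the read length are covered end to end with reads truncated at the region
#' edge. Total per-region depth therefore equals `count * read_length` minus
#' edge truncation. Intended for base-resolution QC (target sensitivity,
#' covered-fraction metrics); profiles for a full 280-genotype panel are
#' large, so a genotype subset can be requested.
#'
#' @param panel A [coverage_panel()], typically from [simulate_panel()].
#' @param regions Region table matching the panel.
#' @param genotypes Genotype ids to simulate profiles for (default: all).
#' @param seed Optional integer seed.
#' @return Depth-profile tibble (`genotype_id`, `region_id`, `depths`
#'   list-column), target regions only.
#' @export
simulate_depth_profiles <- function(panel, regions,
                                    genotypes = genotype_ids(panel),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rl <- panel$read_length
  targets <- regions[regions$is_target, ]
  if (any(targets$length < 1)) abort("region shorter than 1 base")
  grid <- tidyr::expand_grid(genotype_id = genotypes,
                             region_id = targets$region_id)
  len <- setNames(targets$length, targets$region_id)
  grid$depths <- purrr::map2(grid$genotype_id, grid$region_id, function(g, r) {
    n <- panel$counts[g, r]
    l <- len[[r]]
    if (n == 0) return(integer(l))
    if (l <= rl) return(rep.int(as.integer(n), l))
    starts <- sample.int(l - rl + 1L, n, replace = TRUE)
    d <- integer(l + 1L)
    tab <- tabulate(starts, nbins = l + 1L)
    ends <- tabulate(starts + rl, nbins = l + 1L)
    as.integer(cumsum(tab - ends)[seq_len(l)])
  })
  grid
}
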