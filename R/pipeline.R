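# End-to-end orchestration: simulate (or read) -> normalize -> call ->
# classify -> summarize -> validate, with fixed-seed determinism and a
# checksummed output manifest.

#' Configuration for an end-to-end analysis run
#'
#' Inputs are either a simulation config (`sim`) or paths to on-disk tables
#' (counts + metadata + regions, optionally homeolog map and morphotype
#' labels). All thresholds of the downstream stages are collected here.
#'
#' @param sim A [sim_config()], used when no `counts_path` is given. Its
#'   seed is overridden by `seed`.
#' @param counts_path,meta_path Counts and library-metadata TSVs
#'   (see [read_counts()]).
#' @param regions_path,annotation_path Region BED and annotation TSV.
#' @param homeologs_path Optional homeolog-map TSV.
#' @param morphotypes_path Optional morphotype-label TSV.
#' @param lower,upper CNV ratio thresholds (see [call_cnv()]).
#' @param rare_threshold Rare-CNV frequency threshold.
#' @param depth_threshold Depth for the high-coverage QC fraction.
#' @param exclude_random Exclude random-scaffold copies from HNRT pairing.
#' @param marker_call_rate,maf,individual_call_rate Marker filter
#'   thresholds (see [filter_markers()]).
#' @param validation_discordance For simulated runs: fraction of non-missing
#'   marker calls flipped in an emulated re-assay, against which the
#'   concordance stage is run.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed governing every random draw of the run.
#' @param verbose Log stage progress to standard error.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(sim = sim_config(),
                            counts_path = NULL, meta_path = NULL,
                            regions_path = NULL, annotation_path = NULL,
                            homeologs_path = NULL, morphotypes_path = NULL,
                            lower = 0.5, upper = 1.5,
                            rare_threshold = 0.10, depth_threshold = 11,
                            exclude_random = TRUE,
                            marker_call_rate = 0.9, maf = 0.01,
                            individual_call_rate = 0.8,
                            validation_discordance = 0.05,
                            out_dir = tempfile("capcnv_run_"),
                            seed = 1L, verbose = TRUE) {
  cfg <- as.list(environment())
  paths <- c(cfg$counts_path, cfg$meta_path, cfg$regions_path,
             cfg$annotation_path, cfg$homeologs_path, cfg$morphotypes_path)
  missing_p <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing_p) > 0) {
    abort(paste0("input path does not exist: ", missing_p[1]))
  }
  class(cfg) <- "analysis_config"
  cfg
}

run_stage <- function(stage, verbose, expr) {
  if (verbose) message(sprintf("[%s] ...", stage))
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

# All floating-point outputs are written with 6 significant digits so that
# manifest checksums are stable across platforms; full precision is kept
# in memory.
write_tsv_fixed <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                        ~ signif(.x, 6)))
  readr::write_tsv(df, path)
}

#' Run the full CNV analysis pipeline
#'
#' Executes simulate (or load) -> coverage normalisation -> panel-relative
#' CNV calling -> event classification -> frequency / subgenome / landscape
#' summaries -> QC report -> marker recoding, filtering and (for simulated
#' runs) concordance against an emulated re-assay, writing every output as
#' a TSV into `config$out_dir` together with a manifest of MD5 checksums.
#' For simulated inputs a truth-recovery report is written as well.
#' Identical configurations and seeds produce identical manifests.
#'
#' @param config An [analysis_config()].
#' @return Object of class `capcnv_run`: list with `out_dir`, `manifest`
#'   (tibble `file`, `md5`) and the in-memory `results`.
#' @export
run_analysis <- function(config) {
  cfg <- config
  v <- cfg$verbose
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write_tsv_fixed(df, path)
    outputs <<- c(outputs, path)
    path
  }

  sim <- NULL
  panel <- regions <- homeologs <- morphotypes <- NULL
  if (is.null(cfg$counts_path)) {
    sim <- run_stage("simulate", v, {
      sc <- cfg$sim
      sc$seed <- cfg$seed
      simulate_panel(sc)
    })
    panel <- sim$panel; regions <- sim$regions
    homeologs <- sim$homeologs; morphotypes <- sim$morphotypes
    write_regions(regions, file.path(cfg$out_dir, "regions.bed"),
                  file.path(cfg$out_dir, "region_annotation.tsv"))
    outputs <- c(outputs, file.path(cfg$out_dir, "regions.bed"),
                 file.path(cfg$out_dir, "region_annotation.tsv"))
    write_counts(panel, file.path(cfg$out_dir, "counts.tsv"),
                 file.path(cfg$out_dir, "library_meta.tsv"))
    outputs <- c(outputs, file.path(cfg$out_dir, "counts.tsv"),
                 file.path(cfg$out_dir, "library_meta.tsv"))
    emit(sim$truth, "truth.tsv")
    emit(morphotypes, "morphotypes.tsv")
    emit(homeologs, "homeologs.tsv")
  } else {
    loaded <- run_stage("load", v, {
      panel <- read_counts(cfg$counts_path, cfg$meta_path)
      regions <- read_regions(cfg$regions_path, cfg$annotation_path)
      homeologs <- if (!is.null(cfg$homeologs_path)) {
        read_homeolog_map(cfg$homeologs_path, regions)
      } else {
        tibble(group_id = character(), region_id = character())
      }
      morphotypes <- if (!is.null(cfg$morphotypes_path)) {
        read_morphotypes(cfg$morphotypes_path, genotype_ids(panel))
      } else {
        NULL
      }
      list(panel = panel, regions = regions, homeologs = homeologs,
           morphotypes = morphotypes)
    })
    panel <- loaded$panel; regions <- loaded$regions
    homeologs <- loaded$homeologs; morphotypes <- loaded$morphotypes
  }

  norm <- run_stage("normalize", v, normalize_coverage(panel, regions))
  write_norm_coverage_fixed(norm, file.path(cfg$out_dir, "norm_coverage.tsv"))
  outputs <- c(outputs, file.path(cfg$out_dir, "norm_coverage.tsv"))

  qc <- run_stage("qc", v,
                  qc_report(panel, regions, labels = morphotypes,
                            depth_threshold = cfg$depth_threshold))
  emit(qc$per_genotype, "qc_report.tsv")
  emit(qc$panel, "qc_panel_means.tsv")
  if (!is.null(qc$by_morphotype)) emit(qc$by_morphotype, "qc_morphotype_means.tsv")

  calls <- run_stage("call", v, call_cnv(norm, cfg$lower, cfg$upper))
  write_cnv_calls(calls, file.path(cfg$out_dir, "calls.tsv"))
  outputs <- c(outputs, file.path(cfg$out_dir, "calls.tsv"))

  freq <- run_stage("frequency", v,
                    cnv_frequency_spectrum(calls, labels = morphotypes,
                                           rare_threshold = cfg$rare_threshold))
  emit(freq$frequencies, "cnv_frequencies.tsv")
  emit(glance(freq), "cnv_frequency_summary.tsv")

  events <- run_stage("classify", v,
                      classify_events(calls, homeologs, regions,
                                      exclude_random = cfg$exclude_random))
  emit(events, "events.tsv")

  summ <- run_stage("summarize", v, {
    sg <- subgenome_event_counts(events, regions)
    land <- hnrt_landscape(events, regions)
    list(sg = sg, land = land)
  })
  emit(summ$sg$simple, "subgenome_summary.tsv")
  emit(summ$sg$hnrt, "hnrt_directions.tsv")
  emit(summ$land$pairs, "hnrt_landscape_pairs.tsv")
  emit(summ$land$simple, "hnrt_landscape_regions.tsv")

  validation <- run_stage("validate", v, {
    markers <- recode_cnv_markers(calls)
    filtered <- filter_markers(markers, cfg$marker_call_rate, cfg$maf,
                               cfg$individual_call_rate)
    conc <- NULL
    if (!is.null(sim) && ncol(filtered) > 0 && cfg$validation_discordance > 0) {
      reassay <- flip_markers(filtered, cfg$validation_discordance)
      pairs <- tibble(marker_a = colnames(filtered),
                      marker_b = colnames(filtered))
      conc <- concordance_rate(filtered, reassay, pairs)
    }
    list(markers = markers, filtered = filtered, concordance = conc)
  })
  write_marker_matrix(validation$markers,
                      file.path(cfg$out_dir, "cnv_markers.tsv"))
  write_marker_matrix(validation$filtered,
                      file.path(cfg$out_dir, "cnv_markers_filtered.tsv"))
  outputs <- c(outputs, file.path(cfg$out_dir, "cnv_markers.tsv"),
               file.path(cfg$out_dir, "cnv_markers_filtered.tsv"))
  if (!is.null(validation$concordance)) {
    emit(validation$concordance$per_marker, "concordance_per_marker.tsv")
    emit(glance(validation$concordance), "concordance_summary.tsv")
  }

  recovery <- NULL
  if (!is.null(sim)) {
    recovery <- run_stage("recovery", v,
                          recovery_report(calls, events, sim$truth))
    emit(recovery, "recovery.tsv")
  }

  manifest <- tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs))
  ) |>
    dplyr::arrange(.data$file)
  manifest_with_seed <- dplyr::bind_rows(
    manifest, tibble(file = "(seed)", md5 = as.character(cfg$seed)))
  readr::write_tsv(manifest_with_seed, file.path(cfg$out_dir, "manifest.tsv"))
  if (v) message(sprintf("[done] %d outputs in %s", length(outputs),
                         cfg$out_dir))
  structure(
    list(out_dir = cfg$out_dir, manifest = manifest_with_seed,
         results = list(panel = panel, regions = regions,
                        homeologs = homeologs, morphotypes = morphotypes,
                        norm = norm, qc = qc, calls = calls, freq = freq,
                        events = events, subgenome = summ$sg,
                        landscape = summ$land, validation = validation,
                        recovery = recovery, truth = if (!is.null(sim)) sim$truth)),
    class = "capcnv_run"
  )
}

# norm matrix at fixed precision for checksum stability
write_norm_coverage_fixed <- function(norm, path) {
  df <- as_tibble(signif(norm$norm, 6))
  df <- dplyr::bind_cols(tibble(genotype_id = rownames(norm$norm)), df)
  readr::write_tsv(df, path)
}

# Emulated re-assay of a marker matrix: flip a fraction of the non-missing
# calls (0 <-> 1).
flip_markers <- function(m, discordance) {
  idx <- which(!is.na(m))
  n_flip <- round(length(idx) * discordance)
  if (n_flip > 0) {
    flip <- sample(idx, n_flip)
    m[flip] <- 1L - m[flip]
  }
  m
}

#' @export
print.capcnv_run <- function(x, ...) {
  cat(sprintf("<capcnv_run> %d outputs in %s\n",
              nrow(x$manifest) - 1L, x$out_dir))
  invisible(x)
}

#' @describeIn run_analysis the output manifest (file, md5).
#' @param x A `capcnv_run`.
#' @param ... Unused.
#' @method tidy capcnv_run
#' @export
tidy.capcnv_run <- function(x, ...) x$manifest
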