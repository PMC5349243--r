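# Coverage normalisation and target-enrichment QC metrics.

#' Normalise per-region coverage by library size, region length and genome
#' length
#'
#' For each genotype and captured region the aligned-read count is scaled to
#'
#' \deqn{cov_{norm} = \frac{reads_{region} \times L_{genome}}
#'                         {reads_{total} \times L_{region}}}
#'
#' i.e. the region's read density relative to the genome-wide average read
#' density of that genotype's library. A value of 1 means the region drew
#' reads exactly at the genome-average rate; capture-enriched targets sit in
#' the hundreds. The scaling cancels library-size differences between
#' genotypes and length differences between regions, which is what makes the
#' panel-relative CNV ratio of [call_cnv()] meaningful.
#'
#' @param panel A [coverage_panel()].
#' @param regions Region table covering every region of the panel.
#' @return An object of class `norm_coverage`: list with the
#'   genotypes-by-regions matrix `norm`, the named `region_length` vector
#'   and `genome_length`.
#' @export
normalize_coverage <- function(panel, regions) {
  ids <- region_ids(panel)
  missing_r <- setdiff(ids, regions$region_id)
  if (length(missing_r) > 0) {
    abort(paste0("region absent from region table: ", missing_r[1]))
  }
  len <- setNames(as.numeric(regions$length), regions$region_id)[ids]
  if (any(panel$total_aligned_reads <= 0)) {
    abort(paste0("zero total aligned reads for genotype ",
                 names(panel$total_aligned_reads)[panel$total_aligned_reads <= 0][1]))
  }
  norm <- panel$counts * panel$genome_length /
    (panel$total_aligned_reads %o% len)
  structure(
    list(norm = norm, region_length = len, genome_length = panel$genome_length),
    class = "norm_coverage"
  )
}

#' @export
print.norm_coverage <- function(x, ...) {
  cat(sprintf("<norm_coverage> %d genotypes x %d regions\n",
              nrow(x$norm), ncol(x$norm)))
  invisible(x)
}

#' @export
dim.norm_coverage <- function(x) dim(x$norm)

#' @export
genotype_ids.norm_coverage <- function(x) rownames(x$norm)

#' @export
region_ids.norm_coverage <- function(x) colnames(x$norm)

#' @describeIn normalize_coverage long-format view of the normalised matrix.
#' @param x A `norm_coverage` object.
#' @param ... Unused.
#' @method tidy norm_coverage
#' @export
tidy.norm_coverage <- function(x, ...) {
  tibble(
    genotype_id = rep(rownames(x$norm), times = ncol(x$norm)),
    region_id = rep(colnames(x$norm), each = nrow(x$norm)),
    norm_coverage = as.vector(x$norm)
  )
}

#' Write / read a normalised coverage matrix
#'
#' Same layout as the counts TSV (first column `genotype_id`, one column per
#' region). Values are written at full precision.
#'
#' @param norm A `norm_coverage` object (write) or path (read).
#' @param path Output TSV path.
#' @return The object, invisibly (write) or a plain genotypes-by-regions
#'   numeric matrix (read).
#' @export
write_norm_coverage <- function(norm, path) {
  df <- as_tibble(norm$norm)
  df <- dplyr::bind_cols(tibble(genotype_id = rownames(norm$norm)), df)
  readr::write_tsv(df, path)
  invisible(norm)
}

#' @rdname write_norm_coverage
#' @export
read_norm_coverage <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(genotype_id = "c",
                                                .default = "d"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genotype_id
  m
}

#' Per-genotype mean genome-wide coverage
#'
#' The x-fold coverage the library would give spread evenly over the whole
#' genome: `total_aligned_reads * read_length / genome_length`. For capture
#' experiments this is well below 1 (the point of enrichment is that reads
#' are not spread evenly).
#'
#' @param panel A [coverage_panel()].
#' @return Tibble with columns `genotype_id`, `genome_wide_coverage`.
#' @export
genome_wide_coverage <- function(panel) {
  tibble(
    genotype_id = genotype_ids(panel),
    genome_wide_coverage = unname(panel$total_aligned_reads) *
      panel$read_length / panel$genome_length
  )
}

#' Per-genotype mean target coverage
#'
#' X-fold coverage over the intended target space: total bases sequenced in
#' target regions (`count * read_length`, every counted read attributed
#' wholly to its region) divided by the total target length.
#'
#' @param panel A [coverage_panel()].
#' @param regions Region table; rows with `is_target` define the target.
#' @return Tibble with columns `genotype_id`, `target_coverage`.
#' @export
target_coverage <- function(panel, regions) {
  tgt <- intersect(region_ids(panel), regions$region_id[regions$is_target])
  if (length(tgt) == 0) abort("no target regions in panel")
  tgt_len <- sum(regions$length[match(tgt, regions$region_id)])
  tibble(
    genotype_id = genotype_ids(panel),
    target_coverage = unname(rowSums(panel$counts[, tgt, drop = FALSE])) *
      panel$read_length / tgt_len
  )
}

#' Per-genotype enrichment factor
#'
#' Mean target coverage divided by mean genome-wide coverage; measures how
#' strongly the capture concentrated sequencing onto the target.
#'
#' @inheritParams target_coverage
#' @return Tibble with columns `genotype_id`, `enrichment_factor`.
#' @export
enrichment_factor <- function(panel, regions) {
  gw <- genome_wide_coverage(panel)
  if (any(gw$genome_wide_coverage <= 0)) {
    abort("zero genome-wide coverage; enrichment factor undefined")
  }
  tc <- target_coverage(panel, regions)
  tibble(
    genotype_id = gw$genotype_id,
    enrichment_factor = tc$target_coverage / gw$genome_wide_coverage
  )
}

#' Per-genotype target specificity (percent of reads on target)
#'
#' Share of each genotype's aligned reads that were counted in target
#' regions, in percent. Computed on read counts: a read counts wholly toward
#' the region it was assigned to.
#'
#' @inheritParams target_coverage
#' @return Tibble with columns `genotype_id`, `target_specificity`.
#' @export
target_specificity <- function(panel, regions) {
  tgt <- intersect(region_ids(panel), regions$region_id[regions$is_target])
  on_target <- if (length(tgt) > 0) {
    rowSums(panel$counts[, tgt, drop = FALSE])
  } else {
    rep(0, nrow(panel$counts))
  }
  tibble(
    genotype_id = genotype_ids(panel),
    target_specificity = 100 * unname(on_target) /
      unname(panel$total_aligned_reads)
  )
}

#' Target sensitivity from per-base depth profiles
#'
#' Percentage of target bases covered by at least `min_depth` reads,
#' per genotype. `min_depth = 1` gives the classical target sensitivity
#' (any coverage); `min_depth = 11` gives the "covered by more than 10
#' reads" variant.
#'
#' @param profiles Depth-profile tibble (see [read_depth_profiles()]);
#'   must contain every target region for each genotype present.
#' @param regions Region table.
#' @param min_depth Minimum per-base depth, inclusive.
#' @return Tibble with columns `genotype_id`, `target_sensitivity`.
#' @export
target_sensitivity <- function(profiles, regions, min_depth = 1) {
  validate_depth_profiles(profiles, regions)
  tgt <- regions$region_id[regions$is_target]
  prof <- profiles[profiles$region_id %in% tgt, ]
  by_geno <- split(prof, prof$genotype_id)
  out <- purrr::map_dfr(by_geno, function(p) {
    missing_t <- setdiff(tgt, p$region_id)
    if (length(missing_t) > 0) {
      abort(paste0("missing depth profile for target region ", missing_t[1],
                   " (genotype ", p$genotype_id[1], ")"))
    }
    covered <- sum(vapply(p$depths, function(d) sum(d >= min_depth), 0))
    total <- sum(lengths(p$depths))
    tibble(genotype_id = p$genotype_id[1],
           target_sensitivity = 100 * covered / total)
  })
  out[order(out$genotype_id), ]
}

#' Enrichment QC report
#'
#' Aggregates the per-genotype enrichment metrics into one table: mean
#' genome-wide coverage, mean target coverage, enrichment factor, mean
#' normalised target coverage, target specificity and — when per-base depth
#' profiles are supplied — target sensitivity and the fraction of target
#' covered above `depth_threshold - 1` reads. Panel means and, when
#' morphotype labels are given, per-morphotype means are attached.
#'
#' @param panel A [coverage_panel()].
#' @param regions Region table.
#' @param profiles Optional depth-profile tibble.
#' @param labels Optional morphotype label tibble (`genotype_id`,
#'   `morphotype`).
#' @param depth_threshold Depth for the high-coverage fraction metric;
#'   the default 11 counts bases covered by more than 10 reads.
#' @return Object of class `qc_report`: list with tibbles `per_genotype`,
#'   `panel` (one row of panel means) and `by_morphotype` (or `NULL`).
#' @export
qc_report <- function(panel, regions, profiles = NULL, labels = NULL,
                      depth_threshold = 11) {
  norm <- normalize_coverage(panel, regions)
  tgt <- regions$region_id[regions$is_target]
  tgt <- intersect(region_ids(panel), tgt)
  per <- genome_wide_coverage(panel) |>
    dplyr::left_join(target_coverage(panel, regions), by = "genotype_id") |>
    dplyr::left_join(enrichment_factor(panel, regions), by = "genotype_id") |>
    dplyr::left_join(target_specificity(panel, regions), by = "genotype_id") |>
    dplyr::mutate(normalized_target_coverage =
                    rowMeans(norm$norm[, tgt, drop = FALSE]))
  if (!is.null(profiles)) {
    sens <- target_sensitivity(profiles, regions, min_depth = 1)
    deep <- target_sensitivity(profiles, regions, min_depth = depth_threshold)
    names(deep)[2] <- "target_covered_deep"
    per <- per |>
      dplyr::left_join(sens, by = "genotype_id") |>
      dplyr::left_join(deep, by = "genotype_id")
  }
  if (!is.null(labels)) {
    labels <- as_morphotypes(labels, genotype_ids(panel))
    per <- dplyr::left_join(per, labels, by = "genotype_id")
  }
  metric_cols <- setdiff(names(per), c("genotype_id", "morphotype"))
  panel_means <- dplyr::summarise(
    per, dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE)))
  by_morpho <- NULL
  if (!is.null(labels)) {
    by_morpho <- per |>
      dplyr::filter(!is.na(.data$morphotype)) |>
      dplyr::group_by(.data$morphotype) |>
      dplyr::summarise(n = dplyr::n(),
                       dplyr::across(dplyr::all_of(metric_cols),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  }
  structure(list(per_genotype = per, panel = panel_means,
                 by_morphotype = by_morpho, depth_threshold = depth_threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d genotypes\n", nrow(x$per_genotype)))
  print(x$panel)
  invisible(x)
}

#' @describeIn qc_report per-genotype metric table.
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$per_genotype

#' @describeIn qc_report one-row tibble of panel means.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) x$panel
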