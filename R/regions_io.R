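# Data model and I/O for captured regions, coverage count matrices,
# homeolog maps, per-base depth profiles and morphotype labels.

REGION_CLASSES <- c(
  "target_gene", "target_promoter", "pseudogene",
  "non_target_gene", "non_target_other"
)

#' Subgenome of a chromosome name
#'
#' The A and C subgenomes of an allotetraploid are identified from the
#' chromosome-name prefix of the reference assembly: names starting with
#' `"chrA"` belong to the A subgenome, `"chrC"` to the C subgenome, anything
#' else (plastids, unanchored bins with other prefixes) to `"other"`.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector with values `"A"`, `"C"` or `"other"`.
#' @examples
#' subgenome_of(c("chrA03", "chrCnn_random", "chloroplast"))
#' @export
subgenome_of <- function(chrom) {
  dplyr::case_when(
    startsWith(chrom, "chrA") ~ "A",
    startsWith(chrom, "chrC") ~ "C",
    TRUE ~ "other"
  )
}

#' Build a validated region table
#'
#' Normalises a data frame of captured-region intervals into the region
#' table used throughout the package. Coordinates are 0-based half-open
#' (BED convention); `length`, `subgenome` and `is_random_scaffold` are
#' always (re)derived, never trusted from the input. Unassembled scaffold
#' bins are recognised by the substring `"random"` in the chromosome name
#' and can be excluded from homeologous-exchange pairing downstream.
#'
#' @param df Data frame with at least `region_id`, `chrom`, `start`, `end`.
#'   Optional columns `is_target` (logical), `gene_label` (character) and
#'   `annotation_class` (one of `r paste(REGION_CLASSES, collapse = ", ")`)
#'   are kept; absent ones default to non-target with empty labels.
#' @return A tibble with columns `region_id`, `chrom`, `start`, `end`,
#'   `length`, `subgenome`, `is_target`, `is_random_scaffold`, `gene_label`,
#'   `annotation_class`, in the input row order.
#' @export
as_region_table <- function(df) {
  df <- as_tibble(df)
  need <- c("region_id", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("region table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0) {
    abort(sprintf("empty or inverted interval (start >= end) at row %d: %s:%s-%s",
                  bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  if (any(df$start < 0)) {
    abort("negative start coordinate")
  }
  dup <- duplicated(df$region_id)
  if (any(dup)) {
    abort(paste0("duplicate region_id: ", df$region_id[which(dup)[1]]))
  }
  cls <- df[["annotation_class"]] %||% rep("non_target_other", nrow(df))
  cls[is.na(cls)] <- "non_target_other"
  if (!all(cls %in% REGION_CLASSES)) {
    abort(paste0("unknown annotation_class: ",
                 paste(unique(setdiff(cls, REGION_CLASSES)), collapse = ", ")))
  }
  gene_label <- df[["gene_label"]] %||% rep("", nrow(df))
  gene_label[is.na(gene_label)] <- ""
  is_target <- df[["is_target"]] %||% rep(FALSE, nrow(df))
  tibble(
    region_id = as.character(df$region_id),
    chrom = as.character(df$chrom),
    start = as.integer(df$start),
    end = as.integer(df$end),
    length = as.integer(df$end - df$start),
    subgenome = subgenome_of(as.character(df$chrom)),
    is_target = as.logical(is_target),
    is_random_scaffold = grepl("random", df$chrom, fixed = TRUE),
    gene_label = as.character(gene_label),
    annotation_class = cls
  )
}

#' Read captured regions from a BED file
#'
#' Reads a BED-like file (3 or 4 whitespace-separated columns: chrom, start,
#' end and optionally a region name) and an optional annotation TSV keyed by
#' `region_id` supplying `is_target`, `gene_label` and `annotation_class`.
#' When the BED file has no name column, region ids are synthesised as
#' `chrom:start-end`.
#'
#' @param path BED file of captured regions.
#' @param annotation_path Optional TSV with columns `region_id`, `is_target`,
#'   `gene_label`, `annotation_class`.
#' @return A region table (see [as_region_table()]), rows in file order.
#' @export
read_regions <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           colClasses = "character",
                           col.names = c("chrom", "start", "end", "name")[1:4],
                           fill = TRUE, stringsAsFactors = FALSE)
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("unparseable interval at line %d of %s",
                  which(is.na(start) | is.na(end))[1], path))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("empty interval (start >= end) at line %d of %s", bad[1], path))
  }
  region_id <- raw$name
  synth <- is.na(region_id) | region_id == ""
  region_id[synth] <- sprintf("%s:%d-%d", raw$chrom[synth],
                              as.integer(start[synth]), as.integer(end[synth]))
  df <- tibble(region_id = region_id, chrom = raw$chrom,
               start = start, end = end)
  if (!is.null(annotation_path)) {
    ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                           col_types = readr::cols(
                             region_id = "c", is_target = "l",
                             gene_label = "c", annotation_class = "c"))
    df <- dplyr::left_join(df, ann, by = "region_id")
    df$is_target[is.na(df$is_target)] <- FALSE
  }
  as_region_table(df)
}

#' Write a region table
#'
#' Writes the interval part as 4-column BED (chrom, start, end, region_id)
#' and, when `annotation_path` is given, the annotation columns as a TSV, so
#' that [read_regions()] round-trips the table exactly.
#'
#' @param regions A region table.
#' @param path Output BED path.
#' @param annotation_path Optional output TSV path for the annotation.
#' @return `regions`, invisibly.
#' @export
write_regions <- function(regions, path, annotation_path = NULL) {
  bed <- regions[, c("chrom", "start", "end", "region_id")]
  readr::write_tsv(bed, path, col_names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- regions[, c("region_id", "is_target", "gene_label", "annotation_class")]
    readr::write_tsv(ann, annotation_path)
  }
  invisible(regions)
}

#' Coverage panel of aligned-read counts
#'
#' Container for a genotypes-by-regions matrix of aligned, duplicate-removed
#' read counts together with the per-genotype library sizes (total aligned
#' reads), the read length and the reference genome length. These four pieces
#' are exactly what coverage normalisation and the enrichment QC metrics
#' need. Counts must be non-negative and, per genotype, sum to at most the
#' genotype's total aligned reads (reads also align outside captured
#' regions). Missing counts are not permitted: sequencing yields a count,
#' possibly zero, for every captured region.
#'
#' @param counts Integer matrix, genotypes in rows, regions in columns, with
#'   dimnames set to genotype and region ids.
#' @param total_aligned_reads Named (by genotype) vector of positive totals.
#' @param read_length Read length in bases (single-end model).
#' @param genome_length Reference assembly length in bases.
#' @return An object of class `coverage_panel`.
#' @export
coverage_panel <- function(counts, total_aligned_reads,
                           read_length = 100, genome_length = 8.5e8) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts matrix must carry genotype rownames and region colnames")
  }
  if (any(counts < 0)) abort("negative count in coverage matrix")
  if (anyNA(counts)) abort("missing count in coverage matrix")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in sums
  if (is.null(names(total_aligned_reads))) {
    if (length(total_aligned_reads) != nrow(counts)) {
      abort("total_aligned_reads length does not match number of genotypes")
    }
    names(total_aligned_reads) <- rownames(counts)
  }
  absent <- setdiff(rownames(counts), names(total_aligned_reads))
  if (length(absent) > 0) {
    abort(paste0("genotype missing from metadata: ", absent[1]))
  }
  total_aligned_reads <- total_aligned_reads[rownames(counts)]
  if (any(total_aligned_reads <= 0)) {
    abort(paste0("non-positive total_aligned_reads for genotype ",
                 names(total_aligned_reads)[total_aligned_reads <= 0][1]))
  }
  over <- rowSums(counts) > total_aligned_reads
  if (any(over)) {
    abort(paste0("region counts exceed total aligned reads for genotype ",
                 rownames(counts)[over][1]))
  }
  structure(
    list(counts = counts,
         total_aligned_reads = total_aligned_reads,
         read_length = read_length,
         genome_length = genome_length),
    class = "coverage_panel"
  )
}

#' @export
print.coverage_panel <- function(x, ...) {
  cat(sprintf("<coverage_panel> %d genotypes x %d regions\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  read length %d bp, genome length %.3g bp\n",
              x$read_length, x$genome_length))
  cat(sprintf("  median library size %.3g aligned reads\n",
              stats::median(x$total_aligned_reads)))
  invisible(x)
}

#' @export
dim.coverage_panel <- function(x) dim(x$counts)

#' Genotype ids of a panel-like object
#' @param x A `coverage_panel`, `norm_coverage` or `cnv_calls` object.
#' @return Character vector of genotype ids.
#' @export
genotype_ids <- function(x) UseMethod("genotype_ids")

#' @export
genotype_ids.coverage_panel <- function(x) rownames(x$counts)

#' Region ids of a panel-like object
#' @inheritParams genotype_ids
#' @return Character vector of region ids.
#' @export
region_ids <- function(x) UseMethod("region_ids")

#' @export
region_ids.coverage_panel <- function(x) colnames(x$counts)

#' @describeIn coverage_panel long-format view: one row per
#'   (genotype, region) with the raw count.
#' @param x A `coverage_panel`.
#' @param ... Unused.
#' @method tidy coverage_panel
#' @export
tidy.coverage_panel <- function(x, ...) {
  tibble(
    genotype_id = rep(rownames(x$counts), times = ncol(x$counts)),
    region_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
}

#' Read a coverage count matrix with library metadata
#'
#' The counts TSV has genotype ids in the first column (`genotype_id`) and
#' one column per region (header row = region ids). The metadata TSV has
#' columns `genotype_id` and `total_aligned_reads` and may carry single-value
#' columns `read_length` and `genome_length`.
#'
#' @param path Counts TSV.
#' @param meta_path Metadata TSV.
#' @param read_length,genome_length Defaults used when the metadata file
#'   does not supply them.
#' @return A [coverage_panel()].
#' @export
read_counts <- function(path, meta_path, read_length = 100,
                        genome_length = 8.5e8) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(genotype_id = "c",
                                                .default = "d"))
  if (names(df)[1] != "genotype_id") {
    abort("counts file must have 'genotype_id' as its first column")
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$genotype_id
  if (any(counts < 0, na.rm = TRUE)) abort("negative count in counts file")
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          col_types = readr::cols(genotype_id = "c",
                                                  .default = "d"))
  absent <- setdiff(rownames(counts), meta$genotype_id)
  if (length(absent) > 0) {
    abort(paste0("genotype in counts matrix missing from metadata: ", absent[1]))
  }
  totals <- setNames(meta$total_aligned_reads, meta$genotype_id)
  if ("read_length" %in% names(meta)) read_length <- meta$read_length[1]
  if ("genome_length" %in% names(meta)) genome_length <- meta$genome_length[1]
  coverage_panel(counts, totals[rownames(counts)],
                 read_length = read_length, genome_length = genome_length)
}

#' Write a coverage panel as counts + metadata TSVs
#'
#' Inverse of [read_counts()]; counts are written as integers so the
#' round-trip is exact.
#'
#' @param panel A [coverage_panel()].
#' @param path Output counts TSV.
#' @param meta_path Output metadata TSV.
#' @return `panel`, invisibly.
#' @export
write_counts <- function(panel, path, meta_path) {
  df <- as_tibble(panel$counts)
  df <- dplyr::bind_cols(tibble(genotype_id = rownames(panel$counts)), df)
  readr::write_tsv(df, path)
  meta <- tibble(
    genotype_id = rownames(panel$counts),
    total_aligned_reads = unname(panel$total_aligned_reads),
    read_length = panel$read_length,
    genome_length = panel$genome_length
  )
  readr::write_tsv(meta, meta_path)
  invisible(panel)
}

#' Convert a bedtools multicov table into a coverage panel
#'
#' Adapter for the standard preprocessing route: per-region counts extracted
#' from BAM alignments with `bedtools multicov -bams ... -bed regions.bed`.
#' The multicov output has the BED columns first (chrom, start, end, name)
#' followed by one count column per BAM/sample.
#'
#' @param path multicov output TSV (no header).
#' @param sample_ids Character vector naming the count columns, in the order
#'   the BAMs were given to bedtools.
#' @param total_aligned_reads Named vector of per-sample library sizes
#'   (aligned reads after duplicate removal), e.g. from `samtools flagstat`.
#' @param read_length,genome_length See [coverage_panel()].
#' @return A [coverage_panel()]; region ids come from the BED name column.
#' @export
read_multicov <- function(path, sample_ids, total_aligned_reads,
                          read_length = 100, genome_length = 8.5e8) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 4 + length(sample_ids)) {
    abort(sprintf("expected 4 BED columns + %d count columns, found %d columns",
                  length(sample_ids), ncol(raw)))
  }
  counts <- t(as.matrix(raw[, -(1:4), drop = FALSE]))
  rownames(counts) <- sample_ids
  colnames(counts) <- raw[[4]]
  coverage_panel(counts, total_aligned_reads,
                 read_length = read_length, genome_length = genome_length)
}

#' Read and validate a homeolog map
#'
#' A homeolog map groups region ids that are copies of the same gene across
#' subgenomes (e.g. the A03 and C03 copies of a flowering-time gene). Each
#' region may belong to at most one group and every member must exist in the
#' region table.
#'
#' @param path TSV with columns `group_id` and `region_id`.
#' @param regions Region table the map refers to.
#' @return A tibble with columns `group_id`, `region_id`.
#' @export
read_homeolog_map <- function(path, regions) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(group_id = "c", region_id = "c"))
  as_homeolog_map(df, regions)
}

#' @rdname read_homeolog_map
#' @param df Data frame with columns `group_id`, `region_id`.
#' @export
as_homeolog_map <- function(df, regions) {
  df <- as_tibble(df)[, c("group_id", "region_id")]
  unknown <- setdiff(df$region_id, regions$region_id)
  if (length(unknown) > 0) {
    abort(paste0("homeolog map references unknown region: ", unknown[1]))
  }
  dup <- duplicated(df$region_id)
  if (any(dup)) {
    abort(paste0("region assigned to more than one homeolog group: ",
                 df$region_id[which(dup)[1]]))
  }
  df
}

#' Write a homeolog map
#' @param map Homeolog map tibble.
#' @param path Output TSV path.
#' @return `map`, invisibly.
#' @export
write_homeolog_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(map)
}

#' Read per-base depth profiles
#'
#' Depth profiles give base-resolution coverage inside captured regions and
#' back the base-level QC metrics (target sensitivity, fraction of target
#' covered above a depth). Format: TSV with columns `genotype_id`,
#' `region_id`, `depths` where `depths` is a comma-separated vector of
#' per-base depths whose length equals the region length.
#'
#' @param path Profiles TSV.
#' @param regions Optional region table; when given, profile lengths are
#'   checked against region lengths.
#' @return Tibble with columns `genotype_id`, `region_id`, `depths`
#'   (list-column of integer vectors).
#' @export
read_depth_profiles <- function(path, regions = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  out <- tibble(
    genotype_id = df$genotype_id,
    region_id = df$region_id,
    depths = lapply(strsplit(df$depths, ",", fixed = TRUE), as.integer)
  )
  if (!is.null(regions)) validate_depth_profiles(out, regions)
  out
}

validate_depth_profiles <- function(profiles, regions) {
  len <- setNames(regions$length, regions$region_id)
  unknown <- setdiff(profiles$region_id, names(len))
  if (length(unknown) > 0) {
    abort(paste0("depth profile for unknown region: ", unknown[1]))
  }
  got <- lengths(profiles$depths)
  bad <- which(got != len[profiles$region_id])
  if (length(bad) > 0) {
    abort(sprintf("depth profile length %d != region length %d for %s",
                  got[bad[1]], len[profiles$region_id[bad[1]]],
                  profiles$region_id[bad[1]]))
  }
  invisible(profiles)
}

#' Write depth profiles
#' @param profiles Depth-profile tibble (see [read_depth_profiles()]).
#' @param path Output TSV path.
#' @return `profiles`, invisibly.
#' @export
write_depth_profiles <- function(profiles, path) {
  df <- tibble(
    genotype_id = profiles$genotype_id,
    region_id = profiles$region_id,
    depths = vapply(profiles$depths, paste, "", collapse = ",")
  )
  readr::write_tsv(df, path)
  invisible(profiles)
}

#' Read morphotype labels
#'
#' Morphotypes are the crop forms of the panel (winter or spring oilseed,
#' semi-winter, swede, ...), used to stratify QC metrics and CNV
#' frequencies. Labels may cover a subset of the panel but must not name
#' genotypes absent from it.
#'
#' @param path TSV with columns `genotype_id`, `morphotype`.
#' @param genotypes Character vector of panel genotype ids, or a
#'   `coverage_panel`.
#' @return Tibble with columns `genotype_id`, `morphotype`.
#' @export
read_morphotypes <- function(path, genotypes) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(genotype_id = "c",
                                                morphotype = "c"))
  as_morphotypes(df, genotypes)
}

#' @rdname read_morphotypes
#' @param df Data frame with columns `genotype_id`, `morphotype`.
#' @export
as_morphotypes <- function(df, genotypes) {
  if (inherits(genotypes, "coverage_panel")) genotypes <- genotype_ids(genotypes)
  df <- as_tibble(df)[, c("genotype_id", "morphotype")]
  unknown <- setdiff(df$genotype_id, genotypes)
  if (length(unknown) > 0) {
    abort(paste0("morphotype label for unknown genotype: ", unknown[1]))
  }
  if (anyDuplicated(df$genotype_id)) {
    abort("duplicate genotype in morphotype labels")
  }
  df
}
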