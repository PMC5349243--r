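# Panel-relative CNV calling from normalised coverage, and the population
# CNV frequency spectrum.

CALL_LEVELS <- c("deletion", "normal", "duplication", "no_call")
CALL_SYMBOLS <- c(deletion = "DEL", normal = "NORM",
                  duplication = "DUP", no_call = "NC")

#' Per-region panel mean of normalised coverage
#'
#' Arithmetic mean of the normalised coverage over all genotypes of the
#' panel, including the focal one — the reference level against which each
#' genotype's coverage ratio is formed. Requires at least two genotypes: a
#' ratio against oneself alone is meaningless.
#'
#' @param norm A `norm_coverage` object or a plain genotypes-by-regions
#'   numeric matrix.
#' @return Tibble with columns `region_id`, `panel_mean`.
#' @export
panel_mean <- function(norm) {
  m <- if (inherits(norm, "norm_coverage")) norm$norm else as.matrix(norm)
  if (nrow(m) < 2) {
    abort("panel mean needs at least 2 genotypes")
  }
  tibble(region_id = colnames(m), panel_mean = unname(colMeans(m)))
}

#' Call deletions and duplications relative to the panel mean
#'
#' For every genotype and region the coverage ratio
#' `norm_coverage / panel mean of norm_coverage` is formed, and the region
#' is called a `deletion` when the ratio is smaller than `lower` (default
#' 0.5), a `duplication` when it is higher than `upper` (default 1.5), and
#' `normal` otherwise. The inequalities are strict: a ratio of exactly 0.5
#' or 1.5 is `normal`. Regions whose panel mean is zero (targets that failed
#' capture in every genotype) yield `no_call` for every genotype — the ratio
#' is undefined there, and a deletion cannot be distinguished from failed
#' enrichment.
#'
#' Because the panel mean includes carriers, a CNV shared by much of the
#' panel shifts its own reference and can mask itself; calls are
#' panel-relative states, not absolute copy numbers.
#'
#' @param norm A `norm_coverage` object or genotypes-by-regions matrix of
#'   normalised coverage.
#' @param lower,upper Ratio thresholds, `0 <= lower < upper`.
#' @return Object of class `cnv_calls`: list with the character matrix
#'   `calls` (values `r paste(CALL_LEVELS, collapse = ", ")`), the numeric
#'   matrix `ratio` (`NA` where the panel mean is zero) and the thresholds
#'   used.
#' @examples
#' m <- rbind(g1 = c(r1 = 0, r2 = 30), g2 = c(10, 10),
#'            g3 = c(10, 10), g4 = c(10, 10))
#' call_cnv(m)$calls
#' @export
call_cnv <- function(norm, lower = 0.5, upper = 1.5) {
  m <- if (inherits(norm, "norm_coverage")) norm$norm else as.matrix(norm)
  if (!is.numeric(lower) || !is.numeric(upper) || lower < 0 || lower >= upper) {
    abort("thresholds must satisfy 0 <= lower < upper")
  }
  pm <- panel_mean(m)
  mu <- setNames(pm$panel_mean, pm$region_id)[colnames(m)]
  ratio <- sweep(m, 2, mu, "/")
  ratio[, mu == 0] <- NA_real_
  calls <- matrix("normal", nrow(m), ncol(m), dimnames = dimnames(m))
  calls[!is.na(ratio) & ratio < lower] <- "deletion"
  calls[!is.na(ratio) & ratio > upper] <- "duplication"
  calls[is.na(ratio)] <- "no_call"
  structure(list(calls = calls, ratio = ratio, lower = lower, upper = upper),
            class = "cnv_calls")
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("<cnv_calls> %d genotypes x %d regions (thresholds %g / %g)\n",
              nrow(x$calls), ncol(x$calls), x$lower, x$upper))
  print(table(factor(x$calls, levels = CALL_LEVELS)))
  invisible(x)
}

#' @export
dim.cnv_calls <- function(x) dim(x$calls)

#' @export
genotype_ids.cnv_calls <- function(x) rownames(x$calls)

#' @export
region_ids.cnv_calls <- function(x) colnames(x$calls)

#' @describeIn call_cnv long-format view: one row per (genotype, region)
#'   with the coverage ratio and the call.
#' @param x A `cnv_calls` object.
#' @param ... Unused.
#' @method tidy cnv_calls
#' @export
tidy.cnv_calls <- function(x, ...) {
  tibble(
    genotype_id = rep(rownames(x$calls), times = ncol(x$calls)),
    region_id = rep(colnames(x$calls), each = nrow(x$calls)),
    ratio = as.vector(x$ratio),
    call = as.vector(x$calls)
  )
}

#' @describeIn call_cnv one-row summary: dimensions, thresholds, call
#'   counts.
#' @method glance cnv_calls
#' @export
glance.cnv_calls <- function(x, ...) {
  tab <- table(factor(x$calls, levels = CALL_LEVELS))
  tibble(n_genotypes = nrow(x$calls), n_regions = ncol(x$calls),
         lower = x$lower, upper = x$upper,
         n_deletion = as.integer(tab[["deletion"]]),
         n_duplication = as.integer(tab[["duplication"]]),
         n_no_call = as.integer(tab[["no_call"]]))
}

#' Write / read a CNV call matrix
#'
#' TSV with first column `genotype_id` and one column per region; calls are
#' written as the symbols `DEL`, `NORM`, `DUP`, `NC`.
#'
#' @param calls A `cnv_calls` object.
#' @param path TSV path.
#' @return `calls` invisibly (write); for reads, a `cnv_calls`-like object
#'   without ratios (ratios are not serialised).
#' @export
write_cnv_calls <- function(calls, path) {
  sym <- matrix(CALL_SYMBOLS[calls$calls], nrow(calls$calls),
                dimnames = dimnames(calls$calls))
  df <- dplyr::bind_cols(tibble(genotype_id = rownames(sym)), as_tibble(sym))
  readr::write_tsv(df, path)
  invisible(calls)
}

#' @rdname write_cnv_calls
#' @param lower,upper Thresholds to record on the read object.
#' @export
read_cnv_calls <- function(path, lower = 0.5, upper = 1.5) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  sym <- as.matrix(df[, -1, drop = FALSE])
  rownames(sym) <- df$genotype_id
  inv <- setNames(names(CALL_SYMBOLS), CALL_SYMBOLS)
  if (!all(sym %in% names(inv))) {
    abort("unknown call symbol in file (expected DEL/NORM/DUP/NC)")
  }
  calls <- matrix(inv[sym], nrow(sym), dimnames = dimnames(sym))
  structure(list(calls = calls, ratio = NULL, lower = lower, upper = upper),
            class = "cnv_calls")
}

#' Population CNV frequency spectrum
#'
#' Tallies, for every (region, call type) with at least one carrier, the
#' number of carrier genotypes and the carrier frequency, and reports the
#' fraction of such CNVs that are rare (frequency strictly below
#' `rare_threshold`). Genotypes with `no_call` still count toward the panel
#' denominator. With morphotype labels, per-morphotype carrier frequencies
#' are tallied as well.
#'
#' @param calls A `cnv_calls` object.
#' @param labels Optional morphotype label tibble.
#' @param rare_threshold Frequency below which a CNV counts as rare; in
#'   (0, 1].
#' @return Object of class `cnv_freq`: list with `frequencies` (tibble:
#'   `region_id`, `call`, `carriers`, `frequency`), `fraction_rare`,
#'   `rare_threshold`, `n_genotypes` and optionally `by_morphotype`.
#' @export
cnv_frequency_spectrum <- function(calls, labels = NULL, rare_threshold = 0.10) {
  if (rare_threshold <= 0 || rare_threshold > 1) {
    abort("rare_threshold must lie in (0, 1]")
  }
  n_g <- nrow(calls$calls)
  long <- tidy(calls) |>
    dplyr::filter(.data$call %in% c("deletion", "duplication"))
  freq <- long |>
    dplyr::count(.data$region_id, .data$call, name = "carriers") |>
    dplyr::mutate(frequency = .data$carriers / n_g) |>
    dplyr::arrange(.data$region_id, .data$call)
  fraction_rare <- if (nrow(freq) > 0) {
    mean(freq$frequency < rare_threshold)
  } else {
    NA_real_
  }
  by_morpho <- NULL
  if (!is.null(labels)) {
    labels <- as_morphotypes(labels, rownames(calls$calls))
    sizes <- dplyr::count(labels, .data$morphotype, name = "n_group")
    by_morpho <- long |>
      dplyr::inner_join(labels, by = "genotype_id") |>
      dplyr::count(.data$region_id, .data$call, .data$morphotype,
                   name = "carriers") |>
      dplyr::left_join(sizes, by = "morphotype") |>
      dplyr::mutate(frequency = .data$carriers / .data$n_group)
  }
  structure(list(frequencies = freq, fraction_rare = fraction_rare,
                 rare_threshold = rare_threshold, n_genotypes = n_g,
                 by_morphotype = by_morpho),
            class = "cnv_freq")
}

#' @export
print.cnv_freq <- function(x, ...) {
  cat(sprintf("<cnv_freq> %d segregating (region, type) CNVs in %d genotypes\n",
              nrow(x$frequencies), x$n_genotypes))
  cat(sprintf("  fraction rare (< %g): %.3f\n", x$rare_threshold,
              x$fraction_rare))
  invisible(x)
}

#' @describeIn cnv_frequency_spectrum frequency table.
#' @param x A `cnv_freq` object.
#' @param ... Unused.
#' @method tidy cnv_freq
#' @export
tidy.cnv_freq <- function(x, ...) x$frequencies

#' @describeIn cnv_frequency_spectrum one-row summary with `fraction_rare`.
#' @method glance cnv_freq
#' @export
glance.cnv_freq <- function(x, ...) {
  tibble(n_cnv = nrow(x$frequencies), n_genotypes = x$n_genotypes,
         rare_threshold = x$rare_threshold, fraction_rare = x$fraction_rare)
}
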