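# Technical-validation computations: marker recoding, call-rate / MAF
# filtering and cross-platform concordance rates.

#' Recode CNV calls as biallelic presence/absence markers
#'
#' Each (region, event type) with at least one carrier becomes one marker
#' column named `<region>_del` or `<region>_dup`: carriers are 1,
#' non-carriers 0 and `no_call` genotypes missing (`NA`). This is the coding
#' that lets CNVs enter a marker-based population-structure or concordance
#' analysis next to SNPs and InDels.
#'
#' @param calls A `cnv_calls` object.
#' @return Integer individuals-by-markers matrix with values 0/1/`NA`.
#' @export
recode_cnv_markers <- function(calls) {
  m <- calls$calls
  out <- list()
  for (type in c("deletion", "duplication")) {
    carrier <- m == type
    keep <- colSums(carrier) >= 1
    if (!any(keep)) next
    block <- matrix(0L, nrow(m), sum(keep))
    block[carrier[, keep, drop = FALSE]] <- 1L
    block[m[, keep, drop = FALSE] == "no_call"] <- NA_integer_
    colnames(block) <- paste0(colnames(m)[keep],
                              if (type == "deletion") "_del" else "_dup")
    out[[type]] <- block
  }
  if (length(out) == 0) {
    return(matrix(integer(0), nrow(m), 0, dimnames = list(rownames(m), NULL)))
  }
  res <- do.call(cbind, out)
  rownames(res) <- rownames(m)
  res[, order(colnames(res)), drop = FALSE]
}

# Minor allele frequency of one marker column over non-missing calls.
# 0/1 coding is read as allele presence, 0/1/2 as genotype dosage.
marker_maf <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  dosage <- any(x == 2)
  p <- mean(x) / (if (dosage) 2 else 1)
  min(p, 1 - p)
}

#' Filter a marker matrix by call rate and minor allele frequency
#'
#' Keeps markers whose non-missing fraction exceeds `marker_call_rate` and
#' whose minor allele frequency (computed over non-missing calls) exceeds
#' `maf`; then drops individuals whose non-missing fraction over the
#' surviving markers does not exceed `individual_call_rate`. All
#' inequalities are strict, and marker filtering precedes individual
#' filtering (individual call rates are recomputed on the surviving
#' markers). Filtering is idempotent.
#'
#' @param m Individuals-by-markers matrix with values 0/1 (or 0/1/2 dosage)
#'   and `NA` for missing.
#' @param marker_call_rate Markers must have non-missing fraction strictly
#'   above this.
#' @param maf Markers must have minor allele frequency strictly above this.
#' @param individual_call_rate Individuals must have non-missing fraction
#'   strictly above this.
#' @return The filtered matrix. Warns (does not error) when nothing
#'   survives.
#' @export
filter_markers <- function(m, marker_call_rate = 0.9, maf = 0.01,
                           individual_call_rate = 0.8) {
  for (t in c(marker_call_rate, maf, individual_call_rate)) {
    if (t < 0 || t > 1) abort("filter thresholds must lie in [0, 1]")
  }
  m <- as.matrix(m)
  call_rate <- colMeans(!is.na(m))
  mafs <- apply(m, 2, marker_maf)
  keep_marker <- call_rate > marker_call_rate &
    !is.na(mafs) & mafs > maf
  m2 <- m[, keep_marker, drop = FALSE]
  if (ncol(m2) == 0) {
    warn("no markers survive filtering")
    return(m2)
  }
  ind_rate <- rowMeans(!is.na(m2))
  m3 <- m2[ind_rate > individual_call_rate, , drop = FALSE]
  if (nrow(m3) == 0) warn("no individuals survive filtering")
  m3
}

#' Concordance between two marker data sets
#'
#' For each pair of putatively identical markers assayed on two platforms,
#' concordance is the fraction of shared individuals, non-missing in both,
#' whose calls agree; the overall rate pools matches and comparisons over
#' all pairs. Pairs with zero comparisons get `NA` and do not enter the
#' overall rate. The per-pair table is ranked worst-first so that
#' low-concordance markers (e.g. mapping artefacts) can be inspected and
#' removed; `drop_worst` or `min_pair_concordance` recompute the overall
#' rate after such a removal.
#'
#' @param a,b Individuals-by-markers matrices (values compared with `==`;
#'   missing as `NA`). Rownames identify shared individuals.
#' @param pairs Tibble/data frame with columns `marker_a`, `marker_b`.
#' @param drop_worst Drop this many lowest-concordance pairs before
#'   computing the overall rate.
#' @param min_pair_concordance Or drop pairs below this percentage.
#' @return Object of class `concordance`: list with `overall` (percent),
#'   `per_marker` (tibble: `marker_a`, `marker_b`, `n_compared`, `n_match`,
#'   `concordance`, ranked ascending), `n_dropped`.
#' @examples
#' a <- cbind(m1 = c(1, 0, 1, NA)); rownames(a) <- paste0("i", 1:4)
#' b <- cbind(m1 = c(1, 0, 0, 1)); rownames(b) <- paste0("i", 1:4)
#' concordance_rate(a, b, data.frame(marker_a = "m1", marker_b = "m1"))
#' @export
concordance_rate <- function(a, b, pairs, drop_worst = 0,
                             min_pair_concordance = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  pairs <- as_tibble(pairs)[, c("marker_a", "marker_b")]
  if (nrow(pairs) == 0) abort("empty marker pairing")
  bad_a <- setdiff(pairs$marker_a, colnames(a))
  bad_b <- setdiff(pairs$marker_b, colnames(b))
  if (length(bad_a) > 0 || length(bad_b) > 0) {
    abort(paste0("pairing references unknown marker: ",
                 c(bad_a, bad_b)[1]))
  }
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) == 0) abort("no shared individuals between data sets")
  per <- purrr::map2_dfr(pairs$marker_a, pairs$marker_b, function(ma, mb) {
    x <- a[shared, ma]; y <- b[shared, mb]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    nm <- sum(x[ok] == y[ok])
    tibble(marker_a = ma, marker_b = mb, n_compared = n, n_match = nm,
           concordance = if (n > 0) 100 * nm / n else NA_real_)
  })
  per <- dplyr::arrange(per, .data$concordance)
  usable <- per[!is.na(per$concordance), ]
  dropped <- 0L
  if (!is.null(min_pair_concordance)) {
    dropped <- sum(usable$concordance < min_pair_concordance)
    usable <- usable[usable$concordance >= min_pair_concordance, ]
  } else if (drop_worst > 0) {
    dropped <- min(drop_worst, nrow(usable))
    usable <- usable[seq_len(nrow(usable)) > dropped, ]
  }
  overall <- if (sum(usable$n_compared) > 0) {
    100 * sum(usable$n_match) / sum(usable$n_compared)
  } else {
    NA_real_
  }
  structure(list(overall = overall, per_marker = per, n_dropped = dropped),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> overall %.1f%% over %d marker pairs",
              x$overall, nrow(x$per_marker)))
  if (x$n_dropped > 0) cat(sprintf(" (%d dropped)", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' @describeIn concordance_rate per-pair concordance table, worst first.
#' @param x A `concordance` object.
#' @param ... Unused.
#' @method tidy concordance
#' @export
tidy.concordance <- function(x, ...) x$per_marker

#' @describeIn concordance_rate one-row summary with the overall rate.
#' @method glance concordance
#' @export
glance.concordance <- function(x, ...) {
  tibble(overall = x$overall, n_pairs = nrow(x$per_marker),
         n_dropped = x$n_dropped,
         mean_pair = mean(x$per_marker$concordance, na.rm = TRUE),
         min_pair = suppressWarnings(min(x$per_marker$concordance, na.rm = TRUE)),
         max_pair = suppressWarnings(max(x$per_marker$concordance, na.rm = TRUE)))
}

#' Read / write a marker matrix
#'
#' TSV with first column `individual_id` and one column per marker; missing
#' values as `NA`.
#'
#' @param path TSV path.
#' @return Integer individuals-by-markers matrix.
#' @export
read_marker_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(individual_id = "c",
                                                .default = "i"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$individual_id
  m
}

#' @rdname read_marker_matrix
#' @param m Marker matrix.
#' @export
write_marker_matrix <- function(m, path) {
  df <- dplyr::bind_cols(tibble(individual_id = rownames(m)),
                         as_tibble(m))
  readr::write_tsv(df, path)
  invisible(m)
}
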