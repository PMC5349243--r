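# Classification of CNV calls into simple events and directional
# homeologous non-reciprocal translocations (HNRTs), plus subgenome bias
# and landscape summaries.

#' Classify CNV calls into simple events and directional HNRTs
#'
#' An HNRT is a coupled duplication-deletion event in which a gene copy from
#' one subgenome replaces its homeologous counterpart on the other: the
#' donor copy appears duplicated and the acceptor copy deleted in the same
#' genotype. Within each genotype and homeolog group, every pairing of a
#' duplicated A-subgenome copy with a deleted C-subgenome copy (or vice
#' versa) is matched into one `hnrt` event whose direction runs from the
#' duplicated to the deleted copy's subgenome. Matching is greedy in
#' lexicographic `region_id` order, A-to-C pairings are formed before
#' C-to-A, and each call is consumed at most once. Calls left unmatched —
#' including all calls outside homeolog groups — become `simple_duplication`
#' or `simple_deletion` events.
#'
#' Gene copies on unassembled `*_random` scaffolds cannot be placed reliably
#' relative to their homeologs, so with `exclude_random = TRUE` (default)
#' they never enter HNRT pairing; their calls still yield simple events.
#'
#' @param calls A `cnv_calls` object from [call_cnv()].
#' @param map Homeolog map tibble (`group_id`, `region_id`).
#' @param regions Region table.
#' @param exclude_random Exclude random-scaffold regions from HNRT pairing.
#' @return Event table tibble: `genotype_id`, `region_id`, `event_type`
#'   (`simple_deletion`, `simple_duplication`, `hnrt`), `partner_region_id`
#'   (`NA` for simple events; the deleted acceptor copy for HNRTs, whose
#'   `region_id` is the duplicated donor copy), `direction` (`A_to_C`,
#'   `C_to_A`, `none`) and `subgenome` (of `region_id`).
#' @export
classify_events <- function(calls, map, regions, exclude_random = TRUE) {
  absent <- setdiff(map$region_id, colnames(calls$calls))
  if (length(absent) > 0) {
    abort(paste0("homeolog map references region absent from calls: ",
                 absent[1]))
  }
  long <- tidy(calls) |>
    dplyr::filter(.data$call %in% c("deletion", "duplication")) |>
    dplyr::left_join(regions[, c("region_id", "subgenome",
                                 "is_random_scaffold")],
                     by = "region_id") |>
    dplyr::left_join(map, by = "region_id")
  if (nrow(long) == 0) {
    return(empty_event_table())
  }
  pairable <- !is.na(long$group_id) & long$subgenome %in% c("A", "C") &
    !(exclude_random & long$is_random_scaffold)
  cand <- long[pairable, ]
  hnrt <- list()
  consumed <- character(0)  # keys of calls absorbed into HNRTs
  if (nrow(cand) > 0) {
    cand$key <- paste(cand$genotype_id, cand$region_id)
    pieces <- split(cand, paste(cand$genotype_id, cand$group_id))
    hnrt <- purrr::map(pieces, function(p) {
      pair_group_calls(p)
    })
    hnrt <- dplyr::bind_rows(hnrt)
    if (nrow(hnrt) > 0) {
      consumed <- c(paste(hnrt$genotype_id, hnrt$region_id),
                    paste(hnrt$genotype_id, hnrt$partner_region_id))
    }
  }
  simple <- long[!(paste(long$genotype_id, long$region_id) %in% consumed), ]
  simple <- tibble(
    genotype_id = simple$genotype_id,
    region_id = simple$region_id,
    event_type = dplyr::if_else(simple$call == "deletion",
                                "simple_deletion", "simple_duplication"),
    partner_region_id = rep(NA_character_, nrow(simple)),
    direction = rep("none", nrow(simple)),
    subgenome = as.character(simple$subgenome)
  )
  out <- dplyr::bind_rows(if (is.data.frame(hnrt)) hnrt else NULL, simple)
  dplyr::arrange(out, .data$genotype_id, .data$region_id)
}

empty_event_table <- function() {
  tibble(genotype_id = character(), region_id = character(),
         event_type = character(), partner_region_id = character(),
         direction = character(), subgenome = character())
}

# Greedy pairing within one (genotype, homeolog group): duplicated copies of
# one subgenome against deleted copies of the other, in lexicographic
# region_id order.
pair_group_calls <- function(p) {
  pick <- function(call, sub) sort(p$region_id[p$call == call &
                                                 p$subgenome == sub])
  a_dup <- pick("duplication", "A"); c_del <- pick("deletion", "C")
  k1 <- min(length(a_dup), length(c_del))
  c_dup <- pick("duplication", "C"); a_del <- pick("deletion", "A")
  k2 <- min(length(c_dup), length(a_del))
  rows <- list()
  if (k1 > 0) {
    rows$ac <- tibble(genotype_id = p$genotype_id[1],
                      region_id = a_dup[seq_len(k1)],
                      event_type = "hnrt",
                      partner_region_id = c_del[seq_len(k1)],
                      direction = "A_to_C", subgenome = "A")
  }
  if (k2 > 0) {
    rows$ca <- tibble(genotype_id = p$genotype_id[1],
                      region_id = c_dup[seq_len(k2)],
                      event_type = "hnrt",
                      partner_region_id = a_del[seq_len(k2)],
                      direction = "C_to_A", subgenome = "C")
  }
  dplyr::bind_rows(rows)
}

#' Subgenome bias summary of classified events
#'
#' Counts simple deletions and duplications per subgenome at three nested
#' scopes — all captured regions, captured genes, and target genes — and
#' tallies HNRT events by direction. The scopes follow the region
#' annotation: genes are `target_gene` + `non_target_gene`, targets are
#' `target_gene` only.
#'
#' @param events Event table from [classify_events()].
#' @param regions Region table.
#' @return Object of class `subgenome_summary`: list with tibbles `simple`
#'   (`scope`, `subgenome`, `event_type`, `n`) and `hnrt` (`direction`,
#'   `n`).
#' @export
subgenome_event_counts <- function(events, regions) {
  simple <- events |>
    dplyr::filter(.data$event_type != "hnrt") |>
    dplyr::left_join(regions[, c("region_id", "annotation_class")],
                     by = "region_id")
  scopes <- list(
    all = function(cls) TRUE & rep(TRUE, length(cls)),
    genic = function(cls) cls %in% c("target_gene", "non_target_gene"),
    target = function(cls) cls == "target_gene"
  )
  simple_counts <- purrr::imap(scopes, function(f, nm) {
    simple |>
      dplyr::filter(f(.data$annotation_class)) |>
      dplyr::count(.data$subgenome, .data$event_type) |>
      dplyr::mutate(scope = nm, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    tidyr::complete(scope = names(scopes), subgenome = c("A", "C"),
                    event_type = c("simple_deletion", "simple_duplication"),
                    fill = list(n = 0L)) |>
    dplyr::filter(.data$subgenome %in% c("A", "C") |
                    .data$n > 0)
  hnrt_counts <- events |>
    dplyr::filter(.data$event_type == "hnrt") |>
    dplyr::count(.data$direction) |>
    tidyr::complete(direction = c("A_to_C", "C_to_A"), fill = list(n = 0L))
  structure(list(simple = simple_counts, hnrt = hnrt_counts),
            class = "subgenome_summary")
}

#' @export
print.subgenome_summary <- function(x, ...) {
  cat("<subgenome_summary>\nsimple events:\n")
  print(tidyr::pivot_wider(x$simple, names_from = "event_type",
                           values_from = "n"))
  cat("HNRTs by direction:\n")
  print(x$hnrt)
  invisible(x)
}

#' @describeIn subgenome_event_counts simple-event counts in long form.
#' @param x A `subgenome_summary`.
#' @param ... Unused.
#' @method tidy subgenome_summary
#' @export
tidy.subgenome_summary <- function(x, ...) x$simple

#' Correlation between simple deletion and duplication counts
#'
#' Tests, over the target-gene copies of one subgenome, whether copies that
#' are deleted in many genotypes also tend to be duplicated in many
#' genotypes (Pearson correlation of per-copy carrier counts). A positive
#' correlation suggests shared instability of those loci. Alternatively the
#' counts can be aggregated per genotype (`unit = "genotype"`).
#'
#' @param events Event table from [classify_events()].
#' @param regions Region table.
#' @param subgenome `"A"` or `"C"`.
#' @param unit Count simple events per target-gene copy (`"region"`,
#'   default) or per genotype (`"genotype"`).
#' @param exclude_random Drop random-scaffold copies from the unit set.
#' @return One-row tibble: `estimate` (Pearson r), `statistic`, `p.value`,
#'   `parameter` (df), `n_units`, `subgenome`, `unit`.
#' @export
deletion_duplication_correlation <- function(events, regions,
                                             subgenome = c("C", "A"),
                                             unit = c("region", "genotype"),
                                             exclude_random = TRUE) {
  subgenome <- match.arg(subgenome)
  unit <- match.arg(unit)
  copies <- regions[regions$annotation_class == "target_gene" &
                      regions$subgenome == subgenome, ]
  if (exclude_random) copies <- copies[!copies$is_random_scaffold, ]
  simple <- events[events$event_type != "hnrt" &
                     events$region_id %in% copies$region_id, ]
  key <- if (unit == "region") "region_id" else "genotype_id"
  tab <- simple |>
    dplyr::count(.data[[key]], .data$event_type) |>
    tidyr::pivot_wider(names_from = "event_type", values_from = "n",
                       values_fill = 0L)
  for (col in c("simple_deletion", "simple_duplication")) {
    if (!col %in% names(tab)) tab[[col]] <- 0L
  }
  if (unit == "region") {
    # copies with no simple events at all still count, with (0, 0)
    missing_units <- setdiff(copies$region_id, tab$region_id)
    if (length(missing_units) > 0) {
      tab <- dplyr::bind_rows(tab, tibble(region_id = missing_units,
                                          simple_deletion = 0L,
                                          simple_duplication = 0L))
    }
  }
  if (nrow(tab) < 3) {
    abort(sprintf("need >= 3 %ss with counts on subgenome %s, found %d",
                  unit, subgenome, nrow(tab)))
  }
  x <- tab$simple_deletion
  y <- tab$simple_duplication
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance in deletion or duplication counts; r undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p.value = ct$p.value, parameter = unname(ct$parameter),
         n_units = nrow(tab), subgenome = subgenome, unit = unit)
}

#' HNRT landscape: chromosome-pair counts and per-region simple events
#'
#' Summarises classified events the way a chromosome-map figure presents
#' them: HNRT counts per ordered chromosome pair (donor chromosome to
#' acceptor chromosome) and, per region with at least one simple event, the
#' simple duplication and deletion counts.
#'
#' @param events Event table from [classify_events()].
#' @param regions Region table.
#' @return Object of class `hnrt_landscape`: list with tibbles `pairs`
#'   (`from_chrom`, `to_chrom`, `n`) and `simple` (`region_id`, `chrom`,
#'   `simple_duplications`, `simple_deletions`).
#' @export
hnrt_landscape <- function(events, regions) {
  chrom_of <- setNames(regions$chrom, regions$region_id)
  hn <- events[events$event_type == "hnrt", ]
  pairs <- tibble(from_chrom = unname(chrom_of[hn$region_id]),
                  to_chrom = unname(chrom_of[hn$partner_region_id])) |>
    dplyr::count(.data$from_chrom, .data$to_chrom) |>
    dplyr::arrange(dplyr::desc(.data$n))
  simple <- events |>
    dplyr::filter(.data$event_type != "hnrt") |>
    dplyr::count(.data$region_id, .data$event_type) |>
    tidyr::pivot_wider(names_from = "event_type", values_from = "n",
                       values_fill = 0L)
  for (col in c("simple_deletion", "simple_duplication")) {
    if (!col %in% names(simple)) simple[[col]] <- 0L
  }
  simple <- tibble(region_id = simple$region_id,
                   chrom = unname(chrom_of[simple$region_id]),
                   simple_duplications = simple$simple_duplication,
                   simple_deletions = simple$simple_deletion)
  structure(list(pairs = pairs, simple = simple), class = "hnrt_landscape")
}

#' @export
print.hnrt_landscape <- function(x, ...) {
  cat(sprintf("<hnrt_landscape> %d HNRTs over %d chromosome pairs\n",
              sum(x$pairs$n), nrow(x$pairs)))
  print(head(x$pairs, 10))
  invisible(x)
}

#' @describeIn hnrt_landscape chromosome-pair counts.
#' @param x An `hnrt_landscape`.
#' @param ... Unused.
#' @method tidy hnrt_landscape
#' @export
tidy.hnrt_landscape <- function(x, ...) x$pairs

#' Score called events against a simulator truth table
#'
#' Compares calls and classified events with the planted truth of
#' [simulate_panel()]. Call-level sensitivity is the fraction of planted
#' event cells (HNRTs occupy two cells: duplicated donor, deleted acceptor)
#' carrying the matching call; the false-call rate is the fraction of
#' non-event cells called deletion or duplication. Event recovery requires
#' an exact row match (type, partner, direction); HNRT direction accuracy is
#' scored among truth HNRTs recovered as an HNRT of the same homeolog pair.
#'
#' @param calls A `cnv_calls` object.
#' @param events Event table from [classify_events()].
#' @param truth Truth table from [simulate_panel()].
#' @return One-row tibble: `n_truth_events`, `n_called_events`,
#'   `call_sensitivity`, `false_call_rate`, `event_recovery`,
#'   `hnrt_direction_accuracy` (`NA` when no HNRTs were planted).
#' @export
recovery_report <- function(calls, events, truth) {
  cell_key <- function(g, r) paste(g, r, sep = "\r")
  hn <- truth[truth$event_type == "hnrt", ]
  del_cells <- c(cell_key(truth$genotype_id[truth$event_type == "simple_deletion"],
                          truth$region_id[truth$event_type == "simple_deletion"]),
                 cell_key(hn$genotype_id, hn$partner_region_id))
  dup_cells <- c(cell_key(truth$genotype_id[truth$event_type == "simple_duplication"],
                          truth$region_id[truth$event_type == "simple_duplication"]),
                 cell_key(hn$genotype_id, hn$region_id))
  long <- tidy(calls)
  long$key <- cell_key(long$genotype_id, long$region_id)
  called_del <- long$key[long$call == "deletion"]
  called_dup <- long$key[long$call == "duplication"]
  n_truth_cells <- length(del_cells) + length(dup_cells)
  hits <- sum(del_cells %in% called_del) + sum(dup_cells %in% called_dup)
  call_sensitivity <- if (n_truth_cells > 0) hits / n_truth_cells else NA_real_
  event_cells <- c(del_cells, dup_cells)
  false_calls <- sum(!(c(called_del, called_dup) %in% event_cells))
  n_non_event <- nrow(long) - n_truth_cells
  false_call_rate <- if (n_non_event > 0) false_calls / n_non_event else NA_real_

  row_key <- function(df) {
    paste(df$genotype_id, df$region_id, df$event_type,
          dplyr::coalesce(df$partner_region_id, "."), df$direction,
          sep = "\r")
  }
  event_recovery <- if (nrow(truth) > 0) {
    mean(row_key(truth) %in% row_key(events))
  } else {
    NA_real_
  }
  dir_acc <- NA_real_
  if (nrow(hn) > 0) {
    pair_key <- function(df) {
      paste(df$genotype_id,
            pmin(df$region_id, df$partner_region_id),
            pmax(df$region_id, df$partner_region_id), sep = "\r")
    }
    ev_hn <- events[events$event_type == "hnrt", ]
    m <- match(pair_key(hn), pair_key(ev_hn))
    matched <- !is.na(m)
    if (any(matched)) {
      dir_acc <- mean(ev_hn$direction[m[matched]] == hn$direction[matched])
    } else {
      dir_acc <- 0
    }
  }
  tibble(n_truth_events = nrow(truth), n_called_events = nrow(events),
         call_sensitivity = call_sensitivity,
         false_call_rate = false_call_rate,
         event_recovery = event_recovery,
         hnrt_direction_accuracy = dir_acc)
}
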