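# Clone tables keyed on the CDR3 amino-acid sequence, the >1%
# replicated-sequence classification, and genotype-association contingency
# tables.

# Modal call among records sharing a clone key: the call with the largest
# summed abundance, ties broken alphabetically.
modal_call <- function(call, weight) {
  call <- ifelse(is_blank(call), "", call)
  s <- tapply(weight, call, sum)
  s <- s[order(-s, names(s))]
  names(s)[1L]
}

#' Build a pooled clone table
#'
#' Aggregates a group of repertoires (all samples of one genotype within one
#' cell subset) into a clone table keyed on the CDR3 amino-acid sequence.
#' Abundances are pooled across samples, frequencies are each clone's share
#' of the pooled abundance, and a clone is classified *replicated* when its
#' pooled frequency strictly exceeds `threshold` (default 1%). Each clone
#' carries a representative V/D/J/C call — the modal (highest-abundance) call
#' among its records — for downstream pairing analysis.
#'
#' @param data Rearrangement tibble; must contain a single genotype and a
#'   single subset when those columns are present.
#' @param chain Chain class analysed: `"heavy"` (IGH), `"light"` (IGK + IGL)
#'   or `"all"`.
#' @param threshold Replication threshold on the pooled frequency, in (0, 1);
#'   classification uses strict `>`.
#' @param weighting `"abundance"` pools read/consensus counts (the default);
#'   `"clonotype"` counts each record once.
#' @param pooling `"pooled"` classifies on the pooled group frequency (the
#'   default); `"per_sample"` flags a clone as replicated when it exceeds
#'   `threshold` within at least one contributing sample.
#' @return A `clone_tbl`: a tibble with one row per unique `junction_aa`
#'   (columns `junction_aa`, `v_call`, `d_call`, `j_call`, `c_call`, `locus`,
#'   `abundance`, `frequency`, `replicated`, `n_samples`, `samples`), sorted
#'   by decreasing abundance, with the grouping recorded in attributes
#'   `chain`, `threshold`, `weighting`, `pooling`, `genotype`, `subset`,
#'   `total_abundance`.
#' @examples
#' reps <- simulate_repertoire(sim_config(seed = 1, n_clones = 50,
#'                                        reads_per_sample = 500))
#' clone_table(reps$data, chain = "all")
#' @export
clone_table <- function(data, chain = c("heavy", "light", "all"),
                        threshold = 0.01,
                        weighting = c("abundance", "clonotype"),
                        pooling = c("pooled", "per_sample")) {
  chain <- match.arg(chain)
  weighting <- match.arg(weighting)
  pooling <- match.arg(pooling)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.",
          class = "bcrclone_argument_error")
  }
  for (key in c("genotype", "subset")) {
    if (key %in% names(data) && dplyr::n_distinct(data[[key]]) > 1L) {
      abort(sprintf("Clone tables pool one group: column `%s` has multiple values.",
                    key),
            class = "bcrclone_argument_error")
    }
  }
  data <- filter_chain(data, chain)
  if (nrow(data) == 0L) {
    abort("No records left after chain filtering; cannot build a clone table.",
          class = "bcrclone_empty_error")
  }
  w <- if (weighting == "abundance") as.numeric(data$consensus_count) else
    rep(1, nrow(data))
  data$.w <- w

  ct <- data |>
    dplyr::group_by(.data$junction_aa) |>
    dplyr::summarise(
      v_call = modal_call(.data$v_call, .data$.w),
      d_call = modal_call(.data$d_call, .data$.w),
      j_call = modal_call(.data$j_call, .data$.w),
      c_call = modal_call(.data$c_call, .data$.w),
      locus = modal_call(.data$locus, .data$.w),
      abundance = sum(.data$.w),
      n_samples = dplyr::n_distinct(.data$sample_id),
      samples = paste(sort(unique(.data$sample_id)), collapse = ","),
      .groups = "drop"
    )
  total <- sum(ct$abundance)
  ct$frequency <- ct$abundance / total

  if (pooling == "pooled") {
    ct$replicated <- ct$frequency > threshold
  } else {
    per_sample <- data |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(.f = .data$.w / sum(.data$.w)) |>
      dplyr::group_by(.data$junction_aa, .data$sample_id) |>
      dplyr::summarise(.f = sum(.data$.f), .groups = "drop") |>
      dplyr::group_by(.data$junction_aa) |>
      dplyr::summarise(replicated = any(.data$.f > threshold), .groups = "drop")
    ct <- dplyr::left_join(ct, per_sample, by = "junction_aa")
  }

  ct <- dplyr::arrange(ct, dplyr::desc(.data$abundance), .data$junction_aa)
  ct <- dplyr::relocate(ct, "junction_aa", "abundance", "frequency",
                        "replicated")
  attr(ct, "chain") <- chain
  attr(ct, "threshold") <- threshold
  attr(ct, "weighting") <- weighting
  attr(ct, "pooling") <- pooling
  attr(ct, "genotype") <- if ("genotype" %in% names(data))
    unique(data$genotype) else NA_character_
  attr(ct, "subset") <- if ("subset" %in% names(data))
    unique(data$subset) else NA_character_
  attr(ct, "total_abundance") <- total
  class(ct) <- c("clone_tbl", class(ct))
  ct
}

#' Summarise the replicated/non-replicated partition of a clone table
#'
#' Counts replicated and non-replicated unique CDR3 sequences and the
#' *coverage* of the replicated set — the share of the pooled abundance held
#' by replicated clones (e.g. "13 unique sequences covering 72% of all
#' CDR3s"). Coverage and the non-replicated share sum to 1.
#'
#' @param ct A `clone_tbl` from [clone_table()].
#' @return A one-row tibble: `genotype`, `subset`, `chain`, `threshold`,
#'   `n_replicated`, `n_nonreplicated`, `n_unique`, `replicated_coverage`,
#'   `nonreplicated_coverage`, `total_abundance`.
#' @export
replicated_summary <- function(ct) {
  stopifnot(inherits(ct, "clone_tbl"))
  cov <- sum(ct$frequency[ct$replicated])
  tibble(
    genotype = attr(ct, "genotype"),
    subset = attr(ct, "subset"),
    chain = attr(ct, "chain"),
    threshold = attr(ct, "threshold"),
    n_replicated = sum(ct$replicated),
    n_nonreplicated = sum(!ct$replicated),
    n_unique = nrow(ct),
    replicated_coverage = cov,
    nonreplicated_coverage = sum(ct$frequency[!ct$replicated]),
    total_abundance = attr(ct, "total_abundance")
  )
}

#' @method glance clone_tbl
#' @export
glance.clone_tbl <- function(x, ...) replicated_summary(x)

#' Per-sample unique CDR3 counts
#'
#' Counts the unique CDR3 amino-acid sequences per sample, without pooling —
#' the per-mouse diversity statistic compared WT vs KO with
#' [rank_sum_exact()]. Samples present in `data` but holding no records of
#' the requested chain report 0.
#'
#' @inheritParams clone_table
#' @return A tibble with `sample_id` (plus `genotype`/`subset` when present)
#'   and `n_unique`.
#' @export
unique_counts <- function(data, chain = c("heavy", "light", "all")) {
  chain <- match.arg(chain)
  meta_cols <- intersect(c("sample_id", "genotype", "subset"), names(data))
  samples <- dplyr::distinct(data[meta_cols])
  counts <- filter_chain(data, chain) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_unique = dplyr::n_distinct(.data$junction_aa),
                     .groups = "drop")
  samples |>
    dplyr::left_join(counts, by = "sample_id") |>
    dplyr::mutate(n_unique = dplyr::coalesce(.data$n_unique, 0L)) |>
    dplyr::arrange(.data$sample_id)
}

#' Replicated-by-genotype contingency table
#'
#' Assembles the 2x2 table of replicated vs non-replicated CDR3 sequences
#' against genotype from a WT and a KO clone table of the same subset, chain
#' and threshold. In `"unique"` mode cells count unique clones; in `"total"`
#' mode cells are summed abundances (total CDR3 transcripts). Feed the result
#' to [chi2_test()].
#'
#' @param wt,ko `clone_tbl` objects for the two genotypes.
#' @param mode `"unique"` or `"total"`.
#' @return An integer matrix with rows `replicated`/`non_replicated` and
#'   columns `WT`/`KO`, class `"contingency_tbl"`, with the mode and group
#'   key in attributes.
#' @export
clone_contingency <- function(wt, ko, mode = c("unique", "total")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wt, "clone_tbl"), inherits(ko, "clone_tbl"))
  for (key in c("chain", "threshold", "subset", "weighting")) {
    if (!identical(attr(wt, key), attr(ko, key))) {
      abort(sprintf("Clone tables disagree on `%s`; cannot build a contingency table.",
                    key),
            class = "bcrclone_argument_error")
    }
  }
  cell <- function(ct, replicated) {
    rows <- ct$replicated == replicated
    if (mode == "unique") sum(rows) else round(sum(ct$abundance[rows]))
  }
  m <- matrix(
    c(cell(wt, TRUE), cell(wt, FALSE), cell(ko, TRUE), cell(ko, FALSE)),
    nrow = 2L,
    dimnames = list(status = c("replicated", "non_replicated"),
                    genotype = c("WT", "KO"))
  )
  structure(m, mode = mode, subset = attr(wt, "subset"),
            chain = attr(wt, "chain"), threshold = attr(wt, "threshold"),
            class = c("contingency_tbl", class(m)))
}

#' Write a clone table to TSV
#'
#' @param ct A `clone_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(ct, path) {
  out <- as_tibble(ct)
  out$genotype <- attr(ct, "genotype")
  out$subset <- attr(ct, "subset")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
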