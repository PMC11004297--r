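# Multi-set shared-CDR3 analysis and cross-group tracking of top clones.

as_cdr3_set <- function(x) {
  if (inherits(x, "clone_tbl")) unique(x$junction_aa)
  else if (is.character(x)) unique(x)
  else abort("Overlap inputs must be clone tables or character vectors of CDR3s.",
             class = "bcrclone_argument_error")
}

#' Shared CDR3 sequences across groups
#'
#' Computes the sequences shared by every one of two or more labelled groups
#' — a shared sequence is one expressed at least once in each group being
#' compared (abundance is ignored) — together with per-group non-shared
#' counts and percentages, the numbers a Venn diagram of the comparison
#' displays.
#'
#' @param sets A named list of two or more groups, each a `clone_tbl` or a
#'   character vector of CDR3 amino-acid sequences.
#' @param strict Additionally require a matching V family for sharing; the
#'   set elements become `junction_aa|V-family` keys.
#' @return An `overlap_report`: a list with `n_shared`, `shared` (the
#'   sequences), `per_set` (tibble: `label`, `n_unique`, `n_nonshared`,
#'   `pct_nonshared`), `flagged_empty`.
#' @examples
#' shared_sequences(list(a = c("CAAW", "CABW", "CACW"),
#'                       b = c("CABW", "CACW", "CADW")))
#' @export
shared_sequences <- function(sets, strict = FALSE) {
  if (length(sets) < 2L) {
    abort("Overlap needs at least two sets.", class = "bcrclone_argument_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  keys <- lapply(sets, function(s) {
    if (strict && inherits(s, "clone_tbl")) {
      paste(s$junction_aa, parse_segment(s$v_call)$family, sep = "|")
    } else {
      as_cdr3_set(s)
    }
  })
  empty <- vapply(keys, length, 0L) == 0L
  if (any(empty)) {
    warn(sprintf("Empty set(s): %s; overlap reported as 0.",
                 paste(names(sets)[empty], collapse = ", ")))
  }
  shared <- Reduce(intersect, keys)
  per_set <- tibble(
    label = names(sets),
    n_unique = unname(vapply(keys, length, 0L)),
    n_nonshared = unname(vapply(keys, function(k) length(setdiff(k, shared)),
                                0L))
  )
  per_set$pct_nonshared <- ifelse(per_set$n_unique > 0,
                                  100 * per_set$n_nonshared / per_set$n_unique,
                                  NA_real_)
  structure(
    list(n_shared = length(shared), shared = sort(shared), per_set = per_set,
         flagged_empty = names(sets)[empty]),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("CDR3 overlap across %d sets: %d shared sequence(s)\n",
              nrow(x$per_set), x$n_shared))
  df <- x$per_set
  df$pct_nonshared <- sprintf("%.1f%%", df$pct_nonshared)
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' @rdname shared_sequences
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  dplyr::mutate(x$per_set, n_shared = x$n_shared)
}

#' Track a group's top clones across other groups
#'
#' Takes the `k` most abundant CDR3 sequences of a reference clone table and
#' looks up their pooled frequency in each target group (0 when absent) —
#' e.g. the proportion of the top WT B-1a sequence among all CDR3s of every
#' other group. Ties at rank `k` are broken lexicographically on the CDR3
#' string, so the selection is deterministic.
#'
#' @param reference A `clone_tbl` supplying the top clones.
#' @param targets A named list of `clone_tbl` objects to look the clones up
#'   in (may include the reference itself).
#' @param k Number of top clones to track; truncated with a warning when the
#'   reference holds fewer.
#' @return A tibble with one row per clone x group: `rank`, `junction_aa`,
#'   `group`, `frequency`.
#' @export
top_clones <- function(reference, targets, k = 1L) {
  stopifnot(inherits(reference, "clone_tbl"))
  if (!is.list(targets) || is.null(names(targets)) || any(names(targets) == "")) {
    abort("`targets` must be a named list of clone tables.",
          class = "bcrclone_argument_error")
  }
  if (k < 1L) {
    abort("`k` must be at least 1.", class = "bcrclone_argument_error")
  }
  if (k > nrow(reference)) {
    warn(sprintf("k = %d exceeds the reference's %d unique clones; truncating.",
                 k, nrow(reference)))
    k <- nrow(reference)
  }
  top <- reference |>
    dplyr::arrange(dplyr::desc(.data$abundance), .data$junction_aa) |>
    head(k)
  purrr::imap(targets, function(tgt, label) {
    stopifnot(inherits(tgt, "clone_tbl"))
    idx <- match(top$junction_aa, tgt$junction_aa)
    tibble(rank = seq_len(k), junction_aa = top$junction_aa, group = label,
           frequency = dplyr::coalesce(tgt$frequency[idx], 0))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$rank, .data$group)
}
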