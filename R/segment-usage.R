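# V/D/J segment usage at gene and family level, V-J pairing matrices,
# isotype distributions and kappa/lambda ratios.

#' Parse an IMGT-style segment call into gene and family
#'
#' Strips the allele suffix (`*NN`) to obtain the gene, and extracts the
#' family as the locus/segment-class prefix plus the leading family number
#' (everything before the first hyphen): `"IGHV11-2*01"` gives gene
#' `"IGHV11-2"`, family `"IGHV11"`. Calls that do not look like IMGT
#' nomenclature are flagged with family `"unknown"`.
#'
#' @param call Character vector of segment calls.
#' @return A tibble with columns `call`, `gene`, `family`.
#' @examples
#' parse_segment(c("IGHV11-2*01", "IGHJ4*01", "IGKV4-59"))
#' @export
parse_segment <- function(call) {
  gene <- sub("\\*.*$", "", ifelse(is.na(call), "", call))
  family <- stringr::str_extract(gene, "^IG[HKL][VDJ][0-9]+")
  known <- !is.na(family) & grepl("^IG[HKL][VDJ][0-9]*", gene)
  family[!known] <- "unknown"
  tibble(call = call, gene = gene, family = family)
}

usage_attrs <- function(x, level, segment, weighting, scope = NA_character_) {
  attr(x, "level") <- level
  attr(x, "segment") <- segment
  attr(x, "weighting") <- weighting
  attr(x, "scope") <- scope
  class(x) <- unique(c("usage_tbl", class(x)))
  x
}

#' Segment usage frequencies
#'
#' Computes normalised usage frequencies of V, D or J segments at gene or
#' family level. For a rearrangement tibble the result is per sample (each
#' sample's frequencies sum to 1); for a [clone_table()] the result is the
#' pooled usage weighted by clone frequency, optionally restricted to
#' replicated clones — this is the marginal of the V-J pairing matrix under
#' the same weighting and scope.
#'
#' @param data A rearrangement tibble or a `clone_tbl`.
#' @param segment `"v"`, `"d"` or `"j"`.
#' @param level `"family"` (the default reporting level) or `"gene"`.
#' @param ... Passed to methods.
#' @return A `usage_tbl` tibble: `sample_id` (rearrangement input only),
#'   `segment`, `frequency` (plus genotype/subset columns when present).
#' @export
segment_usage <- function(data, segment = c("v", "d", "j"),
                          level = c("family", "gene"), ...) {
  UseMethod("segment_usage")
}

#' @rdname segment_usage
#' @param weighting `"abundance"` (read counts) or `"clonotype"` (each record
#'   once).
#' @param chain Chain class to restrict to before computing usage.
#' @export
segment_usage.data.frame <- function(data, segment = c("v", "d", "j"),
                                     level = c("family", "gene"),
                                     weighting = c("abundance", "clonotype"),
                                     chain = c("heavy", "light", "all"), ...) {
  segment <- match.arg(segment)
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  data <- filter_chain(data, match.arg(chain))
  col <- paste0(segment, "_call")
  keep <- !is_blank(data[[col]])
  dropped <- sum(!keep)
  if (dropped > 0L) {
    inform(sprintf("Excluded %d records without a %s call.", dropped,
                   toupper(segment)))
  }
  data <- data[keep, , drop = FALSE]
  parsed <- parse_segment(data[[col]])
  data$.segment <- if (level == "gene") parsed$gene else parsed$family
  data$.w <- if (weighting == "abundance") as.numeric(data$consensus_count)
             else rep(1, nrow(data))
  meta_cols <- intersect(c("genotype", "subset"), names(data))
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta_cols)))) |>
    dplyr::mutate(.f = .data$.w / sum(.data$.w)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta_cols,
                                                  ".segment")))) |>
    dplyr::summarise(frequency = sum(.data$.f), .groups = "drop") |>
    dplyr::rename(segment = ".segment") |>
    dplyr::arrange(.data$sample_id, .data$segment)
  usage_attrs(out, level, segment, weighting)
}

#' @rdname segment_usage
#' @param scope For clone tables: `"all"` clones or `"replicated"` only
#'   (frequencies renormalised within the replicated set).
#' @export
segment_usage.clone_tbl <- function(data, segment = c("v", "d", "j"),
                                    level = c("family", "gene"),
                                    scope = c("all", "replicated"), ...) {
  segment <- match.arg(segment)
  level <- match.arg(level)
  scope <- match.arg(scope)
  ct <- if (scope == "replicated") data[data$replicated, , drop = FALSE]
        else data
  col <- paste0(segment, "_call")
  keep <- !is_blank(ct[[col]])
  if (any(!keep)) {
    inform(sprintf("Excluded %d clones without a %s call.", sum(!keep),
                   toupper(segment)))
  }
  ct <- ct[keep, , drop = FALSE]
  parsed <- parse_segment(ct[[col]])
  seg <- if (level == "gene") parsed$gene else parsed$family
  f <- ct$frequency / sum(ct$frequency)
  out <- tibble(segment = seg, frequency = f) |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    dplyr::arrange(.data$segment)
  usage_attrs(out, level, segment, attr(data, "weighting"), scope)
}

#' V-J pairing matrix
#'
#' Relative frequency of each V-J segment pairing among the clones of a
#' clone table — the quantity a repertoire circos plot encodes, with cable
#' thickness proportional to the cell value. Pair frequency is the summed
#' clone frequency of clones carrying that (V, J) pair; with `scope =
#' "replicated"` only replicated clones enter and frequencies are
#' renormalised within them. Cells sum to 1, and the row/column marginals
#' equal [segment_usage()] on the same clone table under the same scope.
#'
#' @param ct A `clone_tbl` whose clones retain representative V and J calls.
#' @param level `"family"` or `"gene"`.
#' @param scope `"all"` or `"replicated"`.
#' @return A `vj_pairing` tibble with columns `v`, `j`, `frequency`, sorted
#'   by decreasing frequency; `as.matrix()` yields the V-by-J matrix.
#' @export
vj_pairing <- function(ct, level = c("family", "gene"),
                       scope = c("all", "replicated")) {
  stopifnot(inherits(ct, "clone_tbl"))
  level <- match.arg(level)
  scope <- match.arg(scope)
  if (scope == "replicated") ct <- ct[ct$replicated, , drop = FALSE]
  keep <- !is_blank(ct$v_call) & !is_blank(ct$j_call)
  if (any(!keep)) {
    inform(sprintf("Excluded %d clones with a missing V or J call.", sum(!keep)))
  }
  ct <- ct[keep, , drop = FALSE]
  if (nrow(ct) == 0L) {
    abort("No clones with both V and J calls in the requested scope.",
          class = "bcrclone_empty_error")
  }
  pv <- parse_segment(ct$v_call)
  pj <- parse_segment(ct$j_call)
  v <- if (level == "gene") pv$gene else pv$family
  j <- if (level == "gene") pj$gene else pj$family
  f <- ct$frequency / sum(ct$frequency)
  out <- tibble(v = v, j = j, frequency = f) |>
    dplyr::group_by(.data$v, .data$j) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$v, .data$j)
  attr(out, "level") <- level
  attr(out, "scope") <- scope
  attr(out, "genotype") <- attr(ct, "genotype")
  attr(out, "subset") <- attr(ct, "subset")
  class(out) <- c("vj_pairing", class(out))
  out
}

#' @export
as.matrix.vj_pairing <- function(x, ...) {
  wide <- tidyr::pivot_wider(as_tibble(x), names_from = "j",
                             values_from = "frequency", values_fill = 0)
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$v
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Kappa/lambda light-chain usage ratio
#'
#' Per-sample ratio of kappa (IGK) to lambda (IGL) light-chain usage. A
#' sample with no lambda records reports an infinite ratio and is flagged
#' `degenerate`; ranks handle infinite ratios, so such samples still enter
#' rank-sum comparisons unless every sample of both groups is degenerate.
#'
#' @inheritParams segment_usage.data.frame
#' @param data Rearrangement tibble containing light-chain records.
#' @return A tibble with `sample_id` (plus metadata columns), `igk`, `igl`,
#'   `ratio`, `degenerate`.
#' @export
kappa_lambda_ratio <- function(data, weighting = c("abundance", "clonotype")) {
  weighting <- match.arg(weighting)
  light <- filter_chain(data, "light")
  if (nrow(light) == 0L) {
    abort("No light-chain (IGK/IGL) records present.",
          class = "bcrclone_empty_error")
  }
  light$.w <- if (weighting == "abundance") as.numeric(light$consensus_count)
              else rep(1, nrow(light))
  meta_cols <- intersect(c("genotype", "subset"), names(light))
  light |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta_cols)))) |>
    dplyr::summarise(
      igk = sum(.data$.w[.data$locus == "IGK"]),
      igl = sum(.data$.w[.data$locus == "IGL"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(ratio = .data$igk / .data$igl,
                  degenerate = .data$igl == 0) |>
    dplyr::arrange(.data$sample_id)
}

#' Per-sample isotype distribution
#'
#' Proportions of the five antibody classes among heavy-chain records with a
#' constant-gene call, per sample; proportions sum to 1 over
#' [isotype_levels()] (absent classes report 0). Records without a `c_call`
#' are excluded with a message.
#'
#' @inheritParams kappa_lambda_ratio
#' @return An `isotype_tbl` tibble: `sample_id` (plus metadata columns),
#'   `isotype`, `count`, `proportion`.
#' @export
isotype_distribution <- function(data, weighting = c("abundance", "clonotype")) {
  weighting <- match.arg(weighting)
  heavy <- filter_chain(data, "heavy")
  heavy$isotype <- assign_isotype(heavy$c_call)
  excluded <- sum(is.na(heavy$isotype))
  if (excluded > 0L) {
    inform(sprintf("Excluded %d heavy-chain records without an isotype call.",
                   excluded))
  }
  heavy <- heavy[!is.na(heavy$isotype), , drop = FALSE]
  if (nrow(heavy) == 0L) {
    abort("No isotype-bearing heavy-chain records present.",
          class = "bcrclone_empty_error")
  }
  heavy$.w <- if (weighting == "abundance") as.numeric(heavy$consensus_count)
              else rep(1, nrow(heavy))
  meta_cols <- intersect(c("genotype", "subset"), names(heavy))
  out <- heavy |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta_cols)))) |>
    dplyr::mutate(.f = .data$.w / sum(.data$.w)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta_cols)))) |>
    tidyr::nest() |>
    dplyr::mutate(data = purrr::map(.data$data, function(df) {
      tibble(isotype = factor(isotype_levels(), levels = isotype_levels()),
             count = unname(vapply(isotype_levels(),
                                   function(i) sum(df$.w[df$isotype == i]),
                                   0)),
             proportion = unname(vapply(isotype_levels(),
                                        function(i) sum(df$.f[df$isotype == i]),
                                        0)))
    })) |>
    tidyr::unnest("data") |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, .data$isotype)
  class(out) <- c("isotype_tbl", class(out))
  out
}
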