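# Config-driven orchestration: rearrangement tables + metadata in, full
# analysis bundle out.

#' Analysis configuration
#'
#' @param threshold Replicated-sequence threshold on the pooled frequency.
#' @param chains Chain classes to analyse.
#' @param weighting `"abundance"` or `"clonotype"` (see [clone_table()]).
#' @param pooling `"pooled"` or `"per_sample"` (see [clone_table()]).
#' @param usage_level `"family"` or `"gene"` for segment-usage reporting.
#' @param top_k Number of top reference clones tracked across groups.
#' @param productive_only Apply [filter_productive()] before analysis.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(threshold = 0.01, chains = c("heavy", "light"),
                            weighting = "abundance", pooling = "pooled",
                            usage_level = "family", top_k = 2L,
                            productive_only = TRUE) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.",
          class = "bcrclone_config_error")
  }
  structure(list(threshold = threshold, chains = chains,
                 weighting = weighting, pooling = pooling,
                 usage_level = usage_level, top_k = as.integer(top_k),
                 productive_only = productive_only),
            class = "analysis_config")
}

#' Run the full repertoire analysis
#'
#' Composes every analysis stage over a study's rearrangement table: per
#' subset and chain class, per-sample unique CDR3 counts with the exact
#' WT-vs-KO rank-sum test; pooled clone tables per genotype with replicated
#' summaries; replicated-by-genotype contingency tables (unique and total
#' modes) with chi-squared association tests; isotype distributions,
#' V-family usage and kappa/lambda ratios with per-level genotype
#' comparisons; V-J pairing tables (all and replicated scopes); pairwise
#' shared-CDR3 overlap across the four groups; and top-clone tracking from
#' the WT B-1a reference. Groups with fewer than two samples per genotype
#' skip the rank test with a warning; pooled statistics are still emitted.
#'
#' @param data Rearrangement tibble with `genotype` and `subset` columns
#'   (from [read_study()] or [simulate_study()]`$data`).
#' @param config An [analysis_config()].
#' @return A `bcr_analysis` list: `unique_counts`, `rank_tests`,
#'   `clone_tables` (nested list by chain/subset/genotype), `replicated`,
#'   `contingency`, `chi2`, `isotype`, `isotype_tests`, `usage`,
#'   `usage_tests`, `pairing`, `kappa_lambda`, `kappa_lambda_test`,
#'   `overlap`, `top_clones`, `log`, `config`.
#' @export
run_analysis <- function(data, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  required <- c(airr_columns(), "genotype", "subset")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Input is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "bcrclone_format_error")
  }
  bad <- is.na(data$genotype) | is.na(data$subset) | is.na(data$sample_id)
  if (any(bad)) {
    abort(sprintf("Records with missing metadata in sample(s): %s.",
                  paste(unique(data$sample_id[bad]), collapse = ", ")),
          class = "bcrclone_meta_error")
  }
  log <- list(n_input = nrow(data))
  if (config$productive_only) {
    n0 <- nrow(data)
    suppressMessages(data <- filter_productive(data))
    log$n_dropped_nonproductive <- n0 - nrow(data)
  }
  subsets <- sort(unique(data$subset))
  res <- list(config = config, log = log)

  grp_label <- function(subset, genotype) paste(subset, genotype)

  res$unique_counts <- purrr::map(rlang::set_names(config$chains), function(ch)
    purrr::map(rlang::set_names(subsets), function(ss)
      unique_counts(dplyr::filter(data, .data$subset == ss), chain = ch)))

  res$rank_tests <- purrr::map(res$unique_counts, function(by_subset)
    purrr::imap(by_subset, function(uc, ss) {
      n_per <- table(uc$genotype)
      if (length(n_per) < 2L || any(n_per < 2L)) {
        warn(sprintf("Subset %s: fewer than two samples per genotype; rank test skipped.",
                     ss))
        return(NULL)
      }
      rank_sum_exact(uc$n_unique[uc$genotype == "WT"],
                     uc$n_unique[uc$genotype == "KO"])
    }))

  res$clone_tables <- purrr::map(rlang::set_names(config$chains), function(ch)
    purrr::map(rlang::set_names(subsets), function(ss)
      purrr::map(rlang::set_names(intersect(c("WT", "KO"),
                                            unique(data$genotype))),
                 function(g) {
        suppressMessages(clone_table(
          dplyr::filter(data, .data$subset == ss, .data$genotype == g),
          chain = ch, threshold = config$threshold,
          weighting = config$weighting, pooling = config$pooling))
      })))

  res$replicated <- purrr::map(res$clone_tables, function(by_subset)
    purrr::map(by_subset, function(by_geno)
      dplyr::bind_rows(purrr::map(by_geno, replicated_summary))) |>
      dplyr::bind_rows()) |>
    dplyr::bind_rows(.id = "chain_class")

  res$contingency <- purrr::map(res$clone_tables, function(by_subset)
    purrr::map(by_subset, function(by_geno) {
      if (!all(c("WT", "KO") %in% names(by_geno))) return(NULL)
      list(unique = clone_contingency(by_geno$WT, by_geno$KO, "unique"),
           total = clone_contingency(by_geno$WT, by_geno$KO, "total"))
    }))
  res$chi2 <- purrr::map(res$contingency, function(by_subset)
    purrr::map(by_subset, function(tabs) {
      if (is.null(tabs)) return(NULL)
      purrr::map(tabs, chi2_test)
    }))

  suppressMessages({
    res$isotype <- isotype_distribution(data, weighting = config$weighting)
    res$isotype_tests <- purrr::map(rlang::set_names(subsets), function(ss)
      compare_groups(dplyr::filter(res$isotype, .data$subset == ss),
                     value = "proportion", by = "isotype"))
    res$usage <- purrr::map(rlang::set_names(c("v", "j")), function(seg)
      segment_usage(data, segment = seg, level = config$usage_level,
                    weighting = config$weighting, chain = "heavy"))
    res$usage_tests <- purrr::map(res$usage, function(u)
      purrr::map(rlang::set_names(subsets), function(ss)
        compare_groups(dplyr::filter(u, .data$subset == ss),
                       value = "frequency", by = "segment")))
    res$pairing <- purrr::map(res$clone_tables[["heavy"]] %||% list(),
      function(by_geno) purrr::map(by_geno, function(ct)
        list(all = vj_pairing(ct, level = config$usage_level, scope = "all"),
             replicated = if (any(ct$replicated))
               vj_pairing(ct, level = config$usage_level,
                          scope = "replicated"))))
    res$kappa_lambda <- kappa_lambda_ratio(data, weighting = config$weighting)
    res$kappa_lambda_test <- purrr::map(rlang::set_names(subsets), function(ss)
      compare_groups(dplyr::filter(res$kappa_lambda, .data$subset == ss),
                     value = "ratio"))
  })

  heavy_tables <- res$clone_tables[["heavy"]]
  if (!is.null(heavy_tables)) {
    flat <- purrr::flatten(purrr::imap(heavy_tables, function(by_geno, ss)
      rlang::set_names(by_geno, paste(ss, names(by_geno)))))
    if (length(flat) >= 2L) {
      pairs <- utils::combn(names(flat), 2L, simplify = FALSE)
      res$overlap <- rlang::set_names(
        purrr::map(pairs, function(pr) shared_sequences(flat[pr])),
        purrr::map_chr(pairs, paste, collapse = " vs "))
      ref_name <- grep("B-1a WT", names(flat), value = TRUE)
      if (length(ref_name) == 1L) {
        res$top_clones <- top_clones(flat[[ref_name]], flat,
                                     k = min(config$top_k,
                                             nrow(flat[[ref_name]])))
      }
    }
  }
  res$log$n_analysed <- nrow(data)
  res$log$samples <- sort(unique(data$sample_id))
  class(res) <- "bcr_analysis"
  res
}

#' @export
print.bcr_analysis <- function(x, ...) {
  cat("BCR repertoire analysis\n")
  cat(sprintf("  %d records across %d samples; threshold = %g\n",
              x$log$n_analysed, length(x$log$samples), x$config$threshold))
  cat("  Replicated-sequence summaries:\n")
  print(as.data.frame(x$replicated[c("chain_class", "subset", "genotype",
                                     "n_replicated", "n_unique",
                                     "replicated_coverage")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Writes every machine-readable table of a [run_analysis()] result under a
#' directory: per-group clone tables, replicated summaries, unique counts,
#' usage/isotype/kappa-lambda/pairing TSVs, and a single `report.json`
#' collecting the summary statistics, test results, contingency tables,
#' overlap regions and the configuration. Output is deterministic for a
#' given analysis object.
#'
#' @param res A `bcr_analysis` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(res, out_dir) {
  stopifnot(inherits(res, "bcr_analysis"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  slug <- function(...) gsub("[^A-Za-z0-9_.-]", "_", paste(..., sep = "_"))

  readr::write_tsv(res$replicated,
                   file.path(out_dir, "replicated_summary.tsv"),
                   progress = FALSE)
  for (ch in names(res$unique_counts)) {
    dplyr::bind_rows(res$unique_counts[[ch]]) |>
      readr::write_tsv(file.path(out_dir, slug("unique_counts", ch, ".tsv")),
                       progress = FALSE)
  }
  for (ch in names(res$clone_tables)) {
    for (ss in names(res$clone_tables[[ch]])) {
      for (g in names(res$clone_tables[[ch]][[ss]])) {
        write_clone_table(res$clone_tables[[ch]][[ss]][[g]],
                          file.path(out_dir, slug("clones", ch, ss, g, ".tsv")))
      }
    }
  }
  readr::write_tsv(res$isotype, file.path(out_dir, "isotype.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$kappa_lambda, file.path(out_dir, "kappa_lambda.tsv"),
                   progress = FALSE)
  for (seg in names(res$usage)) {
    readr::write_tsv(res$usage[[seg]],
                     file.path(out_dir, slug("usage", seg, ".tsv")),
                     progress = FALSE)
  }
  for (ss in names(res$pairing %||% list())) {
    for (g in names(res$pairing[[ss]])) {
      for (scope in names(res$pairing[[ss]][[g]])) {
        pm <- res$pairing[[ss]][[g]][[scope]]
        if (is.null(pm)) next
        readr::write_tsv(as_tibble(pm),
                         file.path(out_dir,
                                   slug("vj_pairing", ss, g, scope, ".tsv")),
                         progress = FALSE)
      }
    }
  }
  if (!is.null(res$top_clones)) {
    readr::write_tsv(res$top_clones, file.path(out_dir, "top_clones.tsv"),
                     progress = FALSE)
  }

  report <- list(
    config = unclass(res$config),
    log = res$log,
    replicated = res$replicated,
    rank_tests = purrr::map(res$rank_tests, function(by_ss)
      purrr::map(by_ss, function(t) if (!is.null(t)) tidy(t))),
    chi2 = purrr::map(res$chi2, function(by_ss)
      purrr::map(by_ss, function(tabs) if (!is.null(tabs))
        purrr::map(tabs, tidy))),
    contingency = purrr::map(res$contingency, function(by_ss)
      purrr::map(by_ss, function(tabs) if (!is.null(tabs))
        purrr::map(tabs, function(m) as.data.frame(unclass(m))))),
    isotype_tests = res$isotype_tests,
    usage_tests = res$usage_tests,
    kappa_lambda_test = res$kappa_lambda_test,
    overlap = purrr::map(res$overlap %||% list(), tidy)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
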