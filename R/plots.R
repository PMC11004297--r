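# ggplot2 views of the main result types.

genotype_scale <- function() {
  ggplot2::scale_fill_manual(values = c(WT = "#4477AA", KO = "#EE7733"),
                             drop = FALSE)
}

#' Rank-abundance plot of a clone table
#'
#' Clone frequencies by abundance rank on a log scale, replicated clones
#' highlighted, with the replication threshold drawn as a horizontal line.
#'
#' @param object A `clone_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clone_tbl
#' @export
autoplot.clone_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$frequency,
                                   colour = .data$replicated)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#CC3311",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "Clone rank", y = "Pooled frequency",
                  colour = "Replicated",
                  title = sprintf("%s %s (%s chain)",
                                  attr(object, "subset") %||% "",
                                  attr(object, "genotype") %||% "",
                                  attr(object, "chain")))
}

#' Per-sample unique CDR3 counts by genotype
#'
#' @param counts Output of [unique_counts()] (with a `genotype` column).
#' @return A ggplot object.
#' @export
plot_unique_counts <- function(counts) {
  stopifnot(all(c("genotype", "n_unique") %in% names(counts)))
  p <- ggplot2::ggplot(counts,
                       ggplot2::aes(x = .data$genotype, y = .data$n_unique,
                                    fill = .data$genotype)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    genotype_scale() +
    ggplot2::labs(x = NULL, y = "Unique CDR3 sequences", fill = "Genotype")
  if ("subset" %in% names(counts)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$subset))
  }
  p
}

#' Segment-usage distribution by genotype
#'
#' @param object A `usage_tbl` from [segment_usage()] on per-sample data.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot usage_tbl
#' @export
autoplot.usage_tbl <- function(object, ...) {
  df <- as_tibble(object)
  if (!"genotype" %in% names(df)) df$genotype <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$frequency,
                                   fill = .data$genotype)) +
    ggplot2::geom_boxplot(alpha = 0.7, position = "dodge") +
    genotype_scale() +
    ggplot2::labs(x = sprintf("%s segment (%s level)",
                              toupper(attr(object, "segment") %||% ""),
                              attr(object, "level") %||% ""),
                  y = "Usage frequency", fill = "Genotype") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap view of a V-J pairing matrix
#'
#' Tile heatmap of the relative pairing frequencies (the table a chord
#' diagram encodes).
#'
#' @param object A `vj_pairing` from [vj_pairing()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vj_pairing
#' @export
autoplot.vj_pairing <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$j, y = .data$v,
                               fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = "J segment", y = "V segment",
                  fill = "Pair\nfrequency",
                  title = sprintf("V-J pairing (%s clones)",
                                  attr(object, "scope") %||% "all"))
}

#' Stacked isotype composition per sample
#'
#' @param object An `isotype_tbl` from [isotype_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isotype_tbl
#' @export
autoplot.isotype_tbl <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                        y = .data$proportion,
                                        fill = .data$isotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Proportion of transcripts",
                  fill = "Isotype") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (all(c("subset", "genotype") %in% names(df))) {
    p <- p + ggplot2::facet_grid(cols = ggplot2::vars(.data$subset,
                                                      .data$genotype),
                                 scales = "free_x", space = "free_x")
  }
  p
}
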