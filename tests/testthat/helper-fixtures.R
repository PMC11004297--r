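# In-code fixtures shared across the suite.

# Minimal rearrangement tibble; junction defaults to a translatable stand-in
# (its nt content is irrelevant for clonality tests).
make_rearrangements <- function(junction_aa, consensus_count = 1L,
                                sample_id = "S1", locus = "IGH",
                                v_call = "IGHV11-2*01", d_call = "IGHD1-1*01",
                                j_call = "IGHJ1*01", c_call = "IGHM",
                                genotype = NULL, subset = NULL) {
  n <- length(junction_aa)
  out <- tibble::tibble(
    sequence_id = sprintf("seq%04d", seq_len(n)),
    locus = rep_len(locus, n),
    v_call = rep_len(v_call, n),
    d_call = rep_len(d_call, n),
    j_call = rep_len(j_call, n),
    c_call = rep_len(c_call, n),
    junction = strrep("TGT", nchar(junction_aa)),
    junction_aa = junction_aa,
    productive = TRUE,
    consensus_count = as.integer(rep_len(consensus_count, n)),
    sample_id = rep_len(sample_id, n)
  )
  out$d_call[out$locus != "IGH"] <- ""
  if (!is.null(genotype)) out$genotype <- rep_len(genotype, n)
  if (!is.null(subset)) out$subset <- rep_len(subset, n)
  out
}

# Distinct anchored CDR3 strings: CAR<index in base-20 amino acids>W.
fake_cdr3 <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  idx <- seq_len(n) - 1L
  body <- vapply(idx, function(i) {
    paste(aa[c(i %/% 400L, (i %/% 20L) %% 20L, i %% 20L) + 1L],
          collapse = "")
  }, character(1))
  paste0("CAR", body, "W")
}

write_airr_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Clone table from an explicit abundance spec, one sample.
clone_table_from_counts <- function(counts, ...) {
  aa <- fake_cdr3(length(counts))
  dat <- make_rearrangements(aa, consensus_count = counts,
                             genotype = "WT", subset = "B-1a")
  suppressMessages(clone_table(dat, ...))
}
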