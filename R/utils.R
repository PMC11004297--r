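# Internal helpers shared across modules.

# Standard genetic code, codon -> single-letter amino acid ('*' = stop).
# Frozen against the Bioconductor reference table in the test suite.
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Translate nucleotide sequences to amino acids
#'
#' Vectorised standard-genetic-code translation. Sequences whose length is not
#' a multiple of three translate to `NA` (an out-of-frame junction cannot be
#' read through); unknown codons (ambiguity codes) translate to `X`.
#'
#' @param nt Character vector of nucleotide sequences (A/C/G/T, upper case).
#' @return Character vector of amino-acid sequences; stop codons appear as
#'   `*`.
#' @examples
#' translate_nt(c("TGTGCTTGG", "TGTGA"))
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt))
  out <- rep(NA_character_, length(nt))
  len <- nchar(nt)
  ok <- !is.na(nt) & len > 0L & len %% 3L == 0L
  if (!any(ok)) return(out)
  x <- nt[ok]
  ncod <- nchar(x) %/% 3L
  starts <- unlist(lapply(ncod, function(k) seq.int(1L, by = 3L, length.out = k)),
                   use.names = FALSE)
  codons <- substring(rep.int(x, ncod), starts, starts + 2L)
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  grp <- rep.int(seq_along(x), ncod)
  out[ok] <- vapply(split(aa, grp), paste, character(1), collapse = "")
  out
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. All simulator determinism flows through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive k child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# One random A/C/G/T string per requested length (vectorised via one pooled
# draw; lengths of zero give "").
random_nt <- function(lengths) {
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  pool <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                collapse = "")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  out <- substring(pool, starts, ends)
  out[lengths == 0L] <- ""
  out
}

# Locus from an IMGT-style gene name prefix ("IGHV11-2*01" -> "IGH").
locus_from_call <- function(call) {
  out <- rep(NA_character_, length(call))
  hit <- !is.na(call) & grepl("^IG[HKL]", call)
  out[hit] <- substr(call[hit], 1L, 3L)
  out
}

is_blank <- function(x) is.na(x) | x == "" | x == "." | x == "*"

# Restrict a rearrangement table to a chain class.
filter_chain <- function(data, chain = c("heavy", "light", "all")) {
  chain <- match.arg(chain)
  switch(chain,
    heavy = dplyr::filter(data, .data$locus == "IGH"),
    light = dplyr::filter(data, .data$locus %in% c("IGK", "IGL")),
    all   = data
  )
}

# Complete-CDR3 junction test: starts at the conserved Cys, ends at the
# conserved Trp (heavy) or Phe (light), no stop, no assembler partial marks.
is_complete_junction <- function(junction_aa) {
  !is.na(junction_aa) &
    grepl("^C", junction_aa) &
    grepl("[WF]$", junction_aa) &
    !grepl("[*_?]", junction_aa)
}
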