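#' Rearrangement table columns
#'
#' Canonical column set used for rearrangement tables throughout the package,
#' in writing order. All readers return tibbles with at least these columns.
#'
#' @return Character vector of column names.
#' @export
airr_columns <- function() {
  c("sequence_id", "locus", "v_call", "d_call", "j_call", "c_call",
    "junction", "junction_aa", "productive", "consensus_count", "sample_id")
}

# Attach sample metadata columns, validating the controlled vocabularies.
apply_meta <- function(data, sample_id, genotype, subset) {
  if (!is.null(sample_id)) data$sample_id <- as.character(sample_id)
  if (!is.null(genotype)) {
    if (!genotype %in% c("WT", "KO")) {
      abort(sprintf("`genotype` must be \"WT\" or \"KO\", not \"%s\".", genotype),
            class = "bcrclone_meta_error")
    }
    data$genotype <- genotype
  }
  if (!is.null(subset)) {
    if (!subset %in% c("B-1a", "B-1b")) {
      abort(sprintf("`subset` must be \"B-1a\" or \"B-1b\", not \"%s\".", subset),
            class = "bcrclone_meta_error")
    }
    data$subset <- subset
  }
  data
}

finish_rearrangements <- function(data, source) {
  n0 <- nrow(data)
  data <- dplyr::filter(data, !is_blank(.data$junction_aa))
  dropped <- n0 - nrow(data)
  if (dropped > 0L) {
    inform(sprintf("Dropped %d of %d rows without a CDR3 amino-acid sequence (%s).",
                   dropped, n0, source))
  }
  if (nrow(data) == 0L) {
    abort(sprintf("No usable rearrangement rows in %s.", source),
          class = "bcrclone_empty_error")
  }
  data$d_call[is_blank(data$d_call) | data$locus != "IGH"] <- ""
  data$c_call[is_blank(data$c_call)] <- ""
  data$consensus_count <- as.integer(round(data$consensus_count))
  data <- dplyr::filter(data, .data$consensus_count >= 1L)
  dplyr::relocate(data, dplyr::any_of(airr_columns()))
}

#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated rearrangement table following the AIRR Standards
#' field names into a tidy rearrangement tibble. Rows without a CDR3
#' amino-acid value (`junction_aa`) are dropped with a message. Abundance is
#' taken from `consensus_count`, then `duplicate_count`, then defaults to 1.
#' Locus is taken from an explicit `locus` column when present, otherwise
#' inferred from the `v_call` prefix, then the `c_call` prefix.
#'
#' @param path Path to a tab-separated AIRR rearrangement file.
#' @param sample_id,genotype,subset Optional sample metadata attached as
#'   columns; `genotype` must be `"WT"`/`"KO"`, `subset` `"B-1a"`/`"B-1b"`.
#' @return A tibble with the columns of [airr_columns()] plus any metadata
#'   columns supplied.
#' @seealso [read_trust4()], [write_airr()]
#' @export
read_airr <- function(path, sample_id = NULL, genotype = NULL, subset = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File does not exist: %s", path), class = "bcrclone_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required <- c("v_call", "j_call", "junction_aa", "junction")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("Not an AIRR rearrangement table: %s is missing column(s) %s.",
                  path, paste(missing, collapse = ", ")),
          class = "bcrclone_format_error")
  }
  if (nrow(raw) == 0L) {
    abort(sprintf("Empty rearrangement file: %s", path),
          class = "bcrclone_empty_error")
  }

  count <- if ("consensus_count" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$consensus_count))
  } else if ("duplicate_count" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$duplicate_count))
  } else {
    1
  }
  count[is.na(count)] <- 1

  locus <- if ("locus" %in% names(raw) && !all(is_blank(raw$locus))) {
    raw$locus
  } else {
    NA_character_
  }
  locus <- dplyr::coalesce(locus,
                           locus_from_call(raw$v_call),
                           locus_from_call(raw[["c_call"]] %||% NA_character_))

  productive <- if ("productive" %in% names(raw)) {
    toupper(raw$productive) %in% c("T", "TRUE")
  } else {
    # AIRR files from some assemblers omit the flag; derive it from the
    # junction itself (in frame, translatable without a stop).
    nchar(raw$junction) %% 3L == 0L & !grepl("\\*", raw$junction_aa)
  }

  data <- tibble(
    sequence_id = raw[["sequence_id"]] %||% sprintf("row%06d", seq_len(nrow(raw))),
    locus = locus,
    v_call = raw$v_call,
    d_call = raw[["d_call"]] %||% "",
    j_call = raw$j_call,
    c_call = raw[["c_call"]] %||% "",
    junction = raw$junction,
    junction_aa = raw$junction_aa,
    productive = productive,
    consensus_count = count,
    sample_id = raw[["sample_id"]] %||% NA_character_
  )
  data <- apply_meta(data, sample_id, genotype, subset)
  finish_rearrangements(data, path)
}

#' Read a TRUST4 report table
#'
#' Reads the simple clonotype report emitted by the TRUST4 assembler
#' (columns `#count`, `frequency`, `CDR3nt`, `CDR3aa`, `V`, `D`, `J`, `C`)
#' into the same tidy rearrangement tibble as [read_airr()]. CDR3 amino-acid
#' strings carrying TRUST4 partial/out-of-frame markers (`_` or `?`) are
#' dropped with a message. Abundance is the report's read count; locus is
#' inferred from the V gene prefix, falling back to the constant gene. Allele
#' suffixes are preserved verbatim.
#'
#' @inheritParams read_airr
#' @return A tibble with the columns of [airr_columns()].
#' @export
read_trust4 <- function(path, sample_id = NULL, genotype = NULL, subset = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File does not exist: %s", path), class = "bcrclone_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  names(raw) <- sub("^#", "", names(raw))
  lookup <- c(count = "count", frequency = "frequency", CDR3nt = "cdr3nt",
              CDR3aa = "cdr3aa", V = "v", D = "d", J = "j", C = "c")
  idx <- match(tolower(lookup), tolower(names(raw)))
  names(idx) <- names(lookup)
  required <- c("count", "CDR3nt", "CDR3aa", "V", "J")
  if (anyNA(idx[required])) {
    abort(sprintf("Not a TRUST4 report: %s is missing column(s) %s.",
                  path, paste(required[is.na(idx[required])], collapse = ", ")),
          class = "bcrclone_format_error")
  }
  if (nrow(raw) == 0L) {
    abort(sprintf("Empty report file: %s", path), class = "bcrclone_empty_error")
  }
  col <- function(key) if (is.na(idx[[key]])) rep("", nrow(raw)) else raw[[idx[[key]]]]

  cdr3aa <- col("CDR3aa")
  partial <- grepl("[_?]", cdr3aa) | cdr3aa == "out_of_frame"
  if (any(partial)) {
    inform(sprintf("Dropped %d of %d TRUST4 rows with partial/out-of-frame CDR3 (%s).",
                   sum(partial), nrow(raw), path))
    raw <- raw[!partial, , drop = FALSE]
    cdr3aa <- cdr3aa[!partial]
  }

  v_call <- col("V"); j_call <- col("J")
  locus <- dplyr::coalesce(locus_from_call(v_call), locus_from_call(col("C")),
                           locus_from_call(j_call))
  junction <- col("CDR3nt")
  data <- tibble(
    sequence_id = sprintf("trust4_%06d", seq_len(nrow(raw))),
    locus = locus,
    v_call = ifelse(is_blank(v_call), "", v_call),
    d_call = col("D"),
    j_call = ifelse(is_blank(j_call), "", j_call),
    c_call = col("C"),
    junction = junction,
    junction_aa = cdr3aa,
    productive = nchar(junction) %% 3L == 0L & !grepl("\\*", cdr3aa),
    consensus_count = suppressWarnings(as.numeric(col("count"))),
    sample_id = NA_character_
  )
  data <- apply_meta(data, sample_id, genotype, subset)
  finish_rearrangements(data, path)
}

#' Write a rearrangement table as AIRR TSV
#'
#' Writes the canonical columns of [airr_columns()] as a tab-separated AIRR
#' rearrangement file (`productive` encoded `T`/`F`, empty calls as empty
#' strings). Re-reading with [read_airr()] reproduces the records
#' field-for-field.
#'
#' @param data Rearrangement tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(data, path) {
  out <- dplyr::select(data, dplyr::all_of(airr_columns()))
  out$productive <- ifelse(out$productive, "T", "F")
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a study manifest
#'
#' A manifest is a TSV with columns `sample_id`, `genotype`, `subset`, `path`
#' (paths resolved relative to the manifest unless absolute).
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with one row per sample.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "genotype", "subset", "path")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0L) {
    abort(sprintf("Manifest %s is missing column(s) %s.",
                  path, paste(missing, collapse = ", ")),
          class = "bcrclone_format_error")
  }
  if (anyNA(man[required]) ) {
    bad <- man$sample_id[!stats::complete.cases(man[required])]
    abort(sprintf("Manifest rows with missing metadata: %s",
                  paste(bad, collapse = ", ")),
          class = "bcrclone_meta_error")
  }
  if (anyDuplicated(man$sample_id)) {
    abort("Manifest sample_id values must be unique.",
          class = "bcrclone_meta_error")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Read all samples of a study
#'
#' Maps a manifest through [read_airr()] (or [read_trust4()]) and binds the
#' per-sample tables, carrying genotype and subset as columns.
#'
#' @param manifest Manifest tibble from [read_manifest()], or a path to one.
#' @param format `"airr"` or `"trust4"`.
#' @return A single rearrangement tibble covering every sample.
#' @export
read_study <- function(manifest, format = c("airr", "trust4")) {
  format <- match.arg(format)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  reader <- if (format == "airr") read_airr else read_trust4
  purrr::pmap(manifest[c("sample_id", "genotype", "subset", "path")],
              function(sample_id, genotype, subset, path) {
                reader(path, sample_id = sample_id, genotype = genotype,
                       subset = subset)
              }) |>
    dplyr::bind_rows()
}

#' Assign antibody isotype from a constant-gene call
#'
#' Maps heavy-chain constant genes to the five antibody classes by name
#' prefix, collapsing IgG subclasses: `IGHM` to IgM, `IGHD` to IgD, `IGHG*`
#' (any subclass) to IgG, `IGHA` to IgA, `IGHE` to IgE. Light-chain constants,
#' empty calls and unrecognised names give `NA`.
#'
#' @param c_call Character vector of constant-gene names, allele suffixes
#'   allowed.
#' @return Character vector of isotype labels (`"IgM"`, `"IgD"`, `"IgG"`,
#'   `"IgA"`, `"IgE"`) or `NA`.
#' @examples
#' assign_isotype(c("IGHM*01", "IGHG2B", "IGKC", ""))
#' @export
assign_isotype <- function(c_call) {
  out <- rep(NA_character_, length(c_call))
  x <- toupper(ifelse(is.na(c_call), "", c_call))
  out[startsWith(x, "IGHM")] <- "IgM"
  out[startsWith(x, "IGHD")] <- "IgD"
  out[startsWith(x, "IGHG")] <- "IgG"
  out[startsWith(x, "IGHA")] <- "IgA"
  out[startsWith(x, "IGHE")] <- "IgE"
  out
}

#' Isotype class levels
#' @return The five heavy-chain isotype labels in canonical order.
#' @export
isotype_levels <- function() c("IgM", "IgD", "IgG", "IgA", "IgE")

#' Keep productive rearrangements with complete CDR3 junctions
#'
#' Retains records that are productive and whose CDR3 amino-acid string runs
#' from the conserved cysteine to the conserved tryptophan/phenylalanine
#' anchor with no stop codon. Diversity statistics on translated CDR3s
#' require translatable, anchored junctions, so analysis entry points apply
#' this by default.
#'
#' @param data Rearrangement tibble.
#' @param require_anchors Also require the C...W/F anchors (default `TRUE`);
#'   `FALSE` keeps any productive stop-free junction.
#' @return The filtered tibble; the number of dropped records is reported via
#'   a message.
#' @export
filter_productive <- function(data, require_anchors = TRUE) {
  keep <- data$productive & !grepl("\\*", data$junction_aa)
  if (require_anchors) keep <- keep & is_complete_junction(data$junction_aa)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    inform(sprintf("Dropped %d of %d non-productive or incomplete-CDR3 records.",
                   dropped, nrow(data)))
  }
  data[keep, , drop = FALSE]
}
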