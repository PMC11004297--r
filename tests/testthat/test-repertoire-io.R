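airr_header <- paste("sequence_id", "locus", "v_call", "d_call", "j_call",
                     "c_call", "junction", "junction_aa", "productive",
                     "consensus_count", "sample_id", sep = "\t")

airr_row <- function(id, junction_aa = "CARW", count = "3",
                     v = "IGHV11-2*01", c = "IGHM", locus = "IGH") {
  paste(id, locus, v, "IGHD1-1*01", "IGHJ1*01", c,
        strrep("TGT", nchar(junction_aa)), junction_aa, "T", count, "S1",
        sep = "\t")
}

test_that("read_airr parses well-formed tables and drops CDR3-less rows", {
  path <- write_airr_text(c(airr_header, airr_row("r1"), airr_row("r2", "CASW"),
                            airr_row("r3", "CATW", count = "5")))
  rep <- read_airr(path)
  expect_identical(nrow(rep), 3L)
  expect_identical(rep$consensus_count, c(3L, 3L, 5L))
  expect_true(all(airr_columns() %in% names(rep)))

  blank <- write_airr_text(c(airr_header, airr_row("r1"),
                             airr_row("r2", junction_aa = ""),
                             airr_row("r3", "CATW")))
  expect_message(rep2 <- read_airr(blank), "Dropped 1 of 3")
  expect_identical(nrow(rep2), 2L)
})

test_that("abundance defaults to 1 and respects the column preference order", {
  no_count <- write_airr_text(c(
    paste("v_call", "j_call", "junction", "junction_aa", sep = "\t"),
    paste("IGHV1-4*01", "IGHJ1*01", "TGTTGG", "CW", sep = "\t")
  ))
  expect_identical(read_airr(no_count)$consensus_count, 1L)

  both <- write_airr_text(c(
    paste("v_call", "j_call", "junction", "junction_aa",
          "consensus_count", "duplicate_count", sep = "\t"),
    paste("IGHV1-4*01", "IGHJ1*01", "TGTTGG", "CW", "7", "99", sep = "\t")
  ))
  expect_identical(read_airr(both)$consensus_count, 7L)
})

test_that("locus precedence is explicit column, then V call, then C call", {
  # Deliberately contradictory locus column wins over the V prefix.
  path <- write_airr_text(c(airr_header,
                            airr_row("r1", locus = "IGK", v = "IGHV1-4*01")))
  expect_identical(read_airr(path)$locus, "IGK")
  no_locus <- write_airr_text(c(
    paste("v_call", "j_call", "junction", "junction_aa", "c_call", sep = "\t"),
    paste("IGKV4-59*01", "IGKJ1*01", "TGTTTC", "CF", "IGKC", sep = "\t"),
    paste("", "IGHJ1*01", "TGTTGG", "CW", "IGHM", sep = "\t")
  ))
  rep <- read_airr(no_locus)
  expect_identical(rep$locus, c("IGK", "IGH"))
  expect_identical(rep$d_call, c("", ""))
})

test_that("malformed headers and empty files raise typed errors", {
  bad <- write_airr_text(c(paste("v_call", "j_call", sep = "\t"),
                           paste("IGHV1-4", "IGHJ1", sep = "\t")))
  expect_error(read_airr(bad), "junction", class = "bcrclone_format_error")
  empty <- write_airr_text(airr_header)
  expect_error(read_airr(empty), class = "bcrclone_empty_error")
  expect_error(read_airr(tempfile()), class = "bcrclone_io_error")
})

test_that("AIRR round-trip reproduces records field-for-field and conserves abundance", {
  sim <- simulate_repertoire(sim_config(seed = 2, n_clones = 40,
                                        expanded_count = 2,
                                        expanded_mass = 0.2,
                                        reads_per_sample = 400,
                                        loci = c("IGK", "IGL")))
  out <- tempfile(fileext = ".tsv")
  write_airr(sim$data, out)
  back <- read_airr(out, sample_id = NULL)
  orig <- dplyr::select(sim$data, dplyr::all_of(airr_columns()))
  expect_equal(as.data.frame(back[airr_columns()]), as.data.frame(orig))
  expect_identical(sum(back$consensus_count), sum(orig$consensus_count))
})

test_that("read_trust4 maps the report layout and filters partial CDR3s", {
  header <- paste("#count", "frequency", "CDR3nt", "CDR3aa", "V", "D", "J",
                  "C", "cid", "cid_full_length", sep = "\t")
  rows <- c(
    paste("10", "0.5", "TGTGCTTGG", "CAW", "IGHV11-2*01", "IGHD1-1*01",
          "IGHJ1*01", "IGHM", "a1", "1", sep = "\t"),
    paste("6", "0.3", "TGTGCTTTC", "CAF", "IGKV4-1*01", "*", "IGKJ1*01",
          "*", "a2", "1", sep = "\t"),
    paste("4", "0.2", "TGTNNTTGG", "C_W", "IGHV1-4*01", "*", "IGHJ2*01",
          "IGHM", "a3", "0", sep = "\t")
  )
  path <- write_airr_text(c(header, rows))
  expect_message(rep <- read_trust4(path, sample_id = "m1"), "Dropped 1 of 3")
  expect_identical(nrow(rep), 2L)
  expect_identical(rep$locus, c("IGH", "IGK"))
  expect_identical(rep$d_call, c("IGHD1-1*01", ""))   # light chain: no D
  expect_identical(rep$v_call[1], "IGHV11-2*01")      # allele kept verbatim
  expect_identical(rep$consensus_count, c(10L, 6L))
  expect_identical(rep$sample_id, c("m1", "m1"))

  bad <- write_airr_text(c(paste("count", "CDR3nt", sep = "\t"),
                           paste("3", "TGTTGG", sep = "\t")))
  expect_error(read_trust4(bad), class = "bcrclone_format_error")
})

test_that("assign_isotype maps constant genes totally and deterministically", {
  expect_identical(assign_isotype(c("IGHM*01", "IGHG2B*02", "IGHD", "IGHA1",
                                    "IGHE", "IGKC", "IGLC1", "", NA)),
                   c("IgM", "IgG", "IgD", "IgA", "IgE", NA, NA, NA, NA))
  set.seed(1)
  junk <- c(replicate(50, paste(sample(LETTERS, 5), collapse = "")), "TRBC")
  out <- assign_isotype(junk)
  expect_identical(length(out), length(junk))
  expect_identical(out, assign_isotype(junk))
})

test_that("filter_productive enforces the anchored stop-free junction rule", {
  dat <- make_rearrangements(c("CARDYW", "CARD*YW", "ARDYW", "CARDYF",
                               "CARDY"))
  dat$productive[5] <- FALSE
  expect_message(kept <- filter_productive(dat), "Dropped 3 of 5")
  expect_identical(kept$junction_aa, c("CARDYW", "CARDYF"))
  # Non-anchored junction survives when anchors are not required.
  kept2 <- suppressMessages(filter_productive(dat, require_anchors = FALSE))
  expect_true("ARDYW" %in% kept2$junction_aa)
})

test_that("manifests validate metadata and read_study binds all samples", {
  dir <- tempfile(); dir.create(dir)
  man <- emulate_study(dir, seed = 4, subsets = "B-1a")
  expect_identical(nrow(man), 8L)
  study <- suppressMessages(read_study(file.path(dir, "manifest.tsv")))
  expect_identical(sort(unique(study$sample_id)), sort(man$sample_id))
  expect_true(all(c("genotype", "subset") %in% names(study)))

  broken <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                            show_col_types = FALSE)
  broken$genotype[2] <- NA
  bad_path <- file.path(dir, "broken.tsv")
  readr::write_tsv(broken, bad_path)
  expect_error(read_manifest(bad_path), class = "bcrclone_meta_error")
  broken2 <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                             show_col_types = FALSE)
  broken2$sample_id[2] <- broken2$sample_id[1]
  readr::write_tsv(broken2, bad_path)
  expect_error(read_manifest(bad_path), class = "bcrclone_meta_error")
})

test_that("genotype and subset metadata are validated on read", {
  path <- write_airr_text(c(airr_header, airr_row("r1")))
  expect_error(read_airr(path, genotype = "HET"),
               class = "bcrclone_meta_error")
  expect_error(read_airr(path, subset = "B-2"),
               class = "bcrclone_meta_error")
  rep <- read_airr(path, sample_id = "mX", genotype = "KO", subset = "B-1b")
  expect_identical(rep$genotype, "KO")
  expect_identical(rep$subset, "B-1b")
  expect_identical(rep$sample_id, "mX")
})
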