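test_that("genetic-code table matches the Bioconductor reference", {
  ref <- Biostrings::GENETIC_CODE
  tab <- bcrclone:::GENETIC_CODE_TABLE
  expect_identical(sort(names(tab)), sort(names(ref)))
  expect_identical(unname(tab[names(ref)]), unname(as.character(ref)))
})

test_that("translate_nt agrees with Biostrings and handles frame errors", {
  set.seed(5)
  nt <- vapply(1:25, function(i)
    paste(sample(c("A", "C", "G", "T"), 3 * sample(2:8, 1), replace = TRUE),
          collapse = ""), character(1))
  ref <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
  expect_identical(unname(translate_nt(nt)), unname(ref))
  expect_true(is.na(translate_nt("TGTGA")))
  expect_identical(translate_nt(character(0)), character(0))
})

test_that("germline libraries are deterministic, locus-correct and V11-skewed", {
  lib1 <- germline_library(seed = 1)
  lib2 <- germline_library(seed = 1)
  expect_identical(lib1$segments, lib2$segments)
  expect_false(identical(lib1$segments$seq,
                         germline_library(seed = 2)$segments$seq))

  segs <- lib1$segments
  # Light loci carry no D segments; every class is populated adequately.
  expect_identical(nrow(dplyr::filter(segs, .data$locus != "IGH",
                                      .data$class == "D")), 0L)
  counts <- dplyr::count(segs, .data$locus, .data$class)
  expect_true(all(counts$n[counts$class == "V"] >= 8))
  expect_true(all(counts$n[counts$class == "J"] >= 4))
  expect_identical(counts$n[counts$locus == "IGH" & counts$class == "D"], 4L)

  fam <- segs |>
    dplyr::filter(.data$locus == "IGH", .data$class == "V") |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(w = sum(.data$weight))
  expect_identical(fam$family[which.max(fam$w)], "IGHV11")

  # Anchors: V parts start with a Cys codon, J parts end with W (heavy) or
  # F (light) so anchored junctions are producible.
  expect_true(all(startsWith(segs$seq[segs$class == "V"], "TGT")))
  expect_true(all(endsWith(segs$seq[segs$class == "J" & segs$locus == "IGH"],
                           "TGG")))
  expect_true(all(endsWith(segs$seq[segs$class == "J" & segs$locus != "IGH"],
                           "TTC")))
  for (lc in c("V", "D", "J")) {
    per_class <- segs |>
      dplyr::filter(.data$class == lc) |>
      dplyr::group_by(.data$locus) |>
      dplyr::summarise(s = sum(.data$weight))
    expect_true(all(abs(per_class$s - 1) < 1e-9))
  }
})

test_that("zero junctional noise gives exact germline concatenations", {
  lib <- germline_library(seed = 3)
  segs <- lib$segments
  combos <- expand.grid(
    v = segs$seq[segs$locus == "IGH" & segs$class == "V"],
    d = segs$seq[segs$locus == "IGH" & segs$class == "D"],
    j = segs$seq[segs$locus == "IGH" & segs$class == "J"],
    stringsAsFactors = FALSE
  )
  all_concat <- paste0(combos$v, combos$d, combos$j)
  recs <- simulate_rearrangements(lib, 30, "IGH", deletion_mean = 0,
                                  insertion_mean = 0, seed = 9)
  expect_true(all(recs$junction %in% all_concat))
  # Light chains have no D: junction is V then J directly.
  light_concat <- as.vector(outer(
    segs$seq[segs$locus == "IGK" & segs$class == "V"],
    segs$seq[segs$locus == "IGK" & segs$class == "J"], paste0))
  lrecs <- simulate_rearrangements(lib, 20, "IGK", deletion_mean = 0,
                                   insertion_mean = 0, seed = 10)
  expect_true(all(lrecs$junction %in% light_concat))
  expect_true(all(lrecs$d_call == ""))
})

test_that("productive-only output is anchored, stop-free and reproducible", {
  lib <- germline_library(seed = 4)
  recs <- simulate_rearrangements(lib, 200, c("IGH", "IGK"), seed = 21)
  expect_true(all(recs$productive))
  expect_true(all(grepl("^C", recs$junction_aa)))
  expect_true(all(grepl("[WF]$", recs$junction_aa)))
  expect_false(any(grepl("\\*", recs$junction_aa)))
  expect_true(all(nchar(recs$junction) %% 3 == 0))
  expect_identical(recs,
                   simulate_rearrangements(lib, 200, c("IGH", "IGK"),
                                           seed = 21))
})

test_that("simulated family usage matches the configured weights", {
  lib <- germline_library(seed = 6)
  recs <- simulate_rearrangements(lib, 6000, "IGH", seed = 33)
  genes <- parse_segment(recs$v_call)$gene
  segs <- dplyr::filter(lib$segments, .data$locus == "IGH",
                        .data$class == "V")
  obs <- table(factor(genes, levels = segs$name))
  gof <- stats::chisq.test(as.vector(obs), p = segs$weight)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulate_repertoire conserves reads and returns coherent truth", {
  cfg <- sim_config(seed = 12, n_clones = 120, expanded_count = 5,
                    expanded_mass = 0.6, reads_per_sample = 2500)
  sim <- simulate_repertoire(cfg)
  expect_equal(sum(sim$truth$true_freq), 1, tolerance = 1e-12)
  # Flagged clones are exactly the expanded_count largest, each holding at
  # least expanded_mass / expanded_count.
  expect_identical(sum(sim$truth$expanded), 5L)
  expect_true(all(sim$truth$true_freq[sim$truth$expanded] >= 0.12 - 1e-12))
  expect_true(max(sim$truth$true_freq[!sim$truth$expanded]) <
                min(sim$truth$true_freq[sim$truth$expanded]))
  expect_identical(anyDuplicated(sim$truth$junction_aa), 0L)
  # Per-sample read conservation.
  per_sample <- tapply(sim$data$consensus_count, sim$data$sample_id, sum)
  expect_true(all(per_sample == cfg$reads_per_sample))
  expect_true(all(sim$data$productive))
  expect_identical(nrow(sim$manifest), 4L)
  expect_true(all(sim$manifest$seed < .Machine$integer.max))
})

test_that("realized pooled frequencies converge to truth as depth grows", {
  l1 <- function(reads, seed) {
    cfg <- sim_config(seed = seed, n_clones = 60, expanded_count = 3,
                      expanded_mass = 0.3, reads_per_sample = reads)
    sim <- simulate_repertoire(cfg)
    pooled <- tapply(sim$data$consensus_count, sim$data$junction_aa, sum)
    realized <- rep(0, nrow(sim$truth))
    idx <- match(names(pooled), sim$truth$junction_aa)
    realized[idx] <- pooled / sum(pooled)
    sum(abs(realized - sim$truth$true_freq))
  }
  shallow <- mean(vapply(1:6, function(s) l1(200L, s), 0))
  deep <- mean(vapply(1:6, function(s) l1(8000L, s), 0))
  expect_lt(deep, shallow)
})

test_that("diffuse repertoires yield no >1% pooled clone", {
  # Background-only pools: with 500 clones and 10,000-read samples the
  # multinomial concentrates every pooled frequency far below the threshold.
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_clones = 500, expanded_count = 0,
                      expanded_mass = 0, reads_per_sample = 10000L,
                      sample_design = tibble::tibble(
                        sample_id = "S1", genotype = "WT", subset = "B-1a",
                        replicate = 1L))
    freq <- with(simulate_repertoire(cfg),
                 tapply(data$consensus_count, data$junction_aa, sum) /
                   sum(data$consensus_count))
    expect_true(all(freq < 0.01))
  }
})

test_that("inconsistent configurations fail with typed errors", {
  expect_error(sim_config(expanded_count = 600, n_clones = 500),
               class = "bcrclone_config_error")
  expect_error(sim_config(expanded_mass = 1), class = "bcrclone_config_error")
  expect_error(sim_config(isotype_probs = c(IgM = 0.5)),
               class = "bcrclone_config_error")
  expect_error(sim_config(clone_size_law = list(law = "zipf", param = 1)),
               class = "bcrclone_config_error")
})

test_that("emulate_study writes a byte-stable, re-readable study", {
  dir1 <- tempfile(); dir2 <- tempfile()
  man1 <- emulate_study(dir1, seed = 8)
  man2 <- emulate_study(dir2, seed = 8)
  expect_identical(nrow(man1), 15L)   # 4+4 B-1a, 4+3 B-1b
  expect_identical(sum(man1$subset == "B-1a"), 8L)
  expect_identical(sum(man1$genotype == "KO" & man1$subset == "B-1b"), 3L)
  files <- c(man1$path, "manifest.tsv", "ground_truth.tsv", "config.yaml")
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
  study <- suppressMessages(read_study(file.path(dir1, "manifest.tsv")))
  expect_identical(length(unique(study$sample_id)), 15L)
})

test_that("default study fixtures separate KO below WT in unique counts", {
  for (s in c(31, 32)) {
    sim <- simulate_study(seed = s)
    for (ss in c("B-1a", "B-1b")) {
      uc <- unique_counts(dplyr::filter(sim$data, .data$subset == ss),
                          chain = "heavy")
      expect_lt(max(uc$n_unique[uc$genotype == "KO"]),
                min(uc$n_unique[uc$genotype == "WT"]))
    }
  }
})

test_that("null-effect studies draw both genotypes from one distribution", {
  sim <- simulate_study(seed = 17, effect = "null", subsets = "B-1b")
  p <- sim$params
  for (ch in unique(p$chain)) {
    wt <- p[p$chain == ch & p$genotype == "WT", ]
    ko <- p[p$chain == ch & p$genotype == "KO", ]
    expect_identical(wt$n_clones, ko$n_clones)
    expect_identical(wt$expanded_mass, ko$expanded_mass)
  }
  # No cross-genotype clone sharing is planted under the null.
  truth <- sim$truth
  wt_cl <- truth$junction_aa[truth$genotype == "WT" & truth$chain == "heavy"]
  ko_cl <- truth$junction_aa[truth$genotype == "KO" & truth$chain == "heavy"]
  expect_lt(length(intersect(wt_cl, ko_cl)), 3L)
})
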