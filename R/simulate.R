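# Seeded V(D)J repertoire simulator with ground truth: toy germline
# libraries, junctional diversity (geometric trims, Poisson N-insertions),
# a two-component clone-size model, multinomial per-sample sampling, and a
# study design of WT/KO B-1a and B-1b samples.

random_codons <- function(n_codons) {
  if (n_codons == 0L) return("")
  pool <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

#' Build a toy germline segment library
#'
#' Generates named V/D/J segment sequences per immunoglobulin locus with
#' usage weights, deterministically from a seed. Sequences are synthetic
#' (generated, not copied from IMGT reference directories): each V segment's
#' junction-contributing part begins with a cysteine codon and each J part
#' ends with the tryptophan (heavy) or phenylalanine (light) anchor codon, so
#' anchored, translatable junctions are producible. V names carry IMGT-style
#' family prefixes, with usage skewed towards the IGHV1, IGHV11 and IGHV12
#' families (IGHV11 heaviest) as seen in murine B-1 repertoires; light-chain
#' loci carry no D segments.
#'
#' @param loci Loci to include, among `"IGH"`, `"IGK"`, `"IGL"`.
#' @param seed Integer seed; the same seed always yields the same library.
#' @return A `germline_library`: a list with `segments` (tibble: `locus`,
#'   `class`, `name`, `family`, `seq`, `weight`; weights sum to 1 within each
#'   locus/class) and `seed`.
#' @export
germline_library <- function(loci = c("IGH", "IGK", "IGL"), seed = 1L) {
  loci <- match.arg(loci, several.ok = TRUE)
  defs <- list(
    IGH = list(
      V = c("IGHV1-4" = 0.10, "IGHV1-26" = 0.10, "IGHV2-2" = 0.07,
            "IGHV3-6" = 0.07, "IGHV5-17" = 0.07, "IGHV11-1" = 0.15,
            "IGHV11-2" = 0.15, "IGHV12-3" = 0.11, "IGHV12-5" = 0.11,
            "IGHV14-2" = 0.07),
      D = c("IGHD1-1" = 0.25, "IGHD2-3" = 0.25, "IGHD3-1" = 0.25,
            "IGHD4-1" = 0.25),
      J = c("IGHJ1" = 0.35, "IGHJ2" = 0.25, "IGHJ3" = 0.20, "IGHJ4" = 0.20)
    ),
    IGK = list(
      V = c("IGKV1-110" = 0.10, "IGKV2-137" = 0.10, "IGKV4-59" = 0.15,
            "IGKV4-91" = 0.15, "IGKV5-43" = 0.10, "IGKV6-15" = 0.15,
            "IGKV8-30" = 0.15, "IGKV9-120" = 0.10),
      J = c("IGKJ1" = 0.25, "IGKJ2" = 0.25, "IGKJ4" = 0.25, "IGKJ5" = 0.25)
    ),
    IGL = list(
      V = c("IGLV1-21" = 0.20, "IGLV1-40" = 0.15, "IGLV2-11" = 0.15,
            "IGLV2-23" = 0.10, "IGLV3-1" = 0.10, "IGLV3-19" = 0.10,
            "IGLV5-45" = 0.10, "IGLV7-43" = 0.10),
      J = c("IGLJ1" = 0.25, "IGLJ2" = 0.25, "IGLJ3" = 0.25, "IGLJ4" = 0.25)
    )
  )
  segments <- with_seed(seed, {
    purrr::map(loci, function(locus) {
      purrr::imap(defs[[locus]], function(weights, class) {
        anchor <- if (locus == "IGH") "TGG" else "TTC"
        seqs <- vapply(names(weights), function(nm) {
          switch(class,
            V = paste0("TGT", random_codons(3L)),
            D = random_codons(4L),
            J = paste0(random_codons(2L), anchor)
          )
        }, character(1))
        tibble(locus = locus, class = class, name = names(weights),
               family = parse_segment(names(weights))$family,
               seq = unname(seqs), weight = unname(weights))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  structure(list(segments = segments, seed = seed),
            class = "germline_library")
}

# Sample V/(D/)J segment row indices by usage weight, one triple per locus
# entry.
pick_segments <- function(lib, locus) {
  segs <- lib$segments
  pick <- function(class, loc_vec) {
    out_idx <- integer(length(loc_vec))
    for (loc in unique(loc_vec)) {
      rows <- which(segs$locus == loc & segs$class == class)
      sel <- loc_vec == loc
      if (length(rows) == 0L) { out_idx[sel] <- NA_integer_; next }
      out_idx[sel] <- sample(rows, sum(sel), replace = TRUE,
                             prob = segs$weight[rows])
    }
    out_idx
  }
  heavy <- locus == "IGH"
  list(vi = pick("V", locus),
       di = ifelse(heavy, pick("D", locus), NA_integer_),
       ji = pick("J", locus))
}

# Draw one batch of junctions for fixed segment picks (no productivity
# filtering); only trims and N-insertions are random here, so resampling a
# slot leaves its segment identity untouched.
draw_junctions <- function(lib, locus, deletion_mean, insertion_mean, picks) {
  n <- length(locus)
  segs <- lib$segments
  vi <- picks$vi
  di <- picks$di
  ji <- picks$ji
  heavy <- locus == "IGH"

  geom_del <- function(n) {
    if (deletion_mean <= 0) rep(0L, n)
    else rgeom(n, prob = 1 / (1 + deletion_mean))
  }
  pois_ins <- function(n) {
    if (insertion_mean <= 0) rep(0L, n) else rpois(n, insertion_mean)
  }

  v_seq <- segs$seq[vi]; j_seq <- segs$seq[ji]
  v_len <- nchar(v_seq); j_len <- nchar(j_seq)
  del_v <- pmin(geom_del(n), v_len - 3L)          # keep the Cys codon
  del_j <- pmin(geom_del(n), j_len - 3L)          # keep the W/F codon
  v_part <- substr(v_seq, 1L, v_len - del_v)
  j_part <- substr(j_seq, 1L + del_j, j_len)
  n1 <- pois_ins(n)

  d_part <- character(n)
  n2 <- integer(n)
  if (any(heavy)) {
    d_seq <- ifelse(heavy, segs$seq[di], "")
    d_len <- nchar(d_seq)
    del_d5 <- pmin(geom_del(n), d_len)
    del_d3 <- pmin(geom_del(n), pmax(d_len - del_d5, 0L))
    d_part <- substr(d_seq, 1L + del_d5, d_len - del_d3)
    n2[heavy] <- pois_ins(sum(heavy))
  }
  n1_str <- random_nt(n1)
  n2_str <- ifelse(heavy, random_nt(n2), "")

  junction <- paste0(v_part, n1_str, d_part, n2_str, j_part)
  junction_aa <- translate_nt(junction)
  tibble(
    locus = locus,
    v_call = paste0(segs$name[vi], "*01"),
    d_call = ifelse(heavy, paste0(segs$name[di], "*01"), ""),
    j_call = paste0(segs$name[ji], "*01"),
    junction = junction,
    junction_aa = junction_aa,
    productive = is_complete_junction(junction_aa)
  )
}

#' Simulate V(D)J rearrangements
#'
#' Draws rearranged junctions from a germline library: V, (D,) J segments are
#' sampled by their usage weights, segment edges are trimmed by
#' geometric-distributed deletions (mean `deletion_mean` per edge, anchors
#' protected), and Poisson-length N-insertions of uniform random bases join
#' the pieces (V-N1-D-N2-J for heavy chains, V-N-J for light). With
#' `productive_only = TRUE` (the default) non-productive junctions — out of
#' frame, containing a stop, or losing an anchor — are resampled, so every
#' emitted record is productive and anchored. Resampling redraws only the
#' trims and insertions, holding the drawn segments fixed, so segment usage
#' is not biased by the productivity filter and matches the configured
#' weights up to multinomial error.
#'
#' @param lib A [germline_library()].
#' @param n Number of rearrangements.
#' @param locus Locus per record (recycled), among the library's loci.
#' @param deletion_mean Expected nucleotides trimmed per junction edge.
#' @param insertion_mean Expected N-nucleotides per insertion site.
#' @param productive_only Resample until productive and anchored.
#' @param seed Optional seed for a self-contained deterministic draw.
#' @param max_tries Resampling rounds before signalling a simulation error
#'   (an inconsistent library/configuration).
#' @return A tibble of `n` rearrangement stubs (`locus`, `v_call`, `d_call`,
#'   `j_call`, `junction`, `junction_aa`, `productive`).
#' @examples
#' lib <- germline_library(seed = 1)
#' simulate_rearrangements(lib, 3, "IGH", deletion_mean = 0,
#'                         insertion_mean = 0, seed = 7)
#' @export
simulate_rearrangements <- function(lib, n, locus = "IGH",
                                    deletion_mean = 1.5, insertion_mean = 4,
                                    productive_only = TRUE, seed = NULL,
                                    max_tries = 500L) {
  stopifnot(inherits(lib, "germline_library"), n >= 1L)
  locus <- rep_len(locus, n)
  if (!all(locus %in% unique(lib$segments$locus))) {
    abort("Requested locus not present in the germline library.",
          class = "bcrclone_argument_error")
  }
  run <- function() {
    picks <- pick_segments(lib, locus)
    out <- draw_junctions(lib, locus, deletion_mean, insertion_mean, picks)
    if (!productive_only) return(out)
    tries <- 0L
    while (any(!out$productive)) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort("Failed to produce productive junctions within the retry budget; the simulation configuration is inconsistent.",
              class = "bcrclone_simulation_error")
      }
      redo <- which(!out$productive)
      out[redo, ] <- draw_junctions(lib, locus[redo], deletion_mean,
                                    insertion_mean,
                                    lapply(picks, `[`, redo))
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulation configuration
#'
#' Parameters of one simulated clone pool and its sample design. The clone
#' frequency vector is two-component: `expanded_count` expanded clones share
#' `expanded_mass` of the total frequency in equal parts, and the remaining
#' clones share the rest according to `clone_size_law` (`"dirichlet"`:
#' gamma-distributed shares with shape `param`; `"powerlaw"`: shares
#' proportional to rank^-`param`; `"uniform"`: exactly equal shares). The
#' background weights are constrained below the expanded share, so the
#' flagged clones are exactly the `expanded_count` largest.
#'
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param n_clones Number of distinct clones in the pool.
#' @param expanded_count Number of expanded clones (< `n_clones`).
#' @param expanded_mass Total true frequency held by the expanded block, in
#'   `[0, 1)`.
#' @param clone_size_law List with `law` (`"dirichlet"`, `"powerlaw"`,
#'   `"uniform"`) and `param`.
#' @param reads_per_sample Reads drawn per sample (multinomial over the true
#'   clone frequencies).
#' @param deletion_mean,insertion_mean Junction noise, see
#'   [simulate_rearrangements()].
#' @param isotype_probs Isotype distribution of heavy-chain clones (IgM-
#'   dominant by default, as in B-1 cells).
#' @param kappa_lambda_probs Locus probabilities for light-chain clones.
#' @param loci Loci the pool draws clones from (`"IGH"` for a heavy pool;
#'   `c("IGK", "IGL")` for a light pool).
#' @param productive_only Emit only productive, anchored junctions.
#' @param sample_design Tibble with `sample_id`, `genotype`, `subset`,
#'   `replicate`, one row per sample.
#' @param clone_prefix Prefix for generated clone identifiers.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_clones = 500L, expanded_count = 5L,
                       expanded_mass = 0.3,
                       clone_size_law = list(law = "dirichlet", param = 10),
                       reads_per_sample = 5000L,
                       deletion_mean = 1.5, insertion_mean = 4,
                       isotype_probs = c(IgM = 0.85, IgD = 0.08, IgG = 0.04,
                                         IgA = 0.02, IgE = 0.01),
                       kappa_lambda_probs = c(IGK = 0.95, IGL = 0.05),
                       loci = "IGH", productive_only = TRUE,
                       sample_design = NULL, clone_prefix = "clone") {
  if (is.null(sample_design)) {
    sample_design <- tibble(sample_id = sprintf("S%d", 1:4), genotype = "WT",
                            subset = "B-1a", replicate = 1:4)
  }
  cfg <- list(seed = as.integer(seed), n_clones = as.integer(n_clones),
              expanded_count = as.integer(expanded_count),
              expanded_mass = expanded_mass, clone_size_law = clone_size_law,
              reads_per_sample = as.integer(reads_per_sample),
              deletion_mean = deletion_mean, insertion_mean = insertion_mean,
              isotype_probs = isotype_probs,
              kappa_lambda_probs = kappa_lambda_probs, loci = loci,
              productive_only = productive_only,
              sample_design = sample_design, clone_prefix = clone_prefix)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$expanded_count < 0L ||
      (cfg$expanded_count > 0L && cfg$expanded_count >= cfg$n_clones)) {
    abort("`expanded_count` must be non-negative and below `n_clones`.",
          class = "bcrclone_config_error")
  }
  if (cfg$expanded_mass < 0 || cfg$expanded_mass >= 1) {
    abort("`expanded_mass` must lie in [0, 1).",
          class = "bcrclone_config_error")
  }
  for (p in list(cfg$isotype_probs, cfg$kappa_lambda_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort("Probability vectors must be non-negative and sum to 1.",
            class = "bcrclone_config_error")
    }
  }
  if (!cfg$clone_size_law$law %in% c("dirichlet", "powerlaw", "uniform")) {
    abort("`clone_size_law$law` must be dirichlet, powerlaw or uniform.",
          class = "bcrclone_config_error")
  }
  stopifnot(all(c("sample_id", "genotype", "subset") %in%
                  names(cfg$sample_design)))
  invisible(cfg)
}

# True clone frequency vector under the two-component model. Background
# weights are redrawn (dirichlet) until they all fall below the expanded
# share, keeping the expanded flag identical to "the expanded_count largest".
clone_frequencies <- function(cfg) {
  n <- cfg$n_clones; k <- cfg$expanded_count
  mass <- if (k > 0L) cfg$expanded_mass else 0
  bg_n <- n - k
  law <- cfg$clone_size_law
  draw_bg <- function() {
    w <- switch(law$law,
      uniform = rep(1, bg_n),
      dirichlet = rgamma(bg_n, shape = law$param, rate = 1),
      powerlaw = seq_len(bg_n)^(-law$param)
    )
    w / sum(w) * (1 - mass)
  }
  bg <- draw_bg()
  if (k > 0L) {
    cap <- mass / k
    tries <- 0L
    while (max(bg) >= cap) {
      tries <- tries + 1L
      if (tries > 100L || law$law != "dirichlet") {
        abort("Background clone weights cannot be kept below the expanded share; reduce `n_clones` imbalance or increase `expanded_mass`.",
              class = "bcrclone_config_error")
      }
      bg <- draw_bg()
    }
    c(rep(cap, k), bg)
  } else {
    bg
  }
}

isotype_constant_gene <- function(isotype) {
  igg <- c("IGHG1", "IGHG2B", "IGHG2C", "IGHG3")
  vapply(isotype, function(i) {
    switch(i,
      IgM = "IGHM", IgD = "IGHD", IgA = "IGHA", IgE = "IGHE",
      IgG = sample(igg, 1L))
  }, character(1), USE.NAMES = FALSE)
}

# Generate n distinct clones (unique junction_aa), avoiding the junctions in
# `exclude`.
generate_clones <- function(lib, n, cfg, exclude = character()) {
  out <- NULL
  tries <- 0L
  while (is.null(out) || nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 30L) {
      abort("Could not generate enough distinct clones; junction diversity is too low for `n_clones`.",
            class = "bcrclone_simulation_error")
    }
    need <- n - if (is.null(out)) 0L else nrow(out)
    locus <- if (identical(cfg$loci, "IGH")) {
      rep("IGH", ceiling(need * 1.2))
    } else {
      sample(names(cfg$kappa_lambda_probs), ceiling(need * 1.2),
             replace = TRUE, prob = cfg$kappa_lambda_probs)
    }
    batch <- simulate_rearrangements(lib, length(locus), locus,
                                     cfg$deletion_mean, cfg$insertion_mean,
                                     cfg$productive_only)
    batch <- batch[!duplicated(batch$junction_aa) &
                     !batch$junction_aa %in% exclude, , drop = FALSE]
    out <- dplyr::bind_rows(out, batch)
    out <- out[!duplicated(out$junction_aa), , drop = FALSE]
  }
  out <- head(out, n)
  heavy <- out$locus == "IGH"
  out$isotype <- NA_character_
  if (any(heavy)) {
    iso <- sample(names(cfg$isotype_probs), sum(heavy), replace = TRUE,
                  prob = cfg$isotype_probs)
    out$isotype[heavy] <- iso
  }
  out$c_call <- ifelse(heavy, "",
                       ifelse(out$locus == "IGK", "IGKC", "IGLC1"))
  if (any(heavy)) out$c_call[heavy] <- isotype_constant_gene(out$isotype[heavy])
  out
}

#' Simulate a repertoire with ground truth
#'
#' Generates a clone pool under a [sim_config()], assigns true clone
#' frequencies (expanded block plus background), and draws each sample's
#' reads multinomially from the truth, aggregating abundances per clone per
#' sample. Pre-built clones can be injected: `expanded_clones` become the
#' leading (expanded) block and `extra_clones` join the background — used to
#' plant shared clones across simulated groups.
#'
#' @param cfg A [sim_config()].
#' @param lib Optional [germline_library()]; derived from the config seed
#'   when omitted.
#' @param expanded_clones,extra_clones Optional clone tibbles (as produced in
#'   the `truth` of a previous run) to plant into the pool.
#' @return A list of class `sim_repertoire`: `data` (rearrangement tibble
#'   across all samples, AIRR columns plus `genotype`/`subset`), `truth`
#'   (tibble: clone identity columns, `true_freq`, `expanded`), `manifest`
#'   (sample design plus per-sample derived seeds), `config`.
#' @export
simulate_repertoire <- function(cfg, lib = NULL, expanded_clones = NULL,
                                extra_clones = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- cfg$sample_design
  n_samples <- nrow(design)
  seeds <- derive_seeds(cfg$seed, 3L + n_samples)
  if (is.null(lib)) lib <- germline_library(seed = seeds[1L])

  preset <- dplyr::bind_rows(
    head(expanded_clones, cfg$expanded_count),
    extra_clones
  )
  if (!is.null(preset) && nrow(preset) > 0L) {
    preset <- preset[!duplicated(preset$junction_aa), , drop = FALSE]
  }
  n_preset_exp <- if (is.null(expanded_clones)) 0L
                  else min(nrow(expanded_clones), cfg$expanded_count)
  n_generate <- cfg$n_clones - NROW(preset)
  if (n_generate < 0L) {
    abort("More injected clones than `n_clones`.",
          class = "bcrclone_config_error")
  }
  generated <- if (n_generate > 0L) {
    exclude <- if (NROW(preset) > 0L) preset$junction_aa else character()
    with_seed(seeds[2L],
              generate_clones(lib, n_generate, cfg, exclude = exclude))
  }

  # Pool order: injected expanded, generated fill of the expanded block,
  # injected background, generated background.
  gen_to_exp <- max(0L, cfg$expanded_count - n_preset_exp)
  pool <- dplyr::bind_rows(
    head(preset, n_preset_exp),
    head(generated, gen_to_exp),
    if (!is.null(preset)) preset[seq_len(nrow(preset)) > n_preset_exp, ],
    if (!is.null(generated) && nrow(generated) > gen_to_exp)
      generated[(gen_to_exp + 1L):nrow(generated), ]
  )
  pool <- pool[!duplicated(pool$junction_aa), , drop = FALSE]
  pool$clone_id <- sprintf("%s%05d", cfg$clone_prefix, seq_len(nrow(pool)))

  freq <- with_seed(seeds[3L], {
    cfg2 <- cfg; cfg2$n_clones <- nrow(pool)
    clone_frequencies(cfg2)
  })
  truth <- pool
  truth$true_freq <- freq
  truth$expanded <- seq_len(nrow(pool)) <= cfg$expanded_count

  sample_seeds <- seeds[3L + seq_len(n_samples)]
  data <- purrr::map(seq_len(n_samples), function(i) {
    counts <- with_seed(sample_seeds[i],
                        as.integer(rmultinom(1L, cfg$reads_per_sample, freq)))
    hit <- counts > 0L
    rec <- pool[hit, , drop = FALSE]
    tibble(
      sequence_id = paste(design$sample_id[i], rec$clone_id, sep = ":"),
      locus = rec$locus, v_call = rec$v_call, d_call = rec$d_call,
      j_call = rec$j_call, c_call = rec$c_call, junction = rec$junction,
      junction_aa = rec$junction_aa, productive = rec$productive,
      consensus_count = counts[hit], sample_id = design$sample_id[i],
      genotype = design$genotype[i], subset = design$subset[i]
    )
  }) |> dplyr::bind_rows()

  manifest <- design
  manifest$seed <- sample_seeds
  structure(list(data = data, truth = truth, manifest = manifest,
                 config = cfg),
            class = "sim_repertoire")
}

# Group-level generative parameters of the emulated study, per subset x
# genotype x chain pool. The coverage masses mirror the replicated-coverage
# pattern the analysis is designed to detect (KO: fewer clones, more mass in
# the expanded block); pool sizes are scaled to desk-size repertoires.
study_params <- function(effect = c("default", "null")) {
  effect <- match.arg(effect)
  p <- dplyr::bind_rows(
    tibble(subset = c("B-1a", "B-1a", "B-1b", "B-1b"),
           genotype = c("WT", "KO", "WT", "KO"), chain = "heavy",
           n_clones = c(800L, 300L, 1000L, 600L),
           expanded_count = c(4L, 13L, 4L, 12L),
           expanded_mass = c(0.15, 0.72, 0.10, 0.25),
           reads_per_sample = 3000L),
    tibble(subset = c("B-1a", "B-1a", "B-1b", "B-1b"),
           genotype = c("WT", "KO", "WT", "KO"), chain = "light",
           n_clones = c(500L, 200L, 700L, 400L),
           expanded_count = c(4L, 10L, 4L, 10L),
           expanded_mass = c(0.15, 0.65, 0.10, 0.22),
           reads_per_sample = 2000L)
  )
  if (effect == "null") {
    wt <- dplyr::filter(p, .data$genotype == "WT")
    ko <- dplyr::mutate(wt, genotype = "KO")
    p <- dplyr::bind_rows(wt, ko)
  }
  dplyr::arrange(p, .data$chain, .data$subset, .data$genotype != "WT")
}

study_design <- function(subsets) {
  reps <- list(`B-1a` = c(WT = 4L, KO = 4L), `B-1b` = c(WT = 4L, KO = 3L))
  purrr::map(subsets, function(ss) {
    purrr::map(c("WT", "KO"), function(g) {
      n <- reps[[ss]][[g]]
      tibble(sample_id = sprintf("%s_%s_%d", gsub("-", "", ss), g, seq_len(n)),
             genotype = g, subset = ss, replicate = seq_len(n))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Simulate the full study design in memory
#'
#' Simulates the whole sorted-cell study — 4 WT + 4 KO B-1a samples and
#' 4 WT + 3 KO B-1b samples, each with a heavy-chain and a light-chain clone
#' pool — from one master seed. Under the default effect configuration KO
#' groups have fewer unique clones and a larger expanded mass than WT
#' (replicated coverage around 72% KO vs 15% WT in B-1a, 25% KO in B-1b),
#' the two KO groups share their expanded clones, and the WT B-1a expanded
#' clones are planted into the KO B-1a background so top-clone tracking finds
#' them at low frequency. With `effect = "null"` both genotypes are drawn
#' from identical generative parameters and nothing is shared or planted.
#'
#' @param seed Master seed; everything (library, clones, frequencies,
#'   per-sample reads) derives from it.
#' @param effect `"default"` (the study's genotype effect) or `"null"`.
#' @param subsets Cell subsets to simulate (default both); restricting to one
#'   subset skips cross-subset clone sharing.
#' @param params Optional override of the group parameter table (as returned
#'   by the internal default; columns `subset`, `genotype`, `chain`,
#'   `n_clones`, `expanded_count`, `expanded_mass`, `reads_per_sample`).
#' @return A list of class `sim_study`: `data` (rearrangements of all
#'   samples and both chains), `truth` (clone-level ground truth with
#'   `subset`, `genotype`, `chain` columns), `manifest`, `params`, `seed`.
#' @seealso [emulate_study()] to write the same simulation to disk.
#' @export
simulate_study <- function(seed = 1L, effect = c("default", "null"),
                           subsets = c("B-1a", "B-1b"), params = NULL) {
  effect <- match.arg(effect)
  subsets <- match.arg(subsets, several.ok = TRUE)
  params <- params %||% study_params(effect)
  params <- dplyr::filter(params, .data$subset %in% subsets)
  design <- study_design(subsets)

  seeds <- derive_seeds(seed, nrow(params) + 1L)
  lib <- germline_library(seed = seeds[1L])

  kl_probs <- list(`B-1a` = c(IGK = 0.95, IGL = 0.05),
                   `B-1b` = c(IGK = 0.88, IGL = 0.12))
  iso_probs <- function(subset, genotype) {
    if (effect == "default" && subset == "B-1a" && genotype == "KO") {
      c(IgM = 0.93, IgD = 0.04, IgG = 0.02, IgA = 0.007, IgE = 0.003)
    } else {
      c(IgM = 0.85, IgD = 0.08, IgG = 0.04, IgA = 0.02, IgE = 0.01)
    }
  }

  groups <- list()
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    key <- paste(row$subset, row$genotype, row$chain, sep = ".")
    gdesign <- dplyr::filter(design, .data$subset == row$subset,
                             .data$genotype == row$genotype)
    cfg <- sim_config(
      seed = seeds[1L + i],
      n_clones = row$n_clones, expanded_count = row$expanded_count,
      expanded_mass = row$expanded_mass,
      reads_per_sample = row$reads_per_sample,
      isotype_probs = iso_probs(row$subset, row$genotype),
      kappa_lambda_probs = kl_probs[[row$subset]],
      loci = if (row$chain == "heavy") "IGH" else c("IGK", "IGL"),
      sample_design = gdesign,
      clone_prefix = paste0(gsub("[^A-Za-z0-9]", "", key), ".")
    )
    expanded_clones <- NULL
    extra_clones <- NULL
    if (effect == "default") {
      # KO B-1b reuses the KO B-1a expanded clones (shared expansion across
      # the KO subsets); KO B-1a receives the WT B-1a expanded clones as
      # ordinary background members.
      if (row$genotype == "KO" && row$subset == "B-1b") {
        src <- groups[[paste("B-1a", "KO", row$chain, sep = ".")]]
        if (!is.null(src)) {
          expanded_clones <- head(dplyr::filter(src$truth, .data$expanded),
                                  row$expanded_count)
        }
      }
      if (row$genotype == "KO" && row$subset == "B-1a") {
        src <- groups[[paste("B-1a", "WT", row$chain, sep = ".")]]
        if (!is.null(src)) {
          extra_clones <- dplyr::filter(src$truth, .data$expanded)
        }
      }
    }
    groups[[key]] <- simulate_repertoire(cfg, lib = lib,
                                         expanded_clones = expanded_clones,
                                         extra_clones = extra_clones)
  }

  data <- purrr::map(groups, "data") |> dplyr::bind_rows()
  truth <- purrr::imap(groups, function(g, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    dplyr::mutate(g$truth, subset = parts[1L], genotype = parts[2L],
                  chain = parts[3L])
  }) |> dplyr::bind_rows()
  manifest <- design
  structure(list(data = data, truth = truth, manifest = manifest,
                 params = params, effect = effect, seed = seed, lib = lib,
                 groups = groups),
            class = "sim_study")
}

#' Write an emulated study to disk
#'
#' Runs [simulate_study()] and writes one AIRR rearrangement TSV per sample,
#' a manifest TSV (`sample_id`, `genotype`, `subset`, `replicate`, `path`
#' relative to the manifest), the clone-level ground truth TSV and the
#' configuration as YAML. Output is byte-identical for a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @inheritParams simulate_study
#' @return The manifest tibble (with `path`), invisibly.
#' @export
emulate_study <- function(out_dir, seed = 1L, effect = c("default", "null"),
                          subsets = c("B-1a", "B-1b"), params = NULL) {
  effect <- match.arg(effect)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      abort(sprintf("Cannot create output directory %s.", out_dir),
            class = "bcrclone_io_error")
    }
  }
  sim <- simulate_study(seed = seed, effect = effect, subsets = subsets,
                        params = params)
  manifest <- sim$manifest
  manifest$path <- paste0(manifest$sample_id, ".tsv")
  for (i in seq_len(nrow(manifest))) {
    rows <- sim$data$sample_id == manifest$sample_id[i]
    write_airr(sim$data[rows, , drop = FALSE],
               file.path(out_dir, manifest$path[i]))
  }
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth, file.path(out_dir, "ground_truth.tsv"),
                   progress = FALSE)
  yaml::write_yaml(
    list(seed = as.integer(seed), effect = effect, subsets = as.list(subsets),
         groups = lapply(seq_len(nrow(sim$params)), function(i)
           as.list(sim$params[i, ]))),
    file.path(out_dir, "config.yaml")
  )
  invisible(manifest)
}
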