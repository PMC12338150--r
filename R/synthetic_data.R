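# Seeded synthetic-study generator. Emulates the screen's study design (a
# 72-strain panel incubated with CA, CDCA or DCA at 100 uM, sampled at 24 and
# 48 h, measured by negative-mode LC-MS/MS with five fixed MS2 windows, plus
# per-strain proteomes searched for HSD and bai homologs) and records every
# planted fact in a truth ledger so each analysis stage can be scored.

#' Default synthetic-study configuration
#'
#' Defaults mirror the screen's stated conditions: 72 strains, ~60%
#' transformer prevalence (43/72), 100 uM substrate doses, sampling at 24 and
#' 48 h, a five-point calibration grid from 0.01 to 1 ug/ml, MS1 mass jitter
#' of 0.3 ppm (Orbitrap at resolution 70,000), 500 decoy features per strain
#' placed at least 5 ppm from any library mass, and per-class product
#' concentration ranges taken from the reported per-activity ranges (floored
#' at 0.12 uM so every planted activity clears the 0.1 uM reporting
#' threshold).
#'
#' @param ... overrides for any default field.
#' @return Named list of configuration values.
#' @export
default_sim_config <- function(...) {
  cfg <- list(
    n_strains = 72,
    prevalence = 0.6,            # fraction of strains with >= 1 core activity
    conjugator_prevalence = 0.39, # 28/72 strains conjugated amino acids
    substrate_uM = 100,
    time_points_h = c(24, 48),
    conditions = c("CA", "CDCA", "DCA", "NONE"),
    # probability a transformer carries each activity class (relative
    # frequencies of the reported 43 transformers)
    activity_probs = c("7a-HSD" = 0.88, "3a-HSD" = 0.58, "12a-HSD" = 0.28,
                       "7a-dehydroxylation" = 0.12, "7-epimerization" = 0.05,
                       "7a+12a-HSD" = 0.03, "other" = 0.05),
    # 48 h product concentration ranges (uM), log-uniform draws
    activity_conc_range = list(
      "7a-HSD" = c(0.12, 93.9), "3a-HSD" = c(0.12, 9.35),
      "12a-HSD" = c(0.12, 28.6), "7a-dehydroxylation" = c(0.12, 20),
      "7-epimerization" = c(0.12, 2), "7a+12a-HSD" = c(0.12, 2),
      "other" = c(0.12, 2)),
    edge_prob = 0.7,             # chance each eligible graph edge is active
    conjugates_per_strain = c(1, 8),
    conjugate_intensity_range = c(2e4, 5e6),
    enantiomer_prob = 0.5,       # Ala/Val conjugates drawn as double peaks
    jitter_ppm_sd = 0.3,
    jitter_ppm_max = 1.0,
    rt_jitter_sd_min = 0.02,
    n_decoys = 500,
    decoy_min_ppm = 5,
    intensity_noise_cv = 0.02,
    cal_grid_ug_ml = c(0.01, 0.05, 0.1, 0.5, 1.0),
    cal_noise_cv = 0.01,
    slope_range = c(500, 5000),
    # proteome geometry and score bands
    n_cds = 80,
    cds_len_bp = c(600, 2400),
    cds_gap_bp = c(50, 800),
    operon_span_bp = c(12000, 40000),
    ref_pos_range = c(150, 300),
    ref_neg_range = c(20, 100),
    planted_score_range = c(180, 300),
    background_score_range = c(5, 80),
    run_length_min = 31.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  problems <- character(0)
  if (!is.numeric(cfg$n_strains) || cfg$n_strains < 1)
    problems <- c(problems, "n_strains")
  for (k in c("prevalence", "conjugator_prevalence", "edge_prob",
              "enantiomer_prob"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1)
      problems <- c(problems, k)
  for (k in c("jitter_ppm_sd", "intensity_noise_cv", "cal_noise_cv",
              "n_decoys", "rt_jitter_sd_min"))
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] < 0))
      problems <- c(problems, k)
  if (length(problems))
    stop("invalid config value(s) for: ", paste(problems, collapse = ", "))
  invisible(cfg)
}

# Fixed standard retention times (min) for the cores; isobaric cores are kept
# >= 1.2 min apart so the +/- 0.5 min standard-RT gate is unambiguous.
.CORE_STD_RT <- c(
  "b-MCA" = 11.7, UDCA = 12.9, HDCA = 14.1, CA = 15.3, `3-oxoCA` = 16.5,
  `7-oxoDCA` = 17.7, CDCA = 18.3, DCA = 19.5, `3-oxoCDCA` = 19.9,
  `12-oxoCDCA` = 20.7, `3-oxoDCA` = 21.1, `7,12-dioxoLCA` = 21.9,
  `7-oxoLCA` = 22.3, LCA = 23.1, `12-oxoLCA` = 24.3
)

# Library entries a synthetic conjugate may be drawn from: [M-H]- unique in
# the full library within `min_sep_ppm` (the library contains exact
# cross-isobars, e.g. alanine+CA vs serine+CDCA) and covered by an MS2
# precursor window so triad confirmation is possible.
.plantable_conjugates <- function(library, min_sep_ppm = 5) {
  conj <- library[library$kind == "conjugate", , drop = FALSE]
  mz <- library$mz_M_minus_H
  sep_ok <- vapply(seq_len(nrow(conj)), function(i) {
    d <- abs(ppm_error(mz, conj$mz_M_minus_H[i]))
    sum(d < min_sep_ppm) == 1  # only itself
  }, logical(1))
  win_ok <- vapply(conj$mz_M_minus_H, function(m)
    any(abs(m - MS2_WINDOW_CENTERS) <= MS2_ISOLATION_WIDTH / 2), logical(1))
  conj[sep_ok & win_ok, , drop = FALSE]
}

#' Simulate a strain panel and produce its truth ledger
#'
#' Assigns each strain a transformation-activity subset and a conjugation
#' repertoire, draws 48 h product concentrations per active graph edge
#' (log-uniform within the per-class range, with 24 h values at 50-100% of
#' the 48 h value), plants per-species calibration slopes, HSD genes and bai
#' operons consistent with the activities, and reference score sets for
#' cutoff selection. Deterministic given (config, seed).
#'
#' @param config list from [default_sim_config()].
#' @param seed integer seed; all generator randomness flows from it.
#' @return list of class `truth_ledger` with elements `seed`, `config`,
#'   `strains`, `activities`, `concentrations`, `conjugates`, `curves`,
#'   `standards`, `genes`, `operons`, `ref_scores`, `library`.
#' @export
simulate_panel <- function(config = default_sim_config(), seed = 1) {
  .validate_sim_config(config)
  withr::with_seed(seed, .simulate_panel_impl(config, seed))
}

.simulate_panel_impl <- function(cfg, seed) {
  n <- cfg$n_strains
  strain_id <- sprintf("S%02d", seq_len(n))
  transformer <- stats::runif(n) < cfg$prevalence
  conjugator <- stats::runif(n) < cfg$conjugator_prevalence
  graph <- transformation_graph()
  cores <- bile_core_registry()
  lib <- build_mz_library(cores)

  # --- activities and per-edge concentrations -----------------------------
  acts <- list(); concs <- list()
  for (i in seq_len(n)) {
    if (!transformer[i]) next
    has <- stats::runif(length(cfg$activity_probs)) < cfg$activity_probs
    if (!any(has)) has[which.max(cfg$activity_probs)] <- TRUE
    classes <- names(cfg$activity_probs)[has]
    for (cl in classes) {
      edges <- graph[graph$activity == cl, , drop = FALSE]
      on <- stats::runif(nrow(edges)) < cfg$edge_prob
      if (!any(on)) on[1] <- TRUE
      edges <- edges[on, , drop = FALSE]
      rng <- cfg$activity_conc_range[[cl]]
      for (k in seq_len(nrow(edges))) {
        c48 <- exp(stats::runif(1, log(rng[1]), log(rng[2])))
        c24 <- c48 * stats::runif(1, 0.5, 1.0)
        concs[[length(concs) + 1]] <- data.frame(
          strain_id = strain_id[i], condition = edges$substrate[k],
          time_h = cfg$time_points_h,
          species_id = edges$product[k],
          conc_uM = c(c24, c48)[order(cfg$time_points_h)],
          activity = cl, stringsAsFactors = FALSE)
      }
      acts[[length(acts) + 1]] <- data.frame(
        strain_id = strain_id[i], activity = cl, stringsAsFactors = FALSE)
    }
  }
  activities <- if (length(acts)) do.call(rbind, acts) else
    data.frame(strain_id = character(), activity = character(),
               stringsAsFactors = FALSE)
  concentrations <- if (length(concs)) do.call(rbind, concs) else
    data.frame(strain_id = character(), condition = character(),
               time_h = numeric(), species_id = character(),
               conc_uM = numeric(), activity = character(),
               stringsAsFactors = FALSE)

  # --- calibration curves and standards -----------------------------------
  gly <- paste0("Gly-", c("CA", "CDCA", "DCA"))
  std_species <- c(cores$abbrev, gly)
  std_mm <- c(cores$avg_mass,
              lib$avg_mass[match(gly, lib$species_id)])
  std_rt <- c(.CORE_STD_RT[cores$abbrev],
              stats::runif(length(gly), 4, 10))
  curves <- data.frame(
    species_id = std_species,
    slope = stats::runif(length(std_species), cfg$slope_range[1],
                         cfg$slope_range[2]),
    intercept = 0,
    stringsAsFactors = FALSE)
  standards <- data.frame(
    species_id = std_species, rt_min = unname(std_rt),
    molar_mass = std_mm, stringsAsFactors = FALSE)

  # --- conjugation repertoires --------------------------------------------
  plantable <- .plantable_conjugates(lib)
  conj <- list()
  for (i in seq_len(n)) {
    if (!conjugator[i] || !nrow(plantable)) next
    k <- sample(seq.int(cfg$conjugates_per_strain[1],
                        cfg$conjugates_per_strain[2]), 1)
    k <- min(k, nrow(plantable))
    pick <- plantable[sample.int(nrow(plantable), k), , drop = FALSE]
    rt <- stats::runif(k, 3, 28)
    # species with an authentic standard elute at the standard RT
    si <- match(pick$species_id, standards$species_id)
    rt[!is.na(si)] <- standards$rt_min[si[!is.na(si)]]
    inten <- exp(stats::runif(k, log(cfg$conjugate_intensity_range[1]),
                              log(cfg$conjugate_intensity_range[2])))
    condition <- sample(c("CA", "CDCA", "DCA"), k, replace = TRUE)
    dbl <- pick$amino_acid %in% c("Ala", "Val") &
      stats::runif(k) < cfg$enantiomer_prob
    conj[[length(conj) + 1]] <- data.frame(
      strain_id = strain_id[i], species_id = pick$species_id,
      mz_theo = pick$mz_M_minus_H, rt_min = rt, intensity = inten,
      condition = condition, double_peak = dbl,
      rt_min_2 = ifelse(dbl, pmin(rt + stats::runif(k, 0.5, 2),
                                  cfg$run_length_min - 0.5), NA_real_),
      stringsAsFactors = FALSE)
  }
  conjugates <- if (length(conj)) do.call(rbind, conj) else
    data.frame(strain_id = character(), species_id = character(),
               mz_theo = numeric(), rt_min = numeric(), intensity = numeric(),
               condition = character(), double_peak = logical(),
               rt_min_2 = numeric(), stringsAsFactors = FALSE)

  # --- genotype truth ------------------------------------------------------
  hsd_map <- c("3a-HSD" = "3a", "7a-HSD" = "7a", "12a-HSD" = "12a")
  genes <- list(); operons <- list()
  for (i in seq_len(n)) {
    st <- strain_id[i]
    st_acts <- activities$activity[activities$strain_id == st]
    hsd_classes <- unique(unname(hsd_map[intersect(names(hsd_map), st_acts)]))
    # the double oxidation implies both single HSD capabilities
    if ("7a+12a-HSD" %in% st_acts)
      hsd_classes <- union(hsd_classes, c("7a", "12a"))
    for (cl in hsd_classes) {
      k <- sample(1:2, 1)
      genes[[length(genes) + 1]] <- data.frame(
        strain_id = st, class = cl,
        cds_id = paste0(st, "_cds", sample.int(cfg$n_cds, k)),
        bit_score = round(stats::runif(k, cfg$planted_score_range[1],
                                       cfg$planted_score_range[2]), 1),
        stringsAsFactors = FALSE)
    }
    if ("7a-dehydroxylation" %in% st_acts) {
      genes_in <- BAI_CANONICAL
      span <- stats::runif(1, cfg$operon_span_bp[1], cfg$operon_span_bp[2])
      starts <- sort(sample.int(floor(span) - 1500, length(genes_in)))
      starts <- starts - min(starts) + 1000
      lens <- round(stats::runif(length(genes_in), 600, 1400))
      operons[[length(operons) + 1]] <- data.frame(
        strain_id = st, gene = genes_in,
        cds_id = paste0(st, "_bai_", genes_in),
        contig_id = paste0(st, "_contig1"),
        start = starts, end = starts + lens,
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(strain_id = character(), class = character(),
               cds_id = character(), bit_score = numeric(),
               stringsAsFactors = FALSE)
  operons <- if (length(operons)) do.call(rbind, operons) else
    data.frame(strain_id = character(), gene = character(),
               cds_id = character(), contig_id = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)

  ref_scores <- lapply(c("3a" = "3a", "7a" = "7a", "12a" = "12a"),
                       function(cl) {
    list(pos = round(stats::runif(6, cfg$ref_pos_range[1],
                                  cfg$ref_pos_range[2]), 1),
         neg = round(stats::runif(11, cfg$ref_neg_range[1],
                                  cfg$ref_neg_range[2]), 1))
  })

  ledger <- list(
    seed = seed,
    config = cfg,
    strains = data.frame(strain_id = strain_id, transformer = transformer,
                         conjugator = conjugator, stringsAsFactors = FALSE),
    activities = activities,
    concentrations = concentrations,
    conjugates = conjugates,
    curves = curves,
    standards = standards,
    genes = genes,
    operons = operons,
    ref_scores = ref_scores
  )
  class(ledger) <- "truth_ledger"
  ledger
}

# intensity for a concentration through the planted curve (noise-free)
.planted_intensity <- function(conc_uM, species_id, curves, standards) {
  mm <- standards$molar_mass[match(species_id, standards$species_id)]
  slope <- curves$slope[match(species_id, curves$species_id)]
  icpt <- curves$intercept[match(species_id, curves$species_id)]
  conc_ug <- conc_uM * mm / 1000
  slope * conc_ug + icpt
}

#' Emit MS1 feature tables and MS2 spectra for a simulated panel
#'
#' For every strain x condition x time point sample: the remaining substrate
#' and each planted product appear at their standard retention times with
#' intensities mapped through the planted calibration line (multiplicative
#' Gaussian noise at the configured CV); planted conjugates appear under
#' their assigned substrate condition with ppm-jittered m/z and an MS2
#' spectrum carrying the full fragment triad in the correct precursor window;
#' decoy features are placed at least `decoy_min_ppm` from every library
#' mass. Feature rows carry a `kind` column ("substrate", "product",
#' "conjugate", "decoy") for scoring; writers drop it.
#'
#' @param ledger a `truth_ledger` from [simulate_panel()].
#' @param dir optional directory; when given, one peak-table CSV per strain
#'   is written in the [read_peak_table()] dialect.
#' @return list with `features` and `spectra` data.frames covering all
#'   samples (sample_id = `strain.condition.time`).
#' @export
emit_peak_tables <- function(ledger, dir = NULL) {
  stopifnot(inherits(ledger, "truth_ledger"))
  cfg <- ledger$config
  withr::with_seed(ledger$seed + 104729L, {
    lib <- build_mz_library()
    lib_mz_sorted <- sort(lib$mz_M_minus_H)
    core_mz <- lib$mz_M_minus_H[match(names(.CORE_STD_RT), lib$species_id)]
    names(core_mz) <- names(.CORE_STD_RT)

    jitter <- function(mz) {
      p <- stats::rnorm(length(mz), 0, cfg$jitter_ppm_sd)
      p <- pmax(pmin(p, cfg$jitter_ppm_max), -cfg$jitter_ppm_max)
      mz * (1 + p * 1e-6)
    }
    noisy <- function(x) pmax(x * (1 + stats::rnorm(length(x), 0,
                                                    cfg$intensity_noise_cv)),
                              0)
    rtj <- function(rt) rt + stats::rnorm(length(rt), 0, cfg$rt_jitter_sd_min)

    feats <- list(); specs <- list()
    add_feat <- function(sample_id, rt, mz, inten, kind) {
      feats[[length(feats) + 1]] <<- data.frame(
        sample_id = sample_id, rt_min = rt, mz = mz, intensity = inten,
        kind = kind, stringsAsFactors = FALSE)
    }

    conds <- cfg$conditions
    times <- cfg$time_points_h
    for (i in seq_len(nrow(ledger$strains))) {
      st <- ledger$strains$strain_id[i]
      st_conc <- ledger$concentrations[
        ledger$concentrations$strain_id == st, , drop = FALSE]
      st_conj <- ledger$conjugates[
        ledger$conjugates$strain_id == st, , drop = FALSE]
      sample_ids <- as.vector(outer(conds, times, function(cn, tm)
        paste(st, cn, tm, sep = ".")))

      for (cn in conds) {
        for (tm in times) {
          sid <- paste(st, cn, tm, sep = ".")
          if (cn != "NONE") {
            prods <- st_conc[st_conc$condition == cn & st_conc$time_h == tm, ,
                             drop = FALSE]
            sub_left <- max(cfg$substrate_uM - sum(prods$conc_uM), 1)
            add_feat(sid, rtj(.CORE_STD_RT[[cn]]), jitter(core_mz[[cn]]),
                     noisy(.planted_intensity(sub_left, cn, ledger$curves,
                                              ledger$standards)),
                     "substrate")
            if (nrow(prods))
              add_feat(sid, rtj(.CORE_STD_RT[prods$species_id]),
                       jitter(core_mz[prods$species_id]),
                       noisy(.planted_intensity(prods$conc_uM,
                                                prods$species_id,
                                                ledger$curves,
                                                ledger$standards)),
                       "product")
            cj <- st_conj[st_conj$condition == cn, , drop = FALSE]
            if (nrow(cj)) {
              rt1 <- rtj(cj$rt_min)
              rt2 <- rtj(cj$rt_min_2)
              add_feat(sid, rt1, jitter(cj$mz_theo), noisy(cj$intensity),
                       "conjugate")
              dbl <- which(cj$double_peak)
              if (length(dbl))
                add_feat(sid, rt2[dbl], jitter(cj$mz_theo[dbl]),
                         noisy(cj$intensity[dbl] * 0.6), "conjugate")
              # MS2 spectrum per conjugate peak (both enantiomer peaks):
              # full triad + noise peaks
              tri <- lib[match(cj$species_id, lib$species_id), ,
                         drop = FALSE]
              for (k in seq_len(nrow(cj))) {
                center <- MS2_WINDOW_CENTERS[
                  which(abs(cj$mz_theo[k] - MS2_WINDOW_CENTERS) <=
                          MS2_ISOLATION_WIDTH / 2)[1]]
                for (rt_k in c(rt1[k], if (cj$double_peak[k]) rt2[k])) {
                  pk_mz <- c(tri$frag_aa_anion[k], tri$frag_aa_loss[k],
                             tri$frag_sterol[k],
                             stats::runif(3, 80, cj$mz_theo[k]))
                  specs[[length(specs) + 1]] <- data.frame(
                    sample_id = sid, rt_min = rt_k,
                    precursor_center = center,
                    isolation_width = MS2_ISOLATION_WIDTH,
                    mz = jitter(pk_mz),
                    intensity = stats::runif(length(pk_mz), 1e3, 1e5),
                    stringsAsFactors = FALSE)
                }
              }
            }
          }
        }
      }
      # decoys: split across this strain's samples, >= decoy_min_ppm from
      # every library mass
      nd <- cfg$n_decoys
      if (nd > 0) {
        mz <- stats::runif(nd, 290, 1000)
        repeat {
          iv <- findInterval(mz, lib_mz_sorted)
          lo <- lib_mz_sorted[pmax(iv, 1)]
          hi <- lib_mz_sorted[pmin(iv + 1, length(lib_mz_sorted))]
          bad <- pmin(abs(ppm_error(mz, lo)), abs(ppm_error(mz, hi))) <
            cfg$decoy_min_ppm
          if (!any(bad)) break
          mz[bad] <- stats::runif(sum(bad), 290, 1000)
        }
        add_feat(sample(sample_ids, nd, replace = TRUE),
                 stats::runif(nd, 0.5, cfg$run_length_min - 0.5), mz,
                 exp(stats::runif(nd, log(1e3), log(1e6))), "decoy")
      }
    }
    features <- do.call(rbind, feats)
    features <- features[order(features$sample_id, features$mz), ,
                         drop = FALSE]
    features$feature_id <- seq_len(nrow(features))
    rownames(features) <- NULL
    spectra <- if (length(specs)) do.call(rbind, specs) else
      data.frame(sample_id = character(), rt_min = numeric(),
                 precursor_center = numeric(), isolation_width = numeric(),
                 mz = numeric(), intensity = numeric(),
                 stringsAsFactors = FALSE)
    rownames(spectra) <- NULL

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (st in ledger$strains$strain_id) {
        sel <- startsWith(features$sample_id, paste0(st, "."))
        ssel <- startsWith(spectra$sample_id, paste0(st, "."))
        write_peak_table(features[sel, , drop = FALSE],
                         spectra[ssel, , drop = FALSE],
                         file.path(dir, paste0(st, "_peaks.csv")))
      }
    }
    list(features = features, spectra = spectra)
  })
}

#' Emit calibration series and the standards table
#'
#' Five-point series per quantified species (the 15 cores and the glycine
#' conjugates) at the configured concentration grid, intensities from the
#' planted slope with multiplicative noise at `cal_noise_cv`.
#'
#' @param ledger a `truth_ledger`.
#' @param dir optional directory; writes `calibration.tsv` and
#'   `standards.tsv` when given.
#' @return list with `calibration` (species_id, conc_ug_ml, intensity) and
#'   `standards` (species_id, rt_min, molar_mass).
#' @export
emit_calibration <- function(ledger, dir = NULL) {
  stopifnot(inherits(ledger, "truth_ledger"))
  cfg <- ledger$config
  withr::with_seed(ledger$seed + 224737L, {
    grid <- cfg$cal_grid_ug_ml
    rows <- lapply(seq_len(nrow(ledger$curves)), function(i) {
      mu <- ledger$curves$slope[i] * grid + ledger$curves$intercept[i]
      data.frame(species_id = ledger$curves$species_id[i],
                 conc_ug_ml = grid,
                 intensity = pmax(mu * (1 + stats::rnorm(length(grid), 0,
                                                         cfg$cal_noise_cv)),
                                  0),
                 stringsAsFactors = FALSE)
    })
    calibration <- do.call(rbind, rows)
    rownames(calibration) <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(calibration, file.path(dir, "calibration.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(ledger$standards, file.path(dir, "standards.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(calibration = calibration, standards = ledger$standards)
  })
}

#' Emit synthetic proteomes, coordinates, and hit/score tables
#'
#' Each strain gets `n_cds` CDS laid sequentially on one contig (planted bai
#' genes on their own coordinates from the ledger). Strains with a planted
#' operon get BLAST-style bai hits (E-values far below the 1e-10 threshold);
#' other strains may get sparse sub-threshold or scattered hits. HSD score
#' tables give planted genes scores in the configured high band and
#' background CDS scores in the low band, so the planted separation is
#' class-specific. Reference score sets for cutoff selection come from the
#' ledger.
#'
#' @param ledger a `truth_ledger`.
#' @param dir optional directory; writes per-strain `*_proteins.faa`,
#'   `*_genes.gff3`, `*_bai_blast.tsv` (outfmt 6) and `*_hsd_tblout.txt`
#'   (hmmsearch --tblout dialect), plus `ref_scores.json`.
#' @param sequences also generate random protein sequences (needed only for
#'   FASTA output; default `!is.null(dir)`).
#' @return list with `cds` (coordinates), `bai_hits`, `hsd_scores`
#'   (cds_id/class/bit_score/strain_id), `ref_scores`, and (if requested)
#'   `proteins` (named character vector).
#' @export
emit_proteomes <- function(ledger, dir = NULL, sequences = !is.null(dir)) {
  stopifnot(inherits(ledger, "truth_ledger"))
  cfg <- ledger$config
  withr::with_seed(ledger$seed + 350377L, {
    cds_rows <- list(); hit_rows <- list(); score_rows <- list()
    proteins <- character(0)
    for (i in seq_len(nrow(ledger$strains))) {
      st <- ledger$strains$strain_id[i]
      contig <- paste0(st, "_contig1")
      n <- cfg$n_cds
      lens <- round(stats::runif(n, cfg$cds_len_bp[1], cfg$cds_len_bp[2]))
      gaps <- round(stats::runif(n, cfg$cds_gap_bp[1], cfg$cds_gap_bp[2]))
      starts <- cumsum(gaps + c(0, lens[-n])) + 1
      cds <- data.frame(
        cds_id = paste0(st, "_cds", seq_len(n)),
        contig_id = contig, start = starts, end = starts + lens - 1,
        strand = sample(c("+", "-"), n, replace = TRUE),
        strain_id = st, stringsAsFactors = FALSE)
      op <- ledger$operons[ledger$operons$strain_id == st, , drop = FALSE]
      if (nrow(op)) {
        offset <- max(cds$end) + 5000
        cds <- rbind(cds, data.frame(
          cds_id = op$cds_id, contig_id = op$contig_id,
          start = op$start + offset, end = op$end + offset,
          strand = "+", strain_id = st, stringsAsFactors = FALSE))
        hit_rows[[length(hit_rows) + 1]] <- data.frame(
          query_id = op$gene, cds_id = op$cds_id,
          evalue = 10^stats::runif(nrow(op), -60, -30),
          bit_score = round(stats::runif(nrow(op), 200, 800), 1),
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.3) {
        # spurious scattered bai homology: few genes, weak or dispersed
        k <- sample(1:3, 1)
        pick <- sample.int(n, k)
        hit_rows[[length(hit_rows) + 1]] <- data.frame(
          query_id = sample(BAI_GENES, k),
          cds_id = cds$cds_id[pick],
          evalue = 10^stats::runif(k, -14, -4),  # some pass, some fail
          bit_score = round(stats::runif(k, 40, 120), 1),
          stringsAsFactors = FALSE)
      }
      cds_rows[[length(cds_rows) + 1]] <- cds

      # HSD scores: planted genes high, a sparse background low
      planted <- ledger$genes[ledger$genes$strain_id == st, , drop = FALSE]
      bg_n <- max(3, round(n * 0.1))
      bg <- data.frame(
        strain_id = st, class = sample(c("3a", "7a", "12a"), bg_n,
                                       replace = TRUE),
        cds_id = cds$cds_id[sample.int(n, bg_n)],
        bit_score = round(stats::runif(bg_n, cfg$background_score_range[1],
                                       cfg$background_score_range[2]), 1),
        stringsAsFactors = FALSE)
      bg <- bg[!bg$cds_id %in% planted$cds_id, , drop = FALSE]
      score_rows[[length(score_rows) + 1]] <-
        rbind(planted[, names(bg)], bg)

      if (sequences) {
        seqs <- vapply(cds$end - cds$start + 1, function(L)
          paste(sample(.AA_ALPHABET, max(floor(L / 3) - 1, 30),
                       replace = TRUE), collapse = ""), character(1))
        names(seqs) <- cds$cds_id
        proteins <- c(proteins, seqs)
      }
    }
    cds <- do.call(rbind, cds_rows)
    bai_hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
      data.frame(query_id = character(), cds_id = character(),
                 evalue = numeric(), bit_score = numeric(),
                 stringsAsFactors = FALSE)
    hsd_scores <- do.call(rbind, score_rows)
    rownames(cds) <- rownames(bai_hits) <- rownames(hsd_scores) <- NULL

    out <- list(cds = cds, bai_hits = bai_hits, hsd_scores = hsd_scores,
                ref_scores = ledger$ref_scores)
    if (sequences) out$proteins <- proteins

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (st in ledger$strains$strain_id) {
        sc <- cds[cds$strain_id == st, , drop = FALSE]
        .write_gff3(sc, file.path(dir, paste0(st, "_genes.gff3")))
        if (sequences) {
          aa <- Biostrings::AAStringSet(proteins[sc$cds_id])
          Biostrings::writeXStringSet(
            aa, file.path(dir, paste0(st, "_proteins.faa")))
        }
        sh <- bai_hits[bai_hits$cds_id %in% sc$cds_id, , drop = FALSE]
        .write_blast_tab(sh, file.path(dir, paste0(st, "_bai_blast.tsv")))
        ss <- hsd_scores[hsd_scores$strain_id == st, , drop = FALSE]
        .write_hmmer_tblout(ss, file.path(dir, paste0(st, "_hsd_tblout.txt")))
      }
      jsonlite::write_json(ledger$ref_scores,
                           file.path(dir, "ref_scores.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out
  })
}

.write_gff3 <- function(cds, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = cds$contig_id,
    ranges = IRanges::IRanges(start = cds$start, end = cds$end),
    strand = cds$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- cds$cds_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.write_blast_tab <- function(hits, path) {
  if (!nrow(hits)) { file.create(path); return(invisible(path)) }
  tab <- data.frame(hits$query_id, hits$cds_id, 90, 300, 10, 1, 1, 300, 1,
                    300, format(hits$evalue, scientific = TRUE, digits = 3),
                    hits$bit_score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.write_hmmer_tblout <- function(scores, path) {
  lines <- c("# target name        accession  query name accession    E-value  score  bias")
  if (nrow(scores)) {
    ev <- format(10^(-scores$bit_score / 10), scientific = TRUE, digits = 2)
    lines <- c(lines, sprintf("%s - %s - %s %.1f 0.1",
                              scores$cds_id, scores$class, ev,
                              scores$bit_score))
  }
  writeLines(c(lines, "#"), path)
  invisible(path)
}

#' Serialize a truth ledger to JSON
#' @param ledger a `truth_ledger`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a truth ledger from JSON
#' @param path JSON path written by [write_ledger()].
#' @return `truth_ledger` list.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop("ledger file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  schemas <- list(
    strains = c(strain_id = "character", transformer = "logical",
                conjugator = "logical"),
    activities = c(strain_id = "character", activity = "character"),
    concentrations = c(strain_id = "character", condition = "character",
                       time_h = "numeric", species_id = "character",
                       conc_uM = "numeric", activity = "character"),
    conjugates = c(strain_id = "character", species_id = "character",
                   mz_theo = "numeric", rt_min = "numeric",
                   intensity = "numeric", condition = "character",
                   double_peak = "logical", rt_min_2 = "numeric"),
    curves = c(species_id = "character", slope = "numeric",
               intercept = "numeric"),
    standards = c(species_id = "character", rt_min = "numeric",
                  molar_mass = "numeric"),
    genes = c(strain_id = "character", class = "character",
              cds_id = "character", bit_score = "numeric"),
    operons = c(strain_id = "character", gene = "character",
                cds_id = "character", contig_id = "character",
                start = "integer", end = "integer"))
  for (f in names(schemas)) {
    df <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
    if (!nrow(df)) {
      # empty tables serialize as [] and lose their schema
      df <- do.call(data.frame, c(lapply(schemas[[f]], function(tp)
        vector(tp, 0)), stringsAsFactors = FALSE))
    }
    x[[f]] <- df
  }
  class(x) <- "truth_ledger"
  x
}

#' Score conjugate recovery of a match report against the truth ledger
#'
#' A planted conjugate counts as recovered when at least one feature in one
#' of its strain's samples matches its species id. False species are matched
#' conjugate species never planted in that strain.
#'
#' @param matches match report from [match_ms1()].
#' @param ledger `truth_ledger`.
#' @return list: `n_planted`, `n_recovered`, `recovery_rate`,
#'   `n_false_species`, `n_decoy_features_matched` (requires the generator's
#'   `kind` column to be joined by the caller via feature ids; NA otherwise).
#' @export
score_conjugate_recovery <- function(matches, ledger) {
  planted_keys <- unique(paste(ledger$conjugates$strain_id,
                               ledger$conjugates$species_id))
  lib <- build_mz_library()
  conj_ids <- lib$species_id[lib$kind == "conjugate"]
  conj_matches <- matches[matches$species_id %in% conj_ids, , drop = FALSE]
  match_keys <- unique(paste(sub("\\..*$", "", conj_matches$sample_id),
                             conj_matches$species_id))
  n_rec <- sum(planted_keys %in% match_keys)
  list(
    n_planted = length(planted_keys),
    n_recovered = n_rec,
    recovery_rate = if (length(planted_keys)) n_rec / length(planted_keys)
      else NA_real_,
    n_false_species = sum(!match_keys %in% planted_keys)
  )
}
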