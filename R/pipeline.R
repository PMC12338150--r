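# Pipeline orchestration: a declarative run configuration with the screen's
# published parameter defaults, stage functions that pure-functionally map
# inputs to outputs, and a file-based runner with a reproducible manifest.

#' Default run configuration
#'
#' Defaults are the screen's stated analysis parameters: 2 ppm MS1 identity
#' tolerance, 0.05 uM detection limit, 0.1 uM reporting threshold, E-value
#' threshold 1e-10, 100,000 bp operon window. MS2 confirmation defaults to 10
#' ppm fragment tolerance and the 2-of-3 triad rule.
#'
#' @param ... overrides for any field.
#' @return Named list of run parameters.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    ms1_ppm = 2,
    ms2_ppm = 10,
    rt_window_min = 0.5,       # standard-RT gate for species with standards
    ms2_rt_window_min = 0.2,   # MS2-to-feature association window
    lod_uM = 0.05,
    report_uM = 0.1,
    evalue_max = 1e-10,
    operon_window_bp = 1e5,
    evidence_rule = "2-of-3",
    normalization = "row",
    substrate_uM = 100,
    seed = 1,
    out_dir = NULL,
    sim = list()               # overrides passed to default_sim_config()
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown run config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validate_run_config(cfg)
  cfg
}

.validate_run_config <- function(cfg) {
  bad <- character(0)
  for (k in c("ms1_ppm", "ms2_ppm", "rt_window_min", "ms2_rt_window_min",
              "evalue_max", "operon_window_bp"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) bad <- c(bad, k)
  for (k in c("lod_uM", "report_uM"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) bad <- c(bad, k)
  if (!cfg$evidence_rule %in% c("2-of-3", "3-of-3"))
    bad <- c(bad, "evidence_rule")
  if (length(bad))
    stop("invalid run config value(s) for: ", paste(bad, collapse = ", "))
  invisible(cfg)
}

.min_fragments <- function(cfg) if (cfg$evidence_rule == "3-of-3") 3L else 2L

#' Match stage: MS1 matching plus MS2 confirmation
#'
#' @param features,spectra data.frames in the [read_peak_table()] schema.
#' @param library m/z library ([build_mz_library()] by default).
#' @param standards optional standards table (`species_id`, `rt_min`) whose
#'   retention times gate the corresponding library entries.
#' @param config run configuration.
#' @return match report data.frame.
#' @export
stage_match <- function(features, spectra = NULL,
                        library = build_mz_library(), standards = NULL,
                        config = default_run_config()) {
  if (!is.null(standards))
    library$rt_min <- standards$rt_min[match(library$species_id,
                                             standards$species_id)]
  matches <- match_ms1(features, library, tol_ppm = config$ms1_ppm,
                       rt_window_min = config$rt_window_min)
  if (!is.null(spectra) && nrow(spectra))
    matches <- confirm_ms2(matches, spectra, library,
                           frag_tol_ppm = config$ms2_ppm,
                           rt_window_min = config$ms2_rt_window_min,
                           min_fragments = .min_fragments(config))
  matches
}

# parse "strain.condition.time" sample ids into design columns
.parse_sample_id <- function(sample_id) {
  parts <- strsplit(sample_id, ".", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 3
  if (!all(ok))
    stop("sample ids must follow 'strain.condition.time': ",
         paste(utils::head(sample_id[!ok], 3), collapse = ", "))
  data.frame(strain_id = vapply(parts, `[`, character(1), 1),
             condition = vapply(parts, `[`, character(1), 2),
             time_h = as.numeric(vapply(parts, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Quantify stage: curves, concentration records, activity calls, Z-scores
#'
#' Fits a standard curve per calibrated species, inverts matched intensities
#' of those species into censored concentrations, calls transformation
#' activities over the graph, and builds the row-normalized Z-score matrix of
#' conjugate intensities (species x strain).
#'
#' @param matches match report (sample ids in `strain.condition.time` form).
#' @param calibration calibration points (`species_id`, `conc_ug_ml`,
#'   `intensity`).
#' @param standards standards table (`species_id`, `rt_min`, `molar_mass`).
#' @param config run configuration.
#' @return list: `curves`, `records`, `calls`, `background`, `zscores`.
#' @export
stage_quantify <- function(matches, calibration, standards,
                           config = default_run_config()) {
  curves <- lapply(split(calibration, calibration$species_id),
                   function(p) fit_standard_curve(p, p$species_id[1]))
  molar_masses <- stats::setNames(standards$molar_mass, standards$species_id)
  q <- quantify_matches(matches, curves, molar_masses,
                        lod_uM = config$lod_uM, report_uM = config$report_uM)
  quantified <- q[!is.na(q$conc_uM), , drop = FALSE]
  records <- cbind(.parse_sample_id(quantified$sample_id),
                   quantified[, c("species_id", "conc_uM", "flag")])
  rownames(records) <- NULL
  ca <- call_activities(records, threshold_uM = config$report_uM,
                        substrate_added_uM = config$substrate_uM)
  conj <- q[is.na(q$conc_uM), , drop = FALSE]
  zs <- NULL
  if (nrow(conj)) {
    conj$strain_id <- .parse_sample_id(conj$sample_id)$strain_id
    conj$sample_id <- conj$strain_id   # aggregate over condition/time
    m <- intensity_matrix(conj)
    zs <- zscore_matrix(m, by = config$normalization)
  }
  list(curves = curves, records = records, calls = ca$calls,
       background = ca$background, zscores = zs)
}

#' Genotype stage: HSD cutoffs + classification and bai operon detection
#'
#' @param hsd_scores data.frame `strain_id`, `cds_id`, `class`, `bit_score`.
#' @param ref_scores list per class with `pos` and `neg` score vectors used
#'   by [select_cutoff()].
#' @param bai_hits optional homology hits (`query_id`, `cds_id`, `evalue`,
#'   `bit_score`).
#' @param cds optional CDS coordinate table; when absent the operon step is
#'   skipped with a warning.
#' @param config run configuration.
#' @return list: `cutoffs` (per class `cutoff_result`), `predictions`
#'   (data.frame `strain_id`, `class` of predicted activities), `hsd_detail`,
#'   `operons` (per-strain `operon_call` or NULL).
#' @export
stage_genotype <- function(hsd_scores, ref_scores, bai_hits = NULL,
                           cds = NULL, config = default_run_config()) {
  cutoffs <- lapply(names(ref_scores), function(cl)
    select_cutoff(ref_scores[[cl]]$pos, ref_scores[[cl]]$neg, class = cl))
  names(cutoffs) <- names(ref_scores)
  cut_vec <- vapply(cutoffs, function(x) x$cutoff, numeric(1))

  detail <- list(); preds <- list()
  for (st in unique(hsd_scores$strain_id)) {
    cls <- classify_hsd(hsd_scores[hsd_scores$strain_id == st, , drop = FALSE],
                        cut_vec)
    cls$strain_id <- st
    detail[[st]] <- cls
    hit <- cls$class[cls$predicted]
    if (length(hit))
      preds[[length(preds) + 1]] <- data.frame(
        strain_id = st, class = paste0(hit, "-HSD"), stringsAsFactors = FALSE)
  }

  operons <- NULL
  if (!is.null(bai_hits) && nrow(bai_hits)) {
    if (is.null(cds)) {
      warning("no CDS coordinates supplied: operon detection skipped")
    } else {
      flt <- filter_hits(bai_hits, e_max = config$evalue_max)
      strain_of_cds <- stats::setNames(cds$strain_id, cds$cds_id)
      flt$strain_id <- strain_of_cds[flt$cds_id]
      operons <- lapply(split(flt, flt$strain_id), function(h)
        detect_bai_operon(h, cds, window_bp = config$operon_window_bp))
      for (st in names(operons)) {
        if (isTRUE(operons[[st]]$canonical))
          preds[[length(preds) + 1]] <- data.frame(
            strain_id = st, class = "7a-dehydroxylation",
            stringsAsFactors = FALSE)
      }
    }
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    data.frame(strain_id = character(), class = character(),
               stringsAsFactors = FALSE)
  rownames(predictions) <- NULL
  list(cutoffs = cutoffs, predictions = predictions,
       hsd_detail = do.call(rbind, detail), operons = operons)
}

#' Concordance stage: genotype predictions vs phenotype calls
#'
#' Restricted to the genotype-predictable classes (the three HSD classes and
#' bai-operon 7a-dehydroxylation); observed activities outside that set
#' cannot be predicted from the searched genes and are excluded.
#'
#' @param predictions data.frame `strain_id`, `class` (genotype stage).
#' @param calls activity calls (quantify stage; `strain_id`, `activity`).
#' @param level `"strain"` or `"species"` matching.
#' @return `concordance_summary`.
#' @export
stage_concord <- function(predictions, calls, level = "strain") {
  predictable <- c("3a-HSD", "7a-HSD", "12a-HSD", "7a-dehydroxylation")
  observed <- data.frame(strain_id = calls$strain_id, class = calls$activity,
                         stringsAsFactors = FALSE)
  observed <- observed[observed$class %in% predictable, , drop = FALSE]
  observed <- observed[!duplicated(observed), , drop = FALSE]
  predicted <- predictions[predictions$class %in% predictable, , drop = FALSE]
  compare_activities(predicted, observed, level = level)
}

# ---------------------------------------------------------------------------
# File-based runner
# ---------------------------------------------------------------------------

.cfg_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

.write_manifest <- function(out_dir, cfg, inputs, outputs) {
  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = .cfg_hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("bilescreen")),
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the pipeline end-to-end on a simulated panel (or stage by stage)
#'
#' Subcommands: `library` (write the conjugate library), `simulate` (generate
#' a synthetic study under `out_dir`), `match`, `quantify`, `genotype`,
#' `concord` (each reads the preceding stage's artifacts from `out_dir`), and
#' `all` (everything in order). Each invocation writes a `manifest.json` with
#' the configuration hash, seed, package version and input checksums;
#' rerunning with identical inputs reproduces identical artifacts.
#'
#' @param subcommand one of library, simulate, match, quantify, genotype,
#'   concord, all.
#' @param config run configuration from [default_run_config()]; `out_dir`
#'   must be set.
#' @return Invisibly, a list of the stage results produced.
#' @export
run_pipeline <- function(subcommand = c("all", "library", "simulate", "match",
                                        "quantify", "genotype", "concord"),
                         config = default_run_config()) {
  subcommand <- match.arg(subcommand)
  .validate_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir must be set")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(path) {
    if (!file.exists(path))
      stop("missing input artifact: ", path, call. = FALSE)
    path
  }
  results <- list()
  steps <- if (subcommand == "all")
    c("library", "simulate", "match", "quantify", "genotype", "concord")
  else subcommand
  inputs <- character(0); outputs <- character(0)

  for (step in steps) {
    if (step == "library") {
      lib <- build_mz_library()
      p <- file.path(out_dir, "species_library.tsv")
      write_species_library(lib[lib$kind == "conjugate", ], p)
      utils::write.table(lib, file.path(out_dir, "mz_library.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, p, file.path(out_dir, "mz_library.tsv"))
      results$library <- lib
    } else if (step == "simulate") {
      ledger <- simulate_panel(do.call(default_sim_config, config$sim),
                               seed = config$seed)
      write_ledger(ledger, file.path(out_dir, "ledger.json"))
      emit_peak_tables(ledger, dir = file.path(out_dir, "peaks"))
      emit_calibration(ledger, dir = out_dir)
      emit_proteomes(ledger, dir = file.path(out_dir, "proteome"),
                     sequences = FALSE)
      outputs <- c(outputs, file.path(out_dir, "ledger.json"))
      results$ledger <- ledger
    } else if (step == "match") {
      need(file.path(out_dir, "mz_library.tsv"))
      lib <- utils::read.delim(file.path(out_dir, "mz_library.tsv"),
                               stringsAsFactors = FALSE)
      standards <- utils::read.delim(need(file.path(out_dir,
                                                    "standards.tsv")),
                                     stringsAsFactors = FALSE)
      peak_files <- list.files(file.path(out_dir, "peaks"),
                               full.names = TRUE, pattern = "\\.csv$")
      if (!length(peak_files))
        stop("missing input artifact: ", file.path(out_dir, "peaks"),
             call. = FALSE)
      inputs <- c(inputs, peak_files)
      matches <- do.call(rbind, lapply(peak_files, function(f) {
        pt <- read_peak_table(f)
        stage_match(pt$features, pt$spectra, lib, standards, config)
      }))
      write_match_report(matches, file.path(out_dir, "matches.tsv"))
      utils::write.table(matches, file.path(out_dir, "matches_full.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, file.path(out_dir, "matches.tsv"))
      results$matches <- matches
    } else if (step == "quantify") {
      matches <- utils::read.delim(need(file.path(out_dir,
                                                  "matches_full.tsv")),
                                   stringsAsFactors = FALSE)
      calibration <- utils::read.delim(need(file.path(out_dir,
                                                      "calibration.tsv")),
                                       stringsAsFactors = FALSE)
      standards <- utils::read.delim(need(file.path(out_dir,
                                                    "standards.tsv")),
                                     stringsAsFactors = FALSE)
      qr <- stage_quantify(matches, calibration, standards, config)
      utils::write.table(qr$records, file.path(out_dir,
                                               "concentrations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(qr$calls, file.path(out_dir, "activity_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(qr$zscores))
        utils::write.table(
          data.frame(species_id = rownames(qr$zscores), qr$zscores,
                     check.names = FALSE),
          file.path(out_dir, "zscore_matrix.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, file.path(out_dir, "activity_calls.tsv"))
      results$quantify <- qr
    } else if (step == "genotype") {
      pdir <- file.path(out_dir, "proteome")
      score_files <- list.files(pdir, pattern = "_hsd_tblout\\.txt$",
                                full.names = TRUE)
      if (!length(score_files))
        stop("missing input artifact: HSD score tables under ", pdir,
             call. = FALSE)
      inputs <- c(inputs, score_files)
      hsd_scores <- do.call(rbind, lapply(score_files, function(f) {
        tb <- read_hmmer_tblout(f)
        data.frame(strain_id = sub("_hsd_tblout\\.txt$", "", basename(f)),
                   cds_id = tb$cds_id, class = tb$query_id,
                   bit_score = tb$bit_score, stringsAsFactors = FALSE)
      }))
      ref_scores <- jsonlite::read_json(need(file.path(pdir,
                                                       "ref_scores.json")),
                                        simplifyVector = TRUE)
      gff_files <- list.files(pdir, pattern = "_genes\\.gff3$",
                              full.names = TRUE)
      blast_files <- list.files(pdir, pattern = "_bai_blast\\.tsv$",
                                full.names = TRUE)
      bai_hits <- do.call(rbind, lapply(blast_files, function(f) {
        if (file.size(f) == 0) return(NULL)
        read_blast_tab(f)
      }))
      cds <- NULL
      if (length(gff_files)) {
        cds <- do.call(rbind, lapply(gff_files, function(f) {
          x <- read_gff_cds(f)
          x$strain_id <- sub("_genes\\.gff3$", "", basename(f))
          x
        }))
      }
      gr <- stage_genotype(hsd_scores, ref_scores, bai_hits, cds, config)
      utils::write.table(gr$predictions,
                         file.path(out_dir, "genotype_predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        lapply(gr$cutoffs, function(x)
          list(class = x$class, cutoff = x$cutoff, f = x$f, scan = x$scan)),
        file.path(out_dir, "cutoffs.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      outputs <- c(outputs, file.path(out_dir, "genotype_predictions.tsv"))
      results$genotype <- gr
    } else if (step == "concord") {
      predictions <- utils::read.delim(
        need(file.path(out_dir, "genotype_predictions.tsv")),
        stringsAsFactors = FALSE)
      calls <- utils::read.delim(need(file.path(out_dir,
                                                "activity_calls.tsv")),
                                 stringsAsFactors = FALSE)
      summary <- stage_concord(predictions, calls)
      write_concordance(summary, file.path(out_dir, "concordance.tsv"),
                        file.path(out_dir, "concordance.json"))
      outputs <- c(outputs, file.path(out_dir, "concordance.tsv"))
      results$concordance <- summary
    }
  }
  .write_manifest(out_dir, config, inputs, outputs)
  invisible(results)
}
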