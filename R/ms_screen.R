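# MS1/MS2 screening: ppm matching against the species library, fragment-triad
# confirmation within the acquisition's fixed precursor windows, and
# enantiomer double-peak detection.

#' Default MS2 precursor window centers (Th)
#'
#' The acquisition scheme fragments five fixed all-ion windows, each 40 Th
#' wide, centered at these m/z values.
#' @export
MS2_WINDOW_CENTERS <- c(370, 408, 446, 484, 522)

#' Default MS2 isolation width (Th)
#' @export
MS2_ISOLATION_WIDTH <- 40

#' Signed parts-per-million mass error
#'
#' @param observed observed m/z (Th).
#' @param theoretical theoretical m/z (Th); must be positive.
#' @return (observed - theoretical) / theoretical * 1e6, vectorised.
#' @examples
#' ppm_error(448.30752, 448.30685)  # +1.49 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Match MS1 features to the species library at ppm tolerance
#'
#' Every (feature, species) pair whose absolute mass error is strictly below
#' `tol_ppm` is reported; a feature may therefore match several isobaric
#' species, and such collisions are flagged via `n_isobaric` rather than
#' resolved. Species with an authentic-standard retention time (an `rt_min`
#' column in the library or a separate standards table) can additionally be
#' gated by an RT window; species without standards are matched on mass alone.
#'
#' @param features data.frame with columns `sample_id`, `rt_min`, `mz`,
#'   `intensity` (MS1 rows of [read_peak_table()]).
#' @param library data.frame with `species_id` and `mz_M_minus_H` (e.g. from
#'   [build_mz_library()]); optional `rt_min` column of standard retention
#'   times (NA where no standard exists).
#' @param tol_ppm strict MS1 tolerance in ppm (default 2, matching the
#'   identification rule "mass error of less than 2 ppm").
#' @param rt_window_min half-width of the RT gate applied only to species with
#'   a standard RT (default 0.5 min).
#' @return data.frame of matches: `sample_id`, `feature_id`, `species_id`,
#'   `rt_min`, `mz_obs`, `mz_theo`, `intensity`, `ppm`, `evidence`
#'   (initially "MS1_only"), `fragments_found` (empty), `isobaric_group`,
#'   `n_isobaric` (features matching >1 species share a count > 1).
#'   Sorted by absolute ppm within feature.
#' @export
match_ms1 <- function(features, library, tol_ppm = 2, rt_window_min = 0.5) {
  stopifnot(tol_ppm > 0)
  if (is.null(library) || nrow(library) == 0) {
    warning("empty species library: no matches possible")
    return(.empty_match_frame())
  }
  if (nrow(features) == 0) return(.empty_match_frame())
  if (is.null(features$feature_id))
    features$feature_id <- seq_len(nrow(features))

  ord <- order(library$mz_M_minus_H)
  lib <- library[ord, , drop = FALSE]
  mzs <- lib$mz_M_minus_H
  has_rt <- "rt_min" %in% names(lib)

  res <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    mz <- features$mz[i]
    lo <- findInterval(mz * (1 - tol_ppm * 1e-6), mzs)
    hi <- findInterval(mz * (1 + tol_ppm * 1e-6), mzs)
    if (hi < 1 || lo >= nrow(lib) + 1) next
    idx <- seq.int(max(lo, 1L), min(hi + 1L, nrow(lib)))
    p <- ppm_error(mz, mzs[idx])
    keep <- abs(p) < tol_ppm
    idx <- idx[keep]; p <- p[keep]
    if (!length(idx)) next
    if (has_rt) {
      std_rt <- lib$rt_min[idx]
      ok <- is.na(std_rt) | abs(features$rt_min[i] - std_rt) <= rt_window_min
      idx <- idx[ok]; p <- p[ok]
      if (!length(idx)) next
    }
    o <- order(abs(p))
    idx <- idx[o]; p <- p[o]
    res[[i]] <- data.frame(
      sample_id = features$sample_id[i],
      feature_id = features$feature_id[i],
      species_id = lib$species_id[idx],
      rt_min = features$rt_min[i],
      mz_obs = mz,
      mz_theo = mzs[idx],
      intensity = features$intensity[i],
      ppm = p,
      evidence = "MS1_only",
      fragments_found = "",
      isobaric_group = if ("isobaric_group" %in% names(lib))
        lib$isobaric_group[idx] else NA_character_,
      n_isobaric = length(idx),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(.empty_match_frame())
  rownames(out) <- NULL
  out
}

.empty_match_frame <- function() {
  data.frame(sample_id = character(), feature_id = integer(),
             species_id = character(), rt_min = numeric(), mz_obs = numeric(),
             mz_theo = numeric(), intensity = numeric(), ppm = numeric(),
             evidence = character(), fragments_found = character(),
             isobaric_group = character(), n_isobaric = integer(),
             stringsAsFactors = FALSE)
}

#' Confirm MS1 matches with MS/MS fragment triads
#'
#' For each match, spectra are eligible when their precursor window contains
#' the matched m/z and their retention time lies within `rt_window_min` of the
#' feature. The three triad fragments (amino acid anion, amino-acid-loss
#' fragment, sterol fragment) are searched at `frag_tol_ppm`; evidence is
#' upgraded to `MS1_plus_MS2` when at least `min_fragments` are found.
#' Core-only matches (no triad) are left untouched.
#'
#' @param matches data.frame from [match_ms1()].
#' @param spectra data.frame of MS2 spectra: `sample_id`, `rt_min`,
#'   `precursor_center`, `isolation_width`, `mz`, `intensity` (one row per
#'   peak; a spectrum is the set of rows sharing sample/rt/center).
#' @param library library carrying `frag_aa_anion`, `frag_aa_loss`,
#'   `frag_sterol` per species.
#' @param frag_tol_ppm fragment tolerance (default 10 ppm; MS2 is acquired at
#'   lower resolution than MS1).
#' @param rt_window_min RT association window (default 0.2 min).
#' @param min_fragments fragments required for the upgrade (default 2 of 3).
#' @return `matches` with `evidence` and `fragments_found` updated.
#' @export
confirm_ms2 <- function(matches, spectra, library, frag_tol_ppm = 10,
                        rt_window_min = 0.2, min_fragments = 2) {
  stopifnot(frag_tol_ppm > 0, min_fragments >= 1)
  if (nrow(matches) == 0 || is.null(spectra) || nrow(spectra) == 0)
    return(matches)
  lib_idx <- match(matches$species_id, library$species_id)
  for (i in seq_len(nrow(matches))) {
    li <- lib_idx[i]
    if (is.na(li)) next
    triad <- c(aa_anion = library$frag_aa_anion[li],
               aa_loss = library$frag_aa_loss[li],
               sterol = library$frag_sterol[li])
    if (anyNA(triad)) next  # core entry: no triad defined
    half <- spectra$isolation_width / 2
    elig <- spectra$sample_id == matches$sample_id[i] &
      abs(spectra$precursor_center - matches$mz_obs[i]) <= half &
      abs(spectra$rt_min - matches$rt_min[i]) <= rt_window_min
    if (!any(elig)) next
    peaks <- spectra$mz[elig]
    found <- vapply(triad, function(fmz)
      any(abs(ppm_error(peaks, fmz)) < frag_tol_ppm), logical(1))
    matches$fragments_found[i] <- paste(names(triad)[found], collapse = ",")
    if (sum(found) >= min_fragments)
      matches$evidence[i] <- "MS1_plus_MS2"
  }
  matches
}

#' Detect enantiomer double peaks
#'
#' A species matched by two chromatographically separated features within one
#' sample is consistent with a pair of enantiomeric conjugates (e.g. d- and
#' l-alanine amidates), which share exact mass but not retention time. For
#' each (sample, species) with two or more matched features, adjacent
#' RT-ordered features separated by at least `min_sep_min` are emitted as one
#' pair each.
#'
#' @param matches data.frame from [match_ms1()] (one sample or many; pairs are
#'   formed within a sample).
#' @param min_sep_min minimum RT separation in minutes (default 0.3).
#' @return data.frame: `sample_id`, `species_id`, `rt_1`, `rt_2`,
#'   `feature_id_1`, `feature_id_2`, `delta_rt`.
#' @export
detect_double_peaks <- function(matches, min_sep_min = 0.3) {
  out <- list()
  if (nrow(matches) == 0) return(.empty_pair_frame())
  for (key in split(seq_len(nrow(matches)),
                    paste(matches$sample_id, matches$species_id, sep = "\r"))) {
    if (length(key) < 2) next
    m <- matches[key, , drop = FALSE]
    m <- m[order(m$rt_min), , drop = FALSE]
    for (j in seq_len(nrow(m) - 1)) {
      drt <- m$rt_min[j + 1] - m$rt_min[j]
      if (drt >= min_sep_min) {
        out[[length(out) + 1]] <- data.frame(
          sample_id = m$sample_id[1], species_id = m$species_id[1],
          rt_1 = m$rt_min[j], rt_2 = m$rt_min[j + 1],
          feature_id_1 = m$feature_id[j], feature_id_2 = m$feature_id[j + 1],
          delta_rt = drt, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.empty_pair_frame())
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.empty_pair_frame <- function() {
  data.frame(sample_id = character(), species_id = character(),
             rt_1 = numeric(), rt_2 = numeric(), feature_id_1 = integer(),
             feature_id_2 = integer(), delta_rt = numeric(),
             stringsAsFactors = FALSE)
}

#' Read a peak table (MS1 features and MS2 peaks)
#'
#' Comma-separated with header; required columns `sample_id`, `ms_level`
#' (1 or 2), `rt_min`, `mz`, `intensity`, `precursor_center`,
#' `isolation_width` (the last two empty/NA on MS1 rows). Malformed rows
#' (non-positive m/z, negative intensity, missing RT) are dropped with a
#' warning naming their line numbers.
#'
#' @param path CSV file path.
#' @param run_length_min chromatographic run length used to validate RT
#'   (default 31.5 min).
#' @return list with `features` (MS1 rows, plus `feature_id`) and `spectra`
#'   (MS2 rows).
#' @export
read_peak_table <- function(path, run_length_min = 31.5) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "ms_level", "rt_min", "mz", "intensity",
                "precursor_center", "isolation_width")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("peak table is empty: ", path)
    return(list(features = cbind(tab[tab$ms_level == 1, ],
                                 feature_id = integer(0)),
                spectra = tab[tab$ms_level == 2, ]))
  }
  bad <- !is.finite(tab$mz) | tab$mz <= 0 |
    !is.finite(tab$intensity) | tab$intensity < 0 |
    !is.finite(tab$rt_min) | tab$rt_min < 0 | tab$rt_min > run_length_min |
    !tab$ms_level %in% c(1, 2)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped (lines ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "", ") in ", path)
    tab <- tab[!bad, , drop = FALSE]
  }
  features <- tab[tab$ms_level == 1,
                  c("sample_id", "rt_min", "mz", "intensity"), drop = FALSE]
  if (nrow(features)) features$feature_id <- seq_len(nrow(features))
  else features$feature_id <- integer(0)
  spectra <- tab[tab$ms_level == 2,
                 c("sample_id", "rt_min", "precursor_center",
                   "isolation_width", "mz", "intensity"), drop = FALSE]
  rownames(features) <- rownames(spectra) <- NULL
  list(features = features, spectra = spectra)
}

#' Write a peak table in the dialect read by [read_peak_table()]
#' @param features MS1 feature data.frame (`sample_id`, `rt_min`, `mz`,
#'   `intensity`).
#' @param spectra MS2 peak data.frame (`sample_id`, `rt_min`,
#'   `precursor_center`, `isolation_width`, `mz`, `intensity`); may be NULL.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(features, spectra = NULL, path) {
  f <- data.frame(sample_id = features$sample_id, ms_level = 1,
                  rt_min = features$rt_min, mz = features$mz,
                  intensity = features$intensity,
                  precursor_center = NA_real_, isolation_width = NA_real_)
  if (!is.null(spectra) && nrow(spectra)) {
    s <- data.frame(sample_id = spectra$sample_id, ms_level = 2,
                    rt_min = spectra$rt_min, mz = spectra$mz,
                    intensity = spectra$intensity,
                    precursor_center = spectra$precursor_center,
                    isolation_width = spectra$isolation_width)
    f <- rbind(f, s)
  }
  utils::write.csv(f, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write the match report TSV
#' @param matches data.frame from [match_ms1()]/[confirm_ms2()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(matches, path) {
  cols <- c("sample_id", "species_id", "rt_min", "mz_obs", "mz_theo", "ppm",
            "intensity", "evidence", "fragments_found", "isobaric_group")
  utils::write.table(matches[, intersect(cols, names(matches))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
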