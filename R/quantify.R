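# Standard-curve quantitation, unit conversion, activity calling over the
# transformation graph, and Z-score matrices for conjugate intensities.

#' Default detection limit (uM)
#' @export
LOD_UM <- 0.05

#' Default reporting threshold for core transformations (uM)
#' @export
REPORT_THRESHOLD_UM <- 0.1

#' Fit a five-point standard curve by ordinary least squares
#'
#' Calibration series run from 0.01 to 1 ug/ml; the fitted line is
#' intensity = slope * concentration + intercept.
#'
#' @param points data.frame with `conc_ug_ml` (> 0, distinct values) and
#'   `intensity` (>= 0); at least 3 points.
#' @param species_id optional label carried on the result.
#' @return list of class `standard_curve`: `species_id`, `slope`, `intercept`,
#'   `r_squared`, `range` (min/max ug/ml), `n`, `usable` (slope > 0).
#' @examples
#' pts <- data.frame(conc_ug_ml = c(0.01, 0.05, 0.1, 0.5, 1),
#'                   intensity = c(10, 50, 100, 500, 1000))
#' fit_standard_curve(pts)$slope  # 1000
#' @export
fit_standard_curve <- function(points, species_id = NA_character_) {
  if (nrow(points) < 3)
    stop("standard curve needs at least 3 calibration points")
  if (any(points$conc_ug_ml <= 0))
    stop("calibration concentrations must be positive")
  if (length(unique(points$conc_ug_ml)) < 3)
    stop("calibration concentrations must be distinct")
  fit <- stats::lm(intensity ~ conc_ug_ml, data = points)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$intensity - mean(points$intensity))^2)
  out <- list(
    species_id = species_id,
    slope = unname(stats::coef(fit)[["conc_ug_ml"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    range = range(points$conc_ug_ml),
    n = nrow(points)
  )
  out$usable <- is.finite(out$slope) && out$slope > 0
  class(out) <- "standard_curve"
  out
}

#' Convert ug/ml to uM
#'
#' @param conc_ug_ml concentration in micrograms per millilitre.
#' @param molar_mass_g_mol average molar mass in g/mol (> 0).
#' @return Concentration in micromolar: `conc * 1000 / molar_mass`.
#' @examples
#' ug_per_ml_to_uM(1, 515.7)   # 1.94 uM
#' ug_per_ml_to_uM(1, 376.57)  # 2.66 uM
#' @export
ug_per_ml_to_uM <- function(conc_ug_ml, molar_mass_g_mol) {
  if (any(molar_mass_g_mol <= 0)) stop("molar mass must be positive")
  conc_ug_ml * 1000 / molar_mass_g_mol
}

#' Invert a standard curve to a censored concentration
#'
#' Computes `(intensity - intercept) / slope` in ug/ml, converts to uM, and
#' applies the censoring rules: negative inversions clamp to 0;
#' concentrations below the detection limit are reported as 0 and flagged
#' `below-LOD`; concentrations between the detection limit and the reporting
#' threshold are flagged `below-report`; the rest are `quantified`.
#'
#' @param intensity observed MS1 intensity (vectorised).
#' @param curve a `standard_curve` (must be usable, slope > 0).
#' @param molar_mass_g_mol average molar mass of the species (g/mol).
#' @param lod_uM detection limit (default 0.05 uM).
#' @param report_uM reporting threshold (default 0.1 uM).
#' @return data.frame with `conc_uM` and `flag`.
#' @export
invert_curve <- function(intensity, curve, molar_mass_g_mol,
                         lod_uM = LOD_UM, report_uM = REPORT_THRESHOLD_UM) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve")
  if (!isTRUE(curve$usable)) stop("standard curve is not usable (slope <= 0)")
  conc_ug <- (intensity - curve$intercept) / curve$slope
  conc_uM <- ug_per_ml_to_uM(pmax(conc_ug, 0), molar_mass_g_mol)
  flag <- ifelse(conc_uM < lod_uM, "below-LOD",
                 ifelse(conc_uM < report_uM, "below-report", "quantified"))
  conc_uM[flag == "below-LOD"] <- 0
  data.frame(conc_uM = conc_uM, flag = flag, stringsAsFactors = FALSE)
}

#' Percent of added substrate converted to products
#'
#' @param product_sum_uM summed product concentration (uM).
#' @param substrate_added_uM substrate supplied (uM, > 0).
#' @return Percentage, `100 * product / substrate`.
#' @export
percent_transformed <- function(product_sum_uM, substrate_added_uM) {
  if (any(substrate_added_uM <= 0)) stop("substrate added must be positive")
  100 * product_sum_uM / substrate_added_uM
}

#' Call transformation activities from concentration records
#'
#' For each strain and each edge of the transformation graph whose substrate
#' matches the incubation condition, an activity is called when the product
#' reaches the reporting threshold at either time point; the call carries the
#' maximum concentration and the time point at which it occurred. Under the
#' MIX condition every graph substrate is considered present, but products
#' that are themselves added substrates (e.g. DCA) are not scored. Products
#' detected under the no-substrate control are flagged as background and
#' never called. Product concentrations exceeding the added substrate by more
#' than 5% are retained but flagged for mass-balance review.
#'
#' @param records data.frame with `strain_id`, `condition`
#'   (CA/CDCA/DCA/MIX/NONE), `time_h`, `species_id`, `conc_uM`, `flag`.
#' @param graph data.frame from [transformation_graph()].
#' @param threshold_uM reporting threshold (default 0.1 uM).
#' @param substrate_added_uM substrate dose per condition (default 100 uM).
#' @return list with `calls` (data.frame: `strain_id`, `activity`,
#'   `substrate`, `product`, `max_conc_uM`, `time_of_max_h`, `condition`,
#'   `mass_balance_flag`) and `background` (products seen under NONE).
#' @export
call_activities <- function(records, graph = transformation_graph(),
                            threshold_uM = REPORT_THRESHOLD_UM,
                            substrate_added_uM = 100) {
  background <- records[records$condition == "NONE" &
                          records$conc_uM >= threshold_uM, , drop = FALSE]
  active <- records[records$condition != "NONE", , drop = FALSE]
  calls <- list()
  for (strain in unique(active$strain_id)) {
    sr <- active[active$strain_id == strain, , drop = FALSE]
    for (k in seq_len(nrow(graph))) {
      sub <- graph$substrate[k]; prod <- graph$product[k]
      cond_ok <- sr$condition == sub | sr$condition == "MIX"
      rows <- sr[cond_ok & sr$species_id == prod, , drop = FALSE]
      # a product that is itself an added substrate cannot be scored under MIX
      rows <- rows[!(rows$condition == "MIX" &
                       rows$species_id %in% c("CA", "CDCA", "DCA")), ,
                   drop = FALSE]
      if (!nrow(rows)) next
      mx <- which.max(rows$conc_uM)
      if (rows$conc_uM[mx] < threshold_uM) next
      calls[[length(calls) + 1]] <- data.frame(
        strain_id = strain,
        activity = graph$activity[k],
        substrate = sub, product = prod,
        max_conc_uM = rows$conc_uM[mx],
        time_of_max_h = rows$time_h[mx],
        condition = rows$condition[mx],
        mass_balance_flag = rows$conc_uM[mx] > substrate_added_uM * 1.05,
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(strain_id = character(), activity = character(),
               substrate = character(), product = character(),
               max_conc_uM = numeric(), time_of_max_h = numeric(),
               condition = character(), mass_balance_flag = logical(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, background = background)
}

#' Row-wise Z-score normalization of an intensity matrix
#'
#' Each row (species) is centered by its mean and scaled by its sample
#' standard deviation (n - 1) across columns (strains). Zero-variance rows
#' are set to all zeros and reported in the `zero_variance` attribute.
#'
#' @param m numeric matrix, species x strains.
#' @param by normalize by `"row"` (species; default) or `"column"` (strain).
#' @return Matrix of the same shape with attribute `zero_variance` (logical
#'   per normalized margin).
#' @examples
#' zscore_matrix(matrix(c(10, 20, 30), nrow = 1))
#' @export
zscore_matrix <- function(m, by = c("row", "column")) {
  by <- match.arg(by)
  if (by == "column") {
    out <- t(zscore_matrix(t(m), by = "row"))
    attr(out, "zero_variance") <- attr(zscore_matrix(t(m), by = "row"),
                                       "zero_variance")
    return(out)
  }
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  zero <- !is.finite(sd_) | sd_ == 0
  z <- (m - mu) / ifelse(zero, 1, sd_)
  z[zero, ] <- 0
  attr(z, "zero_variance") <- zero
  z
}

#' Quantify matched species through their standard curves
#'
#' Joins a match report to a standards table and converts intensities to
#' concentrations. Species without a standard curve (conjugates other than
#' the glycine conjugates, for which authentic standards exist) keep their
#' raw intensity and get `conc_uM = NA`.
#'
#' @param matches match report (needs `species_id`, `intensity`).
#' @param curves named list of `standard_curve` objects keyed by species id.
#' @param molar_masses named numeric vector of average molar masses (g/mol)
#'   keyed by species id.
#' @param lod_uM,report_uM censoring thresholds.
#' @return `matches` with `conc_uM` and `flag` columns appended.
#' @export
quantify_matches <- function(matches, curves, molar_masses,
                             lod_uM = LOD_UM, report_uM = REPORT_THRESHOLD_UM) {
  matches$conc_uM <- NA_real_
  matches$flag <- "unquantified"
  for (sp in intersect(unique(matches$species_id), names(curves))) {
    cv <- curves[[sp]]
    if (!isTRUE(cv$usable)) next
    mm <- molar_masses[[sp]]
    if (is.null(mm) || !is.finite(mm)) next
    rows <- which(matches$species_id == sp)
    inv <- invert_curve(matches$intensity[rows], cv, mm, lod_uM, report_uM)
    matches$conc_uM[rows] <- inv$conc_uM
    matches$flag[rows] <- inv$flag
  }
  matches
}

#' Build a species-by-strain intensity matrix from a match report
#'
#' @param matches match report with `species_id`, `sample_id`, `intensity`.
#' @param value column to aggregate (default `"intensity"`); multiple
#'   features of one species in one sample are summed.
#' @return numeric matrix, species x samples.
#' @export
intensity_matrix <- function(matches, value = "intensity") {
  if (!nrow(matches)) return(matrix(numeric(0), 0, 0))
  tab <- tapply(matches[[value]],
                list(matches$species_id, matches$sample_id),
                sum, default = 0)
  m <- as.matrix(tab)
  m[is.na(m)] <- 0
  m
}
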