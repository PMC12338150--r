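# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: masses are summed from a separately transcribed
# constant table, matching/cutoff/operon oracles are brute force.

# independently transcribed monoisotopic masses (IUPAC/AME values)
ORACLE_ELEMENTS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                     O = 15.9949146221, S = 31.97207069)
ORACLE_PROTON <- 1.00727646688
ORACLE_WATER <- 2 * 1.0078250319 + 15.9949146221

# sum a molecular formula string like "C24H40O5" element by element
oracle_formula_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[A-Za-z]", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    stopifnot(el %in% names(ORACLE_ELEMENTS))
    total <- total + n * ORACLE_ELEMENTS[[el]]
  }
  total
}

# brute-force MS1 matcher: all (feature, species) pairs, no index structure
oracle_match_pairs <- function(features, library, tol_ppm) {
  out <- list()
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(library))) {
      ppm <- (features$mz[i] - library$mz_M_minus_H[j]) /
        library$mz_M_minus_H[j] * 1e6
      if (abs(ppm) < tol_ppm)
        out[[length(out) + 1]] <- data.frame(
          feature = i, species_id = library$species_id[j], ppm = ppm)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# exhaustive F-measure threshold scan
oracle_cutoff <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  best_f <- -1; best_t <- NA
  for (t in cand) {
    tp <- sum(pos >= t); fp <- sum(neg >= t); fn <- sum(pos < t)
    f <- if (tp == 0) 0 else {
      recall <- tp / (tp + fn); precision <- tp / (tp + fp)
      2 / (1 / recall + 1 / precision)
    }
    if (f > best_f + 1e-12) { best_f <- f; best_t <- t }
  }
  list(cutoff = best_t, f = best_f)
}

# brute-force densest-window operon search over all hit subsets
oracle_operon <- function(hits, cds, window_bp) {
  idx <- match(hits$cds_id, cds$cds_id)
  hits <- hits[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!nrow(hits)) return(list(n_genes = 0L, span = NA_real_))
  h <- cbind(hits, contig_id = cds$contig_id[idx], start = cds$start[idx],
             end = cds$end[idx])
  n <- nrow(h)
  best_n <- 0L; best_span <- Inf
  for (mask in seq_len(2^n - 1)) {
    sel <- h[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, , drop = FALSE]
    if (length(unique(sel$contig_id)) != 1) next
    span <- max(sel$end) - min(sel$start)
    if (span >= window_bp) next
    ng <- length(unique(sel$query_id))
    if (ng > best_n || (ng == best_n && span < best_span)) {
      best_n <- ng; best_span <- span
    }
  }
  list(n_genes = best_n, span = best_span)
}

# small ready-made panel shared by several tests (cheap: 6 strains)
tiny_panel <- function(seed = 42, ...) {
  simulate_panel(default_sim_config(n_strains = 6, n_decoys = 50,
                                    n_cds = 30, ...), seed = seed)
}
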