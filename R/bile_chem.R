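# Monoisotopic masses of the most abundant isotope (CODATA/IUPAC values) and
# standard average atomic weights. S is included because methionine conjugates
# carry one sulfur.
.MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.AVG_MASS <- c(
  C = 12.011,
  H = 1.008,
  N = 14.007,
  O = 15.999,
  S = 32.06
)

#' Physical constants used throughout the mass calculations
#'
#' Monoisotopic mass of water (Da) and of the proton (Da). Negative-mode
#' electrospray observes the deprotonated ion, so \code{[M-H]- = M - proton}.
#'
#' @name mass_constants
#' @keywords internal
NULL

MASS_WATER  <- 2 * .MONO_MASS[["H"]] + .MONO_MASS[["O"]]   # 18.0105646
MASS_PROTON <- 1.00727646688

#' Build an elemental composition
#'
#' A composition is a named integer vector over the elements C, H, N, O, S.
#' All counts must be non-negative and at least one must be positive.
#'
#' @param C,H,N,O,S non-negative integer element counts.
#' @return Named integer vector of class `element_composition`.
#' @examples
#' comp(C = 24, H = 40, O = 5)  # cholic acid
#' @export
comp <- function(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L) {
  x <- c(C = as.integer(C), H = as.integer(H), N = as.integer(N),
         O = as.integer(O), S = as.integer(S))
  if (any(is.na(x)) || any(x < 0))
    stop("element counts must be non-negative integers")
  if (sum(x) == 0L)
    stop("composition must contain at least one atom")
  class(x) <- "element_composition"
  x
}

.as_comp_vector <- function(composition) {
  if (!is.numeric(composition) || is.null(names(composition)))
    stop("composition must be a named numeric vector of element counts")
  unknown <- setdiff(names(composition), names(.MONO_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(composition < 0)) stop("element counts must be non-negative")
  composition
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition named numeric vector of element counts (C, H, N, O, S),
#'   e.g. from [comp()].
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(comp(H = 2, O = 1))  # water, 18.010565
#' @export
monoisotopic_mass <- function(composition) {
  x <- .as_comp_vector(composition)
  sum(x * .MONO_MASS[names(x)])
}

#' Average (standard atomic weight) molar mass of a composition
#'
#' Used for the microgram-per-millilitre to micromolar conversion in
#' quantitation; monoisotopic masses are reserved for m/z matching.
#'
#' @inheritParams monoisotopic_mass
#' @return Average molar mass in g/mol.
#' @export
average_mass <- function(composition) {
  x <- .as_comp_vector(composition)
  sum(x * .AVG_MASS[names(x)])
}

#' Molecular formula string for a composition
#' @inheritParams monoisotopic_mass
#' @return Character scalar in Hill-like order (C, H, then N, O, S).
#' @export
formula_string <- function(composition) {
  x <- .as_comp_vector(composition)
  x <- x[x > 0]
  paste0(names(x), ifelse(x > 1, x, ""), collapse = "")
}

# Arithmetic on compositions (element-wise, never negative).
.comp_add <- function(a, b) {
  out <- .as_comp_vector(a)
  b <- .as_comp_vector(b)
  out[names(b)] <- out[names(b)] + b
  class(out) <- "element_composition"
  out
}

.comp_sub <- function(a, b) {
  out <- .as_comp_vector(a)
  b <- .as_comp_vector(b)
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) stop("composition subtraction went negative")
  class(out) <- "element_composition"
  out
}

# ---------------------------------------------------------------------------
# Steroid cores
# ---------------------------------------------------------------------------

# Substituent states at the four ring positions that vary across the screen's
# cores. "H" means an unsubstituted carbon. Starting point is the bare
# 5beta-cholanic acid skeleton C24H40O2 (the carboxylic acid accounts for both
# oxygens); each hydroxyl adds O, each oxo adds O and removes H2.
.CORE_TABLE <- list(
  #                name                          C3      C6      C7      C12
  CA    = list("cholic acid",                 "a-OH",  "H",   "a-OH", "a-OH"),
  CDCA  = list("chenodeoxycholic acid",       "a-OH",  "H",   "a-OH", "H"),
  DCA   = list("deoxycholic acid",            "a-OH",  "H",   "H",    "a-OH"),
  LCA   = list("lithocholic acid",            "a-OH",  "H",   "H",    "H"),
  UDCA  = list("ursodeoxycholic acid",        "a-OH",  "H",   "b-OH", "H"),
  HDCA  = list("hyodeoxycholic acid",         "a-OH",  "a-OH", "H",   "H"),
  `b-MCA` = list("beta-muricholic acid",      "a-OH",  "b-OH", "b-OH", "H"),
  `3-oxoCA`   = list("3-oxocholic acid",          "oxo", "H", "a-OH", "a-OH"),
  `3-oxoCDCA` = list("3-oxochenodeoxycholic acid","oxo", "H", "a-OH", "H"),
  `3-oxoDCA`  = list("3-oxodeoxycholic acid",     "oxo", "H", "H",    "a-OH"),
  `7-oxoDCA`  = list("7-oxodeoxycholic acid",     "a-OH","H", "oxo",  "a-OH"),
  `7-oxoLCA`  = list("7-oxolithocholic acid",     "a-OH","H", "oxo",  "H"),
  `12-oxoCDCA`= list("12-oxochenodeoxycholic acid","a-OH","H","a-OH", "oxo"),
  `12-oxoLCA` = list("12-oxolithocholic acid",    "a-OH","H", "H",    "oxo"),
  `7,12-dioxoLCA` = list("7,12-dioxolithocholic acid","a-OH","H","oxo","oxo")
)

.core_composition <- function(states) {
  x <- comp(C = 24, H = 40, O = 2)  # cholanic acid skeleton
  for (s in states) {
    if (s %in% c("a-OH", "b-OH")) {
      x <- .comp_add(x, c(O = 1))
    } else if (s == "oxo") {
      x <- .comp_add(x, c(O = 1))
      x <- .comp_sub(x, c(H = 2))
    } else if (s != "H") {
      stop("unknown substituent state: ", s)
    }
  }
  x
}

#' Registry of bile acid steroid cores
#'
#' The 15 steroid cores tracked by the screen: the primary bile acids CA and
#' CDCA, the secondary bile acids DCA, LCA, UDCA, HDCA and beta-MCA, and the
#' mono-/di-oxo products of 3alpha-, 7alpha- and 12alpha-HSD activity.
#' Compositions are derived from the cholanic acid skeleton by the substituent
#' state at C-3/C-6/C-7/C-12 (alpha/beta hydroxyl, oxo, or H), so positional
#' isomers such as CDCA and DCA share a formula but differ in state.
#'
#' @return A data.frame with one row per core: `abbrev`, `name`, substituent
#'   states `c3`, `c6`, `c7`, `c12`, `formula`, `mono_mass` (Da), `avg_mass`
#'   (g/mol), and a list-column `composition`.
#' @examples
#' cores <- bile_core_registry()
#' cores[cores$abbrev == "DCA", c("formula", "mono_mass")]
#' @export
bile_core_registry <- function() {
  rows <- lapply(names(.CORE_TABLE), function(ab) {
    e <- .CORE_TABLE[[ab]]
    states <- unlist(e[2:5])
    cc <- .core_composition(states)
    data.frame(
      abbrev = ab, name = e[[1]],
      c3 = states[1], c6 = states[2], c7 = states[3], c12 = states[4],
      formula = formula_string(cc),
      mono_mass = monoisotopic_mass(cc),
      avg_mass = average_mass(cc),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$composition <- lapply(names(.CORE_TABLE), function(ab)
    .core_composition(unlist(.CORE_TABLE[[ab]][2:5])))
  stopifnot(!anyDuplicated(out$abbrev))
  out
}

# ---------------------------------------------------------------------------
# Amino acids
# ---------------------------------------------------------------------------

.AA_TABLE <- list(
  # code = list(name, C, H, N, O, S, isobaric group)
  Gly = list("glycine",        2,  5, 1, 2, 0, "Gly"),
  Ala = list("alanine",        3,  7, 1, 2, 0, "Ala"),
  Ser = list("serine",         3,  7, 1, 3, 0, "Ser"),
  Val = list("valine",         5, 11, 1, 2, 0, "Val"),
  Leu = list("leucine",        6, 13, 1, 2, 0, "Leu/Ile"),
  Ile = list("isoleucine",     6, 13, 1, 2, 0, "Leu/Ile"),
  Asn = list("asparagine",     4,  8, 2, 3, 0, "Asn"),
  Asp = list("aspartate",      4,  7, 1, 4, 0, "Asp"),
  Gln = list("glutamine",      5, 10, 2, 3, 0, "Gln"),
  Lys = list("lysine",         6, 14, 2, 2, 0, "Lys"),
  Glu = list("glutamate",      5,  9, 1, 4, 0, "Glu"),
  Met = list("methionine",     5, 11, 1, 2, 1, "Met"),
  His = list("histidine",      6,  9, 3, 2, 0, "His"),
  Phe = list("phenylalanine",  9, 11, 1, 2, 0, "Phe"),
  Arg = list("arginine",       6, 14, 4, 2, 0, "Arg"),
  Tyr = list("tyrosine",       9, 11, 1, 3, 0, "Tyr"),
  Trp = list("tryptophan",    11, 12, 2, 2, 0, "Trp")
)

#' Registry of conjugatable amino acids
#'
#' The 16 amino acids observed (or searched for) as bile acid amide conjugates:
#' glycine plus the 15 others reported in the screen. Leucine and isoleucine
#' are elementally identical and are collapsed into a single isobaric library
#' entry ("Leu/Ile") by [enumerate_conjugates()]. Taurine is deliberately
#' absent from the default registry (no taurine conjugation was observed);
#' user-supplied residues can be appended as extra rows of the same shape.
#'
#' @param collapse_isobaric collapse Leu/Ile into one row (default TRUE).
#' @return data.frame with `code`, `name`, `isobaric_group`, `formula`,
#'   `free_mass` (free amino acid, Da), `residue_mass` (free - water, Da),
#'   `avg_mass`, and list-column `composition`.
#' @examples
#' aa <- amino_acid_registry()
#' aa[aa$code == "Gly", "free_mass"]  # 75.03203
#' @export
amino_acid_registry <- function(collapse_isobaric = TRUE) {
  rows <- lapply(names(.AA_TABLE), function(code) {
    e <- .AA_TABLE[[code]]
    cc <- comp(C = e[[2]], H = e[[3]], N = e[[4]], O = e[[5]], S = e[[6]])
    data.frame(
      code = code, name = e[[1]], isobaric_group = e[[7]],
      formula = formula_string(cc),
      free_mass = monoisotopic_mass(cc),
      residue_mass = monoisotopic_mass(cc) - MASS_WATER,
      avg_mass = average_mass(cc),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$composition <- lapply(names(.AA_TABLE), function(code) {
    e <- .AA_TABLE[[code]]
    comp(C = e[[2]], H = e[[3]], N = e[[4]], O = e[[5]], S = e[[6]])
  })
  if (collapse_isobaric) {
    keep <- !duplicated(out$isobaric_group)
    out <- out[keep, , drop = FALSE]
    out$code[out$isobaric_group == "Leu/Ile"] <- "Leu/Ile"
    rownames(out) <- NULL
  }
  out
}

# ---------------------------------------------------------------------------
# Conjugate enumeration and fragment prediction
# ---------------------------------------------------------------------------

#' Enumerate amide conjugates of cores with amino acids
#'
#' One conjugate species per (core, amino acid) pair. Amide condensation loses
#' one water: neutral mass = core + free amino acid - H2O. The deprotonated
#' ion observed in negative mode is neutral - proton. Each species carries its
#' predicted fragment triad (see [predict_fragments()]).
#'
#' @param cores data.frame from [bile_core_registry()] (or a subset).
#' @param amino_acids data.frame from [amino_acid_registry()] (or a subset).
#' @param sterol_rule function(core_mass) -> m/z of the major sterol fragment;
#'   default is the dehydrated deprotonated core, `core - H2O - proton`.
#' @return data.frame (the conjugate library): `species_id`, `core_abbrev`,
#'   `amino_acid`, `isobaric_group`, `formula`, `neutral_mono_mass`,
#'   `mz_M_minus_H`, `avg_mass`, `frag_aa_anion`, `frag_aa_loss`,
#'   `frag_sterol`, `ambiguous` (TRUE for Leu/Ile entries).
#' @examples
#' lib <- enumerate_conjugates(bile_core_registry(), amino_acid_registry())
#' nrow(lib)  # 225
#' @export
enumerate_conjugates <- function(cores = bile_core_registry(),
                                 amino_acids = amino_acid_registry(),
                                 sterol_rule = NULL) {
  if (nrow(cores) == 0 || nrow(amino_acids) == 0)
    stop("core and amino acid lists must be non-empty")
  if (is.null(sterol_rule))
    sterol_rule <- function(core_mass) core_mass - MASS_WATER - MASS_PROTON
  grid <- expand.grid(ci = seq_len(nrow(cores)), ai = seq_len(nrow(amino_acids)))
  core <- cores[grid$ci, , drop = FALSE]
  aa <- amino_acids[grid$ai, , drop = FALSE]
  neutral <- core$mono_mass + aa$free_mass - MASS_WATER
  cc <- mapply(function(i, j) {
    formula_string(.comp_sub(.comp_add(cores$composition[[i]],
                                       amino_acids$composition[[j]]),
                             c(H = 2, O = 1)))
  }, grid$ci, grid$ai)
  out <- data.frame(
    species_id = paste0(aa$code, "-", core$abbrev),
    core_abbrev = core$abbrev,
    amino_acid = aa$code,
    isobaric_group = aa$isobaric_group,
    formula = cc,
    neutral_mono_mass = neutral,
    mz_M_minus_H = neutral - MASS_PROTON,
    avg_mass = core$avg_mass + aa$avg_mass - (2 * .AVG_MASS[["H"]] + .AVG_MASS[["O"]]),
    frag_aa_anion = aa$free_mass - MASS_PROTON,
    frag_aa_loss = core$mono_mass - MASS_PROTON,
    frag_sterol = sterol_rule(core$mono_mass),
    ambiguous = aa$isobaric_group == "Leu/Ile",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$species_id))
  out
}

#' Predict the MS/MS fragment triad of a conjugate
#'
#' Three diagnostic fragments identify an amino acid conjugate in negative
#' mode: the amino acid anion (free amino acid - proton), the amino-acid-loss
#' fragment (deprotonated steroid core, i.e. `[M-H]-` minus the amino acid
#' residue mass), and a major sterol fragment. The sterol fragment depends on
#' the core's fragmentation chemistry; the default rule takes the dehydrated
#' deprotonated core and can be replaced per application.
#'
#' @param species one row of the library from [enumerate_conjugates()], or a
#'   list with `core_abbrev` and `amino_acid`.
#' @param cores,amino_acids registries used to resolve masses.
#' @param sterol_rule see [enumerate_conjugates()].
#' @return list with `aa_anion`, `aa_loss`, `sterol` (all Th).
#' @export
predict_fragments <- function(species,
                              cores = bile_core_registry(),
                              amino_acids = amino_acid_registry(),
                              sterol_rule = NULL) {
  if (is.null(sterol_rule))
    sterol_rule <- function(core_mass) core_mass - MASS_WATER - MASS_PROTON
  core_mass <- cores$mono_mass[match(species$core_abbrev, cores$abbrev)]
  aa_mass <- amino_acids$free_mass[match(species$amino_acid, amino_acids$code)]
  if (anyNA(core_mass)) stop("unknown core: ", species$core_abbrev)
  if (anyNA(aa_mass)) stop("unknown amino acid: ", species$amino_acid)
  list(
    aa_anion = aa_mass - MASS_PROTON,
    aa_loss = core_mass - MASS_PROTON,
    sterol = sterol_rule(core_mass)
  )
}

#' Steroid-core transformation graph
#'
#' The substrate-to-product edges observed in the screen, labelled by the
#' activity class responsible: position-specific hydroxysteroid dehydrogenase
#' oxidations (3alpha/7alpha/12alpha-HSD), the double 7,12 oxidation,
#' bai-operon 7alpha-dehydroxylation, 7-epimerization (CDCA to UDCA), and the
#' two rarer multi-step conversions (DCA to HDCA, CA to beta-MCA).
#'
#' @return data.frame with columns `substrate`, `product`, `activity`.
#' @examples
#' g <- transformation_graph()
#' g[g$activity == "7a-dehydroxylation", ]
#' @export
transformation_graph <- function() {
  edges <- rbind(
    c("CA",   "7-oxoDCA",      "7a-HSD"),
    c("CDCA", "7-oxoLCA",      "7a-HSD"),
    c("CA",   "12-oxoCDCA",    "12a-HSD"),
    c("DCA",  "12-oxoLCA",     "12a-HSD"),
    c("CA",   "3-oxoCA",       "3a-HSD"),
    c("CDCA", "3-oxoCDCA",     "3a-HSD"),
    c("DCA",  "3-oxoDCA",      "3a-HSD"),
    c("CA",   "7,12-dioxoLCA", "7a+12a-HSD"),
    c("CA",   "DCA",           "7a-dehydroxylation"),
    c("CDCA", "LCA",           "7a-dehydroxylation"),
    c("CDCA", "UDCA",          "7-epimerization"),
    c("DCA",  "HDCA",          "other"),
    c("CA",   "b-MCA",         "other")
  )
  out <- data.frame(substrate = edges[, 1], product = edges[, 2],
                    activity = edges[, 3], stringsAsFactors = FALSE)
  stopifnot(all(out$substrate != out$product))
  out
}

#' Activity classes of the transformation graph
#' @return Character vector of the distinct activity labels.
#' @export
activity_classes <- function() unique(transformation_graph()$activity)

#' Write the conjugate library to TSV
#'
#' @param library data.frame from [enumerate_conjugates()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_species_library <- function(library, path) {
  cols <- c("species_id", "core_abbrev", "amino_acid", "formula",
            "neutral_mono_mass", "mz_M_minus_H", "frag_aa_anion",
            "frag_aa_loss", "frag_sterol")
  utils::write.table(library[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a conjugate library TSV written by [write_species_library()]
#' @param path file path.
#' @return data.frame.
#' @export
read_species_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Default m/z library for MS1 matching: cores plus conjugates
#'
#' The matchable library is the union of the deprotonated steroid cores (for
#' quantitation against authentic standards) and the conjugate library.
#'
#' @param cores,amino_acids registries.
#' @return data.frame with at least `species_id`, `mz_M_minus_H`,
#'   `isobaric_group`, `kind` ("core" or "conjugate").
#' @export
build_mz_library <- function(cores = bile_core_registry(),
                             amino_acids = amino_acid_registry()) {
  conj <- enumerate_conjugates(cores, amino_acids)
  conj$kind <- "conjugate"
  core_lib <- data.frame(
    species_id = cores$abbrev,
    core_abbrev = cores$abbrev,
    amino_acid = NA_character_,
    isobaric_group = NA_character_,
    formula = cores$formula,
    neutral_mono_mass = cores$mono_mass,
    mz_M_minus_H = cores$mono_mass - MASS_PROTON,
    avg_mass = cores$avg_mass,
    frag_aa_anion = NA_real_, frag_aa_loss = NA_real_, frag_sterol = NA_real_,
    ambiguous = FALSE,
    kind = "core",
    stringsAsFactors = FALSE
  )
  rbind(core_lib, conj)
}
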