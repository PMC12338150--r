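---
title: "bilescreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bilescreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilescreen)
```

This vignette is the package's own account of the science it implements: the
mass model behind the conjugate library, the identification and quantitation
rules, the genotype classifiers, what the synthetic-study generator does and
does not emulate, and the numerical decisions taken where the design was
genuinely open.

## The mass model

All species are described by elemental compositions over C, H, N, O, S.
Monoisotopic masses are sums of the most-abundant-isotope masses
(¹²C = 12 exactly, ¹H = 1.00782503207, and so on); average molar masses, used
only for the µg/ml ↔ µM conversion, come from standard atomic weights. The
15 steroid cores are derived from the C24 cholanic acid skeleton
(C24H40O2) by their substituent state at C-3/C-6/C-7/C-12: each hydroxyl
adds one oxygen, each oxo adds an oxygen and removes H2. This makes the core
registry self-consistent by construction — e.g. every 3-oxo core is exactly
H2 lighter than its hydroxyl parent — and it is cross-checked in the tests
against an independent per-element summation oracle.

Amide conjugation condenses a core with a free amino acid and loses one
water:

- neutral mass: `M = M_core + M_aa − M_H2O`
- observed ion (negative-mode electrospray): `[M−H]⁻ = M − 1.00727646688`

Leucine and isoleucine are elementally identical, so they form one library
entry reported as `Leu/Ile` and flagged ambiguous; mass spectrometry cannot
distinguish them. Taurine is absent from the default registry — taurine
conjugation was not part of the observed repertoire — but
`amino_acid_registry()` output is a plain data frame and user-defined
residues can be appended. With 15 cores and 16 mass-distinct residues the
default conjugate library has 240 entries. Note that the library contains
*exact* cross-isobars: CDCA, DCA, UDCA and HDCA share C24H40O4, so their
conjugates with one amino acid are indistinguishable by mass, and even
cross-residue collisions exist (alanine + CA has the same formula as
serine + CDCA, since serine = alanine + O and CA = CDCA + O). Such
collisions are always reported side by side (`n_isobaric`), never resolved
silently.

### The fragment triad

Three diagnostic fragments identify a conjugate in MS/MS: the amino acid
anion (`M_aa − m_H⁺`), the amino-acid-loss fragment (the deprotonated core,
`[M−H]⁻ − residue mass`), and a major sterol fragment. The first two follow
from the amide bond by algebra and are exact. The sterol fragment depends on
core-specific fragmentation chemistry that cannot be derived from
composition alone, so it is a pluggable rule; the default is the dehydrated
deprotonated core (`[core − H − H2O]⁻`), the dominant neutral loss for
hydroxylated steroids in negative mode. Applications with measured spectra
can substitute a per-core table via the `sterol_rule` argument.

## Identification rules

MS1 assignment uses the strict criterion |ppm| < 2 ("less than", so a
feature at exactly +2.00 ppm fails). Retention time is deliberately **not**
used to identify conjugates without authentic standards: no defensible RT
prediction model for novel amidates exists, so RT serves only to associate
MS2 spectra with features (±0.2 min) and to group double peaks. Species
*with* authentic standards (the cores and the glycine conjugates) carry a
standard RT, and matching to them is additionally gated to ±0.5 min — this
is what disambiguates the four C24H40O4 cores from one another.

MS2 confirmation searches only spectra whose precursor window contains the
matched m/z; the acquisition uses five fixed 40 Th windows centered at
370/408/446/484/522. Fragments are matched at 10 ppm — looser than MS1
because the MS2 scans are acquired at resolution 17,500 vs 70,000 — and
evidence is upgraded to `MS1_plus_MS2` when at least 2 of 3 triad fragments
are found (a 3-of-3 rule is a configuration switch). Tightening either
tolerance can only remove matches or downgrade evidence; this monotonicity
is property-tested.

Enantiomer detection: d- and l-amino-acid conjugates have identical mass but
different retention; a species matched by two features ≥ 0.3 min apart in
one sample is reported as a double-peak pair (adjacent pairs in RT order).

## Quantitation

Standard curves are ordinary least squares on the five-point series
(0.01, 0.05, 0.1, 0.5, 1 µg/ml). Inversion converts to µM via the species'
average molar mass (`µM = µg/ml × 1000 / (g/mol)`). Censoring: below
0.05 µM is below the detection limit and reported as 0 with a `below-LOD`
flag (no imputation); between 0.05 and 0.1 µM is `below-report`; activity
calls require ≥ 0.1 µM. Conjugates without standards are never converted to
concentrations — they are reported as raw intensities, and the conjugate
heat-map input is their per-species Z-score across strains, using the
sample standard deviation (n − 1); zero-variance rows are set to zero and
flagged. Per-strain normalization is available via `by = "column"`.

Activity calls walk the fixed transformation graph (13 edges: the three HSD
oxidation families, the 7,12 double oxidation, 7α-dehydroxylation,
7-epimerization CDCA→UDCA, and the two rarer conversions DCA→HDCA and
CA→β-MCA). A call requires the product to reach the reporting threshold
under the matching substrate condition at 24 or 48 h; the call carries the
per-product maximum, so multiple edges of one activity yield one row each
(summed percentages are available through `percent_transformed()`). Products
observed under the no-substrate control are flagged as background and never
called. Under the MIX condition all three substrates are present, so the
added species themselves (CA, CDCA, DCA) are not scored as products there.
Product concentrations exceeding the dose by > 5% are flagged for
mass-balance review but retained.

## Genotype prediction

*bai* operon detection filters homology hits at E ≤ 1e−10 (inclusive — the
threshold is read as pass-at-threshold), keeps the best hit per
(gene, CDS), and searches each contig for the window of span < 100,000 bp
(1-based inclusive coordinates; span = max end − min start) containing hits
to the most distinct *bai* genes. Strand is ignored. The search anchors the
window at every hit start and picks, per gene, the hit with the smallest end
inside the window, which provably attains the maximal gene count at the
minimal span; the test suite checks exact agreement with brute-force subset
enumeration. A call is *canonical* when BaiA2, BaiB, BaiCD, BaiE, BaiF,
BaiG and BaiH co-localize (BaiI is optional, matching the canonical operon
observed without it).

HSD classification uses per-class bit-score cutoffs selected by maximizing
F = 2/(recall⁻¹ + precision⁻¹), where the positive group is the class's own
reference scores and the negatives are the other two classes combined.
Candidate thresholds are restricted to the observed scores — any threshold
between two adjacent scores gives identical confusion counts, which also
makes the treatment of scores below a search tool's reporting floor
irrelevant. Ties resolve to the *minimal* score achieving the maximal F,
and classification is inclusive (score ≥ cutoff predicts the class), since
the cutoff is itself an observed positive score. F is defined as 0 when
TP = 0 (precision is undefined there); this convention only matters in
degenerate scans. The published cutoffs for HMMER-3.2.1 profiles
(146.1 / 220.6 / 120.2 for 3α/7α/12α) are available as
`hsd_published_cutoffs()`, but bit scores are comparable only within a single
scoring backend and version, so cutoffs are recomputed whenever a different
backend supplies the scores. The package ships a native profile scorer
(`build_pssm()` / `score_with_pssm()`: log-odds over match columns with
≤ 50% gaps, 0.5 pseudocounts against a uniform background, best ungapped
placement) so synthetic tests need no external search tool; real
`hmmsearch --tblout` tables are ingested interchangeably.

## Concordance

Predicted and observed activities are compared as sets of (strain, class)
pairs, yielding confirmed / predicted-only / observed-only counts per class
and per strain. The totals satisfy confirmed + observed-only = observed and
confirmed + predicted-only = predicted by construction. Matching at species
level (strain suffix stripped) is a switch, since confirmations are
sometimes reported at species rather than strain resolution. The pipeline's
concordance stage restricts the comparison to the genotype-predictable
classes (3α/7α/12α-HSD and 7α-dehydroxylation); epimerization and the rarer
conversions have no searched gene and would otherwise inflate
observed-only counts.

## The synthetic-study generator

`simulate_panel()` emulates the screen's study design: a 72-strain panel,
each strain incubated separately with CA, CDCA or DCA at 100 µM (plus a
no-substrate control), sampled at 24 and 48 h. Defaults were chosen once
from the study's stated conditions and are not tuned:

| parameter | default | rationale |
|---|---|---|
| strains | 72 | the screen's scale |
| transformer prevalence | 0.6 | 43/72 strains transformed ≥ 1 bile acid |
| activity class weights | 0.88/0.58/0.28/0.12/… | relative frequencies among the 43 transformers (38 7α, 25 3α, 12 12α, 5 dehydroxylators) |
| product ranges (48 h) | 7α ≤ 93.9 µM, 12α ≤ 28.6, 3α ≤ 9.35, floor 0.12 | the reported per-class ranges; the floor keeps every planted activity above the 0.1 µM reporting threshold so recovery is well-defined |
| conjugator prevalence | 0.39 | 28/72 strains conjugated amino acids |
| m/z jitter | σ = 0.3 ppm, capped at 1.0 | Orbitrap MS1 accuracy at R = 70,000 |
| decoys | 500/strain, ≥ 5 ppm from any library mass | unambiguous false-match accounting |
| intensity noise | 2% CV (1% calibration) | routine LC-MS replicate precision |
| calibration grid | 0.01/0.05/0.1/0.5/1 µg/ml | the five-point standard series |

Planted conjugates are drawn only from library entries whose `[M−H]⁻` is
unique within 5 ppm *and* covered by an MS2 window: the library's exact
cross-isobars (see above) would otherwise make "recovered the planted
species, nothing else" unfalsifiable, and species outside the five windows
can never be triad-confirmed. Ala/Val conjugates may be planted as
enantiomer double peaks. Genotypes are planted consistently with
phenotypes: HSD-active strains get 1–2 genes scoring in a high band
(180–300) against a low background (≤ 80), reference score sets are
separable by construction, and dehydroxylating strains get a 7-gene
canonical operon spanning 12–40 kb; ~30% of other strains get sparse or
sub-threshold *bai* hits as realistic negatives.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: chromatographic peak shapes and integration,
isotope envelopes, co-eluting interferences, retention-time drift and
prediction, matrix effects on ionization, sequence evolution (scores are
planted, not computed from alignments), and genuinely discordant genotypes
(silent genes, non-homologous enzymes). The generator validates the
pipeline's bookkeeping and decision rules, not instrument physics or
biology. All randomness flows from one seed through isolated RNG scopes
(`withr::with_seed`), so ledgers and emitted tables are byte-reproducible
and the global RNG state is never disturbed.

## Numerical choices and degenerate inputs

- Proton mass 1.00727646688 Da; water 18.0105646 Da; strict inequality at
  the 2 ppm boundary.
- Curve fitting requires ≥ 3 distinct concentrations; non-positive slopes
  mark a curve unusable downstream; negative inversions clamp to 0 µM with
  `below-LOD`.
- Z-scores of constant rows are 0, with a `zero_variance` attribute rather
  than NaN.
- `select_cutoff()` requires a non-empty positive set; with no negatives the
  cutoff is the minimal positive score at F = 1.
- Operon windows cannot span contigs; hits on CDS absent from the
  coordinate table are excluded with a warning; the span of a single gene
  is end − start.
- Malformed peak-table rows (negative intensity, non-positive m/z, RT
  outside the 31.5 min run) are dropped with line numbers, not silently.

## Problem sizes

The test suite runs the full 72-strain default panel once for end-to-end
recovery, 100 four-strain panels for the 5%-noise quantitation study, 200
random score sets against the exhaustive cutoff oracle, and 50 random
operon instances (≤ 10 hits) against brute-force subset search; these sizes
give stable statistics while keeping the whole suite under a couple of
minutes on one CPU. `scripts/acceptance.R` re-runs the default-scale study
from a command-line seed.

## Known limitations

- Identification of novel conjugates rests on exact mass plus the fragment
  triad; positional isomers and enantiomers within an isobaric group are
  not distinguishable, and Leu/Ile conjugates are inherently ambiguous.
- The default sterol-fragment rule is a stand-in for per-compound
  fragmentation chemistry and should be replaced with measured values when
  available.
- Bit-score cutoffs transfer across datasets only within one search tool
  and version.
- The operon detector reports co-localization, not operon structure: gene
  order, strand consistency and promoter context are out of scope.
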