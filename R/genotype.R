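# Genotype prediction: bai-operon detection from homology hits co-localized
# on the genome, and HSD classification via F-measure-optimal bit-score
# cutoffs applied to profile search scores.

#' The eight bai operon query genes
#' @export
BAI_GENES <- c("BaiA2", "BaiB", "BaiCD", "BaiE", "BaiF", "BaiG", "BaiH",
               "BaiI")

#' Genes required for a canonical bai operon call (BaiI is optional)
#' @export
BAI_CANONICAL <- setdiff(BAI_GENES, "BaiI")

#' Published HMMER-3.2.1 bit-score cutoffs per HSD class
#'
#' F-measure-optimal cutoffs derived from the curated UniProt reference sets
#' (6 x 3alpha, 5 x 7alpha, 6 x 12alpha sequences), scored with HMMER 3.2.1
#' profiles built from MUSCLE 3.8.31 alignments. Bit scores are comparable
#' only within one scoring backend and version, so these constants apply only
#' to scores produced with that tool chain; [select_cutoff()] recomputes
#' cutoffs for any other backend.
#'
#' @return Named numeric vector: `3a`, `7a`, `12a`.
#' @export
hsd_published_cutoffs <- function() c(`3a` = 146.1, `7a` = 220.6,
                                      `12a` = 120.2)

#' Filter homology hits by E-value and deduplicate per (query, CDS)
#'
#' @param hits data.frame with `query_id`, `cds_id`, `evalue`, `bit_score`.
#' @param e_max inclusive E-value threshold (default 1e-10).
#' @return Filtered hits, one row per (query, CDS): lowest E-value, ties
#'   broken by higher bit score.
#' @export
filter_hits <- function(hits, e_max = 1e-10) {
  stopifnot(e_max > 0)
  keep <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  o <- order(keep$query_id, keep$cds_id, keep$evalue, -keep$bit_score)
  keep <- keep[o, , drop = FALSE]
  keep <- keep[!duplicated(keep[, c("query_id", "cds_id")]), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Detect a co-localized bai operon
#'
#' Joins filtered bai hits to CDS coordinates and searches each contig for
#' the window (span strictly below `window_bp`) containing best hits to the
#' largest number of distinct bai genes; ties prefer the smaller span. The
#' call is canonical when all seven required genes (BaiI optional) fall
#' within one sub-window span. Coordinates are 1-based inclusive; the span of
#' a gene set is `max(end) - min(start)`.
#'
#' @param hits filtered hits from [filter_hits()] whose `query_id` values are
#'   bai gene names.
#' @param cds data.frame of CDS coordinates: `cds_id`, `contig_id`, `start`,
#'   `end`, `strand` (strand is ignored for windowing).
#' @param window_bp window size in bp (default 100000; spans must be < this).
#' @return list of class `operon_call`: `genes_present` (character),
#'   `n_genes`, `span_bp`, `contig_id`, `canonical`, `members` (data.frame of
#'   the chosen best hit per gene), `orphan_hits` (hits on CDS missing from
#'   the coordinate table).
#' @export
detect_bai_operon <- function(hits, cds, window_bp = 1e5) {
  stopifnot(window_bp > 0)
  empty <- list(genes_present = character(0), n_genes = 0L, span_bp = NA_real_,
                contig_id = NA_character_, canonical = FALSE,
                members = NULL, orphan_hits = NULL)
  class(empty) <- "operon_call"
  if (is.null(hits) || !nrow(hits)) return(empty)
  idx <- match(hits$cds_id, cds$cds_id)
  orphan <- hits[is.na(idx), , drop = FALSE]
  if (nrow(orphan))
    warning(nrow(orphan), " hit(s) on CDS absent from the coordinate table, ",
            "excluded")
  hits <- hits[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!nrow(hits)) { empty$orphan_hits <- orphan; return(empty) }
  h <- data.frame(query_id = hits$query_id, cds_id = hits$cds_id,
                  bit_score = hits$bit_score,
                  contig_id = cds$contig_id[idx],
                  start = cds$start[idx], end = cds$end[idx],
                  stringsAsFactors = FALSE)

  best <- NULL
  for (contig in unique(h$contig_id)) {
    hc <- h[h$contig_id == contig, , drop = FALSE]
    hc <- hc[order(hc$start), , drop = FALSE]
    # the optimal set's leftmost member starts at some hit's start, so
    # anchoring every hit in turn and taking, per gene, the hit with the
    # smallest end inside the window yields the maximal gene count at the
    # minimal span
    for (i in seq_len(nrow(hc))) {
      inw <- hc$start >= hc$start[i] & hc$end < hc$start[i] + window_bp
      sel <- hc[inw, , drop = FALSE]
      if (!nrow(sel)) next
      sel <- sel[order(sel$query_id, sel$end, -sel$bit_score), ,
                 drop = FALSE]
      sel <- sel[!duplicated(sel$query_id), , drop = FALSE]
      span <- max(sel$end) - min(sel$start)
      cand <- list(sel = sel, n = nrow(sel), span = span, contig = contig)
      if (is.null(best) || cand$n > best$n ||
          (cand$n == best$n && cand$span < best$span))
        best <- cand
    }
  }
  genes <- sort(unique(best$sel$query_id))
  out <- list(
    genes_present = genes,
    n_genes = length(genes),
    span_bp = best$span,
    contig_id = best$contig,
    canonical = all(BAI_CANONICAL %in% genes) && best$span < window_bp,
    members = best$sel[order(best$sel$start), , drop = FALSE],
    orphan_hits = if (nrow(orphan)) orphan else NULL
  )
  class(out) <- "operon_call"
  out
}

#' F measure from confusion counts
#'
#' Harmonic mean of recall (TP / (TP + FN)) and precision (TP / (TP + FP)),
#' i.e. F = 2 / (recall^-1 + precision^-1). When TP = 0 either quantity is 0
#' or undefined and F is defined as 0.
#'
#' @param tp,fp,fn non-negative confusion counts.
#' @return list: `tp`, `fp`, `fn`, `recall`, `precision`, `f`.
#' @export
f_measure <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (tp == 0) 0 else 2 / (1 / recall + 1 / precision)
  list(tp = tp, fp = fp, fn = fn, recall = recall, precision = precision,
       f = f)
}

#' Select the F-measure-optimal bit-score cutoff
#'
#' Candidate thresholds are the observed scores (any threshold between two
#' adjacent observed scores yields identical confusion counts). At threshold
#' t: TP = positives >= t, FP = negatives >= t, FN = positives < t. The
#' cutoff is the minimal candidate achieving the maximal F.
#'
#' @param pos_scores scores of the positive reference group (non-empty).
#' @param neg_scores scores of the negative group (may be empty).
#' @param class label carried on the result (e.g. "3a").
#' @return list of class `cutoff_result`: `class`, `cutoff`, `f`, `scan`
#'   (data.frame threshold/tp/fp/fn/recall/precision/f).
#' @examples
#' select_cutoff(c(150, 160), 100)$cutoff  # 150, F = 1
#' @export
select_cutoff <- function(pos_scores, neg_scores = numeric(0),
                          class = NA_character_) {
  if (!length(pos_scores)) stop("positive score set must be non-empty")
  cand <- sort(unique(c(pos_scores, neg_scores)))
  scan <- do.call(rbind, lapply(cand, function(t) {
    fm <- f_measure(sum(pos_scores >= t), sum(neg_scores >= t),
                    sum(pos_scores < t))
    data.frame(threshold = t, tp = fm$tp, fp = fm$fp, fn = fm$fn,
               recall = fm$recall, precision = fm$precision, f = fm$f)
  }))
  best_f <- max(scan$f)
  cutoff <- min(scan$threshold[scan$f == best_f])
  out <- list(class = class, cutoff = cutoff, f = best_f, scan = scan)
  class(out) <- "cutoff_result"
  out
}

#' Classify HSD capability per strain from CDS scores
#'
#' A class is predicted when at least one CDS scores at or above the class
#' cutoff (the cutoff itself is an observed positive score, so the boundary
#' is inclusive).
#'
#' @param scores data.frame with `cds_id`, `class`, `bit_score` for one
#'   strain.
#' @param cutoffs named numeric vector of cutoffs per class, or a list of
#'   `cutoff_result` objects keyed by class.
#' @return data.frame: `class`, `predicted`, `n_support`, `support` (CDS ids
#'   in descending score order, comma-joined), `top_score`.
#' @export
classify_hsd <- function(scores, cutoffs) {
  if (is.list(cutoffs) && !is.numeric(cutoffs))
    cutoffs <- vapply(cutoffs, function(x) x$cutoff, numeric(1))
  out <- lapply(names(cutoffs), function(cl) {
    s <- scores[scores$class == cl, , drop = FALSE]
    s <- s[order(-s$bit_score), , drop = FALSE]
    hit <- s[s$bit_score >= cutoffs[[cl]], , drop = FALSE]
    data.frame(class = cl, predicted = nrow(hit) > 0,
               n_support = nrow(hit),
               support = paste(hit$cds_id, collapse = ","),
               top_score = if (nrow(s)) s$bit_score[1] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Native profile scorer (position-specific scoring matrix)
# ---------------------------------------------------------------------------

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a position-specific scoring matrix from an alignment
#'
#' Match columns are alignment columns with at most 50% gaps; per-column
#' amino acid probabilities use additive pseudocounts against a uniform
#' 1/20 background. Deterministic and invariant to row order.
#'
#' @param msa character vector of equal-length aligned sequences (gaps `-`).
#' @param pseudocount added per residue per column (default 0.5).
#' @return matrix of log2 odds, 20 residues x match columns, class `pssm`.
#' @export
build_pssm <- function(msa, pseudocount = 0.5) {
  if (!length(msa)) stop("alignment must be non-empty")
  L <- unique(nchar(msa))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  chars <- do.call(rbind, strsplit(toupper(msa), ""))
  bad <- setdiff(unique(as.vector(chars)), c(.AA_ALPHABET, "-", "."))
  if (length(bad))
    stop("alphabet violation in alignment: ", paste(bad, collapse = ", "))
  gap_frac <- colMeans(chars == "-" | chars == ".")
  match_cols <- which(gap_frac <= 0.5)
  if (!length(match_cols)) stop("alignment has no match columns")
  pssm <- vapply(match_cols, function(j) {
    col <- chars[, j]
    col <- col[col %in% .AA_ALPHABET]
    counts <- table(factor(col, levels = .AA_ALPHABET))
    p <- (as.numeric(counts) + pseudocount) /
      (length(col) + 20 * pseudocount)
    log2(p / (1 / 20))
  }, numeric(20))
  rownames(pssm) <- .AA_ALPHABET
  class(pssm) <- c("pssm", class(pssm))
  pssm
}

#' Score a protein sequence against a PSSM
#'
#' Best ungapped placement: the profile is slid over the sequence and the
#' maximal sum of per-position log-odds over the overlap is returned (a
#' bit-like score). Used as the native profile scorer for synthetic data;
#' external hmmsearch scores are ingested interchangeably when provided, but
#' cutoffs are only comparable within one scoring backend.
#'
#' @param pssm matrix from [build_pssm()] (or an alignment, in which case the
#'   PSSM is built first).
#' @param sequence unaligned protein sequence (character scalar).
#' @param min_overlap minimum profile/sequence overlap scored (default: full
#'   profile, or the whole sequence if shorter).
#' @return numeric score (bits).
#' @export
score_with_pssm <- function(pssm, sequence, min_overlap = NULL) {
  if (is.character(pssm)) pssm <- build_pssm(pssm)
  s <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(s), .AA_ALPHABET)
  if (length(bad))
    stop("alphabet violation in sequence: ", paste(bad, collapse = ", "))
  L <- ncol(pssm); n <- length(s)
  if (is.null(min_overlap)) min_overlap <- min(L, n)
  si <- match(s, .AA_ALPHABET)
  best <- -Inf
  for (off in seq(-(L - min_overlap), n - min_overlap)) {
    jj <- seq_len(L)
    pos <- off + jj
    ok <- pos >= 1 & pos <= n
    if (sum(ok) < min_overlap) next
    sc <- sum(pssm[cbind(si[pos[ok]], jj[ok])])
    if (sc > best) best <- sc
  }
  best
}

# ---------------------------------------------------------------------------
# Format readers
# ---------------------------------------------------------------------------

#' Read BLAST tabular output (12-column outfmt 6)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Mapped to the package's hit schema with `query_id`
#' = qseqid and `cds_id` = sseqid.
#'
#' @param path file path.
#' @return data.frame of homology hits.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  cols <- c("query_id", "cds_id", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bit_score")
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12)
    stop("expected 12 tab-separated columns (outfmt 6), found ", ncol(tab))
  tab <- tab[, 1:12]
  names(tab) <- cols
  tab
}

#' Read hmmsearch --tblout output
#'
#' Whitespace-delimited with `#` comment lines; fields 1 (target), 3 (query),
#' 5 (full-sequence E-value) and 6 (full-sequence bit score) are used.
#'
#' @param path file path.
#' @return data.frame with `cds_id`, `query_id`, `evalue`, `bit_score`.
#' @export
read_hmmer_tblout <- function(path) {
  if (!file.exists(path)) stop("hmmsearch tblout file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(cds_id = character(), query_id = character(),
                      evalue = numeric(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  short <- vapply(parts, length, integer(1)) < 6
  if (any(short)) stop("malformed tblout line(s): ",
                       paste(which(short), collapse = ", "))
  data.frame(
    cds_id = vapply(parts, `[`, character(1), 1),
    query_id = vapply(parts, `[`, character(1), 3),
    evalue = as.numeric(vapply(parts, `[`, character(1), 5)),
    bit_score = as.numeric(vapply(parts, `[`, character(1), 6)),
    stringsAsFactors = FALSE
  )
}

#' Read CDS coordinates from a GFF3 file
#'
#' Imports via rtracklayer and keeps CDS (or gene, if no CDS present)
#' features with 1-based inclusive coordinates.
#'
#' @param path GFF3 file path.
#' @return data.frame: `cds_id`, `contig_id`, `start`, `end`, `strand`.
#' @export
read_gff_cds <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path)
  types <- as.character(gr$type)
  keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids)) ids <- paste0("cds_", seq_along(gr))
  data.frame(
    cds_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
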