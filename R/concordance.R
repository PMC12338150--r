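# Genotype-phenotype concordance: set comparison of predicted vs observed
# activity classes per strain and per class.

.CONCORDANCE_CLASSES <- c("3a-HSD", "7a-HSD", "12a-HSD", "7a-dehydroxylation",
                          "7a+12a-HSD", "7-epimerization", "conjugation",
                          "other")

#' Compare predicted and observed activity records
#'
#' Each record is a (strain, activity class) pair from either the genotype
#' predictions or the phenotype activity calls. The summary counts, per class
#' and per strain, the confirmed pairs (predicted and observed), the
#' predicted-only pairs, and the observed-only pairs, so that
#' confirmed + observed-only = total observed and confirmed + predicted-only
#' = total predicted.
#'
#' @param predicted data.frame with `strain_id` and `class`.
#' @param observed data.frame with `strain_id` and `class`.
#' @param classes allowed class labels; records with other labels are
#'   rejected.
#' @param level `"strain"` (default) matches on the full strain id;
#'   `"species"` matches on the id with a trailing strain suffix (text after
#'   the last underscore) removed.
#' @return list of class `concordance_summary`: `by_class` (data.frame:
#'   `class`, `confirmed`, `predicted_only`, `observed_only`), `by_strain`
#'   (same triple per strain), `pairs` (data.frame of all (strain, class)
#'   pairs with their status), `n_disagreement`.
#' @examples
#' p <- data.frame(strain_id = "s1", class = c("3a-HSD", "7a-HSD", "12a-HSD"))
#' o <- data.frame(strain_id = "s1", class = c("3a-HSD", "7a-HSD"))
#' compare_activities(p, o)$by_class
#' @export
compare_activities <- function(predicted, observed,
                               classes = .CONCORDANCE_CLASSES,
                               level = c("strain", "species")) {
  level <- match.arg(level)
  check <- function(df, what) {
    bad <- setdiff(unique(df$class), classes)
    if (length(bad))
      stop("unknown activity class label(s) in ", what, ": ",
           paste(bad, collapse = ", "))
  }
  check(predicted, "predictions")
  check(observed, "observations")
  key <- function(df) {
    id <- as.character(df$strain_id)
    if (level == "species") id <- sub("_[^_]*$", "", id)
    unique(paste(id, df$class, sep = "\r"))
  }
  p <- key(predicted); o <- key(observed)
  all_pairs <- union(p, o)
  status <- ifelse(all_pairs %in% p & all_pairs %in% o, "confirmed",
                   ifelse(all_pairs %in% p, "predicted_only",
                          "observed_only"))
  parts <- do.call(rbind, strsplit(all_pairs, "\r"))
  pairs <- data.frame(strain_id = parts[, 1], class = parts[, 2],
                      status = status, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$strain_id, pairs$class), , drop = FALSE]
  rownames(pairs) <- NULL
  tally <- function(margin) {
    keys <- sort(unique(pairs[[margin]]))
    do.call(rbind, lapply(keys, function(k) {
      sub <- pairs[pairs[[margin]] == k, , drop = FALSE]
      data.frame(key = k,
                 confirmed = sum(sub$status == "confirmed"),
                 predicted_only = sum(sub$status == "predicted_only"),
                 observed_only = sum(sub$status == "observed_only"),
                 stringsAsFactors = FALSE)
    }))
  }
  by_class <- tally("class"); names(by_class)[1] <- "class"
  by_strain <- tally("strain_id"); names(by_strain)[1] <- "strain_id"
  out <- list(by_class = by_class, by_strain = by_strain, pairs = pairs,
              n_disagreement = sum(pairs$status != "confirmed"))
  class(out) <- "concordance_summary"
  out
}

#' Write a concordance summary (TSV pairs + JSON totals)
#'
#' @param summary result of [compare_activities()].
#' @param tsv_path path for the per-pair TSV.
#' @param json_path path for the JSON totals (optional).
#' @return `tsv_path`, invisibly.
#' @export
write_concordance <- function(summary, tsv_path, json_path = NULL) {
  utils::write.table(summary$pairs, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(by_class = summary$by_class, by_strain = summary$by_strain,
           n_disagreement = summary$n_disagreement),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tsv_path)
}
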