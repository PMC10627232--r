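#' Significance-gated rank scores for one metric
#'
#' Sequences are ordered best-to-worst by central tendency (under the
#' metric's direction) and partitioned into tiers: a tier boundary between
#' ordered positions i and i+1 is placed only when EVERY sequence at or above
#' position i differs significantly from EVERY sequence at or below position
#' i+1 (the strong reading of "better only if significant against all
#' lower-scored pairs"). Members of a tier share a score; tier scores are the
#' average of the consecutive ranks the tier spans (see [rescale_ties()]), so
#' with no placeable boundary all S sequences share (S+1)/2 — e.g. all 2.5
#' for S = 4.
#'
#' @param result a `significance_result` (see [pairwise_significance()]).
#' @param direction `"higher_better"` or `"lower_better"` for the metric.
#' @return named numeric vector of metric scores (one per sequence, in the
#'   result's sequence order), summing to `S(S+1)/2`. Attribute `raw` holds
#'   the pre-rescaling tier scores (1 + number of sequences in strictly
#'   lower tiers).
#' @export
gated_rank_scores <- function(result,
                              direction = c("higher_better", "lower_better")) {
  stopifnot(inherits(result, "significance_result"))
  direction <- match.arg(direction)
  center <- result$center
  S <- length(center)
  if (S < 2L) stop("need at least 2 sequences to score")
  sig <- significance_matrix(result)
  ord <- order(center, decreasing = (direction == "higher_better"))
  tiers <- tier_partition(ord, sig)
  scores <- raw <- numeric(S)
  below <- 0
  for (t in rev(seq_along(tiers))) {          # bottom tier first
    members <- tiers[[t]]
    sz <- length(members)
    raw[members] <- below + 1
    scores[members] <- mean(below + seq_len(sz))
    below <- below + sz
  }
  names(scores) <- names(raw) <- result$sequences
  attr(scores, "raw") <- raw
  scores
}

# Partition ordered sequence indices (best first) into tiers under the
# all-above-vs-all-below boundary rule. Returns a list of index vectors,
# best tier first, each vector holding positions in the original ordering.
tier_partition <- function(ord, sig) {
  S <- length(ord)
  boundary <- logical(S - 1)
  for (i in seq_len(S - 1)) {
    above <- ord[seq_len(i)]
    belowi <- ord[(i + 1):S]
    boundary[i] <- all(sig[above, belowi, drop = FALSE])
  }
  cuts <- c(0, which(boundary), S)
  lapply(seq_len(length(cuts) - 1),
         function(t) ord[(cuts[t] + 1):cuts[t + 1]])
}

#' Rescale tied scores to average ranks
#'
#' Raw tiered scores over S sequences are rescaled so that each tie group
#' receives the arithmetic mean of the consecutive ranks it spans; the
#' rescaled scores always sum to `S(S+1)/2`. For example `{4, 2, 2, 1}`
#' becomes `{4, 2.5, 2.5, 1}` where `2.5 = (3 + 2)/2`.
#'
#' @param raw numeric vector of raw scores (larger = better tier); equal
#'   values form a tie group.
#' @return numeric vector of rescaled scores in the same order.
#' @export
#' @examples
#' rescale_ties(c(4, 2, 2, 1))   # 4 2.5 2.5 1
rescale_ties <- function(raw) {
  if (length(raw) == 0L) stop("empty score vector")
  if (any(!is.finite(raw))) stop("malformed tier scores")
  out <- rank(raw, ties.method = "average")
  names(out) <- names(raw)
  out
}

#' Normalised category scores
#'
#' Metric scores within one analysis category are (weight-)summed per
#' (sequence, structure) and the sums re-ranked across sequences within each
#' structure (average-rank ties), yielding scores back on the 1..S scale so
#' that categories with many metrics weigh the same as categories with few.
#' Structure-agnostic metrics (e.g. the fat SNR) must be broadcast to every
#' structure before calling.
#'
#' @param metric_scores data frame with columns `sequence_id`,
#'   `structure_label`, `metric`, `score`.
#' @param weights optional named numeric vector of per-metric weights
#'   (default 1 for every metric).
#' @return data frame `sequence_id`, `structure_label`, `category_sum`,
#'   `category_score`.
#' @export
category_scores <- function(metric_scores, weights = NULL) {
  w <- function(m) if (!is.null(weights) && m %in% names(weights))
    weights[[m]] else 1
  metric_scores$wscore <- metric_scores$score *
    vapply(metric_scores$metric, w, numeric(1))
  sums <- aggregate(wscore ~ sequence_id + structure_label, metric_scores,
                    sum)
  names(sums)[names(sums) == "wscore"] <- "category_sum"
  sums$category_score <- NA_real_
  for (st in unique(sums$structure_label)) {
    i <- sums$structure_label == st
    sums$category_score[i] <- rescale_ties(sums$category_sum[i])
  }
  sums
}

#' Total and normalised total scores per sequence-structure pair
#'
#' Normalised category scores are (weight-)summed into a total score per
#' (sequence, structure); totals are then re-ranked across sequences within
#' each structure (average-rank ties) into the normalised total score.
#'
#' @param category_tbl data frame with columns `sequence_id`,
#'   `structure_label`, `category`, `category_score`.
#' @param weights optional named per-category weights (default 1).
#' @return data frame `sequence_id`, `structure_label`, `total`,
#'   `normalized_total`.
#' @export
total_scores <- function(category_tbl, weights = NULL) {
  w <- function(cg) if (!is.null(weights) && cg %in% names(weights))
    weights[[cg]] else 1
  category_tbl$wscore <- category_tbl$category_score *
    vapply(category_tbl$category, w, numeric(1))
  tot <- aggregate(wscore ~ sequence_id + structure_label, category_tbl, sum)
  names(tot)[names(tot) == "wscore"] <- "total"
  tot$normalized_total <- NA_real_
  for (st in unique(tot$structure_label)) {
    i <- tot$structure_label == st
    tot$normalized_total[i] <- rescale_ties(tot$total[i])
  }
  tot
}

#' Combined scores per sequence
#'
#' Total scores are (structure-weight-)summed across structures into the
#' combined total score. The combined normalised score ranks, by default, the
#' per-sequence sums of NORMALISED total scores (average-rank ties); the
#' alternative that ranks the combined totals themselves is also returned.
#' The two orderings can genuinely differ (the per-structure normalisation
#' equalises structures before summing; the raw totals do not), which is why
#' both are reported — `combined_normalized` follows the default rule, and
#' `combined_normalized_alt` the combined-total ranking.
#'
#' @param totals_tbl output of [total_scores()].
#' @param structure_weights optional named per-structure weights (default 1).
#' @return data frame `sequence_id`, `combined_total`,
#'   `sum_normalized_totals`, `combined_normalized`,
#'   `combined_normalized_alt`.
#' @export
combined_scores <- function(totals_tbl, structure_weights = NULL) {
  w <- function(st) if (!is.null(structure_weights) &&
                        st %in% names(structure_weights))
    structure_weights[[st]] else 1
  sw <- vapply(totals_tbl$structure_label, w, numeric(1))
  totals_tbl$wtotal <- totals_tbl$total * sw
  totals_tbl$wnorm <- totals_tbl$normalized_total * sw
  ct <- aggregate(cbind(wtotal, wnorm) ~ sequence_id, totals_tbl, sum)
  out <- data.frame(sequence_id = ct$sequence_id,
                    combined_total = ct$wtotal,
                    sum_normalized_totals = ct$wnorm)
  out$combined_normalized <- rescale_ties(out$sum_normalized_totals)
  out$combined_normalized_alt <- rescale_ties(out$combined_total)
  out
}

#' Assemble a score ledger from normalised category scores
#'
#' Runs the aggregation half of the rubric (categories -> totals -> combined)
#' on a table of normalised category scores, producing the full score ledger
#' for the study.
#'
#' @param category_tbl data frame with columns `sequence_id`,
#'   `structure_label`, `category`, `category_score`.
#' @param category_weights,structure_weights optional named weights.
#' @return object of class `score_ledger` with elements `categories`,
#'   `totals`, `combined`, `weights`.
#' @export
score_ledger <- function(category_tbl, category_weights = NULL,
                         structure_weights = NULL) {
  totals <- total_scores(category_tbl, category_weights)
  combined <- combined_scores(totals, structure_weights)
  structure(
    list(categories = category_tbl, totals = totals, combined = combined,
         weights = list(category = category_weights,
                        structure = structure_weights)),
    class = "score_ledger")
}

#' @export
print.score_ledger <- function(x, ...) {
  cat("<score_ledger>\n\nTotals per sequence-structure pair:\n")
  print(x$totals, row.names = FALSE)
  cat("\nCombined per sequence:\n")
  print(x$combined, row.names = FALSE)
  invisible(x)
}

#' Direction convention per metric
#'
#' Higher is better for SNR, both CNRs, conspicuity, DSC, grade score and
#' comment metric; lower is better for the fat SNR (good suppression = low
#' residual fat signal) and HD95.
#'
#' @param metric metric name.
#' @return `"higher_better"` or `"lower_better"`.
#' @export
metric_direction <- function(metric) {
  lower <- c("fat_snr", "hd95")
  ifelse(metric %in% lower, "lower_better", "higher_better")
}

#' Category membership per metric
#'
#' @return named character vector mapping metric name to analysis category
#'   (`snr_cnr`, `conspicuity`, `pairwise_distance`, `segmentor`).
#' @export
metric_categories <- function() {
  c(snr = "snr_cnr", fat_snr = "snr_cnr", cnr_fat = "snr_cnr",
    cnr_muscle = "snr_cnr",
    conspicuity = "conspicuity",
    dsc = "pairwise_distance", hd95 = "pairwise_distance",
    grade = "segmentor", comment = "segmentor")
}
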