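#' Render a human-readable report for a pipeline run
#'
#' Writes (or returns) a score matrix shaped like the study's summary score
#' table (stages x (sequence, structure)), per-metric summary tables with
#' central tendency and dispersion, and a ranked-sequence verdict naming the
#' winning sequence — or stating that no sequence is distinguishable when the
#' rubric ties everywhere.
#'
#' @param ledger a [score_ledger()] (or a `pipeline_result`).
#' @param significance optional list of `significance_result`s (taken from
#'   the `pipeline_result` automatically).
#' @param dir optional output directory; when given, CSV/JSON/text files are
#'   written there.
#' @return invisibly, a list with `score_matrix`, `metric_summaries`,
#'   `verdict` (character).
#' @export
render_report <- function(ledger, significance = NULL, dir = NULL) {
  if (inherits(ledger, "pipeline_result")) {
    significance <- ledger$significance
    ledger <- ledger$ledger
  }
  stopifnot(inherits(ledger, "score_ledger"))

  cat_tbl <- ledger$categories
  tot <- ledger$totals
  comb <- ledger$combined
  seqs <- comb$sequence_id
  structs <- unique(tot$structure_label)

  cell <- function(df, value_col, sq, st)
    df[[value_col]][df$sequence_id == sq & df$structure_label == st][1]
  stages <- c(sort(unique(cat_tbl$category)), "total", "normalized_total")
  cols <- expand.grid(structure = structs, sequence = seqs,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  score_matrix <- matrix(NA_real_, nrow = length(stages), ncol = nrow(cols),
                         dimnames = list(stages,
                                         paste(cols$sequence, cols$structure,
                                               sep = ".")))
  for (j in seq_len(nrow(cols))) {
    sq <- cols$sequence[j]; st <- cols$structure[j]
    for (cg in sort(unique(cat_tbl$category)))
      score_matrix[cg, j] <- cat_tbl$category_score[
        cat_tbl$sequence_id == sq & cat_tbl$structure_label == st &
        cat_tbl$category == cg][1]
    score_matrix["total", j] <- cell(tot, "total", sq, st)
    score_matrix["normalized_total", j] <- cell(tot, "normalized_total",
                                                sq, st)
  }

  metric_summaries <- NULL
  if (!is.null(significance)) {
    metric_summaries <- do.call(rbind, lapply(significance, function(r)
      data.frame(metric = r$metric_name, structure = r$structure_label,
                 sequence = r$sequences, branch = r$branch,
                 center = as.numeric(r$center),
                 dispersion = as.numeric(r$dispersion))))
  }

  ord <- order(-comb$combined_normalized)
  if (length(unique(comb$combined_normalized)) == 1L) {
    verdict <- "No sequence is distinguishable: all combined scores tied."
  } else {
    best <- comb$sequence_id[which.max(comb$combined_normalized)]
    verdict <- sprintf(
      "Ranking (best first): %s. Winning sequence: %s (combined normalized score %.3g, combined total %.3g).",
      paste(comb$sequence_id[ord], collapse = " > "), best,
      max(comb$combined_normalized),
      comb$combined_total[which.max(comb$combined_normalized)])
  }
  non_default <- Filter(Negate(is.null), ledger$weights)
  if (length(non_default) > 0)
    verdict <- paste(verdict, "Non-default weights applied:",
                     paste(names(non_default), collapse = ", "), "level.")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(score_matrix),
              file.path(dir, "score_matrix.csv"))
    write.csv(comb, file.path(dir, "combined_scores.csv"),
              row.names = FALSE)
    if (!is.null(metric_summaries))
      write.csv(metric_summaries, file.path(dir, "metric_summaries.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(totals = tot, combined = comb, verdict = verdict),
      file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
    writeLines(verdict, file.path(dir, "verdict.txt"))
  }
  invisible(list(score_matrix = score_matrix,
                 metric_summaries = metric_summaries, verdict = verdict))
}

#' Export pooled metric samples as a tidy table
#'
#' @param samples nested sample list from [compute_metric_samples()].
#' @param path optional CSV path.
#' @return data frame `metric`, `structure_label`, `sequence_id`, `value`
#'   plus provenance columns where available.
#' @export
metrics_table <- function(samples, path = NULL) {
  rows <- list()
  for (metric in names(samples))
    for (g in names(samples[[metric]]))
      for (sq in names(samples[[metric]][[g]])) {
        s <- samples[[metric]][[g]][[sq]]
        df <- data.frame(metric = metric, structure_label = g,
                         sequence_id = sq, value = s$values)
        if ("subject_id" %in% names(s$provenance))
          df$subject_id <- s$provenance$subject_id
        rows[[length(rows) + 1L]] <- df
      }
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(c("metric", "structure_label", "sequence_id", "subject_id",
                "value"), names(r))] <- NA
    r[c("metric", "structure_label", "sequence_id", "subject_id", "value")]
  }))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
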