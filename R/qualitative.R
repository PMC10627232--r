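#' Observer comment metric
#'
#' Net favourable-opinion fraction for a sequence-structure pair:
#' `(#positive - #negative) / #possible`, in `[-1, 1]`. Neutral comments are
#' omitted from the numerator (a neutral baseline opinion is assumed); the
#' denominator is the number of comments that could have been submitted
#' (e.g. the number of commenting observers).
#'
#' @param n_positive,n_negative,n_possible non-negative integer counts with
#'   `n_positive + n_negative <= n_possible` and `n_possible >= 1`.
#' @return scalar in `[-1, 1]`.
#' @export
#' @examples
#' comment_metric(2, 1, 4)   # 0.25
comment_metric <- function(n_positive, n_negative, n_possible) {
  if (any(n_possible < 1)) stop("n_possible must be at least 1")
  if (any(n_positive < 0) || any(n_negative < 0))
    stop("comment counts must be non-negative")
  if (any(n_positive + n_negative > n_possible))
    stop("positive + negative comments exceed the number possible")
  (n_positive - n_negative) / n_possible
}

#' Read the qualitative feedback table
#'
#' Expected columns: `subject_id`, `sequence_id`, `structure_label`,
#' `observer_id`, `grade` (preference rank, 1 = most preferred of the
#' sequences), `comment` in `positive` / `neutral` / `negative` / `none`.
#'
#' @param path CSV path.
#' @return data frame of qualitative records.
#' @export
read_qualitative_csv <- function(path) {
  q <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sequence_id", "structure_label", "observer_id",
            "grade", "comment")
  if (!all(need %in% names(q)))
    stop("qualitative CSV must have columns: ", paste(need, collapse = ", "))
  bad <- !q$comment %in% c("positive", "neutral", "negative", "none")
  if (any(bad))
    stop("unknown comment categories: ",
         paste(unique(q$comment[bad]), collapse = ", "))
  q
}

#' Pooled grade samples per sequence-structure pair
#'
#' Grades are elicited as preference ranks (1 = most preferred of the `S`
#' sequences) and converted to higher-is-better scores
#' `S + 1 - rank` so every metric shares one direction convention in the
#' statistics layer. One value per (observer, subject), so each group's
#' sample size is `observers x subjects`; missing grades are excluded with a
#' warning.
#'
#' @param records qualitative data frame (see [read_qualitative_csv()]).
#' @param n_sequences number of sequences under comparison; default the
#'   number of distinct `sequence_id`s in `records`.
#' @return named list (by sequence, then pooled structure group) of
#'   [metric_sample()]s with metric name `"grade"`.
#' @export
grade_samples <- function(records, n_sequences = NULL) {
  if (is.null(n_sequences))
    n_sequences <- length(unique(records$sequence_id))
  miss <- is.na(records$grade)
  if (any(miss)) {
    warning(sum(miss), " missing grade(s) excluded from pooled samples",
            call. = FALSE)
    records <- records[!miss, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no grades to pool")
  records$group <- structure_group(records$structure_label)
  out <- list()
  for (sq in unique(records$sequence_id)) {
    for (g in unique(records$group)) {
      r <- records[records$sequence_id == sq & records$group == g, ,
                   drop = FALSE]
      if (nrow(r) == 0L) next
      out[[sq]][[g]] <- metric_sample(
        "grade", sq, g, n_sequences + 1 - r$grade,
        data.frame(subject_id = r$subject_id, observer_id = r$observer_id))
    }
  }
  out
}

#' Per-subject comment-metric samples per sequence-structure pair
#'
#' Counts positive and negative comments across observers for each
#' (subject, sequence, structure group) and applies [comment_metric()]. Each
#' record row is one comment opportunity, so the number of possible comments
#' per cell is the number of rows (a `"none"` row marks an observer who
#' submitted no comment but keeps the denominator honest; observers who never
#' comment should simply have no rows). One value per subject, so each
#' group's sample size equals the number of subjects.
#'
#' @inheritParams grade_samples
#' @return named list (by sequence, then pooled structure group) of
#'   [metric_sample()]s with metric name `"comment"`.
#' @export
comment_samples <- function(records) {
  records$group <- structure_group(records$structure_label)
  out <- list()
  for (sq in unique(records$sequence_id)) {
    for (g in unique(records$group)) {
      r <- records[records$sequence_id == sq & records$group == g, ,
                   drop = FALSE]
      if (nrow(r) == 0L) next
      vals <- numeric(0); subj <- character(0)
      for (s in unique(r$subject_id)) {
        rs <- r[r$subject_id == s, , drop = FALSE]
        n_pos <- sum(rs$comment == "positive")
        n_neg <- sum(rs$comment == "negative")
        n_poss <- nrow(rs)
        vals <- c(vals, comment_metric(n_pos, n_neg, n_poss))
        subj <- c(subj, s)
      }
      out[[sq]][[g]] <- metric_sample("comment", sq, g, vals,
                                      data.frame(subject_id = subj))
    }
  }
  out
}
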