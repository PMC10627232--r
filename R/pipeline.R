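#' Compute all pooled metric samples for a study
#'
#' Runs every quantitative metric on each sequence / pooled structure group
#' and attaches the qualitative samples, producing the per-metric,
#' per-group, per-sequence samples the statistics layer consumes. Bilateral
#' structures are pooled (see [structure_group()]); the fat SNR is computed
#' once per sequence under the structure-agnostic group `"fat"`.
#'
#' Sample sizes follow the study bookkeeping: SNR/CNR one value per subject;
#' conspicuity about `inner_fraction x slices x subjects x observers` after
#' filtering; DSC/HD95 about `inner_fraction x subjects x choose(observers,
#' 2)`; grades `observers x subjects`; comment metric one value per subject.
#'
#' @param study a `phantom_study` (from [generate_phantom()] or
#'   [read_study_manifest()]).
#' @param qualitative optional qualitative records data frame.
#' @param inner_fraction inner percentile band for slice/pairwise pooling.
#' @param distances_mm conspicuity morphology distances.
#' @return nested list `samples[[metric]][[group]][[sequence]]` of
#'   [metric_sample()]s.
#' @export
compute_metric_samples <- function(study, qualitative = NULL,
                                   inner_fraction = 0.90,
                                   distances_mm = c(1, 2)) {
  subjects <- names(study$volumes)
  sequences <- names(study$volumes[[subjects[1]]])
  all_structs <- names(study$observer_masks[[subjects[1]]][[sequences[1]]])
  delineated <- setdiff(all_structs, c("fat", "noise"))
  groups <- unique(structure_group(delineated))
  samples <- list()

  group_masks <- function(subj, sq, grp) {
    labs <- delineated[structure_group(delineated) == grp]
    out <- list()
    for (lb in labs) {
      oms <- study$observer_masks[[subj]][[sq]][[lb]]
      for (ob in names(oms)) out[[paste(lb, ob, sep = ":")]] <- oms[[ob]]
    }
    out
  }

  ## ---- intensity metrics: one value per subject -------------------------
  for (sq in sequences) {
    snr_vals <- lapply(groups, function(g) numeric(0))
    names(snr_vals) <- groups
    cnr_fat_vals <- cnr_mus_vals <- snr_vals
    fat_vals <- numeric(0)
    for (subj in subjects) {
      vol <- study$volumes[[subj]][[sq]]
      noise_m <- study$observer_masks[[subj]][[sq]][["noise"]][[1]]
      fat_m <- study$observer_masks[[subj]][[sq]][["fat"]][[1]]
      nsd <- noise_sd(vol, noise_m)
      fat_snr_subj <- mean(vol$intensities[fat_m$voxels]) / nsd
      fat_vals <- c(fat_vals, fat_snr_subj)
      muscle_masks <- group_masks(subj, sq, "pterygoid")
      muscle_snr <- if (length(muscle_masks))
        snr(vol, muscle_masks, noise_m) else NA_real_
      for (g in groups) {
        gm <- group_masks(subj, sq, g)
        s <- snr(vol, gm, noise_m)
        snr_vals[[g]] <- c(snr_vals[[g]], s)
        cnr_fat_vals[[g]] <- c(cnr_fat_vals[[g]], s - fat_snr_subj)
        if (g != "pterygoid" && is.finite(muscle_snr))
          cnr_mus_vals[[g]] <- c(cnr_mus_vals[[g]], s - muscle_snr)
      }
    }
    prov <- data.frame(subject_id = subjects)
    for (g in groups) {
      samples$snr[[g]][[sq]] <-
        metric_sample("snr", sq, g, snr_vals[[g]], prov)
      samples$cnr_fat[[g]][[sq]] <-
        metric_sample("cnr_fat", sq, g, cnr_fat_vals[[g]], prov)
      if (g != "pterygoid")   # CNR of muscle against itself is degenerate
        samples$cnr_muscle[[g]][[sq]] <-
          metric_sample("cnr_muscle", sq, g, cnr_mus_vals[[g]], prov)
    }
    samples$fat_snr[["fat"]][[sq]] <-
      metric_sample("fat_snr", sq, "fat", fat_vals, prov)
  }

  ## ---- conspicuity: slice stack pooled over observers/subjects/sides ----
  for (sq in sequences) for (g in groups) {
    vals <- numeric(0); prov <- list()
    for (subj in subjects) {
      vol <- study$volumes[[subj]][[sq]]
      gm <- group_masks(subj, sq, g)
      for (key in names(gm)) {
        sl <- conspicuity_slices(vol, gm[[key]], distances_mm)
        if (nrow(sl) == 0L) next
        vals <- c(vals, sl$value)
        prov[[length(prov) + 1L]] <- data.frame(
          subject_id = subj, observer_id = key, slice = sl$slice)
      }
    }
    if (length(vals) == 0L)
      stop("no valid conspicuity slice for ", sq, " / ", g)
    samples$conspicuity[[g]][[sq]] <- pool_and_filter(
      metric_sample("conspicuity", sq, g, vals, do.call(rbind, prov)),
      inner_fraction)
  }

  ## ---- pairwise agreement ----------------------------------------------
  for (sq in sequences) for (g in groups) {
    labs <- delineated[structure_group(delineated) == g]
    dvals <- hvals <- numeric(0); prov <- list()
    for (subj in subjects) for (lb in labs) {
      oms <- Filter(function(m) !mask_is_empty(m),
                    study$observer_masks[[subj]][[sq]][[lb]])
      if (length(oms) < 2L) next
      obn <- names(oms)
      pm <- pairwise_surface_metrics(oms)
      dvals <- c(dvals, pm$dsc)
      hvals <- c(hvals, pm$hd95)
      prov[[length(prov) + 1L]] <- data.frame(
        subject_id = subj,
        observer_pair = paste(lb, obn[pm$i], obn[pm$j], sep = "|"))
    }
    if (length(dvals) == 0L)
      stop("no observer pair for ", sq, " / ", g)
    prov <- do.call(rbind, prov)
    samples$dsc[[g]][[sq]] <- pool_and_filter(
      metric_sample("dsc", sq, g, dvals, prov), inner_fraction)
    samples$hd95[[g]][[sq]] <- pool_and_filter(
      metric_sample("hd95", sq, g, hvals, prov), inner_fraction)
  }

  ## ---- qualitative ------------------------------------------------------
  if (!is.null(qualitative)) {
    gr <- grade_samples(qualitative, n_sequences = length(sequences))
    cm <- comment_samples(qualitative)
    for (sq in names(gr)) for (g in names(gr[[sq]]))
      samples$grade[[g]][[sq]] <- gr[[sq]][[g]]
    for (sq in names(cm)) for (g in names(cm[[sq]]))
      samples$comment[[g]][[sq]] <- cm[[sq]][[g]]
  }
  samples
}

#' Run the full scoring pipeline on a study
#'
#' metrics -> pooling -> distribution-adaptive statistics -> significance-
#' gated rubric, producing the score ledger plus every intermediate object.
#'
#' @param study a `phantom_study` or the result of [read_study_manifest()].
#' @param qualitative optional qualitative records data frame (or path to
#'   its CSV).
#' @param alpha significance threshold (default 0.05).
#' @param inner_fraction inner percentile band (default 0.90).
#' @param metric_weights,category_weights,structure_weights optional named
#'   weight vectors (default 1 everywhere).
#' @param gate_omnibus honour pairwise significance only under a significant
#'   omnibus test (default `TRUE`).
#' @param p_adjust_method Dunn multiplicity family (default
#'   `"bonferroni"`).
#' @param distances_mm conspicuity morphology distances.
#' @return object of class `pipeline_result`: `ledger` ([score_ledger()]),
#'   `significance` (list of `significance_result`s), `metric_scores`
#'   (data frame), `samples`, and a `log` data frame of branch choices and
#'   sample sizes.
#' @export
run_pipeline <- function(study, qualitative = NULL, alpha = 0.05,
                         inner_fraction = 0.90, metric_weights = NULL,
                         category_weights = NULL, structure_weights = NULL,
                         gate_omnibus = TRUE,
                         p_adjust_method = "bonferroni",
                         distances_mm = c(1, 2)) {
  if (is.character(qualitative))
    qualitative <- read_qualitative_csv(qualitative)
  samples <- compute_metric_samples(study, qualitative, inner_fraction,
                                    distances_mm)
  cats <- metric_categories()
  groups <- unique(unlist(lapply(samples, names)))
  groups <- setdiff(groups, "fat")

  sig_list <- list()
  rows <- list(); log_rows <- list()
  for (metric in names(samples)) {
    for (g in names(samples[[metric]])) {
      seq_samples <- samples[[metric]][[g]]
      if (length(seq_samples) < 2L) next
      res <- suppressWarnings(pairwise_significance(
        seq_samples, alpha = alpha, p_adjust_method = p_adjust_method,
        gate_omnibus = gate_omnibus, metric_name = metric,
        structure_label = g))
      sig_list[[paste(metric, g, sep = ".")]] <- res
      sc <- gated_rank_scores(res, metric_direction(metric))
      targets <- if (g == "fat") groups else g  # broadcast fat SNR
      for (tg in targets)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = names(sc), structure_label = tg, metric = metric,
          category = unname(cats[[metric]]), score = as.numeric(sc))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        metric = metric, structure = g, branch = res$branch,
        omnibus_p = res$omnibus_p,
        n = paste(vapply(seq_samples, function(s)
          length(if (inherits(s, "metric_sample")) s$values else s),
          integer(1)), collapse = "/"))
    }
  }
  metric_scores <- do.call(rbind, rows)

  cat_rows <- list()
  for (cg in unique(metric_scores$category)) {
    ms <- metric_scores[metric_scores$category == cg, , drop = FALSE]
    cs <- category_scores(ms, metric_weights)
    cs$category <- cg
    cat_rows[[length(cat_rows) + 1L]] <- cs
  }
  category_tbl <- do.call(rbind, cat_rows)
  ledger <- score_ledger(category_tbl, category_weights, structure_weights)

  structure(
    list(ledger = ledger, significance = sig_list,
         metric_scores = metric_scores, samples = samples,
         log = do.call(rbind, log_rows)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$ledger)
  invisible(x)
}
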