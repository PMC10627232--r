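#' Choose the parametric or nonparametric branch for a metric
#'
#' Every sequence's pooled sample is screened for normality with the
#' Kolmogorov-Smirnov test in its Lilliefors form (mean and SD estimated from
#' the sample, as they always are in practice). The parametric branch is taken
#' only when every group passes at `alpha`; a group that is too small to test
#' (n < 5), or constant, forces the nonparametric branch with a warning.
#'
#' @param samples named list (by sequence) of numeric vectors or
#'   [metric_sample()]s.
#' @param alpha normality screen level, default 0.05.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_branch <- function(samples, alpha = 0.05) {
  vals <- sample_values_list(samples)
  if (length(vals) < 2L) stop("need samples for at least 2 sequences")
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) < 5L) {
      warning("group '", nm, "' has fewer than 5 values; ",
              "normality cannot be assessed, using nonparametric branch",
              call. = FALSE)
      return("nonparametric")
    }
    if (sd(v) == 0) return("nonparametric")
    if (nortest::lillie.test(v)$p.value < alpha) return("nonparametric")
  }
  "parametric"
}

#' Omnibus test and corrected pairwise comparisons across sequences
#'
#' The distribution-adaptive significance layer behind rubric scoring. On the
#' parametric branch: one-way ANOVA with Tukey HSD pairwise comparisons, and
#' group means / SDs as central tendencies. On the nonparametric branch:
#' Kruskal-Wallis with Dunn's rank-sum pairwise z tests (tie-corrected) and a
#' multiplicity adjustment over all pairs, and medians / IQRs. Pairwise
#' comparisons are honoured only when the omnibus test is itself significant
#' at `alpha` (the gate); with `gate_omnibus = FALSE` the pairwise p-values
#' stand on their own.
#'
#' @param samples named list (by sequence) of numeric vectors or
#'   [metric_sample()]s; at least 2 groups.
#' @param branch `"parametric"`, `"nonparametric"`, or `NULL` to decide via
#'   [normality_branch()].
#' @param alpha significance threshold, default 0.05.
#' @param p_adjust_method multiplicity family for Dunn's test, default
#'   `"bonferroni"` (any [stats::p.adjust()] method).
#' @param gate_omnibus logical, default `TRUE`.
#' @param metric_name,structure_label provenance tags carried on the result.
#' @return object of class `significance_result` with fields `sequences`,
#'   `branch`, `center` (named: means or medians), `dispersion` (SDs or
#'   IQRs), `omnibus_p`, `p_matrix` (symmetric, `NA` diagonal), `alpha`,
#'   `gate_omnibus`.
#' @export
pairwise_significance <- function(samples, branch = NULL, alpha = 0.05,
                                  p_adjust_method = "bonferroni",
                                  gate_omnibus = TRUE,
                                  metric_name = NA_character_,
                                  structure_label = NA_character_) {
  vals <- sample_values_list(samples)
  k <- length(vals)
  if (k < 2L) stop("need at least 2 sequences")
  if (is.null(branch))
    branch <- suppressWarnings(normality_branch(vals, alpha))
  branch <- match.arg(branch, c("parametric", "nonparametric"))
  seqs <- names(vals)
  x <- unlist(vals, use.names = FALSE)
  g <- factor(rep(seqs, lengths(vals)), levels = seqs)

  pmat <- matrix(NA_real_, k, k, dimnames = list(seqs, seqs))
  if (sd(x) == 0) {
    # fully degenerate: no evidence of any difference
    omnibus_p <- 1
    pmat[] <- 1; diag(pmat) <- NA_real_
    center <- vapply(vals, mean, numeric(1))
    dispersion <- vapply(vals, sd, numeric(1))
  } else if (branch == "parametric") {
    fit <- aov(x ~ g)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    for (r in rownames(tk)) {
      ab <- strsplit(r, "-", fixed = TRUE)[[1]]
      pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tk[r, "p adj"]
    }
    center <- vapply(vals, mean, numeric(1))
    dispersion <- vapply(vals, sd, numeric(1))
  } else {
    kw <- kruskal.test(x, g)
    omnibus_p <- kw$p.value
    pmat <- dunn_test(x, g, p_adjust_method)
    center <- vapply(vals, median, numeric(1))
    dispersion <- vapply(vals, IQR, numeric(1))
  }
  structure(
    list(sequences = seqs, branch = branch, center = center,
         dispersion = dispersion, omnibus_p = omnibus_p, p_matrix = pmat,
         alpha = alpha, gate_omnibus = isTRUE(gate_omnibus),
         metric_name = metric_name, structure_label = structure_label),
    class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<significance_result> %s | %s : %s branch, omnibus p = %.4g\n",
              x$metric_name, x$structure_label, x$branch, x$omnibus_p))
  print(round(x$p_matrix, 4))
  invisible(x)
}

#' Gated pairwise significance matrix
#'
#' Logical matrix saying which sequence pairs differ significantly at the
#' result's `alpha`, honouring the omnibus gate: when the omnibus test is not
#' significant (and gating is on), every pairwise comparison is reported
#' non-significant. Missing p-values count as non-significant.
#'
#' @param result a `significance_result`.
#' @return symmetric logical matrix, diagonal `FALSE`.
#' @export
significance_matrix <- function(result) {
  stopifnot(inherits(result, "significance_result"))
  sig <- !is.na(result$p_matrix) & result$p_matrix < result$alpha
  if (result$gate_omnibus &&
      !(is.finite(result$omnibus_p) && result$omnibus_p < result$alpha))
    sig[] <- FALSE
  diag(sig) <- FALSE
  sig
}

#' Dunn's rank-sum pairwise test
#'
#' Post-hoc z tests on mean ranks after a Kruskal-Wallis omnibus, with the
#' standard tie correction, adjusted for multiplicity over all pairs.
#' Implemented here because no installed package provides it.
#'
#' @param x numeric response vector.
#' @param g grouping factor.
#' @param p_adjust_method [stats::p.adjust()] family, default Bonferroni.
#' @return symmetric matrix of adjusted p-values, `NA` diagonal.
#' @export
dunn_test <- function(x, g, p_adjust_method = "bonferroni") {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  idx <- combn(k, 2)
  z <- p <- numeric(ncol(idx))
  for (c in seq_len(ncol(idx))) {
    i <- idx[1, c]; j <- idx[2, c]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    z[c] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p[c] <- 2 * pnorm(-abs(z[c]))
  }
  p <- pmin(1, p.adjust(p, method = p_adjust_method))
  lev <- levels(g)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (c in seq_len(ncol(idx))) {
    i <- idx[1, c]; j <- idx[2, c]
    pmat[i, j] <- pmat[j, i] <- p[c]
  }
  pmat
}

sample_values_list <- function(samples) {
  vals <- lapply(samples, function(s) {
    if (inherits(s, "metric_sample")) s$values else as.numeric(s)
  })
  if (is.null(names(vals)) || any(names(vals) == ""))
    names(vals) <- paste0("seq", seq_along(vals))
  vals
}
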