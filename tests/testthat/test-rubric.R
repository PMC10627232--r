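test_that("tie rescaling assigns average spanned ranks", {
  expect_equal(rescale_ties(c(4, 2, 2, 1)), c(4, 2.5, 2.5, 1))
  expect_equal(rescale_ties(c(1, 1, 1, 1)), rep(2.5, 4))
  expect_equal(rescale_ties(c(4, 3, 2, 1)), c(4, 3, 2, 1))
  expect_equal(rescale_ties(c(2, 2, 1)), c(2.5, 2.5, 1))
  expect_error(rescale_ties(c(1, NA)), "malformed")
})

test_that("gated rank scores honour the all-above-vs-all-below boundary rule", {
  center <- setNames(c(40, 30, 20, 10), paste0("S", 1:4))
  none <- matrix(FALSE, 4, 4, dimnames = list(names(center), names(center)))
  all_sig <- !diag(4); dimnames(all_sig) <- dimnames(none)

  res_none <- make_sig_result(center, p_from_sig(none))
  expect_equal(as.numeric(gated_rank_scores(res_none)), rep(2.5, 4))

  res_all <- make_sig_result(center, p_from_sig(all_sig))
  expect_equal(as.numeric(gated_rank_scores(res_all)), c(4, 3, 2, 1))

  # best separated from everything, rest indistinguishable
  top_only <- none
  top_only["S1", 2:4] <- top_only[2:4, "S1"] <- TRUE
  res_top <- make_sig_result(center, p_from_sig(top_only))
  sc <- gated_rank_scores(res_top)
  expect_equal(as.numeric(sc), c(4, 2, 2, 2))
  expect_equal(unname(attr(sc, "raw")), c(4, 1, 1, 1))

  # lower-is-better flips the ordering
  res_low <- make_sig_result(center, p_from_sig(all_sig))
  expect_equal(as.numeric(gated_rank_scores(res_low, "lower_better")),
               c(1, 2, 3, 4))
})

test_that("adjacent-only significance cannot split tiers", {
  center <- setNames(c(3, 2, 1), c("A", "B", "C"))
  sig <- matrix(FALSE, 3, 3, dimnames = list(names(center), names(center)))
  sig["A", "B"] <- sig["B", "A"] <- TRUE   # A vs C not significant
  res <- make_sig_result(center, p_from_sig(sig))
  expect_equal(as.numeric(gated_rank_scores(res)), rep(2, 3))
})

test_that("gated scores match the enumeration oracle and conserve rank mass", {
  seqs <- paste0("S", 1:4)
  center <- setNames(c(4, 3, 2, 1), seqs)
  n_pairs <- choose(4, 2)
  pair_idx <- combn(4, 2)
  for (code in 0:(2^n_pairs - 1)) {
    sig <- matrix(FALSE, 4, 4, dimnames = list(seqs, seqs))
    on <- which(bitwAnd(code, 2^(seq_len(n_pairs) - 1)) > 0)
    for (k in on) {
      i <- pair_idx[1, k]; j <- pair_idx[2, k]
      sig[i, j] <- sig[j, i] <- TRUE
    }
    res <- make_sig_result(center, p_from_sig(sig))
    got <- gated_rank_scores(res)
    expect_equal(as.numeric(got), unname(oracle_gated_scores(center, sig)))
    expect_equal(sum(got), 10)   # 4*5/2
  }
})

test_that("adding significance never lowers the upper tier (monotone gating)", {
  seqs <- paste0("S", 1:3)
  center <- setNames(c(3, 2, 1), seqs)
  pair_idx <- combn(3, 2)
  mats <- lapply(0:7, function(code) {
    sig <- matrix(FALSE, 3, 3, dimnames = list(seqs, seqs))
    on <- which(bitwAnd(code, 2^(0:2)) > 0)
    for (k in on) {
      i <- pair_idx[1, k]; j <- pair_idx[2, k]
      sig[i, j] <- sig[j, i] <- TRUE
    }
    sig
  })
  for (a in mats) for (b in mats) {
    if (!all(b[a])) next        # b must contain a's significances
    sa <- gated_rank_scores(make_sig_result(center, p_from_sig(a)))
    sb <- gated_rank_scores(make_sig_result(center, p_from_sig(b)))
    expect_gte(sb[["S1"]], sa[["S1"]])
  }
})

test_that("category, total, and combined aggregation conserve rank mass", {
  tbl <- published_category_table()
  led <- score_ledger(tbl)
  for (st in unique(led$totals$structure_label))
    expect_equal(sum(led$totals$normalized_total[
      led$totals$structure_label == st]), 10)
  expect_equal(sum(led$combined$combined_normalized), 10)

  ms <- data.frame(
    sequence_id = rep(c("A", "B", "C", "D"), 2),
    structure_label = "GTV",
    metric = rep(c("snr", "cnr_fat"), each = 4),
    score = c(4, 2.5, 2.5, 1, 4, 3, 2, 1))
  cs <- category_scores(ms)
  expect_equal(sum(cs$category_score), 10)
  expect_equal(cs$category_score[cs$sequence_id == "A"], 4)
})

test_that("metric weights shift category sums", {
  ms <- data.frame(
    sequence_id = rep(c("A", "B"), 2), structure_label = "GTV",
    metric = rep(c("snr", "fat_snr"), each = 2),
    score = c(2, 1, 1, 2))
  even <- category_scores(ms)
  expect_equal(even$category_score, c(1.5, 1.5))
  up <- category_scores(ms, weights = c(snr = 3))
  expect_equal(up$category_score[up$sequence_id == "A"], 2)
})
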