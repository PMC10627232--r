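test_that("normality screen routes clean Gaussians parametric, others not", {
  set.seed(71)
  gauss <- lapply(1:4, function(i) rnorm(120, mean = i))
  names(gauss) <- paste0("S", 1:4)
  expect_equal(normality_branch(gauss), "parametric")

  bimodal <- gauss
  bimodal$S2 <- c(rnorm(60, -4, 0.3), rnorm(60, 4, 0.3))
  expect_equal(normality_branch(bimodal), "nonparametric")

  tiny <- list(S1 = c(1, 2), S2 = c(2, 3))
  expect_warning(br <- normality_branch(tiny), "fewer than 5")
  expect_equal(br, "nonparametric")
})

test_that("degenerate all-identical groups report no significance", {
  samples <- list(A = rep(2, 10), B = rep(2, 10), C = rep(2, 10))
  res <- pairwise_significance(samples, branch = "parametric")
  expect_equal(res$omnibus_p, 1)
  expect_true(all(res$p_matrix[upper.tri(res$p_matrix)] == 1))
  expect_false(any(significance_matrix(res)))
})

test_that("well-separated groups are detected on both branches", {
  set.seed(72)
  x <- list(A = rnorm(25, 0), B = rnorm(25, 10))
  for (br in c("parametric", "nonparametric")) {
    res <- pairwise_significance(x, branch = br)
    expect_lt(res$p_matrix["A", "B"], 0.05)
    expect_true(significance_matrix(res)["A", "B"])
    expect_equal(res$branch, br)
  }
  # central tendencies follow the branch
  resp <- pairwise_significance(x, branch = "parametric")
  resn <- pairwise_significance(x, branch = "nonparametric")
  expect_equal(resp$center[["A"]], mean(x$A))
  expect_equal(resn$center[["A"]], median(x$A))
})

test_that("p-values are location invariant and permute with labels", {
  set.seed(73)
  x <- list(A = rnorm(20, 0), B = rnorm(20, 1), C = rnorm(20, 2))
  for (br in c("parametric", "nonparametric")) {
    res <- pairwise_significance(x, branch = br)
    shifted <- lapply(x, function(v) v + 137.5)
    res2 <- pairwise_significance(shifted, branch = br)
    expect_equal(res$p_matrix, res2$p_matrix, tolerance = 1e-10)
    perm <- x[c("C", "A", "B")]
    res3 <- pairwise_significance(perm, branch = br)
    expect_equal(res3$p_matrix[names(x), names(x)], res$p_matrix,
                 tolerance = 1e-10)
  }
})

test_that("Dunn z-test for two groups agrees with the Kruskal-Wallis statistic", {
  # with k = 2 groups the squared Dunn z equals the (tie-corrected) KW H,
  # so the unadjusted Dunn p must equal pchisq(H, 1, lower = FALSE)
  set.seed(74)
  for (rep in 1:5) {
    x <- c(rnorm(12), rnorm(15, 0.8))
    x[sample(27, 4)] <- x[1]   # inject ties
    g <- factor(rep(c("A", "B"), c(12, 15)))
    p_dunn <- dunn_test(x, g, p_adjust_method = "none")["A", "B"]
    H <- kruskal.test(x, g)$statistic
    expect_equal(unname(p_dunn),
                 unname(pchisq(H, 1, lower.tail = FALSE)),
                 tolerance = 1e-10)
  }
})

test_that("the omnibus gate suppresses pairwise significance when closed", {
  set.seed(75)
  # one pair nominally significant but omnibus p forced above alpha
  x <- list(A = rnorm(8, 0, 1), B = rnorm(8, 0.2, 1), C = rnorm(8, 0.4, 1))
  res <- pairwise_significance(x, branch = "parametric", gate_omnibus = TRUE)
  if (res$omnibus_p >= res$alpha)
    expect_false(any(significance_matrix(res)))
  res_off <- pairwise_significance(x, branch = "parametric",
                                   gate_omnibus = FALSE)
  expect_equal(any(significance_matrix(res_off)),
               any(res_off$p_matrix < 0.05, na.rm = TRUE))
})
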