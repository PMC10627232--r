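# Fixture builders and brute-force oracles shared across tests.

# Ball (sphere) mask with radius in mm on a grid with given spacing.
ball_mask <- function(grid_dim, spacing_mm, center_vox, radius_mm,
                      label = "GTV", ...) {
  ax <- lapply(1:3, function(k) (seq_len(grid_dim[k]) - center_vox[k]) *
                 spacing_mm[k])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  structure_mask(d2 <= radius_mm^2, spacing_mm, label, ...)
}

# Random connected-ish blob: a ball plus uniform voxel noise, <= max_vox.
random_blob <- function(grid_dim, spacing_mm, rng_radius = c(1.5, 4),
                        label = "GTV") {
  repeat {
    ctr <- sapply(grid_dim, function(n) sample(2:(n - 1), 1))
    r <- runif(1, rng_radius[1], rng_radius[2])
    m <- ball_mask(grid_dim, spacing_mm, ctr, r, label)
    extra <- array(runif(prod(grid_dim)) < 0.02, grid_dim)
    m$voxels <- m$voxels | extra
    if (any(m$voxels)) return(m)
  }
}

# O(n * m) brute-force distance transform.
brute_edt <- function(features, spacing_mm) {
  d <- dim(features)
  feat <- which(features, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(feat) == 0) return(out)
  fx <- feat[, 1] * spacing_mm[1]
  fy <- feat[, 2] * spacing_mm[2]
  fz <- feat[, 3] * spacing_mm[3]
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    dx <- idx[r, 1] * spacing_mm[1] - fx
    dy <- idx[r, 2] * spacing_mm[2] - fy
    dz <- idx[r, 3] * spacing_mm[3] - fz
    out[idx[r, 1], idx[r, 2], idx[r, 3]] <- sqrt(min(dx^2 + dy^2 + dz^2))
  }
  out
}

# Brute-force surface extraction: loop over voxels, face neighbours.
brute_surface <- function(vox) {
  d <- dim(vox)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!vox[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    outside <- apply(nb, 1, function(p)
      any(p < 1) || any(p > d) || !vox[p[1], p[2], p[3]])
    out[i, j, k] <- any(outside)
  }
  out
}

# Brute-force percentile Hausdorff via full pairwise surface distances.
brute_hausdorff <- function(a_vox, b_vox, spacing_mm, prob = 0.95) {
  pa <- which(brute_surface(a_vox), arr.ind = TRUE)
  pb <- which(brute_surface(b_vox), arr.ind = TRUE)
  pa <- sweep(pa, 2, spacing_mm, `*`)
  pb <- sweep(pb, 2, spacing_mm, `*`)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  quantile(c(dab, dba), prob, type = 7, names = FALSE)
}

brute_dice <- function(a_vox, b_vox)
  2 * sum(a_vox & b_vox) / (sum(a_vox) + sum(b_vox))

# Independent oracle for tier scores: enumerate every subset of candidate
# tier boundaries, keep the subsets whose boundaries are all individually
# valid (every member above significant vs every member below), take the
# largest, and score each sequence as the mean bottom-up rank of its tier.
oracle_gated_scores <- function(center, sig, direction = "higher_better") {
  S <- length(center)
  ord <- order(center, decreasing = (direction == "higher_better"))
  valid <- vapply(seq_len(S - 1), function(i)
    all(sig[ord[seq_len(i)], ord[(i + 1):S], drop = FALSE]),
    logical(1))
  best <- integer(0)
  for (code in 0:(2^(S - 1) - 1)) {
    bs <- which(bitwAnd(code, 2^(seq_len(S - 1) - 1)) > 0)
    if (all(valid[bs]) && length(bs) > length(best)) best <- bs
  }
  cuts <- c(0, best, S)
  rank_bottom_up <- S - seq_len(S) + 1   # by ordered position
  scores <- numeric(S)
  for (t in seq_len(length(cuts) - 1)) {
    pos <- (cuts[t] + 1):cuts[t + 1]
    scores[ord[pos]] <- mean(rank_bottom_up[pos])
  }
  names(scores) <- names(center)
  scores
}

# Build a significance_result by hand for rubric tests.
make_sig_result <- function(center, p_matrix, alpha = 0.05,
                            gate_omnibus = FALSE,
                            omnibus_p = 0) {
  seqs <- names(center)
  dimnames(p_matrix) <- list(seqs, seqs)
  structure(list(sequences = seqs, branch = "parametric", center = center,
                 dispersion = setNames(rep(1, length(center)), seqs),
                 omnibus_p = omnibus_p, p_matrix = p_matrix, alpha = alpha,
                 gate_omnibus = gate_omnibus,
                 metric_name = "test", structure_label = "GTV"),
            class = "significance_result")
}

# Symmetric p-matrix from a logical "significant" matrix.
p_from_sig <- function(sig_logical, p_sig = 0.01, p_ns = 0.9) {
  p <- ifelse(sig_logical, p_sig, p_ns)
  diag(p) <- NA_real_
  p
}

# Small fast phantom configuration used across tests.
tiny_phantom_config <- function(seed = 1, sequences = c("NonFS", "SPAIR1"),
                                n_subjects = 2, n_observers = 3, ...) {
  phantom_config(grid_dim = c(44, 44, 28), spacing_mm = c(2, 2, 2),
                 sequences = sequences, n_subjects = n_subjects,
                 n_observers = n_observers, seed = seed, ...)
}

# The published summary score table used by the rubric acceptance checks:
# normalized category scores per sequence x structure.
published_category_table <- function() {
  seqs <- c("NonFS", "SPAIR1", "SPAIR3", "SPAIR4")
  structs <- c("GTV", "LN", "Par", "Pty")
  scores <- list(
    snr_cnr = c(1, 2, 4, 2.5,   3, 2, 2, 2.5,   3, 2, 2, 2.5,  3, 4, 2, 2.5),
    conspicuity = c(1.5, 1, 1, 4, 3.5, 2.5, 3.5, 2.5,
                    1.5, 2.5, 2, 1, 3.5, 4, 3.5, 2.5),
    pairwise_distance = c(2.5, 2, 1, 4, 2.5, 2, 3, 2,
                          2.5, 2, 3, 2, 2.5, 4, 3, 2),
    segmentor = rep(2.5, 16))
  grid <- expand.grid(structure_label = structs, sequence_id = seqs,
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(names(scores), function(cg)
    data.frame(sequence_id = grid$sequence_id,
               structure_label = grid$structure_label,
               category = cg, category_score = scores[[cg]])))
}
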