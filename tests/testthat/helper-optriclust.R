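# Shared fixtures and independent oracles.

# The worked order-preserving matrix: 3 genes x 1 sample x 4 time points,
# rows [2,8,5,3], [0,7,4,1], [1,5,3,2].
op_example_gst <- function() {
  gst_matrix(c(2, 0, 1, 8, 7, 5, 5, 4, 3, 3, 1, 2),
             gene_ids = paste0("g", 1:3), sample_ids = "s1",
             time_labels = paste0("t", 1:4))
}

# random GST matrix (integer-valued so ties occur)
random_gst <- function(N, M, L, max_val = 4L) {
  gst_matrix(sample.int(max_val, N * M * L, replace = TRUE),
             paste0("g", seq_len(N)), paste0("s", seq_len(M)),
             paste0("t", seq_len(L)))
}

# independent oracle: all permutations of 1..n via expand.grid filtering
perms_oracle <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1L, function(r) length(unique(r)) == n), , drop = FALSE]
}

# brute-force Lambda oracle: per subset, group genes by exhaustive pairwise
# comparison of restricted signatures, count the groups, sum over subsets.
brute_lambda <- function(ranks, space) {
  N <- dim(ranks)[1L]
  total <- 0L
  for (J in space$subsets) {
    sig <- function(n) as.integer(ranks[n, J, ])
    assigned <- rep(NA_integer_, N)
    ngrp <- 0L
    for (n in seq_len(N)) {
      placed <- FALSE
      if (n > 1L) for (m in seq_len(n - 1L)) {
        if (identical(sig(n), sig(m))) {
          assigned[n] <- assigned[m]; placed <- TRUE; break
        }
      }
      if (!placed) { ngrp <- ngrp + 1L; assigned[n] <- ngrp }
    }
    total <- total + ngrp
  }
  total
}

# hand-coded ARI from the pairwise contingency table (independent of mclust)
ari_formula <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  np <- choose(length(a), 2)
  expected <- si * sj / np
  (sij - expected) / ((si + sj) / 2 - expected)
}

# does some single permutation of the time columns make every row of the
# (gene*sample) x L value matrix non-decreasing?
has_op_certificate <- function(prof_mat) {
  L <- ncol(prof_mat)
  for (i in seq_len(nrow(perms_oracle(L)))) {
    p <- perms_oracle(L)[i, ]
    if (all(apply(prof_mat[, p, drop = FALSE], 1L,
                  function(r) all(diff(r) >= 0))))
      return(TRUE)
  }
  FALSE
}

# collect a cluster's quantized profiles as a (genes*samples) x L matrix
cluster_profiles <- function(data, rec, delta = NULL) {
  rows <- list()
  for (g in rec$genes) for (s in rec$samples) {
    p <- data[g, s, ]
    if (!is.null(delta)) p <- quantize_profile(p, delta)
    rows[[length(rows) + 1L]] <- p
  }
  do.call(rbind, rows)
}
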