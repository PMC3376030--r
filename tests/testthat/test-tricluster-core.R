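test_that("sample subsets are enumerated completely and in canonical order", {
  sp3 <- enumerate_sample_subsets(3)
  expect_equal(sp3$count, 7L)
  expect_equal(sp3$subsets,
               list(1:3, 1:2, c(1L, 3L), 2:3, 1L, 2L, 3L))
  expect_equal(enumerate_sample_subsets(4)$count, 15L)
  expect_equal(enumerate_sample_subsets(2)$count, 3L)
  expect_equal(enumerate_sample_subsets(1)$count, 1L)
  # j_min trims small subsets: sum over C(M, j) for j >= j_min
  expect_equal(enumerate_sample_subsets(4, j_min = 2)$count,
               choose(4, 2) + choose(4, 3) + choose(4, 4))
  expect_equal(enumerate_sample_subsets(4, j_min = 4)$subsets, list(1:4))
  expect_error(enumerate_sample_subsets(3, j_min = 4), "j_min")
})

test_that("catalog_patterns partitions the genes within every subset", {
  set.seed(21)
  g <- random_gst(12, 3, 3)
  ranks <- build_rank_matrix(g, quantize = FALSE)
  cat_ <- catalog_patterns(ranks, enumerate_sample_subsets(3))
  for (grp in cat_$groups) {
    all_genes <- sort(unlist(grp$genes, use.names = FALSE))
    expect_equal(all_genes, 1:12)  # disjoint and exhaustive
  }
  expect_equal(cat_$Lambda, sum(cat_$h))
  expect_equal(cat_$Gamma, 7L)
})

test_that("degenerate catalogues: identical profiles and the worked matrix", {
  same <- gst_matrix(rep(c(1, 5, 2), each = 8), paste0("g", 1:4),
                     paste0("s", 1:2), paste0("t", 1:3))
  ranks <- build_rank_matrix(same, quantize = FALSE)
  cat_ <- catalog_patterns(ranks, enumerate_sample_subsets(2))
  expect_true(all(cat_$h == 1L))
  expect_equal(cat_$Lambda, cat_$Gamma)

  r2 <- build_rank_matrix(op_example_gst(), quantize = FALSE)
  cat2 <- catalog_patterns(r2, enumerate_sample_subsets(1))
  expect_equal(cat2$Lambda, 1L)
  recs <- form_conserved_triclusters(cat2)
  expect_length(recs, 1L)
  expect_equal(sort(recs[[1]]$genes), paste0("g", 1:3))
  expect_equal(as.integer(recs[[1]]$signature[1, ]), c(1L, 4L, 3L, 2L))
  expect_equal(recs[[1]]$pattern_class, "conserved")
})

test_that("Lambda agrees with the brute-force pairwise grouping oracle", {
  set.seed(22)
  for (i in 1:30) {
    N <- sample(2:20, 1); M <- sample(1:3, 1); L <- sample(2:4, 1)
    g <- random_gst(N, M, L, max_val = 3L)
    ranks <- build_rank_matrix(g, quantize = FALSE)
    space <- enumerate_sample_subsets(M)
    expect_equal(catalog_patterns(ranks, space)$Lambda,
                 brute_lambda(ranks, space))
  }
})

test_that("conserved clusters respect i_min and classify constant patterns", {
  const <- gst_matrix(rep(3, 3 * 2 * 3), paste0("g", 1:3),
                      paste0("s", 1:2), paste0("t", 1:3))
  cat_ <- catalog_patterns(build_rank_matrix(const, delta = 1),
                           enumerate_sample_subsets(2))
  recs <- form_conserved_triclusters(cat_)
  expect_equal(vapply(recs, `[[`, "", "pattern_class"),
               rep("constant", 3L))  # one per subset
  expect_true(all(vapply(recs, function(r) length(r$genes), 0L) == 3L))
  expect_length(form_conserved_triclusters(cat_, i_min = 4), 0L)
})

test_that("gene sets shrink monotonically along superset chains (downward closure)", {
  set.seed(23)
  g <- random_gst(15, 3, 3)
  cat_ <- catalog_patterns(build_rank_matrix(g, quantize = FALSE),
                           enumerate_sample_subsets(3))
  recs <- form_conserved_triclusters(cat_)
  key <- function(r) paste(r$signature[1, ], collapse = "-")
  for (a in recs) for (b in recs) {
    if (key(a) != key(b)) next
    if (length(a$samples) >= length(b$samples)) next
    if (!all(a$samples %in% b$samples)) next
    # b's genes (conserved on the superset) must all appear in a's set
    expect_true(all(b$genes %in% a$genes))
  }
})

test_that("every reported conserved tricluster has an OP certificate", {
  set.seed(24)
  g <- random_gst(10, 2, 3)
  delta <- 0.5
  cat_ <- catalog_patterns(build_rank_matrix(g, delta = delta),
                           enumerate_sample_subsets(2))
  recs <- form_conserved_triclusters(cat_)
  expect_gt(length(recs), 0L)
  for (r in recs)
    expect_true(has_op_certificate(cluster_profiles(g, r, delta = delta)))
})

test_that("cluster memberships are invariant to a consistent time permutation", {
  set.seed(25)
  g <- random_gst(12, 3, 4)
  perm <- c(3L, 1L, 4L, 2L)
  gp <- gst_matrix(as.numeric(unclass(g)[, , perm]), dimnames(g)$gene,
                   dimnames(g)$sample, dimnames(g)$time)
  space <- enumerate_sample_subsets(3)
  memberships <- function(x) {
    recs <- form_conserved_triclusters(
      catalog_patterns(build_rank_matrix(x, quantize = FALSE), space))
    sort(vapply(recs, function(r)
      paste(paste(r$samples, collapse = ","), "::",
            paste(sort(r$genes), collapse = ",")), ""))
  }
  expect_equal(memberships(gp), memberships(g))
})

test_that("derive_divergent reproduces the worked example and its edge cases", {
  sig <- c(1L, 2L, 3L)
  cp <- tricluster_record(paste0("g", 1:4), c("s1", "s2"), paste0("t", 1:3),
                          rbind(sig, sig), "conserved")
  cq <- tricluster_record(paste0("g", 1:2), c("s1", "s2", "s3"),
                          paste0("t", 1:3), rbind(sig, sig, sig), "conserved")
  d <- derive_divergent(cp, cq)
  expect_equal(sort(d$genes), c("g3", "g4"))
  expect_equal(d$samples, "s3")
  expect_equal(d$times, paste0("t", 1:3))
  expect_equal(d$pattern_class, "divergent")

  # all genes extend: empty divergent set
  cp2 <- tricluster_record(paste0("g", 1:2), c("s1", "s2"), paste0("t", 1:3),
                           rbind(sig, sig), "conserved")
  expect_null(derive_divergent(cp2, cq))

  # more than one non-extending sample
  cp1 <- tricluster_record(paste0("g", 1:4), "s1", paste0("t", 1:3),
                           matrix(sig, 1), "conserved")
  d2 <- derive_divergent(cp1, cq)
  expect_equal(sort(d2$genes), c("g3", "g4"))
  expect_equal(sort(d2$samples), c("s2", "s3"))
  expect_equal(nrow(d2$signature), 2L)
  expect_equal(as.integer(d2$signature[2, ]), sig)

  # usage errors: different patterns, non-nested subsets
  other <- tricluster_record(paste0("g", 1:2), c("s1", "s2", "s3"),
                             paste0("t", 1:3),
                             rbind(c(3L, 2L, 1L), c(3L, 2L, 1L),
                                   c(3L, 2L, 1L)), "conserved")
  expect_error(derive_divergent(cp, other), "same")
  expect_error(derive_divergent(cq, cp), "strict subset")
})

test_that("divergent gene sets equal the set-difference oracle on random nests", {
  set.seed(26)
  for (i in 1:20) {
    genes_q <- sample(paste0("g", 1:20), sample(2:6, 1))
    extra <- sample(setdiff(paste0("g", 1:20), genes_q), sample(0:5, 1))
    genes_p <- c(genes_q, extra)
    sig <- sample.int(3)
    cp <- tricluster_record(genes_p, c("s1", "s2"), paste0("t", 1:3),
                            rbind(sig, sig), "conserved")
    cq <- tricluster_record(genes_q, c("s1", "s2", "s4"), paste0("t", 1:3),
                            rbind(sig, sig, sig), "conserved")
    d <- derive_divergent(cp, cq)
    if (length(extra) == 0L) {
      expect_null(d)
    } else {
      expect_equal(sort(d$genes), sort(extra))
      expect_equal(d$samples, "s4")
    }
  }
})

test_that("unique_to_subset subtracts every strict superset", {
  # gene gS1 changes only in s1; gene gALL changes identically everywhere;
  # gene gFLAT never changes
  N <- 5; M <- 2; L <- 3
  vals <- array(0, c(N, M, L))
  vals[1, 1, ] <- c(0, 5, 9)      # gS1 in s1: rising
  vals[1, 2, ] <- c(4, 4, 4)      # gS1 flat in s2
  for (m in 1:2) vals[2, m, ] <- c(0, 5, 9)  # gALL rises everywhere
  vals[3, , ] <- 1                # gFLAT constant
  vals[4, 1, ] <- c(9, 5, 0); vals[4, 2, ] <- c(0, 5, 9)  # opposite trends
  vals[5, 1, ] <- c(2, 2, 2); vals[5, 2, ] <- c(9, 0, 5)
  g <- gst_matrix(vals, c("gS1", "gALL", "gFLAT", "gOPP", "gS2"),
                  c("s1", "s2"), paste0("t", 1:3))
  cat_ <- catalog_patterns(build_rank_matrix(g, quantize = FALSE),
                           enumerate_sample_subsets(2))
  u1 <- unique_to_subset(cat_, "s1")
  expect_true("gS1" %in% u1)
  expect_true("gOPP" %in% u1)      # changes in s1, differently in s2
  expect_false("gALL" %in% u1)     # conserved in the superset {s1,s2}
  expect_false("gFLAT" %in% u1)    # constant patterns are not "changed"
  expect_false("gS2" %in% u1)
  expect_true("gS2" %in% unique_to_subset(cat_, "s2"))
  expect_equal(unique_to_subset(cat_, c("s1", "s2")), "gALL")
  expect_error(unique_to_subset(cat_, "sX"), "unknown")

  # single-sample data: no supersets, so all non-constant genes are unique
  g1 <- gst_matrix(vals[, 1, , drop = FALSE], dimnames(g)$gene, "s1",
                   paste0("t", 1:3))
  cat1 <- catalog_patterns(build_rank_matrix(g1, quantize = FALSE),
                           enumerate_sample_subsets(1))
  expect_equal(sort(unique_to_subset(cat1, "s1")),
               sort(c("gS1", "gALL", "gOPP")))
})

test_that("runtime grows roughly linearly in the number of genes", {
  space <- enumerate_sample_subsets(3)
  t_for <- function(N) {
    set.seed(27)
    g <- random_gst(N, 3, 3)
    system.time({
      catalog_patterns(build_rank_matrix(g, quantize = FALSE), space)
    })[["elapsed"]]
  }
  t1 <- t_for(400); t2 <- t_for(3200)
  # 8x the genes should cost far less than ~8x^2; loose trend check only
  expect_lt(t2, 64 * max(t1, 0.02))
})
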