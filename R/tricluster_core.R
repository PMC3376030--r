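# all permutations of 1..n as an n! x n matrix (n is small: L <= ~8)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  k <- 0L
  for (i in seq_len(n)) {
    rows <- k + seq_len(nrow(sub))
    out[rows, i] <- n
    out[rows, -i] <- sub
    k <- k + nrow(sub)
  }
  out
}

#' Enumerate the biological sample-subset space
#'
#' The sample space \eqn{\Omega} is the set of all subsets of the M
#' samples with at least \code{j_min} members; its cardinality is
#' \eqn{\Gamma = \sum_{j = j_{min}}^{M} \binom{M}{j}} (\eqn{2^M - 1} when
#' \code{j_min = 1}). Subsets are listed in a deterministic order: by
#' decreasing size, then lexicographically by sample index.
#'
#' @param M number of biological samples (>= 1).
#' @param j_min minimum subset size (default 1).
#' @return An object of class \code{sample_subset_space}: a list with
#'   \code{subsets} (list of integer index vectors), \code{count}
#'   (\eqn{\Gamma}), \code{M} and \code{j_min}.
#' @examples
#' enumerate_sample_subsets(3)$count  # 7
#' @export
enumerate_sample_subsets <- function(M, j_min = 1L) {
  if (!is.numeric(M) || M < 1L) stop("M must be >= 1", call. = FALSE)
  if (j_min < 1L || j_min > M)
    stop("j_min must satisfy 1 <= j_min <= M", call. = FALSE)
  M <- as.integer(M); j_min <- as.integer(j_min)
  subsets <- list()
  for (sz in seq(M, j_min)) {
    cmb <- utils::combn(M, sz)
    subsets <- c(subsets, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  structure(list(subsets = subsets, count = length(subsets),
                 M = M, j_min = j_min),
            class = "sample_subset_space")
}

#' @export
print.sample_subset_space <- function(x, ...) {
  cat(sprintf("sample_subset_space: M = %d, j_min = %d, Gamma = %d\n",
              x$M, x$j_min, x$count))
  invisible(x)
}

#' Catalogue the distinct rank signatures in every sample subset
#'
#' For each subset \eqn{\Omega_i} of the sample space, genes are grouped
#' by exact equality of their restricted 2D rank signature (the tuple of
#' per-sample rank vectors over the subset's samples, in subset order).
#' \eqn{h_i} is the number of distinct signatures in subset \eqn{i} and
#' \eqn{\Lambda = \sum_i h_i} is the exact total number of
#' order-preserving triclusters in the data. Within every subset the
#' signature groups partition the gene set.
#'
#' @param ranks a \code{rank_matrix} from \code{\link{build_rank_matrix}}.
#' @param space a \code{\link{enumerate_sample_subsets}} result with the
#'   same M as \code{ranks}.
#' @return An object of class \code{pattern_catalog}: per-subset signature
#'   groups plus \code{h}, \code{Gamma} and \code{Lambda}.
#' @export
catalog_patterns <- function(ranks, space) {
  stopifnot(inherits(ranks, "rank_matrix"),
            inherits(space, "sample_subset_space"))
  d <- dim(ranks)
  if (space$M != d[2L])
    stop("subset space is over ", space$M, " samples but the rank matrix has ",
         d[2L], call. = FALSE)
  N <- d[1L]; M <- d[2L]; L <- d[3L]
  # per-sample rank strings, computed once
  rs <- matrix("", N, M)
  for (m in seq_len(M))
    rs[, m] <- apply(matrix(ranks[, m, ], nrow = N), 1L, paste, collapse = "-")
  flat <- paste(rep(1L, L), collapse = "-")  # the all-ties (constant) vector
  groups <- vector("list", space$count)
  h <- integer(space$count)
  subset_names <- character(space$count)
  sids <- dimnames(ranks)[["sample"]]
  for (i in seq_len(space$count)) {
    J <- space$subsets[[i]]
    key <- do.call(paste, c(lapply(J, function(m) rs[, m]), list(sep = "|")))
    g <- split(seq_len(N), key)
    # deterministic: larger groups first, then signature string
    g <- g[order(-lengths(g), names(g))]
    rows1 <- vapply(strsplit(names(g), "|", fixed = TRUE), `[[`, "", 1L)
    conserved <- vapply(strsplit(names(g), "|", fixed = TRUE),
                        function(r) length(unique(r)) == 1L, NA)
    groups[[i]] <- list(genes = g, conserved = conserved,
                        constant = conserved & rows1 == flat)
    h[i] <- length(g)
    subset_names[i] <- paste(sids[J], collapse = ",")
  }
  names(groups) <- subset_names
  structure(list(space = space, groups = groups, h = h,
                 Gamma = space$count, Lambda = sum(h),
                 gene_ids = dimnames(ranks)[["gene"]], sample_ids = sids,
                 time_labels = dimnames(ranks)[["time"]]),
            class = "pattern_catalog")
}

#' @export
print.pattern_catalog <- function(x, ...) {
  cat(sprintf("pattern_catalog: Gamma = %d subsets, Lambda = %d distinct OP patterns\n",
              x$Gamma, x$Lambda))
  invisible(x)
}

parse_signature <- function(key) {
  rows <- strsplit(key, "|", fixed = TRUE)[[1L]]
  t(vapply(rows,
           function(r) as.integer(strsplit(r, "-", fixed = TRUE)[[1L]]),
           integer(length(strsplit(rows[1L], "-", fixed = TRUE)[[1L]]))))
}

#' Form conserved (and constant) triclusters from a pattern catalogue
#'
#' A conserved tricluster is a (subset, signature) group whose per-sample
#' rank vectors are all identical: its genes follow the same temporal
#' pattern in every sample of the subset. When that shared vector is flat
#' the pattern is constant (no temporal change). Groups with fewer than
#' \code{i_min} genes are dropped. This enumeration is exhaustive: every
#' conserved tricluster with at least \code{i_min} genes over a subset of
#' the space is reported.
#'
#' @param catalog a \code{\link{catalog_patterns}} result.
#' @param i_min minimum number of genes in a reported tricluster.
#' @param include_general also report groups whose 2D signature rows
#'   differ across samples (class \code{"general"}); default FALSE.
#' @return list of \code{\link{tricluster_record}}s, ordered by subset
#'   size (desc), gene count (desc), then signature.
#' @export
form_conserved_triclusters <- function(catalog, i_min = 1L,
                                       include_general = FALSE) {
  stopifnot(inherits(catalog, "pattern_catalog"))
  if (i_min < 1L) stop("i_min must be >= 1", call. = FALSE)
  recs <- list()
  for (i in seq_along(catalog$groups)) {
    J <- catalog$space$subsets[[i]]
    grp <- catalog$groups[[i]]
    for (k in seq_along(grp$genes)) {
      if (length(grp$genes[[k]]) < i_min) next
      if (!grp$conserved[k] && !include_general) next
      cls <- if (grp$constant[k]) "constant"
             else if (grp$conserved[k]) "conserved"
             else "general"
      recs[[length(recs) + 1L]] <- tricluster_record(
        genes = catalog$gene_ids[grp$genes[[k]]],
        samples = catalog$sample_ids[J],
        times = catalog$time_labels,
        signature = parse_signature(names(grp$genes)[k]),
        pattern_class = cls)
    }
  }
  if (length(recs)) {
    ord <- order(-vapply(recs, function(r) length(r$samples), 0L),
                 -vapply(recs, function(r) length(r$genes), 0L),
                 vapply(recs, function(r) sig_string(r$signature), ""))
    recs <- recs[ord]
  }
  recs
}

#' Derive the divergent pattern between two nested conserved triclusters
#'
#' Given two conserved triclusters with the same shared rank pattern,
#' \eqn{C_p} on sample subset \eqn{J_p} and \eqn{C_q} on a strict superset
#' \eqn{J_q \supsetneq J_p}, the divergent pattern is
#' \eqn{D = \{I_p \setminus I_q,\; J_q \setminus J_p,\; T\}}: the genes
#' that follow the pattern on \eqn{J_p} but fail to extend it to the extra
#' samples, i.e. behave differently there.
#'
#' @param cluster_p,cluster_q \code{\link{tricluster_record}}s of class
#'   conserved or constant sharing the same rank vector, with
#'   \code{cluster_p}'s samples a strict subset of \code{cluster_q}'s.
#' @return A \code{\link{tricluster_record}} of class \code{"divergent"},
#'   or \code{NULL} when every gene of \eqn{C_p} extends
#'   (\eqn{I_p \setminus I_q = \emptyset}).
#' @export
derive_divergent <- function(cluster_p, cluster_q) {
  stopifnot(inherits(cluster_p, "tricluster_record"),
            inherits(cluster_q, "tricluster_record"))
  if (!identical(cluster_p$signature[1L, ], cluster_q$signature[1L, ]))
    stop("divergent derivation compares only triclusters with the same ",
         "rank pattern", call. = FALSE)
  if (!all(cluster_p$samples %in% cluster_q$samples) ||
      length(cluster_p$samples) >= length(cluster_q$samples))
    stop("cluster_p's samples must be a strict subset of cluster_q's",
         call. = FALSE)
  genes <- setdiff(cluster_p$genes, cluster_q$genes)
  if (length(genes) == 0L) return(NULL)
  extra <- setdiff(cluster_q$samples, cluster_p$samples)
  shared <- cluster_p$signature[1L, ]
  tricluster_record(genes, samples = extra, times = cluster_p$times,
                    signature = matrix(shared, nrow = length(extra),
                                       ncol = length(shared), byrow = TRUE),
                    pattern_class = "divergent")
}

#' Derive all divergent patterns from a set of conserved triclusters
#'
#' Compares every pair of same-pattern conserved/constant records whose
#' sample subsets are strictly nested and collects the non-empty divergent
#' sets. Only same-pattern pairs are compared, which keeps this step cheap.
#'
#' @param records list of \code{\link{tricluster_record}}s (classes other
#'   than conserved/constant are ignored).
#' @return list of divergent \code{\link{tricluster_record}}s.
#' @export
derive_all_divergent <- function(records) {
  keep <- vapply(records, function(r)
    r$pattern_class %in% c("conserved", "constant"), NA)
  records <- records[keep]
  if (length(records) < 2L) return(list())
  pat <- vapply(records, function(r) paste(r$signature[1L, ], collapse = "-"), "")
  out <- list()
  for (p in unique(pat)) {
    grp <- records[pat == p]
    sz <- vapply(grp, function(r) length(r$samples), 0L)
    for (a in seq_along(grp)) for (b in seq_along(grp)) {
      if (sz[a] >= sz[b]) next
      if (!all(grp[[a]]$samples %in% grp[[b]]$samples)) next
      d <- derive_divergent(grp[[a]], grp[[b]])
      if (!is.null(d)) out[[length(out) + 1L]] <- d
    }
  }
  out
}

coherent_gene_idx <- function(catalog, i, include_constant = FALSE) {
  grp <- catalog$groups[[i]]
  keep <- grp$conserved & (include_constant | !grp$constant)
  if (!any(keep)) return(integer())
  sort(unlist(grp$genes[keep], use.names = FALSE))
}

#' Genes whose temporal change is unique to one sample subset
#'
#' Returns the genes that change coherently (identical non-constant rank
#' vector across all samples of \code{subset}) within \code{subset} but do
#' not do so in any strict superset of it — the genes whose response is
#' specific to exactly that combination of samples. Constant patterns are
#' excluded: an unchanged gene is not "affected" in any sample.
#'
#' @param catalog a \code{\link{catalog_patterns}} result built over a
#'   space that contains \code{subset} and its supersets.
#' @param subset character vector of sample ids (or integer indices).
#' @return character vector of gene ids.
#' @export
unique_to_subset <- function(catalog, subset) {
  stopifnot(inherits(catalog, "pattern_catalog"))
  if (is.numeric(subset)) subset <- catalog$sample_ids[subset]
  if (!all(subset %in% catalog$sample_ids))
    stop("unknown sample id(s): ",
         paste(setdiff(subset, catalog$sample_ids), collapse = ", "),
         call. = FALSE)
  idx <- match(list(sort(match(subset, catalog$sample_ids))),
               lapply(catalog$space$subsets, sort))
  if (is.na(idx))
    stop("subset {", paste(subset, collapse = ","),
         "} is not part of the enumerated sample space", call. = FALSE)
  own <- coherent_gene_idx(catalog, idx)
  J <- catalog$space$subsets[[idx]]
  super <- which(vapply(catalog$space$subsets, function(s)
    length(s) > length(J) && all(J %in% s), NA))
  for (i in super) own <- setdiff(own, coherent_gene_idx(catalog, i))
  catalog$gene_ids[own]
}
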