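#' Binomial tail probability for an order-preserving tricluster
#'
#' Under the null of L independent, identically distributed (uniform) time
#' points, a random gene-sample profile supports a given order-preserving
#' pattern with probability \eqn{p = 1/L!}. With genes independent, the
#' probability that at least I of N genes support the pattern is the
#' I-tail of the Binomial(N, 1/L!) distribution,
#' \eqn{P(X \ge I) = \sum_{n=I}^{N} \binom{N}{n} p^n (1-p)^{N-n}}.
#' Computed via the survival form of \code{\link[stats]{pbinom}}, which is
#' numerically stable up to very large N.
#'
#' @param N total number of genes in the dataset.
#' @param I tricluster gene count, 0 <= I <= N.
#' @param L number of time points (>= 1).
#' @return the tail probability, in [0, 1].
#' @examples
#' binomial_tail(3, 2, 2)  # 0.5
#' @export
binomial_tail <- function(N, I, L) {
  if (I < 0L || I > N) stop("need 0 <= I <= N", call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (I == 0L) return(1)
  p <- 1 / factorial(L)
  stats::pbinom(I - 1L, N, p, lower.tail = FALSE)
}

#' Significance upper bound Z(I, J, L) for a tricluster
#'
#' Since there are \eqn{L!} possible order-preserving patterns over L time
#' points, \eqn{Z(I,J,L) = J \cdot L! \cdot P(X \ge I)} is an upper bound
#' on the probability that a random N x M x L dataset contains an
#' order-preserving tricluster with at least I genes and J samples. It is
#' a union bound, so it can exceed 1; \code{z_capped} = min(Z, 1) is also
#' reported as a conservative p-value-like score. The most significant
#' tricluster is the one with the smallest Z.
#'
#' @inheritParams binomial_tail
#' @param J tricluster sample count (>= 1).
#' @return An object of class \code{significance_result}: a list with
#'   \code{tail_prob}, \code{z_bound}, \code{z_capped} and \code{params}.
#' @examples
#' z_bound(3, 2, 1, 2)$z_bound  # 1
#' @export
z_bound <- function(N, I, J, L) {
  if (J < 1L) stop("J must be >= 1", call. = FALSE)
  tail <- binomial_tail(N, I, L)
  z <- J * factorial(L) * tail
  structure(list(tail_prob = tail, z_bound = z, z_capped = min(z, 1),
                 params = list(N = N, I = I, J = J, L = L)),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("Z(I=%d, J=%d, L=%d | N=%d) = %.4g (tail %.4g, capped %.4g)\n",
              x$params$I, x$params$J, x$params$L, x$params$N,
              x$z_bound, x$tail_prob, x$z_capped))
  invisible(x)
}

#' Attach Z significance bounds to tricluster records
#'
#' Computes \code{\link{z_bound}} for every record using its gene and
#' sample counts and stores the (uncapped) bound in the record's
#' \code{z_bound} field. Optionally applies a Bonferroni factor equal to
#' the number of records — an extension beyond the basic bound, off by
#' default.
#'
#' @param records list of \code{\link{tricluster_record}}s.
#' @param N total number of genes in the mined dataset.
#' @param L number of time points.
#' @param bonferroni multiply each bound by \code{length(records)}.
#' @return the records, with \code{z_bound} filled in.
#' @export
attach_significance <- function(records, N, L, bonferroni = FALSE) {
  k <- if (bonferroni) length(records) else 1
  lapply(records, function(r) {
    r$z_bound <- k * z_bound(N, length(r$genes), length(r$samples), L)$z_bound
    r
  })
}
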