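#' Quantize a time profile on a delta-grid
#'
#' The range \eqn{[b_0, b_E]} of the profile (its min and max) is divided
#' into \eqn{E = \lceil (b_E - b_0)/\delta \rceil} intervals of width
#' \eqn{\delta}, with boundaries \eqn{b_e = b_0 + e\delta}. Each value
#' falling in \eqn{[b_{e-1}, b_e)} (the last interval closed on the right)
#' is replaced by the interval centroid
#' \eqn{\alpha_e = (b_{e-1} + b_e)/2}, so no value moves by more than
#' \eqn{\delta/2}. Differences smaller than \eqn{\delta} are thereby
#' absorbed before ranking, which is how the method copes with measurement
#' noise: \eqn{\delta} is the minimum expression change treated as real.
#'
#' A zero-range (constant) profile is already quantized and is returned
#' unchanged (degenerate single interval).
#'
#' @param profile numeric vector of length L >= 2, one expression value per
#'   time point.
#' @param delta ranking threshold \eqn{\delta > 0}, in the units of the
#'   expression values (e.g. log2 units).
#' @return numeric vector of length L of interval centroids.
#' @examples
#' quantize_profile(c(0, 1, 2, 3), delta = 1)   # 0.5 1.5 2.5 2.5
#' quantize_profile(c(1.5, 3, 0.5), delta = 1)  # 2 3 1
#' @export
quantize_profile <- function(profile, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
    stop("delta must be a single positive number", call. = FALSE)
  if (length(profile) < 2L)
    stop("profile needs at least 2 time points", call. = FALSE)
  if (!all(is.finite(profile)))
    stop("profile contains non-finite values", call. = FALSE)
  b0 <- min(profile); bE <- max(profile)
  if (bE == b0) return(profile)
  E <- ceiling((bE - b0) / delta)
  bounds <- b0 + (0:E) * delta
  e <- findInterval(profile, bounds, rightmost.closed = TRUE)
  e[e > E] <- E  # guard: bE can sit on the nominal last boundary
  (bounds[e] + bounds[e + 1L]) / 2
}

#' Dense ranks of a time profile
#'
#' Returns the rank of each value in ascending order, with dense ranking:
#' the smallest value gets rank 1, tied values share a rank, and the next
#' distinct value gets the next integer, so the ranks used are exactly
#' \eqn{1, \dots, d} for \eqn{d} distinct values. The result depends only
#' on the ordering and tie structure of the input, hence is invariant to
#' adding a constant or positive scaling.
#'
#' @param profile numeric vector of length L >= 2, finite values.
#' @return integer vector of dense ranks.
#' @examples
#' rank_profile(c(2, 8, 5, 3))    # 1 4 3 2
#' rank_profile(c(0.5, 3, 0.5))   # 1 2 1
#' @export
rank_profile <- function(profile) {
  if (length(profile) < 2L)
    stop("profile needs at least 2 time points", call. = FALSE)
  if (!all(is.finite(profile)))
    stop("profile contains non-finite values", call. = FALSE)
  match(profile, sort(unique(profile)))
}

#' Build the 3D rank matrix of a GST matrix
#'
#' Applies \code{\link{quantize_profile}} (optionally) followed by
#' \code{\link{rank_profile}} to every (gene, sample) time profile
#' independently, yielding the integer array \eqn{R = \{r_{nml}\}} on which
#' all pattern mining operates. Two profiles belong to the same
#' order-preserving pattern exactly when their rank vectors are identical.
#'
#' @param data a \code{\link{gst_matrix}}.
#' @param delta ranking threshold passed to \code{\link{quantize_profile}};
#'   required when \code{quantize = TRUE}.
#' @param quantize apply delta-grid quantization before ranking
#'   (default TRUE). Quantization is optional in the method; disable it to
#'   rank the raw values.
#' @return A \code{rank_matrix}: integer array with the same dimensions and
#'   dimnames as \code{data}, ranks in 1..L.
#' @export
build_rank_matrix <- function(data, delta = NULL, quantize = TRUE) {
  stopifnot(inherits(data, "gst_matrix"))
  if (quantize && is.null(delta))
    stop("delta is required when quantize = TRUE (it is data-dependent; ",
         "inspect the distribution of your expression values)", call. = FALSE)
  d <- dim(data)
  r <- array(NA_integer_, dim = d, dimnames = dimnames(data))
  for (m in seq_len(d[2L])) {
    prof <- matrix(data[, m, ], nrow = d[1L])  # N x L slice for sample m
    for (n in seq_len(d[1L])) {
      p <- prof[n, ]
      if (quantize) p <- quantize_profile(p, delta)
      r[n, m, ] <- rank_profile(p)
    }
  }
  structure(r, class = c("rank_matrix", "array"),
            delta = if (quantize) delta else NA_real_, quantized = quantize)
}

#' @export
print.rank_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("rank_matrix: %d genes x %d samples x %d time points%s\n",
              d[1], d[2], d[3],
              if (isTRUE(attr(x, "quantized")))
                sprintf(" (quantized, delta = %g)", attr(x, "delta")) else ""))
  invisible(x)
}
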