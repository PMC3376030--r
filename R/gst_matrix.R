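#' Construct a gene-sample-time (GST) expression matrix
#'
#' A GST matrix is the 3D container \eqn{A = \{a_{nml}\}} holding the
#' expression level of gene \eqn{n} in biological sample \eqn{m} at time
#' point \eqn{l}. It is stored as an N x M x L numeric array with
#' dimnames \code{(gene, sample, time)}; the time dimension keeps the
#' experimental order exactly as supplied and is never reordered.
#'
#' @param values numeric array or vector with N*M*L entries, indexed
#'   (gene, sample, time).
#' @param gene_ids character vector of N unique gene/probe identifiers.
#' @param sample_ids character vector of M unique sample identifiers.
#' @param time_labels vector of L (>= 2) unique time labels in
#'   experimental order; coerced to character.
#' @return An object of class \code{gst_matrix}: a named 3D array.
#' @examples
#' g <- gst_matrix(1:12, paste0("g", 1:2), paste0("s", 1:2), c("t1", "t2", "t3"))
#' dim(g)
#' @export
gst_matrix <- function(values, gene_ids, sample_ids, time_labels) {
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  time_labels <- as.character(time_labels)
  N <- length(gene_ids); M <- length(sample_ids); L <- length(time_labels)
  if (N < 1L || M < 1L || L < 2L)
    stop("need at least 1 gene, 1 sample and 2 time points", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(time_labels)) stop("duplicate time labels", call. = FALSE)
  if (length(values) != N * M * L)
    stop(sprintf("values has %d entries, expected %d (= %d x %d x %d)",
                 length(values), N * M * L, N, M, L), call. = FALSE)
  a <- array(as.numeric(values), dim = c(N, M, L),
             dimnames = list(gene = gene_ids, sample = sample_ids,
                             time = time_labels))
  structure(a, class = c("gst_matrix", "array"))
}

#' @export
print.gst_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("gst_matrix: %d genes x %d samples x %d time points\n",
              d[1], d[2], d[3]))
  cat("samples:", paste(dimnames(x)$sample, collapse = ", "), "\n")
  cat("times:  ", paste(dimnames(x)$time, collapse = ", "), "\n")
  invisible(x)
}

gene_ids <- function(x) dimnames(x)[["gene"]]
sample_ids <- function(x) dimnames(x)[["sample"]]
time_labels <- function(x) dimnames(x)[["time"]]

#' Read a GST matrix from a tab-delimited file
#'
#' The expected layout is one header row and one row per gene: the first
#' column holds the gene identifier, every other column is named
#' \code{<sample><sep><time>} (default separator \code{":"}). The M x L
#' column grid must be complete and every sample must list its time points
#' in the same order; the order of first appearance defines the sample
#' order and the time order of the returned matrix.
#'
#' @param path path to a tab-delimited text file.
#' @param layout \code{"sample.time"} (default) when the token before the
#'   separator is the sample, \code{"time.sample"} for the reverse.
#' @param sep_header separator between the sample and time tokens in the
#'   value-column names.
#' @param impute if \code{TRUE}, a missing entry is replaced by the mean of
#'   the remaining values of the same (gene, sample) time profile; by
#'   default missing values are an error (the method never invents data
#'   silently).
#' @return A \code{\link{gst_matrix}}.
#' @export
read_gst <- function(path, layout = c("sample.time", "time.sample"),
                     sep_header = ":", impute = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 3L) stop("expected a gene-id column plus sample:time columns",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cols <- colnames(df)[-1L]
  parts <- strsplit(cols, sep_header, fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed value-column name (expected <sample>", sep_header,
         "<time>): ", cols[bad][1L], call. = FALSE)
  smp <- vapply(parts, `[[`, "", if (layout == "sample.time") 1L else 2L)
  tim <- vapply(parts, `[[`, "", if (layout == "sample.time") 2L else 1L)
  samples <- unique(smp)
  times <- tim[smp == samples[1L]]
  if (anyDuplicated(times))
    stop("duplicate time point for sample ", samples[1L], call. = FALSE)
  # every sample must carry the identical ordered time series
  for (s in samples) {
    ts <- tim[smp == s]
    if (!identical(ts, times)) {
      miss <- setdiff(times, ts)
      off <- if (length(miss)) paste0(s, sep_header, miss[1L])
             else paste0(s, sep_header, setdiff(ts, times)[1L])
      stop("sample/time grid mismatch at column ", off,
           " (every sample needs the same ordered time series)",
           call. = FALSE)
    }
  }
  if (length(cols) != length(samples) * length(times))
    stop("incomplete sample/time grid: ", length(cols), " value columns for ",
         length(samples), " samples x ", length(times), " times",
         call. = FALSE)
  vals <- array(NA_real_, c(length(ids), length(samples), length(times)))
  for (k in seq_along(cols)) {
    v <- df[[k + 1L]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    vals[, match(smp[k], samples), match(tim[k], times)] <- v
  }
  if (anyNA(vals)) {
    if (!impute) {
      w <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value for gene %s, sample %s, time %s %s",
                   ids[w[1L]], samples[w[2L]], times[w[3L]],
                   "(use impute = TRUE for profile-mean imputation)"),
           call. = FALSE)
    }
    for (n in seq_along(ids)) for (m in seq_along(samples)) {
      p <- vals[n, m, ]
      if (anyNA(p)) {
        if (all(is.na(p)))
          stop(sprintf("all values missing for gene %s, sample %s",
                       ids[n], samples[m]), call. = FALSE)
        p[is.na(p)] <- mean(p, na.rm = TRUE)
        vals[n, m, ] <- p
      }
    }
  }
  gst_matrix(vals, ids, samples, times)
}

#' Write a GST matrix as a tab-delimited file
#'
#' Inverse of \code{\link{read_gst}}: columns are written sample-major
#' (\code{s1:t1 s1:t2 ... s2:t1 ...}) with full floating-point precision so
#' a write/read round trip reproduces the values bit-exactly.
#'
#' @param data a \code{\link{gst_matrix}}.
#' @param path output file path.
#' @param sep_header separator between sample and time in column names.
#' @export
write_gst <- function(data, path, sep_header = ":") {
  stopifnot(inherits(data, "gst_matrix"))
  d <- dim(data)
  hdr <- c("id", as.vector(t(outer(sample_ids(data), time_labels(data),
                                   paste, sep = sep_header))))
  flat <- flatten_gst(data)
  lines <- c(paste(hdr, collapse = "\t"),
             vapply(seq_len(d[1L]), function(n) {
               paste(c(gene_ids(data)[n], sprintf("%.17g", flat[n, ])),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Flatten a GST matrix to the N x (M*L) 2D form
#'
#' Converts the 3D array into the two-dimensional gene x (sample, time)
#' matrix used to feed conventional 2D clustering algorithms (for example
#' k-means on the flattened profiles). Columns are sample-major and named
#' \code{<sample>:<time>}.
#'
#' @param data a \code{\link{gst_matrix}}.
#' @return numeric matrix with N rows and M*L columns.
#' @export
flatten_gst <- function(data) {
  stopifnot(inherits(data, "gst_matrix"))
  d <- dim(data)
  out <- matrix(NA_real_, d[1L], d[2L] * d[3L])
  k <- 0L
  for (m in seq_len(d[2L])) for (l in seq_len(d[3L])) {
    k <- k + 1L
    out[, k] <- data[, m, l]
  }
  rownames(out) <- gene_ids(data)
  colnames(out) <- as.vector(t(outer(sample_ids(data), time_labels(data),
                                     paste, sep = ":")))
  out
}
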