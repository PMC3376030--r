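#' Construct a tricluster record
#'
#' A tricluster \eqn{C = \{I, J, K\}} is a gene set \eqn{I}, a sample
#' subset \eqn{J} and the (full) time series \eqn{K}, together with the
#' rank signature its genes share and a pattern class:
#' \describe{
#'   \item{constant}{one shared rank vector, all ranks equal (no temporal
#'     change).}
#'   \item{conserved}{one shared rank vector across every sample of the
#'     subset.}
#'   \item{general}{identical 2D signatures whose per-sample rows differ
#'     (order preserving within each sample, but sample-specific).}
#'   \item{divergent}{genes following a pattern on \eqn{J} that fail to
#'     extend it to the listed extra samples.}
#' }
#'
#' @param genes character vector of gene ids (I).
#' @param samples character vector of sample ids (J).
#' @param times character vector of time labels (K, the full series).
#' @param signature integer matrix, one row per sample of \code{samples}
#'   (rows are recycled from a single shared vector for conserved
#'   patterns), L columns of dense ranks.
#' @param pattern_class one of \code{"constant"}, \code{"conserved"},
#'   \code{"general"}, \code{"divergent"}.
#' @param z_bound optional significance upper bound attached to the record.
#' @return An object of class \code{tricluster_record}.
#' @export
tricluster_record <- function(genes, samples, times, signature,
                              pattern_class = c("conserved", "constant",
                                                "general", "divergent"),
                              z_bound = NA_real_) {
  pattern_class <- match.arg(pattern_class)
  genes <- as.character(genes); samples <- as.character(samples)
  if (length(genes) < 1L || length(samples) < 1L)
    stop("a tricluster needs at least one gene and one sample", call. = FALSE)
  signature <- matrix(as.integer(signature), nrow = length(samples))
  if (pattern_class %in% c("conserved", "constant", "divergent")) {
    shared <- signature[1L, ]
    if (!all(apply(signature, 1L, identical, shared)))
      stop("class '", pattern_class,
           "' requires identical rank vectors across samples", call. = FALSE)
    if (pattern_class == "constant" && length(unique(shared)) != 1L)
      stop("class 'constant' requires a flat rank vector", call. = FALSE)
  }
  structure(list(genes = genes, samples = samples,
                 times = as.character(times), signature = signature,
                 pattern_class = pattern_class, z_bound = z_bound),
            class = "tricluster_record")
}

#' @export
print.tricluster_record <- function(x, ...) {
  cat(sprintf("tricluster [%s]: %d genes x {%s}, signature %s\n",
              x$pattern_class, length(x$genes),
              paste(x$samples, collapse = ","),
              sig_string(x$signature)))
  invisible(x)
}

sig_string <- function(signature) {
  rows <- apply(signature, 1L, paste, collapse = "-")
  if (length(unique(rows)) == 1L) rows[1L]
  else paste(rows, collapse = ";")
}

#' Convert tricluster records to a data frame
#'
#' One row per record, in the column layout of the on-disk TSV.
#'
#' @param records list of \code{\link{tricluster_record}} objects.
#' @return data.frame with columns pattern_class, sample_subset, signature,
#'   n_genes, gene_ids, z_bound.
#' @export
triclusters_to_df <- function(records) {
  if (length(records) == 0L)
    return(data.frame(pattern_class = character(), sample_subset = character(),
                      signature = character(), n_genes = integer(),
                      gene_ids = character(), z_bound = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(
    pattern_class = vapply(records, `[[`, "", "pattern_class"),
    sample_subset = vapply(records, function(r) paste(r$samples, collapse = ","), ""),
    signature = vapply(records, function(r) sig_string(r$signature), ""),
    n_genes = vapply(records, function(r) length(r$genes), 0L),
    gene_ids = vapply(records, function(r) paste(r$genes, collapse = ","), ""),
    z_bound = vapply(records, function(r) as.numeric(r$z_bound), 0),
    stringsAsFactors = FALSE)
}

#' Write tricluster records to a TSV plus a JSON run summary
#'
#' The TSV has one row per tricluster (see \code{\link{triclusters_to_df}}
#' for the columns); the JSON summary records cluster counts per sample
#' subset and pattern class, the totals \eqn{\Gamma} and \eqn{\Lambda} when
#' a \code{\link{catalog_patterns}} result is supplied, and any parameter
#' list passed in. Reading the TSV back with \code{\link{read_triclusters}}
#' reproduces gene sets and signatures exactly.
#'
#' @param records list of \code{\link{tricluster_record}}s (may be empty).
#' @param path output TSV path; the JSON summary defaults to the same path
#'   with a \code{_summary.json} suffix.
#' @param summary_path optional explicit path for the JSON summary.
#' @param catalog optional \code{pattern_catalog} used for Gamma/Lambda.
#' @param params optional named list of run parameters echoed into the
#'   summary.
#' @export
write_triclusters <- function(records, path, summary_path = NULL,
                              catalog = NULL, params = list()) {
  df <- triclusters_to_df(records)
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(summary_path))
    summary_path <- paste0(tools::file_path_sans_ext(path), "_summary.json")
  per_subset <- list()
  if (nrow(df)) {
    tab <- table(df$sample_subset, df$pattern_class)
    per_subset <- lapply(rownames(tab), function(s) {
      counts <- tab[s, , drop = TRUE]
      as.list(counts[counts > 0L])
    })
    names(per_subset) <- rownames(tab)
  }
  summ <- list(n_clusters = nrow(df),
               clusters_per_subset = per_subset,
               parameters = params)
  if (!is.null(catalog)) {
    summ$Gamma <- catalog$Gamma
    summ$Lambda <- catalog$Lambda
    summ$h <- as.list(stats::setNames(catalog$h, names(catalog$groups)))
  }
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read tricluster records back from a TSV written by write_triclusters
#'
#' @param path TSV path.
#' @param times time labels to attach to each record (the TSV does not
#'   store them); defaults to an empty vector.
#' @return list of \code{\link{tricluster_record}}s.
#' @export
read_triclusters <- function(path, times = character()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    samples <- strsplit(df$sample_subset[i], ",", fixed = TRUE)[[1L]]
    rows <- strsplit(df$signature[i], ";", fixed = TRUE)[[1L]]
    sig <- t(vapply(rows,
                    function(r) as.integer(strsplit(r, "-", fixed = TRUE)[[1L]]),
                    integer(length(strsplit(rows[1L], "-", fixed = TRUE)[[1L]]))))
    if (nrow(sig) == 1L && length(samples) > 1L)
      sig <- sig[rep(1L, length(samples)), , drop = FALSE]
    tricluster_record(strsplit(df$gene_ids[i], ",", fixed = TRUE)[[1L]],
                      samples, times, sig, df$pattern_class[i],
                      z_bound = df$z_bound[i])
  })
}
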