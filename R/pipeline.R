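#' Run the full order-preserving triclustering pipeline
#'
#' Executes the five mining steps in sequence: read (or accept) the GST
#' matrix, quantize (optional), rank, catalogue the distinct patterns over
#' the sample-subset space, form conserved/constant triclusters and derive
#' divergent patterns, then (optionally) attach significance bounds and
#' write the result files.
#'
#' @param input path to a tab-delimited GST file (see
#'   \code{\link{read_gst}}) or a \code{\link{gst_matrix}}.
#' @param delta ranking threshold; required when \code{quantize = TRUE}.
#' @param i_min,j_min minimum genes / samples per reported tricluster.
#' @param quantize apply delta-grid quantization before ranking.
#' @param pattern_class which classes to keep in the output:
#'   \code{"all"}, \code{"conserved"}, \code{"constant"} or
#'   \code{"divergent"}.
#' @param significance attach \code{\link{z_bound}} values to records.
#' @param out_dir optional output directory; when given, writes
#'   \code{triclusters.tsv}, \code{triclusters_summary.json} and
#'   \code{manifest.json} there (partial outputs are removed on failure).
#' @param layout,sep_header,impute passed to \code{\link{read_gst}}.
#' @return (invisibly) a list with \code{records}, \code{divergent},
#'   \code{catalog} and \code{manifest}.
#' @export
run_optriclust <- function(input, delta = NULL, i_min = 1L, j_min = 1L,
                           quantize = TRUE,
                           pattern_class = c("all", "conserved", "constant",
                                             "divergent"),
                           significance = FALSE, out_dir = NULL,
                           layout = "sample.time", sep_header = ":",
                           impute = FALSE) {
  pattern_class <- match.arg(pattern_class)
  data <- if (inherits(input, "gst_matrix")) input
          else read_gst(input, layout = layout, sep_header = sep_header,
                        impute = impute)
  d <- dim(data)
  if (j_min > d[2L])
    stop("j_min = ", j_min, " exceeds the number of samples (", d[2L], ")",
         call. = FALSE)
  if (i_min > d[1L])
    warning("i_min = ", i_min, " exceeds the number of genes (", d[1L],
            "); the result set is empty", call. = FALSE)
  message("step 1/5: quantization ",
          if (quantize) sprintf("(delta = %g)", delta) else "(skipped)")
  message("step 2/5: ranking time profiles")
  ranks <- build_rank_matrix(data, delta = delta, quantize = quantize)
  message("step 3/5: cataloguing distinct patterns over the sample space")
  space <- enumerate_sample_subsets(d[2L], j_min = j_min)
  catalog <- catalog_patterns(ranks, space)
  message("step 4/5: forming conserved triclusters, deriving divergent ones")
  records <- form_conserved_triclusters(catalog, i_min = i_min)
  divergent <- derive_all_divergent(records)
  message("step 5/5: significance", if (significance) "" else " (skipped)")
  if (significance) {
    records <- attach_significance(records, N = d[1L], L = d[3L])
    divergent <- attach_significance(divergent, N = d[1L], L = d[3L])
  }
  out <- switch(pattern_class,
                all = c(records, divergent),
                divergent = divergent,
                records[vapply(records, function(r)
                  r$pattern_class == pattern_class, NA)])
  params <- list(delta = if (quantize) delta else NULL, i_min = i_min,
                 j_min = j_min, quantize = quantize,
                 pattern_class = pattern_class, significance = significance)
  manifest <- list(
    package_version = as.character(utils::packageVersion("optriclust")),
    dimensions = list(N = d[1L], M = d[2L], L = d[3L]),
    parameters = params, Gamma = catalog$Gamma, Lambda = catalog$Lambda,
    n_conserved = sum(vapply(records, function(r)
      r$pattern_class == "conserved", NA)),
    n_constant = sum(vapply(records, function(r)
      r$pattern_class == "constant", NA)),
    n_divergent = length(divergent))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(out_dir, "triclusters.tsv")
    ok <- FALSE
    on.exit(if (!ok) unlink(c(tsv, file.path(out_dir, "triclusters_summary.json"),
                              file.path(out_dir, "manifest.json"))))
    write_triclusters(out, tsv, catalog = catalog, params = params)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ok <- TRUE
  }
  invisible(list(records = out, divergent = divergent, catalog = catalog,
                 manifest = manifest))
}
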