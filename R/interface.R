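with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full matching pipeline on files
#'
#' Orchestrates load, marker projection, normalization, matching,
#' correction, assignment, and summarization, writing every result table
#' and a JSON run manifest into `out_dir`. Errors name the failing stage
#' and the offending entity. All outputs are plain CSV/JSON re-parseable by
#' the package readers.
#'
#' Written files: `pvalues.csv` (raw), `pvalues_adjusted.csv`,
#' `assignments.csv` (`unit`, `matched`, `confidence`, `tie`),
#' `proportions.csv` (cell-to-cluster scheme), `matched_pairs.csv`
#' (two-way scheme), and `manifest.json` with all parameters, seeds,
#' versions and the multiple-testing scope.
#'
#' @param query_expr,ref_expr expression files (see [read_expression()]).
#' @param query_labels,ref_labels label files.
#' @param markers_path marker gene list file.
#' @param out_dir output directory (created if needed).
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param cells_as_rows dense layouts only: cells in rows on disk.
#' @param layer layer tag of the input files (`"counts"` or `"logCPM"`).
#' @param query_platform,ref_platform platform tags.
#' @param scheme matching scheme (see [frmatch()]).
#' @param params a [match_params()].
#' @param normalization a [norm_config()].
#' @return The [frmatch()] object, invisibly.
#' @export
run_matching <- function(query_expr, query_labels, ref_expr, ref_labels,
                         markers_path, out_dir,
                         format = "csv", cells_as_rows = FALSE,
                         layer = "counts",
                         query_platform = "other", ref_platform = "other",
                         scheme = "cell2cluster",
                         params = match_params(),
                         normalization = norm_config()) {
  t0 <- Sys.time()
  q <- with_stage("load-query",
                  read_expression(query_expr, query_labels, format,
                                  cells_as_rows, layer = layer,
                                  platform = query_platform))
  r <- with_stage("load-reference",
                  read_expression(ref_expr, ref_labels, format,
                                  cells_as_rows, layer = layer,
                                  platform = ref_platform))
  markers <- with_stage("load-markers", read_markers(markers_path))
  fit <- with_stage("match",
                    frmatch(q$matrix, r$matrix, q$labels, r$labels, markers,
                            scheme = scheme, params = params,
                            normalization = normalization))
  with_stage("write", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wmat <- function(m, path) {
      df <- data.frame(unit = rownames(m), unclass(m), check.names = FALSE)
      write.csv(df, file.path(out_dir, path), row.names = FALSE,
                quote = FALSE)
    }
    wmat(fit$pvalues, "pvalues.csv")
    wmat(fit$pvalues_adj, "pvalues_adjusted.csv")
    if (!is.null(fit$assignments))
      write.csv(fit$assignments, file.path(out_dir, "assignments.csv"),
                row.names = FALSE, quote = FALSE)
    if (!is.null(fit$proportions))
      wmat(fit$proportions, "proportions.csv")
    if (!is.null(fit$matched_pairs))
      write.csv(fit$matched_pairs, file.path(out_dir, "matched_pairs.csv"),
                row.names = FALSE, quote = FALSE)
    manifest <- list(
      scheme = scheme,
      params = unclass(params),
      normalization = unclass(normalization),
      bh_scope = attr(fit$pvalues_adj, "bh_scope"),
      inputs = list(query_expr = query_expr, query_labels = query_labels,
                    ref_expr = ref_expr, ref_labels = ref_labels,
                    markers = markers_path, format = format,
                    layer = layer),
      versions = list(package = as.character(packageVersion("frcellmatch")),
                      r = R.version.string),
      n_workers = params$n_workers,
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(fit)
}
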