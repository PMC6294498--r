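# Tabular and JSON analysis reports.

#' Write a per-residue CSP table
#'
#' One row per residue (deterministic residue-id order) with the weighted
#' CSP at every titration point (`csp_point_0`, ...), the observed
#' maximal CSP, the exchange-regime label and the saturation flag.
#' Missing (untracked) points are written as empty cells, not zeros; ppm
#' values use fixed 6-decimal formatting so re-running on the same input
#' is byte-identical.
#'
#' @param profiles A `csp_profiles` object from [compute_profiles()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_csp_table <- function(profiles, path) {
  stopifnot(inherits(profiles, "csp_profiles"))
  if (length(profiles$residue_id) == 0L) stopf("no profiles to write")
  ord <- order(profiles$residue_id)
  n_pts <- ncol(profiles$csp)
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write CSP table: %s (%s)", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(c("residue_id", sprintf("csp_point_%d", seq_len(n_pts) - 1L),
                     "csp_max_observed", "regime", "saturated"),
                   collapse = "\t"), con)
  for (i in ord) {
    row <- c(as.character(profiles$residue_id[i]),
             fmt_ppm(profiles$csp[i, ]),
             fmt_ppm(profiles$csp_max_observed[i]),
             profiles$regime[i],
             ifelse(profiles$saturated[i], "TRUE", "FALSE"))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read back a CSP table written by [write_csp_table()]
#'
#' @param path Path to the TSV.
#' @return A data frame with numeric CSP columns (`NA` for empty cells).
#' @export
read_csp_table <- function(path) {
  if (!file.exists(path)) stopf("CSP table not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  num_cols <- c(grep("^csp_point_", names(tab), value = TRUE),
                "csp_max_observed")
  for (cl in num_cols) tab[[cl]] <- suppressWarnings(as.numeric(tab[[cl]]))
  tab
}

#' Export a structure-coloring attribute map
#'
#' Per-residue normalized color score
#' `clamp((csp_max_observed - low) / (high - low), 0, 1)`, suitable for
#' import as a structure-coloring attribute (small-to-large CSP
#' gradient).
#'
#' @param profiles A `csp_profiles` object.
#' @param low,high CSP window in ppm mapped to scores 0 and 1
#'   (`low < high`).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
export_structure_map <- function(profiles, low, high, path) {
  stopifnot(inherits(profiles, "csp_profiles"))
  if (!is_scalar_number(low) || !is_scalar_number(high) || low >= high)
    stopf("need low < high (got low = %s, high = %s)", low, high)
  ord <- order(profiles$residue_id)
  score <- pmin(pmax((profiles$csp_max_observed - low) / (high - low), 0), 1)
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write structure map: %s (%s)", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines("residue_id\tscore", con)
  writeLines(paste(profiles$residue_id[ord], fmt_ppm(score[ord]), sep = "\t"),
             con)
  invisible(path)
}

#' Write a binding-fit report as JSON
#'
#' The report carries the fitted dissociation constant and its standard
#' error, the per-residue maximal CSPs, residual diagnostics, the
#' convergence flag, the package version and a deterministic digest of
#' the fit content (the timestamp is excluded from the digest, so two
#' runs on identical input differ only in the timestamp).  `kd_se_uM` is
#' omitted for non-converged fits.
#'
#' @param fit A `binding_fit` from [fit_global()].
#' @param path Output JSON path.
#' @param config Optional named list echoed verbatim into the report
#'   (e.g. the pipeline configuration).
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path, config = NULL) {
  stopifnot(inherits(fit, "binding_fit"))
  digest <- content_digest(list(fit$kd_uM, unlist(fit$delta_max_by_residue),
                                fit$rss, fit$n_points, fit$n_residues,
                                fit$converged))
  doc <- list(
    kd_uM = fit$kd_uM,
    kd_se_uM = if (isTRUE(fit$converged) && is.finite(fit$kd_se_uM))
      fit$kd_se_uM else NULL,
    delta_max_by_residue = as.list(fit$delta_max_by_residue),
    rss = fit$rss,
    n_points = fit$n_points,
    n_residues = fit$n_residues,
    converged = fit$converged,
    software_version = as.character(packageVersion("cspfit")),
    input_digest = digest,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(config)) doc$config <- config
  doc <- doc[!vapply(doc, is.null, logical(1))]
  tryCatch(
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE),
    error = function(e) stopf("cannot write fit report: %s (%s)", path,
                              conditionMessage(e)))
  invisible(path)
}

#' Read a binding-fit report
#'
#' @param path Path to a JSON report written by [write_fit_report()].
#' @return The report as a named list.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stopf("fit report not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
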