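# Peak-list and titration-table input/output.
#
# Two on-disk dialects are supported for 2D HSQC peak lists:
#   * "sparky": whitespace-separated columns  Assignment  w1  w2  [height]
#     with w1 = 15N (ppm) and w2 = 1H (ppm) by default; residue numbers are
#     parsed from assignment labels of the form <aa><number><atom>, e.g.
#     "V18N-H".
#   * "tsv": tab-separated columns residue_id, shift_H_ppm, shift_N_ppm,
#     intensity.
# Chemical shifts are ppm; concentrations are uM throughout the package.

PPM_H_RANGE <- c(-2, 15)
PPM_N_RANGE <- c(90, 140)

new_peak_list <- function(label, residue_id, shift_H, shift_N, intensity,
                          point_index = NA_integer_, dialect = "tsv") {
  pl <- data.frame(
    label = as.character(label),
    residue_id = as.integer(residue_id),
    shift_H = as.numeric(shift_H),
    shift_N = as.numeric(shift_N),
    intensity = as.numeric(intensity),
    stringsAsFactors = FALSE
  )
  validate_peak_list(pl)
  structure(pl, point_index = point_index, dialect = dialect,
            class = c("peak_list", "data.frame"))
}

validate_peak_list <- function(pl) {
  if (nrow(pl) == 0L) return(invisible(pl))
  if (any(!is.finite(pl$shift_H)) || any(!is.finite(pl$shift_N)))
    stopf("peak list contains non-finite chemical shifts")
  ids <- pl$residue_id[!is.na(pl$residue_id)]
  if (anyDuplicated(ids))
    stopf("duplicate residue_id in peak list: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out_h <- pl$shift_H < PPM_H_RANGE[1] | pl$shift_H > PPM_H_RANGE[2]
  out_n <- pl$shift_N < PPM_N_RANGE[1] | pl$shift_N > PPM_N_RANGE[2]
  if (any(out_h))
    warnf("%d peak(s) with 1H shift outside [%g, %g] ppm",
          sum(out_h), PPM_H_RANGE[1], PPM_H_RANGE[2])
  if (any(out_n))
    warnf("%d peak(s) with 15N shift outside [%g, %g] ppm",
          sum(out_n), PPM_N_RANGE[1], PPM_N_RANGE[2])
  invisible(pl)
}

# Residue number from a Sparky-style assignment label ("V18N-H" -> 18).
parse_sparky_residue <- function(label) {
  m <- regmatches(label, regexec("^[A-Za-z]([0-9]+)", label))
  vapply(m, function(g) {
    if (length(g) == 2L) as.integer(g[2]) else NA_integer_
  }, integer(1))
}

#' Read a 2D peak list
#'
#' Reads an HSQC peak list in either the Sparky `.list` dialect
#' (`Assignment w1 w2 [height]`, `w1` = 15N ppm, `w2` = 1H ppm) or a
#' generic TSV dialect (`residue_id`, `shift_H_ppm`, `shift_N_ppm`,
#' `intensity`).  A warning is emitted for shifts outside the plausible
#' amide window (1H in \[-2, 15\] ppm, 15N in \[90, 140\] ppm); duplicate
#' residue ids and non-numeric shift fields are errors that name the
#' offending line.
#'
#' @param path Path to the peak-list file.
#' @param dialect `"tsv"` or `"sparky"`.
#' @param swap_axes For the Sparky dialect only: interpret `w1` as 1H and
#'   `w2` as 15N (the opposite of the default column convention).
#' @param point_index Optional titration point index stored as an
#'   attribute.
#' @return A `peak_list`, a data frame with columns `label`,
#'   `residue_id`, `shift_H`, `shift_N`, `intensity`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("residue_id\tshift_H_ppm\tshift_N_ppm\tintensity",
#'              "18\t8.12\t121.4\t1.0e6"), tf)
#' read_peak_list(tf, "tsv")
#' @export
read_peak_list <- function(path, dialect = c("tsv", "sparky"),
                           swap_axes = FALSE, point_index = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("peak list file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tsv") {
    read_peak_list_tsv(lines, path, point_index)
  } else {
    read_peak_list_sparky(lines, path, swap_axes, point_index)
  }
}

read_peak_list_tsv <- function(lines, path, point_index) {
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    warnf("empty peak list: %s", path)
    return(new_peak_list(character(0), integer(0), numeric(0), numeric(0),
                         numeric(0), point_index, "tsv"))
  }
  header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
  need <- c("residue_id", "shift_H_ppm", "shift_N_ppm")
  if (!all(need %in% header))
    stopf("peak list %s: missing column(s) %s", path,
          paste(setdiff(need, header), collapse = ", "))
  body <- keep[-1]
  if (length(body) == 0L) {
    warnf("empty peak list: %s", path)
    return(new_peak_list(character(0), integer(0), numeric(0), numeric(0),
                         numeric(0), point_index, "tsv"))
  }
  grab <- function(fields, col) {
    i <- match(col, header)
    if (is.na(i) || i > length(fields)) NA_character_ else fields[i]
  }
  n <- length(body)
  rid <- integer(n); sh <- numeric(n); sn <- numeric(n); ii <- numeric(n)
  for (k in seq_len(n)) {
    ln <- body[k]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    num <- function(col, required = TRUE) {
      raw <- grab(fields, col)
      if (is.na(raw) || !nzchar(raw)) {
        if (required) stopf("%s line %d: missing %s", path, ln, col)
        return(NA_real_)
      }
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) stopf("%s line %d: non-numeric %s (%s)", path, ln, col, raw)
      v
    }
    rv <- num("residue_id", required = FALSE)
    rid[k] <- if (is.na(rv)) NA_integer_ else as.integer(rv)
    sh[k] <- num("shift_H_ppm")
    sn[k] <- num("shift_N_ppm")
    ii[k] <- if ("intensity" %in% header) num("intensity", required = FALSE)
             else NA_real_
  }
  lab <- ifelse(is.na(rid), "?-?", paste0("R", rid))
  new_peak_list(lab, rid, sh, sn, ii, point_index, "tsv")
}

read_peak_list_sparky <- function(lines, path, swap_axes, point_index) {
  is_data <- function(x) {
    t <- trimws(x)
    nzchar(t) && !grepl("^Assignment", t) && !grepl("\\bw1\\b", t)
  }
  body <- which(vapply(lines, is_data, logical(1), USE.NAMES = FALSE))
  if (length(body) == 0L) {
    warnf("empty peak list: %s", path)
    return(new_peak_list(character(0), integer(0), numeric(0), numeric(0),
                         numeric(0), point_index, "sparky"))
  }
  n <- length(body)
  lab <- character(n); w1 <- numeric(n); w2 <- numeric(n); ht <- numeric(n)
  for (k in seq_len(n)) {
    ln <- body[k]
    f <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(f) < 3L)
      stopf("%s line %d: expected assignment and two shift columns", path, ln)
    lab[k] <- f[1]
    v1 <- suppressWarnings(as.numeric(f[2]))
    v2 <- suppressWarnings(as.numeric(f[3]))
    if (is.na(v1) || is.na(v2))
      stopf("%s line %d: non-numeric shift (%s, %s)", path, ln, f[2], f[3])
    w1[k] <- v1; w2[k] <- v2
    ht[k] <- if (length(f) >= 4L) {
      h <- suppressWarnings(as.numeric(f[4]))
      if (is.na(h)) stopf("%s line %d: non-numeric height (%s)", path, ln, f[4])
      h
    } else NA_real_
  }
  rid <- parse_sparky_residue(lab)
  rid[lab == "?-?"] <- NA_integer_
  if (swap_axes) new_peak_list(lab, rid, w1, w2, ht, point_index, "sparky")
  else           new_peak_list(lab, rid, w2, w1, ht, point_index, "sparky")
}

#' Write a peak list
#'
#' Serializes a `peak_list` in either dialect with fixed formatting
#' (6-decimal ppm, scientific-notation intensities) so that write/read
#' round trips are bit-stable.
#'
#' @param peaks A `peak_list` (or data frame with the same columns).
#' @param path Output path.
#' @param dialect `"tsv"` or `"sparky"`.
#' @return Invisibly, `path`.
#' @export
write_peak_list <- function(peaks, path, dialect = c("tsv", "sparky")) {
  dialect <- match.arg(dialect)
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write peak list: %s (%s)", path, conditionMessage(e)))
  on.exit(close(con))
  if (dialect == "tsv") {
    writeLines("residue_id\tshift_H_ppm\tshift_N_ppm\tintensity", con)
    if (nrow(peaks)) {
      writeLines(paste(ifelse(is.na(peaks$residue_id), "",
                              as.character(peaks$residue_id)),
                       fmt_ppm(peaks$shift_H), fmt_ppm(peaks$shift_N),
                       fmt_intensity(peaks$intensity), sep = "\t"), con)
    }
  } else {
    writeLines(sprintf("%17s %10s %10s %14s", "Assignment", "w1", "w2",
                       "Data Height"), con)
    if (nrow(peaks)) {
      lab <- ifelse(is.na(peaks$residue_id), "?-?",
                    ifelse(nzchar(peaks$label) & peaks$label != "?-?",
                           peaks$label, paste0("A", peaks$residue_id, "N-H")))
      writeLines(sprintf("%17s %10s %10s %14s", lab, fmt_ppm(peaks$shift_N),
                         fmt_ppm(peaks$shift_H),
                         fmt_intensity(peaks$intensity)), con)
    }
  }
  invisible(path)
}

new_titration_point <- function(point_index, protein_total_uM,
                                ligand_total_uM, peaks) {
  if (!is_scalar_number(protein_total_uM) || protein_total_uM <= 0)
    stopf("point %s: protein_total_uM must be > 0", point_index)
  if (!is_scalar_number(ligand_total_uM) || ligand_total_uM < 0)
    stopf("point %s: ligand_total_uM must be >= 0", point_index)
  list(point_index = as.integer(point_index),
       protein_total_uM = protein_total_uM,
       ligand_total_uM = ligand_total_uM,
       peaks = peaks)
}

#' Construct a titration series
#'
#' Bundles ordered titration points (each a peak list with total protein
#' and ligand concentrations, uM) with the spectrometer 1H base frequency
#' and the 15N/1H Larmor frequency ratio.  The first point must be the
#' ligand-free reference and the ligand schedule must be non-decreasing.
#'
#' @param points List of points as built by [read_titration_table()] or
#'   [simulate_titration()]; each has `point_index`, `protein_total_uM`,
#'   `ligand_total_uM` and a `peaks` peak list.
#' @param spectrometer_1H_MHz 1H base frequency, MHz.
#' @param nitrogen_frequency_ratio Dimensionless 15N/1H Larmor magnitude
#'   ratio.
#' @return A `titration_series` object.
#' @export
titration_series <- function(points, spectrometer_1H_MHz = 600,
                             nitrogen_frequency_ratio = 0.1013291) {
  if (length(points) == 0L) stopf("titration series has no points")
  if (!is_scalar_number(spectrometer_1H_MHz) || spectrometer_1H_MHz <= 0)
    stopf("spectrometer_1H_MHz must be > 0")
  idx <- vapply(points, `[[`, integer(1), "point_index")
  points <- points[order(idx)]
  lig <- vapply(points, `[[`, numeric(1), "ligand_total_uM")
  if (lig[1] != 0)
    stopf("first titration point must be ligand-free (found %g uM)", lig[1])
  if (is.unsorted(lig))
    stopf("non-monotone ligand schedule: %s", paste(lig, collapse = ", "))
  structure(list(points = points,
                 spectrometer_1H_MHz = spectrometer_1H_MHz,
                 nitrogen_frequency_ratio = nitrogen_frequency_ratio),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  lig <- vapply(x$points, `[[`, numeric(1), "ligand_total_uM")
  cat(sprintf("titration_series: %d points, [P]T = %g uM, [L]T = %g..%g uM, %g MHz\n",
              length(x$points), x$points[[1]]$protein_total_uM,
              min(lig), max(lig), x$spectrometer_1H_MHz))
  invisible(x)
}

#' Read a titration concentration table
#'
#' The table is a TSV with columns `point_index`, `peaklist_path`,
#' `protein_total_uM`, `ligand_total_uM` and an optional `dialect`
#' column; `peaklist_path` is resolved relative to the table's
#' directory (files ending in `.list` default to the Sparky dialect).
#' Leading comment lines of the form `# key value` may set
#' `spectrometer_1H_MHz` and `nitrogen_frequency_ratio`; defaults are
#' 600 MHz and 0.1013291.  Rows are sorted by `point_index` and the
#' series invariants (ligand-free first point, non-decreasing schedule)
#' are enforced.
#'
#' @param path Path to the table.
#' @param swap_axes Passed to [read_peak_list()] for Sparky files.
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path, swap_axes = FALSE) {
  if (!file.exists(path)) stopf("titration table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr_keys <- list(spectrometer_1H_MHz = 600,
                   nitrogen_frequency_ratio = 0.1013291)
  com <- grep("^#", lines)
  for (i in com) {
    kv <- strsplit(sub("^#\\s*", "", lines[i]), "[=\t ]+")[[1]]
    if (length(kv) >= 2L && kv[1] %in% names(hdr_keys)) {
      v <- suppressWarnings(as.numeric(kv[2]))
      if (is.na(v)) stopf("%s line %d: non-numeric header value", path, i)
      hdr_keys[[kv[1]]] <- v
    }
  }
  body <- lines[setdiff(seq_along(lines), com)]
  tab <- read.delim(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE)
  need <- c("point_index", "peaklist_path", "protein_total_uM",
            "ligand_total_uM")
  if (!all(need %in% names(tab)))
    stopf("titration table %s: missing column(s) %s", path,
          paste(setdiff(need, names(tab)), collapse = ", "))
  base <- dirname(path)
  points <- lapply(seq_len(nrow(tab)), function(k) {
    plp <- tab$peaklist_path[k]
    full <- if (grepl("^(/|[A-Za-z]:)", plp)) plp else file.path(base, plp)
    dia <- if ("dialect" %in% names(tab) && nzchar(tab$dialect[k]))
      tab$dialect[k]
    else if (identical(tolower(file_ext(full)), "list")) "sparky" else "tsv"
    pk <- read_peak_list(full, dia, swap_axes = swap_axes,
                         point_index = tab$point_index[k])
    new_titration_point(tab$point_index[k], tab$protein_total_uM[k],
                        tab$ligand_total_uM[k], pk)
  })
  titration_series(points,
                   spectrometer_1H_MHz = hdr_keys$spectrometer_1H_MHz,
                   nitrogen_frequency_ratio = hdr_keys$nitrogen_frequency_ratio)
}
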