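test_that("TSV peak lists parse, validate ranges, and reject bad rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_peaklist(c("18\t8.12\t121.4\t1.0e6", "27\t7.95\t118.2\t9.0e5"), tf)
  pl <- read_peak_list(tf, "tsv")
  expect_setequal(pl$residue_id, c(18L, 27L))
  expect_equal(pl$shift_H[pl$residue_id == 18], 8.12)
  expect_equal(pl$shift_N[pl$residue_id == 18], 121.4)

  # empty file: zero peaks plus a warning, not an error
  ef <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), ef)
  expect_warning(pe <- read_peak_list(ef, "tsv"), "empty")
  expect_equal(nrow(pe), 0L)

  # non-numeric shift names the line
  bf <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_peaklist(c("18\t8.12\t121.4\t1.0e6", "27\tabc\t118.2\t1"), bf)
  expect_error(read_peak_list(bf, "tsv"), "line 3")

  # duplicate residue id is an error
  df <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_peaklist(c("18\t8.12\t121.4\t1", "18\t7.95\t118.2\t1"), df)
  expect_error(read_peak_list(df, "tsv"), "duplicate")

  # implausible shifts warn but load
  wf <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_peaklist("18\t25.0\t121.4\t1", wf)
  expect_warning(read_peak_list(wf, "tsv"), "1H shift outside")
})

test_that("Sparky labels parse by grammar and match a hand parser", {
  sf <- withr::local_tempfile(fileext = ".list")
  writeLines(c("      Assignment         w1         w2   Data Height",
               "         V18N-H     121.40       8.12        1.0e6",
               "         A27N-H     118.20       7.95        9.0e5",
               "            ?-?     110.00       8.50        1.0e5"), sf)
  pl <- read_peak_list(sf, "sparky")
  expect_equal(nrow(pl), 3L)
  # independent hand parse of the label grammar: letter then digits
  hand <- function(lab) {
    if (!grepl("^[A-Za-z][0-9]", lab)) return(NA_integer_)
    as.integer(sub("^[A-Za-z]([0-9]+).*$", "\\1", lab))
  }
  expect_equal(pl$residue_id, vapply(pl$label, hand, integer(1),
                                     USE.NAMES = FALSE))
  v18 <- pl[pl$label == "V18N-H", ]
  expect_equal(v18$shift_N, 121.40)
  expect_equal(v18$shift_H, 8.12)
  expect_equal(v18$intensity, 1.0e6)
  expect_true(is.na(pl$residue_id[pl$label == "?-?"]))

  # swap_axes flips the column convention (range warnings expected, since
  # this file is written in the default convention)
  pl2 <- suppressWarnings(read_peak_list(sf, "sparky", swap_axes = TRUE))
  expect_equal(pl2$shift_H[pl2$label == "V18N-H"], 121.40)
})

test_that("Sparky and TSV dialects of the same peaks are equivalent", {
  sim <- make_fast_sim(n = 6, seed = 11, noise_H = 0.003, noise_N = 0.015)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_titration(sim, d1, "tsv")
  write_titration(sim, d2, "sparky")
  s1 <- read_titration_table(file.path(d1, "titration.tsv"))
  s2 <- read_titration_table(file.path(d2, "titration.tsv"))
  for (i in seq_along(s1$points)) {
    a <- s1$points[[i]]$peaks; b <- s2$points[[i]]$peaks
    expect_equal(a$shift_H, b$shift_H)
    expect_equal(a$shift_N, b$shift_N)
    expect_equal(a$residue_id, b$residue_id)
  }
})

test_that("titration tables sort, default, and enforce the ligand schedule", {
  dir <- withr::local_tempdir()
  for (i in 0:2)
    write_tsv_peaklist(sprintf("%d\t8.%d\t121.4\t1e6", 10 + i, i),
                       file.path(dir, sprintf("p%d.tsv", i)))
  tab <- file.path(dir, "titration.tsv")
  hdr <- "point_index\tpeaklist_path\tprotein_total_uM\tligand_total_uM"
  # rows deliberately out of order
  writeLines(c(hdr, "2\tp2.tsv\t100\t100", "0\tp0.tsv\t100\t0",
               "1\tp1.tsv\t100\t50"), tab)
  ser <- read_titration_table(tab)
  expect_equal(vapply(ser$points, `[[`, integer(1), "point_index"), 0:2)
  expect_equal(vapply(ser$points, `[[`, numeric(1), "ligand_total_uM"),
               c(0, 50, 100))
  expect_equal(ser$spectrometer_1H_MHz, 600)
  expect_equal(ser$nitrogen_frequency_ratio, 0.1013291)

  writeLines(c(hdr, "0\tp0.tsv\t100\t0", "1\tp1.tsv\t100\t100",
               "2\tp2.tsv\t100\t50"), tab)
  expect_error(read_titration_table(tab), "non-monotone ligand schedule")

  writeLines(c(hdr, "0\tp0.tsv\t100\t10", "1\tp1.tsv\t100\t50",
               "2\tp2.tsv\t100\t100"), tab)
  expect_error(read_titration_table(tab), "ligand-free")

  # header comments override the spectrometer frequency
  writeLines(c("# spectrometer_1H_MHz\t800", hdr, "0\tp0.tsv\t100\t0",
               "1\tp1.tsv\t100\t50", "2\tp2.tsv\t100\t100"), tab)
  expect_equal(read_titration_table(tab)$spectrometer_1H_MHz, 800)
})

test_that("FASTA reading validates the amino-acid alphabet", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "MKP"), fa)
  seqs <- read_fasta(fa)
  expect_length(seqs, 1L)
  expect_equal(nchar(seqs[[1]]), 3L)

  writeLines(c(">x", "MKP", ">y", "ACDEFG"), fa)
  expect_equal(names(read_fasta(fa)), c("x", "y"))

  writeLines(c(">x", "M1K"), fa)
  expect_error(read_fasta(fa), "'1'")
})

test_that("interval arithmetic and HSQC visibility agree with hand counts", {
  expect_equal(interval_length(domain_interval(688, 717)), 30L)
  expect_equal(interval_length(domain_interval(1, 107)), 107L)
  expect_equal(interval_length(domain_interval(5, 5)), 1L)
  expect_error(domain_interval(10, 5), "invalid interval")

  expect_equal(hsqc_visible("AAAA", domain_interval(1, 4)),
               list(n_visible = 4L, n_proline = 0L))
  expect_equal(hsqc_visible("APPA", domain_interval(1, 4)),
               list(n_visible = 2L, n_proline = 2L))
  expect_error(hsqc_visible("APPA", domain_interval(1, 5)), "exceeds")

  # the bundled synthetic CTD stand-in: 30 residues, 2 prolines
  fa <- system.file("extdata", "cstf77_ctd_synthetic.fasta",
                    package = "cspfit")
  ctd <- read_fasta(fa)[[1]]
  vis <- hsqc_visible(ctd, domain_interval(1, 30))
  expect_equal(vis$n_visible, 28L)
  expect_equal(vis$n_proline, 2L)

  # invariant: visible + proline == interval length, random sequences
  set.seed(99)
  for (k in 1:25) {
    n <- sample(5:60, 1)
    s <- paste(sample(c("A", "P", "G", "K", "L"), n, replace = TRUE),
               collapse = "")
    a <- sample(seq_len(n), 1)
    b <- a + sample.int(n - a + 1L, 1) - 1L
    iv <- domain_interval(a, b)
    v <- hsqc_visible(s, iv)
    expect_identical(v$n_visible + v$n_proline, interval_length(iv))
  }
})

test_that("CSP tables round-trip exactly as formatted and are deterministic", {
  sim <- make_fast_sim(n = 4, seed = 5, noise_H = 0.003, noise_N = 0.015)
  pr <- compute_profiles(track_peaks(sim$series, max_step = 0.1))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_csp_table(pr, f1)
  write_csp_table(pr, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical re-run

  back <- read_csp_table(f1)
  expect_equal(nrow(back), 4L)
  for (i in seq_len(pr$n_points))
    expect_identical(back[[sprintf("csp_point_%d", i - 1L)]],
                     as.numeric(sprintf("%.6f", pr$csp[order(pr$residue_id), i])))

  # a missing point becomes an empty cell, not zero
  H <- rbind(c(8, 8.02, NA, 8.06))
  N <- rbind(c(120, 120.1, NA, 120.3))
  ser <- make_manual_series(H, N)
  prm <- compute_profiles(track_peaks(ser))
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_csp_table(prm, fm)
  fields <- strsplit(readLines(fm)[2], "\t")[[1]]
  expect_identical(fields[4], "")  # csp_point_2 empty
})

test_that("structure maps clamp and scale the CSP window", {
  pr <- structure(list(residue_id = 1:4,
                       csp = matrix(0, 4, 2),
                       csp_max_observed = c(0.037, (0.037 + 0.24) / 2, 0.24,
                                            0.5),
                       regime = rep("fast", 4), saturated = rep(TRUE, 4),
                       n_points = 2L),
                  class = "csp_profiles")
  f <- withr::local_tempfile(fileext = ".tsv")
  export_structure_map(pr, 0.037, 0.24, f)
  sm <- read.delim(f)
  expect_equal(sm$score, c(0, 0.5, 1, 1), tolerance = 1e-6)
  expect_error(export_structure_map(pr, 0.24, 0.037, f), "low < high")
})

test_that("fit reports round-trip numerically and flag non-convergence", {
  sim <- make_fast_sim(n = 5, seed = 3)
  pr <- compute_profiles(track_peaks(sim$series, max_step = 0.1))
  fit <- fit_global(pr, sim$series)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, f)
  rep1 <- read_fit_report(f)
  expect_equal(rep1$kd_uM, fit$kd_uM, tolerance = 1e-12)
  expect_equal(rep1$rss, fit$rss, tolerance = 1e-12)
  expect_equal(sort(names(rep1$delta_max_by_residue)),
               sort(names(fit$delta_max_by_residue)))
  expect_true(rep1$converged)

  # identical reruns differ only in the timestamp
  f2 <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, f2)
  rep2 <- read_fit_report(f2)
  expect_identical(rep1$input_digest, rep2$input_digest)
  expect_identical(rep1[setdiff(names(rep1), "timestamp")],
                   rep2[setdiff(names(rep2), "timestamp")])

  # a non-converged fit serializes without kd_se
  bad <- fit; bad$converged <- FALSE
  f3 <- withr::local_tempfile(fileext = ".json")
  write_fit_report(bad, f3)
  rep3 <- read_fit_report(f3)
  expect_false(rep3$converged)
  expect_null(rep3$kd_se_uM)
})
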