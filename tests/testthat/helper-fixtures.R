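# Shared fixtures, all generated in code.

default_schedule <- function() seq(0, 200, length.out = 11)

# Deep-fast-exchange simulation used throughout the fit tests.
make_fast_sim <- function(kd = 3.5, n = 12, seed = 42, noise_H = 0,
                          noise_N = 0) {
  spec <- synthetic_titration_spec(kd, 100, default_schedule(),
                                   noise_sd_H = noise_H,
                                   noise_sd_N = noise_N, seed = seed)
  simulate_titration(spec, fast_residue_set(spec, n = n))
}

# Hand-built series: one or more residues with explicit per-point
# positions (list of H/N matrices residues x points).
make_manual_series <- function(H, N, I = NULL, residue_id = seq_len(nrow(H)),
                               P = 100, lig = NULL) {
  n_pts <- ncol(H)
  if (is.null(lig)) lig <- seq(0, by = 20, length.out = n_pts)
  if (is.null(I)) I <- matrix(1e6, nrow(H), n_pts)
  points <- lapply(seq_len(n_pts), function(i) {
    keep <- which(is.finite(H[, i]))
    pl <- cspfit:::new_peak_list(
      label = ifelse(rep(i == 1, length(keep)),
                     paste0("A", residue_id[keep], "N-H"), "?-?"),
      residue_id = if (i == 1) residue_id[keep]
                   else rep(NA_integer_, length(keep)),
      shift_H = H[keep, i], shift_N = N[keep, i],
      intensity = I[keep, i], point_index = i - 1L)
    cspfit:::new_titration_point(i - 1L, P, lig[i], pl)
  })
  titration_series(points)
}

write_tsv_peaklist <- function(rows, path) {
  writeLines(c("residue_id\tshift_H_ppm\tshift_N_ppm\tintensity", rows), path)
  path
}
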