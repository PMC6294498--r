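# Synthetic-data generators with known ground truth.
#
# Titration peak lists are generated from a two-site (free/bound)
# exchange model layered on the one-site binding equilibrium: each
# residue has free and bound endpoint shifts and an off-rate; at every
# titration point the bound population comes from the mass-action
# equilibrium and the observable peak(s) follow the exchange regime set
# by k_ex = k_on * [L_free] + k_off relative to the free-bound frequency
# difference.  Positions receive seeded Gaussian noise; reporter wells
# and cell boxes receive seeded lognormal multiplicative noise.

TAU_EVOLUTION_S <- 0.01  # effective evolution time for broadening losses

#' Specify a synthetic titration
#'
#' @param true_kd_uM Ground-truth dissociation constant, uM.
#' @param protein_total_uM Total protein concentration, uM.
#' @param ligand_schedule_uM Non-decreasing ligand schedule starting
#'   at 0, uM.
#' @param noise_sd_H,noise_sd_N Gaussian positional noise SDs, ppm.
#' @param spectrometer_1H_MHz 1H base frequency, MHz.
#' @param nitrogen_frequency_ratio 15N/1H Larmor magnitude ratio.
#' @param seed RNG seed: identical spec and seed give byte-identical
#'   output.
#' @return A `synthetic_titration_spec` list.
#' @export
synthetic_titration_spec <- function(true_kd_uM, protein_total_uM,
                                     ligand_schedule_uM,
                                     noise_sd_H = 0.003, noise_sd_N = 0.015,
                                     spectrometer_1H_MHz = 600,
                                     nitrogen_frequency_ratio = 0.1013291,
                                     seed = 1L) {
  if (!is_scalar_number(true_kd_uM) || true_kd_uM <= 0)
    stopf("true_kd_uM must be > 0")
  if (!is_scalar_number(protein_total_uM) || protein_total_uM <= 0)
    stopf("protein_total_uM must be > 0")
  if (length(ligand_schedule_uM) < 2L || ligand_schedule_uM[1] != 0 ||
      is.unsorted(ligand_schedule_uM) || any(ligand_schedule_uM < 0))
    stopf("ligand_schedule_uM must be non-decreasing and start at 0")
  if (noise_sd_H < 0 || noise_sd_N < 0) stopf("noise SDs must be >= 0")
  structure(list(true_kd_uM = true_kd_uM,
                 protein_total_uM = protein_total_uM,
                 ligand_schedule_uM = as.numeric(ligand_schedule_uM),
                 noise_sd_H = noise_sd_H, noise_sd_N = noise_sd_N,
                 spectrometer_1H_MHz = spectrometer_1H_MHz,
                 nitrogen_frequency_ratio = nitrogen_frequency_ratio,
                 seed = as.integer(seed)),
            class = "synthetic_titration_spec")
}

#' Define per-residue ground truth
#'
#' @param residue_id Positive integer ids.
#' @param free_H,free_N Free-state shifts, ppm.
#' @param bound_H,bound_N Bound-state shifts, ppm.
#' @param k_off Off-rate, 1/s (> 0).
#' @param base_intensity Free-state peak intensity, arbitrary units.
#' @return A data frame of residue truths.
#' @export
residue_truth <- function(residue_id, free_H, free_N, bound_H, bound_N,
                          k_off, base_intensity = 1e6) {
  if (any(k_off <= 0)) stopf("k_off must be > 0")
  if (any(base_intensity <= 0)) stopf("base_intensity must be > 0")
  data.frame(residue_id = as.integer(residue_id),
             free_H = free_H, free_N = free_N,
             bound_H = bound_H, bound_N = bound_N,
             k_off = k_off, base_intensity = base_intensity)
}

#' Exchange observables for one residue at one titration point
#'
#' Computes the bound population (via [equilibrium_oracle()]), the
#' exchange rate `k_ex = k_on * [L_free] + k_off` with
#' `k_on = k_off / K_D`, the free-bound frequency differences
#' `delta_omega = delta_ppm * nu0 * 2*pi` (rad/s, `nu0(15N) = nu0(1H) *
#' nitrogen_frequency_ratio`), and the regime from
#' `k_ex / max(|dw_H|, |dw_N|)`: fast at >= 5, slow at <= 0.2,
#' intermediate between.  Fast and intermediate regimes yield one peak at
#' the population-weighted position with the fast-exchange broadening
#' `r_ex = p_free * p_bound * (dw_H^2 + dw_N^2) / k_ex` applied as an
#' intensity factor `exp(-r_ex * tau)` (`tau` = 0.01 s); an intermediate
#' peak attenuated below 0.1 is dropped.  Slow exchange yields two peaks
#' at the free and bound positions with intensities proportional to the
#' populations (no additional broadening term).
#'
#' @param truth One row of [residue_truth()].
#' @param spec A [synthetic_titration_spec()].
#' @param ligand_total_uM Total ligand at the point, uM.
#' @return A list: `p_bound`, `k_ex`, `delta_omega_H`, `delta_omega_N`,
#'   `obs_H`, `obs_N` (population-weighted), `r_ex`, `regime_truth`, and
#'   `peaks` (data frame `shift_H`, `shift_N`, `rel_intensity`; 0-2
#'   rows).
#' @export
two_site_observables <- function(truth, spec, ligand_total_uM) {
  stopifnot(inherits(spec, "synthetic_titration_spec"))
  P <- spec$protein_total_uM
  p <- equilibrium_oracle(spec$true_kd_uM, P, ligand_total_uM)
  q <- 1 - p
  k_on <- truth$k_off / spec$true_kd_uM               # 1/(uM s)
  L_free <- max(ligand_total_uM - p * P, 0)
  k_ex <- k_on * L_free + truth$k_off
  dH <- truth$bound_H - truth$free_H
  dN <- truth$bound_N - truth$free_N
  two_pi <- 2 * pi
  dw_H <- dH * spec$spectrometer_1H_MHz * two_pi      # ppm * MHz = Hz
  dw_N <- dN * spec$spectrometer_1H_MHz * spec$nitrogen_frequency_ratio *
    two_pi
  dw_max <- max(abs(dw_H), abs(dw_N))
  ratio <- if (dw_max == 0) Inf else k_ex / dw_max
  regime <- if (ratio >= 5) "fast" else if (ratio <= 0.2) "slow"
            else "intermediate"
  obs_H <- truth$free_H + p * dH
  obs_N <- truth$free_N + p * dN
  if (regime == "slow") {
    r_ex <- 0
    peaks <- data.frame(shift_H = c(truth$free_H, truth$bound_H),
                        shift_N = c(truth$free_N, truth$bound_N),
                        rel_intensity = c(q, p))
    peaks <- peaks[peaks$rel_intensity > 0, , drop = FALSE]
  } else {
    r_ex <- p * q * (dw_H^2 + dw_N^2) / k_ex
    atten <- exp(-r_ex * TAU_EVOLUTION_S)
    peaks <- if (regime == "intermediate" && atten < 0.1) {
      data.frame(shift_H = numeric(0), shift_N = numeric(0),
                 rel_intensity = numeric(0))
    } else {
      data.frame(shift_H = obs_H, shift_N = obs_N, rel_intensity = atten)
    }
  }
  list(p_bound = p, k_ex = k_ex, delta_omega_H = dw_H, delta_omega_N = dw_N,
       obs_H = obs_H, obs_N = obs_N, r_ex = r_ex, regime_truth = regime,
       peaks = peaks)
}

#' Simulate a titration with known ground truth
#'
#' Emits a [titration_series()] whose first point carries assignments
#' (residue ids and Sparky-style labels) and whose later points are
#' unassigned peak lists built from [two_site_observables()] plus seeded
#' Gaussian positional noise.  Peaks below `detection_floor` times the
#' residue's base intensity are not emitted (finite signal-to-noise).
#'
#' @param spec A [synthetic_titration_spec()].
#' @param residues A [residue_truth()] data frame (>= 1 row).
#' @param detection_floor Relative intensity below which a peak is not
#'   detected.
#' @return A list with `series` (the titration) and `truth`: per-point
#'   regime labels (`regime_by_point`, residues x points), the final
#'   labels (`regime_final`), noiseless population-weighted positions
#'   (`obs_H`, `obs_N`), the noiseless weighted CSP matrix
#'   (`csp_noiseless`), per-residue endpoint CSPs (`delta_max`), and the
#'   spec itself.
#' @export
simulate_titration <- function(spec, residues, detection_floor = 0.1) {
  stopifnot(inherits(spec, "synthetic_titration_spec"))
  if (nrow(residues) == 0L) stopf("need at least one residue")
  lig <- spec$ligand_schedule_uM
  n_pts <- length(lig)
  n_res <- nrow(residues)
  regime_mat <- matrix(NA_character_, n_res, n_pts)
  obs_H <- matrix(NA_real_, n_res, n_pts)
  obs_N <- matrix(NA_real_, n_res, n_pts)
  points <- with_seed(spec$seed, lapply(seq_len(n_pts), function(i) {
    sh <- numeric(0); sn <- numeric(0); ii <- numeric(0)
    rid <- integer(0); lab <- character(0)
    for (r in seq_len(n_res)) {
      tr <- residues[r, ]
      o <- two_site_observables(tr, spec, lig[i])
      regime_mat[r, i] <<- o$regime_truth
      obs_H[r, i] <<- o$obs_H
      obs_N[r, i] <<- o$obs_N
      pk <- o$peaks[o$peaks$rel_intensity >= detection_floor, , drop = FALSE]
      if (nrow(pk) == 0L) next
      keep_id <- if (i == 1L) tr$residue_id else NA_integer_
      for (j in seq_len(nrow(pk))) {
        sh <- c(sh, pk$shift_H[j] + rnorm(1, 0, spec$noise_sd_H))
        sn <- c(sn, pk$shift_N[j] + rnorm(1, 0, spec$noise_sd_N))
        ii <- c(ii, pk$rel_intensity[j] * tr$base_intensity)
        rid <- c(rid, if (j == 1L) keep_id else NA_integer_)
        lab <- c(lab, if (j == 1L && i == 1L)
          paste0("A", tr$residue_id, "N-H") else "?-?")
      }
    }
    pl <- new_peak_list(lab, rid, sh, sn, ii, point_index = i - 1L,
                        dialect = "tsv")
    new_titration_point(i - 1L, spec$protein_total_uM, lig[i], pl)
  }))
  series <- titration_series(points, spec$spectrometer_1H_MHz,
                             spec$nitrogen_frequency_ratio)
  csp_noiseless <- matrix(NA_real_, n_res, n_pts)
  for (r in seq_len(n_res))
    csp_noiseless[r, ] <- weighted_csp(obs_H[r, ], obs_N[r, ],
                                       residues$free_H[r],
                                       residues$free_N[r])
  delta_max <- weighted_csp(residues$bound_H, residues$bound_N,
                            residues$free_H, residues$free_N)
  rownames(regime_mat) <- rownames(obs_H) <- rownames(obs_N) <-
    rownames(csp_noiseless) <- residues$residue_id
  list(series = series,
       truth = list(spec = spec, residues = residues,
                    regime_by_point = regime_mat,
                    regime_final = setNames(regime_mat[, n_pts],
                                            residues$residue_id),
                    obs_H = obs_H, obs_N = obs_N,
                    csp_noiseless = csp_noiseless,
                    delta_max = setNames(delta_max, residues$residue_id)))
}

# Collision-free free-state peak layout: 3-ppm 15N lanes, and once the
# lanes are exhausted a fresh 1H band 1.5 ppm away.  With endpoint shift
# changes bounded by 0.3 ppm (1H) and 1.4 ppm (15N), no two peaks of
# different residues ever approach within the tracking step limits used
# in this package.
layout_free_positions <- function(n) {
  k <- seq_len(n) - 1L
  lane <- k %% 12L
  band <- k %/% 12L
  list(free_H = 6 + 1.5 * band + stats::runif(n, 0, 0.6),
       free_N = 100 + 3 * lane)
}

#' Build a residue set that lands in a target exchange regime
#'
#' Residues are placed on well-separated 15N lanes (no tracking
#' cross-talk) with endpoint CSP amplitudes typical of an RNA-binding
#' interface, and each residue's off-rate is chosen so that
#' `k_ex / max(|dw|)` equals `target_ratio` at an anchor titration
#' point.  Because `k_ex = k_on [L_free] + k_off` grows as ligand is
#' added, the anchor matters: fast and intermediate targets are anchored
#' at the first ligand point (the ratio then drifts upward but stays in
#' class for moderate `K_D / P_T`), while slow targets are anchored at
#' the final point (earlier points are slower still).
#'
#' @param spec A [synthetic_titration_spec()].
#' @param n Number of residues.
#' @param target_ratio Desired `k_ex / max(|delta_omega|)` at the anchor
#'   (>= 5 fast, <= 0.2 slow, else intermediate).
#' @param anchor `"auto"` (first point for `target_ratio >= 1`, final
#'   otherwise), `"first"` or `"final"`.
#' @param id_offset Residue ids start at `id_offset + 1`.
#' @param dmax_H,dmax_N Ranges (ppm) for the endpoint 1H and 15N shift
#'   differences.
#' @return A [residue_truth()] data frame.
#' @export
regime_fixture_residues <- function(spec, n, target_ratio,
                                    anchor = c("auto", "first", "final"),
                                    id_offset = 0L,
                                    dmax_H = c(0.15, 0.3),
                                    dmax_N = c(0.75, 1.4)) {
  stopifnot(inherits(spec, "synthetic_titration_spec"))
  anchor <- match.arg(anchor)
  if (anchor == "auto") anchor <- if (target_ratio >= 1) "first" else "final"
  lig <- spec$ligand_schedule_uM
  L_anchor <- if (anchor == "first") lig[lig > 0][1] else max(lig)
  p_a <- equilibrium_oracle(spec$true_kd_uM, spec$protein_total_uM, L_anchor)
  L_free_a <- max(L_anchor - p_a * spec$protein_total_uM, 0)
  sub_seed <- as.integer((spec$seed + 97 * round(target_ratio * 1000)) %%
                           2147483647)
  with_seed(sub_seed, {
    dH <- stats::runif(n, dmax_H[1], dmax_H[2]) *
      sample(c(-1, 1), n, replace = TRUE)
    dN <- stats::runif(n, dmax_N[1], dmax_N[2])
    pos <- layout_free_positions(n)
    dw_H <- abs(dH) * spec$spectrometer_1H_MHz * 2 * pi
    dw_N <- abs(dN) * spec$spectrometer_1H_MHz *
      spec$nitrogen_frequency_ratio * 2 * pi
    dw_max <- pmax(dw_H, dw_N)
    # k_ex(anchor) = k_off * (1 + L_free_a / K_D) = target_ratio * dw_max
    k_off <- target_ratio * dw_max / (1 + L_free_a / spec$true_kd_uM)
    residue_truth(id_offset + seq_len(n), pos$free_H, pos$free_N,
                  pos$free_H + dH, pos$free_N + dN, k_off)
  })
}

#' Build a deep-fast-exchange residue set
#'
#' Residues on well-separated 15N lanes with a very large off-rate
#' (default 1e6 1/s), so that exchange is fast at every titration point
#' regardless of how much `k_ex` grows with free ligand; peak positions
#' then report the population-weighted average throughout and broadening
#' losses are negligible.  This is the fixture of choice for
#' dissociation-constant recovery studies.
#'
#' @inheritParams regime_fixture_residues
#' @param k_off Off-rate, 1/s.
#' @return A [residue_truth()] data frame.
#' @export
fast_residue_set <- function(spec, n, id_offset = 0L, k_off = 1e6,
                             dmax_H = c(0.08, 0.2), dmax_N = c(0.4, 1.0)) {
  stopifnot(inherits(spec, "synthetic_titration_spec"))
  with_seed(as.integer((spec$seed + 31L) %% 2147483647), {
    dH <- stats::runif(n, dmax_H[1], dmax_H[2]) *
      sample(c(-1, 1), n, replace = TRUE)
    dN <- stats::runif(n, dmax_N[1], dmax_N[2])
    pos <- layout_free_positions(n)
    residue_truth(id_offset + seq_len(n), pos$free_H, pos$free_N,
                  pos$free_H + dH, pos$free_N + dN, k_off)
  })
}

#' Simulate dual-luciferase reporter wells
#'
#' Renilla/firefly pairs with lognormal multiplicative noise: each
#' firefly reading is `F0 * exp(e_f)` and each Renilla reading is
#' `true_nlu * (R0/F0) * firefly * exp(e_r)`, with `e` centred so the
#' expected well ratio equals the condition's true NLU times the control
#' ratio; `normalize_slap()` on noiseless wells therefore returns the
#' specified means exactly.
#'
#' @param effects Named numeric vector of true mean NLUs per condition;
#'   must include the control at 1.
#' @param n Replicates per condition.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @param control Name of the control condition within `effects`.
#' @return A wells data frame (`condition`, `replicate`, `renilla_rlu`,
#'   `firefly_rlu`).
#' @export
simulate_slap <- function(effects, n = 3, noise_cv = 0.05, seed = 1L,
                          control = "control") {
  if (is.null(names(effects)) || !(control %in% names(effects)))
    stopf("effects must be named and include the control condition '%s'",
          control)
  if (effects[[control]] != 1)
    stopf("control condition must have true mean NLU 1")
  if (n < 1L) stopf("need n >= 1 replicates")
  s <- sqrt(log(1 + noise_cv^2))
  F0 <- 1e6; R0_over_F0 <- 0.1
  with_seed(seed, {
    rows <- lapply(names(effects), function(cond) {
      ef <- stats::rnorm(n, 0, s) - s^2 / 2   # E[exp(ef)] = 1
      er <- stats::rnorm(n, 0, s) - s^2 / 2
      if (noise_cv == 0) ef <- er <- rep(0, n)
      firefly <- F0 * exp(ef)
      renilla <- effects[[cond]] * R0_over_F0 * firefly * exp(er)
      data.frame(condition = cond, replicate = seq_len(n),
                 renilla_rlu = renilla, firefly_rlu = firefly)
    })
    do.call(rbind, rows)
  })
}

#' Simulate per-cell nuclear/cytoplasmic box intensities
#'
#' Three cytoplasmic boxes near intensity 1 and three nuclear boxes near
#' `true_ratio`, with lognormal multiplicative noise of coefficient of
#' variation `noise_cv`; with zero noise every per-cell ratio equals
#' `true_ratio` exactly.
#'
#' @param true_ratio Ground-truth nuclear/cytoplasmic ratio (> 0).
#' @param n_cells Number of cells (>= 1).
#' @param noise_cv Coefficient of variation of the box noise.
#' @param seed RNG seed.
#' @param channel Channel label stored in the table.
#' @return A cell-box data frame (`cell_id`, `channel`, `nuc1..3`,
#'   `cyt1..3`).
#' @export
simulate_cell_boxes <- function(true_ratio, n_cells, noise_cv = 0.1,
                                seed = 1L, channel = "ch1") {
  if (!is_scalar_number(true_ratio) || true_ratio <= 0)
    stopf("true_ratio must be > 0")
  if (n_cells < 1L) stopf("need n_cells >= 1")
  s <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    noise <- function(k) if (noise_cv == 0) rep(1, k)
                         else exp(stats::rnorm(k, -s^2 / 2, s))
    nuc <- matrix(true_ratio * noise(3 * n_cells), n_cells, 3)
    cyt <- matrix(noise(3 * n_cells), n_cells, 3)
    data.frame(cell_id = sprintf("cell_%03d", seq_len(n_cells)),
               channel = channel,
               nuc1 = nuc[, 1], nuc2 = nuc[, 2], nuc3 = nuc[, 3],
               cyt1 = cyt[, 1], cyt2 = cyt[, 2], cyt3 = cyt[, 3])
  })
}

#' Write a simulated titration to disk
#'
#' Emits one peak-list file per point plus a titration table consumable
#' by [read_titration_table()], in either dialect.
#'
#' @param sim Result of [simulate_titration()] (or a bare
#'   [titration_series()]).
#' @param dir Output directory (created if needed).
#' @param dialect `"tsv"` or `"sparky"`.
#' @return Invisibly, the titration-table path.
#' @export
write_titration <- function(sim, dir, dialect = c("tsv", "sparky")) {
  dialect <- match.arg(dialect)
  series <- if (inherits(sim, "titration_series")) sim else sim$series
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "sparky") "list" else "tsv"
  rows <- character(0)
  for (pt in series$points) {
    fn <- sprintf("point_%02d.%s", pt$point_index, ext)
    write_peak_list(pt$peaks, file.path(dir, fn), dialect)
    rows <- c(rows, paste(pt$point_index, fn, pt$protein_total_uM,
                          pt$ligand_total_uM, sep = "\t"))
  }
  tab <- file.path(dir, "titration.tsv")
  writeLines(c(sprintf("# spectrometer_1H_MHz\t%.10g",
                       series$spectrometer_1H_MHz),
               sprintf("# nitrogen_frequency_ratio\t%.10g",
                       series$nitrogen_frequency_ratio),
               "point_index\tpeaklist_path\tprotein_total_uM\tligand_total_uM",
               rows), tab)
  invisible(tab)
}
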