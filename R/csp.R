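# Weighted chemical shift perturbations, peak tracking across a
# titration, saturation detection and exchange-regime classification.

#' Weighted 1H/15N chemical shift perturbation
#'
#' The combined amide CSP between a state and a reference state,
#' \deqn{\Delta\delta = \sqrt{((\delta_N - \delta_N^{ref})^2/25 +
#'   (\delta_H - \delta_H^{ref})^2)/2}}
#' i.e. the 15N difference is down-weighted by the conventional factor 5
#' before the root-mean-square combination with the 1H difference.  The
#' result is a scaled Euclidean metric on the (1H, 15N) plane: symmetric
#' in its two states, zero iff both differences are zero, and satisfying
#' the triangle inequality.
#'
#' @param shift_H,shift_N Chemical shifts of the state, ppm.
#' @param ref_H,ref_N Chemical shifts of the reference state, ppm.
#' @return The weighted CSP in ppm (vectorized).
#' @examples
#' weighted_csp(8.22, 121.9, 8.12, 121.4)  # = 0.1 ppm exactly
#' @export
weighted_csp <- function(shift_H, shift_N, ref_H, ref_N) {
  if (any(!is.finite(c(shift_H, shift_N, ref_H, ref_N))))
    stopf("weighted_csp: all chemical shifts must be finite")
  sqrt((((shift_N - ref_N)^2) / 25 + (shift_H - ref_H)^2) / 2)
}

new_residue_trajectory <- function(residue_id, shift_H, shift_N, intensity) {
  structure(list(residue_id = residue_id,
                 shift_H = shift_H, shift_N = shift_N,
                 intensity = intensity,
                 observed = is.finite(shift_H) & is.finite(shift_N)),
            class = "residue_trajectory")
}

#' Track assigned peaks across a titration
#'
#' Starting from the assigned peaks of the ligand-free reference point,
#' each residue's peak is followed greedily through successive titration
#' points: from its last observed position it is linked to the nearest
#' peak (in the [weighted_csp()] metric) of the next point's list,
#' provided the distance does not exceed `max_step`.  Each peak is
#' consumed by at most one trajectory; conflicts are resolved by smaller
#' distance, then by intensity ratio closest to 1, then by lower residue
#' id, making the result deterministic.  Points with no admissible peak
#' are marked missing; linking always anchors at the last observed
#' position (no extrapolation across gaps).
#'
#' @param series A [titration_series()] whose first point carries residue
#'   assignments.
#' @param max_step Maximum combined-metric movement (ppm) allowed for a
#'   single link.  The default suits titrations whose per-step peak
#'   movement is small compared to peak separation.
#' @return A `residue_trajectories` object (list of per-residue
#'   trajectories, attribute `n_points`).
#' @export
track_peaks <- function(series, max_step = 0.04) {
  stopifnot(inherits(series, "titration_series"))
  if (!is_scalar_number(max_step) || max_step <= 0)
    stopf("max_step must be > 0")
  p0 <- series$points[[1]]$peaks
  seed_rows <- which(!is.na(p0$residue_id))
  if (length(seed_rows) == 0L)
    stopf("first titration point carries no residue assignments")
  rid <- p0$residue_id[seed_rows]
  n_res <- length(rid)
  n_pts <- length(series$points)
  H <- matrix(NA_real_, n_res, n_pts)
  N <- matrix(NA_real_, n_res, n_pts)
  I <- matrix(NA_real_, n_res, n_pts)
  H[, 1] <- p0$shift_H[seed_rows]
  N[, 1] <- p0$shift_N[seed_rows]
  I[, 1] <- p0$intensity[seed_rows]
  last_H <- H[, 1]; last_N <- N[, 1]; last_I <- I[, 1]
  for (t in seq_len(n_pts)[-1]) {
    pk <- series$points[[t]]$peaks
    if (nrow(pk) == 0L) next
    # candidate links within max_step, greedy resolution
    cand <- NULL
    for (r in seq_len(n_res)) {
      d <- weighted_csp(pk$shift_H, pk$shift_N, last_H[r], last_N[r])
      ok <- which(d <= max_step)
      if (length(ok))
        cand <- rbind(cand, data.frame(res = r, peak = ok, d = d[ok]))
    }
    if (!is.null(cand) && nrow(cand)) {
      ratio <- pk$intensity[cand$peak] / last_I[cand$res]
      # distance from an intensity ratio of 1, symmetric in r and 1/r
      cand$tie <- ifelse(is.finite(ratio) & ratio > 0,
                         abs(log(ratio)), Inf)
      cand$rid <- rid[cand$res]
      cand <- cand[order(cand$d, cand$tie, cand$rid), , drop = FALSE]
      used_res <- logical(n_res)
      used_peak <- logical(nrow(pk))
      for (k in seq_len(nrow(cand))) {
        r <- cand$res[k]; p <- cand$peak[k]
        if (used_res[r] || used_peak[p]) next
        used_res[r] <- TRUE; used_peak[p] <- TRUE
        H[r, t] <- pk$shift_H[p]
        N[r, t] <- pk$shift_N[p]
        I[r, t] <- pk$intensity[p]
        last_H[r] <- H[r, t]; last_N[r] <- N[r, t]
        if (is.finite(I[r, t])) last_I[r] <- I[r, t]
      }
    }
  }
  trajs <- lapply(seq_len(n_res), function(r)
    new_residue_trajectory(rid[r], H[r, ], N[r, ], I[r, ]))
  structure(trajs, n_points = n_pts, class = "residue_trajectories")
}

#' @export
print.residue_trajectories <- function(x, ...) {
  n_obs <- vapply(x, function(t) sum(t$observed), integer(1))
  cat(sprintf("residue_trajectories: %d residues x %d points (median %d observed)\n",
              length(x), attr(x, "n_points"), as.integer(stats::median(n_obs))))
  invisible(x)
}

#' Has a trajectory reached saturation?
#'
#' A titration is saturated for a residue when its peak has stopped
#' moving: the weighted CSP between the last two observed states is at
#' most `tol`.
#'
#' @param traj A `residue_trajectory`.
#' @param tol Saturation tolerance, ppm.
#' @return `TRUE` or `FALSE`.
#' @export
check_saturation <- function(traj, tol = 0.005) {
  stopifnot(inherits(traj, "residue_trajectory"))
  obs <- which(traj$observed)
  if (length(obs) < 2L)
    stopf("residue %s: fewer than 2 observed states", traj$residue_id)
  i <- obs[length(obs) - 1L]; j <- obs[length(obs)]
  weighted_csp(traj$shift_H[j], traj$shift_N[j],
               traj$shift_H[i], traj$shift_N[i]) <= tol
}

#' Classify the chemical-exchange regime of a trajectory
#'
#' Data-driven classification from peak positions and intensities (the
#' exchange rate itself is not observable from peak lists):
#' \itemize{
#'   \item \emph{fast}: the peak is observed at every point with
#'     intensity at least `min_intensity_frac` of its ligand-free
#'     intensity -- one population-averaged peak migrating smoothly.
#'   \item \emph{intermediate}: the peak is attenuated (an interior or
#'     trailing point missing, or intensity dropping below the fraction)
#'     \emph{while} its position has migrated by more than `reappear_tol`
#'     -- exchange broadening of a moving peak.
#'   \item \emph{slow}: the peak is attenuated but its position has not
#'     moved (net CSP at most `reappear_tol`) -- the free-state peak
#'     fades in place while a bound-state peak grows elsewhere.
#'   \item \emph{unresolved}: fewer than two observed states.
#' }
#' Intensity criteria are skipped when intensities are absent from the
#' peak lists.
#'
#' @param traj A `residue_trajectory` with at least 3 points.
#' @param min_intensity_frac Fraction of the ligand-free intensity below
#'   which a peak counts as attenuated.
#' @param reappear_tol Net positional movement (ppm, combined metric)
#'   separating a migrating peak from one fading in place.
#' @return One of `"fast"`, `"intermediate"`, `"slow"`, `"unresolved"`.
#' @export
classify_exchange <- function(traj, min_intensity_frac = 0.5,
                              reappear_tol = 0.02) {
  stopifnot(inherits(traj, "residue_trajectory"))
  n <- length(traj$observed)
  if (n < 3L) stopf("residue %s: too few titration points (%d < 3)",
                    traj$residue_id, n)
  obs <- which(traj$observed)
  if (length(obs) < 2L) return("unresolved")
  i0 <- obs[1]
  attenuated <- any(!traj$observed)
  ints <- traj$intensity[obs]
  if (!attenuated && all(is.finite(ints)) && is.finite(ints[1]) && ints[1] > 0)
    attenuated <- any(ints / traj$intensity[i0] < min_intensity_frac)
  il <- obs[length(obs)]
  total_move <- weighted_csp(traj$shift_H[il], traj$shift_N[il],
                             traj$shift_H[i0], traj$shift_N[i0])
  if (!attenuated) "fast"
  else if (total_move > reappear_tol) "intermediate"
  else "slow"
}

#' Compute per-residue CSP profiles
#'
#' For each tracked residue, the weighted CSP of every observed point
#' against the ligand-free reference, the observed maximal CSP (at the
#' last observed point), the saturation flag (`FALSE` whenever the final
#' point is untracked) and the exchange-regime label.
#'
#' @param trajectories A `residue_trajectories` object from
#'   [track_peaks()].
#' @param tol Saturation tolerance (ppm), see [check_saturation()].
#' @param min_intensity_frac,reappear_tol Passed to
#'   [classify_exchange()].
#' @return A `csp_profiles` object: residue ids, a residues-by-points CSP
#'   matrix (`NA` where untracked), `csp_max_observed`, `regime`,
#'   `saturated`.
#' @export
compute_profiles <- function(trajectories, tol = 0.005,
                             min_intensity_frac = 0.5, reappear_tol = 0.02) {
  stopifnot(inherits(trajectories, "residue_trajectories"))
  n_pts <- attr(trajectories, "n_points")
  n_res <- length(trajectories)
  csp <- matrix(NA_real_, n_res, n_pts)
  rid <- integer(n_res)
  cmax <- numeric(n_res)
  regime <- character(n_res)
  sat <- logical(n_res)
  for (r in seq_len(n_res)) {
    tr <- trajectories[[r]]
    rid[r] <- tr$residue_id
    obs <- which(tr$observed)
    csp[r, obs] <- weighted_csp(tr$shift_H[obs], tr$shift_N[obs],
                                tr$shift_H[1], tr$shift_N[1])
    last <- obs[length(obs)]
    cmax[r] <- csp[r, last]
    sat[r] <- length(obs) >= 2L && last == n_pts && check_saturation(tr, tol)
    regime[r] <- if (n_pts >= 3L)
      classify_exchange(tr, min_intensity_frac, reappear_tol)
    else "unresolved"
  }
  rownames(csp) <- rid
  structure(list(residue_id = rid, csp = csp, csp_max_observed = cmax,
                 regime = regime, saturated = sat, n_points = n_pts),
            class = "csp_profiles")
}

#' @export
print.csp_profiles <- function(x, ...) {
  cat(sprintf("csp_profiles: %d residues x %d points\n",
              length(x$residue_id), x$n_points))
  cat("  regimes:", paste(sprintf("%s=%d", names(table(x$regime)),
                                  table(x$regime)), collapse = ", "), "\n")
  cat(sprintf("  csp_max_observed: %.4f .. %.4f ppm; %d/%d saturated\n",
              min(x$csp_max_observed), max(x$csp_max_observed),
              sum(x$saturated), length(x$saturated)))
  invisible(x)
}
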