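# One-site binding isotherm and global dissociation-constant fitting.
#
# The bound fraction of protein under a 1:1 equilibrium P + L <-> PL with
# dissociation constant K_D and *total* concentrations [P]_T, [L]_T is the
# physical root of the mass-action quadratic,
#   f_b = ((K_D + P_T + L_T) - sqrt((K_D + P_T + L_T)^2 - 4 P_T L_T)) / (2 P_T),
# evaluated here in the conjugate (cancellation-safe) form
#   f_b = 2 L_T / (b + sqrt(b^2 - 4 P_T L_T)),   b = K_D + P_T + L_T,
# which avoids subtractive cancellation when K_D >> P_T.  A per-residue
# CSP trajectory is modelled as delta_max * f_b; the global fit shares
# K_D across residues while each residue keeps its own delta_max.

#' Fraction of protein bound at a titration point
#'
#' @param kd_uM Dissociation constant, uM (> 0).
#' @param protein_total_uM Total protein concentration, uM (> 0).
#' @param ligand_total_uM Total ligand concentration, uM (>= 0);
#'   vectorized.
#' @return Bound fraction in `[0, min(1, L_T/P_T)]`.
#' @examples
#' fraction_bound(100, 100, 100)  # (3 - sqrt(5)) / 2
#' @export
fraction_bound <- function(kd_uM, protein_total_uM, ligand_total_uM) {
  if (any(!is.finite(kd_uM)) || any(kd_uM <= 0))
    stopf("kd_uM must be a positive finite number")
  if (any(!is.finite(protein_total_uM)) || any(protein_total_uM <= 0))
    stopf("protein_total_uM must be a positive finite number")
  if (any(!is.finite(ligand_total_uM)) || any(ligand_total_uM < 0))
    stopf("ligand_total_uM must be finite and >= 0")
  b <- kd_uM + protein_total_uM + ligand_total_uM
  disc <- pmax(b^2 - 4 * protein_total_uM * ligand_total_uM, 0)
  fb <- 2 * ligand_total_uM / (b + sqrt(disc))
  pmax(pmin(fb, 1, ligand_total_uM / protein_total_uM), 0)
}

#' Independent mass-action equilibrium oracle
#'
#' Solves `K_D = (P_T - PL)(L_T - PL) / PL` for the complex concentration
#' `PL` by bisection on `[0, min(P_T, L_T)]` to an absolute tolerance of
#' 1e-12 uM and returns `PL / P_T`.  This is a deliberately independent
#' route to the same quantity as [fraction_bound()], used to validate the
#' closed-form root.
#'
#' @inheritParams fraction_bound
#' @return Bound fraction in `[0, 1]` (vectorized over
#'   `ligand_total_uM`).
#' @export
equilibrium_oracle <- function(kd_uM, protein_total_uM, ligand_total_uM) {
  if (any(!is.finite(kd_uM)) || any(kd_uM <= 0))
    stopf("kd_uM must be a positive finite number")
  if (any(!is.finite(protein_total_uM)) || any(protein_total_uM <= 0))
    stopf("protein_total_uM must be a positive finite number")
  if (any(!is.finite(ligand_total_uM)) || any(ligand_total_uM < 0))
    stopf("ligand_total_uM must be finite and >= 0")
  solve1 <- function(kd, P, L) {
    if (L == 0) return(0)
    lo <- 0; hi <- min(P, L)
    # f(PL) = (P - PL)(L - PL) - kd * PL, strictly decreasing on [lo, hi]
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if ((P - mid) * (L - mid) - kd * mid > 0) lo <- mid else hi <- mid
      if (hi - lo <= 1e-12) break
    }
    ((lo + hi) / 2) / P
  }
  mapply(solve1, kd_uM, protein_total_uM, ligand_total_uM)
}

#' Predicted weighted CSP under the one-site model
#'
#' @inheritParams fraction_bound
#' @param delta_max Maximal (fully bound) weighted CSP of the residue,
#'   ppm (>= 0).
#' @return `delta_max * fraction_bound(...)`, ppm.
#' @export
predict_csp <- function(kd_uM, delta_max, protein_total_uM, ligand_total_uM) {
  if (any(!is.finite(delta_max)) || any(delta_max < 0))
    stopf("delta_max must be finite and >= 0")
  delta_max * fraction_bound(kd_uM, protein_total_uM, ligand_total_uM)
}

#' Global one-site fit of a CSP titration
#'
#' Minimizes the unweighted sum over residues and titration points of
#' `(csp_observed - delta_max_res * fraction_bound(K_D, P_T, L_T))^2`
#' with a single shared `K_D` and one `delta_max` per residue
#' (Levenberg-Marquardt damped least squares; parameters bounded below at
#' 1e-6).  Missing points are excluded.  Because the model is linear in
#' each `delta_max` at fixed `K_D`, the fit is initialized from a
#' one-dimensional minimization of the profiled objective over `K_D`
#' (with the per-residue closed-form `delta_max`), which the joint
#' optimizer then refines.  The standard error
#' of `K_D` is `sqrt(s^2 * [(J'J)^-1]_{KD,KD})` with
#' `s^2 = rss / (n_points - n_parameters)` and `J` the Jacobian at the
#' optimum; a near-singular `J'J` (e.g. all-zero CSPs) yields `kd_se_uM =
#' NA` with a warning.  Optimizer failure is reported via
#' `converged = FALSE`, not an exception.
#'
#' @param profiles A `csp_profiles` object from [compute_profiles()].
#' @param series The [titration_series()] the profiles came from.
#' @param include Exchange regimes admitted to the fit (default
#'   `"fast"`, the only regime for which peak positions report the
#'   population-weighted average faithfully).
#' @param fix_dmax If `TRUE`, hold every `delta_max` fixed at the
#'   observed final CSP and fit `K_D` alone.
#' @param maxiter Iteration cap for the optimizer.
#' @return A `binding_fit` object: `kd_uM`, `kd_se_uM`,
#'   `delta_max_by_residue` (named, ppm), `rss` (ppm^2), `n_points`
#'   (residual count), `n_residues`, `converged`.
#' @export
fit_global <- function(profiles, series, include = "fast",
                       fix_dmax = FALSE, maxiter = 500) {
  stopifnot(inherits(profiles, "csp_profiles"),
            inherits(series, "titration_series"))
  n_pts <- length(series$points)
  if (n_pts < 3L) stopf("need >= 3 titration points for a global fit")
  if (profiles$n_points != n_pts)
    stopf("profiles (%d points) do not match series (%d points)",
          profiles$n_points, n_pts)
  sel <- which(profiles$regime %in% include)
  if (length(sel) == 0L)
    stopf("no residues pass the regime filter (%s)",
          paste(include, collapse = ", "))
  P_T <- vapply(series$points, `[[`, numeric(1), "protein_total_uM")
  L_T <- vapply(series$points, `[[`, numeric(1), "ligand_total_uM")
  # observation table: residue index (within sel), point index, csp
  res_i <- integer(0); pt_i <- integer(0); y <- numeric(0)
  for (k in seq_along(sel)) {
    r <- sel[k]
    obs <- which(!is.na(profiles$csp[r, ]))
    obs <- obs[obs > 1L]  # the reference point is identically zero
    res_i <- c(res_i, rep.int(k, length(obs)))
    pt_i <- c(pt_i, obs)
    y <- c(y, profiles$csp[r, obs])
  }
  n_res <- length(sel)
  n_obs <- length(y)
  dmax0 <- pmax(profiles$csp_max_observed[sel], 1e-6)
  n_par <- if (fix_dmax) 1L else 1L + n_res
  if (n_obs <= n_par)
    stopf("fewer residuals (%d) than parameters (%d): fit not identifiable",
          n_obs, n_par)
  resid_fun <- function(par) {
    kd <- par[1]
    dmax <- if (fix_dmax) dmax0 else par[-1]
    y - dmax[res_i] * fraction_bound(kd, P_T[pt_i], L_T[pt_i])
  }
  # Initialization: the model is separable -- at fixed K_D every
  # delta_max has the closed-form least-squares value
  # sum(y * f_b) / sum(f_b^2) -- so the profiled objective is
  # one-dimensional in K_D and can be minimized directly (on log K_D) to
  # seed the joint Levenberg-Marquardt refinement.  Starting the damped
  # least squares from an arbitrary K_D such as P_T can stall against
  # the lower parameter bound.
  dmax_at <- function(kd) {
    fb <- fraction_bound(kd, P_T[pt_i], L_T[pt_i])
    if (fix_dmax) return(dmax0)
    vapply(seq_len(n_res), function(k) {
      idx <- res_i == k
      den <- sum(fb[idx]^2)
      if (den == 0) dmax0[k] else max(sum(y[idx] * fb[idx]) / den, 1e-6)
    }, numeric(1))
  }
  profiled <- function(log_kd) {
    kd <- exp(log_kd)
    sum((y - dmax_at(kd)[res_i] *
           fraction_bound(kd, P_T[pt_i], L_T[pt_i]))^2)
  }
  scan <- stats::optimize(profiled, c(log(1e-6), log(1e6)), tol = 1e-10)
  kd0 <- exp(scan$minimum)
  par0 <- if (fix_dmax) kd0 else c(kd0, dmax_at(kd0))
  out <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = rep(1e-6, n_par), fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(out)) {
    warnf("optimizer failed; returning non-converged fit at initial values")
    fit <- list(kd_uM = kd0, kd_se_uM = NA_real_,
                delta_max_by_residue = setNames(dmax0,
                                                profiles$residue_id[sel]),
                rss = sum(resid_fun(par0)^2), n_points = n_obs,
                n_residues = n_res, converged = FALSE,
                include = include, fix_dmax = fix_dmax)
    return(structure(fit, class = "binding_fit"))
  }
  par <- out$par
  kd_hat <- par[1]
  dmax_hat <- if (fix_dmax) dmax0 else par[-1]
  rss <- sum(resid_fun(par)^2)
  converged <- out$info %in% c(1L, 2L, 3L, 4L)
  kd_se <- NA_real_
  if (n_obs > n_par) {
    J <- numeric_jacobian(resid_fun, par)
    JtJ <- crossprod(J)
    s2 <- rss / (n_obs - n_par)
    inv <- tryCatch(solve(JtJ), error = function(e) NULL)
    if (is.null(inv) || !is.finite(inv[1, 1]) || inv[1, 1] <= 0 ||
        rcond_est(JtJ) < 1e-12) {
      warnf("near-singular covariance matrix; kd_se_uM is unreliable (NA)")
      kd_se <- NA_real_
    } else {
      kd_se <- sqrt(s2 * inv[1, 1])
    }
  }
  fit <- list(kd_uM = kd_hat, kd_se_uM = kd_se,
              delta_max_by_residue = setNames(dmax_hat,
                                              profiles$residue_id[sel]),
              rss = rss, n_points = n_obs, n_residues = n_res,
              converged = converged, include = include, fix_dmax = fix_dmax)
  structure(fit, class = "binding_fit")
}

# Forward-difference Jacobian of a residual function.
numeric_jacobian <- function(fn, par, rel_step = 1e-7) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- rel_step * max(abs(par[j]), 1e-3)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

rcond_est <- function(M) {
  d <- tryCatch(svd(M, nu = 0, nv = 0)$d, error = function(e) c(1, 0))
  if (max(d) == 0) 0 else min(d) / max(d)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Global one-site binding fit\n")
  cat(sprintf("  K_D = %.4g uM (SE %.3g uM, 1-sigma from covariance)\n",
              x$kd_uM, x$kd_se_uM))
  cat(sprintf("  %d residues (%s exchange), %d residuals, rss = %.4g ppm^2\n",
              x$n_residues, paste(x$include, collapse = "/"), x$n_points,
              x$rss))
  cat(sprintf("  converged: %s; delta_max %s\n", x$converged,
              if (x$fix_dmax) "fixed at observed endpoints" else "fitted"))
  invisible(x)
}
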