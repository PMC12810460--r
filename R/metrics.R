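# Agreement metrics between phase sets and ground truth, with search over the
# permissible origins of P2(1)/c.

#' Permissible origin shifts of P2\eqn{_1}/c
#'
#' The eight inversion centres at coordinates 0 or 1/2 along each axis.
#' Shifting the origin by `delta` changes every phase by `-2 pi (h . delta)`,
#' i.e. flips the sign of reflections with odd `h . 2delta`.
#'
#' @return 8 x 3 matrix of fractional shifts.
#' @export
origin_shifts <- function() {
  as.matrix(expand.grid(dx = c(0, 0.5), dy = c(0, 0.5), dz = c(0, 0.5)))
}

# phase increment (radians) applied to each reflection by origin shift delta
origin_phase_shift <- function(hkl, delta) {
  H <- as_hkl_matrix(hkl)
  pi * (H %*% (2 * delta))[, 1L]
}

#' Mean phase error with permissible-origin search
#'
#' Unweighted mean of the wrapped absolute phase difference over the common
#' reflections, minimized over the eight permissible origin shifts applied to
#' the second argument.
#'
#' @param hkl n x 3 canonical Miller indices of the compared reflections.
#' @param phi,truth Phase vectors in radians.
#' @param origin_search If `FALSE`, compare at the fixed origin.
#' @return Mean phase error in degrees, in `[0, 180]`.
#' @export
mean_phase_error <- function(hkl, phi, truth, origin_search = TRUE) {
  if (length(phi) == 0L) stopf("mean_phase_error: empty reflection set")
  deltas <- if (origin_search) origin_shifts() else matrix(0, 1, 3)
  best <- Inf
  for (i in seq_len(nrow(deltas))) {
    sh <- origin_phase_shift(hkl, deltas[i, ])
    mpe <- mean(abs(wrap_angle(phi - truth - sh)))
    best <- min(best, mpe)
  }
  deg(best)
}

#' Map correlation with permissible-origin search
#'
#' Pearson correlation between the electron-density maps synthesized from the
#' two phase sets on identical grids with identical amplitudes. By Parseval's
#' theorem (the F(000) term is excluded, so both maps have zero mean) this
#' equals the multiplicity- and amplitude-weighted mean of
#' `cos(phi1 - phi2)` over the unique reflections, which is how it is
#' computed; the grid route is available through [fourier_synthesis()] for
#' cross-checking.
#'
#' @param hkl n x 3 canonical Miller indices.
#' @param phi,truth Phase vectors in radians.
#' @param amp Shared amplitudes (normally `E` values).
#' @param origin_search Maximize over the eight permissible origins.
#' @return Correlation in `[-1, 1]`.
#' @export
map_correlation <- function(hkl, phi, truth, amp, origin_search = TRUE) {
  if (all(amp == 0)) stopf("map_correlation: zero-variance map")
  w <- orbit_multiplicity(hkl) * amp^2
  deltas <- if (origin_search) origin_shifts() else matrix(0, 1, 3)
  best <- -Inf
  for (i in seq_len(nrow(deltas))) {
    sh <- origin_phase_shift(hkl, deltas[i, ])
    cc <- sum(w * cos(phi - truth - sh)) / sum(w)
    best <- max(best, cc)
  }
  best
}

#' Crystallographic agreement factor
#'
#' `R_f = sum | |F_obs| - k |F_calc| | / sum |F_obs|` with the least-squares
#' scale `k = sum |F_obs||F_calc| / sum |F_calc|^2`; invariant under uniform
#' rescaling of either amplitude list.
#'
#' @param f_obs,f_calc Matched amplitude vectors (`>= 0`).
#' @return The scaled R factor.
#' @examples
#' r_factor(c(10, 20), c(20, 10))  # 0.6
#' @export
r_factor <- function(f_obs, f_calc) {
  if (length(f_obs) != length(f_calc)) stopf("r_factor: length mismatch")
  if (all(f_obs == 0)) stopf("r_factor: all observations zero")
  k <- sum(f_obs * f_calc) / sum(f_calc^2)
  sum(abs(f_obs - k * f_calc)) / sum(f_obs)
}

# Joint metric evaluation for a solution: one physical origin (the shift that
# minimizes the MPE) is used for both MPE and CORR.
solution_metrics <- function(rs, phi) {
  refl <- rs$refl
  if (is.null(refl$phi_true)) return(list(MPE_final = NA_real_, CORR_final = NA_real_))
  H <- as.matrix(refl[, c("h", "k", "l")])
  deltas <- origin_shifts()
  w <- orbit_multiplicity(H) * refl$E^2
  best <- NULL
  for (i in seq_len(nrow(deltas))) {
    sh <- origin_phase_shift(H, deltas[i, ])
    diffs <- wrap_angle(phi - refl$phi_true - sh)
    mpe <- mean(abs(diffs))
    if (is.null(best) || mpe < best$mpe) {
      best <- list(mpe = mpe, corr = sum(w * cos(diffs)) / sum(w))
    }
  }
  list(MPE_final = deg(best$mpe), CORR_final = best$corr)
}
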