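# Reflection lists, structure factors and normalized E values for Laue
# class 2/m with the P2(1)/c translational symmetry.

#' Canonical representative of a reflection under Laue class 2/m
#'
#' The orbit of `(h,k,l)` under 2/m (plus Friedel symmetry) is
#' `{(h,k,l), (-h,k,-l), (-h,-k,-l), (h,-k,l)}`. The canonical representative
#' is the member with `k >= 0` and (`l > 0`, or `l = 0` and `h > 0`, or
#' `l = h = 0` and `k > 0`). Because of the 2\eqn{_1} screw and c-glide
#' translations, the phase of an orbit member differs from the canonical
#' phase by `pi*(k + l)`; the returned `factor` is the corresponding sign
#' (`+1` or `-1`) relating structure-factor signs.
#'
#' @param hkl Length-3 integer vector or n x 3 matrix.
#' @return List with `hkl` (n x 3 canonical indices) and `factor` (signs).
#' @export
canonical_hkl <- function(hkl) {
  H <- as_hkl_matrix(hkl)
  n <- nrow(H)
  h <- H[, 1L]; k <- H[, 2L]; l <- H[, 3L]
  if (any(h == 0 & k == 0 & l == 0)) stopf("canonical_hkl: (0,0,0) is not a reflection")
  f <- ifelse((k + l) %% 2L == 0L, 1, -1)
  mh <- list(h, -h, -h, h)
  mk <- list(k, -k, k, -k)
  ml <- list(l, -l, -l, l)
  mf <- list(rep(1, n), rep(1, n), f, f)
  outh <- integer(n); outk <- integer(n); outl <- integer(n); outf <- numeric(n)
  done <- rep(FALSE, n)
  for (m in 1:4) {
    hh <- mh[[m]]; kk <- mk[[m]]; ll <- ml[[m]]
    ok <- !done & kk >= 0L &
      (ll > 0L | (ll == 0L & hh > 0L) | (ll == 0L & hh == 0L & kk > 0L))
    outh[ok] <- hh[ok]; outk[ok] <- kk[ok]; outl[ok] <- ll[ok]; outf[ok] <- mf[[m]][ok]
    done <- done | ok
  }
  if (!all(done)) stopf("canonical_hkl: internal orbit failure")
  list(hkl = cbind(h = outh, k = outk, l = outl), factor = outf)
}

# systematic absences of P2(1)/c: h0l with l odd (c glide), 0k0 with k odd (2_1)
is_absent <- function(hkl) {
  H <- as_hkl_matrix(hkl)
  (H[, 2L] == 0L & H[, 3L] %% 2L != 0L) |
    (H[, 1L] == 0L & H[, 3L] == 0L & H[, 2L] %% 2L != 0L)
}

# epsilon (symmetry enhancement) factor for Laue 2/m: 2 on h0l and 0k0, else 1
epsilon_factor <- function(hkl) {
  H <- as_hkl_matrix(hkl)
  ifelse(H[, 2L] == 0L | (H[, 1L] == 0L & H[, 3L] == 0L), 2L, 1L)
}

# orbit multiplicity (number of distinct 2/m+Friedel mates / 2); 4/epsilon
orbit_multiplicity <- function(hkl) 4L / epsilon_factor(hkl)

#' Enumerate unique reflections to a resolution limit
#'
#' Lists one canonical representative per Laue 2/m orbit with `d >= res_limit`,
#' excluding the systematic absences of P2\eqn{_1}/c.
#'
#' @param cell A [unit_cell()].
#' @param res_limit Resolution limit in angstroms (`> 0`).
#' @return data.frame with columns `h`, `k`, `l`, `d`, `epsilon`, sorted by
#'   decreasing `d`.
#' @export
generate_hkl <- function(cell, res_limit) {
  if (res_limit <= 0) stopf("res_limit must be positive")
  hm <- ceiling(cell$a / res_limit) + 1L
  km <- ceiling(cell$b / res_limit) + 1L
  lm <- ceiling(cell$c / res_limit) + 1L
  g <- expand.grid(h = -hm:hm, k = 0:km, l = 0:lm)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  H <- as.matrix(g)
  can <- canonical_hkl(H)$hkl
  keep <- can[, 1L] == H[, 1L] & can[, 2L] == H[, 2L] & can[, 3L] == H[, 3L]
  H <- H[keep, , drop = FALSE]
  H <- H[!is_absent(H), , drop = FALSE]
  d <- d_spacing(cell, H)
  sel <- d >= res_limit
  H <- H[sel, , drop = FALSE]; d <- d[sel]
  o <- order(-d, H[, 1L], H[, 2L], H[, 3L])
  H <- H[o, , drop = FALSE]; d <- d[o]
  data.frame(h = H[, 1L], k = H[, 2L], l = H[, 3L], d = d,
             epsilon = epsilon_factor(H))
}

# point-atom scattering factor with thermal falloff: f = Z * exp(-b s^2 / 4),
# s = 1/d. E-normalization divides the radial part back out, so this simple
# model is adequate for normalized-amplitude work.
scatter_factor <- function(Z, b_iso, occ, s2) {
  # Z, b_iso, occ: length M; s2: length n -> n x M matrix
  outer(s2, b_iso, function(s, b) exp(-b * s / 4)) *
    rep(Z * occ, each = length(s2))
}

#' Structure factors by direct summation
#'
#' Sums `f_j exp(2 pi i h.x_j)` over all symmetry-expanded unit-cell sites.
#' For P2\eqn{_1}/c with the origin on the inversion centre the result is real
#' up to numerical noise; phases are snapped to `{0, pi}` by the sign of the
#' real part.
#'
#' @param structure A [crystal_structure()].
#' @param hkl n x 3 integer matrix of Miller indices (must not contain
#'   systematic absences).
#' @return List with complex `F`, real `F_real`, `phi` (0 or pi), and the
#'   maximum relative imaginary residue `im_residue`.
#' @export
calc_structure_factors <- function(structure, hkl) {
  H <- as_hkl_matrix(hkl)
  if (any(is_absent(H))) stopf("calc_structure_factors: systematically absent reflection requested")
  ex <- symmetry_expand(structure)
  P <- as.matrix(ex[, c("x", "y", "z")])
  s2 <- 1 / d_spacing(structure$cell, H)^2
  f <- scatter_factor(ex$Z, ex$b_iso, ex$occupancy, s2)   # n x M
  arg <- 2 * pi * (H %*% t(P))                            # n x M
  Fre <- rowSums(f * cos(arg))
  Fim <- rowSums(f * sin(arg))
  Fc <- complex(real = Fre, imaginary = Fim)
  amp <- Mod(Fc)
  imres <- max(abs(Fim) / pmax(amp, 1e-12))
  phi <- ifelse(Fre > 0, 0, ifelse(Fre < 0, pi, 0))
  if (any(Fre == 0)) warnf("calc_structure_factors: zero real part snapped to phi = 0")
  list(F = Fc, F_real = Fre, phi = phi, im_residue = imres)
}

# scatter sums over the full unit-cell content: sigma_n = sum (occ * Z)^n
scatter_sums <- function(structure) {
  ex <- symmetry_expand(structure)
  z <- ex$Z * ex$occupancy
  c(sigma2 = sum(z^2), sigma3 = sum(z^3))
}

#' Build the reflection set of a synthetic structure
#'
#' Enumerates unique reflections, computes true structure factors and phases,
#' sets noise-free observations `F_obs = |F_true|`, and fills normalized `E`
#' values.
#'
#' @param structure A [crystal_structure()].
#' @param res_limit Resolution limit in angstroms.
#' @return Object of class `reflection_set`: list with `cell`, `refl`
#'   (data.frame `h,k,l,d,epsilon,F_true,phi_true,F_obs,sigma,E`), `res_limit`,
#'   `scatter` (sigma2, sigma3 over the cell content) and `content` (expanded
#'   sites used for normalization).
#' @export
make_reflections <- function(structure, res_limit = 0.9) {
  hkl <- generate_hkl(structure$cell, res_limit)
  sf <- calc_structure_factors(structure, as.matrix(hkl[, c("h", "k", "l")]))
  refl <- hkl
  refl$F_true <- abs(sf$F_real)
  refl$phi_true <- sf$phi
  refl$F_obs <- refl$F_true
  refl$sigma <- 0
  rs <- structure(list(cell = structure$cell, refl = refl,
                       res_limit = res_limit,
                       completeness = 1,
                       scatter = scatter_sums(structure),
                       content = symmetry_expand(structure)),
                  class = "reflection_set")
  normalize_reflections(rs)
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection_set: %d unique reflections, res_limit=%.2f A\n",
              nrow(x$refl), x$res_limit))
  invisible(x)
}

#' Normalize amplitudes to E values
#'
#' Converts `F_obs` to normalized structure factors with
#' `E^2 = F^2 / (epsilon * Sigma f_j^2)`, then rescales in resolution shells
#' (equal-count, scale interpolated linearly between shell centres in
#' `s^2 = 1/d^2`) so that `<|E|^2> = 1`. When the cell content is unknown a
#' Wilson fit (`ln<F^2/epsilon> = ln K - 2 B s^2` by least squares) supplies
#' the radial falloff instead.
#'
#' @param rs A `reflection_set` with `F_obs` present.
#' @param nshells Number of resolution shells.
#' @return The reflection set with the `E` column (re)filled.
#' @export
normalize_reflections <- function(rs, nshells = 10) {
  refl <- rs$refl
  n <- nrow(refl)
  if (n == 0L) stopf("normalize_reflections: empty reflection set")
  s2 <- 1 / refl$d^2
  if (!is.null(rs$content)) {
    f <- scatter_factor(rs$content$Z, rs$content$b_iso, rs$content$occupancy, s2)
    sig <- rowSums(f^2)
  } else {
    y <- log(pmax(refl$F_obs^2 / refl$epsilon, 1e-12))
    fit <- stats::lm.fit(cbind(1, s2), y)
    sig <- exp(fit$coefficients[1] + fit$coefficients[2] * s2)
  }
  e2 <- refl$F_obs^2 / (refl$epsilon * sig)
  nshells <- max(1L, min(nshells, floor(n / 20)))
  if (nshells < 2L) {
    scale <- rep(mean(e2), n)
  } else {
    qs <- stats::quantile(s2, probs = seq(0, 1, length.out = nshells + 1))
    shell <- cut(s2, breaks = unique(qs), include.lowest = TRUE)
    if (nlevels(droplevels(shell)) < nshells)
      warnf("normalize_reflections: empty shells merged")
    ctr <- tapply(s2, shell, mean)
    m <- tapply(e2, shell, mean)
    ok <- is.finite(ctr) & is.finite(m) & m > 0
    scale <- stats::approx(ctr[ok], m[ok], xout = s2, rule = 2)$y
  }
  E2 <- e2 / scale
  E2 <- E2 / mean(E2)
  rs$refl$E <- sqrt(E2)
  rs
}

#' Simulate noisy, incomplete observations
#'
#' Applies multiplicative Gaussian noise `F_obs = |F_true| (1 + eta)`,
#' `eta ~ N(0, noise_fraction)`, removes a deterministic count
#' `n - round(completeness * n)` of randomly chosen reflections, and
#' re-normalizes E values from the observed amplitudes.
#'
#' @param rs A `reflection_set` carrying `F_true`.
#' @param noise_fraction Relative amplitude noise level (`>= 0`).
#' @param completeness Fraction of reflections retained, in `(0, 1]`.
#' @param rng_seed Integer seed.
#' @return A new `reflection_set`.
#' @export
simulate_observations <- function(rs, noise_fraction = 0, completeness = 1,
                                  rng_seed = 1) {
  if (noise_fraction < 0) stopf("noise_fraction must be >= 0")
  if (completeness <= 0 || completeness > 1) stopf("completeness must be in (0,1]")
  with_rng(rng_seed, {
    refl <- rs$refl
    n <- nrow(refl)
    eta <- if (noise_fraction > 0) stats::rnorm(n, 0, noise_fraction) else numeric(n)
    refl$F_obs <- pmax(refl$F_true * (1 + eta), 0)
    refl$sigma <- noise_fraction * refl$F_true
    keep_n <- round(completeness * n)
    if (keep_n < n) refl <- refl[sort(sample.int(n, keep_n)), ]
    rs$refl <- refl
    rs$completeness <- (rs$completeness %||% 1) * completeness
    normalize_reflections(rs)
  })
}

#' Apply a resolution cut-off
#'
#' Removes reflections with `d < cutoff` and re-normalizes E on the surviving
#' set.
#'
#' @param rs A `reflection_set`.
#' @param cutoff New resolution limit in angstroms (`>= rs$res_limit`).
#' @return A `reflection_set` with `res_limit = cutoff`.
#' @export
apply_resolution_cutoff <- function(rs, cutoff) {
  if (cutoff < rs$res_limit) stopf("cutoff must be >= current res_limit")
  keep <- rs$refl$d >= cutoff
  if (!any(keep)) stopf("apply_resolution_cutoff: no reflections survive")
  rs$refl <- rs$refl[keep, ]
  rs$res_limit <- cutoff
  normalize_reflections(rs)
}
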