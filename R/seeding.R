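# Seed-phase selection, providers and quality scoring.

#' Select the seed reflection subset
#'
#' Seed reflections are those whose canonical Miller indices satisfy
#' `sqrt(h^2+k^2+l^2) <= 10` and lie in the index box `h in [-10,10]`,
#' `k in [0,10]`, `l in [0,10]` (the 21 x 11 x 11 grid of a fixed-size phasing
#' network; canonical representatives already have `k, l >= 0`). With
#' `strict = TRUE` the box bounds are exclusive instead.
#'
#' @param rs A `reflection_set`.
#' @param strict Use strict inequalities on the index box.
#' @return Integer row indices into `rs$refl`; attribute `coverage` holds the
#'   seed fraction Perc (seed count / total unique reflections).
#' @export
select_seed <- function(rs, strict = FALSE) {
  refl <- rs$refl
  nrm <- sqrt(refl$h^2 + refl$k^2 + refl$l^2)
  if (strict) {
    inbox <- abs(refl$h) < 10 & refl$k < 10 & refl$l < 10
  } else {
    inbox <- abs(refl$h) <= 10 & refl$k <= 10 & refl$l <= 10
  }
  idx <- which(nrm <= 10 & inbox)
  if (length(idx) == 0L)
    stopf("select_seed: no reflections meet the seed index criteria")
  attr(idx, "coverage") <- length(idx) / nrow(refl)
  idx
}

new_phase_seed <- function(hkl, phi, provenance, coverage) {
  stopifnot(all(phi %in% c(0, pi)))
  structure(list(hkl = as_hkl_matrix(hkl), phi = phi,
                 provenance = provenance, coverage = coverage),
            class = "phase_seed")
}

#' @export
print.phase_seed <- function(x, ...) {
  cat(sprintf("phase_seed [%s]: %d reflections, coverage %.1f%%\n",
              x$provenance, length(x$phi), 100 * x$coverage))
  invisible(x)
}

#' Seed-phase providers
#'
#' `true_seed()` copies the ground-truth phases of the seed reflections;
#' `random_seed()` assigns independent random 0/pi phases; `noisy_seed()`
#' starts from the truth and flips (0 <-> pi) a uniformly chosen fraction
#' `flip_fraction` of entries, so the expected seed mean phase error is
#' `180 * flip_fraction` degrees.
#'
#' @param rs A `reflection_set` with `phi_true` (synthetic path).
#' @param flip_fraction Fraction of seed phases to flip, in `[0, 1]`.
#' @param rng_seed Integer seed.
#' @param strict Passed to [select_seed()].
#' @return A `phase_seed`.
#' @export
true_seed <- function(rs, strict = FALSE) {
  idx <- select_seed(rs, strict)
  new_phase_seed(as.matrix(rs$refl[idx, c("h", "k", "l")]),
                 rs$refl$phi_true[idx], "true", attr(idx, "coverage"))
}

#' @rdname true_seed
#' @export
random_seed <- function(rs, rng_seed = 1, strict = FALSE) {
  idx <- select_seed(rs, strict)
  phi <- with_rng(rng_seed, sample(c(0, pi), length(idx), replace = TRUE))
  new_phase_seed(as.matrix(rs$refl[idx, c("h", "k", "l")]),
                 phi, "random", attr(idx, "coverage"))
}

#' @rdname true_seed
#' @export
noisy_seed <- function(rs, flip_fraction = 0.1, rng_seed = 1, strict = FALSE) {
  if (flip_fraction < 0 || flip_fraction > 1) stopf("flip_fraction must be in [0,1]")
  idx <- select_seed(rs, strict)
  phi <- rs$refl$phi_true[idx]
  nflip <- round(flip_fraction * length(idx))
  if (nflip > 0) {
    flip <- with_rng(rng_seed, sample.int(length(idx), nflip))
    phi[flip] <- pi - phi[flip]
  }
  new_phase_seed(as.matrix(rs$refl[idx, c("h", "k", "l")]),
                 phi, sprintf("noisy(%.3g)", flip_fraction), attr(idx, "coverage"))
}

#' Convenience seed dispatcher
#'
#' @param rs A `reflection_set`.
#' @param provider One of `"true"`, `"random"`, `"noisy"`.
#' @param flip_fraction For the noisy provider.
#' @param rng_seed Integer seed for the stochastic providers.
#' @return A `phase_seed`.
#' @export
make_seed <- function(rs, provider = c("true", "random", "noisy"),
                      flip_fraction = 0.1, rng_seed = 1) {
  provider <- match.arg(provider)
  switch(provider,
         true = true_seed(rs),
         random = random_seed(rs, rng_seed),
         noisy = noisy_seed(rs, flip_fraction, rng_seed))
}

#' Import a seed-phase list from TSV
#'
#' Reads a tab-separated file with header `h k l phi_deg` (phases must be 0 or
#' 180 degrees), matches rows to the reflection set through the canonical
#' index convention, and reports unmatched rows.
#'
#' @param path Path to the TSV file.
#' @param rs A `reflection_set`.
#' @return A `phase_seed` with provenance `"imported"`; attribute `unmatched`
#'   lists input rows that do not occur in `rs`.
#' @export
import_seed <- function(path, rs) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("h", "k", "l", "phi_deg")
  if (!all(need %in% names(tab))) stopf("import_seed: header must contain %s",
                                        paste(need, collapse = " "))
  if (nrow(tab) == 0L) stopf("import_seed: file contains no seed entries")
  bad <- which(!tab$phi_deg %in% c(0, 180) | !is.finite(tab$h + tab$k + tab$l))
  if (length(bad)) stopf("import_seed: invalid phase or indices at data row(s) %s",
                         paste(bad, collapse = ", "))
  can <- canonical_hkl(as.matrix(tab[, c("h", "k", "l")]))
  # phases transform with the orbit sign factor: factor -1 flips 0 <-> pi
  phi <- ifelse(can$factor > 0, rad(tab$phi_deg), pi - rad(tab$phi_deg))
  keys <- hkl_key(can$hkl)
  rkeys <- hkl_key(as.matrix(rs$refl[, c("h", "k", "l")]))
  m <- match(keys, rkeys)
  unmatched <- which(is.na(m))
  if (length(unmatched))
    warnf("import_seed: %d row(s) not present in the reflection set", length(unmatched))
  keep <- !is.na(m)
  if (!any(keep)) stopf("import_seed: no rows match the reflection set")
  new_phase_seed(can$hkl[keep, , drop = FALSE], phi[keep], "imported",
                 sum(keep) / nrow(rs$refl))
}

# row indices of seed entries in rs$refl (assumes canonical seed indices)
seed_rows <- function(seed, rs) {
  m <- match(hkl_key(seed$hkl), hkl_key(as.matrix(rs$refl[, c("h", "k", "l")])))
  if (anyNA(m)) stopf("seed contains reflections absent from the reflection set")
  m
}

#' Score seed-phase quality against ground truth
#'
#' `MPE_seed` is the unweighted mean absolute phase discrepancy (each term 0 or
#' 180 degrees for centric phases). `CORR_seed` is the Pearson correlation
#' between the seed-only Fourier map computed with the seed phases and the one
#' computed with the true phases; for maps sharing amplitudes it equals the
#' E^2- and multiplicity-weighted sign agreement, which is how it is evaluated
#' here (no grid required).
#'
#' @param seed A `phase_seed`.
#' @param rs A `reflection_set` with `phi_true`.
#' @return List with `MPE_seed` (degrees) and `CORR_seed`.
#' @export
evaluate_seed <- function(seed, rs) {
  if (is.null(rs$refl$phi_true)) stopf("evaluate_seed: ground-truth phases unavailable")
  rows <- seed_rows(seed, rs)
  truth <- rs$refl$phi_true[rows]
  dphi <- abs(wrap_angle(seed$phi - truth))
  w <- orbit_multiplicity(seed$hkl) * rs$refl$E[rows]^2
  agree <- cos(seed$phi - truth)   # +1 / -1 for centric phases
  list(MPE_seed = deg(mean(dphi)),
       CORR_seed = sum(w * agree) / sum(w))
}
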