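# Direct-methods engine: triplet invariants, the centric tangent formula, the
# prior-weighted variant that folds in externally supplied seed phases, and
# multisolution trials.

# exact integer encoding of index triples for fast joins
int_key <- function(H) {
  H <- as_hkl_matrix(H)
  (H[, 1L] + 256) + 512 * (H[, 2L] + 256) + 512^2 * (H[, 3L] + 256)
}

#' Select the strong-reflection set N_large
#'
#' @param rs A `reflection_set` with E values.
#' @param threshold Strict lower bound on `|E|` (reflections with
#'   `|E| = threshold` are excluded).
#' @param min_count Minimum acceptable size; fewer strong reflections aborts
#'   with an "insufficient statistics" error, mirroring the behaviour of
#'   direct-methods programs on data that cannot support invariant estimation.
#' @return Integer row indices into `rs$refl`, sorted by decreasing `|E|`.
#' @export
select_n_large <- function(rs, threshold = 1.2, min_count = 30) {
  idx <- which(rs$refl$E > threshold)
  if (length(idx) < min_count)
    stopf("select_n_large: insufficient statistics (%d reflections with |E| > %.2f, need %d)",
          length(idx), threshold, min_count)
  idx[order(-rs$refl$E[idx])]
}

# orbit member table for a set of canonical reflections: all distinct 2/m +
# Friedel mates, with the sign factor relating each member's structure-factor
# sign to the canonical one
orbit_members <- function(H) {
  H <- as_hkl_matrix(H)
  n <- nrow(H)
  f <- ifelse((H[, 2L] + H[, 3L]) %% 2L == 0L, 1, -1)
  mem <- rbind(H,
               cbind(-H[, 1L], -H[, 2L], -H[, 3L]),
               cbind(-H[, 1L], H[, 2L], -H[, 3L]),
               cbind(H[, 1L], -H[, 2L], H[, 3L]))
  owner <- rep(seq_len(n), 4L)
  fac <- c(rep(1, n), rep(1, n), f, f)
  dup <- duplicated(cbind(mem, owner))
  list(hkl = mem[!dup, , drop = FALSE], owner = owner[!dup], factor = fac[!dup])
}

#' Find triplet invariants among the strong reflections
#'
#' Enumerates every triplet `h = k + (h - k)` whose three members (up to 2/m
#' equivalence and Friedel mates) belong to `N_large`. Each triplet carries
#' the concentration parameter
#' `G = 2 sigma3 sigma2^(-3/2) |E_h E_k E_{h-k}|` and the sign `c` (+1/-1)
#' accumulated from the screw/glide translations of the orbit members
#' involved, so that the centric triplet relation reads
#' `s_h ~ c * s_k * s_{h-k}` in terms of canonical structure-factor signs.
#'
#' @param rs A `reflection_set`.
#' @param n_idx Indices from [select_n_large()].
#' @return data.frame with columns `t`, `i`, `j` (positions in `n_idx` of the
#'   target and the two contributors), `c` and `G`.
#' @export
find_triplets <- function(rs, n_idx) {
  H <- as.matrix(rs$refl[n_idx, c("h", "k", "l")])
  E <- rs$refl$E[n_idx]
  n <- nrow(H)
  mem <- orbit_members(H)
  mkey <- int_key(mem$hkl)
  sig <- rs$scatter
  gfac <- 2 * sig["sigma3"] / sig["sigma2"]^1.5
  out <- vector("list", n)
  M <- mem$hkl
  for (t in seq_len(n)) {
    D <- cbind(H[t, 1L] - M[, 1L], H[t, 2L] - M[, 2L], H[t, 3L] - M[, 3L])
    dkey <- (D[, 1L] + 256) + 512 * (D[, 2L] + 256) + 512^2 * (D[, 3L] + 256)
    r2 <- match(dkey, mkey)
    r1 <- which(!is.na(r2))
    if (!length(r1)) next
    r2 <- r2[r1]
    keep <- r1 <= r2
    r1 <- r1[keep]; r2 <- r2[keep]
    if (!length(r1)) next
    i <- mem$owner[r1]; j <- mem$owner[r2]
    cc <- mem$factor[r1] * mem$factor[r2]
    out[[t]] <- data.frame(t = t, i = i, j = j, c = cc,
                           G = gfac * abs(E[t] * E[i] * E[j]))
  }
  tri <- do.call(rbind, out)
  if (is.null(tri)) tri <- data.frame(t = integer(), i = integer(),
                                      j = integer(), c = numeric(), G = numeric())
  rownames(tri) <- NULL
  tri
}

#' Centric tangent-formula update for one reflection
#'
#' Evaluates the weighted vector sum of the triplet phase estimates plus an
#' optional prior term in the complex plane. For centric phases every
#' argument is 0 or pi, so the sum is the real number
#' `T = sum_j G_j cos(arg_j) + G' cos(prior_arg)`: the updated phase is 0 if
#' `T > 0`, pi if `T < 0`, and unchanged (with zero reliability) if `T = 0`.
#' This is exactly the maximizer of the two-point von Mises product
#' probability `P(theta) ~ prod_j exp(G_j cos(theta - arg_j)) *
#' exp(G' cos(theta - prior_arg))` evaluated at `theta in {0, pi}` (the
#' normalizer cancels).
#'
#' @param G Triplet weights (`>= 0`).
#' @param arg Triplet phase arguments `phi_k + phi_{h-k}` (radians).
#' @param prior_G Prior weight (0 for no prior).
#' @param prior_arg Prior phase (radians).
#' @param phi Current phase, returned when the total weight vanishes.
#' @return List with `phi` (0 or pi) and reliability `alpha = |T|`.
#' @export
tangent_update <- function(G, arg, prior_G = 0, prior_arg = 0, phi = 0) {
  tt <- sum(G * cos(arg)) + prior_G * cos(prior_arg)
  list(phi = if (tt > 0) 0 else if (tt < 0) pi else phi, alpha = abs(tt))
}

# prior weight G'_h for seeded reflections: prior_scale * 2 sigma3
# sigma2^(-3/2) * |E_h| * <|E|^2>_seed (dimensionally consistent with the
# triplet G and vanishing smoothly with prior_scale)
prior_weights <- function(rs, n_idx, seeded_mask, prior_scale) {
  E <- rs$refl$E[n_idx]
  sig <- rs$scatter
  if (!any(seeded_mask) || prior_scale == 0) return(numeric(length(n_idx)))
  e2seed <- mean(E[seeded_mask]^2)
  w <- numeric(length(n_idx))
  w[seeded_mask] <- prior_scale * 2 * sig[["sigma3"]] / sig[["sigma2"]]^1.5 *
    E[seeded_mask] * e2seed
  w
}

#' Iterative tangent refinement over the strong reflections
#'
#' Jacobi-style full sweeps of [tangent_update()] over all `N_large`
#' reflections until no sign changes or the cycle cap is reached. When a seed
#' is supplied, each seeded reflection contributes a prior term with weight
#' `G'_h`, and triplets with one (both) seeded contributors have their `G`
#' multiplied by `1 + prior_scale/2` (`1 + prior_scale`), so externally
#' estimated phases enhance the reliability of the invariants they enter
#' without overriding the triplet consensus.
#'
#' @param rs A `reflection_set`.
#' @param n_idx Indices from [select_n_large()].
#' @param triplets data.frame from [find_triplets()].
#' @param start_phi Starting phases (radians, 0/pi) for the `N_large`
#'   reflections, in `n_idx` order.
#' @param seed Optional `phase_seed`.
#' @param prior_scale Scale of the prior weight; 0 reproduces the seed-free
#'   trajectory exactly.
#' @param cycles Sweep cap.
#' @param prior_mode `"always"` applies the prior in every sweep, `"first"`
#'   only in the first.
#' @return List with `phi` (refined phases), `alpha` (reliabilities),
#'   `converged`, `cycles`.
#' @export
run_tangent <- function(rs, n_idx, triplets, start_phi, seed = NULL,
                        prior_scale = 1, cycles = 50,
                        prior_mode = c("always", "first")) {
  prior_mode <- match.arg(prior_mode)
  n <- length(n_idx)
  s <- ifelse(cos(start_phi) >= 0, 1, -1)
  seeded <- rep(FALSE, n)
  prior_sign <- numeric(n)
  if (!is.null(seed)) {
    rows <- seed_rows(seed, rs)
    pos <- match(rows, n_idx)
    keep <- !is.na(pos)
    seeded[pos[keep]] <- TRUE
    prior_sign[pos[keep]] <- ifelse(cos(seed$phi[keep]) >= 0, 1, -1)
  }
  gw <- prior_weights(rs, n_idx, seeded, prior_scale)
  G_eff <- triplets$G
  if (any(seeded) && prior_scale > 0) {
    nseed <- seeded[triplets$i] + seeded[triplets$j]
    G_eff <- G_eff * (1 + prior_scale * nseed / 2)
  }
  vfac <- G_eff * triplets$c
  tlev <- triplets$t
  alpha <- numeric(n)
  converged <- FALSE
  cyc <- 0L
  for (cyc in seq_len(cycles)) {
    v <- vfac * s[triplets$i] * s[triplets$j]
    tt <- numeric(n)
    if (length(v)) {
      agg <- rowsum(v, tlev)
      tt[as.integer(rownames(agg))] <- agg[, 1L]
    }
    if (prior_mode == "always" || cyc == 1L) tt <- tt + gw * prior_sign
    s_new <- ifelse(tt > 0, 1, ifelse(tt < 0, -1, s))
    alpha <- abs(tt)
    if (all(s_new == s)) { converged <- TRUE; s <- s_new; break }
    s <- s_new
  }
  list(phi = ifelse(s > 0, 0, pi), alpha = alpha, converged = converged,
       cycles = cyc)
}

# pick up to 3 strong reflections with GF(2)-independent index parities to
# remove the origin degeneracy of seed-free trials
origin_fixing_set <- function(rs, n_idx) {
  H <- as.matrix(rs$refl[n_idx, c("h", "k", "l")])
  par <- (H[, 1L] %% 2L) + 2L * (H[, 2L] %% 2L) + 4L * (H[, 3L] %% 2L)
  basis <- integer(0)
  chosen <- integer(0)
  for (i in seq_along(par)) {
    v <- par[i]
    for (b in basis) v <- min(v, bitwXor(v, b))
    if (v > 0L) {
      basis <- c(basis, v)
      chosen <- c(chosen, i)
      if (length(chosen) == 3L) break
    }
  }
  chosen
}

#' Multisolution tangent-formula phasing
#'
#' Runs `n_trials` tangent refinements from independent random 0/pi starting
#' signs on `N_large` (seeded reflections start at, and are reinforced by, the
#' seed values when one is supplied). Trials are ranked by mean reliability
#' `alpha`; the top trials are then re-ranked by the R factor after a short
#' electron-density-modification run, and the best trial's phases are
#' returned.
#'
#' @param rs A `reflection_set`.
#' @param n_trials Number of random trials.
#' @param seed Optional `phase_seed` (turns plain direct methods into the
#'   prior-weighted variant).
#' @param rng_seed Integer seed; fixed seeds reproduce ranking and phases.
#' @param prior_scale Prior weight scale (see [run_tangent()]).
#' @param threshold,min_count Passed to [select_n_large()].
#' @param rank_edm Re-rank the top trials by R factor after `edm_cycles`
#'   density-modification cycles (recommended); if `FALSE`, rank by mean
#'   alpha only.
#' @param edm_cycles,keep_fraction Short-EDM ranking parameters.
#' @param cycles,prior_mode Passed to [run_tangent()].
#' @return List with `phi` (phases over all reflections of `rs`, the
#'   non-`N_large` part coming from the winning trial's random fill),
#'   `n_idx`, `trials` (per-trial figures of merit), `best` (winning trial
#'   number).
#' @export
multisolution <- function(rs, n_trials = 20, seed = NULL, rng_seed = 1,
                          prior_scale = 1, threshold = 1.2, min_count = 30,
                          rank_edm = TRUE, edm_cycles = 5, keep_fraction = 0.025,
                          cycles = 50, prior_mode = "always") {
  stopifnot(n_trials >= 1)
  n_idx <- select_n_large(rs, threshold, min_count)
  tri <- find_triplets(rs, n_idx)
  n <- length(n_idx)
  nr <- nrow(rs$refl)
  fix <- if (is.null(seed)) origin_fixing_set(rs, n_idx) else integer(0)
  seed_pos <- NULL
  if (!is.null(seed)) {
    rows <- seed_rows(seed, rs)
    pos <- match(rows, n_idx)
    seed_pos <- list(pos = pos[!is.na(pos)], phi = seed$phi[!is.na(pos)])
  }
  res <- vector("list", n_trials)
  starts <- vector("list", n_trials)
  with_rng(rng_seed, {
    for (tr in seq_len(n_trials)) {
      phi0 <- sample(c(0, pi), n, replace = TRUE)
      if (length(fix)) phi0[fix] <- 0
      if (!is.null(seed_pos)) phi0[seed_pos$pos] <- seed_pos$phi
      fill <- sample(c(0, pi), nr, replace = TRUE)  # non-N_large fill
      starts[[tr]] <- fill
      res[[tr]] <- run_tangent(rs, n_idx, tri, phi0, seed = seed,
                               prior_scale = prior_scale, cycles = cycles,
                               prior_mode = prior_mode)
    }
  })
  fom <- vapply(res, function(r) mean(r$alpha), numeric(1))
  trials <- data.frame(trial = seq_len(n_trials), mean_alpha = fom,
                       converged = vapply(res, `[[`, logical(1), "converged"),
                       r_edm = NA_real_)
  cand <- order(-fom)[seq_len(min(10L, n_trials))]
  full_phi <- function(tr) {
    phi <- starts[[tr]]
    phi[n_idx] <- res[[tr]]$phi
    phi
  }
  if (rank_edm) {
    for (tr in cand) {
      sol <- edm_refine(rs, full_phi(tr), seed = NULL, cycles = edm_cycles,
                        keep_fraction = keep_fraction, lock_cycles = 0,
                        consolidate = FALSE, compute_metrics = FALSE)
      trials$r_edm[tr] <- sol$R_f
    }
    best <- cand[which.min(trials$r_edm[cand])]
  } else {
    best <- cand[1L]
  }
  list(phi = full_phi(best), n_idx = n_idx, trials = trials, best = best)
}
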