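# Crystal structures in P2(1)/c and the synthetic ground-truth generator.

# P2(1)/c symmetry operators (origin on the inversion centre):
# (x,y,z), (-x,y+1/2,-z+1/2), (-x,-y,-z), (x,-y+1/2,z+1/2)
SYMOPS <- list(
  list(R = diag(3),                          t = c(0, 0, 0)),
  list(R = diag(c(-1, 1, -1)),               t = c(0, 0.5, 0.5)),
  list(R = diag(c(-1, -1, -1)),              t = c(0, 0, 0)),
  list(R = diag(c(1, -1, 1)),                t = c(0, 0.5, 0.5))
)

# small element palette: symbol, atomic number, standard atomic weight
ELEMENTS <- data.frame(
  symbol = c("C", "N", "O", "F", "Na", "Mg", "Si", "P", "S", "Cl", "K", "Ca",
             "Fe", "Cu", "Zn", "Br", "Mo", "I", "W", "Hg", "U"),
  Z = c(6L, 7L, 8L, 9L, 11L, 12L, 14L, 15L, 16L, 17L, 19L, 20L,
        26L, 29L, 30L, 35L, 42L, 53L, 74L, 80L, 92L),
  weight = c(12.011, 14.007, 15.999, 18.998, 22.990, 24.305, 28.085, 30.974,
             32.06, 35.45, 39.098, 40.078, 55.845, 63.546, 65.38, 79.904,
             95.95, 126.904, 183.84, 200.59, 238.029),
  stringsAsFactors = FALSE
)

element_info <- function(symbol) {
  i <- match(symbol, ELEMENTS$symbol)
  if (anyNA(i)) stopf("unknown element(s): %s",
                      paste(symbol[is.na(i)], collapse = ", "))
  ELEMENTS[i, , drop = FALSE]
}

#' Crystal structure in space group P2\eqn{_1}/c
#'
#' Bundles a unit cell with the non-hydrogen atoms of the asymmetric unit and
#' derives the structure feature vector used throughout the evaluation
#' harness: `N_asym` (atoms in the asymmetric unit), `Vol` (cell volume),
#' `maxW` (atomic weight of the heaviest element), `maxCellSize`/`minCellSize`
#' (largest/smallest cell edge) and `Pseudo` (percentage of atoms related by
#' the half-cell pseudo-translation, as recorded by the generator).
#'
#' @param cell A [unit_cell()].
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (fractional,
#'   wrapped into `[0,1)`), and optionally `b_iso` (default 3.0) and
#'   `occupancy` (default 1).
#' @param pseudo_pct Percentage of atoms affected by pseudo-translational
#'   symmetry (bookkeeping from the generator; 0 for imported structures).
#' @return Object of class `crystal_structure` with fields `cell`, `atoms`
#'   (augmented with `Z` and `weight`), `space_group = "P21/c"`, `features`.
#' @export
crystal_structure <- function(cell, atoms, pseudo_pct = 0) {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(atoms))
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms))) stopf("atoms needs columns %s",
                                          paste(need, collapse = ", "))
  if (is.null(atoms$b_iso)) atoms$b_iso <- 3.0
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1.0
  if (any(atoms$b_iso < 0)) stopf("b_iso must be >= 0")
  if (any(atoms$occupancy <= 0 | atoms$occupancy > 1)) stopf("occupancy must be in (0,1]")
  info <- element_info(atoms$element)
  atoms$Z <- info$Z
  atoms$weight <- info$weight
  atoms[, c("x", "y", "z")] <- lapply(atoms[, c("x", "y", "z")], function(v) v %% 1)
  st <- structure(list(cell = cell, atoms = atoms, space_group = "P21/c"),
                  class = "crystal_structure")
  edges <- c(cell$a, cell$b, cell$c)
  st$features <- list(
    N_asym = nrow(atoms),
    Vol = cell_volume(cell),
    maxW = max(atoms$weight),
    maxCellSize = max(edges),
    minCellSize = min(edges),
    Pseudo = pseudo_pct
  )
  st
}

#' @export
print.crystal_structure <- function(x, ...) {
  f <- x$features
  cat(sprintf("crystal_structure [P21/c]: N_asym=%d Vol=%.0f A^3 maxW=%.1f Pseudo=%.0f%%\n",
              f$N_asym, f$Vol, f$maxW, f$Pseudo))
  invisible(x)
}

#' Expand the asymmetric unit by the P2\eqn{_1}/c operators
#'
#' Applies the four space-group operators to every asymmetric-unit atom, wraps
#' the images into `[0,1)^3` and removes duplicates arising from special
#' positions (within `tol` fractional units).
#'
#' @param structure A [crystal_structure()].
#' @param tol Fractional deduplication tolerance for special positions.
#' @return data.frame of unit-cell atom sites with columns `x`, `y`, `z`, `Z`,
#'   `weight`, `b_iso`, `occupancy`, `atom` (asymmetric-unit index).
#' @export
symmetry_expand <- function(structure, tol = 1e-4) {
  at <- structure$atoms
  out <- vector("list", nrow(at))
  for (j in seq_len(nrow(at))) {
    x0 <- as.numeric(at[j, c("x", "y", "z")])
    pos <- t(vapply(SYMOPS, function(op) (op$R %*% x0 + op$t) %% 1, numeric(3)))
    keep <- rep(TRUE, nrow(pos))
    for (i in seq_len(nrow(pos))[-1]) {
      prev <- pos[seq_len(i - 1L)[keep[seq_len(i - 1L)]], , drop = FALSE]
      dd <- sweep(prev, 2L, pos[i, ])
      dd <- abs(dd - round(dd))
      if (nrow(prev) && any(rowSums(dd) >= 0 & apply(dd, 1L, max) < tol))
        keep[i] <- FALSE
    }
    pos <- pos[keep, , drop = FALSE]
    out[[j]] <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                           Z = at$Z[j], weight = at$weight[j],
                           b_iso = at$b_iso[j], occupancy = at$occupancy[j],
                           atom = j)
  }
  do.call(rbind, out)
}

#' Generate a random synthetic P2\eqn{_1}/c structure
#'
#' Draws a monoclinic cell and packs random atoms into the asymmetric unit so
#' that no two symmetry-expanded sites come closer than `min_dist`. The
#' defaults emulate the feature spread of small-molecule structures with cell
#' volumes of 1000-3500 cubic angstroms: a C/N/O palette with an optional
#' heavy atom, beta in `[95, 120]` degrees, and an optional half-cell
#' pseudo-translation applied to a fraction of the atoms.
#'
#' @param vol_range Unit-cell volume range in cubic angstroms.
#' @param n_asym_range Range for the number of non-H atoms in the asymmetric
#'   unit (inclusive).
#' @param heavy Heavy-atom option: `"random"` draws one of
#'   S, Cl, Fe, Br, Mo, I, W with probability `2/3` (no heavy atom otherwise);
#'   `NULL` means light atoms only; an element symbol forces that element for
#'   one atom.
#' @param min_dist Minimum distance between any two expanded sites, angstroms.
#' @param pseudo_fraction Fraction of asymmetric-unit atoms to be related by
#'   the pseudo-translation `(0, 0, 1/2)`.
#' @param beta_range Sampling range for the monoclinic angle, degrees.
#' @param b_iso Isotropic displacement parameter assigned to all atoms.
#' @param rng_seed Integer seed; the same seed reproduces the same structure.
#' @param max_tries Placement attempts per atom before the cell is re-drawn.
#' @return A [crystal_structure()].
#' @examples
#' st <- generate_structure(vol_range = c(1000, 1500), n_asym_range = c(10, 14),
#'                          rng_seed = 1)
#' st$features$Vol
#' @export
generate_structure <- function(vol_range = c(1000, 3500),
                               n_asym_range = c(10, 55),
                               heavy = "random",
                               min_dist = 1.5,
                               pseudo_fraction = 0,
                               beta_range = c(95, 120),
                               b_iso = 3.0,
                               rng_seed = 1,
                               max_tries = 200) {
  if (pseudo_fraction < 0 || pseudo_fraction > 1) stopf("pseudo_fraction must be in [0,1]")
  with_rng(rng_seed, {
    for (attempt in 1:20) {
      vol <- runif(1, vol_range[1], vol_range[2])
      beta <- runif(1, beta_range[1], beta_range[2])
      n_asym <- if (n_asym_range[1] == n_asym_range[2]) n_asym_range[1] else
        sample(n_asym_range[1]:n_asym_range[2], 1)
      base <- (vol / sin(rad(beta)))^(1 / 3)
      fa <- runif(1, 0.7, 1.5); fb <- runif(1, 0.7, 1.5)
      a <- base * fa; b <- base * fb
      c_ <- vol / (a * b * sin(rad(beta)))
      if (min(a, b, c_) < 2 * min_dist) next
      cell <- unit_cell(a, b, c_, beta)

      # element assignment
      elems <- sample(c("C", "N", "O"), n_asym, replace = TRUE,
                      prob = c(0.7, 0.15, 0.15))
      if (!is.null(heavy)) {
        hv <- if (identical(heavy, "random")) {
          if (runif(1) < 2 / 3) sample(c("S", "Cl", "Fe", "Br", "Mo", "I", "W"), 1) else NA
        } else heavy
        if (!is.na(hv)) elems[1] <- hv
      }

      n_pair <- round(pseudo_fraction * n_asym / 2)
      n_free <- n_asym - 2L * n_pair
      placed <- matrix(numeric(0), 0, 3)  # expanded sites so far (fractional)
      coords <- matrix(NA_real_, n_asym, 3)
      ok <- TRUE
      slot <- 1L
      place_one <- function(x) {
        # expanded images of candidate x
        img <- t(vapply(SYMOPS, function(op) (op$R %*% x + op$t) %% 1, numeric(3)))
        # self-clash among its own images (special-position guard)
        for (i in 2:nrow(img))
          if (min_periodic_dist(cell, img[i, ], img[seq_len(i - 1L), , drop = FALSE]) < min_dist)
            return(NULL)
        if (min_periodic_dist(cell, img[1, ], placed) < min_dist) return(NULL)
        for (i in 2:nrow(img))
          if (min_periodic_dist(cell, img[i, ], placed) < min_dist) return(NULL)
        img
      }
      n_to_place <- n_free + n_pair
      for (j in seq_len(n_to_place)) {
        pair <- j > n_free
        done <- FALSE
        for (try in seq_len(max_tries)) {
          x <- runif(3)
          img <- place_one(x)
          if (is.null(img)) next
          if (pair) {
            x2 <- (x + c(0, 0, 0.5)) %% 1
            placed_try <- rbind(placed, img)
            img2 <- {
              im <- t(vapply(SYMOPS, function(op) (op$R %*% x2 + op$t) %% 1, numeric(3)))
              bad <- FALSE
              for (i in seq_len(nrow(im)))
                if (min_periodic_dist(cell, im[i, ], placed_try) < min_dist) { bad <- TRUE; break }
              if (bad) NULL else im
            }
            if (is.null(img2)) next
            coords[slot, ] <- x; coords[slot + 1L, ] <- x2
            placed <- rbind(placed, img, img2)
            slot <- slot + 2L
          } else {
            coords[slot, ] <- x
            placed <- rbind(placed, img)
            slot <- slot + 1L
          }
          done <- TRUE
          break
        }
        if (!done) { ok <- FALSE; break }
      }
      if (!ok) next
      atoms <- data.frame(element = elems, x = coords[, 1], y = coords[, 2],
                          z = coords[, 3], b_iso = b_iso, occupancy = 1.0)
      return(crystal_structure(cell, atoms, pseudo_pct = 100 * 2 * n_pair / n_asym))
    }
    stopf("generate_structure: could not pack %s atoms at min_dist=%.2f", n_asym, min_dist)
  })
}

#' Generate a cohort of synthetic structures
#'
#' @param n Number of structures.
#' @param rng_seed Integer seed; structure `i` uses seed `rng_seed * 10000 + i`.
#' @param ... Passed to [generate_structure()].
#' @return List of [crystal_structure()] objects.
#' @export
generate_cohort <- function(n, rng_seed = 1, ...) {
  lapply(seq_len(n), function(i)
    generate_structure(..., rng_seed = (rng_seed * 10000L + i) %% .Machine$integer.max))
}
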