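#' Monoclinic unit cell (b-unique)
#'
#' Constructs a monoclinic unit cell with `alpha = gamma = 90` degrees, the
#' setting used by space group P2\eqn{_1}/c. Lengths are in angstroms, `beta`
#' in degrees.
#'
#' @param a,b,c Cell edge lengths in angstroms (must be positive).
#' @param beta Monoclinic angle in degrees, `90 <= beta < 150`.
#' @return An object of class `unit_cell` with fields `a`, `b`, `c`, `beta`.
#' @examples
#' cell <- unit_cell(12.3, 7.1, 15.8, 105)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, beta = 90) {
  if (!all(is.finite(c(a, b, c, beta)))) stopf("non-finite cell parameters")
  if (a <= 0 || b <= 0 || c <= 0) stopf("cell lengths must be positive")
  if (beta < 90 || beta >= 150) stopf("beta must satisfy 90 <= beta < 150 degrees")
  structure(list(a = a, b = b, c = c, beta = beta), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit_cell: a=%.4f b=%.4f c=%.4f beta=%.3f V=%.1f A^3\n",
              x$a, x$b, x$c, x$beta, cell_volume(x)))
  invisible(x)
}

#' Unit-cell volume
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic angstroms (`a*b*c*sin(beta)` for the monoclinic case).
#' @export
cell_volume <- function(cell) {
  cell$a * cell$b * cell$c * sin(rad(cell$beta))
}

#' Direct-space metric tensor of a monoclinic cell
#' @param cell A [unit_cell()].
#' @return 3x3 matrix G with `G[i,j] = a_i . a_j`.
#' @export
direct_metric <- function(cell) {
  cb <- cos(rad(cell$beta))
  matrix(c(cell$a^2,             0, cell$a * cell$c * cb,
           0,              cell$b^2, 0,
           cell$a * cell$c * cb, 0, cell$c^2), 3, 3)
}

#' Reciprocal metric tensor
#' @param cell A [unit_cell()].
#' @return 3x3 inverse of the direct metric tensor.
#' @export
reciprocal_metric <- function(cell) solve(direct_metric(cell))

#' Resolution (d-spacing) of reflections
#'
#' Evaluates `1/d^2 = h G* h'` with the reciprocal metric tensor, valid for any
#' monoclinic cell.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3 or an n x 3 integer matrix of Miller
#'   indices. `(0,0,0)` is rejected.
#' @return d-spacings in angstroms.
#' @examples
#' d_spacing(unit_cell(10, 10, 10), c(1, 0, 0))  # 10
#' @export
d_spacing <- function(cell, hkl) {
  h <- as_hkl_matrix(hkl)
  if (any(rowSums(abs(h)) == 0)) stopf("d_spacing: (0,0,0) has no d-spacing")
  gs <- reciprocal_metric(cell)
  q <- rowSums((h %*% gs) * h)
  1 / sqrt(q)
}

# orthogonalization matrix (columns = a, b, c vectors in cartesian frame)
orth_matrix <- function(cell) {
  cb <- cos(rad(cell$beta)); sb <- sin(rad(cell$beta))
  matrix(c(cell$a, 0, 0,
           0, cell$b, 0,
           cell$c * cb, 0, cell$c * sb), 3, 3)
}

#' Fractional to cartesian coordinates
#' @param cell A [unit_cell()].
#' @param frac n x 3 matrix of fractional coordinates.
#' @return n x 3 matrix of cartesian coordinates in angstroms.
#' @export
frac_to_cart <- function(cell, frac) {
  frac <- matrix(as.numeric(frac), ncol = 3L)
  frac %*% t(orth_matrix(cell))
}

# minimum distance between one fractional position and a set, under lattice
# translations (checks the 27 neighbouring images; exact for the beta range
# the generator samples)
min_periodic_dist <- function(cell, x, pts) {
  if (nrow(pts) == 0L) return(Inf)
  d0 <- sweep(pts, 2L, x)
  d0 <- d0 - round(d0)
  shifts <- as.matrix(expand.grid(s1 = -1:1, s2 = -1:1, s3 = -1:1))
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(shifts))) {
    cart <- frac_to_cart(cell, sweep(d0, 2L, shifts[i, ], "+"))
    best <- pmin(best, sqrt(rowSums(cart^2)))
  }
  min(best)
}
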