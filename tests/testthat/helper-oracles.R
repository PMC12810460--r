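# Shared fixtures (memoized) and independent brute-force oracles.

.fx <- new.env(parent = emptyenv())

fx_structure <- function(seed = 3, vol = c(1000, 1600), n = c(10, 16), ...) {
  key <- paste0("st_", seed, "_", paste(vol, collapse = "-"), "_",
                paste(n, collapse = "-"))
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_structure(vol_range = vol, n_asym_range = n,
                                     rng_seed = seed, ...)
  .fx[[key]]
}

fx_rs <- function(seed = 3, res = 0.9, ...) {
  key <- paste0("rs_", seed, "_", res, "_",
                paste(deparse(list(...)), collapse = ""))
  if (is.null(.fx[[key]]))
    .fx[[key]] <- make_reflections(fx_structure(seed, ...), res)
  .fx[[key]]
}

# P2(1)/c operators, written out independently of the package internals
oracle_ops <- list(
  function(x) x,
  function(x) c(-x[1], x[2] + 0.5, -x[3] + 0.5),
  function(x) -x,
  function(x) c(x[1], -x[2] + 0.5, x[3] + 0.5)
)

# brute-force structure factor by direct summation over every expanded site,
# scalar accumulation (independent of the vectorized implementation)
oracle_sf <- function(structure, hkl) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  at <- structure$atoms
  gs <- solve(phaseseed::direct_metric(structure$cell))
  out <- complex(nrow(hkl))
  for (r in seq_len(nrow(hkl))) {
    h <- hkl[r, ]
    s2 <- sum((h %*% gs) * h)
    acc <- 0 + 0i
    for (j in seq_len(nrow(at))) {
      x0 <- as.numeric(at[j, c("x", "y", "z")])
      f <- at$Z[j] * at$occupancy[j] * exp(-at$b_iso[j] * s2 / 4)
      seen <- list()
      for (op in oracle_ops) {
        x <- op(x0) %% 1
        dup <- FALSE
        for (s in seen) {
          dd <- abs(x - s); dd <- pmin(dd, 1 - dd)
          if (max(dd) < 1e-4) { dup <- TRUE; break }
        }
        if (dup) next
        seen[[length(seen) + 1]] <- x
        acc <- acc + f * exp(2i * pi * sum(h * x))
      }
    }
    out[r] <- acc
  }
  out
}

# reciprocal basis vectors by cross products (independent d-spacing oracle)
oracle_d <- function(cell, hkl) {
  M <- matrix(c(cell$a, 0, 0,
                0, cell$b, 0,
                cell$c * cos(cell$beta * pi / 180), 0,
                cell$c * sin(cell$beta * pi / 180)), 3, 3)
  av <- M[, 1]; bv <- M[, 2]; cv <- M[, 3]
  vol <- sum(av * pracma_cross(bv, cv))
  as <- pracma_cross(bv, cv) / vol
  bs <- pracma_cross(cv, av) / vol
  cs <- pracma_cross(av, bv) / vol
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  apply(hkl, 1, function(h) {
    1 / sqrt(sum((h[1] * as + h[2] * bs + h[3] * cs)^2))
  })
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# minimum periodic distance between two fractional points (27 images)
oracle_pdist <- function(cell, x, y) {
  M <- matrix(c(cell$a, 0, 0,
                0, cell$b, 0,
                cell$c * cos(cell$beta * pi / 180), 0,
                cell$c * sin(cell$beta * pi / 180)), 3, 3)
  d0 <- x - y
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    dv <- M %*% (d0 - round(d0) + c(i, j, k))
    best <- min(best, sqrt(sum(dv^2)))
  }
  best
}

# exhaustive two-point evaluation of the centric phase probability
# P(theta) ~ prod_j exp(G_j cos(theta - arg_j)) * exp(Gp cos(theta - parg))
oracle_two_point <- function(G, arg, Gp = 0, parg = 0) {
  lp0 <- sum(G * cos(0 - arg)) + Gp * cos(0 - parg)
  lppi <- sum(G * cos(pi - arg)) + Gp * cos(pi - parg)
  p0 <- exp(lp0) / (exp(lp0) + exp(lppi))
  list(phi = if (p0 > 0.5) 0 else if (p0 < 0.5) pi else NA,
       alpha = abs(lp0 - lppi) / 2)
}
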