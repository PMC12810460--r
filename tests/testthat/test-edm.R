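test_that("fourier synthesis and inversion are exact inverses", {
  rs <- fx_rs(3)
  dims <- grid_dims(rs$cell, rs$res_limit)
  expect_true(all(dims >= 3 * c(rs$cell$a, rs$cell$b, rs$cell$c) / rs$res_limit - 1))
  setup <- phaseseed:::synthesis_setup(rs, dims)
  phi <- phaseseed:::with_rng(2, sample(c(0, pi), nrow(rs$refl), TRUE))
  rho <- fourier_synthesis(rs, phi, setup = setup)
  back <- phaseseed:::invert_map(rho, setup)
  signed <- rs$refl$E * ifelse(cos(phi) >= 0, 1, -1)
  expect_lt(max(abs(back - signed)) / max(abs(signed)), 1e-10)
  # Parseval: grid energy equals the coefficient energy over the full sphere
  # (the 2/m orbit of 4 members already contains the Friedel mates)
  w <- (4 / rs$refl$epsilon) * rs$refl$E^2
  expect_equal(mean(rho^2), sum(w), tolerance = 1e-6)
  # linearity: negating all coefficients negates the grid
  rho2 <- fourier_synthesis(rs, pi - phi, setup = setup)
  expect_equal(rho2, -rho, tolerance = 1e-12)
})

test_that("a single (2,0,0) coefficient gives a cosine wave peaking at x = 0", {
  st <- crystal_structure(unit_cell(10, 10, 10),
                          data.frame(element = "C", x = 0.21, y = 0.37, z = 0.43))
  rs <- make_reflections(st, 2.0)
  one <- rs
  one$refl <- rs$refl[rs$refl$h == 2 & rs$refl$k == 0 & rs$refl$l == 0, ]
  one$refl$E <- 1
  rho <- fourier_synthesis(one, 0)
  expect_equal(which.max(rho[, 1, 1]), 1)
  prof <- rho[, 1, 1]
  xs <- (seq_along(prof) - 1) / length(prof)
  expect_equal(prof, 2 * cos(4 * pi * xs), tolerance = 1e-9)
})

test_that("density modification keeps exactly the requested point count", {
  g <- array(1, c(10, 10, 10))
  out <- modify_density(g, 0.025)
  expect_equal(sum(out > 0), ceiling(0.025 * 1000))
  # peaks survive, background does not
  xs <- seq(0, 1, length.out = 24)
  blob <- function(c1) outer(outer(exp(-80 * (xs - c1[1])^2),
                                   exp(-80 * (xs - c1[2])^2)),
                             exp(-80 * (xs - c1[3])^2))
  g2 <- blob(c(0.25, 0.5, 0.5)) + blob(c(0.75, 0.3, 0.6))
  out2 <- modify_density(g2, 0.01)
  peaks <- which(out2 > 0, arr.ind = TRUE)
  expect_true(all(out2[out2 > 0] >= max(g2) * 0.2))
  expect_error(modify_density(g2, 0), "keep_fraction")
})

test_that("true phases of noise-free data are an exact EDM fixed point", {
  rs <- fx_rs(9, vol = c(1200, 1800), n = c(12, 18))
  for (kf in c(0.01, 0.025, 0.1)) {
    sol <- edm_refine(rs, rs$refl$phi_true, keep_fraction = kf)
    expect_identical(sol$phi, rs$refl$phi_true)
    expect_equal(sol$MPE_final, 0)
    expect_equal(sol$CORR_final, 1)
    expect_true(sol$converged)
  }
})

test_that("seed quality orders EDM success on matched runs", {
  # paired runs on the same structures: true seed beats random seed
  mpe_true <- c(); mpe_rand <- c()
  for (i in c(3, 8)) {
    rs <- fx_rs(i, vol = c(1000, 1400), n = c(12, 15))
    mpe_true <- c(mpe_true,
                  solve_structure(rs, true_seed(rs), "seed", rng_seed = i)$MPE_final)
    mpe_rand <- c(mpe_rand,
                  solve_structure(rs, random_seed(rs, i), "seed", rng_seed = i)$MPE_final)
  }
  expect_true(all(mpe_true < 20))
  expect_true(all(mpe_rand > mpe_true))
})

test_that("resolution cut-off filters, renormalizes and grows seed coverage", {
  rs <- fx_rs(3)
  expect_equal(nrow(apply_resolution_cutoff(rs, rs$res_limit)$refl),
               nrow(rs$refl))
  cut <- apply_resolution_cutoff(rs, 1.6)
  expect_true(all(cut$refl$d >= 1.6))
  expect_gt(mean(cut$refl$E^2), 0.9); expect_lt(mean(cut$refl$E^2), 1.1)
  cov <- vapply(c(1.0, 1.2, 1.4, 1.6), function(co)
    attr(select_seed(apply_resolution_cutoff(rs, co)), "coverage"), numeric(1))
  # coverage grows until the whole set lies inside the seed index box
  expect_true(all(diff(cov) >= 0))
  expect_gt(cov[2], cov[1])
  expect_error(apply_resolution_cutoff(rs, 0.5), "res_limit")
})

test_that("the auto strategy dispatches on data resolution", {
  rs <- fx_rs(8, vol = c(1000, 1400), n = c(12, 15))
  lo <- apply_resolution_cutoff(rs, 1.6)
  sol_lo <- solve_structure(lo, true_seed(lo), "auto", rng_seed = 1,
                            n_trials = 5)
  expect_identical(sol_lo$path, "C")
  sol_hi <- solve_structure(rs, true_seed(rs), "auto", rng_seed = 1)
  expect_identical(sol_hi$path, "A")
})

test_that("strategy A with a true seed reduces to seeded EDM refinement", {
  rs <- fx_rs(3)
  seed <- true_seed(rs)
  sol <- solve_structure(rs, seed, "seed", rng_seed = 11)
  phi0 <- phaseseed:::with_rng(11, sample(c(0, pi), nrow(rs$refl), TRUE))
  phi0[phaseseed:::seed_rows(seed, rs)] <- seed$phi
  ref <- edm_refine(rs, phi0, seed = seed, path = "A")
  expect_identical(sol$phi, ref$phi)
  expect_identical(sol$R_f, ref$R_f)
})

test_that("classical direct methods solve a small noise-free structure", {
  rs <- fx_rs(21, vol = c(1000, 1300), n = c(10, 11))
  sol <- solve_structure(rs, NULL, "dm", rng_seed = 21, n_trials = 40)
  expect_identical(sol$path, "B")
  expect_lt(sol$MPE_final, 20)
})
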