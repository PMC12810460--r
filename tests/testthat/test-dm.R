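test_that("N_large selection is strict and guards against thin statistics", {
  rs <- fx_rs(3)
  rs$refl$E[1] <- 1.2
  nl <- select_n_large(rs)
  expect_true(all(rs$refl$E[nl] > 1.2))
  expect_false(1 %in% nl)
  expect_true(all(diff(rs$refl$E[nl]) <= 0))
  tiny <- rs
  tiny$refl <- rs$refl[1:10, ]
  expect_error(select_n_large(tiny), "insufficient statistics")
  # centric tail size
  expect_equal(length(select_n_large(rs)) / nrow(rs$refl), 0.23,
               tolerance = 0.2)
})

test_that("triplet G follows the equal-atom concentration formula", {
  # 100 equal atoms: sigma3 * sigma2^(-3/2) = 1/10; |E| = 2 each -> G = 1.6
  rs <- structure(list(
    cell = unit_cell(10, 10, 10),
    refl = data.frame(h = c(1, 2), k = c(1, 2), l = c(1, 2),
                      d = c(2, 1), epsilon = c(1, 1), E = c(2, 2)),
    res_limit = 1, scatter = c(sigma2 = 100 * 36, sigma3 = 100 * 216)),
    class = "reflection_set")
  tri <- find_triplets(rs, 1:2)
  expect_true(nrow(tri) >= 1)
  expect_equal(unique(tri$G), 1.6, tolerance = 1e-12)
  # the self-convolution (2,2,2) = (1,1,1) + (1,1,1) appears exactly once
  self_tri <- tri[tri$t == 2 & tri$i == 1 & tri$j == 1, ]
  expect_equal(nrow(self_tri), 1)
})

test_that("triplet search equals the exhaustive pair-scan oracle", {
  rs <- fx_rs(3)
  nl <- select_n_large(rs)[1:20]
  tri <- find_triplets(rs, nl)
  H <- as.matrix(rs$refl[nl, c("h", "k", "l")])
  # oracle: all ordered pairs of all orbit members (incl. Friedel mates)
  mem <- list()
  for (i in seq_len(nrow(H))) {
    h <- H[i, ]
    ms <- unique(rbind(h, -h, c(-h[1], h[2], -h[3]), c(h[1], -h[2], h[3])))
    for (r in seq_len(nrow(ms))) mem[[length(mem) + 1]] <- list(i = i, m = ms[r, ])
  }
  found <- character(0)
  key <- function(v) paste(v, collapse = ",")
  tkeys <- apply(H, 1, key)
  for (a in seq_along(mem)) for (b in seq_along(mem)) {
    s <- mem[[a]]$m + mem[[b]]$m
    if (all(s == 0)) next
    kt <- match(key(s), tkeys)
    if (!is.na(kt))
      found <- c(found, paste(kt, paste(sort(c(a, b)), collapse = "-")))
  }
  # oracle counts each unordered member pair once per target
  expect_equal(nrow(tri), length(unique(found)))
})

test_that("triplet sums are origin invariant and concentrate near zero", {
  rs <- fx_rs(3)
  nl <- select_n_large(rs)
  tri <- find_triplets(rs, nl)
  s_true <- ifelse(cos(rs$refl$phi_true[nl]) >= 0, 1, -1)
  inv <- tri$c * s_true[tri$t] * s_true[tri$i] * s_true[tri$j]
  base <- sum(tri$G * inv) / sum(tri$G)
  expect_gt(base, 0.5)
  H <- as.matrix(rs$refl[nl, c("h", "k", "l")])
  for (r in 2:8) {
    delta <- origin_shifts()[r, ]
    flip <- ifelse((H %*% (2 * delta)) %% 2 == 1, -1, 1)
    s_sh <- s_true * flip
    inv_sh <- tri$c * s_sh[tri$t] * s_sh[tri$i] * s_sh[tri$j]
    expect_equal(inv_sh, inv)
  }
  # G-weighted cosine increases with G decile
  dec <- cut(tri$G, stats::quantile(tri$G, c(0, 0.25, 0.5, 0.75, 1)),
             include.lowest = TRUE)
  m <- tapply(inv, dec, mean)
  expect_gt(m[[4]], m[[1]])
})

test_that("tangent_update matches exhaustive two-point evaluation", {
  set.seed(42)
  for (r in 1:300) {
    k <- sample(1:6, 1)
    G <- stats::runif(k, 0, 3)
    arg <- sample(c(0, pi), k, replace = TRUE)
    Gp <- if (r %% 2) stats::runif(1, 0, 2) else 0
    parg <- sample(c(0, pi), 1)
    got <- tangent_update(G, arg, Gp, parg, phi = pi)
    want <- oracle_two_point(G, arg, Gp, parg)
    if (!is.na(want$phi)) expect_identical(got$phi, want$phi)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-12)
  }
  # hand examples
  expect_equal(tangent_update(2, 0), list(phi = 0, alpha = 2))
  expect_equal(tangent_update(c(2, 1), c(0, pi)), list(phi = 0, alpha = 1))
  expect_equal(tangent_update(1, 0, prior_G = 3, prior_arg = pi),
               list(phi = pi, alpha = 2))
  expect_equal(tangent_update(numeric(0), numeric(0), 0, 0, phi = pi)$alpha, 0)
})

test_that("true phases are a fixed point of tangent refinement", {
  rs <- fx_rs(3)
  nl <- select_n_large(rs)
  tri <- find_triplets(rs, nl)
  rt <- run_tangent(rs, nl, tri, rs$refl$phi_true[nl])
  expect_true(rt$converged)
  expect_equal(rt$cycles, 1)
  expect_identical(rt$phi, rs$refl$phi_true[nl])
})

test_that("zero prior scale reproduces the seed-free trajectory", {
  rs <- fx_rs(3)
  nl <- select_n_large(rs)
  tri <- find_triplets(rs, nl)
  phi0 <- phaseseed:::with_rng(5, sample(c(0, pi), length(nl), TRUE))
  seed <- noisy_seed(rs, 0.2, rng_seed = 3)
  a <- run_tangent(rs, nl, tri, phi0, seed = NULL)
  b <- run_tangent(rs, nl, tri, phi0, seed = seed, prior_scale = 0)
  expect_identical(a$phi, b$phi)
  expect_identical(a$alpha, b$alpha)
})

test_that("seeded priors steer the refinement toward the truth", {
  rs <- fx_rs(8, vol = c(1000, 1400), n = c(12, 15))
  nl <- select_n_large(rs)
  tri <- find_triplets(rs, nl)
  truth <- rs$refl$phi_true[nl]
  seed <- true_seed(rs)
  H <- as.matrix(rs$refl[nl, c("h", "k", "l")])
  pos <- match(phaseseed:::seed_rows(seed, rs), nl)
  keep <- !is.na(pos)
  wins <- 0
  for (s in 1:6) {
    phi0 <- phaseseed:::with_rng(s, sample(c(0, pi), length(nl), TRUE))
    free <- run_tangent(rs, nl, tri, phi0)
    # seeded protocol: seeded reflections start at the seed values and carry
    # the prior; the rest starts random
    phi0s <- phi0
    phi0s[pos[keep]] <- seed$phi[keep]
    prio <- run_tangent(rs, nl, tri, phi0s, seed = seed)
    # origin-searched comparison: the free trial may converge in any
    # permissible origin, the seeded one is pinned to the seed origin
    if (mean_phase_error(H, prio$phi, truth) <=
        mean_phase_error(H, free$phi, truth) + 1e-9) wins <- wins + 1
  }
  expect_gte(wins, 5)
  expect_lt(mean_phase_error(H, prio$phi, truth), 20)
})

test_that("multisolution is reproducible and respects a true start", {
  rs <- fx_rs(8, vol = c(1000, 1400), n = c(12, 15))
  a <- multisolution(rs, n_trials = 5, rng_seed = 4)
  b <- multisolution(rs, n_trials = 5, rng_seed = 4)
  expect_identical(a$phi, b$phi)
  expect_identical(a$trials, b$trials)
  expect_s3_class(a$trials, "data.frame")
  expect_equal(nrow(a$trials), 5)
})
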