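test_that("seed selection follows the norm rule and index box", {
  rs <- fx_rs(3)
  idx <- select_seed(rs)
  H <- as.matrix(rs$refl[idx, c("h", "k", "l")])
  expect_true(all(sqrt(rowSums(H^2)) <= 10))
  expect_true(all(abs(H[, 1]) <= 10 & H[, 2] <= 10 & H[, 3] <= 10))
  expect_gt(attr(idx, "coverage"), 0)
  # (3,4,5) admissible, (10,1,0) excluded by the norm rule
  expect_true(sqrt(sum(c(3, 4, 5)^2)) <= 10)
  expect_false(sqrt(sum(c(10, 1, 0)^2)) <= 10)
  expect_false(any(H[, 1] == 10 & H[, 2] == 1 & H[, 3] == 0))
})

test_that("seed selection equals exhaustive box-and-ball enumeration", {
  # a cell large enough that every admissible index survives the resolution
  # limit, so select_seed must return exactly the canonical box content
  st <- crystal_structure(unit_cell(26, 25, 27, 95),
                          data.frame(element = "C", x = 0.123, y = 0.271,
                                     z = 0.377))
  rs <- make_reflections(st, 2.3)
  idx <- select_seed(rs)
  g <- expand.grid(h = -10:10, k = 0:10, l = 0:10)
  g <- g[sqrt(g$h^2 + g$k^2 + g$l^2) <= 10 & !(g$h == 0 & g$k == 0 & g$l == 0), ]
  can <- canonical_hkl(as.matrix(g))$hkl
  is_can <- can[, 1] == g$h & can[, 2] == g$k & can[, 3] == g$l
  absent <- (g$k == 0 & g$l %% 2 != 0) | (g$h == 0 & g$l == 0 & g$k %% 2 != 0)
  d <- d_spacing(st$cell, as.matrix(g))
  expect_equal(length(idx), sum(is_can & !absent & d >= 2.3))
})

test_that("seed selection is invariant to reflection order", {
  rs <- fx_rs(3)
  k1 <- hkl_keyset <- paste(rs$refl$h, rs$refl$k, rs$refl$l)[select_seed(rs)]
  rs2 <- rs
  perm <- rev(seq_len(nrow(rs$refl)))
  rs2$refl <- rs$refl[perm, ]
  k2 <- paste(rs2$refl$h, rs2$refl$k, rs2$refl$l)[select_seed(rs2)]
  expect_setequal(k1, k2)
})

test_that("seed providers deliver the expected phase-error levels", {
  rs <- fx_rs(3)
  ts <- true_seed(rs)
  expect_equal(evaluate_seed(ts, rs)$MPE_seed, 0)
  expect_equal(evaluate_seed(ts, rs)$CORR_seed, 1)

  nz0 <- noisy_seed(rs, 0, rng_seed = 1)
  expect_equal(evaluate_seed(nz0, rs)$MPE_seed, 0)

  n <- length(ts$phi)
  nz <- noisy_seed(rs, 0.1, rng_seed = 2)
  expect_equal(evaluate_seed(nz, rs)$MPE_seed, 180 * round(0.1 * n) / n)

  all_flipped <- ts
  all_flipped$phi <- pi - ts$phi
  ev <- evaluate_seed(all_flipped, rs)
  expect_equal(ev$MPE_seed, 180)
  expect_equal(ev$CORR_seed, -1)

  mpes <- vapply(1:6, function(s)
    evaluate_seed(random_seed(rs, s), rs)$MPE_seed, numeric(1))
  expect_gt(mean(mpes), 90 - 3 * 180 * sqrt(0.25 / n) * 2)
  expect_lt(mean(mpes), 90 + 3 * 180 * sqrt(0.25 / n) * 2)

  expect_error(noisy_seed(rs, 1.5), "flip_fraction")
})

test_that("seed MPE is linear in the flip fraction and CORR decreases", {
  rs <- fx_rs(3)
  n <- length(true_seed(rs)$phi)
  fr <- c(0.05, 0.15, 0.3, 0.5)
  for (f in fr) {
    m <- evaluate_seed(noisy_seed(rs, f, rng_seed = 11), rs)$MPE_seed
    expect_lt(abs(m - 180 * f), 3 * 180 * sqrt(f * (1 - f) / n) + 180 / n)
  }
  cors <- vapply(c(0, fr), function(f)
    mean(vapply(1:5, function(s)
      evaluate_seed(noisy_seed(rs, f, rng_seed = s), rs)$CORR_seed,
      numeric(1))), numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("CORR_seed agrees with the direct grid-map correlation", {
  rs <- fx_rs(3)
  seed <- noisy_seed(rs, 0.05, rng_seed = 5)
  rows <- match(paste(seed$hkl[, 1], seed$hkl[, 2], seed$hkl[, 3]),
                paste(rs$refl$h, rs$refl$k, rs$refl$l))
  sub <- rs
  sub$refl <- rs$refl[rows, ]
  m1 <- fourier_synthesis(sub, seed$phi)
  m2 <- fourier_synthesis(sub, rs$refl$phi_true[rows])
  expect_equal(evaluate_seed(seed, rs)$CORR_seed,
               stats::cor(as.vector(m1), as.vector(m2)), tolerance = 1e-9)
})

test_that("seed import validates, matches and round-trips", {
  rs <- fx_rs(3)
  ts <- true_seed(rs)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  write_seed_tsv(ts, tmp)
  imp <- import_seed(tmp, rs)
  expect_equal(evaluate_seed(imp, rs)$MPE_seed, 0)
  expect_identical(imp$provenance, "imported")

  # one flipped sign out of the first 100 rows
  tab <- utils::read.delim(tmp)
  tab <- tab[1:100, ]
  tab$phi_deg[7] <- 180 - tab$phi_deg[7]
  utils::write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(evaluate_seed(import_seed(tmp, rs), rs)$MPE_seed, 1.8)

  # invalid phase value is rejected with its row number
  tab$phi_deg[3] <- 90
  utils::write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(import_seed(tmp, rs), "row")

  writeLines("h\tk\tl\tphi_deg", tmp)
  expect_error(import_seed(tmp, rs), "no seed entries")
})
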