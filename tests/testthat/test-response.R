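small_field <- function(values, e0 = 0, i0 = 0, de = 0.01, di = 0.01,
                        kind = "isostable") {
  g <- grid2d(c(e0, e0 + nrow(values) * de), c(i0, i0 + ncol(values) * di),
              de = de, di = di)
  isostim:::new_amplitude_field(g, values, is.na(values), kind, "full",
                                meta = list())
}

test_that("constant field gives an identically zero response where defined", {
  f <- small_field(matrix(1.5, 5, 5))
  rf <- instantaneous_response(f, dE = 0.02) # 2 bins
  expect_true(all(rf$gamma0[1:3, ] == 0))
  expect_true(all(is.na(rf$gamma0[4:5, ]))) # shifted lookup out of range
})

test_that("linear-in-E field gives Gamma0 = dE on an exact grid", {
  ctr <- isostim:::grid_centers(grid2d(c(0, 0.05), c(0, 0.05)))
  f <- small_field(matrix(rep(seq(0.0005, by = 0.001, length.out = 50), 50),
                          50, 50), de = 0.001, di = 0.001)
  rf <- instantaneous_response(f, dE = 0.003) # 3 bins
  defined <- !is.na(rf$gamma0)
  expect_true(all(abs(rf$gamma0[defined] - 0.003) < 1e-12))
})

test_that("masked own or shifted bins are missing; zero_fill closes them", {
  v <- matrix(1, 4, 4)
  v[2, 3] <- NA
  rf <- instantaneous_response(small_field(v), dE = 0.01) # 1-bin shift
  expect_true(is.na(rf$gamma0[2, 3])) # own value missing
  expect_true(is.na(rf$gamma0[1, 3])) # shifted lookup hits the masked bin
  expect_true(all(is.na(rf$gamma0[4, ]))) # shift out of range
  z <- zero_fill(rf)
  expect_true(z$zero_filled)
  expect_false(anyNA(z$gamma0))
})

test_that("support harmonization empties isostable bins missing in the Hilbert field", {
  v <- matrix(-0.5, 4, 4)
  iso <- instantaneous_response(small_field(v), dE = 0.01)
  hil_v <- v
  hil_v[1, 1] <- NA
  hil <- instantaneous_response(small_field(hil_v, kind = "hilbert-mean"),
                                dE = 0.01)
  out <- harmonize_support(iso, hil)
  expect_identical(out$gamma0[1, 1], 0)
  expect_identical(out$gamma0[2, 2], iso$gamma0[2, 2])
  # fully-missing Hilbert support zeroes everything
  hil_all <- hil
  hil_all$gamma0[] <- NA_real_
  expect_true(all(harmonize_support(iso, hil_all)$gamma0 == 0))
  # mismatched grids are rejected
  other <- instantaneous_response(small_field(matrix(1, 5, 5)), dE = 0.01)
  expect_error(harmonize_support(iso, other), class = "isostim_grid_mismatch")
})

test_that("augmentation rule invariants hold for random fields and trajectories", {
  set.seed(14)
  nE <- 6L; nI <- 5L; u <- 7L
  gamma0 <- matrix(round(runif(nE * nI, -1, 1), 2), nE, nI)
  nb <- nE * nI
  P <- matrix(sample(c(NA_integer_, 1:nE), nb * u, replace = TRUE), nb, u)
  Q <- matrix(sample(1:nI, nb * u, replace = TRUE), nb, u)
  # k = 1 is the own bin by construction of the discretized rule
  P[, 1] <- rep(1:nE, nI)
  Q[, 1] <- rep(1:nI, each = nE)
  G <- apply_algorithm1(gamma0, P, Q)
  expect_true(all(G <= 0))
  expect_equal(G[, , 1], pmin(gamma0, 0))
  for (k in 2:u) {
    slice <- G[, , k]
    own <- gamma0
    sel <- slice < 0
    expect_true(all(slice[sel] <= own[sel]))
    expect_true(all(slice[sel] %in% gamma0))
  }
})

test_that("augment(): zero field stays zero; first slice and tensor signs on a real model", {
  nm <- patient_names()[1]
  pt <- patients()[[nm]]
  fa <- fa_of(nm)
  g <- grid2d(fa$x_star[1] + c(-0.02, 0.02), fa$x_star[2] + c(-0.02, 0.02),
              de = 0.002, di = 0.002)
  f <- compute_isostable_field(pt$params, g, iso_config("quick"), fa = fa)
  rf <- zero_fill(instantaneous_response(f, pt$params$dE0))
  gam <- augment(rf, pt$params, fa, dt = 1e-3)
  expect_identical(gam$u, as.integer(round(fa$period_T / 1e-3)) + 1L)
  expect_true(all(gam$gamma <= 0))
  expect_equal(gam$gamma[, , 1], pmin(rf$gamma0, 0))
  # deterministic given inputs
  gam2 <- augment(rf, pt$params, fa, dt = 1e-3)
  expect_identical(gam$gamma, gam2$gamma)
  # all-zero response field augments to an all-zero tensor
  rf0 <- rf
  rf0$gamma0[] <- 0
  expect_true(all(augment(rf0, pt$params, fa)$gamma == 0))
  # un-zero-filled input is rejected
  expect_error(augment(instantaneous_response(f, pt$params$dE0),
                       pt$params, fa),
               class = "isostim_bad_argument")
})
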