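test_that("observables vanish at the focus, kill the a-direction, and are linear", {
  fa <- fa_of(patient_names()[1])
  xs <- as.numeric(fa$x_star)
  expect_equal(unname(observables(xs, fa)), c(0, 0))
  g <- observables(xs + fa$a, fa)
  expect_equal(unname(g), c(fa$a[1] * fa$b[2] - fa$a[2] * fa$b[1], 0))
  u <- c(0.013, -0.007)
  expect_equal(unname(observables(xs + 2 * u, fa)),
               2 * unname(observables(xs + u, fa)))
})

test_that("linear toy focus: map formula equals the eigenbasis amplitude and decays with the flow", {
  tc <- toy_cases()$linear_focus
  set.seed(3)
  for (rep in 1:5) {
    x <- runif(2, -0.1, 0.1)
    expect_equal(tc$amp(2 * x), 2 * tc$amp(x))
    t <- runif(1, 0, 3) * tc$period_T
    expect_equal(tc$amp(tc$flow(x, t)), exp(tc$sigma * t) * tc$amp(x),
                 tolerance = 1e-9)
  }
})

test_that("isostable amplitude: zero at the focus, near-focus scaling law", {
  nm <- patient_names()[1]
  p <- patients()[[nm]]$params
  fa <- fa_of(nm)
  expect_identical(isostable_amplitude(as.numeric(fa$x_star), fa, p), 0)
  set.seed(8)
  for (rep in 1:4) {
    u <- runif(2, -1, 1); u <- u / sqrt(sum(u^2))
    eps <- 5e-5
    r1 <- isostable_amplitude(as.numeric(fa$x_star) + eps * u, fa, p)
    r2 <- isostable_amplitude(as.numeric(fa$x_star) + 2 * eps * u, fa, p)
    expect_equal(r1 / r2, 0.5, tolerance = 0.01)
  }
})

test_that("isostable amplitude converges in the number of periods", {
  nm <- patient_names()[1]
  p <- patients()[[nm]]$params
  fa <- fa_of(nm)
  n_full <- isostim:::choose_n_periods(fa, "full")
  set.seed(12)
  th <- runif(10, 0, 2 * pi)
  X <- cbind(fa$x_star[1] + 0.01 * cos(th), fa$x_star[2] + 0.01 * sin(th))
  r_n <- isostable_amplitude(X, fa, p, cfg = iso_config("full", n = n_full))
  r_n10 <- isostable_amplitude(X, fa, p,
                               cfg = iso_config("full", n = n_full + 10))
  expect_lt(max(abs(r_n10 / r_n - 1)), 1e-3)
})

test_that("divergent start points raise a divergence error", {
  nm <- patient_names()[1]
  p <- patients()[[nm]]$params
  fa <- fa_of(nm)
  expect_error(
    isostable_amplitude(as.numeric(fa$x_star) + c(0.2, 0), fa, p,
                        box = as.numeric(fa$x_star) + c(-0.1, 0.1, -0.1, 0.1)),
    class = "isostim_divergence")
})

test_that("isostable field on a small grid: minimum at X*, continuity, linear contours, preset agreement", {
  nm <- patient_names()[1]
  p <- patients()[[nm]]$params
  fa <- fa_of(nm)
  g <- grid2d(fa$x_star[1] + c(-0.02, 0.02), fa$x_star[2] + c(-0.02, 0.02),
              de = 0.002, di = 0.002)
  f_full <- compute_isostable_field(p, g, iso_config("full"), fa = fa)
  expect_true(all(f_full$values[!f_full$mask] >= 0))
  ctr <- grid_centers(g)
  idx <- which(f_full$values == min(f_full$values, na.rm = TRUE),
               arr.ind = TRUE)[1, ]
  expect_lt(abs(ctr$e[idx[1]] - fa$x_star[1]), g$de)
  expect_lt(abs(ctr$i[idx[2]] - fa$x_star[2]), g$di)
  # continuity: no adjacent-bin jumps > 20% away from the focus region
  # (r is linear in the distance to X*, so the bound only makes sense
  # where the bin spacing is small relative to that distance)
  v <- f_full$values
  big <- !is.na(v) & v > 0.4 * max(v, na.rm = TRUE)
  jumps_e <- abs(v[-1, ] / v[-nrow(v), ] - 1)
  ok_e <- big[-1, ] & big[-nrow(v), ]
  expect_lt(max(jumps_e[ok_e], na.rm = TRUE), 0.2)
  # near-focus contours match the linearization (elliptic level sets)
  low <- !is.na(v) & v > 0 &
    v <= quantile(v[!is.na(v) & v > 0], 0.05)
  cells <- which(low, arr.ind = TRUE)
  lin <- apply(cells, 1, function(ij)
    linear_amp(c(ctr$e[ij[1]], ctr$i[ij[2]]), fa))
  expect_lt(max(abs(v[low] / lin - 1)), 0.1)
  # quick preset preserves the ranking
  f_quick <- compute_isostable_field(p, g, iso_config("quick"), fa = fa)
  sh <- !f_full$mask & !f_quick$mask
  expect_gt(cor(f_full$values[sh], f_quick$values[sh], method = "spearman"),
            0.95)
})

test_that("degenerate eigenbasis is rejected", {
  fa <- fa_of(patient_names()[1])
  fa$b <- fa$a # force |b2 a1 - b1 a2| = 0
  expect_error(isostable_amplitude(c(0.4, 0.7), fa,
                                   patients()[[patient_names()[1]]]$params),
               class = "isostim_degenerate_eigenbasis")
})
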