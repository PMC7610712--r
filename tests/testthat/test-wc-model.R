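decoupled <- function(eta = 1) {
  wc_params(nu = 0.02, beta = 4, eta_E = eta, eta_I = eta,
            w_EE = 0, w_IE = 0, w_EI = 0, zeta = 0.01, dE0 = 0.01,
            label = "decoupled")
}

test_that("sigmoid midpoint, saturation and hand value", {
  for (beta in c(0.5, 2, 7)) expect_equal(wc_sigmoid(1, beta), 0.5)
  expect_equal(wc_sigmoid(1e4, 3), 1)
  expect_equal(wc_sigmoid(-1e4, 3), 0)
  expect_equal(wc_sigmoid(2, log(3)), 0.75) # 1/(1 + 1/3)
  x <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(wc_sigmoid(x, 2)) > 0))
  expect_true(all(wc_sigmoid(x, 2) > 0 & wc_sigmoid(x, 2) < 1))
})

test_that("drift vanishes at fixed points and matches hand evaluation", {
  p <- decoupled()
  expect_equal(wc_drift(c(0.5, 0.5), p), c(0, 0))
  pt <- isostim_patients()[[1]]
  fa <- analyze_focus(pt$params)
  expect_lt(sqrt(sum(wc_drift(as.numeric(fa$x_star), pt$params)^2)), 1e-9)
})

test_that("analytic Jacobian agrees with central finite differences", {
  pt <- isostim_patients()[[1]]
  p <- pt$params
  h <- 1e-6
  set.seed(2)
  for (rep in 1:10) {
    x <- runif(2, 0.1, 0.9)
    J <- wc_jacobian(x, p)
    Jfd <- cbind((wc_drift(x + c(h, 0), p) - wc_drift(x - c(h, 0), p)) / (2 * h),
                 (wc_drift(x + c(0, h), p) - wc_drift(x - c(0, h), p)) / (2 * h))
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
  expect_equal(wc_jacobian(c(0.3, 0.6), decoupled()),
               diag(c(-1 / 0.02, -1 / 0.02)))
})

test_that("trace/determinant identities hold at the focus", {
  fa <- analyze_focus(isostim_patients()[[1]]$params)
  expect_equal(sum(diag(fa$jacobian)), 2 * fa$sigma, tolerance = 1e-10)
  expect_equal(det(fa$jacobian), fa$sigma^2 + fa$omega^2, tolerance = 1e-10)
})

test_that("fixed point search: decoupled closed form, monotonicity, residual", {
  p <- decoupled(eta = 1)
  expect_equal(find_fixed_point(p), c(0.5, 0.5), tolerance = 1e-10)
  # increasing eta_E strictly increases E* in the decoupled case
  es <- vapply(c(0.8, 1.0, 1.2, 1.4),
               function(e) find_fixed_point(decoupled(eta = e))[1], numeric(1))
  expect_true(all(diff(es) > 0))
  xs <- find_fixed_point(isostim_patients()[[2]]$params)
  expect_lt(sqrt(sum(wc_drift(xs, isostim_patients()[[2]]$params)^2)), 1e-10)
})

test_that("analyze_focus validates the focus and fixes the eigenvector deterministically", {
  expect_error(analyze_focus(decoupled()), class = "isostim_not_a_focus")
  fa <- analyze_focus(isostim_patients()[[1]]$params)
  expect_lt(fa$sigma, 0)
  expect_gt(fa$omega, 0)
  v <- fa$v1
  expect_equal(sqrt(sum(Mod(v)^2)), 1)
  expect_gt(fa$a[1], 0)
  expect_lt(sqrt(sum(Mod(fa$jacobian %*% v - (fa$sigma + 1i * fa$omega) * v)^2)),
            1e-8)
  expect_gt(abs(fa$b[2] * fa$a[1] - fa$b[1] * fa$a[2]), 0)
})

test_that("deterministic integration: equilibrium, solver agreement, spectral decay", {
  pt <- isostim_patients()[[1]]
  p <- pt$params
  fa <- analyze_focus(p)
  x0 <- as.numeric(fa$x_star)
  rec <- integrate_deterministic(x0, p, 0.5, "rk45")
  expect_lt(max(abs(t(rec$states) - x0)), 1e-7)
  # step-size refinement oracle: rk45 vs fine Euler endpoint on 2 s
  xa <- x0 + c(0.02, 0.01)
  e1 <- integrate_deterministic(xa, p, 2, "rk45", dt = 1e-3)
  e2 <- integrate_deterministic(xa, p, 2, "euler", dt = 1e-6)
  expect_lt(max(abs(e1$states[nrow(e1$states), ] -
                    e2$states[nrow(e2$states), ])), 1e-5)
  # decay rate of log ||x - X*|| sampled at period multiples matches sigma
  # (tight tolerances: the deviation is ~1e-6 of the state scale)
  eps <- 1e-4 * 0.025
  rec <- integrate_deterministic(x0 + eps * c(1, 0), p, 10 * fa$period_T,
                                 "rk45", dt = fa$period_T / 100,
                                 rtol = 1e-12, atol = 1e-14)
  tt <- (1:10) * fa$period_T
  nrm <- vapply(tt, function(t) {
    i <- which.min(abs(rec$times - t))
    sqrt(sum((as.numeric(rec$states[i, ]) - x0)^2))
  }, numeric(1))
  slope <- coef(lm(log(nrm) ~ tt))[2]
  expect_lt(abs(slope / fa$sigma - 1), 0.05)
})

test_that("SDE: zero-noise limit, seeded reproducibility, seed decorrelation", {
  pt <- isostim_patients()[[1]]
  p <- pt$params
  x0 <- find_fixed_point(p) + c(0.01, 0)
  det <- integrate_deterministic(x0, p, 1, "euler", dt = 1e-3)
  p0 <- p; p0$zeta <- 0
  sde <- integrate_sde(x0, p0, 1, seed = 5)
  expect_identical(sde$states, det$states)
  a <- integrate_sde(x0, p, 5, seed = 9)
  b <- integrate_sde(x0, p, 5, seed = 9)
  expect_identical(a$states, b$states)
  long1 <- integrate_sde(x0, p, 500, seed = 1, store_I = FALSE)
  long2 <- integrate_sde(x0, p, 500, seed = 2, store_I = FALSE)
  expect_lt(abs(cor(long1$E, long2$E)), 0.2)
})

test_that("SDE stationary variance grows with the noise SD", {
  pt <- isostim_patients()[[1]]
  p <- pt$params
  x0 <- as.numeric(analyze_focus(p)$x_star)
  vars <- vapply(c(0.5, 1, 2), function(zs)
    var(integrate_sde(x0, p, 500, seed = 3, zeta_scale = zs,
                      store_I = FALSE)$E), numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("apply_pulse shifts E only and composes additively", {
  expect_identical(apply_pulse(c(0.4, 0.3), 0), c(0.4, 0.3))
  expect_equal(apply_pulse(c(0.4, 0.3), 0.05), c(0.45, 0.3))
  expect_equal(apply_pulse(apply_pulse(c(0.4, 0.3), 0.025), 0.025),
               apply_pulse(c(0.4, 0.3), 0.05))
})

test_that("R-function controller hook path matches the fast engine without a controller", {
  p <- isostim_patients()[[1]]$params
  x0 <- find_fixed_point(p)
  fast <- integrate_sde(x0, p, 1, seed = 4)
  slow <- integrate_sde(x0, p, 1, seed = 4,
                        controller = function(state, step, dt) 0)
  expect_equal(slow$states, fast$states)
  # a hook that pulses once is logged and applied
  rec <- integrate_sde(x0, p, 0.1, seed = 4,
                       controller = function(state, step, dt)
                         if (step == 50) 0.02 else 0)
  expect_identical(rec$stim_steps, 51L)
  expect_identical(rec$stim_magnitude, 0.02)
})
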