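#' Sigmoid activation of the Wilson-Cowan model
#'
#' The logistic response function `1 / (1 + exp(-beta * (x - 1)))`, with
#' inflection at `x = 1`, used for both populations.
#'
#' @param x input (vectorized).
#' @param beta steepness (> 0).
#' @return Values strictly in (0, 1).
#' @export
wc_sigmoid <- function(x, beta) {
  stopifnot_scalar(beta, "beta", positive = TRUE)
  cpp_sigmoid(as.numeric(x), beta)
}

#' Deterministic drift of the Wilson-Cowan model
#'
#' Right-hand side of the noiseless model:
#' `dE/dt = (-E + f(eta_E + w_EE*E - w_IE*I)) / nu`,
#' `dI/dt = (-I + f(eta_I + w_EI*E)) / nu`.
#'
#' @param x state, numeric length-2 `(E, I)`.
#' @param p a [wc_params()] object.
#' @return Numeric length-2 drift vector (activity / s).
#' @export
wc_drift <- function(x, p) {
  if (!all(is.finite(x))) iso_stop("bad_argument", "state must be finite")
  cpp_drift(as.numeric(x), param_vector(p))
}

#' Analytic Jacobian of the drift
#'
#' Partial derivatives of [wc_drift()] using
#' `f'(u) = beta * f(u) * (1 - f(u))`.
#'
#' @inheritParams wc_drift
#' @return 2x2 numeric matrix.
#' @export
wc_jacobian <- function(x, p) {
  if (!all(is.finite(x))) iso_stop("bad_argument", "state must be finite")
  cpp_jacobian(as.numeric(x), param_vector(p))
}

#' Apply one stimulation pulse
#'
#' Stimulation increments the excitatory activity only: the stimulation
#' vector is `(dE, 0)`.
#'
#' @param x state `(E, I)`.
#' @param dE pulse magnitude (finite, may be 0 or negative).
#' @return The displaced state.
#' @export
apply_pulse <- function(x, dE) {
  stopifnot_scalar(dE, "dE")
  c(x[1] + dE, x[2])
}

newton_root <- function(p, x0, tol = 1e-12, maxit = 100L) {
  x <- as.numeric(x0)
  pv <- param_vector(p)
  for (it in seq_len(maxit)) {
    f <- cpp_drift(x, pv)
    if (!all(is.finite(f))) return(NULL)
    if (sqrt(sum(f^2)) < tol) return(x)
    J <- cpp_jacobian(x, pv)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    x <- x - step
  }
  f <- cpp_drift(x, pv)
  if (all(is.finite(f)) && sqrt(sum(f^2)) < 1e-10) x else NULL
}

#' Find a fixed point of the deterministic model
#'
#' Newton iteration from `guess`; if that fails, a 5x5 multi-start lattice
#' over the unit square is tried. When several distinct roots exist, a
#' warning of class `isostim_multiple_fixed_points` is raised and the root
#' with a stable complex-pair linearization is preferred.
#'
#' @param p a [wc_params()] object.
#' @param guess initial state, default `c(0.5, 0.5)`.
#' @return Numeric length-2 fixed point with drift norm below `1e-10`.
#' @export
find_fixed_point <- function(p, guess = c(0.5, 0.5)) {
  starts <- rbind(guess,
                  as.matrix(expand.grid(E = seq(0.1, 0.9, by = 0.2),
                                        I = seq(0.1, 0.9, by = 0.2))))
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    r <- newton_root(p, starts[k, ])
    if (is.null(r)) next
    dup <- any(vapply(roots, function(z) max(abs(z - r)) < 1e-6, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots))
    iso_stop("no_fixed_point", "no fixed point found from any start")
  if (length(roots) > 1L) {
    iso_warn("multiple_fixed_points",
             sprintf("%d distinct fixed points found; returning the stable focus",
                     length(roots)),
             data = list(roots = roots))
    is_focus <- vapply(roots, function(r) {
      ev <- eigen(cpp_jacobian(r, param_vector(p)), only.values = TRUE)$values
      is.complex(ev) && all(Re(ev) < 0) && any(abs(Im(ev)) > 1e-12)
    }, logical(1))
    if (any(is_focus)) return(roots[[which(is_focus)[1L]]])
  }
  roots[[1L]]
}

#' Linearization analysis at the stable focus
#'
#' Finds the fixed point, computes the Jacobian and its eigen-decomposition,
#' and returns the focus data: eigenvalues `sigma +/- i omega` (requiring
#' `sigma < 0`, `omega > 0`), the right eigenvector `v1 = a - i b` of the
#' `+ i omega` eigenvalue, and the linear period `T = 2 pi / omega`.
#'
#' The eigenvector is defined only up to a complex scalar; it is fixed
#' deterministically by unit norm and by rotating its first component onto
#' the positive real axis (so `a[1] > 0` and `b[1] = 0` generically), which
#' makes the observables and hence isostable fields reproducible.
#'
#' @inheritParams find_fixed_point
#' @return An object of class `focus_analysis` with elements `x_star`,
#'   `jacobian`, `sigma`, `omega`, `a`, `b`, `v1`, `v2`, `period_T`.
#' @export
analyze_focus <- function(p, guess = c(0.5, 0.5)) {
  xs <- find_fixed_point(p, guess)
  focus_at(p, xs)
}

# eigen-analysis at a known fixed point (shared with the fixture sampler)
focus_at <- function(p, xs) {
  J <- cpp_jacobian(xs, param_vector(p))
  ev <- eigen(J)
  vals <- ev$values
  if (!is.complex(vals) || all(abs(Im(vals)) < 1e-10))
    iso_stop("not_a_focus", "Jacobian eigenvalues are real: not a focus")
  if (any(Re(vals) >= 0))
    iso_stop("not_a_focus", "fixed point is not stable (Re(lambda) >= 0)")
  k <- which(Im(vals) > 0)[1L]
  lam <- vals[k]
  v <- ev$vectors[, k]
  v <- v / sqrt(sum(Mod(v)^2))
  # phase fix: first component real positive (fallback on second component)
  ref <- if (Mod(v[1]) > 1e-12) v[1] else v[2]
  v <- v * Conj(ref) / Mod(ref)
  if (Re(v[1]) < 0) v <- -v
  a <- Re(v); b <- -Im(v)
  if (abs(a[1]) < 1e-12 && b[1] < 0) { v <- -v; a <- Re(v); b <- -Im(v) }
  resid <- sqrt(sum(Mod(J %*% v - lam * v)^2))
  if (resid > 1e-8)
    iso_stop("not_a_focus", sprintf("eigenpair residual too large (%.3g)",
                                    resid))
  if (abs(b[2] * a[1] - b[1] * a[2]) <= 0)
    iso_stop("degenerate_eigenbasis", "degenerate eigenvector basis")
  structure(list(x_star = c(E = xs[1], I = xs[2]), jacobian = J,
                 sigma = Re(lam), omega = Im(lam),
                 a = a, b = b, v1 = v, v2 = Conj(v),
                 period_T = 2 * pi / Im(lam)),
            class = "focus_analysis")
}

#' @export
print.focus_analysis <- function(x, ...) {
  cat("<focus_analysis>\n")
  cat(sprintf("  X* = (%.5f, %.5f)\n", x$x_star[1], x$x_star[2]))
  cat(sprintf("  lambda = %.4g +/- %.4gi  (f = %.3f Hz, T = %.4f s)\n",
              x$sigma, x$omega, x$omega / (2 * pi), x$period_T))
  invisible(x)
}

new_sim_record <- function(E, I, dt, seed, config, stim_steps,
                           stim_magnitudes, crossings = integer()) {
  n <- length(E)
  states <- if (length(I)) cbind(E = E, I = I) else NULL
  structure(list(times = seq(0, by = dt, length.out = n),
                 states = states, E = E, dt = dt,
                 stim_steps = as.integer(stim_steps),
                 stim_times = (as.integer(stim_steps) - 1L) * dt,
                 stim_magnitude = as.numeric(stim_magnitudes),
                 crossings = as.integer(crossings),
                 seed = seed, config = config),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record> %d samples, dt=%g s, %d pulses, seed=%s\n",
              length(x$E), x$dt, length(x$stim_steps),
              if (is.null(x$seed)) "NA" else format(x$seed)))
  invisible(x)
}

#' Integrate the deterministic model
#'
#' Noiseless trajectory (the noise SD `zeta` is ignored). `method = "rk45"`
#' uses an adaptive Dormand-Prince 5(4) scheme with dense output resampled
#' onto the uniform `dt` grid; `method = "euler"` is the fixed-step explicit
#' scheme.
#'
#' @param x0 initial state `(E, I)`.
#' @param p a [wc_params()] object.
#' @param duration run time in seconds (> 0).
#' @param method `"rk45"` (default) or `"euler"`.
#' @param dt output grid step (and Euler step), seconds.
#' @param rtol,atol adaptive tolerances for RK45.
#' @return A `sim_record` (no stimulation events, `seed = NA`).
#' @export
integrate_deterministic <- function(x0, p, duration,
                                    method = c("rk45", "euler"),
                                    dt = 1e-3, rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  n <- as.integer(round(duration / dt))
  pv <- param_vector(p)
  tr <- tryCatch(
    if (method == "euler") cpp_integrate_euler(as.numeric(x0), pv, n, dt)
    else cpp_integrate_rk45(as.numeric(x0), pv, n, dt, rtol, atol),
    error = function(e) iso_stop("integration", conditionMessage(e)))
  new_sim_record(tr[, 1], tr[, 2], dt, NA_integer_,
                 list(method = method, duration = duration, rtol = rtol,
                      atol = atol, model = p$label),
                 integer(), numeric())
}

#' Integrate the stochastic model (Euler-Maruyama)
#'
#' Independent Wiener increments act on E and I with standard deviation
#' `zeta * zeta_scale * sqrt(dt)` per step, entering the increments directly
#' (set `noise_inside_nu = TRUE` to divide the noise term by `nu` instead;
#' the literal model statement keeps it outside).  With `zeta = 0` the path
#' equals the fixed-step Euler deterministic path exactly.
#'
#' @inheritParams integrate_deterministic
#' @param seed integer seed (required: runs are reproducible bit-for-bit).
#' @param controller optional decision hook. Either `NULL`, a controller
#'   configuration understood by the fast engine (see [run_closed_loop()],
#'   [run_phase_locked()], [run_hf()]) or an R function
#'   `function(state, step, dt)` returning a pulse magnitude (0 = no pulse);
#'   the R-function route is slow and intended for small tests.
#' @param zeta_scale multiplier on the noise SD (e.g. 2 for noise doubling).
#' @param noise_inside_nu if TRUE the noise coefficient is `zeta / nu`.
#' @param store_I keep the I component (default TRUE).
#' @return A `sim_record` with any stimulation events logged.
#' @export
integrate_sde <- function(x0, p, duration, dt = 1e-3, seed = 1L,
                          controller = NULL, zeta_scale = 1,
                          noise_inside_nu = FALSE, store_I = TRUE) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  n <- round(duration / dt)
  pv <- param_vector(p)
  set.seed(as.integer(seed))
  if (is.function(controller)) {
    res <- sde_loop_r(as.numeric(x0), pv, n, dt,
                      p$zeta * zeta_scale / (if (noise_inside_nu) p$nu else 1),
                      controller)
  } else {
    res <- tryCatch(
      cpp_sde_run(as.numeric(x0), pv, n, dt, zeta_scale, noise_inside_nu,
                  0L, list(), store_I),
      error = function(e) iso_stop("integration", conditionMessage(e)))
  }
  new_sim_record(res$E, res$I, dt, seed,
                 list(duration = duration, zeta_scale = zeta_scale,
                      noise_inside_nu = noise_inside_nu, model = p$label),
                 res$stim_steps, res$stim_magnitudes, res$crossings)
}

# slow reference path supporting arbitrary R decision hooks
sde_loop_r <- function(x0, pv, n, dt, sig_coef, hook) {
  sig <- sig_coef * sqrt(dt)
  E <- numeric(n + 1); I <- numeric(n + 1)
  x <- x0
  stim_steps <- integer(); stim_mags <- numeric()
  for (i in 0:n) {
    E[i + 1] <- x[1]; I[i + 1] <- x[2]
    dE <- hook(x, i, dt)
    if (is.numeric(dE) && length(dE) == 1L && dE != 0) {
      x[1] <- x[1] + dE
      stim_steps <- c(stim_steps, i + 1L)
      stim_mags <- c(stim_mags, dE)
    }
    if (i == n) break
    f <- cpp_drift(x, pv)
    x <- x + f * dt
    if (sig > 0) x <- x + sig * rnorm(2)
    if (!all(is.finite(x)))
      iso_stop("integration", sprintf("non-finite state at step %d", i + 1))
  }
  list(E = E, I = I, stim_steps = stim_steps, stim_magnitudes = stim_mags,
       crossings = integer())
}
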