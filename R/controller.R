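#' Closed-loop controller configuration
#'
#' Settings of the phase-space stimulation decision rule: the augmented
#' response field, the discounting parameter `b` (larger `b` discounts
#' future benefits more heavily), the pulse magnitude, and the hard rate cap
#' (default 10 Hz, roughly twice the tremor frequency) which translates into
#' a minimum of `N_lim = ceiling(1 / (max_rate_hz * dt))` steps between
#' pulses.
#'
#' @param gamma an `augmented_response_field` from [augment()].
#' @param b discounting parameter (real; e.g. -5 ... 5).
#' @param dE pulse magnitude.
#' @param max_rate_hz maximum stimulation rate (default 10).
#' @return An object of class `controller_config` (with derived `n_lim`).
#' @export
controller_config <- function(gamma, b, dE, max_rate_hz = 10) {
  stopifnot(inherits(gamma, "augmented_response_field"))
  stopifnot_scalar(b, "b")
  stopifnot_scalar(dE, "dE")
  stopifnot_scalar(max_rate_hz, "max_rate_hz", positive = TRUE)
  structure(list(gamma = gamma, b = b, dE = dE, max_rate_hz = max_rate_hz,
                 n_lim = as.integer(ceiling(1 / (max_rate_hz * gamma$dt)))),
            class = "controller_config")
}

#' Temporal discount factor for future stimulation benefit
#'
#' The `k - 1` step ahead discount applied to the predicted benefit of
#' stimulating later in the current period:
#' `alpha = ((t_{i+k-1} - t_{n0})^-b - (t_{n1} - t_{n0})^-b) /
#'          ((t_i - t_{n0})^-b - (t_{n1} - t_{n0})^-b)`
#' with `t = step * dt`. `alpha = 1` at `k = 1` (the present is not
#' discounted) and `alpha = 0` when `i + k - 1 = n1` (the predicted period
#' end). The `b = 0` and `t_i = t_{n0}` cases are defined by their
#' continuous limits.
#'
#' @param i current step index.
#' @param k lookahead index (>= 1, vectorized).
#' @param n0 step index of the current period start.
#' @param n1 predicted period end step index (> n0).
#' @param b discounting parameter.
#' @param dt step duration in seconds.
#' @return Discount factor(s) in `[0, 1]`.
#' @export
discount_factor <- function(i, k, n0, n1, b, dt) {
  if (n1 == n0)
    iso_stop("degenerate_window", "n1 == n0: degenerate period window")
  if (i < n0 || i >= n1)
    iso_stop("bad_argument", "`i` must satisfy n0 <= i < n1")
  if (any(k < 1)) iso_stop("bad_argument", "`k` must be >= 1")
  if (any(i + k - 1 > n1))
    iso_stop("bad_argument", "lookahead i + k - 1 must not exceed n1")
  vapply(k, function(kk) cpp_discount(i, kk, n0, n1, b, dt), numeric(1))
}

#' Zero-crossing phase tracking
#'
#' Runs the online phase estimator over a centered signal: phase resets to 0
#' at positive zero-crossings (sign change - to +) and advances linearly at
#' `2 pi / previous period` per step, with the previous period measured
#' between crossings. Until the second crossing the bootstrap period
#' `bootstrap_steps` (typically `round(T / dt)` from the linearization) is
#' used.
#'
#' @param e_centered centered signal samples.
#' @param dt step in seconds.
#' @param bootstrap_steps bootstrap period in steps.
#' @return A list: `phase` (radians in `[0, 2 pi)` per sample), `n0`, `n1`
#'   (1-based period start / predicted end step per sample), `crossings`
#'   (1-based crossing sample indices).
#' @export
track_phase <- function(e_centered, dt, bootstrap_steps) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  cpp_track_phase(as.numeric(e_centered), dt, as.integer(bootstrap_steps))
}

#' Single stimulation decision
#'
#' Evaluates the per-step decision rule for a given phase-tracker state:
#' stimulate only if (a) at least `n_lim` steps since the last pulse and no
#' pulse yet this period, (b) the current bin's instantaneous benefit
#' `Gamma(p,q,1)` is negative, and (c) the predicted period end has been
#' reached, or the present benefit beats every discounted future benefit
#' `alpha_{i,k} Gamma(p,q,k)` for `k` up to `min(n1 - i + 1, u)`.
#' Positions outside the grid never stimulate.
#'
#' @param tracker list with `n0`, `n1`, `last_stim_step`,
#'   `stimulated_this_period` (steps are 0-based like `i`).
#' @param cfg a [controller_config()].
#' @param x state `(E, I)`.
#' @param i current step index (0-based).
#' @return `"stimulate"` or `"wait"`.
#' @export
decide <- function(tracker, cfg, x, i) {
  if ((i - tracker$last_stim_step) < cfg$n_lim ||
      isTRUE(tracker$stimulated_this_period))
    return("wait")
  g <- cfg$gamma
  pq <- locate_bin(g$grid, x[1], x[2])
  if (anyNA(pq)) return("wait")
  gvec <- g$gamma[pq[1], pq[2], ]
  ok <- cpp_decide_core(gvec, i, tracker$n0, tracker$n1, cfg$b, g$dt)
  if (ok) "stimulate" else "wait"
}

# 1-based bin indices of a point, NA outside; boundary ties -> lower bin
locate_bin <- function(grid, e, i) {
  idx1 <- function(x, lo, w, n) {
    u <- (x - lo) / w
    if (u < 0 || u >= n) return(NA_integer_)
    k <- floor(u)
    if (k == u && k > 0) k <- k - 1
    as.integer(k) + 1L
  }
  c(idx1(e, grid$e_min, grid$de, grid$n_E),
    idx1(i, grid$i_min, grid$di, grid$n_I))
}

#' Run the closed-loop phase-space stimulation strategy
#'
#' Euler-Maruyama integration with the per-step decision rule of [decide()]
#' evaluated in the loop: zero-crossing phase tracking on the E signal
#' (centered by a causal 2 s running mean, with E* as fallback before 2 s
#' have elapsed), the Eq-style temporal discounting of future benefits, a
#' hard rate cap and a once-per-detected-period rule. Pulses are applied
#' before the next integration step and logged.
#'
#' @param p the [wc_params()] model.
#' @param cfg a [controller_config()].
#' @param duration run time in seconds.
#' @param seed integer seed.
#' @param zeta_scale noise scaling (default 1).
#' @param x0 initial state (default: the fixed point).
#' @param fa optional precomputed [analyze_focus()].
#' @return A `sim_record` including the stimulation event log and detected
#'   crossings.
#' @export
run_closed_loop <- function(p, cfg, duration, seed, zeta_scale = 1,
                            x0 = NULL, fa = NULL) {
  stopifnot(inherits(cfg, "controller_config"))
  if (is.null(fa)) fa <- analyze_focus(p)
  if (is.null(x0)) x0 <- as.numeric(fa$x_star)
  g <- cfg$gamma
  dt <- g$dt
  n <- round(duration / dt)
  ctrl <- list(dE = cfg$dE, n_lim = cfg$n_lim, b = cfg$b,
               gamma = g$gamma,
               e_min = g$grid$e_min, de = g$grid$de,
               i_min = g$grid$i_min, di = g$grid$di,
               bootstrap_steps = round(fa$period_T / dt),
               e_star = as.numeric(fa$x_star[1]),
               centering_window_steps = round(2 / dt))
  set.seed(as.integer(seed))
  res <- tryCatch(
    cpp_sde_run(as.numeric(x0), param_vector(p), n, dt, zeta_scale, FALSE,
                3L, ctrl, FALSE),
    error = function(e) iso_stop("integration", conditionMessage(e)))
  new_sim_record(res$E, res$I, dt, seed,
                 list(strategy = "phase-space", b = cfg$b, dE = cfg$dE,
                      n_lim = cfg$n_lim, duration = duration,
                      zeta_scale = zeta_scale, model = p$label,
                      source_kind = g$provenance$source_kind,
                      source_quality = g$provenance$source_quality),
                 res$stim_steps, res$stim_magnitudes, res$crossings)
}
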