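#' Hilbert field estimation settings
#'
#' The Hilbert amplitude field is built by ensemble averaging: many
#' stochastic trajectories are started at random positions in the region of
#' interest, the Hilbert (analytic-signal) amplitude of each trajectory's E
#' component is computed, edges are clipped to remove transform edge
#' effects, trajectories and amplitude series are lightly smoothed, and
#' samples are averaged within space bins.
#'
#' Full preset: 2000 trajectories x 1000 periods. Quick preset: 200 x 100
#' (matching the quick isostable compute budget exactly is model-specific;
#' these defaults keep the quick estimate in the minutes regime on one
#' thread).
#'
#' @param quality `"full"` or `"quick"` (sets `n_traj`/`n_periods` defaults).
#' @param n_traj number of random initial positions.
#' @param n_periods periods simulated per trajectory.
#' @param clip_frac fraction of samples dropped at each end of every
#'   trajectory and amplitude series (default 0.005, i.e. 0.5%).
#' @param smooth_window moving-average window in samples (centered, edges
#'   truncated; default 4).
#' @param centering `"mean"` (per-trajectory mean removed) or
#'   `"fixed_point"` (E* removed).
#' @param seed integer seed (mandatory for reproducibility).
#' @param dt integration step, seconds.
#' @return An object of class `hilbert_config`.
#' @export
hilbert_config <- function(quality = c("full", "quick"),
                           n_traj = NULL, n_periods = NULL,
                           clip_frac = 0.005, smooth_window = 4L,
                           centering = c("mean", "fixed_point"),
                           seed = 1L, dt = 1e-3) {
  quality <- match.arg(quality)
  centering <- match.arg(centering)
  if (is.null(n_traj)) n_traj <- if (quality == "full") 2000L else 200L
  if (is.null(n_periods)) n_periods <- if (quality == "full") 1000L else 100L
  if (clip_frac < 0 || clip_frac >= 0.5)
    iso_stop("bad_argument", "`clip_frac` must be in [0, 0.5)")
  if (smooth_window < 1) iso_stop("bad_argument", "`smooth_window` must be >= 1")
  structure(list(quality = quality, n_traj = as.integer(n_traj),
                 n_periods = as.integer(n_periods), clip_frac = clip_frac,
                 smooth_window = as.integer(smooth_window),
                 centering = centering, seed = as.integer(seed), dt = dt),
            class = "hilbert_config")
}

#' Analytic signal of a real series
#'
#' FFT implementation: the negative-frequency half of the spectrum is
#' zeroed and the positive half doubled, so the result is
#' `x + i H(x)` with `H` the Hilbert transform.
#'
#' @param x real numeric series.
#' @return Complex series of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Hilbert amplitude of a tremor-like series
#'
#' Centers the series (per-series mean, or the fixed-point coordinate E*)
#' and returns the modulus of its analytic signal, i.e. the envelope of the
#' oscillation.
#'
#' @param e_series real numeric series, length >= 16.
#' @param centering `"mean"` or `"fixed_point"`.
#' @param e_star E* used for fixed-point centering.
#' @return Non-negative amplitude series.
#' @export
analytic_amplitude <- function(e_series, centering = c("mean", "fixed_point"),
                               e_star = NULL) {
  centering <- match.arg(centering)
  if (length(e_series) < 16L)
    iso_stop("series_too_short", "series length must be >= 16")
  centered <- if (centering == "mean") e_series - mean(e_series)
              else {
                stopifnot_scalar(e_star, "e_star")
                e_series - e_star
              }
  Mod(analytic_signal(centered))
}

# centered moving average, window w, edges truncated to available samples
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  lo <- pmax(seq_len(n) - floor((w - 1) / 2), 1L)
  hi <- pmin(seq_len(n) + ceiling((w - 1) / 2), n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Hilbert amplitude field by ensemble averaging
#'
#' Draws `cfg$n_traj` initial positions uniformly over the grid rectangle,
#' simulates the stochastic model for `cfg$n_periods` linear periods each,
#' computes per-trajectory Hilbert amplitudes, clips `cfg$clip_frac` of the
#' samples at both ends, smooths trajectories and amplitude series with the
#' `cfg$smooth_window` moving average, and averages amplitude samples within
#' grid bins. Bins never visited are masked.
#'
#' @param p the [wc_params()] model (its baseline `zeta` is used, scaled by
#'   `zeta_scale`).
#' @param grid a [grid2d()].
#' @param cfg a [hilbert_config()].
#' @param zeta_scale noise scaling (default 1).
#' @param fa optional precomputed [analyze_focus()] result.
#' @return An `amplitude_field` with `kind = "hilbert-mean"` or
#'   `"hilbert-fp"` according to the centering.
#' @export
estimate_hilbert_field <- function(p, grid, cfg = hilbert_config(),
                                   zeta_scale = 1, fa = NULL) {
  if (is.null(fa)) fa <- analyze_focus(p)
  dt <- cfg$dt
  n_steps <- as.integer(round(cfg$n_periods * fa$period_T / dt))
  nb <- grid$n_E * grid$n_I
  sums <- numeric(nb)
  counts <- integer(nb)
  pv <- param_vector(p)
  set.seed(cfg$seed)
  x0E <- runif(cfg$n_traj, grid$e_min, grid$e_max)
  x0I <- runif(cfg$n_traj, grid$i_min, grid$i_max)
  for (tr in seq_len(cfg$n_traj)) {
    res <- tryCatch(
      cpp_sde_run(c(x0E[tr], x0I[tr]), pv, n_steps, dt, zeta_scale, FALSE,
                  0L, list(), TRUE),
      error = function(e) iso_stop("integration", conditionMessage(e)))
    amp <- analytic_amplitude(res$E, cfg$centering, e_star = fa$x_star[1])
    n <- length(res$E)
    nclip <- floor(cfg$clip_frac * n)
    keep <- (nclip + 1L):(n - nclip)
    E <- moving_average(res$E[keep], cfg$smooth_window)
    I <- moving_average(res$I[keep], cfg$smooth_window)
    A <- moving_average(amp[keep], cfg$smooth_window)
    cpp_bin_accumulate(E, I, A, grid$e_min, grid$de, grid$n_E,
                       grid$i_min, grid$di, grid$n_I, sums, counts)
  }
  values <- matrix(ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
                   nrow = grid$n_E, ncol = grid$n_I)
  mask <- matrix(counts == 0L, nrow = grid$n_E, ncol = grid$n_I)
  kind <- if (cfg$centering == "mean") "hilbert-mean" else "hilbert-fp"
  new_amplitude_field(grid, values, mask, kind, cfg$quality,
                      meta = list(model = p$label, n_traj = cfg$n_traj,
                                  n_periods = cfg$n_periods,
                                  seed = cfg$seed, zeta_scale = zeta_scale))
}
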