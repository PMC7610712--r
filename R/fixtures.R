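# Synthetic "patient-like" model generation. No clinical parameters are
# reproduced here: models are rejection-sampled to share the qualitative
# properties of tremor fits (stable focus, 4-6 Hz, activities inside (0,1))
# and are labelled synthetic throughout.

#' Specification for synthetic focus models
#'
#' Controls the rejection sampler of [generate_focus_model()]: the target
#' oscillation frequency (tremor band, default 5 Hz +/- 0.5), the admissible
#' focus damping `sigma` (per second; weakly damped foci, as strong damping
#' makes the long-horizon amplitude map numerically meaningless), the target
#' stationary standard deviation of the E activity (which fixes the noise SD
#' `zeta`), and the seed.
#'
#' @param target_freq_hz desired `omega / 2 pi` (default 5).
#' @param freq_tol_hz tolerance on the frequency (default 0.5).
#' @param damping_range admissible `sigma` interval (default `c(-3, -0.5)`).
#' @param target_sd_e stationary SD of E fixing the noise level
#'   (default 0.02 activity units).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget (default 20000).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(target_freq_hz = 5, freq_tol_hz = 0.5,
                         damping_range = c(-3, -0.5), target_sd_e = 0.02,
                         seed = 1L, max_attempts = 20000L) {
  stopifnot_scalar(target_freq_hz, "target_freq_hz", positive = TRUE)
  stopifnot_scalar(freq_tol_hz, "freq_tol_hz", positive = TRUE)
  if (any(damping_range >= 0))
    iso_stop("bad_argument", "`damping_range` must be negative")
  structure(list(target_freq_hz = target_freq_hz,
                 freq_tol_hz = freq_tol_hz,
                 damping_range = sort(damping_range),
                 target_sd_e = target_sd_e,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "fixture_spec")
}

# stationary covariance of the linearization for unit noise SD:
# J S + S J' + I = 0, solved for the three unknowns of symmetric S
lyapunov_cov_unit <- function(J) {
  A <- rbind(c(2 * J[1, 1], 2 * J[1, 2], 0),
             c(J[2, 1], J[1, 1] + J[2, 2], J[1, 2]),
             c(0, 2 * J[2, 1], 2 * J[2, 2]))
  s <- solve(A, c(-1, 0, -1))
  matrix(c(s[1], s[2], s[2], s[3]), 2, 2)
}

#' Generate a synthetic patient-like focus model
#'
#' Rejection-samples Wilson-Cowan shape parameters (beta in \[2, 8\],
#' weights in \[0, 6\], inputs in \[0, 2\]) until the deterministic model
#' has a stable focus with its fixed point well inside the unit square.
#' Because the fixed point does not depend on the time constant and the
#' eigenvalues scale as `1 / nu`, `nu` is then chosen to place the
#' oscillation frequency at a seeded draw within
#' `spec$target_freq_hz +/- spec$freq_tol_hz` (so distinct seeds give
#' distinct frequencies), and the candidate is accepted only if the
#' resulting damping `sigma` falls inside `spec$damping_range` and `nu`
#' inside the physiological 5-40 ms window. The noise SD `zeta` is then set
#' so that the stationary SD of E matches `spec$target_sd_e` (a linearized
#' Lyapunov solution refined on a 200 s calibration run), and the reference
#' pulse magnitude `dE0` is set to 10% of the RMS orbit radius measured on a
#' 200 s run.
#'
#' @param spec a [fixture_spec()].
#' @return A [wc_params()] object (label `synthetic-seed<seed>`).
#' @export
generate_focus_model <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  target_f <- spec$target_freq_hz +
    runif(1, -0.8, 0.8) * spec$freq_tol_hz
  found <- NULL
  for (attempt in seq_len(spec$max_attempts)) {
    cand <- list(beta = runif(1, 2, 8),
                 eta_E = runif(1, 0, 2), eta_I = runif(1, 0, 2),
                 w_EE = runif(1, 0, 6), w_IE = runif(1, 0, 6),
                 w_EI = runif(1, 0, 6))
    p <- wc_params(nu = 1, beta = cand$beta, eta_E = cand$eta_E,
                   eta_I = cand$eta_I, w_EE = cand$w_EE, w_IE = cand$w_IE,
                   w_EI = cand$w_EI, zeta = 0, dE0 = 1,
                   label = sprintf("synthetic-seed%d", spec$seed))
    xs <- newton_root(p, c(0.5, 0.5))
    if (is.null(xs)) next
    fa1 <- tryCatch(focus_at(p, xs), isostim_error = function(e) NULL)
    if (is.null(fa1)) next
    if (any(fa1$x_star < 0.1) || any(fa1$x_star > 0.9)) next
    nu <- fa1$omega / (2 * pi * target_f)
    if (nu < 0.005 || nu > 0.040) next
    sigma <- fa1$sigma / nu
    if (sigma < spec$damping_range[1] || sigma > spec$damping_range[2]) next
    p$nu <- nu
    fa <- suppressWarnings(analyze_focus(p))
    found <- list(p = p, fa = fa)
    break
  }
  if (is.null(found))
    iso_stop("fixture_search_exhausted",
             sprintf("no admissible focus in %d attempts", spec$max_attempts))
  p <- found$p; fa <- found$fa
  # noise calibration: linearized prediction, then one empirical correction
  sd_unit <- sqrt(lyapunov_cov_unit(fa$jacobian)[1, 1])
  zeta0 <- spec$target_sd_e / sd_unit
  p$zeta <- zeta0
  burn_s <- min(50, 5 / abs(fa$sigma))
  rec <- integrate_sde(as.numeric(fa$x_star), p, duration = 200,
                       seed = spec$seed + 10007L)
  keep <- rec$times > burn_s
  p$zeta <- zeta0 * spec$target_sd_e / sd(rec$E[keep])
  # reference pulse: 10% of the RMS orbit radius
  rec <- integrate_sde(as.numeric(fa$x_star), p, duration = 200,
                       seed = spec$seed + 20011L)
  dev <- cbind(rec$E[keep] - fa$x_star[1], rec$states[keep, 2] - fa$x_star[2])
  p$dE0 <- 0.1 * sqrt(mean(dev[, 1]^2 + dev[, 2]^2))
  p
}

#' Phase-space region of interest from occupancy
#'
#' Runs a stochastic calibration trajectory and returns the tightest
#' axis-aligned rectangle containing `coverage` of its samples (symmetric
#' quantiles per axis), snapped outward to 0.001-unit bin edges. When the I
#' range would span fewer than 50 bins the I bin width is reduced to 0.0002
#' (narrow-I models get a finer I discretization).
#'
#' @param p the [wc_params()] model.
#' @param coverage fraction of samples to contain (default 0.995).
#' @param seed integer seed.
#' @param duration calibration run length in seconds (default 500).
#' @param zeta_scale noise scaling.
#' @return A [grid2d()].
#' @export
grid_from_occupancy <- function(p, coverage = 0.995, seed = 1L,
                                duration = 500, zeta_scale = 1) {
  if (coverage <= 0 || coverage > 1)
    iso_stop("bad_argument", "`coverage` must be in (0, 1]")
  fa <- analyze_focus(p)
  rec <- integrate_sde(as.numeric(fa$x_star), p, duration = duration,
                       seed = seed, zeta_scale = zeta_scale)
  lohi <- function(x) {
    if (coverage >= 1) range(x)
    else quantile(x, c((1 - coverage) / 2, 1 - (1 - coverage) / 2),
                  names = FALSE)
  }
  e <- lohi(rec$E)
  i <- lohi(rec$states[, 2])
  snap <- c(floor(e[1] / 0.001), ceiling(e[2] / 0.001)) * 0.001
  snap_i <- c(floor(i[1] / 0.001), ceiling(i[2] / 0.001)) * 0.001
  di <- if (diff(snap_i) / 0.001 < 50) 0.0002 else 0.001
  grid2d(snap, snap_i, de = 0.001, di = di)
}

# shared eigen-convention helper for toy oracles (mirrors analyze_focus)
focus_eigen <- function(J) {
  ev <- eigen(J)
  k <- which(Im(ev$values) > 0)[1L]
  lam <- ev$values[k]
  v <- ev$vectors[, k]
  v <- v / sqrt(sum(Mod(v)^2))
  ref <- if (Mod(v[1]) > 1e-12) v[1] else v[2]
  v <- v * Conj(ref) / Mod(ref)
  if (Re(v[1]) < 0) v <- -v
  list(sigma = Re(lam), omega = Im(lam), a = Re(v), b = -Im(v), v1 = v)
}

#' Canned toy cases for oracle testing
#'
#' Returns closed-form scenarios used by the test suite:
#' \describe{
#'   \item{linear_focus}{a purely linear stable focus (Jacobian given) with
#'     closed-form flow `exp(J t)` and closed-form amplitude `2 |c1|` from
#'     the eigenbasis change of coordinates, plus the linear observables
#'     machinery, for validating the amplitude-map formula independently of
#'     any ODE solver.}
#'   \item{algo1_trace}{the stored 3x3 pencil-and-paper augmentation trace
#'     (gamma0, hand-specified 4-step bin trajectories, expected tensor).}
#'   \item{tone, am_tone}{stub signal generators for envelope and
#'     phase-tracker tests.}
#' }
#' @return A named list.
#' @export
toy_cases <- function() {
  J <- matrix(c(-0.8, 35, -25, -1.2), 2, 2) # eigenvalues -1 +/- ~29.6i
  eg <- focus_eigen(J)
  denom <- abs(eg$b[2] * eg$a[1] - eg$b[1] * eg$a[2])
  M <- 2 * cbind(eg$a, eg$b) # x = 2 (p a + q b) for c1 = p + i q
  linear <- list(
    jacobian = J, sigma = eg$sigma, omega = eg$omega,
    a = eg$a, b = eg$b, x_star = c(0, 0),
    period_T = 2 * pi / eg$omega,
    amp = function(x) {
      pq <- solve(M, as.numeric(x))
      2 * sqrt(sum(pq^2))
    },
    flow = function(x, t) {
      e <- exp(eg$sigma * t)
      R <- e * (cos(eg$omega * t) * diag(2) +
                  sin(eg$omega * t) * (J - eg$sigma * diag(2)) / eg$omega)
      as.numeric(R %*% as.numeric(x))
    },
    eq4_estimate = function(x, t) {
      y <- exp(eg$sigma * t) *
        (cos(eg$omega * t) * diag(2) +
           sin(eg$omega * t) * (J - eg$sigma * diag(2)) / eg$omega) %*%
        as.numeric(x)
      g1 <- y[1] * eg$b[2] - y[2] * eg$b[1]
      g2 <- y[1] * eg$a[2] - y[2] * eg$a[1]
      exp(-eg$sigma * t) * sqrt(g1^2 + g2^2) / denom
    })
  tracefile <- system.file("extdata", "algo1_trace.json", package = "isostim",
                           mustWork = TRUE)
  tr <- jsonlite::read_json(tracefile, simplifyVector = TRUE)
  algo1 <- list(
    gamma0 = matrix(tr$gamma0, tr$n_E, tr$n_I),
    p_idx = matrix(as.integer(tr$p_idx), tr$n_E * tr$n_I, tr$u),
    q_idx = matrix(as.integer(tr$q_idx), tr$n_E * tr$n_I, tr$u),
    expected = array(tr$expected, dim = c(tr$n_E, tr$n_I, tr$u)))
  list(
    linear_focus = linear,
    algo1_trace = algo1,
    tone = function(freq, amp, duration, fs, offset = 0) {
      t <- seq(0, duration, by = 1 / fs)
      offset + amp * sin(2 * pi * freq * t)
    },
    am_tone = function(fc, fm, amp, depth, duration, fs) {
      t <- seq(0, duration, by = 1 / fs)
      amp * (1 + depth * sin(2 * pi * fm * t)) * sin(2 * pi * fc * t)
    })
}

#' Frozen synthetic patients
#'
#' Loads the three frozen synthetic "patients" shipped with the package
#' (JSON parameter files plus a manifest with the stored focus metadata and
#' occupancy grid). These stand in for heterogeneous patient fits; their
#' focus analysis is re-verified by the test suite.
#'
#' @return A named list; each element has `params` ([wc_params()]), `grid`
#'   ([grid2d()]), and the stored `sigma`, `omega`, `seed`.
#' @export
isostim_patients <- function() {
  dir <- system.file("extdata", "patients", package = "isostim",
                     mustWork = TRUE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  out <- lapply(man$patients, function(m) {
    params <- read_wc_params(file.path(dir, m$file))
    g <- grid2d(c(m$grid$e_min, m$grid$e_max), c(m$grid$i_min, m$grid$i_max),
                de = m$grid$de, di = m$grid$di)
    list(params = params, grid = g, sigma = m$sigma, omega = m$omega,
         seed = m$seed)
  })
  names(out) <- vapply(man$patients, `[[`, character(1), "label")
  out
}
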