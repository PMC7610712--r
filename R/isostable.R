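#' Isostable estimation settings
#'
#' The isostable amplitude of a point is estimated by flowing it forward for
#' `n` linear periods `T = 2 pi / omega` and rescaling linear observables at
#' the endpoint (a map-based variant of Koopman eigenfunction evaluation).
#' The "full" preset integrates with adaptive RK45; the "quick" preset
#' relaxes the convergence requirement (`n` about one sixth of the full
#' value, minimum 10) and uses fixed-step Euler integration, which trades
#' accuracy of the field scale for a large speed-up while preserving the
#' field shape.
#'
#' When `n` is `NULL` it is chosen per model so that the trajectory has
#' decayed by about `e^-10` at the evaluation time while keeping
#' `exp(sigma * n * T)` comfortably above the floating-point noise floor of
#' the state (strongly damped foci forbid very large `n`).
#'
#' @param quality `"full"` or `"quick"`.
#' @param n number of periods of the map (>= 1) or `NULL` for the automatic
#'   per-model rule.
#' @param integrator `"rk45"` or `"euler"`; defaults follow `quality`.
#' @param dt Euler step in seconds (quick preset).
#' @param rtol,atol RK45 tolerances (full preset). The integration runs in
#'   deviation coordinates `y = X - X*` with the error controlled relative
#'   to `|y|`, which preserves the relative accuracy of the exponentially
#'   decaying observables; `atol` is therefore 0 by default.
#' @return An object of class `iso_config`.
#' @export
iso_config <- function(quality = c("full", "quick"), n = NULL,
                       integrator = NULL, dt = 1e-3,
                       rtol = 1e-8, atol = 0) {
  quality <- match.arg(quality)
  if (is.null(integrator))
    integrator <- if (quality == "full") "rk45" else "euler"
  integrator <- match.arg(integrator, c("rk45", "euler"))
  if (!is.null(n)) {
    stopifnot_scalar(n, "n", positive = TRUE)
    if (n < 1) iso_stop("bad_argument", "`n` must be >= 1")
  }
  structure(list(quality = quality, n = n, integrator = integrator,
                 dt = dt, rtol = rtol, atol = atol),
            class = "iso_config")
}

# per-model period count: ~e^-10 decay, capped at e^-25 against roundoff
choose_n_periods <- function(fa, quality) {
  decay_per_period <- abs(fa$sigma) * fa$period_T
  n_full <- max(20, round(10 / decay_per_period))
  cap <- max(1, floor(25 / decay_per_period))
  n_full <- min(n_full, cap)
  if (quality == "full") n_full else max(10, round(n_full / 6))
}

resolve_iso_n <- function(cfg, fa) {
  if (!is.null(cfg$n)) as.integer(cfg$n)
  else as.integer(choose_n_periods(fa, cfg$quality))
}

#' Linear observables of the focus
#'
#' `g1 = <X - X*, (b2, -b1)>` and `g2 = <X - X*, (a2, -a1)>` where
#' `v1 = a - i b` is the eigenvector of the leading eigenvalue. Both are
#' linear in `X` and vanish at the fixed point; `g2` vanishes on the `a`
#' direction by construction.
#'
#' @param x state `(E, I)` or an m x 2 matrix of states.
#' @param fa a [analyze_focus()] result.
#' @return Numeric `c(g1, g2)` (or an m x 2 matrix).
#' @export
observables <- function(x, fa) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 2)
  dE <- x[, 1] - fa$x_star[1]
  dI <- x[, 2] - fa$x_star[2]
  g <- cbind(g1 = dE * fa$b[2] - dI * fa$b[1],
             g2 = dE * fa$a[2] - dI * fa$a[1])
  if (nrow(g) == 1L) g[1, ] else g
}

default_bound_box <- function(fa, half_width = 1.5) {
  c(fa$x_star[1] - half_width, fa$x_star[1] + half_width,
    fa$x_star[2] - half_width, fa$x_star[2] + half_width)
}

inflate_grid_box <- function(grid, factor = 3) {
  ce <- (grid$e_min + grid$e_max) / 2
  ci <- (grid$i_min + grid$i_max) / 2
  he <- (grid$e_max - grid$e_min) / 2 * factor
  hi <- (grid$i_max - grid$i_min) / 2 * factor
  c(ce - he, ce + he, ci - hi, ci + hi)
}

#' Isostable amplitude of phase-space points
#'
#' Estimates `r(X) = exp(-sigma n T) * sqrt(g1^2 + g2^2) / |b2 a1 - b1 a2|`
#' with the observables evaluated at the deterministic flow endpoint
#' `Phi_{nT}(X)` (noiseless dynamics).  `r(X*) = 0`, and along deterministic
#' trajectories `r(Phi_t X) = exp(sigma t) r(X)`.
#'
#' @param x state `(E, I)` or an m x 2 matrix.
#' @param fa a [analyze_focus()] result for the same model.
#' @param p the [wc_params()] model.
#' @param cfg an [iso_config()].
#' @param box numeric length-4 bounding box `(e_lo, e_hi, i_lo, i_hi)`;
#'   trajectories leaving it raise a divergence error (point outside the
#'   basin of the focus). Defaults to a generous box around the fixed point.
#' @return Non-negative amplitude(s).
#' @export
isostable_amplitude <- function(x, fa, p, cfg = iso_config(), box = NULL) {
  denom <- abs(fa$b[2] * fa$a[1] - fa$b[1] * fa$a[2])
  if (denom < 1e-12)
    iso_stop("degenerate_eigenbasis",
             "|b2 a1 - b1 a2| < 1e-12: eigenbasis degenerate")
  if (is.null(box)) box <- default_bound_box(fa)
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 2)
  n <- resolve_iso_n(cfg, fa)
  r <- cpp_iso_amp(xm, param_vector(p), as.numeric(fa$x_star), fa$sigma,
                   fa$a, fa$b, n * fa$period_T,
                   cfg$integrator == "euler", cfg$dt, cfg$rtol, cfg$atol,
                   as.numeric(box))
  if (!is.matrix(x) && is.na(r[1]))
    iso_stop("divergence", "trajectory left the bounding box (outside basin)")
  r
}

#' Isostable amplitude field on a grid
#'
#' Evaluates [isostable_amplitude()] at every bin center of the grid, for
#' the deterministic model (noise SD treated as zero). Bins whose
#' trajectories leave the inflated grid box are masked.
#'
#' @param p the [wc_params()] model.
#' @param grid a [grid2d()].
#' @param cfg an [iso_config()].
#' @param fa optional precomputed [analyze_focus()] result.
#' @return An `amplitude_field` with `kind = "isostable"`.
#' @export
compute_isostable_field <- function(p, grid, cfg = iso_config(), fa = NULL) {
  if (is.null(fa)) fa <- analyze_focus(p)
  ctr <- grid_centers(grid)
  X <- cbind(rep(ctr$e, times = grid$n_I), rep(ctr$i, each = grid$n_E))
  n <- resolve_iso_n(cfg, fa)
  r <- cpp_iso_amp(X, param_vector(p), as.numeric(fa$x_star), fa$sigma,
                   fa$a, fa$b, n * fa$period_T,
                   cfg$integrator == "euler", cfg$dt, cfg$rtol, cfg$atol,
                   inflate_grid_box(grid))
  values <- matrix(r, nrow = grid$n_E, ncol = grid$n_I)
  mask <- is.na(values)
  values[mask] <- NA_real_
  new_amplitude_field(grid, values, mask, "isostable", cfg$quality,
                      meta = list(model = p$label, n = n,
                                  integrator = cfg$integrator,
                                  dt = cfg$dt, sigma = fa$sigma,
                                  omega = fa$omega))
}
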