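#' Instantaneous amplitude response field
#'
#' `Gamma0(X) = Omega(X + dX) - Omega(X)` with stimulation vector
#' `dX = (dE, 0)`; the shifted value is looked up by nearest bin (no
#' interpolation). Bins whose own value is missing, or whose shifted lookup
#' is masked or falls outside the grid, are missing (`NA`). Negative values
#' mark states where a pulse is beneficial (amplitude decreases).
#'
#' @param field an `amplitude_field`.
#' @param dE stimulation magnitude (> 0).
#' @return An object of class `response_field` (`zero_filled = FALSE`).
#' @export
instantaneous_response <- function(field, dE) {
  stopifnot_scalar(dE, "dE", positive = TRUE)
  if (all(field$mask)) iso_stop("empty_field", "field has no unmasked bins")
  g <- field$grid
  omega <- field$values
  omega[field$mask] <- NA_real_
  centers_e <- g$e_min + (seq_len(g$n_E) - 0.5) * g$de
  u <- (centers_e + dE - g$e_min) / g$de
  k <- floor(u)
  k[k == u & k > 0] <- k[k == u & k > 0] - 1 # boundary tie: lower bin wins
  valid <- k >= 0 & k < g$n_E
  gamma0 <- matrix(NA_real_, g$n_E, g$n_I)
  if (any(valid))
    gamma0[valid, ] <- omega[k[valid] + 1L, , drop = FALSE] -
      omega[valid, , drop = FALSE]
  structure(list(grid = g, gamma0 = gamma0, source_kind = field$kind,
                 source_quality = field$quality, stim_dE = dE,
                 zero_filled = FALSE),
            class = "response_field")
}

#' @export
print.response_field <- function(x, ...) {
  cat(sprintf("<response_field from %s/%s, dE=%.4g> %d x %d, %.1f%% missing%s\n",
              x$source_kind, x$source_quality, x$stim_dE,
              x$grid$n_E, x$grid$n_I, 100 * mean(is.na(x$gamma0)),
              if (x$zero_filled) " (zero-filled)" else ""))
  invisible(x)
}

#' Harmonize the support of an isostable response field
#'
#' For a fair strategy comparison, bins with no Hilbert-field estimate are
#' made non-actionable in the isostable response field: every bin missing in
#' `hil` is set to exactly 0 in `iso` (stimulation cannot be triggered
#' there). `hil` is left unchanged.
#'
#' @param iso,hil `response_field`s on the same grid.
#' @return The harmonized isostable `response_field`.
#' @export
harmonize_support <- function(iso, hil) {
  if (!grids_equal(iso$grid, hil$grid))
    iso_stop("grid_mismatch", "response fields are on different grids")
  iso$gamma0[is.na(hil$gamma0)] <- 0
  iso
}

#' Replace missing response values by zero
#'
#' Missing bins are logged as zeros so the discretized controller never
#' triggers on them; this is a precondition of [augment()].
#'
#' @param rf a `response_field`.
#' @return The field with `zero_filled = TRUE`.
#' @export
zero_fill <- function(rf) {
  rf$gamma0[is.na(rf$gamma0)] <- 0
  rf$zero_filled <- TRUE
  rf
}

#' Apply the augmentation rule to precomputed bin trajectories
#'
#' The discrete rule building `Gamma` from `Gamma0`: for each start bin
#' `(i, j)` and time index `k`, let `(p, q)` be the bin visited at step `k`;
#' then `Gamma(i,j,k) = Gamma0(p,q)` if `Gamma0(p,q) < 0` and
#' `Gamma0(p,q) <= Gamma0(i,j)`, else 0. Steps outside the grid
#' (`NA` indices) contribute 0.
#'
#' @param gamma0 zero-filled `n_E x n_I` matrix.
#' @param p_idx,q_idx integer matrices (`n_E * n_I` rows in column-major bin
#'   order, `u` columns) of 1-based bin indices, `NA` when out of grid.
#' @return `n_E x n_I x u` array.
#' @export
apply_algorithm1 <- function(gamma0, p_idx, q_idx) {
  P <- p_idx; Q <- q_idx
  P[is.na(P)] <- 0L; Q[is.na(Q)] <- 0L
  cpp_algo1(gamma0, P - 1L, Q - 1L)
}

#' Augmented amplitude response field
#'
#' Embeds the values of `Gamma0` along deterministic trajectories over one
#' linear period: from each bin center the noiseless model is integrated for
#' `t in [0, T]` at step `dt` (`u = round(T / dt) + 1` samples), visited bins
#' are found by nearest-bin lookup, and the rule of [apply_algorithm1()] is
#' applied. The `k = 1` slice equals `min(Gamma0, 0)`.
#'
#' @param g0 a zero-filled `response_field` (see [zero_fill()]).
#' @param p the [wc_params()] model.
#' @param fa a [analyze_focus()] result (provides `T`).
#' @param dt time step in seconds; equals the simulation step so the
#'   controller can index the time dimension by integration steps.
#' @return An object of class `augmented_response_field` with the
#'   `n_E x n_I x u` tensor `gamma` (all entries <= 0).
#' @export
augment <- function(g0, p, fa, dt = 1e-3) {
  if (!isTRUE(g0$zero_filled))
    iso_stop("bad_argument", "response field must be zero-filled first")
  g <- g0$grid
  u <- as.integer(round(fa$period_T / dt)) + 1L
  traj <- tryCatch(
    cpp_bin_trajectories(param_vector(p), g$e_min, g$de, g$n_E,
                         g$i_min, g$di, g$n_I, dt, u),
    error = function(e) iso_stop("integration", conditionMessage(e)))
  gamma <- cpp_algo1(g0$gamma0, traj$p, traj$q)
  structure(list(grid = g, gamma = gamma, dt = dt, u = u,
                 stim_dE = g0$stim_dE,
                 provenance = list(source_kind = g0$source_kind,
                                   source_quality = g0$source_quality,
                                   period_T = fa$period_T, model = p$label)),
            class = "augmented_response_field")
}

#' @export
print.augmented_response_field <- function(x, ...) {
  cat(sprintf("<augmented_response_field> %d x %d x %d (dt=%g s, dE=%.4g, from %s/%s)\n",
              x$grid$n_E, x$grid$n_I, x$u, x$dt, x$stim_dE,
              x$provenance$source_kind, x$provenance$source_quality))
  invisible(x)
}
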