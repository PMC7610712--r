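#' Phase-space grid
#'
#' A rectangular (E, I) grid of half-open bins `[lo, lo + width)` with
#' centers at `lo + width / 2`. Bounds are snapped outward so that an
#' integer number of bins spans each range exactly. The default bin is
#' 0.001 x 0.001 activity units; an anisotropic I width (e.g. 0.0002) is
#' used when the I range is narrow.
#'
#' @param e_range,i_range numeric length-2 bounds (lo, hi).
#' @param de,di bin widths (> 0).
#' @return An object of class `grid2d` with fields `e_min`, `e_max`,
#'   `i_min`, `i_max`, `de`, `di`, `n_E`, `n_I`.
#' @export
grid2d <- function(e_range, i_range, de = 0.001, di = 0.001) {
  stopifnot_scalar(de, "de", positive = TRUE)
  stopifnot_scalar(di, "di", positive = TRUE)
  if (diff(e_range) <= 0 || diff(i_range) <= 0)
    iso_stop("bad_argument", "ranges must have positive extent")
  n_E <- as.integer(ceiling(diff(e_range) / de - 1e-9))
  n_I <- as.integer(ceiling(diff(i_range) / di - 1e-9))
  structure(list(e_min = e_range[1], e_max = e_range[1] + n_E * de,
                 i_min = i_range[1], i_max = i_range[1] + n_I * di,
                 de = de, di = di, n_E = n_E, n_I = n_I),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> E: [%.4f, %.4f] x %d bins (de=%g); I: [%.4f, %.4f] x %d bins (di=%g)\n",
              x$e_min, x$e_max, x$n_E, x$de, x$i_min, x$i_max, x$n_I, x$di))
  invisible(x)
}

#' Bin centers of a grid
#' @param grid a [grid2d()] object.
#' @return A list with vectors `e` (length `n_E`) and `i` (length `n_I`).
#' @export
grid_centers <- function(grid) {
  list(e = grid$e_min + (seq_len(grid$n_E) - 0.5) * grid$de,
       i = grid$i_min + (seq_len(grid$n_I) - 0.5) * grid$di)
}

grids_equal <- function(g1, g2) {
  isTRUE(all.equal(unclass(g1)[c("e_min", "i_min", "de", "di")],
                   unclass(g2)[c("e_min", "i_min", "de", "di")],
                   tolerance = 1e-12)) &&
    g1$n_E == g2$n_E && g1$n_I == g2$n_I
}

new_amplitude_field <- function(grid, values, mask, kind, quality, meta) {
  structure(list(grid = grid, values = values, mask = mask,
                 kind = kind, quality = quality, meta = meta),
            class = "amplitude_field")
}

#' @export
print.amplitude_field <- function(x, ...) {
  cat(sprintf("<amplitude_field kind=%s quality=%s> %d x %d bins, %.1f%% masked\n",
              x$kind, x$quality, x$grid$n_E, x$grid$n_I,
              100 * mean(x$mask)))
  invisible(x)
}
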