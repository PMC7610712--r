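# classed conditions used across the package

iso_stop <- function(class, message, ..., data = list()) {
  cond <- structure(
    class = c(paste0("isostim_", class), "isostim_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

iso_warn <- function(class, message, ..., data = list()) {
  cond <- structure(
    class = c(paste0("isostim_", class), "isostim_warning", "warning",
              "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  warning(cond)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    iso_stop("bad_argument", sprintf("`%s` must be a finite numeric scalar",
                                     name))
  if (positive && x <= 0)
    iso_stop("bad_argument", sprintf("`%s` must be > 0", name))
  invisible(x)
}
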