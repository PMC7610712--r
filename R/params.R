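#' Wilson-Cowan model parameters
#'
#' Bundles all constants of the stochastic Wilson-Cowan neural mass model:
#' the shared time constant `nu` (seconds), sigmoid steepness `beta`, constant
#' inputs `eta_E`/`eta_I`, connection weights (`w_EE` excitatory self-loop,
#' `w_IE` inhibition of E by I, `w_EI` excitation of I by E), the Gaussian
#' white-noise standard deviation `zeta`, and the reference stimulation
#' magnitude `dE0` (activity units added to E by one pulse).
#'
#' @param nu time constant in seconds (> 0).
#' @param beta sigmoid steepness (> 0).
#' @param eta_E,eta_I constant inputs to the E and I populations.
#' @param w_EE,w_IE,w_EI connection weights (finite).
#' @param zeta noise standard deviation (>= 0), entering the E and I
#'   increments directly as written in the model equations.
#' @param dE0 reference stimulation magnitude (> 0).
#' @param label identifier string.
#' @return An object of class `wc_params`.
#' @examples
#' p <- wc_params(nu = 0.02, beta = 4, eta_E = 1, eta_I = 1,
#'                w_EE = 2, w_IE = 3, w_EI = 3, zeta = 0.02, dE0 = 0.01)
#' @export
wc_params <- function(nu, beta, eta_E, eta_I, w_EE, w_IE, w_EI,
                      zeta, dE0, label = "unnamed") {
  stopifnot_scalar(nu, "nu", positive = TRUE)
  stopifnot_scalar(beta, "beta", positive = TRUE)
  for (nm in c("eta_E", "eta_I", "w_EE", "w_IE", "w_EI"))
    stopifnot_scalar(get(nm), nm)
  stopifnot_scalar(zeta, "zeta")
  if (zeta < 0) iso_stop("bad_argument", "`zeta` must be >= 0")
  stopifnot_scalar(dE0, "dE0", positive = TRUE)
  structure(list(nu = nu, beta = beta, eta_E = eta_E, eta_I = eta_I,
                 w_EE = w_EE, w_IE = w_IE, w_EI = w_EI,
                 zeta = zeta, dE0 = dE0, label = as.character(label)),
            class = "wc_params")
}

# packed numeric form handed to the C++ kernels
param_vector <- function(p) {
  c(p$nu, p$beta, p$eta_E, p$eta_I, p$w_EE, p$w_IE, p$w_EI, p$zeta)
}

#' @export
print.wc_params <- function(x, ...) {
  cat(sprintf("<wc_params '%s'>\n", x$label))
  cat(sprintf("  nu=%.4g s  beta=%.4g  eta_E=%.4g  eta_I=%.4g\n",
              x$nu, x$beta, x$eta_E, x$eta_I))
  cat(sprintf("  w_EE=%.4g  w_IE=%.4g  w_EI=%.4g\n", x$w_EE, x$w_IE, x$w_EI))
  cat(sprintf("  zeta=%.4g  dE0=%.4g\n", x$zeta, x$dE0))
  invisible(x)
}

#' Read / write model parameters as JSON
#'
#' The serialized form uses exactly the keys `nu`, `beta`, `eta_E`, `eta_I`,
#' `w_EE`, `w_IE`, `w_EI`, `zeta`, `dE0`, `label`.
#'
#' @param path file path.
#' @param p a [wc_params()] object.
#' @return `read_wc_params()` returns a `wc_params` object;
#'   `write_wc_params()` returns `path` invisibly.
#' @export
read_wc_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("nu", "beta", "eta_E", "eta_I", "w_EE", "w_IE", "w_EI",
            "zeta", "dE0", "label")
  missing_keys <- setdiff(need, names(x))
  if (length(missing_keys))
    iso_stop("bad_params_file",
             paste("missing keys:", paste(missing_keys, collapse = ", ")))
  do.call(wc_params, x[need])
}

#' @rdname read_wc_params
#' @export
write_wc_params <- function(p, path) {
  stopifnot(inherits(p, "wc_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
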