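# runtime artifact containers: a compressed RDS payload with a small JSON
# sidecar so field/record provenance is inspectable without R

#' Write / read an amplitude or response field container
#'
#' Stores the object as compressed RDS plus a `<path>.json` sidecar holding
#' kind/quality/grid/provenance metadata.
#'
#' @param x an `amplitude_field`, `response_field` or
#'   `augmented_response_field`.
#' @param path destination file (conventionally `.rds`).
#' @return `write_field()` returns `path` invisibly; `read_field()` returns
#'   the stored object.
#' @export
write_field <- function(x, path) {
  saveRDS(x, path, compress = "gzip")
  meta <- list(class = class(x)[1],
               kind = x$kind %||% x$source_kind %||%
                 x$provenance$source_kind,
               quality = x$quality %||% x$source_quality %||%
                 x$provenance$source_quality,
               grid = unclass(x$grid))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) readRDS(path)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export / import a simulation record
#'
#' Columnar binary export: gzipped doubles for times, E (and I when
#' stored), a JSON sidecar with seed and config, and a CSV of stimulation
#' events (`time,magnitude`).
#'
#' @param rec a `sim_record`.
#' @param path base path; files `<path>.bin.gz`, `<path>.json`,
#'   `<path>.events.csv` are written.
#' @return `write_sim_record()` returns `path` invisibly;
#'   `read_sim_record()` returns a `sim_record`.
#' @export
write_sim_record <- function(rec, path) {
  has_I <- !is.null(rec$states)
  con <- gzfile(paste0(path, ".bin.gz"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(rec$times, rec$E, if (has_I) rec$states[, 2]), con,
           size = 8, endian = "little")
  jsonlite::write_json(
    list(n = length(rec$E), dt = rec$dt, has_I = has_I,
         seed = rec$seed, config = rec$config),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  ev <- data.frame(time = rec$stim_times, magnitude = rec$stim_magnitude)
  utils::write.csv(ev, paste0(path, ".events.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_record
#' @export
read_sim_record <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n
  ncol <- if (isTRUE(meta$has_I)) 3L else 2L
  con <- gzfile(paste0(path, ".bin.gz"), "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, "double", n = n * ncol, size = 8, endian = "little")
  ev <- utils::read.csv(paste0(path, ".events.csv"))
  E <- v[(n + 1):(2 * n)]
  I <- if (ncol == 3L) v[(2 * n + 1):(3 * n)] else numeric()
  steps <- as.integer(round(ev$time / meta$dt)) + 1L
  new_sim_record(E, I, meta$dt, meta$seed, as.list(meta$config),
                 steps, ev$magnitude)
}
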