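# Reproducibility plumbing: JSON serialization of parameter sets and run
# manifests. Together with seed_sequence() this gives a single RNG
# hierarchy: one master seed deterministically spawns per-agent,
# per-restart and per-Monte-Carlo child seeds.

#' Write / read a parameter set as JSON
#'
#' @param params A `surnor_params` object.
#' @param path File path.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(as.list(unclass(params)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(surnor_params, as.list(obj))
}

#' Run manifest
#'
#' Records everything needed to reproduce a run exactly: package version,
#' master seed, model, parameters and any extra fields.
#'
#' @param seed Master seed of the run.
#' @param model Model name.
#' @param params Parameter set.
#' @param ... Extra named fields to record.
#' @param path Optional path; if given the manifest is written as JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(seed, model = NULL, params = NULL, ..., path = NULL) {
  m <- list(package = "surnor",
            version = as.character(utils::packageVersion("surnor")),
            timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
            seed = seed, model = model,
            params = if (!is.null(params)) as.list(unclass(params)), ...)
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
    return(invisible(m))
  }
  m
}
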