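#' Write a JSON run manifest
#'
#' Records the parameters, seed and input-file digests of a pipeline stage
#' so that any output can be regenerated from the manifest plus the inputs.
#' Deliberately contains no timestamps: rerunning a stage with the same
#' inputs produces a byte-identical manifest.
#'
#' @param path Output JSON path.
#' @param stage Stage name (e.g. "fit", "sweep").
#' @param params Named list of stage parameters.
#' @param inputs Character vector of input file paths to digest (optional).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, params, inputs = character(0)) {
  digests <- if (length(inputs)) {
    files <- unlist(lapply(inputs, function(p) {
      if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = TRUE)
      else p
    }))
    files <- sort(files[file.exists(files)])
    stats::setNames(as.vector(tools::md5sum(files)), files)
  } else NULL
  jsonlite::write_json(list(stage = stage, params = params,
                            input_digests = digests),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Derive a stage seed from a base seed
#'
#' Deterministic forking of one user-supplied seed into per-stage seeds,
#' kept within the 32-bit integer range.
#'
#' @param seed Base integer seed.
#' @param offset Non-negative stage offset.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}
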