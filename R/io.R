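#' Read and write trial tensors as long-format CSV
#'
#' The on-disk interchange format is a long table with columns
#' `trial`, `time_ms`, `channel`, `value` (one row per sample), which
#' any toolchain can produce or consume. The sampling rate is recovered
#' from the time stamps on read.
#'
#' @param x a [trial_tensor()].
#' @param path CSV file path.
#' @export
write_trial_tensor <- function(x, path) {
  stopifnot(inherits(x, "trial_tensor"))
  d <- dim(x)
  dt <- data.table::data.table(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    time_ms = rep(rep(time_ms(x), each = d[1]), times = d[3]),
    channel = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(unclass(x)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_trial_tensor
#' @param region label attached to the tensor on read.
#' @export
read_trial_tensor <- function(path, region = "") {
  dt <- data.table::fread(path)
  need <- c("trial", "time_ms", "channel", "value")
  if (!all(need %in% names(dt)))
    stop("schema mismatch: expected columns ", paste(need, collapse = ", "))
  trials <- sort(unique(dt$trial)); times <- sort(unique(dt$time_ms))
  chans <- sort(unique(dt$channel))
  if (nrow(dt) != length(trials) * length(times) * length(chans))
    stop("schema mismatch: table is not a complete trial x time x channel grid")
  data.table::setorder(dt, channel, time_ms, trial)
  arr <- array(dt$value, dim = c(length(trials), length(times), length(chans)))
  fs <- if (length(times) > 1) 1000 / stats::median(diff(times)) else 1000
  trial_tensor(arr, fs = fs, t0_ms = times[1], region = region)
}

#' Write / read a fitted model or inference result
#'
#' Fit and inference objects are stored with R serialization (`.rds`);
#' the cluster table additionally round-trips as plain CSV via
#' [data.table::fwrite()].
#'
#' @param object a `ladyns_fit` or `inference_result`.
#' @param path destination `.rds` path.
#' @export
write_result <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_result
#' @param expect optional class name to validate against.
#' @export
read_result <- function(path, expect = NULL) {
  obj <- readRDS(path)
  if (!is.null(expect) && !inherits(obj, expect))
    stop("version/type mismatch: expected a ", expect, " object")
  obj
}

#' Run manifest
#'
#' Records everything needed to re-run a pipeline stage bit-compatibly:
#' the resolved configuration (including calibrated penalties), seeds,
#' package version, input file checksums and a timestamp. Written as
#' JSON next to each output artifact.
#'
#' @param command stage name.
#' @param config named list of resolved parameters.
#' @param seeds named list/vector of seeds in use.
#' @param inputs character vector of input file paths (checksummed).
#' @param path output JSON path.
#' @export
write_manifest <- function(command, config, seeds, inputs = character(), path) {
  man <- list(command = command,
              config = config,
              seeds = seeds,
              package_version = as.character(utils::packageVersion("ladyns")),
              input_checksums = as.list(tools::md5sum(inputs)),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path)
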