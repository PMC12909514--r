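#' Trial-by-time-by-channel tensor
#'
#' The basic data container: an `N x T x d` numeric array holding `N`
#' repeated trials of a `d`-channel time series sampled at `fs` Hz,
#' together with its time axis. All preprocessing and fitting functions
#' consume and return `trial_tensor` objects.
#'
#' @param values numeric array with dimensions trials x time x channels.
#' @param fs sampling frequency in Hz.
#' @param t0_ms time of the first sample, in ms.
#' @param region free-text label for the recorded region.
#' @return an object of class `trial_tensor` (a 3-d array with attributes).
#' @export
trial_tensor <- function(values, fs, t0_ms = 0, region = "") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (trials x time x channels)")
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  structure(values,
            fs = fs, t0_ms = t0_ms, region = region,
            class = c("trial_tensor", "array"))
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("trial_tensor: %d trials x %d time points x %d channels\n",
              d[1], d[2], d[3]))
  cat(sprintf("  fs = %g Hz, t = [%g, %g] ms%s\n", attr(x, "fs"),
              attr(x, "t0_ms"),
              attr(x, "t0_ms") + (d[2] - 1) / attr(x, "fs") * 1000,
              if (nzchar(attr(x, "region"))) paste0(", region = ", attr(x, "region")) else ""))
  invisible(x)
}

#' @rdname trial_tensor
#' @param x a `trial_tensor`.
#' @export
n_trials <- function(x) dim(x)[1]

#' @rdname trial_tensor
#' @export
n_times <- function(x) dim(x)[2]

#' @rdname trial_tensor
#' @export
n_channels <- function(x) dim(x)[3]

#' @rdname trial_tensor
#' @export
time_ms <- function(x) {
  attr(x, "t0_ms") + (seq_len(dim(x)[2]) - 1) / attr(x, "fs") * 1000
}

## rebuild a tensor with new values but metadata carried over
tensor_like <- function(values, template, fs = attr(template, "fs"),
                        t0_ms = attr(template, "t0_ms")) {
  trial_tensor(values, fs = fs, t0_ms = t0_ms, region = attr(template, "region"))
}
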