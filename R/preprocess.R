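#' Complex Morlet amplitude envelope
#'
#' Convolves each trial/channel series with a complex Morlet wavelet (a
#' complex sinusoid at `f0` Hz under a Gaussian envelope whose SD is
#' `bandwidth_ms`) and takes the pointwise modulus. The kernel is
#' normalized so that a unit-amplitude sinusoid at `f0` yields an
#' envelope of 1 in the trial interior. Convolution uses "same" mode
#' with the kernel truncated at +/- 4 SD; edge samples within
#' `2 * bandwidth_ms` of either end are retained but flagged via the
#' `edge_ms` attribute, and assertions in analyses should be restricted
#' to the interior.
#'
#' @param x a raw [trial_tensor()].
#' @param f0 centre frequency, Hz; must be below Nyquist.
#' @param bandwidth_ms Gaussian envelope SD of the wavelet, ms.
#' @param edge_correct divide edge samples by the fraction of the kernel
#'   mass that actually overlapped the trial (normalized convolution),
#'   removing the amplitude roll-off where the wavelet is truncated.
#' @return envelope [trial_tensor()] of the same dimensions, with an
#'   `edge_ms` attribute flagging the edge-affected margin.
#' @export
morlet_envelope <- function(x, f0, bandwidth_ms, edge_correct = TRUE) {
  stopifnot(inherits(x, "trial_tensor"), bandwidth_ms > 0)
  fs <- attr(x, "fs")
  if (f0 >= fs / 2) stop("`f0` must be below the Nyquist frequency fs/2")
  kern <- morlet_kernel(f0, bandwidth_ms, fs)
  Tn <- n_times(x); N <- n_trials(x); d <- n_channels(x)
  if (Tn < length(kern)) stop("trial length is shorter than the wavelet support")
  env <- array(0, dim = dim(x))
  ## FFT convolution, one trial at a time (columns = channels)
  half <- (length(kern) - 1L) %/% 2L
  L <- stats::nextn(Tn + length(kern) - 1L, 2)
  Kf <- stats::fft(c(kern, rep(0, L - length(kern))))
  for (n in seq_len(N)) {
    Xn <- matrix(x[n, , ], Tn, d)
    Xp <- rbind(Xn, matrix(0, L - Tn, d))
    Y <- stats::mvfft(stats::mvfft(Xp) * Kf, inverse = TRUE) / L
    env[n, , ] <- Mod(Y[half + seq_len(Tn), , drop = FALSE])
  }
  if (edge_correct) {
    gk <- Mod(kern)
    mass <- stats::convolve(rep(1, Tn), rev(gk), type = "open")
    mass <- mass[half + seq_len(Tn)] / sum(gk)
    env <- env / rep(mass, each = N)
  }
  out <- tensor_like(env, x)
  attr(out, "edge_ms") <- 2 * bandwidth_ms
  out
}

## complex Morlet kernel, truncated at 4 SD, normalized to unit response
## at f0 (a cosine of amplitude 1 maps to modulus ~1 in the interior)
morlet_kernel <- function(f0, bandwidth_ms, fs) {
  sd_samp <- bandwidth_ms / 1000 * fs
  half <- ceiling(4 * sd_samp)
  u <- (-half):half
  k <- exp(2i * pi * f0 * u / fs) * exp(-u^2 / (2 * sd_samp^2))
  ## response to exp(-2i pi f0 t) component of a cosine is sum(gauss)/2
  k / (sum(exp(-u^2 / (2 * sd_samp^2))) / 2)
}

#' Downsample an envelope tensor by decimation
#'
#' Keeps every `fs / target_fs`-th sample (starting at the first); the
#' envelope is already low-pass by construction so simple decimation is
#' used rather than block averaging.
#'
#' @param x a [trial_tensor()].
#' @param target_fs target sampling rate, Hz; must divide `fs` exactly.
#' @export
downsample <- function(x, target_fs) {
  stopifnot(inherits(x, "trial_tensor"), target_fs > 0)
  fs <- attr(x, "fs")
  stride <- fs / target_fs
  if (abs(stride - round(stride)) > 1e-9)
    stop("`fs` must be an integer multiple of `target_fs`")
  stride <- as.integer(round(stride))
  if (stride == 1L) return(x)
  idx <- seq(1L, n_times(x), by = stride)
  out <- tensor_like(x[, idx, , drop = FALSE], x, fs = target_fs)
  if (!is.null(attr(x, "edge_ms"))) attr(out, "edge_ms") <- attr(x, "edge_ms")
  out
}

#' Centre trials at each (time, channel)
#'
#' Subtracts the across-trial mean at every time/channel cell; the
#' returned means can be reapplied to held-out data.
#'
#' @param x a [trial_tensor()] with at least two trials.
#' @param means optional T x d matrix of means to subtract (reuse on
#'   held-out data); computed from `x` when `NULL`.
#' @return list with the centred tensor `x` and the `means` matrix.
#' @export
center_trials <- function(x, means = NULL) {
  stopifnot(inherits(x, "trial_tensor"))
  if (is.null(means)) {
    if (n_trials(x) < 2L) stop("need at least 2 trials to estimate means")
    means <- apply(x, c(2, 3), mean)
  }
  vals <- unclass(x) - rep(means, each = n_trials(x))
  out <- tensor_like(array(vals, dim(x)), x)
  if (!is.null(attr(x, "edge_ms"))) attr(out, "edge_ms") <- attr(x, "edge_ms")
  list(x = out, means = means)
}

#' Pick the dominant oscillation frequency
#'
#' Utility for frequency selection: averages per-trial, per-channel
#' periodograms and returns the frequency with maximum power within
#' `range_hz` (default 12-40 Hz).
#'
#' @param x a raw [trial_tensor()].
#' @param range_hz frequency search window, Hz.
#' @return the selected frequency in Hz.
#' @export
select_f0 <- function(x, range_hz = c(12, 40)) {
  stopifnot(inherits(x, "trial_tensor"))
  fs <- attr(x, "fs"); Tn <- n_times(x)
  freqs <- (seq_len(Tn) - 1) * fs / Tn
  keep <- freqs >= range_hz[1] & freqs <= range_hz[2]
  if (!any(keep)) stop("no Fourier frequency falls inside `range_hz`")
  pow <- numeric(Tn)
  for (n in seq_len(n_trials(x))) {
    Xn <- matrix(x[n, , ], Tn, n_channels(x))
    pow <- pow + rowSums(Mod(stats::mvfft(Xn))^2)
  }
  freqs[keep][which.max(pow[keep])]
}
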