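#' Haemodynamic response function specification
#'
#' A canonical two-gamma HRF (positive peak gamma minus a scaled undershoot
#' gamma), or a user-supplied kernel. The kernel is normalised to unit
#' integral so that a sustained neural response of amplitude `a` converges to
#' a BOLD plateau of `a`, making GLM slopes interpretable in neural
#' amplitude units.
#'
#' @param kind `"canonical_two_gamma"` or `"user_kernel"`.
#' @param peak_delay_s,undershoot_delay_s gamma delays in seconds (defaults
#'   6 and 16).
#' @param peak_dispersion_s,undershoot_dispersion_s gamma dispersions in
#'   seconds (defaults 1 and 1).
#' @param peak_undershoot_ratio undershoot amplitude relative to the peak
#'   (default 1/6).
#' @param sample_interval_s internal convolution grid in seconds (default
#'   0.1; the 1.4 s TR must be an integer multiple).
#' @param duration_s kernel support in seconds (default 32, at least 24).
#' @param kernel numeric vector for `kind = "user_kernel"`, sampled at
#'   `sample_interval_s`.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(kind = c("canonical_two_gamma", "user_kernel"),
                     peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                     peak_undershoot_ratio = 1 / 6,
                     sample_interval_s = 0.1, duration_s = 32,
                     kernel = NULL) {
  kind <- match.arg(kind)
  if (peak_dispersion_s <= 0 || undershoot_dispersion_s <= 0)
    stop("HRF dispersions must be positive", call. = FALSE)
  if (duration_s < 24)
    stop("HRF kernel must cover at least 24 s", call. = FALSE)
  structure(list(kind = kind, peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 sample_interval_s = sample_interval_s,
                 duration_s = duration_s, kernel = kernel),
            class = "hrf_spec")
}

#' Sample an HRF kernel
#'
#' @param spec an [hrf_spec()].
#' @return Numeric kernel sampled at `spec$sample_interval_s`, normalised to
#'   unit integral; attribute `dt` holds the sample interval.
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  dt <- spec$sample_interval_s
  if (spec$kind == "user_kernel") {
    k <- spec$kernel
    if (is.null(k) || !all(is.finite(k)))
      stop("user_kernel requires a finite `kernel` vector", call. = FALSE)
  } else {
    t <- seq(0, spec$duration_s, by = dt)
    k <- stats::dgamma(t, shape = spec$peak_delay_s / spec$peak_dispersion_s,
                       scale = spec$peak_dispersion_s) -
      spec$peak_undershoot_ratio *
      stats::dgamma(t, shape = spec$undershoot_delay_s / spec$undershoot_dispersion_s,
                    scale = spec$undershoot_dispersion_s)
  }
  s <- sum(k) * dt
  if (!is.finite(s) || abs(s) < .Machine$double.eps)
    stop("HRF kernel must have a finite, non-zero integral", call. = FALSE)
  k <- k / s
  attr(k, "dt") <- dt
  k
}

#' Convolve a sampled series with an HRF kernel
#'
#' Discrete linear convolution scaled by the sample interval (so it
#' approximates the continuous convolution integral), truncated to the input
#' length. With `pad = "steady"` the series is assumed to have been at its
#' initial value long before the first sample (the adaptor is shown before
#' each run and pre-steady-state frames are discarded), so a constant input
#' maps exactly to a constant output.
#'
#' @param x numeric series sampled at the kernel's `dt`.
#' @param kernel an [hrf_kernel()] (or any numeric vector with a `dt`
#'   attribute).
#' @param pad `"zero"` (default; a unit impulse returns the kernel itself)
#'   or `"steady"`.
#' @return Numeric vector, `length(x)`.
#' @export
convolve_hrf <- function(x, kernel = hrf_kernel(), pad = c("zero", "steady")) {
  pad <- match.arg(pad)
  dt <- attr(kernel, "dt")
  if (is.null(dt)) stop("`kernel` needs a `dt` attribute", call. = FALSE)
  npad <- if (pad == "steady") length(kernel) else 0L
  xin <- c(rep(x[1], npad), x)
  out <- stats::convolve(xin, rev(kernel), type = "open")[seq_along(xin)] * dt
  out[npad + seq_along(x)]
}

# Convolve a per-TR neural amplitude series: upsample to the HRF grid as a
# boxcar, convolve with steady-state onset padding, and average within each
# TR window.
convolve_tr_series <- function(x_tr, spec = hrf_spec(), tr_seconds = 1.4,
                               pad = "steady") {
  dt <- spec$sample_interval_s
  up <- round(tr_seconds / dt)
  if (abs(up * dt - tr_seconds) > 1e-9)
    stop("TR must be an integer multiple of the HRF sample interval",
         call. = FALSE)
  k <- hrf_kernel(spec)
  y <- convolve_hrf(rep(x_tr, each = up), k, pad = pad)
  colMeans(matrix(y, nrow = up))
}
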