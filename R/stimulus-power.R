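#' Aggregate Fourier power of a luminance image
#'
#' Quantifies the spatial-frequency-domain contrast energy of a display.
#' The image mean (DC component) is removed, the 2D FFT is taken, and the
#' non-DC coefficient magnitudes are aggregated.
#'
#' Two aggregations are provided. `"magnitude"` (default) sums |F(u,v)|;
#' because the total dot surface area is held constant across numerosities,
#' the total squared contrast energy is fixed (Parseval), while higher
#' numerosities spread that energy across more frequency bins, so the
#' magnitude sum grows monotonically with numerosity. `"squared"` sums
#' |F(u,v)|^2 (contrast energy itself), which is essentially invariant to
#' numerosity at fixed total dot area and is kept as an explicit alternative,
#' optionally band-limited.
#'
#' @param image numeric matrix of finite luminance values; an attribute
#'   `pixels_per_degree` (as set by [rasterize_display()]) is required when
#'   `band` is given.
#' @param aggregation `"magnitude"` or `"squared"`.
#' @param band optional length-2 numeric, a radial spatial-frequency band
#'   `[lo, hi)` in cycles/degree over which to aggregate.
#' @return Non-negative scalar; exactly 0 for a uniform image.
#' @export
aggregate_fourier_power <- function(image,
                                    aggregation = c("magnitude", "squared"),
                                    band = NULL) {
  aggregation <- match.arg(aggregation)
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("`image` must be a finite numeric matrix", call. = FALSE)
  x <- image - mean(image)
  F <- stats::fft(x)
  mag <- Mod(F)
  mag[1, 1] <- 0  # DC bin excluded (already ~0 after mean removal)
  if (!is.null(band)) {
    ppd <- attr(image, "pixels_per_degree")
    if (is.null(ppd))
      stop("band-limited aggregation needs a `pixels_per_degree` attribute",
           call. = FALSE)
    f <- fft_freq_grid(nrow(image), ncol(image), ppd)
    keep <- f >= band[1] & f < band[2]
    mag <- mag * keep
  }
  if (aggregation == "squared") sum(mag^2) else sum(mag)
}

# Radial spatial frequency (cycles/degree) of every 2D FFT bin.
fft_freq_grid <- function(nr, nc, pixels_per_degree) {
  fr <- function(n) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
    if (n == 1) k <- 0
    k / n * pixels_per_degree
  }
  outer(fr(nr)^2, fr(nc)^2, `+`)^0.5
}

#' Mean aggregate Fourier power per numerosity
#'
#' Builds the numerosity-to-power lookup used by the monotonic response
#' model: for each numerosity level, displays are generated at fixed total
#' dot area over several seeds, rasterized, and their aggregate Fourier
#' power averaged. Deterministic given `seed`.
#'
#' @param numerosities integer vector of levels (default the stimulus levels
#'   1-7 and 20).
#' @param n_seeds displays averaged per level (default 20).
#' @param seed base seed.
#' @param total_area total dot area in deg^2.
#' @param pixels_per_degree,image_extent raster settings.
#' @param aggregation,band passed to [aggregate_fourier_power()].
#' @return Named numeric vector of mean power, names = numerosities.
#' @export
fourier_power_table <- function(numerosities = NUM_LEVELS, n_seeds = 20, seed = 1L,
                        total_area = default_total_area(),
                        pixels_per_degree = 64, image_extent = 2,
                        aggregation = "magnitude", band = NULL) {
  vals <- vapply(numerosities, function(n) {
    mean(vapply(seq_len(n_seeds), function(s) {
      d <- generate_dot_display(n, total_area = total_area,
                                seed = child_seed(seed, n, s))
      aggregate_fourier_power(
        rasterize_display(d, pixels_per_degree = pixels_per_degree,
                          image_extent = image_extent),
        aggregation = aggregation, band = band)
    }, numeric(1)))
  }, numeric(1))
  names(vals) <- as.character(numerosities)
  vals
}
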