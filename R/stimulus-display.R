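#' Default total dot surface area
#'
#' The total surface area shared by all display items is held constant across
#' numerosities so that display luminance does not covary with numerosity.
#' The default is chosen so a single dot has a 0.5 degree diameter, well
#' inside the 0.75 degree stimulus field.
#'
#' @return Total dot area in squared degrees of visual angle.
#' @export
default_total_area <- function() pi * 0.25^2

#' Generate a numerosity dot display
#'
#' Places `numerosity` equal-sized dots pseudo-randomly within a circular
#' field centred on fixation. Dot radius is set analytically so that the
#' total dot surface area equals `total_area` for every numerosity. Centres
#' are drawn by rejection sampling under a minimum centre-to-centre spacing,
#' which keeps items evenly spread and avoids perceptual grouping; whole dot
#' discs are constrained to lie inside the field.
#'
#' @param numerosity positive integer, number of dots.
#' @param total_area total dot surface area in deg^2 (default
#'   [default_total_area()]).
#' @param seed integer seed; identical `(seed, parameters)` give identical
#'   displays.
#' @param min_spacing minimum pairwise centre distance in degrees. `NULL`
#'   (default) uses 2.2 times the dot radius.
#' @param field_radius radius in degrees of the circular stimulus field
#'   (default 0.75).
#' @param colour `"black"` or `"white"` (white displays are the rare oddball
#'   attention targets).
#' @param max_restarts number of full rejection-sampling restarts (each with
#'   up to 1e4 proposals) before the packing is declared infeasible.
#' @return An object of class `dot_display`: list with `numerosity`,
#'   `dot_centres` (n x 2 matrix, degrees, y-up), `dot_radius`, `colour`,
#'   `field_radius`, `total_area`.
#' @export
generate_dot_display <- function(numerosity, total_area = default_total_area(),
                                 seed = 1L, min_spacing = NULL,
                                 field_radius = 0.75,
                                 colour = c("black", "white"),
                                 max_restarts = 50L) {
  colour <- match.arg(colour)
  stopifnot(numerosity >= 1, numerosity == round(numerosity))
  assert_scalar_num(total_area, "total_area", lower = .Machine$double.eps)
  dot_radius <- sqrt(total_area / (numerosity * pi))
  if (dot_radius >= field_radius)
    stop("infeasible packing: dot radius ", signif(dot_radius, 3),
         " exceeds the stimulus field radius", call. = FALSE)
  if (is.null(min_spacing)) min_spacing <- 2.2 * dot_radius
  place_max <- field_radius - dot_radius

  sample_centres <- function() {
    for (restart in seq_len(max_restarts)) {
      cx <- cy <- numeric(0)
      fails <- 0L
      while (length(cx) < numerosity && fails < 1e4) {
        theta <- stats::runif(1, 0, 2 * pi)
        rad <- place_max * sqrt(stats::runif(1))
        x <- rad * cos(theta); y <- rad * sin(theta)
        ok <- !length(cx) || min((cx - x)^2 + (cy - y)^2) >= min_spacing^2
        if (ok) { cx <- c(cx, x); cy <- c(cy, y) } else fails <- fails + 1L
      }
      if (length(cx) == numerosity)
        return(cbind(x = cx, y = cy))
    }
    NULL
  }
  centres <- with_seed(seed, sample_centres())
  if (is.null(centres))
    stop("infeasible packing: could not place ", numerosity,
         " dots of radius ", signif(dot_radius, 3), " at min spacing ",
         signif(min_spacing, 3), " within a ", field_radius,
         " degree field", call. = FALSE)

  structure(list(numerosity = as.integer(numerosity),
                 dot_centres = centres,
                 dot_radius = dot_radius,
                 colour = colour,
                 field_radius = field_radius,
                 total_area = total_area),
            class = "dot_display")
}

#' Rasterize a dot display into a luminance image
#'
#' Renders the display on a square pixel grid. A pixel takes the dot
#' luminance when its centre falls inside any dot disc, else the background
#' luminance, so the summed deviation from background is proportional to
#' total dot area up to pixelation.
#'
#' @param display a [generate_dot_display()] object (or any list with the
#'   same fields; zero dots yields a uniform background image).
#' @param pixels_per_degree raster resolution (default 64).
#' @param image_extent side length of the square image in degrees (default
#'   2); must cover the stimulus field.
#' @param background,black,white luminance levels in [0, 1].
#' @return Numeric matrix (row-major, row 1 = top of the visual field,
#'   y-up coordinates; origin at image centre), with attribute
#'   `pixels_per_degree`.
#' @export
rasterize_display <- function(display, pixels_per_degree = 64,
                              image_extent = 2,
                              background = 0.5, black = 0, white = 1) {
  assert_scalar_num(pixels_per_degree, "pixels_per_degree",
                    lower = .Machine$double.eps)
  if (image_extent < 2 * display$field_radius)
    stop("image_extent (", image_extent, " deg) does not cover the ",
         display$field_radius, " deg radius stimulus field", call. = FALSE)
  npx <- round(image_extent * pixels_per_degree)
  # pixel-centre coordinates, ascending
  coord <- ((seq_len(npx) - 0.5) / pixels_per_degree) - image_extent / 2
  img <- matrix(background, npx, npx)
  level <- if (identical(display$colour, "white")) white else black
  n <- if (is.null(display$dot_centres)) 0L else nrow(display$dot_centres)
  if (n > 0) {
    r2 <- display$dot_radius^2
    # rows index y descending (top of image = +y), columns index x ascending
    yy <- rev(coord)
    for (i in seq_len(n)) {
      dx2 <- (coord - display$dot_centres[i, 1])^2
      dy2 <- (yy - display$dot_centres[i, 2])^2
      img[outer(dy2, dx2, `+`) <= r2] <- level
    }
  }
  attr(img, "pixels_per_degree") <- pixels_per_degree
  img
}

#' Write a display as a delimited dot table
#'
#' One row per dot: `x_deg`, `y_deg`, `radius_deg`, `colour`.
#'
#' @param display a `dot_display`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_display_table <- function(display, path, sep = "\t") {
  df <- data.frame(x_deg = display$dot_centres[, 1],
                   y_deg = display$dot_centres[, 2],
                   radius_deg = display$dot_radius,
                   colour = display$colour)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a display as a PNG image
#'
#' Requires the optional `png` package.
#'
#' @inheritParams write_display_table
#' @param ... passed to [rasterize_display()].
#' @return `path`, invisibly.
#' @export
write_display_png <- function(display, path, ...) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("PNG export needs the `png` package", call. = FALSE)
  img <- rasterize_display(display, ...)
  png::writePNG(img, path)
  invisible(path)
}
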