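#' Select voxels for the monotonic slope analyses
#'
#' Keeps voxels that (1) have a preferred visual field eccentricity below
#' the threshold, so their spatial population receptive field covers the
#' central numerosity stimulus; (2) have a positive monotonic slope in the
#' control (changing adaptor) condition, so responses increase with
#' numerosity; (3) reach the minimum monotonic variance explained in the
#' changing condition; and (4) are classified monotonic under
#' cross-validation. Selection is idempotent and order-independent.
#'
#' @param meta voxel metadata data frame with `voxel_id`, `participant`,
#'   `hemisphere`, `map_label`, `ecc_deg`.
#' @param fits fit table from [fit_voxel_dataset()].
#' @param ecc_max eccentricity threshold in degrees (default 1).
#' @param r2_min monotonic variance-explained threshold (default 0.1).
#' @param r2_source `"plain"` (default) applies the threshold to the
#'   within-condition fit R2; `"cv"` to the cross-validated R2.
#' @return Subset of `meta` with changing-condition `slope` and `r2`
#'   appended.
#' @export
select_voxels <- function(meta, fits, ecc_max = 1, r2_min = 0.1,
                          r2_source = c("plain", "cv")) {
  r2_source <- match.arg(r2_source)
  ch <- fits[fits$condition == "changing", ]
  r2 <- if (r2_source == "plain") ch$r2 else ch$cv_r2_monotonic
  idx <- match(meta$voxel_id, ch$voxel_id)
  keep <- !is.na(idx) &
    meta$ecc_deg < ecc_max &
    ch$slope[idx] > 0 &
    r2[idx] >= r2_min &
    ch$model_class[idx] == "monotonic"
  out <- meta[keep, , drop = FALSE]
  out$slope_changing <- ch$slope[idx][keep]
  out$r2_changing <- ch$r2[idx][keep]
  rownames(out) <- NULL
  out
}

#' Aggregate selected voxels into visual-field-map examples
#'
#' A map example is one visual field map in one hemisphere of one
#' participant: the unit of the group statistics. Per-condition voxel
#' slopes and variance explained are averaged (unweighted) across the
#' selected voxels. Examples whose mean variance explained falls below
#' `r2_min` in both the low and high adaptor conditions show no clear
#' response to those conditions and are flagged excluded. The proportional
#' slope reduction is attached via [proportional_reduction()].
#'
#' @param selected output of [select_voxels()].
#' @param fits fit table from [fit_voxel_dataset()].
#' @param r2_min map-example variance-explained floor (default 0.1).
#' @return Data frame, one row per participant x hemisphere x map with at
#'   least one selected voxel: `n_voxels`, `mean_slope_low`,
#'   `mean_slope_high`, `mean_slope_changing`, `mean_r2_low`,
#'   `mean_r2_high`, `included`, `proportional_reduction` (`NA` when the
#'   example is excluded or its changing slope is not positive).
#' @export
aggregate_map_examples <- function(selected, fits, r2_min = 0.1) {
  if (!nrow(selected)) {
    return(data.frame(participant = character(), hemisphere = character(),
                      map_label = character(), n_voxels = integer(),
                      mean_slope_low = numeric(), mean_slope_high = numeric(),
                      mean_slope_changing = numeric(), mean_r2_low = numeric(),
                      mean_r2_high = numeric(), included = logical(),
                      proportional_reduction = numeric()))
  }
  wide <- stats::reshape(
    fits[fits$voxel_id %in% selected$voxel_id,
         c("voxel_id", "condition", "slope", "r2")],
    idvar = "voxel_id", timevar = "condition", direction = "wide")
  d <- merge(selected, wide, by = "voxel_id")
  key <- interaction(d$participant, d$hemisphere, d$map_label, drop = TRUE)
  agg <- function(x) tapply(x, key, mean)
  ex <- data.frame(do.call(rbind, strsplit(levels(key), ".", fixed = TRUE)))
  names(ex) <- c("participant", "hemisphere", "map_label")
  ex$n_voxels <- as.integer(tapply(d$voxel_id, key, length))
  ex$mean_slope_low <- as.numeric(agg(d$slope.low))
  ex$mean_slope_high <- as.numeric(agg(d$slope.high))
  ex$mean_slope_changing <- as.numeric(agg(d$slope.changing))
  ex$mean_r2_low <- as.numeric(agg(d$r2.low))
  ex$mean_r2_high <- as.numeric(agg(d$r2.high))
  ex$included <- !(ex$mean_r2_low < r2_min & ex$mean_r2_high < r2_min)
  ex$proportional_reduction <- vapply(seq_len(nrow(ex)), function(i)
    proportional_reduction(ex[i, ], warn = FALSE), numeric(1))
  rownames(ex) <- NULL
  ex
}

#' Proportional slope reduction of a map example
#'
#' The neural adaptation effect strength: the drop in monotonic slope from
#' the low to the high adaptor condition, as a proportion of the slope in
#' the changing (control) adaptor condition. Dividing by the control slope
#' makes the metric comparable between visual field maps with different
#' absolute response amplitudes; it is invariant to a global multiplicative
#' gain on all slopes.
#'
#' @param example one row of [aggregate_map_examples()] (or any list with
#'   `mean_slope_low`, `mean_slope_high`, `mean_slope_changing`,
#'   `included`).
#' @param warn warn when the example is dropped (default TRUE).
#' @return `(mean_slope_low - mean_slope_high) / mean_slope_changing`, or
#'   `NA` when the example is excluded or its changing slope is not
#'   positive.
#' @export
proportional_reduction <- function(example, warn = TRUE) {
  if (!is.null(example$included) && !isTRUE(as.logical(example$included))) {
    if (warn) warning("map example excluded (low variance explained)")
    return(NA_real_)
  }
  if (!is.finite(example$mean_slope_changing) ||
      example$mean_slope_changing <= 0) {
    if (warn) warning("non-positive changing-condition slope; ",
                      "proportional reduction undefined")
    return(NA_real_)
  }
  (example$mean_slope_low - example$mean_slope_high) / example$mean_slope_changing
}

#' Write the map-example table as delimited text
#' @param examples data frame from [aggregate_map_examples()].
#' @param path output path.
#' @param sep separator (default tab).
#' @return `path`, invisibly.
#' @export
write_map_examples <- function(examples, path, sep = "\t") {
  utils::write.table(examples, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
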