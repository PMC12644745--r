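#' Fit the monotonic response model by ordinary least squares
#'
#' Regresses a voxel's BOLD time series on a [build_design()] matrix. The
#' slope is the coefficient of the stimulus column: the BOLD amplitude
#' change per unit increase of the log predictor. The slope sign is
#' unconstrained at fit time; positivity is a later selection criterion.
#'
#' @param y numeric BOLD vector, one sample per design row.
#' @param X design matrix with `stimulus` and `baseline` columns.
#' @return An object of class `monotonic_fit`: `slope`, `baseline`,
#'   `coefficients`, `fitted`, `r2` (1 - SS_res / SS_tot).
#' @export
fit_glm <- function(y, X) {
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design matrix (", qx$rank, " < ", ncol(X), ")",
         call. = FALSE)
  coef <- qr.coef(qx, y)
  fitted <- drop(X %*% coef)
  sstot <- sum((y - mean(y))^2)
  ssres <- sum((y - fitted)^2)
  structure(list(slope = unname(coef["stimulus"]),
                 baseline = unname(coef["baseline"]),
                 coefficients = coef, fitted = fitted,
                 r2 = if (sstot > 0) 1 - ssres / sstot else NA_real_,
                 sse = ssres),
            class = "monotonic_fit")
}

# Closed-form evaluation of a fixed prediction shape on held-out data:
# y ~ alpha * p + b with alpha >= 0 (the prediction may rescale in amplitude
# between scanning sessions but not change sign) and a free baseline.
ols_rescale_sse <- function(y, p) {
  yc <- y - mean(y)
  pc <- p - mean(p)
  syy <- sum(yc^2)
  spp <- sum(pc^2)
  if (spp <= 1e-12 * max(syy, 1)) return(list(alpha = 0, sse = syy, syy = syy))
  spy <- sum(pc * yc)
  alpha <- max(0, spy / spp)
  list(alpha = alpha, sse = syy - 2 * alpha * spy + alpha^2 * spp, syy = syy)
}

#' Precompute the shared state of the tuned grid search
#'
#' The tuned prediction for any candidate is a fixed HRF-convolved level
#' basis times the candidate's per-level Gaussian amplitudes, so the sums of
#' squares needed by every least-squares candidate fit reduce to small
#' matrix products that can be shared across voxels. Build this once per
#' run-sequence/HRF/grid combination and pass it to [grid_fit_tuned()] and
#' [crossval_compare()].
#'
#' @param seq a run sequence (the changing schedule is shared across
#'   conditions, so one context serves all three).
#' @param hrf an [hrf_spec()].
#' @param grid a [tuned_grid()] data frame.
#' @return An object of class `tuned_grid_context`.
#' @export
tuned_grid_context <- function(seq, hrf = hrf_spec(), grid = tuned_grid()) {
  if (!nrow(grid)) stop("empty tuned grid", call. = FALSE)
  B <- numerosity_basis(seq, "changing", hrf)
  levels <- as.numeric(colnames(B))
  w2 <- 2 * grid$width_log^2
  D <- outer(log(levels), grid$pref_log, `-`)^2
  G <- exp(-sweep(D, 2, w2, `/`))        # levels x candidates
  Bc <- scale(B, center = TRUE, scale = FALSE)
  Sxx <- colSums((crossprod(Bc) %*% G) * G)
  structure(list(grid = grid, levels = levels, B = B, Bc = Bc, G = G,
                 Sxx = Sxx, bmean = drop(colMeans(B) %*% G)),
            class = "tuned_grid_context")
}

# Merge factor of the stimulus column for a condition: in the changing
# adaptor condition the identical adaptor regressor doubles the amplitude.
merge_factor <- function(seq) {
  if (identical(attr(seq, "condition"), "changing")) 2 else 1
}

#' Exhaustive grid fit of the numerosity-tuned model
#'
#' For every candidate (preference, width) pair, the amplitude (clipped at
#' zero) and baseline are solved by least squares and the candidate with the
#' lowest residual sum of squares is returned. Ties break deterministically
#' to the lowest preference, then the lowest width.
#'
#' @param y BOLD vector (typically a run average).
#' @param seq the condition's run sequence (used for the merge factor and,
#'   if no `context` is given, to build one).
#' @param grid a [tuned_grid()]; ignored when `context` is supplied.
#' @param hrf an [hrf_spec()]; ignored when `context` is supplied.
#' @param context optional [tuned_grid_context()] for speed.
#' @return An object of class `tuned_fit`: `params` ([tuned_params()]),
#'   `amplitude` (>= 0), `baseline`, `r2`, `sse`.
#' @export
grid_fit_tuned <- function(y, seq, grid = tuned_grid(), hrf = hrf_spec(),
                           context = NULL) {
  ctx <- context %||% tuned_grid_context(seq, hrf, grid)
  m <- merge_factor(seq)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  sxy <- m * drop(crossprod(ctx$G, crossprod(ctx$Bc, yc)))
  sxx <- m^2 * ctx$Sxx
  ok <- sxx > 1e-12 * max(sxx)
  gain <- ifelse(ok & sxy > 0, sxy^2 / sxx, 0)
  sse <- syy - gain
  best <- which.min(sse)
  amp <- if (ok[best] && sxy[best] > 0) sxy[best] / sxx[best] else 0
  structure(list(
    params = tuned_params(ctx$grid$pref_log[best], ctx$grid$width_log[best]),
    amplitude = amp,
    baseline = mean(y) - amp * m * ctx$bmean[best],
    r2 = if (syy > 0) 1 - sse[best] / syy else NA_real_,
    sse = sse[best]),
    class = "tuned_fit")
}

# Predicted BOLD shape (un-scaled) of a tuned fit on a given context.
tuned_prediction <- function(fit, ctx, m) {
  g <- tuned_amplitude(ctx$levels, fit$params$pref_log, fit$params$width_log)
  m * drop(ctx$B %*% g)
}

#' Cross-validated comparison of the monotonic and tuned models
#'
#' Runs are split into odd- and even-numbered halves (acquisition order) and
#' averaged within each half. Both models are fit on each half and their
#' predictions evaluated on the complementary half, allowing a free
#' non-negative amplitude rescale and a free baseline (scan sessions differ
#' arbitrarily in signal amplitude, but the prediction may not change sign).
#' Residual sums of squares are summed over both directions; the model with
#' the lower total wins, with ties going to the simpler monotonic model.
#'
#' @param runs matrix of BOLD runs (runs x timepoints), at least 2 runs.
#' @param seq the condition's run sequence.
#' @param mode monotonic predictor mode, `"log_power"` or
#'   `"log_numerosity"`.
#' @param power_table numerosity-to-power lookup for `"log_power"` (see
#'   [fourier_power_table()]).
#' @param hrf an [hrf_spec()].
#' @param grid,context tuned grid (see [grid_fit_tuned()]).
#' @return List with `model_class` (`"monotonic"` or `"tuned"`), `sse` and
#'   `cv_r2` (named per model; `cv_r2 = 1 -` summed cross-fold SSE / summed
#'   cross-fold total SS), and the per-half fits.
#' @export
crossval_compare <- function(runs, seq, mode = "log_power",
                             power_table = NULL, hrf = hrf_spec(),
                             grid = tuned_grid(), context = NULL) {
  if (!is.matrix(runs) || nrow(runs) < 2)
    stop("cross-validation needs at least 2 runs", call. = FALSE)
  ctx <- context %||% tuned_grid_context(seq, hrf, grid)
  m <- merge_factor(seq)
  X <- build_design(seq, "monotonic",
                    list(mode = mode, power_table = power_table), hrf)
  halves <- list(odd = colMeans(runs[seq(1, nrow(runs), 2), , drop = FALSE]),
                 even = colMeans(runs[seq(2, nrow(runs), 2), , drop = FALSE]))
  mono_fits <- lapply(halves, function(h) fit_glm(h, X))
  tuned_fits <- lapply(halves, grid_fit_tuned, seq = seq, context = ctx)
  sse <- c(monotonic = 0, tuned = 0)
  syy <- 0
  for (a in 1:2) {
    b <- 3 - a
    pm <- X[, "stimulus"] * mono_fits[[a]]$slope
    em <- ols_rescale_sse(halves[[b]], pm)
    et <- ols_rescale_sse(halves[[b]], tuned_prediction(tuned_fits[[a]], ctx, m))
    sse["monotonic"] <- sse["monotonic"] + em$sse
    sse["tuned"] <- sse["tuned"] + et$sse
    syy <- syy + em$syy
  }
  list(model_class = if (sse["monotonic"] <= sse["tuned"]) "monotonic" else "tuned",
       sse = sse,
       cv_r2 = if (syy > 0) 1 - sse / syy else c(monotonic = NA_real_, tuned = NA_real_),
       mono_fits = mono_fits, tuned_fits = tuned_fits)
}

#' Classify a voxel's response type
#'
#' A voxel is monotonic if cross-validation favours the monotonic model, or
#' if the winning tuned model's preferred numerosity exceeds 7 (preferences
#' above the changing range cannot be distinguished from monotonic
#' responses, and true preferences above 7 are rare). Otherwise the voxel is
#' tuned; tuned voxels whose changing-condition tuned model explains less
#' than `tuned_r2_threshold` of the response variance are excluded from
#' tuned-response analyses.
#'
#' @param cv a [crossval_compare()] result on the changing adaptor
#'   condition.
#' @param tuned_fit the full-data [grid_fit_tuned()] of the changing
#'   condition.
#' @param pref_cutoff numerosity preference above which tuned winners are
#'   reclassified monotonic (default 7).
#' @param tuned_r2_threshold variance-explained floor for tuned analyses
#'   (default 0.2).
#' @return `"monotonic"`, `"tuned"` or `"excluded"`.
#' @export
classify_voxel <- function(cv, tuned_fit, pref_cutoff = 7,
                           tuned_r2_threshold = 0.2) {
  if (cv$model_class == "monotonic") return("monotonic")
  if (exp(tuned_fit$params$pref_log) > pref_cutoff) return("monotonic")
  if (is.na(tuned_fit$r2) || tuned_fit$r2 < tuned_r2_threshold) return("excluded")
  "tuned"
}

#' Fit every voxel of a dataset in all three adaptor conditions
#'
#' For each voxel: runs are averaged per condition and the monotonic model
#' is fit in each condition; the changing condition is cross-validated
#' between the monotonic and tuned models and the voxel classified; tuned
#' and excluded voxels additionally get per-condition tuned grid fits.
#'
#' @param dataset a voxel dataset as produced by [generate_voxel_dataset()]
#'   or [read_voxel_dataset()]: list with `meta`, `bold` (condition ->
#'   voxels x runs x timepoints array) and `seqs` (condition ->
#'   run sequence).
#' @param mode `"log_power"` or `"log_numerosity"`.
#' @param power_table lookup for `"log_power"`; defaults to the dataset's
#'   own table if present, else [fourier_power_table()].
#' @param hrf an [hrf_spec()].
#' @param grid a [tuned_grid()].
#' @return Data frame, one row per voxel x condition: `voxel_id`,
#'   `condition`, `model_class`, `slope`, `baseline`, `r2` (monotonic fit),
#'   `pref_log`, `width_log`, `amplitude`, `tuned_r2` (tuned fit, `NA` for
#'   monotonic-class voxels outside the changing condition),
#'   `cv_r2_monotonic`, `cv_r2_tuned` (changing condition only).
#' @export
fit_voxel_dataset <- function(dataset, mode = c("log_power", "log_numerosity"),
                              power_table = NULL, hrf = hrf_spec(),
                              grid = tuned_grid()) {
  mode <- match.arg(mode)
  if (mode == "log_power" && is.null(power_table))
    power_table <- dataset$power_table %||% fourier_power_table()
  seqs <- dataset$seqs
  conds <- names(dataset$bold)
  ctx <- tuned_grid_context(seqs[[1]], hrf, grid)
  designs <- lapply(seqs, build_design, model = "monotonic",
                    params = list(mode = mode, power_table = power_table),
                    hrf = hrf)
  nvox <- nrow(dataset$meta)
  rows <- vector("list", nvox)
  for (v in seq_len(nvox)) {
    avg <- lapply(conds, function(cn) {
      m <- dataset$bold[[cn]][v, , , drop = FALSE]
      dim(m) <- dim(m)[2:3]
      colMeans(m)
    })
    names(avg) <- conds
    mono <- Map(function(y, X) fit_glm(y, X), avg, designs[conds])
    cv <- crossval_compare(dataset$bold[["changing"]][v, , ], seqs[["changing"]],
                           mode = mode, power_table = power_table, hrf = hrf,
                           context = ctx)
    tuned_ch <- grid_fit_tuned(avg[["changing"]], seqs[["changing"]], context = ctx)
    cls <- classify_voxel(cv, tuned_ch)
    tuned <- if (cls %in% c("tuned", "excluded")) {
      lapply(conds, function(cn)
        if (cn == "changing") tuned_ch
        else grid_fit_tuned(avg[[cn]], seqs[[cn]], context = ctx))
    } else {
      lapply(conds, function(cn) if (cn == "changing") tuned_ch else NULL)
    }
    names(tuned) <- conds
    rows[[v]] <- data.frame(
      voxel_id = dataset$meta$voxel_id[v],
      condition = conds,
      model_class = cls,
      slope = vapply(mono, `[[`, numeric(1), "slope"),
      baseline = vapply(mono, `[[`, numeric(1), "baseline"),
      r2 = vapply(mono, `[[`, numeric(1), "r2"),
      pref_log = vapply(tuned, function(f) if (is.null(f)) NA_real_ else f$params$pref_log, numeric(1)),
      width_log = vapply(tuned, function(f) if (is.null(f)) NA_real_ else f$params$width_log, numeric(1)),
      amplitude = vapply(tuned, function(f) if (is.null(f)) NA_real_ else f$amplitude, numeric(1)),
      tuned_r2 = vapply(tuned, function(f) if (is.null(f)) NA_real_ else f$r2, numeric(1)),
      cv_r2_monotonic = ifelse(conds == "changing", cv$cv_r2[["monotonic"]], NA_real_),
      cv_r2_tuned = ifelse(conds == "changing", cv$cv_r2[["tuned"]], NA_real_),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a fit table as delimited text
#' @param fits data frame from [fit_voxel_dataset()].
#' @param path output path.
#' @param sep separator (default tab).
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fits, path, sep = "\t") {
  utils::write.table(fits, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
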