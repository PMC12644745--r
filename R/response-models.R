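#' Monotonic neural response time course
#'
#' One neural amplitude per TR for the requested display role, proportional
#' to the logarithm of the display's aggregate Fourier power (default) or of
#' its numerosity. Both follow numerosity monotonically; the power mode is
#' the contrast-driven account of early visual responses, the numerosity
#' mode its simpler alternative.
#'
#' @param seq a [build_run_sequence()] object.
#' @param role `"changing"` or `"adaptor"`.
#' @param mode `"log_power"` or `"log_numerosity"`.
#' @param power_table named vector mapping numerosity to aggregate Fourier
#'   power (see [power_table()]); required for `mode = "log_power"`.
#' @return Numeric vector, one value per TR.
#' @export
monotonic_neural_timecourse <- function(seq, role = c("changing", "adaptor"),
                                        mode = c("log_power", "log_numerosity"),
                                        power_table = NULL) {
  role <- match.arg(role)
  mode <- match.arg(mode)
  n <- if (role == "changing") seq$changing_numerosity else seq$adaptor_numerosity
  if (mode == "log_numerosity") return(log(n))
  if (is.null(power_table))
    stop("`power_table` is required for mode = \"log_power\"", call. = FALSE)
  key <- as.character(n)
  missing <- setdiff(unique(key), names(power_table))
  if (length(missing))
    stop("power_table is missing numerosities: ",
         paste(missing, collapse = ", "), call. = FALSE)
  log(unname(power_table[key]))
}

#' Numerosity-tuned pRF parameters
#'
#' Log-Gaussian tuning: preferred numerosity `exp(pref_log)` and tuning
#' width `width_log` (SD in log-numerosity space). Candidates with a
#' preference more than two widths above log(14) = 2.64 are excluded because
#' they only predict responses to the 20-dot baseline.
#'
#' @param pref_log preferred log numerosity, in [0.007, 5.491].
#' @param width_log log-space tuning width, in [0.03, 3].
#' @return An object of class `tuned_params`.
#' @export
tuned_params <- function(pref_log, width_log) {
  assert_scalar_num(pref_log, "pref_log", 0.007, 5.491)
  assert_scalar_num(width_log, "width_log", 0.03, 3)
  if (pref_log > 2.64 + 2 * width_log)
    stop("excluded tuning: pref_log ", pref_log, " > 2.64 + 2 * ", width_log,
         call. = FALSE)
  structure(list(pref_log = pref_log, width_log = width_log),
            class = "tuned_params")
}

# Log-Gaussian tuned amplitude for numerosity vector n: peak 1 at
# ln n == pref_log.
tuned_amplitude <- function(n, pref_log, width_log) {
  exp(-(log(n) - pref_log)^2 / (2 * width_log^2))
}

#' Tuned neural response time course
#'
#' @inheritParams monotonic_neural_timecourse
#' @param params a [tuned_params()].
#' @return Numeric vector in (0, 1], one value per TR; equals 1 iff the
#'   shown numerosity matches the preference exactly.
#' @export
tuned_neural_timecourse <- function(seq, role = c("changing", "adaptor"),
                                    params) {
  role <- match.arg(role)
  stopifnot(inherits(params, "tuned_params"))
  n <- if (role == "changing") seq$changing_numerosity else seq$adaptor_numerosity
  tuned_amplitude(n, params$pref_log, params$width_log)
}

#' Candidate grid for the tuned model
#'
#' Preferred log numerosities from 0.007 (log 1.007) to 5.491 (log 242) in
#' steps of 0.01; log-space widths from 0.03 to 3 in steps of 0.0074;
#' candidates with `pref_log > 2.64 + 2 * width_log` removed. Rows are
#' ordered by ascending preference, then ascending width, which fixes the
#' deterministic tie-break of the grid search.
#'
#' @param pref_range,pref_step,width_range,width_step grid geometry.
#' @param pref_cap centre of the exclusion rule (log 14 = 2.64).
#' @return Data frame with columns `pref_log`, `width_log`.
#' @export
tuned_grid <- function(pref_range = c(0.007, 5.491), pref_step = 0.01,
                       width_range = c(0.03, 3), width_step = 0.0074,
                       pref_cap = 2.64) {
  prefs <- seq(pref_range[1], pref_range[2], by = pref_step)
  widths <- seq(width_range[1], width_range[2], by = width_step)
  g <- expand.grid(width_log = widths, pref_log = prefs,
                   KEEP.OUT.ATTRS = FALSE)[, c("pref_log", "width_log")]
  g <- g[g$pref_log <= pref_cap + 2 * g$width_log, ]
  rownames(g) <- NULL
  g
}

#' Convolved indicator basis for the numerosity levels
#'
#' For each distinct numerosity level, the indicator series of TRs showing
#' that level (in the given role), convolved with the HRF. Any neural model
#' that assigns one amplitude per level has a predicted BOLD course equal to
#' this basis times the per-level amplitude vector, which makes exhaustive
#' grid fits cheap.
#'
#' @param seq a run sequence.
#' @param role `"changing"` or `"adaptor"`.
#' @param hrf an [hrf_spec()].
#' @param levels numerosity levels (columns), default the stimulus levels.
#' @return Matrix, TRs x levels, with `levels` as column names.
#' @export
numerosity_basis <- function(seq, role = c("changing", "adaptor"),
                             hrf = hrf_spec(), levels = NUM_LEVELS) {
  role <- match.arg(role)
  n <- if (role == "changing") seq$changing_numerosity else seq$adaptor_numerosity
  B <- vapply(levels,
              function(l) convolve_tr_series(as.numeric(n == l), hrf,
                                             attr(seq, "tr_seconds")),
              numeric(nrow(seq)))
  colnames(B) <- as.character(levels)
  B
}

#' Build a GLM design matrix for one condition
#'
#' Converts the changing-role and adaptor-role neural time courses of the
#' chosen response model into HRF-convolved predictors plus a constant
#' baseline. In the low and high adaptor conditions the adaptor predictor is
#' constant over time and is absorbed by the baseline (dropped). In the
#' changing condition the adaptor predictor is identical to the changing
#' predictor; to keep the design full rank the two are merged into a single
#' column of doubled amplitude, which halves the fitted slope relative to a
#' changing-only design.
#'
#' @param seq a run sequence.
#' @param model `"monotonic"` or `"tuned"`.
#' @param params for `"monotonic"`, a list with `mode` and (for log-power)
#'   `power_table`; for `"tuned"`, a [tuned_params()]. The adaptor role uses
#'   the same response function as the changing role.
#' @param hrf an [hrf_spec()].
#' @param include_adaptor include the adaptor regressor (default TRUE; the
#'   changing-only design is used to expose the slope-halving property).
#' @return Numeric matrix with named columns (`stimulus`, optionally
#'   `adaptor`, and `baseline`); attributes `merged_adaptor` and
#'   `dropped_adaptor` record how the adaptor column was handled.
#' @export
build_design <- function(seq, model = c("monotonic", "tuned"), params,
                         hrf = hrf_spec(), include_adaptor = TRUE) {
  model <- match.arg(model)
  neural <- function(role) {
    if (model == "monotonic")
      monotonic_neural_timecourse(seq, role, mode = params$mode %||% "log_power",
                                  power_table = params$power_table)
    else
      tuned_neural_timecourse(seq, role, params)
  }
  tr <- attr(seq, "tr_seconds")
  ch <- convolve_tr_series(neural("changing"), hrf, tr)
  merged <- dropped <- FALSE
  if (include_adaptor) {
    ad <- convolve_tr_series(neural("adaptor"), hrf, tr)
    scale <- max(abs(ch), abs(ad), 1e-12)
    if (diff(range(ad)) <= 1e-9 * scale) {
      dropped <- TRUE  # constant adaptor response, absorbed by the baseline
    } else if (max(abs(ad - ch)) <= 1e-9 * scale) {
      ch <- ch + ad    # identical regressors merged: doubled amplitude
      merged <- TRUE
    } else {
      if (stats::sd(ad) > 0 && stats::sd(ch) > 0 &&
          abs(stats::cor(ch, ad)) > 1 - 1e-9)
        stop("collinear non-identical stimulus and adaptor columns ",
             "(|cor| ~ 1); check the response model inputs", call. = FALSE)
      X <- cbind(stimulus = ch, adaptor = ad, baseline = 1)
      return(structure(X, merged_adaptor = FALSE, dropped_adaptor = FALSE))
    }
  }
  structure(cbind(stimulus = ch, baseline = 1),
            merged_adaptor = merged, dropped_adaptor = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
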