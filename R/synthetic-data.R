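#' Ground-truth configuration for the synthetic fMRI generator
#'
#' Encodes the statistical structure the analysis assumes: monotonic voxels
#' whose response amplitude scales with the log aggregate Fourier power of
#' the displays, with condition-specific gain (low adaptor > changing >
#' high adaptor), a V1 -> V3A/B gradient of proportional slope suppression,
#' a minority of numerosity-tuned voxels in the later maps, eccentricities
#' straddling the 1 degree selection threshold, and additive per-run noise.
#'
#' The true proportional reduction of map `k` (1 = V1, ..., 7 = V3A/B) is
#' `reduction_v1 + hierarchy_gradient * (k - 1)`; condition gains are
#' `g_changing = 1`, `g_low`, and `g_high = g_low - reduction`.
#'
#' @param n_participants number of participants (default 8).
#' @param hemispheres_per_participant default 2.
#' @param maps visual field map labels, hierarchy-ordered.
#' @param voxels_per_map voxels per map per hemisphere (default 8).
#' @param fraction_tuned_by_map per-map probability a voxel is tuned
#'   (default 0 for V1-hV4, 0.2 for LO1/LO2/V3A/B).
#' @param base_slope_by_map monotonic slope in BOLD units per unit log
#'   predictor, per map.
#' @param g_low low-adaptor gain (default 1.1; changing gain is 1).
#' @param reduction_v1 true proportional reduction in V1 (default 0.25).
#' @param hierarchy_gradient per-map increase of the true reduction
#'   (default 0.10).
#' @param slope_jitter_sd lognormal SD of voxel-to-voxel slope variation.
#' @param frac_negative fraction of voxels with a negative (sign-flipped)
#'   slope, planted to exercise the selection criteria (default 0.05).
#' @param ecc_range uniform eccentricity range in degrees; extends above
#'   1 degree so selection is exercised (default c(0, 1.5)).
#' @param noise_sd absolute per-run noise SD in BOLD units, or `NULL` to
#'   use `noise_frac`.
#' @param noise_frac per-run noise SD as a fraction of each voxel's
#'   noiseless changing-condition signal SD (default 0.10).
#' @param noise_model `"white"` or `"ar1"`.
#' @param ar1_rho AR(1) coefficient when `noise_model = "ar1"`.
#' @param runs_per_condition named integer vector (default 3 each; the
#'   acquisition-matched variant uses 10 for low/high).
#' @param pref_log_range,width_log_range tuned-voxel parameter ranges
#'   (preferences kept within the 1-7 changing range).
#' @param pref_shift_intercept,pref_shift_slope the tuned preference change
#'   (low minus high, log units) of a voxel with changing-condition
#'   preference `p` is `intercept + slope * p`.
#' @param seed base seed; the generator is a pure function of
#'   (config, seed).
#' @return List of class `ground_truth_config`.
#' @export
ground_truth_config <- function(n_participants = 8,
                                hemispheres_per_participant = 2,
                                maps = VF_MAPS,
                                voxels_per_map = 8,
                                fraction_tuned_by_map =
                                  c(0, 0, 0, 0, 0.2, 0.2, 0.2),
                                base_slope_by_map =
                                  seq(1, 0.7, length.out = length(maps)),
                                g_low = 1.1,
                                reduction_v1 = 0.25,
                                hierarchy_gradient = 0.10,
                                slope_jitter_sd = 0.15,
                                frac_negative = 0.05,
                                ecc_range = c(0, 1.5),
                                noise_sd = NULL,
                                noise_frac = 0.10,
                                noise_model = c("white", "ar1"),
                                ar1_rho = 0.3,
                                runs_per_condition =
                                  c(low = 3, high = 3, changing = 3),
                                pref_log_range = log(c(1.2, 6)),
                                width_log_range = c(0.4, 1),
                                pref_shift_intercept = 0.25,
                                pref_shift_slope = -0.12,
                                seed = 1L) {
  noise_model <- match.arg(noise_model)
  reduction <- reduction_v1 + hierarchy_gradient * (seq_along(maps) - 1)
  g_high <- g_low - reduction
  if (any(g_high <= 0))
    stop("condition gains must stay positive; lower the gradient", call. = FALSE)
  stopifnot(length(fraction_tuned_by_map) == length(maps),
            all(fraction_tuned_by_map >= 0 & fraction_tuned_by_map <= 1),
            length(base_slope_by_map) == length(maps),
            all(runs_per_condition >= 1))
  structure(c(as.list(environment()),
              list(g_changing = 1, reduction_true = reduction,
                   g_high_by_map = g_high)),
            class = "ground_truth_config")
}

# Draw one run's noise vector.
draw_noise <- function(n, sd, model, rho) {
  if (sd <= 0) return(numeric(n))
  if (model == "white") return(stats::rnorm(n, 0, sd))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

#' Generate a synthetic voxel dataset with known ground truth
#'
#' Builds the run sequences for the three adaptor conditions, computes the
#' numerosity-to-Fourier-power table from the stimulus engine, and for each
#' voxel draws a response class and parameters, synthesises noiseless BOLD
#' through the same forward models used for fitting (including the adaptor
#' display's contribution, so the changing condition carries the doubled
#' stimulus response), and adds independent per-run noise.
#'
#' @param config a [ground_truth_config()].
#' @return List: `meta` (voxel metadata), `bold` (condition -> voxels x
#'   runs x 264 array), `seqs` (condition -> run sequence), `power_table`,
#'   `truth` (per-voxel true parameters incl. `reduction_true` per map) and
#'   `config`.
#' @export
generate_voxel_dataset <- function(config = ground_truth_config()) {
  cf <- config
  seqs <- lapply(stats::setNames(ADAPTOR_CONDITIONS, ADAPTOR_CONDITIONS),
                 function(cn) build_run_sequence(cn, seed = child_seed(cf$seed, match(cn, ADAPTOR_CONDITIONS))))
  pt <- fourier_power_table()
  hrf <- hrf_spec()
  nT <- nrow(seqs[[1]])
  designs <- lapply(seqs, build_design, model = "monotonic",
                    params = list(mode = "log_power", power_table = pt),
                    hrf = hrf)
  B <- numerosity_basis(seqs[["changing"]], "changing", hrf)
  levels <- as.numeric(colnames(B))
  gains <- data.frame(map_label = cf$maps, g_low = cf$g_low,
                      g_high = cf$g_high_by_map, g_changing = cf$g_changing)

  grid_df <- expand.grid(voxel = seq_len(cf$voxels_per_map),
                         map = cf$maps,
                         hemisphere = c("L", "R")[seq_len(cf$hemispheres_per_participant)],
                         participant = sprintf("P%02d", seq_len(cf$n_participants)),
                         stringsAsFactors = FALSE)
  nvox <- nrow(grid_df)
  conds <- ADAPTOR_CONDITIONS
  bold <- lapply(stats::setNames(conds, conds), function(cn)
    array(NA_real_, c(nvox, cf$runs_per_condition[[cn]], nT)))
  meta <- data.frame(voxel_id = sprintf("vox%05d", seq_len(nvox)),
                     participant = grid_df$participant,
                     hemisphere = grid_df$hemisphere,
                     map_label = grid_df$map, ecc_deg = NA_real_,
                     polar_deg = NA_real_)
  truth <- cbind(meta[, c("voxel_id", "participant", "hemisphere", "map_label")],
                 class_true = NA_character_, slope_base = NA_real_,
                 slope_low = NA_real_, slope_high = NA_real_,
                 slope_changing = NA_real_, pref_log_true = NA_real_,
                 width_log_true = NA_real_, reduction_true = NA_real_,
                 noise_sd = NA_real_)

  for (v in seq_len(nvox)) {
    mi <- match(grid_df$map[v], cf$maps)
    vs <- child_seed(cf$seed, 1000 + v)
    with_seed(vs, {
      meta$ecc_deg[v] <- stats::runif(1, cf$ecc_range[1], cf$ecc_range[2])
      meta$polar_deg[v] <- stats::runif(1, 0, 360)
      tuned <- stats::runif(1) < cf$fraction_tuned_by_map[mi]
      g <- c(low = cf$g_low, high = cf$g_high_by_map[mi], changing = cf$g_changing)
      baseline <- stats::rnorm(1, 100, 2)
      if (!tuned) {
        s <- cf$base_slope_by_map[mi] * exp(stats::rnorm(1, 0, cf$slope_jitter_sd))
        if (stats::runif(1) < cf$frac_negative) s <- -s
        noiseless <- lapply(conds, function(cn)
          baseline + g[[cn]] * s * designs[[cn]][, "stimulus"])
        truth$class_true[v] <- "monotonic"
        truth$slope_base[v] <- s
        truth$slope_low[v] <- g[["low"]] * s
        truth$slope_high[v] <- g[["high"]] * s
        truth$slope_changing[v] <- g[["changing"]] * s
        truth$reduction_true[v] <- cf$reduction_true[mi]
      } else {
        pref <- stats::runif(1, cf$pref_log_range[1], cf$pref_log_range[2])
        width <- stats::runif(1, cf$width_log_range[1], cf$width_log_range[2])
        dpref <- cf$pref_shift_intercept + cf$pref_shift_slope * pref
        pref_c <- c(low = pref + dpref / 2, high = pref - dpref / 2,
                    changing = pref)
        amp <- exp(stats::rnorm(1, 0, cf$slope_jitter_sd))
        noiseless <- lapply(conds, function(cn) {
          gv <- tuned_amplitude(levels, pref_c[[cn]], width)
          m <- if (cn == "changing") 2 else 1
          baseline + g[[cn]] * amp * m * drop(B %*% gv)
        })
        truth$class_true[v] <- "tuned"
        truth$pref_log_true[v] <- pref
        truth$width_log_true[v] <- width
        truth$reduction_true[v] <- cf$reduction_true[mi]
      }
      names(noiseless) <- conds
      sig_sd <- stats::sd(noiseless[["changing"]])
      nsd <- if (!is.null(cf$noise_sd)) cf$noise_sd else cf$noise_frac * sig_sd
      truth$noise_sd[v] <- nsd
      for (cn in conds)
        for (r in seq_len(cf$runs_per_condition[[cn]]))
          bold[[cn]][v, r, ] <- noiseless[[cn]] +
            draw_noise(nT, nsd, cf$noise_model, cf$ar1_rho)
    })
  }
  list(meta = meta, bold = bold, seqs = seqs, power_table = pt,
       truth = truth, config = cf)
}

#' Generate a synthetic behavioural 2AFC dataset
#'
#' Per-participant true PSEs are drawn around the condition means (the
#' repulsive pattern puts the low-adaptor PSE above and the high-adaptor
#' PSE below the no-adaptor PSE) and trials are simulated through
#' [simulate_observer()].
#'
#' @param pse_means named condition means in numerosity units (default
#'   `c(low_adaptor = 12, no_adaptor = 10, high_adaptor = 8)`, a 2-unit
#'   repulsive effect).
#' @param sd_between between-participant PSE SD (default 0.5), > 0.
#' @param observer_sigma psychometric slope of each observer (default 1.5).
#' @param n_participants default 10.
#' @param n_trials answered trials per participant per condition
#'   (default 100).
#' @param placement test-level placement passed to [simulate_observer()]
#'   (default `"fixed_grid"`; `"staircase"` for the adaptive rule).
#' @param seed base seed.
#' @return List: `trials` (all trials with a `participant` column), `truth`
#'   (participant x condition true PSEs).
#' @export
generate_behavioral_dataset <- function(pse_means = c(low_adaptor = 12,
                                                      no_adaptor = 10,
                                                      high_adaptor = 8),
                                        sd_between = 0.5,
                                        observer_sigma = 1.5,
                                        n_participants = 10,
                                        n_trials = 100,
                                        placement = "fixed_grid",
                                        seed = 1L) {
  stopifnot(sd_between > 0, observer_sigma > 0)
  conds <- names(pse_means)
  truth <- expand.grid(participant = sprintf("S%02d", seq_len(n_participants)),
                       condition = conds, stringsAsFactors = FALSE)
  truth$true_pse <- with_seed(child_seed(seed, 7), {
    stats::rnorm(nrow(truth), pse_means[truth$condition], sd_between)
  })
  trials <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    tr <- simulate_observer(truth$true_pse[i], observer_sigma,
                            n_trials = n_trials,
                            seed = child_seed(seed, 100 + i),
                            placement = placement,
                            condition = truth$condition[i])
    tr$participant <- truth$participant[i]
    tr
  }))
  rownames(trials) <- NULL
  list(trials = trials, truth = truth)
}

#' Fit PSEs for every participant x condition of a behavioural dataset
#'
#' @param behav a [generate_behavioral_dataset()] result (or any trial data
#'   frame with `participant` and `condition`).
#' @param method passed to [fit_psychometric()].
#' @return Data frame `participant`, `condition`, `pse`, `sigma`,
#'   `flagged`, ready for [compare_pse()].
#' @export
fit_behavioral_dataset <- function(behav, method = "ml") {
  trials <- if (is.data.frame(behav)) behav else behav$trials
  key <- interaction(trials$participant, trials$condition, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    g <- trials[key == k, ]
    f <- fit_psychometric(g, method = method)
    data.frame(participant = g$participant[1], condition = g$condition[1],
               pse = f$pse, sigma = f$sigma, flagged = f$flagged)
  }))
  rownames(out) <- NULL
  out
}
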