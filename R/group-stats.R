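#' Two-sided Wilcoxon signed-rank test
#'
#' One-sample (or paired, via `y`) signed-rank test of the median against
#' `mu`. Zero differences are removed. For `n <= exact_max` the null
#' distribution of the rank sum is computed exactly by dynamic programming
#' over all sign assignments, which remains exact under ties (average
#' ranks); larger samples use the normal approximation with tie and
#' continuity corrections. The two-sided p is `2 * min(P(W <= w),
#' P(W >= w))`, capped at 1.
#'
#' @param x numeric values or differences.
#' @param y optional paired second sample (`x - y` is tested).
#' @param mu null median (default 0).
#' @param exact_max largest n for the exact distribution (default 25).
#' @return List of class `test_result`: `test_name`, `statistic` (positive
#'   rank sum V), `p_value`, `n` (after zero removal), `method`.
#' @export
signed_rank_test <- function(x, y = NULL, mu = 0, exact_max = 25) {
  d <- if (is.null(y)) x - mu else x - y - mu
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(structure(list(test_name = "wilcoxon_signed_rank", statistic = 0,
                          p_value = 1, n = 0L, method = "degenerate"),
                     class = "test_result"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: W = sum of a uniformly random subset of the ranks;
    # doubling average ranks keeps the DP integral under ties
    r2 <- round(2 * r)
    counts <- numeric(sum(r2) + 1)
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- round(2 * w)
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[seq.int(w2 + 1, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu_w <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    corr <- sign(w - mu_w) * 0.5
    z <- (w - mu_w - corr) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(list(test_name = "wilcoxon_signed_rank", statistic = w,
                 p_value = p, n = n, method = method),
            class = "test_result")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p values, clipped at 1 and monotone non-decreasing
#' after reordering.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return Adjusted p values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Two-factor ANOVA on proportional slope reductions
#'
#' Tests whether the adaptation effect strength differs between visual
#' field maps, with participant as an additive blocking factor (one
#' observation per map x hemisphere, so the additive two-way model is the
#' standard formulation), followed by Tukey's honestly-significant-
#' difference comparisons on the map marginal means.
#'
#' @param examples map-example table with `map_label`, `participant` and the
#'   response column; rows with `NA` response are dropped.
#' @param response response column name (default
#'   `"proportional_reduction"`).
#' @return List: `F` statistic, `df` (numerator, denominator), `p_value`
#'   for the map effect, `tukey` data frame of pairwise map contrasts, and
#'   the underlying `aov` fit.
#' @export
map_effect_anova <- function(examples, response = "proportional_reduction") {
  d <- examples[is.finite(examples[[response]]), , drop = FALSE]
  d$map_label <- factor(d$map_label)
  d$participant <- factor(d$participant)
  if (nlevels(d$map_label) < 2)
    stop("ANOVA needs at least 2 visual field maps", call. = FALSE)
  if (nlevels(d$participant) < 2)
    stop("ANOVA needs at least 2 participants", call. = FALSE)
  d$.y <- d[[response]]
  fit <- stats::aov(.y ~ map_label + participant, data = d)
  tab <- summary(fit)[[1]]
  i <- trimws(rownames(tab)) == "map_label"
  tk <- stats::TukeyHSD(fit, which = "map_label")$map_label
  tukey <- data.frame(contrast = rownames(tk), tk, row.names = NULL)
  names(tukey) <- c("contrast", "diff", "lwr", "upr", "p_adj")
  list(F = tab$`F value`[i],
       df = c(tab$Df[i], tab$Df[trimws(rownames(tab)) == "Residuals"]),
       p_value = tab$`Pr(>F)`[i],
       tukey = tukey, fit = fit)
}

#' Pearson correlation between two regional adaptation metrics
#'
#' Pairwise-complete Pearson correlation across hemispheres, with an
#' Anderson-Darling normality check on the residuals of the linear fit of
#' `b` on `a` (flagged when its p < 0.05; requires at least 8 residuals,
#' else `NA`).
#'
#' @param a,b paired numeric vectors (one value per hemisphere example).
#' @param min_n minimum complete pairs (default 4).
#' @return List of class `test_result`: `r`, `p_value`, `n`,
#'   `ad_p`, `normality_flag` (TRUE when residual normality is rejected).
#' @export
region_correlations <- function(a, b, min_n = 4) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < min_n)
    stop("need at least ", min_n, " complete pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(list(test_name = "pearson", r = NA_real_,
                          p_value = NA_real_, n = n, ad_p = NA_real_,
                          normality_flag = NA),
                     class = "test_result"))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  res <- stats::residuals(stats::lm(b ~ a))
  ad_p <- if (length(res) >= 8 && stats::sd(res) > 0)
    nortest::ad.test(res)$p.value else NA_real_
  structure(list(test_name = "pearson", r = unname(ct$estimate),
                 p_value = ct$p.value, n = n, ad_p = ad_p,
                 normality_flag = if (is.na(ad_p)) NA else ad_p < 0.05),
            class = "test_result")
}

#' Per-map adaptation metric by hemisphere, in wide form
#'
#' @param examples map-example table.
#' @param value column to spread (default `"proportional_reduction"`).
#' @return Data frame: `participant`, `hemisphere`, one column per map.
#' @export
reduction_by_hemisphere <- function(examples, value = "proportional_reduction") {
  w <- stats::reshape(examples[, c("participant", "hemisphere", "map_label", value)],
                      idvar = c("participant", "hemisphere"),
                      timevar = "map_label", direction = "wide")
  names(w) <- sub(paste0("^", value, "\\."), "", names(w))
  rownames(w) <- NULL
  w
}

#' Summaries of tuned-response adaptation effects
#'
#' For the tuned voxels of each visual field map x hemisphere: the drop in
#' tuned variance explained from the low to the high adaptor condition
#' (greater suppression lowers the tuned model's R2), and the slope of the
#' linear relationship between each voxel's preference change (low minus
#' high, in log numerosity) and its changing-condition log preference.
#'
#' @param meta voxel metadata.
#' @param fits fit table from [fit_voxel_dataset()] (tuned columns filled
#'   for tuned-class voxels).
#' @return Data frame per participant x hemisphere x map with `n_tuned`,
#'   `delta_r2`, `pref_change_slope`.
#' @export
tuned_effect_summary <- function(meta, fits) {
  tf <- fits[fits$model_class == "tuned" & !is.na(fits$tuned_r2), ]
  if (!nrow(tf)) {
    return(data.frame(participant = character(), hemisphere = character(),
                      map_label = character(), n_tuned = integer(),
                      delta_r2 = numeric(), pref_change_slope = numeric()))
  }
  wide <- stats::reshape(tf[, c("voxel_id", "condition", "pref_log", "tuned_r2")],
                         idvar = "voxel_id", timevar = "condition",
                         direction = "wide")
  d <- merge(meta, wide, by = "voxel_id")
  key <- interaction(d$participant, d$hemisphere, d$map_label, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    g <- d[key == k, ]
    slope <- if (nrow(g) >= 3 && stats::sd(g$pref_log.changing) > 0)
      unname(stats::coef(stats::lm(I(pref_log.low - pref_log.high) ~
                                     pref_log.changing, data = g))[2])
    else NA_real_
    data.frame(participant = g$participant[1], hemisphere = g$hemisphere[1],
               map_label = g$map_label[1], n_tuned = nrow(g),
               delta_r2 = mean(g$tuned_r2.low - g$tuned_r2.high),
               pref_change_slope = slope)
  }))
  rownames(out) <- NULL
  out
}

#' Full inferential battery over map examples
#'
#' Per visual field map: one-sample signed-rank tests of the low- and
#' high-condition slopes against zero, and the paired signed-rank test of
#' low versus high, each family FDR-corrected across all maps; the
#' two-factor ANOVA with Tukey contrasts on the proportional reductions;
#' and the pairwise Pearson correlations of the proportional reduction
#' between maps across hemispheres.
#'
#' @param examples map-example table (included examples are used).
#' @return List: `slope_tests` (long data frame), `anova`, `map_correlations`.
#' @export
group_statistics <- function(examples) {
  ex <- examples[examples$included, , drop = FALSE]
  maps <- intersect(VF_MAPS, unique(ex$map_label))
  one_sample <- function(col) {
    do.call(rbind, lapply(maps, function(m) {
      v <- ex[[col]][ex$map_label == m]
      t <- signed_rank_test(v)
      data.frame(map_label = m, test = col, statistic = t$statistic,
                 p_value = t$p_value, n = t$n)
    }))
  }
  paired <- do.call(rbind, lapply(maps, function(m) {
    g <- ex[ex$map_label == m, ]
    t <- signed_rank_test(g$mean_slope_low, g$mean_slope_high)
    data.frame(map_label = m, test = "low_vs_high", statistic = t$statistic,
               p_value = t$p_value, n = t$n)
  }))
  st <- rbind(one_sample("mean_slope_low"), one_sample("mean_slope_high"),
              paired)
  st$p_adjusted <- NA_real_
  for (fam in unique(st$test))
    st$p_adjusted[st$test == fam] <- fdr_adjust(st$p_value[st$test == fam])

  an <- tryCatch(map_effect_anova(ex), error = function(e) NULL)

  wide <- reduction_by_hemisphere(ex)
  pres <- list()
  for (i in seq_along(maps)) for (j in seq_len(i - 1L)) {
    r <- tryCatch(region_correlations(wide[[maps[j]]], wide[[maps[i]]]),
                  error = function(e) NULL)
    if (!is.null(r))
      pres[[length(pres) + 1L]] <- data.frame(
        map_a = maps[j], map_b = maps[i], r = r$r, p_value = r$p_value,
        n = r$n, ad_p = r$ad_p)
  }
  corr <- if (length(pres)) do.call(rbind, pres) else NULL
  list(slope_tests = st, anova = an, map_correlations = corr)
}
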