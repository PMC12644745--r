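#' Simulate a 2AFC numerosity-comparison observer
#'
#' Trials compare a changing test numerosity against a fixed reference
#' (10 dots) after adaptation. The observer judges the test "more numerous"
#' with probability `pnorm((test - true_pse) / sigma)`, the cumulative-
#' Gaussian psychometric function with its point of subjective equality
#' (PSE) at `true_pse`. Test levels are chosen either by a greedy minimum-
#' expected-posterior-entropy adaptive rule over a discrete (mu, sigma)
#' lattice (an idealisation of a Minimum Expected Entropy staircase) or
#' cycled over a fixed grid.
#'
#' @param true_pse the observer's PSE in numerosity units.
#' @param sigma psychometric slope (SD of the cumulative Gaussian), > 0.
#' @param n_trials number of answered trials.
#' @param seed integer seed.
#' @param placement `"staircase"` or `"fixed_grid"`.
#' @param condition condition label stored on the trials
#'   (`"low_adaptor"`, `"high_adaptor"`, `"no_adaptor"`).
#' @param reference reference numerosity (default 10).
#' @param test_levels candidate test numerosities (default 2:19).
#' @param lapse_miss probability a trial goes unanswered and is re-queued
#'   (default 0; re-queued trials are recorded with `responded = FALSE`).
#' @return Data frame of `psycho_trial` rows: `condition`,
#'   `test_numerosity`, `reference_numerosity`, `side`, `response_more`,
#'   `responded`.
#' @export
simulate_observer <- function(true_pse, sigma, n_trials = 100, seed = 1L,
                              placement = c("staircase", "fixed_grid"),
                              condition = "no_adaptor", reference = 10,
                              test_levels = 2:19, lapse_miss = 0) {
  placement <- match.arg(placement)
  stopifnot(sigma > 0, n_trials >= 1)
  if (placement == "fixed_grid" && lapse_miss == 0) {
    # no adaptive state: draw the whole session at once
    return(with_seed(seed, {
      level <- rep_len(sample(test_levels), n_trials)
      out <- data.frame(
        condition = condition, test_numerosity = level,
        reference_numerosity = reference,
        side = sample(c("left", "right"), n_trials, replace = TRUE),
        response_more = stats::runif(n_trials) <
          stats::pnorm((level - true_pse) / sigma),
        responded = TRUE)
      class(out) <- c("psycho_trials", "data.frame")
      out
    }))
  }
  with_seed(seed, {
    lattice <- expand.grid(mu = seq(min(test_levels), max(test_levels),
                                    length.out = 41),
                           sigma = exp(seq(log(0.25), log(6), length.out = 12)))
    post <- rep(1 / nrow(lattice), nrow(lattice))
    # P(respond "more" | level, lattice point), levels x lattice
    L <- vapply(seq_len(nrow(lattice)), function(k)
      stats::pnorm((test_levels - lattice$mu[k]) / lattice$sigma[k]),
      numeric(length(test_levels)))
    entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    rows <- vector("list", 0L)
    done <- 0L
    fixed_cycle <- rep_len(sample(test_levels), n_trials)
    while (done < n_trials) {
      if (placement == "staircase") {
        eh <- vapply(seq_along(test_levels), function(i) {
          pm <- sum(post * L[i, ])
          if (pm <= 0 || pm >= 1) return(entropy(post))
          p1 <- post * L[i, ]; p0 <- post * (1 - L[i, ])
          pm * entropy(p1 / sum(p1)) + (1 - pm) * entropy(p0 / sum(p0))
        }, numeric(1))
        level <- test_levels[which.min(eh)]
      } else {
        level <- fixed_cycle[done + 1L]
      }
      responded <- stats::runif(1) >= lapse_miss
      side <- sample(c("left", "right"), 1)
      if (!responded) {
        # unanswered: re-queued, trial recorded but does not count
        rows[[length(rows) + 1L]] <- data.frame(
          condition = condition, test_numerosity = level,
          reference_numerosity = reference, side = side,
          response_more = NA, responded = FALSE)
        next
      }
      resp <- stats::runif(1) < stats::pnorm((level - true_pse) / sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition, test_numerosity = level,
        reference_numerosity = reference, side = side,
        response_more = resp, responded = TRUE)
      if (placement == "staircase") {
        i <- match(level, test_levels)
        post <- post * (if (resp) L[i, ] else 1 - L[i, ])
        post <- post / sum(post)
      }
      done <- done + 1L
    }
    out <- do.call(rbind, rows)
    class(out) <- c("psycho_trials", "data.frame")
    out
  })
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Estimates the PSE (mu) and slope (sigma) of
#' `P(more) = pnorm((x - mu) / sigma)`. The default is the Bernoulli
#' maximum-likelihood fit, computed as a probit regression (with a bounded
#' direct likelihood optimisation as fallback when the regression is
#' degenerate, e.g. under complete separation, in which case sigma is
#' bounded and the fit flagged). `method = "binned_ls"` instead least-
#' squares fits the proportions judged "more numerous" per test-numerosity
#' bin, the classical descriptive approach; both agree closely on large
#' samples.
#'
#' @param trials data frame from [simulate_observer()] (unanswered trials
#'   are dropped).
#' @param method `"ml"` or `"binned_ls"`.
#' @param sigma_bounds allowed sigma range for the bounded fits.
#' @return List of class `psychometric_fit`: `pse`, `sigma`, `goodness`
#'   (residual deviance vs. the binned saturated model), `n_trials`,
#'   `flagged` (TRUE for boundary/separation fits or a PSE outside the
#'   tested range), `binned` (per-level response table).
#' @export
fit_psychometric <- function(trials, method = c("ml", "binned_ls"),
                             sigma_bounds = c(0.05, 50)) {
  method <- match.arg(method)
  t <- trials[trials$responded & !is.na(trials$response_more), ]
  if (length(unique(t$test_numerosity)) < 3)
    stop("need responses at >= 3 distinct test levels", call. = FALSE)
  x <- t$test_numerosity
  r <- as.numeric(t$response_more)
  binned <- stats::aggregate(list(p_more = r), list(test_numerosity = x), mean)
  binned$n <- as.vector(table(x)[as.character(binned$test_numerosity)])

  nll <- function(par) {
    p <- stats::pnorm((x - par[1]) / par[2])
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(r * log(p) + (1 - r) * log(1 - p))
  }
  flagged <- FALSE
  if (method == "ml") {
    est <- NULL
    gf <- tryCatch(
      suppressWarnings(stats::glm(r ~ x, family = stats::binomial("probit"))),
      error = function(e) NULL)
    if (!is.null(gf) && gf$converged && is.finite(stats::coef(gf)[2]) &&
        stats::coef(gf)[2] > 1 / sigma_bounds[2] &&
        stats::coef(gf)[2] < 1 / sigma_bounds[1]) {
      b <- stats::coef(gf)
      est <- c(-b[1] / b[2], 1 / b[2])
    }
    if (is.null(est)) {
      o <- stats::optim(c(mean(range(x)), diff(range(x)) / 4), nll,
                        method = "L-BFGS-B",
                        lower = c(min(x) - diff(range(x)), sigma_bounds[1]),
                        upper = c(max(x) + diff(range(x)), sigma_bounds[2]))
      est <- o$par
      flagged <- TRUE
    }
  } else {
    ls <- function(par) {
      p <- stats::pnorm((binned$test_numerosity - par[1]) / par[2])
      sum(binned$n * (binned$p_more - p)^2)
    }
    o <- stats::optim(c(mean(range(x)), diff(range(x)) / 4), ls,
                      method = "L-BFGS-B",
                      lower = c(min(x) - diff(range(x)), sigma_bounds[1]),
                      upper = c(max(x) + diff(range(x)), sigma_bounds[2]))
    est <- o$par
    flagged <- any(abs(est[2] - sigma_bounds) < 1e-8)
  }
  pse <- unname(est[1]); sigma <- unname(est[2])
  if (pse < min(x) || pse > max(x)) flagged <- TRUE
  # deviance relative to the binned saturated model
  psat <- pmin(pmax(binned$p_more, 1e-10), 1 - 1e-10)
  ll_sat <- sum(binned$n * (binned$p_more * log(psat) +
                              (1 - binned$p_more) * log(1 - psat)))
  structure(list(pse = pse, sigma = sigma,
                 goodness = 2 * (ll_sat + nll(c(pse, sigma))),
                 n_trials = nrow(t), flagged = flagged, binned = binned),
            class = "psychometric_fit")
}

#' Paired comparisons of PSEs across adaptor conditions
#'
#' For each of the three condition pairs: Shapiro-Wilk normality check on
#' the paired PSE differences, a paired two-sided t-test, and Bonferroni
#' correction for the three comparisons. Participants missing a condition
#' are dropped from the affected pairs.
#'
#' @param fits data frame with `participant`, `condition` (levels
#'   `low_adaptor`, `no_adaptor`, `high_adaptor`) and `pse`.
#' @param min_n minimum participants per pair (default 3).
#' @return Data frame, one row per pair: `pair`, `n`, `mean_diff`,
#'   `shapiro_p`, `t`, `df`, `p_value`, `p_bonferroni`, `direction`.
#' @export
compare_pse <- function(fits, min_n = 3) {
  conds <- c("low_adaptor", "no_adaptor", "high_adaptor")
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  wide <- stats::reshape(fits[, c("participant", "condition", "pse")],
                         idvar = "participant", timevar = "condition",
                         direction = "wide")
  rows <- lapply(pairs, function(pr) {
    a <- wide[[paste0("pse.", pr[1])]]
    b <- wide[[paste0("pse.", pr[2])]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < nrow(wide))
      message("dropping ", nrow(wide) - sum(ok),
              " participant(s) with missing conditions from ",
              paste(pr, collapse = " vs "))
    if (sum(ok) < min_n)
      stop("need at least ", min_n, " participants with both conditions",
           call. = FALSE)
    d <- a[ok] - b[ok]
    sh <- if (stats::sd(d) > 0) stats::shapiro.test(d)$p.value else NA_real_
    if (stats::sd(d) == 0) {
      tt <- list(statistic = if (all(d == 0)) 0 else Inf * sign(mean(d)),
                 parameter = length(d) - 1,
                 p.value = if (all(d == 0)) 1 else 0)
    } else {
      tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
    }
    data.frame(pair = paste(pr, collapse = "_vs_"), n = sum(ok),
               mean_diff = mean(d), shapiro_p = sh,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               p_bonferroni = min(1, 3 * tt$p.value),
               direction = c("equal", "greater", "less")[
                 1 + (mean(d) > 0) + 2 * (mean(d) < 0)])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
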