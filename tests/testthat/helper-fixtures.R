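# Shared fixtures, built once per test run. The power table and grid
# context dominate set-up cost, so they are cached here.

fx <- new.env()

fx_power_table <- function() {
  if (is.null(fx$pt)) fx$pt <- fourier_power_table(n_seeds = 4, seed = 11)
  fx$pt
}

fx_seq <- function(condition) {
  key <- paste0("seq_", condition)
  if (is.null(fx[[key]])) fx[[key]] <- build_run_sequence(condition, seed = 2)
  fx[[key]]
}

fx_context <- function() {
  if (is.null(fx$ctx)) fx$ctx <- tuned_grid_context(fx_seq("changing"))
  fx$ctx
}

fx_design <- function(condition, include_adaptor = TRUE) {
  build_design(fx_seq(condition), "monotonic",
               list(mode = "log_power", power_table = fx_power_table()),
               include_adaptor = include_adaptor)
}

# Noiseless BOLD for a monotonic voxel with the given condition gain.
fx_monotonic_bold <- function(condition, slope, baseline = 100) {
  baseline + slope * fx_design(condition)[, "stimulus"]
}

# Noiseless BOLD for a tuned voxel (merge factor applied per condition).
fx_tuned_bold <- function(condition, pref_log, width_log, amplitude = 1,
                          baseline = 100) {
  ctx <- fx_context()
  g <- exp(-(log(ctx$levels) - pref_log)^2 / (2 * width_log^2))
  m <- if (condition == "changing") 2 else 1
  baseline + amplitude * m * drop(ctx$B %*% g)
}
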