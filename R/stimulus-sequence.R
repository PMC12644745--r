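#' Changing-numerosity schedule for one run
#'
#' One cycle shows numerosities 1 through 7 in ascending order for 3 TRs
#' each, then 12 TRs of 20 dots, then 7 through 1 descending for 3 TRs each,
#' then another 12 TRs of 20. A run is four cycles (264 TRs). The
#' ascending/descending alternation counterbalances the influence of
#' preceding changing numerosities.
#'
#' @return Integer vector of length 264.
#' @export
changing_schedule <- function() {
  cycle <- c(rep(1:7, each = 3), rep(20L, 12), rep(7:1, each = 3), rep(20L, 12))
  rep(as.integer(cycle), 4)
}

#' Build the per-TR run sequence for one adaptor condition
#'
#' Each 1.4 s TR contains an adaptor display (300 ms), a 400 ms blank ISI,
#' a changing-numerosity display (300 ms) and a final 400 ms ISI. The
#' changing schedule is identical across conditions; the adaptor is constant
#' at 1 (low), constant at 20 (high), or matches the changing numerosity
#' (changing). A fixed fraction of presentations show white instead of black
#' dots (oddball attention targets); these are flagged but never enter the
#' response models.
#'
#' @param condition `"low"`, `"high"` or `"changing"`.
#' @param oddball_fraction probability a presentation is an oddball
#'   (default 0.10).
#' @param seed integer seed for the oddball draws.
#' @return An object of class `run_sequence`: data frame with columns
#'   `tr_index`, `adaptor_numerosity`, `changing_numerosity`,
#'   `oddball_adaptor`, `oddball_changing`; attributes `condition`,
#'   `tr_seconds` (1.4) and `within_tr_timing`.
#' @export
build_run_sequence <- function(condition = c("low", "high", "changing"),
                               oddball_fraction = 0.10, seed = 1L) {
  condition <- match.arg(condition)
  ch <- changing_schedule()
  ad <- switch(condition,
               low = rep(1L, length(ch)),
               high = rep(20L, length(ch)),
               changing = ch)
  odd <- with_seed(seed, matrix(stats::runif(2 * length(ch)) < oddball_fraction,
                                ncol = 2))
  seq_df <- data.frame(tr_index = seq_along(ch),
                       adaptor_numerosity = ad,
                       changing_numerosity = ch,
                       oddball_adaptor = odd[, 1],
                       oddball_changing = odd[, 2])
  structure(seq_df,
            condition = condition,
            tr_seconds = 1.4,
            within_tr_timing = c(adaptor_s = 0.3, isi1_s = 0.4,
                                 changing_s = 0.3, isi2_s = 0.4),
            class = c("run_sequence", "data.frame"))
}

#' Total duration of a run sequence in seconds
#' @param seq a `run_sequence`.
#' @return Scalar seconds (264 TRs x 1.4 s = 369.6 s).
#' @export
run_duration <- function(seq) nrow(seq) * attr(seq, "tr_seconds")

#' Export a run sequence as a BIDS-style events table
#'
#' Two events per TR: the adaptor display at the TR onset and the changing
#' display 700 ms later, each lasting 300 ms.
#'
#' @param seq a `run_sequence`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return The events data frame, invisibly; written to `path` if non-NULL.
#' @export
write_events_table <- function(seq, path = NULL, sep = "\t") {
  tr <- attr(seq, "tr_seconds")
  onset <- (seq$tr_index - 1) * tr
  ev <- rbind(
    data.frame(onset_s = onset, duration_s = 0.3, role = "adaptor",
               numerosity = seq$adaptor_numerosity,
               oddball = seq$oddball_adaptor),
    data.frame(onset_s = onset + 0.7, duration_s = 0.3, role = "changing",
               numerosity = seq$changing_numerosity,
               oddball = seq$oddball_changing))
  ev <- ev[order(ev$onset_s), ]
  rownames(ev) <- NULL
  if (!is.null(path))
    utils::write.table(ev, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(ev)
}
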