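#' Pipeline configuration
#'
#' Bundles every setting of the staged analysis with the protocol's
#' default thresholds: eccentricity below 1 degree, monotonic variance
#' explained at least 0.1, tuned variance explained at least 0.2, and the
#' 0.1 map-example variance floor.
#'
#' @param out_dir artifact directory.
#' @param mode monotonic predictor mode, `"log_power"` or
#'   `"log_numerosity"`; both run through identical code paths.
#' @param ecc_max,monotonic_r2_min,tuned_r2_min,map_example_r2_min
#'   selection thresholds.
#' @param voxel_config a [ground_truth_config()] for the simulate stage.
#' @param behav_args list of arguments for
#'   [generate_behavioral_dataset()].
#' @param hrf an [hrf_spec()].
#' @param seed master seed; stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("numadapt_"),
                            mode = c("log_power", "log_numerosity"),
                            ecc_max = 1.0, monotonic_r2_min = 0.1,
                            tuned_r2_min = 0.2, map_example_r2_min = 0.1,
                            voxel_config = ground_truth_config(),
                            behav_args = list(),
                            hrf = hrf_spec(),
                            seed = 1L) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # volatile path; the hash tracks analysis settings
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}

provenance_header <- function(config, stage) {
  sprintf("# numadapt %s | stage=%s | seed=%s | config_hash=%s",
          as.character(utils::packageVersion("numadapt")), stage,
          config$seed, config_hash(config))
}

write_stage_table <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, stage), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_stage_table <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

#' Write a voxel dataset as delimited tables
#'
#' Emits `meta.tsv`, `truth.tsv` (if present), `power_table.tsv` and one
#' long-format `bold_<condition>.tsv` (voxel_id, run, tr, bold) per
#' condition.
#'
#' @param dataset a [generate_voxel_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_voxel_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$truth))
    utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$power_table))
    utils::write.table(
      data.frame(numerosity = names(dataset$power_table),
                 power = as.numeric(dataset$power_table)),
      file.path(dir, "power_table.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
  for (cn in names(dataset$bold)) {
    a <- dataset$bold[[cn]]
    long <- data.frame(
      voxel_id = rep(dataset$meta$voxel_id, times = dim(a)[2] * dim(a)[3]),
      run = rep(rep(seq_len(dim(a)[2]), each = dim(a)[1]), times = dim(a)[3]),
      tr = rep(seq_len(dim(a)[3]), each = dim(a)[1] * dim(a)[2]),
      bold = as.vector(a))
    utils::write.table(long, file.path(dir, paste0("bold_", cn, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a voxel dataset
#'
#' Reads either the delimited layout written by [write_voxel_dataset()] or
#' a NIfTI layout (one 4D volume per condition with voxels along the first
#' axis plus a JSON sidecar; requires the optional `RNifti` package).
#' Validates map labels, consistent run lengths, and the expected number of
#' retained samples per run.
#'
#' @param dir dataset directory.
#' @param format `"delimited"` or `"nifti"`.
#' @param n_timepoints expected samples per run (default 264).
#' @return List with `meta`, `bold`, `seqs`, `power_table`, `truth` as in
#'   [generate_voxel_dataset()].
#' @export
read_voxel_dataset <- function(dir, format = c("delimited", "nifti"),
                               n_timepoints = 264) {
  format <- match.arg(format)
  meta <- utils::read.table(file.path(dir, "meta.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  bad <- setdiff(unique(meta$map_label), VF_MAPS)
  if (length(bad))
    stop("unknown map label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(VF_MAPS, collapse = ", "), call. = FALSE)
  ptf <- file.path(dir, "power_table.tsv")
  pt <- NULL
  if (file.exists(ptf)) {
    p <- utils::read.table(ptf, header = TRUE, sep = "\t")
    pt <- stats::setNames(p$power, p$numerosity)
  }
  trf <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(trf))
    utils::read.table(trf, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  bold <- list()
  for (cn in ADAPTOR_CONDITIONS) {
    if (format == "delimited") {
      f <- file.path(dir, paste0("bold_", cn, ".tsv"))
      if (!file.exists(f)) stop("missing ", f, call. = FALSE)
      long <- utils::read.table(f, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      nrun <- max(long$run)
      ntr <- max(long$tr)
      exp_rows <- nrow(meta) * nrun * ntr
      if (nrow(long) != exp_rows)
        stop("bold_", cn, ".tsv: ", nrow(long), " rows but ", exp_rows,
             " expected for ", nrow(meta), " voxels x ", nrun, " runs x ",
             ntr, " TRs (truncated or duplicated rows?)", call. = FALSE)
      if (ntr != n_timepoints)
        stop("bold_", cn, ".tsv: runs have ", ntr,
             " samples; expected ", n_timepoints, call. = FALSE)
      a <- array(NA_real_, c(nrow(meta), nrun, ntr))
      idx <- cbind(match(long$voxel_id, meta$voxel_id), long$run, long$tr)
      if (anyNA(idx[, 1]))
        stop("bold_", cn, ".tsv row ",
             which(is.na(idx[, 1]))[1] + 1L,
             ": voxel_id not present in meta.tsv", call. = FALSE)
      a[idx] <- long$bold
      if (anyNA(a))
        stop("bold_", cn, ".tsv: incomplete voxel x run x TR grid",
             call. = FALSE)
    } else {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("NIfTI input needs the `RNifti` package", call. = FALSE)
      f <- file.path(dir, paste0("bold_", cn, ".nii.gz"))
      img <- RNifti::readNifti(f)
      d <- dim(img)
      if (d[4] != n_timepoints)
        stop(basename(f), ": ", d[4], " volumes; expected ", n_timepoints,
             call. = FALSE)
      a <- aperm(array(img, c(d[1], d[3], d[4])), c(1, 2, 3))
    }
    bold[[cn]] <- a
  }
  lens <- vapply(bold, function(a) dim(a)[3], numeric(1))
  if (length(unique(lens)) != 1)
    stop("conditions disagree on run length: ",
         paste(names(lens), lens, sep = "=", collapse = ", "), call. = FALSE)
  seqs <- lapply(stats::setNames(ADAPTOR_CONDITIONS, ADAPTOR_CONDITIONS),
                 build_run_sequence)
  list(meta = meta, bold = bold, seqs = seqs, power_table = pt, truth = truth)
}

#' Write a voxel dataset as NIfTI volumes
#'
#' One 4D volume per condition and run concatenation (voxels x 1 x runs x
#' timepoints) plus a JSON sidecar with the TR and condition; the delimited
#' metadata table is written alongside. Requires the optional `RNifti`
#' package.
#'
#' @inheritParams write_voxel_dataset
#' @return `dir`, invisibly.
#' @export
write_voxel_dataset_nifti <- function(dataset, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI output needs the `RNifti` package", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (cn in names(dataset$bold)) {
    a <- dataset$bold[[cn]]
    img <- array(a, c(dim(a)[1], 1, dim(a)[2], dim(a)[3]))
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = c(1, 1, 1, 1.4)),
                       file.path(dir, paste0("bold_", cn, ".nii.gz")))
    jsonlite::write_json(list(condition = cn, tr_seconds = 1.4,
                              n_runs = dim(a)[2]),
                         file.path(dir, paste0("bold_", cn, ".json")),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Run the staged analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' `simulate` (synthetic dataset) -> `fit` (voxelwise model fits) ->
#' `metrics` (selection + map examples) -> `stats` (group statistics);
#' `behavior` (behavioural PSE validation) and `report` (JSON summary) are
#' appended independently. Every output table carries a provenance header
#' (package version, stage, seed, config hash). A stage whose upstream
#' artifacts are missing fails with an error naming the missing stage.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("simulate", "fit", "metrics", "stats", "behavior", "report")`.
#' @return The artifact directory, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "fit", "metrics", "stats",
                                    "behavior", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  need <- function(file, stage) {
    if (!file.exists(file.path(out, file)))
      stop("missing artifact `", file, "`: run the `", stage,
           "` stage first", call. = FALSE)
  }
  log_msg <- function(...) message("[numadapt] ", ...)

  if ("simulate" %in% stages) {
    log_msg("simulate: generating synthetic dataset")
    vc <- config$voxel_config
    vc$seed <- child_seed(config$seed, 1)
    ds <- generate_voxel_dataset(vc)
    write_voxel_dataset(ds, out)
  }
  if ("fit" %in% stages) {
    need("meta.tsv", "simulate")
    need("bold_changing.tsv", "simulate")
    log_msg("fit: voxelwise model fitting")
    ds <- read_voxel_dataset(out)
    fits <- fit_voxel_dataset(ds, mode = config$mode, hrf = config$hrf)
    write_stage_table(fits, file.path(out, "fits.tsv"), config, "fit")
  }
  if ("metrics" %in% stages) {
    need("fits.tsv", "fit")
    need("meta.tsv", "simulate")
    log_msg("metrics: voxel selection and map examples")
    meta <- utils::read.table(file.path(out, "meta.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    fits <- read_stage_table(file.path(out, "fits.tsv"))
    sel <- select_voxels(meta, fits, ecc_max = config$ecc_max,
                         r2_min = config$monotonic_r2_min)
    ex <- aggregate_map_examples(sel, fits, r2_min = config$map_example_r2_min)
    write_stage_table(ex, file.path(out, "map_examples.tsv"), config, "metrics")
    ts <- tuned_effect_summary(meta, fits)
    write_stage_table(ts, file.path(out, "tuned_summary.tsv"), config, "metrics")
  }
  if ("stats" %in% stages) {
    need("map_examples.tsv", "metrics")
    log_msg("stats: group statistics")
    ex <- read_stage_table(file.path(out, "map_examples.tsv"))
    gs <- group_statistics(ex)
    write_stage_table(gs$slope_tests, file.path(out, "slope_tests.tsv"),
                      config, "stats")
    if (!is.null(gs$anova)) {
      write_stage_table(gs$anova$tukey, file.path(out, "tukey.tsv"),
                        config, "stats")
      jsonlite::write_json(
        list(F = gs$anova$F, df = gs$anova$df, p_value = gs$anova$p_value),
        file.path(out, "anova.json"), auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(gs$map_correlations))
      write_stage_table(gs$map_correlations,
                        file.path(out, "map_correlations.tsv"),
                        config, "stats")
  }
  if ("behavior" %in% stages) {
    log_msg("behavior: PSE validation")
    args <- config$behav_args
    args$seed <- child_seed(config$seed, 2)
    behav <- do.call(generate_behavioral_dataset, args)
    pse <- fit_behavioral_dataset(behav)
    write_stage_table(pse, file.path(out, "pse.tsv"), config, "behavior")
    write_stage_table(compare_pse(pse), file.path(out, "pse_tests.tsv"),
                      config, "behavior")
  }
  if ("report" %in% stages) {
    need("map_examples.tsv", "metrics")
    log_msg("report: summary JSON")
    ex <- read_stage_table(file.path(out, "map_examples.tsv"))
    rep <- list(
      n_examples = nrow(ex),
      n_included = sum(ex$included),
      mean_reduction_by_map = as.list(tapply(
        ex$proportional_reduction[ex$included],
        ex$map_label[ex$included], mean, na.rm = TRUE)))
    if (file.exists(file.path(out, "anova.json")))
      rep$anova <- jsonlite::read_json(file.path(out, "anova.json"))
    jsonlite::write_json(rep, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
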