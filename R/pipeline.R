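#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow so a run is fully
#' described by (config, seed): segmentation parameters, box-size
#' ladder, cohort distribution parameters, ROC situations, staging rule,
#' and phantom geometry.
#'
#' @param segmentation a [segmentation_config()].
#' @param box_sizes box-size ladder for [estimate_fd()].
#' @param cohort_params a `cohort_params` list.
#' @param situations list of [situation_spec()]s.
#' @param rule a [staging_rule()].
#' @param n_per_stage subjects per stage for `cmd_simulate` phantoms.
#' @param image_size phantom side length in px.
#' @param seed integer seed recorded in every output.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = segmentation_config(),
                            box_sizes = default_box_sizes(),
                            cohort_params = default_cohort_params(),
                            situations = default_situations(),
                            rule = staging_rule(),
                            n_per_stage = NULL,
                            image_size = 256L,
                            seed = 1L) {
  structure(list(segmentation = segmentation, box_sizes = box_sizes,
                 cohort_params = cohort_params, situations = situations,
                 rule = rule, n_per_stage = n_per_stage,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

manifest_entry <- function(config, inputs = character(0)) {
  cfg_plain <- list(
    segmentation = unclass(config$segmentation),
    box_sizes = config$box_sizes,
    cohort_params = lapply(unclass(config$cohort_params), unclass),
    situations = lapply(config$situations, unclass),
    rule = unclass(config$rule),
    n_per_stage = config$n_per_stage,
    image_size = config$image_size,
    seed = config$seed
  )
  list(tool = "perioFD",
       version = as.character(utils::packageVersion("perioFD")),
       config_hash = hash_config(cfg_plain),
       seed = config$seed,
       input_checksums = as.list(tools::md5sum(inputs)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest$config_hash)
}

#' Simulate a self-contained demo dataset
#'
#' Writes phantom radiographs (PGM) with ROI/landmark sidecar JSONs plus
#' a simulated cohort CSV to `outdir`. Phantom texture roughness and
#' defect position follow the per-stage defaults
#' ([phantom_stage_params()], [phantom_stage_bone_loss()]).
#'
#' @param outdir output directory (created if needed).
#' @param config a [pipeline_config()]; `n_per_stage = NULL` uses each
#'   stage's cohort `n`.
#' @return invisibly, a list with `cohort_csv`, `image_dir`, `roi_dir`,
#'   `manifest`.
#' @export
cmd_simulate <- function(outdir, config = pipeline_config()) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop_io("cannot create output directory: ", outdir)
  }
  params <- config$cohort_params
  if (!is.null(config$n_per_stage)) {
    for (st in names(params)) params[[st]]$n <- as.integer(config$n_per_stage)
  }
  cohort <- simulate_cohort(params, seed = config$seed)
  cohort_csv <- file.path(outdir, "cohort.csv")
  write_cohort_csv(cohort, cohort_csv)

  img_dir <- file.path(outdir, "images")
  roi_dir <- file.path(outdir, "roi")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(roi_dir, showWarnings = FALSE)
  tex <- phantom_stage_params()
  blf <- phantom_stage_bone_loss()
  seeds <- derive_seeds(config$seed, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    st <- as.character(cohort$stage[i])
    ph <- synth_radiograph(tex[[st]], width = config$image_size,
                           height = config$image_size,
                           bone_loss_frac = unname(blf[st]),
                           seed = seeds[i])
    write_radiograph(ph$image, file.path(img_dir, paste0(cohort$subject_id[i], ".pgm")))
    write_roi_json(ph$roi, file.path(roi_dir, paste0(cohort$subject_id[i], ".json")))
  }
  manifest <- manifest_entry(config, cohort_csv)
  write_manifest(manifest, outdir)
  invisible(list(cohort_csv = cohort_csv, image_dir = img_dir,
                 roi_dir = roi_dir, manifest = manifest))
}

#' Process a directory of radiographs into per-subject FD and bone loss
#'
#' Every image must have a matching ROI/landmark sidecar JSON (same base
#' name) in `roi_dir`. Per-subject failures are isolated: the subject is
#' recorded in the failure list and processing continues.
#'
#' @param image_dir directory of `.pgm`/`.png` radiographs.
#' @param roi_dir directory of sidecar JSONs.
#' @param out_csv output CSV path (columns `subject_id, fd, r_squared,
#'   n_points_used, bone_loss_pct, sizes_counts_json`).
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `results` (data.frame), `failures`
#'   (data.frame of subject_id/message), and `status` (0 if all subjects
#'   processed, 1 if any failed).
#' @export
cmd_process_images <- function(image_dir, roi_dir, out_csv,
                               config = pipeline_config()) {
  files <- list.files(image_dir, pattern = "\\.(pgm|png)$", full.names = TRUE)
  if (!length(files)) stop_io("no images found in ", image_dir)
  rows <- list(); fails <- list()
  for (f in files) {
    sid <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      sidecar <- file.path(roi_dir, paste0(sid, ".json"))
      if (!file.exists(sidecar)) stop_io("missing ROI sidecar: ", sidecar)
      img <- read_radiograph(f)
      roi <- read_roi_json(sidecar)
      check_roi_in_image(img, roi)
      patch <- crop_roi(img, roi)
      skel <- extract_skeleton(patch, config$segmentation)
      sizes <- config$box_sizes[config$box_sizes <= min(dim(skel$pixels))]
      est <- estimate_fd(skel$pixels, sizes)
      bl <- percent_bone_loss(roi)
      data.frame(subject_id = sid, fd = est$fd, r_squared = est$r_squared,
                 n_points_used = est$n_points_used,
                 bone_loss_pct = bl$percent,
                 sizes_counts_json = as.character(jsonlite::toJSON(
                   list(sizes = est$curve$sizes, counts = est$curve$counts))),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[sid]] <- data.frame(subject_id = sid, message = conditionMessage(res),
                                 stringsAsFactors = FALSE)
    } else {
      rows[[sid]] <- res
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), fd = numeric(0))
  rownames(results) <- NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(subject_id = character(0), message = character(0))
  rownames(failures) <- NULL
  utils::write.csv(results, out_csv, row.names = FALSE, quote = TRUE)
  if (nrow(failures)) {
    utils::write.csv(failures, sub("\\.csv$", "_failures.csv", out_csv),
                     row.names = FALSE, quote = TRUE)
  }
  invisible(list(results = results, failures = failures,
                 status = if (nrow(failures)) 1L else 0L))
}

stage_summary_block <- function(values, stages) {
  do.call(rbind, lapply(levels(stages)[levels(stages) %in% stages], function(st) {
    v <- values[stages == st]
    data.frame(stage = st, n = length(v),
               mean = mean(v), sd = stats::sd(v),
               median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               min = min(v), max = max(v),
               mean_rank = NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Cohort summary statistics report
#'
#' Per-stage mean/SD/median/range/mean-rank blocks for percent bone loss
#' (staged subjects) and fractal dimension (all subjects), with pooled
#' "Total" rows, Kruskal-Wallis tests across stages, and per-stage plus
#' overall Pearson correlation between the two measures. Written as CSV
#' (summary blocks) and JSON (full report).
#'
#' @param cohort_csv cohort CSV path (see [read_cohort_csv()]).
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @return invisibly, the report list.
#' @export
cmd_cohort_stats <- function(cohort_csv, outdir, config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  coh <- read_cohort_csv(cohort_csv)
  coh$stage <- droplevels(coh$stage)
  staged <- coh[coh$stage != "Control" & !is.na(coh$bone_loss_pct), ]
  staged$stage <- droplevels(staged$stage)
  if (!nrow(staged)) stop_invalid("no staged subjects with bone-loss values after filtering")
  empty <- levels(coh$stage)[!levels(coh$stage) %in% unique(as.character(coh$stage))]
  if (length(empty)) stop_invalid("empty stage after filtering: ", paste(empty, collapse = ", "))

  fd_groups <- split(coh$fd, coh$stage)
  kw_fd <- kruskal_wallis(fd_groups)
  fd_block <- stage_summary_block(coh$fd, coh$stage)
  fd_block$mean_rank <- kw_fd$mean_ranks
  fd_pool <- pooled_summary(fd_block$mean, fd_block$sd, fd_block$n)
  fd_block <- rbind(fd_block, data.frame(stage = "Total", n = fd_pool$n,
                                         mean = fd_pool$mean, sd = fd_pool$sd,
                                         median = stats::median(coh$fd),
                                         q1 = unname(stats::quantile(coh$fd, 0.25)),
                                         q3 = unname(stats::quantile(coh$fd, 0.75)),
                                         min = min(coh$fd), max = max(coh$fd),
                                         mean_rank = NA_real_))

  bl_groups <- split(staged$bone_loss_pct, staged$stage)
  kw_bl <- kruskal_wallis(bl_groups)
  bl_block <- stage_summary_block(staged$bone_loss_pct, staged$stage)
  bl_block$mean_rank <- kw_bl$mean_ranks
  bl_pool <- pooled_summary(bl_block$mean, bl_block$sd, bl_block$n)
  bl_block <- rbind(bl_block, data.frame(stage = "Total", n = bl_pool$n,
                                         mean = bl_pool$mean, sd = bl_pool$sd,
                                         median = stats::median(staged$bone_loss_pct),
                                         q1 = unname(stats::quantile(staged$bone_loss_pct, 0.25)),
                                         q3 = unname(stats::quantile(staged$bone_loss_pct, 0.75)),
                                         min = min(staged$bone_loss_pct),
                                         max = max(staged$bone_loss_pct),
                                         mean_rank = NA_real_))

  safe_cor <- function(x, y) {
    tryCatch(pearson_correlation(x, y),
             error = function(e) list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  cors <- list(Overall = safe_cor(staged$bone_loss_pct, staged$fd))
  for (st in levels(staged$stage)) {
    sub <- staged[staged$stage == st, ]
    cors[[st]] <- safe_cor(sub$bone_loss_pct, sub$fd)
  }
  cor_block <- do.call(rbind, lapply(names(cors), function(nm) {
    data.frame(group = nm, r = cors[[nm]]$r, p_value = cors[[nm]]$p_value,
               n = cors[[nm]]$n, stringsAsFactors = FALSE)
  }))

  report <- list(
    bone_loss = list(summary = bl_block, kruskal_wallis = kw_bl),
    fd = list(summary = fd_block, kruskal_wallis = kw_fd),
    correlations = cor_block,
    manifest = manifest_entry(config, cohort_csv)
  )
  utils::write.csv(bl_block, file.path(outdir, "bone_loss_summary.csv"), row.names = FALSE)
  utils::write.csv(fd_block, file.path(outdir, "fd_summary.csv"), row.names = FALSE)
  utils::write.csv(cor_block, file.path(outdir, "correlations.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(outdir, "cohort_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  invisible(report)
}

#' ROC situations report and per-subject staging
#'
#' Runs every configured ROC situation on the cohort and writes a
#' one-row-per-situation table (n, AUC with CI, p vs 0.5, criterion,
#' sensitivity and specificity with exact CIs), the ROC curve points,
#' and the cohort with each subject's staging-rule category appended.
#'
#' @param cohort_csv cohort CSV path.
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `table` (data.frame), `results` (list
#'   of `roc_result`), `staged_cohort`.
#' @export
cmd_roc <- function(cohort_csv, outdir, config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  coh <- read_cohort_csv(cohort_csv)
  results <- lapply(config$situations, function(s) run_situation(coh, s))
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(situation = r$situation, n = r$n,
               auc = r$auc, auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
               p_vs_half = r$p_vs_half,
               criterion = r$criterion,
               sensitivity = r$sensitivity,
               sens_lo = r$sensitivity_ci[1], sens_hi = r$sensitivity_ci[2],
               specificity = r$specificity,
               spec_lo = r$specificity_ci[1], spec_hi = r$specificity_ci[2],
               stringsAsFactors = FALSE)
  }))
  coh$staging_category <- classify_stage(coh$fd, config$rule)
  utils::write.csv(tab, file.path(outdir, "roc_situations.csv"), row.names = FALSE)
  curves <- do.call(rbind, lapply(results, function(r) {
    cbind(situation = r$situation, r$curve)
  }))
  utils::write.csv(curves, file.path(outdir, "roc_curves.csv"), row.names = FALSE)
  utils::write.csv(coh, file.path(outdir, "cohort_staged.csv"), row.names = FALSE, na = "")
  manifest <- manifest_entry(config, cohort_csv)
  write_manifest(manifest, outdir)
  invisible(list(table = tab, results = results, staged_cohort = coh,
                 manifest = manifest))
}

#' Run the full pipeline: simulate, process images, stats, ROC
#'
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the sub-command results.
#' @export
cmd_all <- function(outdir, config = pipeline_config()) {
  sim <- cmd_simulate(outdir, config)
  proc <- cmd_process_images(sim$image_dir, sim$roi_dir,
                             file.path(outdir, "image_measurements.csv"), config)
  stats_rep <- cmd_cohort_stats(sim$cohort_csv, file.path(outdir, "stats"), config)
  roc_rep <- cmd_roc(sim$cohort_csv, file.path(outdir, "roc"), config)
  invisible(list(simulate = sim, process = proc, stats = stats_rep, roc = roc_rep))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `process-images`,
#' `cohort-stats`, `roc`, `all`. Intended to be called from an Rscript
#' wrapper (see `inst/cli/periofd`).
#'
#' @param argv character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` by default).
#' @return exit status integer (0 on success), invisibly.
#' @export
pipeline_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat("usage: periofd <simulate|process-images|cohort-stats|roc|all> [options]\n")
    return(invisible(2L))
  }
  cmd <- argv[1]
  rest <- argv[-1]
  opts <- optparse::OptionParser(option_list = list(
    optparse::make_option("--outdir", type = "character", default = "periofd_out"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--cohort", type = "character", default = NULL,
                          help = "cohort CSV (cohort-stats, roc)"),
    optparse::make_option("--images", type = "character", default = NULL),
    optparse::make_option("--roi", type = "character", default = NULL),
    optparse::make_option("--n-per-stage", type = "integer", default = NULL,
                          dest = "n_per_stage"),
    optparse::make_option("--image-size", type = "integer", default = 256L,
                          dest = "image_size")
  ))
  o <- optparse::parse_args(opts, args = rest)
  config <- pipeline_config(seed = o$seed, n_per_stage = o$n_per_stage,
                            image_size = o$image_size)
  status <- 0L
  switch(cmd,
    "simulate" = cmd_simulate(o$outdir, config),
    "process-images" = {
      if (is.null(o$images) || is.null(o$roi)) stop_invalid("--images and --roi required")
      r <- cmd_process_images(o$images, o$roi,
                              file.path(o$outdir, "image_measurements.csv"), config)
      status <- r$status
    },
    "cohort-stats" = {
      if (is.null(o$cohort)) stop_invalid("--cohort required")
      cmd_cohort_stats(o$cohort, o$outdir, config)
    },
    "roc" = {
      if (is.null(o$cohort)) stop_invalid("--cohort required")
      cmd_roc(o$cohort, o$outdir, config)
    },
    "all" = {
      r <- cmd_all(o$outdir, config)
      status <- r$process$status
    },
    stop_invalid("unknown subcommand: ", cmd)
  )
  invisible(status)
}
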