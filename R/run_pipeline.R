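#' Run a pipeline over a cohort
#'
#' Executes the spec's stages in order for every subject of the selected
#' split (`train` mode processes `split == "train"`, `test` mode
#' `split == "test"`, `deploy` mode `split == "new"` rows — or, if none are
#' marked `new`, every row). Subject images are resolved in `subjects_dir`
#' as `<subject_id>_vol.nii[.gz]` / `<subject_id>_mask.nii[.gz]`.
#'
#' The whole run is validated before any image work: covariate coverage,
#' image files, referenced statistics and model files. Subjects whose ROI
#' becomes empty during mask stages are skipped with a logged reason (the
#' run continues; the manifest records them). Execution is sequential and
#' deterministic: the spec, the inputs and the seed fix every output byte.
#'
#' Outputs written to `out_dir`: `features.csv` (post-processed feature
#' table), `manifest.json` (per-subject stage log with content hashes),
#' `harmonization_stats.json` (train mode with fit-type stages), and
#' `predictions.csv` (deploy mode).
#'
#' @param spec a `pipeline_spec`.
#' @param subjects_dir directory of NIfTI volume/mask pairs.
#' @param covariates covariate table (`data.frame` or CSV path) with
#'   `subject_id`, `batch`, `split` and optionally `label`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with `features`, `manifest`, `stats` (fitted
#'   harmonization statistics or `NULL`), `predictions` (deploy mode) and
#'   `skipped`.
#' @export
run_pipeline <- function(spec, subjects_dir, covariates, out_dir) {
  stopifnot(inherits(spec, "pipeline_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cov <- if (is.character(covariates)) {
    utils::read.csv(covariates, stringsAsFactors = FALSE)
  } else covariates
  for (need in c("subject_id", "batch", "split"))
    if (!need %in% names(cov))
      stop("covariate table lacks column: ", need, call. = FALSE)
  cov$subject_id <- as.character(cov$subject_id)

  mode <- spec$global$mode
  sel <- switch(mode,
                train = cov$split == "train",
                test = cov$split == "test",
                deploy = if (any(cov$split == "new")) cov$split == "new"
                         else rep(TRUE, nrow(cov)))
  subjects <- cov[sel, , drop = FALSE]
  if (nrow(subjects) == 0L)
    stop("no subjects selected for mode '", mode, "'", call. = FALSE)

  # fail-fast validation before any image work
  stage_names <- vapply(spec$stages, `[[`, "", "stage")
  if ("predict" %in% stage_names && mode == "train")
    stop("a pipeline with a predict stage refuses to run in train mode",
         call. = FALSE)
  for (id in subjects$subject_id) {
    find_subject_file(subjects_dir, id, "vol")
    find_subject_file(subjects_dir, id, "mask")
  }
  frozen <- NULL
  if (mode %in% c("test", "deploy")) {
    for (st in spec$stages) {
      if (st$stage %in% c("combat", "zscore") &&
          !isTRUE(st$params$fit_per_split)) {
        if (is.na(st$params$stats %||% NA_character_))
          stop("stage '", st$stage, "' needs a stats file in ", mode,
               " mode (derive the pipeline from a training run)",
               call. = FALSE)
        frozen <- load_harmonization_stats(st$params$stats)
      }
    }
  }
  clf <- NULL
  pred_stage <- pipeline_stage(spec, "predict")
  if (!is.null(pred_stage)) clf <- load_classifier(pred_stage$params$model)

  ext <- extract_cohort_features(spec, subjects_dir, subjects)
  table <- ext$features
  if (nrow(table) == 0L)
    stop("every subject was skipped; no features extracted", call. = FALSE)

  # cohort-level post-processing in listed order
  stats_out <- list(combat = NULL, zscore = NULL)
  for (st in spec$stages) {
    if (st$stage == "combat") {
      if (mode == "train" || isTRUE(st$params$fit_per_split)) {
        model <- fit_combat(table, spec$global$batch_column,
                            st$params$reference)
      } else {
        model <- frozen$combat
        if (is.null(model))
          stop("statistics file lacks the ComBat model", call. = FALSE)
      }
      table <- apply_combat(table, model)
      if (mode == "train") stats_out$combat <- model
    } else if (st$stage == "zscore") {
      if (mode == "train" || isTRUE(st$params$fit_per_split)) {
        zs <- fit_zscore(table)
      } else {
        zs <- frozen$zscore
        if (is.null(zs))
          stop("statistics file lacks z-score statistics", call. = FALSE)
      }
      table <- apply_zscore(table, zs)
      if (mode == "train") stats_out$zscore <- zs
    }
  }

  stats_path <- NULL
  if (mode == "train" && any(stage_names %in% c("combat", "zscore"))) {
    stats_path <- file.path(out_dir, "harmonization_stats.json")
    save_harmonization_stats(stats_out$combat, stats_out$zscore,
                             feature_columns(table), ext$config_hash,
                             stats_path)
  }

  predictions <- NULL
  if (!is.null(clf)) {
    predictions <- tryCatch(
      classify_records(predict_proba(clf, table),
                       threshold = pred_stage$params$threshold),
      error = function(e) stop("predict stage failed for cohort [",
                               paste(table$subject_id, collapse = ","), "]: ",
                               conditionMessage(e), call. = FALSE))
    utils::write.csv(data.frame(
      subject_id = predictions$subject_id,
      probability = sprintf("%.17g", predictions$probability),
      predicted_class = predictions$predicted_class,
      true_label = predictions$true_label),
      file.path(out_dir, "predictions.csv"), row.names = FALSE, quote = FALSE)
  }

  manifest <- list(framework = "radpipe",
                   version = as.character(utils::packageVersion("radpipe")),
                   mode = mode,
                   config_hash = hash_object(unclass(spec)),
                   n_subjects = nrow(table),
                   skipped = ext$skipped,
                   subjects = ext$manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  write_feature_table(table, file.path(out_dir, "features.csv"))
  invisible(list(features = table, manifest = manifest,
                 stats = if (mode == "train") stats_out,
                 stats_path = stats_path,
                 predictions = predictions, skipped = ext$skipped))
}

# per-subject image stages + extraction; shared by run_pipeline and the
# perturbation suite (which caches on the image/extract stage fingerprint)
extract_cohort_features <- function(spec, subjects_dir, subjects) {
  rows <- list()
  manifest <- list()
  skipped <- list()
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    res <- tryCatch(
      process_subject(spec, subjects_dir, id),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (grepl("empty ROI|all ROI voxels", conditionMessage(res))) {
        skipped[[id]] <- conditionMessage(res)
        next
      }
      stop("subject ", id, ": ", conditionMessage(res), call. = FALSE)
    }
    row <- as.data.frame(as.list(res$features), check.names = FALSE)
    row <- cbind(data.frame(subject_id = id, stringsAsFactors = FALSE), row)
    for (cv in intersect(c("batch", "split", "label"), names(subjects)))
      row[[cv]] <- subjects[[cv]][i]
    rows[[id]] <- row
    manifest[[id]] <- res$log
  }
  features <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(subject_id = character(0))
  rownames(features) <- NULL
  config_hash <- hash_object(pipeline_stage(spec, "extract")$params)
  list(features = features, manifest = manifest, skipped = skipped,
       config_hash = config_hash)
}

process_subject <- function(spec, subjects_dir, id) {
  volume <- read_volume(find_subject_file(subjects_dir, id, "vol"))
  mask <- read_mask(find_subject_file(subjects_dir, id, "mask"))
  log <- list()
  features <- NULL
  for (st in spec$stages) {
    p <- st$params
    in_hash <- NULL  # input hash folded into output hash chain
    switch(st$stage,
      merge_labels = {
        mask <- merge_labels(mask, p$labels)
      },
      fat_removal = {
        mask <- remove_subzero_voxels(mask, volume)
      },
      window = {
        volume <- apply_window(volume,
                               window_params(p$level, p$width, p$out_min,
                                             p$out_max),
                               clip = p$clip, rescale = p$rescale,
                               round_to_int = p$round_to_int)
      },
      resample = {
        rp <- resample_params(p$spacing, p$interpolator, p$implementation)
        volume <- resample_volume(volume, rp)
        mask <- resample_mask(mask, rp)
      },
      extract = {
        if (!any(mask$labels > 0L)) stop("empty ROI", call. = FALSE)
        cfg <- extraction_config(families = p$families,
                                 bin_width = p$bin_width,
                                 dialect = p$dialect, distance = p$distance)
        features <- extract_features(volume, mask, cfg)
      },
      combat = , zscore = , predict = NULL)
    if (st$stage %in% c("merge_labels", "fat_removal", "window", "resample",
                        "extract")) {
      out_hash <- if (st$stage == "extract") hash_object(features) else
        hash_object(list(volume$data, mask$labels))
      log[[length(log) + 1L]] <- list(stage = st$stage, params = p,
                                      output_hash = out_hash)
    }
  }
  list(features = features, log = log)
}

find_subject_file <- function(dir, id, what) {
  for (ext in c(".nii", ".nii.gz")) {
    f <- file.path(dir, paste0(id, "_", what, ext))
    if (file.exists(f)) return(f)
  }
  stop("missing ", what, " image for subject ", id, " in ", dir,
       call. = FALSE)
}
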