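#' Pipeline perturbation variants
#'
#' The nine deterministic alterations of the reference pipeline studied by
#' the perturbation suite:
#'
#' * `v1_no_fat_removal` — drop the sub-zero-HU fat-removal stage.
#' * `v2_alt_binning` — discretize with the `edge_variant` dialect
#'   (generic histogram-edge semantics instead of the top-clamped rule).
#' * `v3_separate_postproc` — fit ComBat/z-score separately on each split
#'   instead of freezing training statistics.
#' * `v4_alt_resampler` — resample with the `alt` (center-aligned) grid
#'   convention, standing in for a different resampling library.
#' * `v5_resample_first` — move spatial resampling (alt convention) to the
#'   front of the pipeline.
#' * `v6_no_window` — remove the window clip; the 0-255 rescale then uses
#'   each image's own min/max.
#' * `v7_no_spatial_resample` — drop spatial resampling entirely.
#' * `v8_bspline_interp` — resample with the cubic B-spline interpolator.
#' * `v9_no_intensity_rescale` — remove the 0-255 rescale; features are
#'   computed on clipped HU.
#'
#' @return Character vector of the nine variant identifiers.
#' @export
variant_ids <- function() {
  c("v1_no_fat_removal", "v2_alt_binning", "v3_separate_postproc",
    "v4_alt_resampler", "v5_resample_first", "v6_no_window",
    "v7_no_spatial_resample", "v8_bspline_interp", "v9_no_intensity_rescale")
}

#' Apply a perturbation variant to a pipeline
#'
#' Each variant is a deterministic transformation of the spec; everything it
#' does not touch stays byte-identical. Applying a variant twice equals
#' applying it once (stage drops are no-ops when the stage is already
#' absent; parameter edits require their target stage and error otherwise).
#'
#' @param base the reference `pipeline_spec`.
#' @param id one of [variant_ids()].
#' @return The transformed `pipeline_spec`.
#' @export
make_variant <- function(base, id) {
  stopifnot(inherits(base, "pipeline_spec"))
  id <- match.arg(id, variant_ids())
  spec <- base
  edit_stage <- function(spec, name, edit) {
    i <- pipeline_stage_index(spec, name)
    if (is.na(i))
      stop("variant ", id, " requires a '", name, "' stage, absent from base",
           call. = FALSE)
    spec$stages[[i]] <- edit(spec$stages[[i]])
    spec
  }
  drop_stage <- function(spec, name) {
    i <- pipeline_stage_index(spec, name)
    if (!is.na(i)) spec$stages[[i]] <- NULL
    spec
  }
  switch(id,
    v1_no_fat_removal = drop_stage(spec, "fat_removal"),
    v2_alt_binning = edit_stage(spec, "extract", function(st) {
      st$params$dialect <- "edge_variant"
      st
    }),
    v3_separate_postproc = {
      i_c <- pipeline_stage_index(spec, "combat")
      i_z <- pipeline_stage_index(spec, "zscore")
      if (is.na(i_c) && is.na(i_z))
        stop("variant v3_separate_postproc requires a combat or zscore stage",
             call. = FALSE)
      if (!is.na(i_c)) spec$stages[[i_c]]$params$fit_per_split <- TRUE
      if (!is.na(i_z)) spec$stages[[i_z]]$params$fit_per_split <- TRUE
      spec
    },
    v4_alt_resampler = edit_stage(spec, "resample", function(st) {
      st$params$implementation <- "alt"
      st
    }),
    v5_resample_first = {
      spec <- edit_stage(spec, "resample", function(st) {
        st$params$implementation <- "alt"
        st
      })
      i <- pipeline_stage_index(spec, "resample")
      st <- spec$stages[[i]]
      spec$stages[[i]] <- NULL
      spec$stages <- c(list(st), spec$stages)
      spec
    },
    v6_no_window = edit_stage(spec, "window", function(st) {
      st$params$clip <- FALSE
      st
    }),
    v7_no_spatial_resample = drop_stage(spec, "resample"),
    v8_bspline_interp = edit_stage(spec, "resample", function(st) {
      st$params$interpolator <- "bspline3"
      st
    }),
    v9_no_intensity_rescale = edit_stage(spec, "window", function(st) {
      st$params$rescale <- FALSE
      st
    }))
}

#' Run the full perturbation comparison study
#'
#' Runs the reference pipeline on the cohort (train fit, frozen-statistics
#' test application), trains the reference classifier, then for each
#' requested variant extracts variant features and evaluates both regimes:
#'
#' * **non-retrained** — the reference classifier applied to variant test
#'   features (a site reusing a published model with its own pipeline);
#' * **retrained** — a classifier retrained on the variant training
#'   features with the same hyperparameters and seed (a site replicating
#'   the study), applied to variant test features.
#'
#' For every variant and regime the report carries the evaluation metrics
#' against truth, the agreement statistics against the reference
#' predictions (Cohen's kappa, discordance %, absolute probability
#' differences; overall and per label group), and per regime the pairwise
#' kappa matrix over reference plus variants. A variant whose pipeline
#' fails is recorded with its error; the suite continues.
#'
#' Image and extraction stages are cached on their configuration
#' fingerprint, so variants sharing the image chain (e.g. the
#' post-processing-only variant) do not recompute features.
#'
#' @param base_spec reference train-mode `pipeline_spec`.
#' @param subjects_dir,covariates cohort location, as [run_pipeline()].
#' @param work_dir scratch directory for per-variant runs.
#' @param feature_list,hyperparams classifier configuration.
#' @param seed seed for reference and retrained classifiers.
#' @param variants subset of [variant_ids()].
#' @param regimes `"non_retrained"`, `"retrained"` or both.
#' @param threshold decision threshold.
#' @return A `comparison_report` list.
#' @export
run_variant_suite <- function(base_spec, subjects_dir, covariates, work_dir,
                              feature_list = default_model_features(),
                              hyperparams = default_hyperparams(),
                              seed = 0L, variants = variant_ids(),
                              regimes = c("non_retrained", "retrained"),
                              threshold = 0.5) {
  stopifnot(inherits(base_spec, "pipeline_spec"))
  variants <- match.arg(variants, variant_ids(), several.ok = TRUE)
  regimes <- match.arg(regimes, c("non_retrained", "retrained"),
                       several.ok = TRUE)
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  cache <- new.env(parent = emptyenv())

  ref <- run_pipeline_cached(base_spec, subjects_dir, covariates,
                             file.path(work_dir, "reference"), cache)
  ref_model <- train_classifier(ref$train$features, feature_list,
                                hyperparams, seed)
  ref_pred <- classify_records(predict_proba(ref_model, ref$test$features),
                               threshold)

  results <- list()
  class_sets <- list(non_retrained = list(reference = ref_pred),
                     retrained = list(reference = ref_pred))
  for (id in variants) {
    res <- tryCatch({
      vspec <- make_variant(base_spec, id)
      vrun <- run_pipeline_cached(vspec, subjects_dir, covariates,
                                  file.path(work_dir, id), cache)
      out <- list()
      if ("non_retrained" %in% regimes) {
        pred <- classify_records(predict_proba(ref_model, vrun$test$features),
                                 threshold)
        out$non_retrained <- compare_predictions(pred, ref_pred)
        class_sets$non_retrained[[id]] <- pred
      }
      if ("retrained" %in% regimes) {
        vmodel <- train_classifier(vrun$train$features, feature_list,
                                   hyperparams, seed)
        pred <- classify_records(predict_proba(vmodel, vrun$test$features),
                                 threshold)
        out$retrained <- compare_predictions(pred, ref_pred)
        class_sets$retrained[[id]] <- pred
      }
      out
    }, error = function(e) list(error = conditionMessage(e)))
    results[[id]] <- res
  }

  kappa <- lapply(regimes, function(rg) {
    sets <- class_sets[[rg]]
    nm <- names(sets)
    k <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    for (a in nm) for (b in nm)
      k[a, b] <- cohen_kappa(sets[[a]]$predicted_class,
                             sets[[b]]$predicted_class)
    k
  })
  names(kappa) <- regimes

  structure(list(
    reference = list(evaluation = as.list(evaluation_report(ref_pred)),
                     self_agreement = agreement_stats(ref_pred, ref_pred)),
    variants = results,
    kappa_matrix = kappa,
    regimes = regimes,
    seed = as.integer(seed),
    threshold = threshold,
    # v6 removes the window clip, v9 the 0-255 rescale; both halves of the
    # windowing step are independently removable and logged here
    windowing_split = c(v6_no_window = "drops the clip to [-200, 300] HU",
                        v9_no_intensity_rescale = "drops the 0-255 rescale")),
    class = "comparison_report")
}

compare_predictions <- function(pred, ref_pred) {
  list(evaluation = as.list(evaluation_report(pred)),
       agreement = agreement_stats(pred, ref_pred))
}

# train + derived-test execution with caching of the image/extract work on
# its configuration fingerprint (stage list up to extract + subject set)
run_pipeline_cached <- function(spec, subjects_dir, covariates, out_dir,
                                cache) {
  cov <- if (is.character(covariates)) {
    utils::read.csv(covariates, stringsAsFactors = FALSE)
  } else covariates
  cov$subject_id <- as.character(cov$subject_id)
  train_res <- run_split_cached(spec, subjects_dir, cov,
                                file.path(out_dir, "train"), cache)
  test_spec <- derive_test_pipeline(spec, file.path(out_dir, "train"))
  test_res <- run_split_cached(test_spec, subjects_dir, cov,
                               file.path(out_dir, "test"), cache)
  list(train = train_res, test = test_res)
}

run_split_cached <- function(spec, subjects_dir, cov, out_dir, cache) {
  sel <- switch(spec$global$mode,
                train = cov$split == "train",
                test = cov$split == "test")
  subjects <- cov[sel, , drop = FALSE]
  image_stages <- Filter(function(st)
    st$stage %in% c("merge_labels", "fat_removal", "window", "resample",
                    "extract"), spec$stages)
  key <- hash_object(list(image_stages, subjects$subject_id, subjects_dir))
  ext <- cache[[key]]
  if (is.null(ext)) {
    ext <- extract_cohort_features(spec, subjects_dir, subjects)
    cache[[key]] <- ext
  }
  run_pipeline_postproc(spec, ext, subjects, out_dir)
}

# replay post-processing on a cached raw feature table (mirrors the post
# stage block of run_pipeline)
run_pipeline_postproc <- function(spec, ext, subjects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mode <- spec$global$mode
  table <- ext$features
  stats_out <- list(combat = NULL, zscore = NULL)
  frozen <- NULL
  for (st in spec$stages) {
    if (st$stage %in% c("combat", "zscore") && mode != "train" &&
        !isTRUE(st$params$fit_per_split) && is.null(frozen))
      frozen <- load_harmonization_stats(st$params$stats)
    if (st$stage == "combat") {
      model <- if (mode == "train" || isTRUE(st$params$fit_per_split))
        fit_combat(table, spec$global$batch_column, st$params$reference)
      else frozen$combat
      table <- apply_combat(table, model)
      if (mode == "train") stats_out$combat <- model
    } else if (st$stage == "zscore") {
      zs <- if (mode == "train" || isTRUE(st$params$fit_per_split))
        fit_zscore(table) else frozen$zscore
      table <- apply_zscore(table, zs)
      if (mode == "train") stats_out$zscore <- zs
    }
  }
  stats_path <- NULL
  if (mode == "train") {
    stats_path <- file.path(out_dir, "harmonization_stats.json")
    save_harmonization_stats(stats_out$combat, stats_out$zscore,
                             feature_columns(table), ext$config_hash,
                             stats_path)
  }
  write_feature_table(table, file.path(out_dir, "features.csv"))
  invisible(list(features = table, manifest = NULL,
                 stats = if (mode == "train") stats_out,
                 stats_path = stats_path, predictions = NULL,
                 skipped = ext$skipped))
}

#' Write a comparison report as JSON
#'
#' @param report a `comparison_report` from [run_variant_suite()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  out <- unclass(report)
  out$kappa_matrix <- lapply(out$kappa_matrix, function(k) {
    list(models = rownames(k), kappa = unname(k))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}
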