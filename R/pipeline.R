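#' Pipeline stage registry
#'
#' The framework executes a fixed vocabulary of stages. Image stages run per
#' subject in the order listed; the `extract` stage turns each subject into
#' a feature row; post-processing stages (`combat`, `zscore`) operate on the
#' cohort feature table; `predict` (deploy pipelines only) applies a frozen
#' classifier. Fit-type stages (`combat`, `zscore`) estimate their
#' statistics only in `train` mode — in `test`/`deploy` mode they load and
#' apply the frozen statistics, unless `fit_per_split` requests an
#' independent refit on the current split.
#'
#' @return Named list describing each stage's parameters and defaults.
#' @export
pipeline_stage_registry <- function() {
  list(
    merge_labels = list(kind = "image",
                        params = list(labels = quote(required))),
    fat_removal = list(kind = "image", params = list()),
    window = list(kind = "image",
                  params = list(level = 50, width = 500, clip = TRUE,
                                rescale = TRUE, out_min = 0, out_max = 255,
                                round_to_int = FALSE)),
    resample = list(kind = "image",
                    params = list(spacing = c(1, 1, 1),
                                  interpolator = "trilinear",
                                  implementation = "native")),
    extract = list(kind = "extract",
                   params = list(bin_width = 25, dialect = "ibsi",
                                 families = c("first_order", "shape", "glcm",
                                              "glrlm", "glszm"),
                                 distance = 1L)),
    combat = list(kind = "post",
                  params = list(reference = quote(required),
                                fit_per_split = FALSE, stats = NA_character_)),
    zscore = list(kind = "post",
                  params = list(fit_per_split = FALSE, stats = NA_character_)),
    predict = list(kind = "predict",
                   params = list(model = quote(required), threshold = 0.5))
  )
}

#' Parse a pipeline file
#'
#' A pipeline is a structured text (YAML) document with a `global` block
#' (`mode`, `batch_column`, `seed`, optional `name`) and an ordered `stages`
#' list, each entry naming a registered stage plus its parameters. Parsing
#' validates the whole document before any image work: unknown stages or
#' parameters, missing required parameters and duplicate global keys are
#' rejected with the offending entry named. Parsed specs are normalized
#' (defaults filled in, registry parameter order), so
#' `parse_pipeline(serialize_pipeline(spec))` is the identity.
#'
#' @param path pipeline file path.
#' @return A `pipeline_spec` object.
#' @export
parse_pipeline <- function(path) {
  if (!file.exists(path)) stop("pipeline file not found: ", path, call. = FALSE)
  check_duplicate_global_keys(path)
  doc <- yaml::read_yaml(path)
  as_pipeline_spec(doc)
}

#' Build a pipeline spec from R lists
#'
#' @param doc list with elements `global` and `stages` in the file layout of
#'   [parse_pipeline()].
#' @return A validated, normalized `pipeline_spec`.
#' @export
as_pipeline_spec <- function(doc) {
  if (is.null(doc$global)) stop("pipeline lacks a global block", call. = FALSE)
  if (is.null(doc$stages) || length(doc$stages) == 0L)
    stop("pipeline lacks stages", call. = FALSE)
  g <- doc$global
  mode <- g$mode
  if (is.null(mode) || !mode %in% c("train", "test", "deploy"))
    stop("global.mode must be train, test or deploy", call. = FALSE)
  global <- list(mode = mode,
                 batch_column = g$batch_column %||% "batch",
                 seed = as.integer(g$seed %||% 0L),
                 name = g$name %||% NULL)
  known_globals <- c("mode", "batch_column", "seed", "name")
  extra <- setdiff(names(g), known_globals)
  if (length(extra) > 0L)
    stop("unknown global key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)

  registry <- pipeline_stage_registry()
  stages <- lapply(seq_along(doc$stages), function(i) {
    st <- doc$stages[[i]]
    name <- st$stage
    if (is.null(name) || !name %in% names(registry))
      stop("unknown stage at position ", i, ": ",
           if (is.null(name)) "<missing 'stage' key>" else name,
           call. = FALSE)
    spec <- registry[[name]]
    given <- st[setdiff(names(st), "stage")]
    extra <- setdiff(names(given), names(spec$params))
    if (length(extra) > 0L)
      stop("unknown parameter(s) for stage '", name, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    params <- spec$params
    for (p in names(params)) {
      if (p %in% names(given)) {
        params[[p]] <- normalize_stage_param(name, p, given[[p]])
      } else if (identical(params[[p]], quote(required))) {
        stop("missing required parameter '", p, "' for stage '", name, "'",
             call. = FALSE)
      }
    }
    list(stage = name, params = params)
  })
  stage_names <- vapply(stages, `[[`, "", "stage")
  for (unique_stage in c("extract", "combat", "zscore", "predict"))
    if (sum(stage_names == unique_stage) > 1L)
      stop("stage '", unique_stage, "' may appear only once", call. = FALSE)
  if (!"extract" %in% stage_names)
    stop("pipeline must contain an extract stage", call. = FALSE)
  post_pos <- which(stage_names %in% c("combat", "zscore", "predict"))
  if (length(post_pos) > 0L && any(post_pos < which(stage_names == "extract")))
    stop("post-processing stages must come after extract", call. = FALSE)
  if ("predict" %in% stage_names && global$mode == "train")
    stop("a pipeline with a predict stage refuses to run in train mode",
         call. = FALSE)
  structure(list(global = global, stages = stages), class = "pipeline_spec")
}

normalize_stage_param <- function(stage, param, value) {
  if (stage == "merge_labels" && param == "labels") {
    v <- as.integer(unlist(value))
    if (length(v) == 0L) stop("merge_labels.labels must be non-empty",
                              call. = FALSE)
    return(v)
  }
  if (stage == "resample" && param == "spacing") {
    v <- as.numeric(unlist(value))
    if (length(v) == 1L) v <- rep(v, 3L)
    return(v)
  }
  if (stage == "resample" && param == "interpolator") {
    return(match.arg(value, c("trilinear", "bspline3", "nearest")))
  }
  if (stage == "resample" && param == "implementation") {
    return(match.arg(value, c("native", "alt")))
  }
  if (stage == "extract" && param == "families") {
    return(match.arg(unlist(value),
                     c("first_order", "shape", "glcm", "glrlm", "glszm"),
                     several.ok = TRUE))
  }
  if (stage == "extract" && param == "dialect") {
    return(match.arg(value, c("ibsi", "edge_variant")))
  }
  if (stage == "extract" && param == "distance") return(as.integer(value))
  if (param %in% c("clip", "rescale", "round_to_int", "fit_per_split")) {
    return(isTRUE(value))
  }
  if (param %in% c("level", "width", "out_min", "out_max", "threshold")) {
    return(as.numeric(value))
  }
  value
}

#' Serialize a pipeline spec
#'
#' Writes the canonical YAML form (defaults explicit, registry parameter
#' order).
#'
#' @param spec a `pipeline_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
serialize_pipeline <- function(spec, path) {
  stopifnot(inherits(spec, "pipeline_spec"))
  doc <- list(global = drop_nulls(spec$global),
              stages = lapply(spec$stages, function(st) {
                c(list(stage = st$stage), drop_nulls(st$params))
              }))
  yaml::write_yaml(doc, path,
                   handlers = list(logical = yaml::verbatim_logical))
  invisible(path)
}

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]

`%||%` <- function(a, b) if (is.null(a)) b else a

# yaml collapses duplicate mapping keys silently; catch duplicated keys in
# the global block by a line scan of its immediate children
check_duplicate_global_keys <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^global:", lines)
  if (length(start) == 0L) return(invisible(TRUE))
  if (length(start) > 1L)
    stop("duplicate global block in pipeline file", call. = FALSE)
  keys <- character(0)
  for (ln in lines[-seq_len(start)]) {
    if (grepl("^\\S", ln)) break  # next top-level key
    m <- regmatches(ln, regexec("^[ \t]+([A-Za-z_][A-Za-z0-9_]*):", ln))[[1]]
    if (length(m) == 2L) keys <- c(keys, m[2])
  }
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0L)
    stop("duplicate global key(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

# accessors
pipeline_stage <- function(spec, name) {
  for (st in spec$stages) if (st$stage == name) return(st)
  NULL
}

pipeline_stage_index <- function(spec, name) {
  for (i in seq_along(spec$stages)) if (spec$stages[[i]]$stage == name)
    return(i)
  NA_integer_
}

#' Reference pipeline specification
#'
#' The canonical seven-stage training pipeline: label merging, sub-zero-HU
#' fat removal, soft-tissue window (level 50 HU, width 500 HU) with 0-255
#' rescale, 1 mm isotropic trilinear resampling, feature extraction at bin
#' width 25, reference-batch ComBat (reference `"iterative"`), z-score
#' normalization.
#'
#' @param include_labels mask labels merged into the ROI.
#' @param reference_batch ComBat reference batch level.
#' @param seed pipeline seed.
#' @return A `pipeline_spec` in train mode.
#' @export
reference_pipeline <- function(include_labels = c(1L, 2L, 3L),
                               reference_batch = "iterative", seed = 0L) {
  as_pipeline_spec(list(
    global = list(mode = "train", batch_column = "batch",
                  seed = as.integer(seed), name = "reference"),
    stages = list(
      list(stage = "merge_labels", labels = include_labels),
      list(stage = "fat_removal"),
      list(stage = "window"),
      list(stage = "resample"),
      list(stage = "extract"),
      list(stage = "combat", reference = reference_batch),
      list(stage = "zscore")
    )))
}

#' Derive the test-mode pipeline from a trained run
#'
#' Keeps the stage sequence identical and rewrites the fit-type stages to
#' apply-mode, pointing them at the statistics file the training run wrote.
#'
#' @param train_spec the train-mode `pipeline_spec`.
#' @param stats_dir directory of the training run outputs (must contain
#'   `harmonization_stats.json` when the pipeline has fit-type stages).
#' @return A test-mode `pipeline_spec`.
#' @export
derive_test_pipeline <- function(train_spec, stats_dir) {
  stopifnot(inherits(train_spec, "pipeline_spec"))
  if (train_spec$global$mode != "train")
    stop("derive_test_pipeline expects a train-mode pipeline", call. = FALSE)
  spec <- train_spec
  spec$global$mode <- "test"
  has_fit <- FALSE
  stats_path <- file.path(stats_dir, "harmonization_stats.json")
  for (i in seq_along(spec$stages)) {
    if (spec$stages[[i]]$stage %in% c("combat", "zscore")) {
      has_fit <- TRUE
      spec$stages[[i]]$params$stats <- stats_path
    }
  }
  if (has_fit) load_harmonization_stats(stats_path)  # fail fast + schema check
  spec
}

#' Derive the deployment pipeline
#'
#' The deploy pipeline is the test pipeline plus a terminal `predict` stage
#' referencing a serialized classifier; running it on new subjects emits
#' prediction records. The classifier's feature signature must be covered by
#' the features the pipeline extracts.
#'
#' @inheritParams derive_test_pipeline
#' @param model_path serialized classifier (see [save_classifier()]).
#' @param threshold decision threshold of the terminal classification.
#' @return A deploy-mode `pipeline_spec`.
#' @export
derive_deploy_pipeline <- function(train_spec, stats_dir, model_path,
                                   threshold = 0.5) {
  spec <- derive_test_pipeline(train_spec, stats_dir)
  spec$global$mode <- "deploy"
  clf <- load_classifier(model_path)
  stats_path <- file.path(stats_dir, "harmonization_stats.json")
  if (file.exists(stats_path)) {
    stats <- load_harmonization_stats(stats_path)
    missing <- setdiff(clf$feature_list, stats$features)
    if (length(missing) > 0L)
      stop("model consumes feature(s) the pipeline does not extract: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  spec$stages <- c(spec$stages,
                   list(list(stage = "predict",
                             params = list(model = model_path,
                                           threshold = threshold))))
  spec
}
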