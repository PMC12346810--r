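#' Gradient-boosted tree classifier over a feature table
#'
#' Trains a binary gradient-boosted decision-tree classifier (xgboost,
#' logistic objective) on the named feature columns. Training is
#' single-threaded with all stochastic sampling disabled by default, so the
#' model is fully determined by the seed, the hyperparameters and the input
#' table — a requirement for deployment reproducibility, not an
#' optimization choice.
#'
#' @param table feature table with a 0/1 `label` column.
#' @param feature_list character vector of feature columns the model
#'   consumes (the published model's signature; defaults are set by
#'   [default_model_features()]).
#' @param hyperparams list of hyperparameters; see
#'   [default_hyperparams()].
#' @param seed integer seed recorded in the model and passed to the
#'   learner.
#' @return A `radpipe_classifier` object.
#' @export
train_classifier <- function(table, feature_list = default_model_features(),
                             hyperparams = default_hyperparams(), seed = 0L) {
  table <- validate_feature_table(table)
  if (!"label" %in% names(table) || anyNA(table$label))
    stop("label column absent or incomplete", call. = FALSE)
  missing <- setdiff(feature_list, names(table))
  if (length(missing) > 0L)
    stop("feature(s) missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  y <- as.numeric(table$label)
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; cannot train", call. = FALSE)
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  X <- as.matrix(table[, feature_list, drop = FALSE])
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  params <- list(objective = "binary:logistic",
                 eta = hp$eta, max_depth = hp$max_depth,
                 min_child_weight = hp$min_child_weight,
                 lambda = hp$lambda,
                 subsample = hp$subsample, colsample_bytree = hp$colsample,
                 tree_method = "exact", nthread = 1L, seed = as.integer(seed))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$nrounds, verbose = 0)
  structure(list(booster = booster, feature_list = feature_list,
                 hyperparams = hp, seed = as.integer(seed)),
            class = "radpipe_classifier")
}

#' Default classifier hyperparameters
#'
#' The original model's hyperparameters are not published; these defaults
#' are a documented stand-in sized for small tabular radiomics problems.
#' Sampling fractions are 1 so training is deterministic.
#'
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function() {
  list(nrounds = 150L, eta = 0.1, max_depth = 3L, min_child_weight = 1,
       lambda = 1, subsample = 1, colsample = 1)
}

#' Default model feature signature
#'
#' The deployed model consumes a configured list of 10 features drawn from
#' the extracted families (the identities of the original model's features
#' are external configuration, not derivable here).
#'
#' @return Character vector of 10 feature names.
#' @export
default_model_features <- function() {
  c("first_order.mean", "first_order.entropy", "first_order.p90",
    "shape.volume_mm3", "glcm.contrast", "glcm.joint_entropy",
    "glcm.correlation", "glrlm.lre", "glrlm.run_pct", "glszm.zone_pct")
}

#' Predict case probabilities
#'
#' @param classifier a `radpipe_classifier`.
#' @param table feature table containing the model's feature columns.
#' @return A prediction-record `data.frame` (`subject_id`, `probability`,
#'   `predicted_class` = `NA` until [classify_records()] is applied,
#'   `true_label` when a label column is present), in table row order.
#' @export
predict_proba <- function(classifier, table) {
  stopifnot(inherits(classifier, "radpipe_classifier"))
  table <- validate_feature_table(table)
  missing <- setdiff(classifier$feature_list, names(table))
  if (length(missing) > 0L)
    stop("feature(s) missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(table[, classifier$feature_list, drop = FALSE])
  p <- stats::predict(classifier$booster, xgboost::xgb.DMatrix(X))
  data.frame(subject_id = table$subject_id,
             probability = as.numeric(p),
             predicted_class = NA_integer_,
             true_label = if ("label" %in% names(table))
               as.integer(table$label) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Threshold probabilities into classes
#'
#' `predicted_class = 1` when `probability >= threshold` (a probability
#' exactly at the threshold is called a case; the tie rule is configurable
#' only through the threshold itself).
#'
#' @param records prediction records from [predict_proba()].
#' @param threshold decision threshold (default 0.5).
#' @return The records with `predicted_class` filled in.
#' @export
classify_records <- function(records, threshold = 0.5) {
  records$predicted_class <- as.integer(records$probability >= threshold)
  records
}

#' Save / load a classifier
#'
#' The booster is stored in the learner's native format next to a JSON
#' sidecar (`<path>.meta.json`) carrying the feature signature,
#' hyperparameters and seed. A reloaded model produces identical
#' probabilities.
#'
#' @param classifier a `radpipe_classifier`.
#' @param path model file path (e.g. `model.ubj`).
#' @return `save_classifier()`: `path` invisibly; `load_classifier()`: the
#'   classifier.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "radpipe_classifier"))
  xgboost::xgb.save(classifier$booster, path)
  jsonlite::write_json(list(feature_list = classifier$feature_list,
                            hyperparams = classifier$hyperparams,
                            seed = classifier$seed),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("model metadata not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(list(booster = xgboost::xgb.load(path),
                 feature_list = meta$feature_list,
                 hyperparams = as.list(meta$hyperparams),
                 seed = as.integer(meta$seed)),
            class = "radpipe_classifier")
}
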