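#' Fit reference-batch ComBat harmonization
#'
#' Parametric empirical-Bayes location/scale harmonization of feature values
#' across batches (here: reconstruction kernels), in reference-batch mode:
#' every feature is standardized by the reference batch's location and scale,
#' per-batch location (`gamma`) and scale (`delta`) effects are estimated and
#' shrunk toward batch-level priors (normal for `gamma`, inverse-gamma for
#' `delta^2`) by the iterative parametric EB update (relative change below
#' `conv`), and all parameters are stored so the identical transform can be
#' replayed on new subjects. The reference batch is, by construction, not
#' adjusted (`gamma* = 0`, `delta* = 1`).
#'
#' No outcome or other biological covariate enters the model; the design is
#' batch-only (a covariate hook is deliberately absent from the model file so
#' deployment needs nothing but the batch label).
#'
#' @param table a feature table (see [read_feature_table()]).
#' @param batch_column name of the categorical batch column.
#' @param reference batch level to harmonize toward.
#' @param covariates covariate column names (excluded from features).
#' @param conv convergence threshold of the EB iteration.
#' @param max_iter iteration cap.
#' @return A `combat_model` object.
#' @export
fit_combat <- function(table, batch_column = "batch", reference,
                       covariates = c("batch", "split", "label"),
                       conv = 1e-4, max_iter = 1000L) {
  table <- validate_feature_table(table, covariates)
  if (!batch_column %in% names(table))
    stop("batch column not found: ", batch_column, call. = FALSE)
  batch <- as.character(table[[batch_column]])
  levels <- sort(unique(batch))
  if (length(levels) < 2L)
    stop("ComBat needs at least 2 batches; found ", length(levels),
         call. = FALSE)
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop("singleton (or empty) batch: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  if (!reference %in% levels)
    stop("reference batch not present: ", reference, call. = FALSE)
  feats <- feature_columns(table, covariates)
  if (length(feats) < 2L)
    stop("ComBat priors need at least 2 features", call. = FALSE)
  X <- t(as.matrix(table[, feats, drop = FALSE]))  # features x samples

  ref_idx <- which(batch == reference)
  alpha <- rowMeans(X[, ref_idx, drop = FALSE])
  var_pooled <- rowMeans((X[, ref_idx, drop = FALSE] - alpha)^2)  # N denom
  if (any(var_pooled == 0))
    stop("constant feature within the reference batch: ",
         paste(feats[var_pooled == 0], collapse = ", "), call. = FALSE)
  Z <- (X - alpha) / sqrt(var_pooled)

  nb <- length(levels)
  nf <- length(feats)
  gamma_hat <- delta_hat <- gamma_star <- delta_star <-
    matrix(NA_real_, nb, nf, dimnames = list(levels, feats))
  gamma_bar <- tau_sq <- a_prior <- b_prior <- stats::setNames(
    numeric(nb), levels)
  for (b in seq_len(nb)) {
    idx <- which(batch == levels[b])
    Zb <- Z[, idx, drop = FALSE]
    gamma_hat[b, ] <- rowMeans(Zb)
    delta_hat[b, ] <- apply(Zb, 1, stats::var)  # sample variance (n - 1)
    gamma_bar[b] <- mean(gamma_hat[b, ])
    tau_sq[b] <- stats::var(gamma_hat[b, ])
    m <- mean(delta_hat[b, ])
    s2 <- stats::var(delta_hat[b, ])
    a_prior[b] <- (2 * s2 + m^2) / s2
    b_prior[b] <- (m * s2 + m^3) / s2
    eb <- combat_it_sol(Zb, gamma_hat[b, ], delta_hat[b, ], gamma_bar[b],
                        tau_sq[b], a_prior[b], b_prior[b], conv, max_iter)
    gamma_star[b, ] <- eb$gamma
    delta_star[b, ] <- eb$delta
  }
  gamma_star[reference, ] <- 0
  delta_star[reference, ] <- 1

  structure(list(batch_levels = levels, reference = reference,
                 features = feats, alpha = alpha, var_pooled = var_pooled,
                 gamma_star = gamma_star, delta_star = delta_star,
                 gamma_bar = gamma_bar, tau_sq = tau_sq,
                 a_prior = a_prior, b_prior = b_prior,
                 batch_column = batch_column),
            class = "combat_model")
}

# parametric EB iteration: posterior mean for gamma given current delta,
# posterior variance for delta given current gamma, to joint convergence
combat_it_sol <- function(Zb, g_hat, d_hat, g_bar, t2, a, b, conv, max_iter) {
  n <- ncol(Zb)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((Zb - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (is.finite(change) && change < conv) break
  }
  list(gamma = g_new, delta = d_new)
}

#' Apply a fitted ComBat model
#'
#' Adjusts each subject's features with the frozen batch parameters:
#' `y* = sigma_f * (z - gamma*_bf) / sqrt(delta*_bf) + alpha_f` on the
#' reference-standardized scale `z`. Subjects in the reference batch pass
#' through numerically unchanged. Deterministic: the model carries
#' everything, so repeated application to the same table is bit-identical.
#'
#' @param table a feature table whose batch levels were all seen at fit time.
#' @param model a `combat_model` from [fit_combat()].
#' @param covariates covariate column names.
#' @return The adjusted feature table (same shape and column order).
#' @export
apply_combat <- function(table, model,
                         covariates = c("batch", "split", "label")) {
  stopifnot(inherits(model, "combat_model"))
  table <- validate_feature_table(table, covariates)
  batch <- as.character(table[[model$batch_column]])
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen) > 0L)
    stop("unseen batch level(s): ", paste(unseen, collapse = ", "),
         "; deployment must declare all batches at fit time", call. = FALSE)
  missing <- setdiff(model$features, names(table))
  if (length(missing) > 0L)
    stop("feature(s) missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- t(as.matrix(table[, model$features, drop = FALSE]))
  sigma <- sqrt(model$var_pooled)
  for (b in setdiff(model$batch_levels, model$reference)) {
    idx <- which(batch == b)
    if (length(idx) == 0L) next
    Z <- (X[, idx, drop = FALSE] - model$alpha) / sigma
    Z <- (Z - model$gamma_star[b, ]) / sqrt(model$delta_star[b, ])
    X[, idx] <- Z * sigma + model$alpha
  }
  table[, model$features] <- t(X)
  table
}

#' Fit z-score normalization statistics
#'
#' Per-feature mean and sample standard deviation (`N - 1` denominator),
#' intended to be computed on the training split after ComBat.
#'
#' @inheritParams fit_combat
#' @return A `zscore_stats` object.
#' @export
fit_zscore <- function(table, covariates = c("batch", "split", "label")) {
  table <- validate_feature_table(table, covariates)
  if (nrow(table) < 2L)
    stop("z-score fitting needs at least 2 subjects", call. = FALSE)
  feats <- feature_columns(table, covariates)
  X <- as.matrix(table[, feats, drop = FALSE])
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd == 0))
    stop("constant feature(s): ", paste(feats[sd == 0], collapse = ", "),
         call. = FALSE)
  structure(list(features = feats, mean = mu, sd = sd),
            class = "zscore_stats")
}

#' Apply frozen z-score statistics
#'
#' `(x - mean_f) / sd_f` per cell. Applying the statistics to their own
#' fitting table yields column means 0 and standard deviations 1.
#'
#' @param table a feature table containing every fitted feature.
#' @param stats a `zscore_stats` from [fit_zscore()].
#' @param covariates covariate column names.
#' @return The normalized feature table.
#' @export
apply_zscore <- function(table, stats,
                         covariates = c("batch", "split", "label")) {
  stopifnot(inherits(stats, "zscore_stats"))
  table <- validate_feature_table(table, covariates)
  missing <- setdiff(stats$features, names(table))
  if (length(missing) > 0L)
    stop("feature(s) missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (f in stats$features)
    table[[f]] <- (table[[f]] - stats$mean[[f]]) / stats$sd[[f]]
  table
}

#' Persist / reload harmonization statistics
#'
#' The harmonization statistics file is a single JSON document holding the
#' full ComBat model, the z-score statistics, the feature-name list and the
#' extraction config hash. Numbers are serialized with 17 significant digits
#' so doubles round-trip exactly; reloading and applying is bit-identical to
#' applying the in-memory objects. This file (plus the pipeline file and the
#' classifier) is everything an external site needs to process new subjects.
#'
#' @param combat a `combat_model` (or `NULL` if the pipeline has no ComBat
#'   stage).
#' @param zscore a `zscore_stats` (or `NULL`).
#' @param features character vector of feature names in table order.
#' @param config_hash provenance hash of the extraction configuration.
#' @param path JSON file path.
#' @return `save_harmonization_stats()`: `path`, invisibly;
#'   `load_harmonization_stats()`: a list with elements `combat`, `zscore`,
#'   `features`, `config_hash`.
#' @export
save_harmonization_stats <- function(combat, zscore, features, config_hash,
                                     path) {
  doc <- list(format = "radpipe_harmonization_stats",
              version = 1L,
              features = features,
              config_hash = config_hash,
              combat = if (!is.null(combat)) combat_to_list(combat),
              zscore = if (!is.null(zscore))
                list(features = zscore$features,
                     mean = unname(zscore$mean), sd = unname(zscore$sd)))
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_harmonization_stats
#' @export
load_harmonization_stats <- function(path) {
  if (!file.exists(path))
    stop("harmonization statistics file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "radpipe_harmonization_stats"))
    stop("not a harmonization statistics file: ", path, call. = FALSE)
  combat <- if (!is.null(doc$combat)) combat_from_list(doc$combat)
  zscore <- if (!is.null(doc$zscore)) {
    structure(list(features = doc$zscore$features,
                   mean = stats::setNames(doc$zscore$mean, doc$zscore$features),
                   sd = stats::setNames(doc$zscore$sd, doc$zscore$features)),
              class = "zscore_stats")
  }
  list(combat = combat, zscore = zscore, features = doc$features,
       config_hash = doc$config_hash)
}

combat_to_list <- function(m) {
  list(batch_levels = m$batch_levels, reference = m$reference,
       features = m$features, batch_column = m$batch_column,
       alpha = unname(m$alpha), var_pooled = unname(m$var_pooled),
       gamma_star = unname(m$gamma_star), delta_star = unname(m$delta_star),
       gamma_bar = unname(m$gamma_bar), tau_sq = unname(m$tau_sq),
       a_prior = unname(m$a_prior), b_prior = unname(m$b_prior))
}

combat_from_list <- function(l) {
  dn <- list(l$batch_levels, l$features)
  structure(list(batch_levels = l$batch_levels, reference = l$reference,
                 features = l$features,
                 alpha = stats::setNames(l$alpha, l$features),
                 var_pooled = stats::setNames(l$var_pooled, l$features),
                 gamma_star = matrix(l$gamma_star, length(l$batch_levels),
                                     dimnames = dn),
                 delta_star = matrix(l$delta_star, length(l$batch_levels),
                                     dimnames = dn),
                 gamma_bar = stats::setNames(l$gamma_bar, l$batch_levels),
                 tau_sq = stats::setNames(l$tau_sq, l$batch_levels),
                 a_prior = stats::setNames(l$a_prior, l$batch_levels),
                 b_prior = stats::setNames(l$b_prior, l$batch_levels),
                 batch_column = l$batch_column),
            class = "combat_model")
}
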