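#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' case scores above a random control, with half credit for ties. Exact and
#' identical to pair enumeration, with no curve interpolation.
#'
#' @param records prediction records with `probability` and `true_label`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(records) {
  y <- records$true_label
  p <- records$probability
  if (anyNA(y) || anyNA(p)) stop("labels or probabilities missing", call. = FALSE)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(p)  # midranks handle ties with half credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based confusion metrics
#'
#' Accuracy, sensitivity, specificity, positive predictive value and
#' F1-score from the 2x2 table of `predicted_class` against `true_label`.
#' A metric whose denominator is zero (e.g. PPV with no predicted
#' positives) is reported as `NA`, never as 0.
#'
#' @param records classified prediction records.
#' @return Named numeric vector (`accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `f1`).
#' @export
confusion_metrics <- function(records) {
  y <- records$true_label
  k <- records$predicted_class
  if (anyNA(y) || anyNA(k)) stop("labels or classes missing", call. = FALSE)
  tp <- sum(k == 1 & y == 1)
  tn <- sum(k == 0 & y == 0)
  fp <- sum(k == 1 & y == 0)
  fn <- sum(k == 0 & y == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  ppv <- ratio(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_ else
    2 * sens * ppv / (sens + ppv)
  c(accuracy = ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = sens,
    specificity = ratio(tn, tn + fp),
    ppv = ppv,
    f1 = f1)
}

#' Cohen's kappa agreement
#'
#' Chance-corrected agreement between two classification vectors, with
#' expected agreement from the marginal products. When both raters are
#' constant and identical (`p_e = 1`), kappa is defined as 1.
#'
#' @param classes_a,classes_b equal-length classification vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(classes_a, classes_b) {
  if (length(classes_a) != length(classes_b))
    stop("classification vectors differ in length", call. = FALSE)
  if (length(classes_a) == 0L) stop("empty classifications", call. = FALSE)
  a <- as.character(classes_a)
  b <- as.character(classes_b)
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  po <- mean(a == b)
  pe <- sum((tabulate(match(a, lev), length(lev)) / n) *
            (tabulate(match(b, lev), length(lev)) / n))
  if (pe == 1) return(if (po == 1) 1 else (po - pe))  # both raters constant
  (po - pe) / (1 - pe)
}

#' Agreement statistics between two prediction sets
#'
#' Quantifies how far two pipelines/models diverge on the same subjects:
#' percentage of classification discordance, and mean and sample SD of the
#' absolute probability difference — overall and within each true-label
#' group (control, case).
#'
#' @param records_a,records_b classified prediction records for the same
#'   subjects in the same order.
#' @return A `data.frame` with rows `overall`, `control`, `case` and
#'   columns `n`, `discordance_pct`, `prob_diff_mean`, `prob_diff_sd`,
#'   `kappa`.
#' @export
agreement_stats <- function(records_a, records_b) {
  if (!identical(records_a$subject_id, records_b$subject_id))
    stop("prediction sets cover different subjects or orders", call. = FALSE)
  groups <- list(overall = rep(TRUE, nrow(records_a)),
                 control = records_a$true_label == 0,
                 case = records_a$true_label == 1)
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]] & !is.na(groups[[g]])
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(group = g, n = 0L, discordance_pct = NA_real_,
                        prob_diff_mean = NA_real_, prob_diff_sd = NA_real_,
                        kappa = NA_real_))
    d <- abs(records_a$probability[sel] - records_b$probability[sel])
    ka <- records_a$predicted_class[sel]
    kb <- records_b$predicted_class[sel]
    data.frame(group = g, n = n,
               discordance_pct = 100 * mean(ka != kb),
               prob_diff_mean = mean(d),
               prob_diff_sd = if (n > 1L) stats::sd(d) else 0,
               kappa = cohen_kappa(ka, kb))
  })
  do.call(rbind, rows)
}

#' Full evaluation report of one prediction set
#'
#' @param records classified prediction records with true labels.
#' @return Named numeric vector: `auc` plus the [confusion_metrics()].
#' @export
evaluation_report <- function(records) {
  c(auc = roc_auc(records), confusion_metrics(records))
}
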