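# linearly separable feature table for classifier tests
make_separable_table <- function(seed, n = 80, nf = 5) {
  set.seed(seed)
  label <- rep(0:1, n / 2)
  X <- matrix(stats::rnorm(n * nf), n, nf)
  X[, 1] <- X[, 1] + 6 * label  # wide margin on the first feature
  colnames(X) <- paste0("f", seq_len(nf))
  data.frame(subject_id = sprintf("s%03d", seq_len(n)), X,
             batch = "iterative", split = "train", label = label,
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("training separates a separable cohort and is seed-deterministic", {
  tab <- make_separable_table(31)
  m <- train_classifier(tab, paste0("f", 1:5), seed = 1)
  pr <- classify_records(predict_proba(m, tab))
  expect_equal(roc_auc(pr), 1.0)

  m2 <- train_classifier(tab, paste0("f", 1:5), seed = 1)
  probe <- make_separable_table(32, n = 20)
  expect_identical(predict_proba(m, probe)$probability,
                   predict_proba(m2, probe)$probability)

  expect_error(train_classifier(tab, c("f1", "nope")), "missing")
  expect_error(train_classifier(tab[, setdiff(names(tab), "label")],
                                paste0("f", 1:5)), "label")
  single <- tab; single$label <- 0L
  expect_error(train_classifier(single, paste0("f", 1:5)), "single class")
})

test_that("probabilities are bounded, order-preserving and survive serialization", {
  dir <- withr::local_tempdir()
  tab <- make_separable_table(33)
  m <- train_classifier(tab, paste0("f", 1:5), seed = 2)
  probe <- make_separable_table(34, n = 1000)
  p <- predict_proba(m, probe)
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  expect_identical(p$subject_id, probe$subject_id)

  perm <- probe[sample(nrow(probe)), ]
  pp <- predict_proba(m, perm)
  expect_identical(pp$probability, p$probability[match(perm$subject_id,
                                                       p$subject_id)])

  path <- file.path(dir, "model.ubj")
  save_classifier(m, path)
  m3 <- load_classifier(path)
  expect_identical(predict_proba(m3, probe)$probability, p$probability)
  expect_identical(m3$feature_list, m$feature_list)
})

test_that("thresholding uses the >= tie rule", {
  rec <- data.frame(subject_id = c("a", "b", "c"),
                    probability = c(0.5, 0.49, 0.51),
                    predicted_class = NA_integer_, true_label = c(1L, 0L, 1L))
  out <- classify_records(rec)
  expect_identical(out$predicted_class, c(1L, 0L, 1L))
  expect_identical(classify_records(rec, threshold = 0)$predicted_class,
                   c(1L, 1L, 1L))
})

test_that("AUC equals brute-force pair counting", {
  rec <- data.frame(subject_id = letters[1:4],
                    probability = c(0.9, 0.4, 0.6, 0.1),
                    predicted_class = NA_integer_,
                    true_label = c(1L, 1L, 0L, 0L))
  expect_equal(roc_auc(rec), 0.75)  # 3 of 4 pairs concordant

  sep <- data.frame(subject_id = letters[1:4],
                    probability = c(0.9, 0.8, 0.2, 0.1),
                    predicted_class = NA_integer_,
                    true_label = c(1L, 1L, 0L, 0L))
  expect_equal(roc_auc(sep), 1)
  ties <- transform(sep, probability = 0.5)
  expect_equal(roc_auc(ties), 0.5)

  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:200, 1)
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    p <- round(stats::runif(n), 2)  # rounding forces ties
    rec <- data.frame(subject_id = as.character(seq_len(n)), probability = p,
                      predicted_class = NA_integer_, true_label = y)
    stopifnot(abs(roc_auc(rec) - oracle_auc(y, p)) < 1e-12)
  }
  expect_error(roc_auc(transform(sep, true_label = 1L)), "both classes")
  succeed()
})

test_that("confusion metrics match the hand 2x2 table and the brute-force oracle", {
  rec <- data.frame(subject_id = letters[1:4],
                    probability = c(0.9, 0.9, 0.1, 0.1),
                    predicted_class = c(1L, 1L, 0L, 0L),
                    true_label = c(1L, 0L, 1L, 0L))
  expect_equal(unname(confusion_metrics(rec)), rep(0.5, 5))

  perfect <- transform(rec, predicted_class = true_label)
  expect_equal(unname(confusion_metrics(perfect)), rep(1, 5))

  nopos <- transform(rec, predicted_class = 0L)
  cm <- confusion_metrics(nopos)
  expect_true(is.na(cm[["ppv"]]))  # undefined, not zero

  for (seed in 1:500) {
    set.seed(seed)
    n <- sample(2:60, 1)
    truth <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    rec <- data.frame(subject_id = as.character(seq_len(n)),
                      probability = 0.5, predicted_class = pred,
                      true_label = truth)
    got <- confusion_metrics(rec)
    want <- oracle_confusion(pred, truth)
    for (k in names(want))
      stopifnot(identical(is.na(got[[k]]), is.na(want[[k]])) &&
                (is.na(want[[k]]) || abs(got[[k]] - want[[k]]) < 1e-12))
  }
  succeed()
})

test_that("Cohen's kappa matches hand cases and is symmetric", {
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  expect_equal(cohen_kappa(c(1, 1, 1), c(1, 1, 1)), 1)  # both constant, equal

  set.seed(35)
  a <- sample(0:1, 10000, replace = TRUE)
  b <- sample(0:1, 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)  # independent raters
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
  expect_error(cohen_kappa(1:3, 1:4), "length")
})

test_that("agreement statistics quantify discordance and probability drift", {
  a <- data.frame(subject_id = c("x", "y"), probability = c(0.2, 0.8),
                  predicted_class = c(0L, 1L), true_label = c(0L, 1L))
  b <- data.frame(subject_id = c("x", "y"), probability = c(0.4, 0.6),
                  predicted_class = c(0L, 1L), true_label = c(0L, 1L))
  st <- agreement_stats(a, b)
  ov <- st[st$group == "overall", ]
  expect_equal(ov$prob_diff_mean, 0.2)
  expect_equal(ov$prob_diff_sd, 0)
  expect_equal(ov$discordance_pct, 0)

  self <- agreement_stats(a, a)
  expect_true(all(self$discordance_pct == 0))
  expect_true(all(self$prob_diff_mean == 0))
  expect_true(all(self$kappa == 1))

  c3 <- data.frame(subject_id = c("1", "2", "3"),
                   probability = c(0.9, 0.2, 0.8),
                   predicted_class = c(1L, 0L, 1L), true_label = c(1L, 0L, 1L))
  d3 <- transform(c3, predicted_class = c(1L, 1L, 1L))
  expect_equal(agreement_stats(c3, d3)$discordance_pct[1], 100 / 3)

  expect_error(agreement_stats(a, transform(b, subject_id = c("x", "z"))),
               "different subjects")
})
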