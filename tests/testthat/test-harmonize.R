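# small synthetic feature tables for harmonization tests
make_batch_table <- function(seed, n_per_batch = 50, nf = 10, shift = 0,
                             scale = 1) {
  set.seed(seed)
  n <- 2 * n_per_batch
  batch <- rep(c("iterative", "standard"), each = n_per_batch)
  X <- matrix(stats::rnorm(n * nf), n, nf)
  X[batch == "standard", ] <- X[batch == "standard", ] * scale + shift
  colnames(X) <- paste0("f", seq_len(nf))
  data.frame(subject_id = sprintf("s%03d", seq_len(n)), X, batch = batch,
             split = "train", label = rep(0:1, n / 2),
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("ComBat removes an injected batch mean shift", {
  tab <- make_batch_table(seed = 21, shift = 5)
  model <- fit_combat(tab, "batch", "iterative")
  adj <- apply_combat(tab, model)
  for (f in paste0("f", 1:10)) {
    gap <- abs(mean(adj[[f]][adj$batch == "iterative"]) -
               mean(adj[[f]][adj$batch == "standard"]))
    expect_lt(gap, 0.2)
  }
})

test_that("reference-batch subjects pass through ComBat unchanged", {
  tab <- make_batch_table(seed = 22, shift = 3, scale = 1.5)
  model <- fit_combat(tab, "batch", "iterative")
  adj <- apply_combat(tab, model)
  ref <- tab$batch == "iterative"
  expect_equal(as.matrix(adj[ref, paste0("f", 1:10)]),
               as.matrix(tab[ref, paste0("f", 1:10)]), tolerance = 1e-8)
  # and each feature's reference-batch mean/variance is preserved
  for (f in c("f1", "f5")) {
    expect_equal(mean(adj[[f]][ref]), mean(tab[[f]][ref]), tolerance = 1e-6)
    expect_equal(stats::var(adj[[f]][ref]), stats::var(tab[[f]][ref]),
                 tolerance = 1e-6)
  }
})

test_that("ComBat agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  tab <- make_batch_table(seed = 23, shift = 2, scale = 1.7, n_per_batch = 20)
  model <- fit_combat(tab, "batch", "iterative")
  adj <- apply_combat(tab, model)
  dat <- t(as.matrix(tab[, paste0("f", 1:10)]))
  want <- suppressMessages(sva::ComBat(dat, batch = tab$batch,
                                       ref.batch = "iterative"))
  expect_equal(t(as.matrix(adj[, paste0("f", 1:10)])), want,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("ComBat preconditions: batches, reference, constant features", {
  tab <- make_batch_table(seed = 24)
  one <- tab[tab$batch == "iterative", ]
  expect_error(fit_combat(one, "batch", "iterative"), "at least 2 batches")
  tiny <- tab[c(1, 51, 52), ]  # singleton reference batch
  expect_error(fit_combat(tiny, "batch", "iterative"), "singleton")
  expect_error(fit_combat(tab, "batch", "sharp"), "reference batch")
  tab$f1 <- ifelse(tab$batch == "iterative", 1, tab$f1)
  expect_error(fit_combat(tab, "batch", "iterative"),
               "constant feature within the reference")
  expect_error(apply_combat(make_batch_table(25),
                            fit_combat(tab[, -2], "batch", "iterative")),
               NA)
})

test_that("apply_combat rejects unseen batch levels by name", {
  tab <- make_batch_table(seed = 26)
  model <- fit_combat(tab, "batch", "iterative")
  tab$batch[1] <- "sharp"
  expect_error(apply_combat(tab, model), "sharp")
})

test_that("z-score statistics match hand values and self-normalize", {
  tab <- data.frame(subject_id = c("a", "b", "c"), f1 = c(1, 2, 3),
                    f2 = c(10, 30, 20), batch = "x", split = "train",
                    label = 0L, stringsAsFactors = FALSE)
  zs <- fit_zscore(tab)
  expect_equal(zs$mean[["f1"]], 2)
  expect_equal(zs$sd[["f1"]], 1)  # sample SD, N - 1
  norm <- apply_zscore(tab, zs)
  expect_equal(colMeans(as.matrix(norm[, c("f1", "f2")])), c(f1 = 0, f2 = 0),
               tolerance = 1e-10)
  expect_equal(apply(as.matrix(norm[, c("f1", "f2")]), 2, stats::sd),
               c(f1 = 1, f2 = 1), tolerance = 1e-10)

  # single new subject at the mean maps to 0; one SD above maps to 1
  new <- data.frame(subject_id = "z", f1 = 2, f2 = 20 + zs$sd[["f2"]],
                    batch = "x", split = "new", label = NA_integer_,
                    stringsAsFactors = FALSE)
  out <- apply_zscore(new, zs)
  expect_equal(out$f1, 0)
  expect_equal(out$f2, 1)

  tab$f1 <- 5
  expect_error(fit_zscore(tab), "constant feature.*f1")
})

test_that("separate split fitting (leakage variant) differs from frozen statistics", {
  train <- make_batch_table(seed = 27)
  test <- make_batch_table(seed = 28, shift = 1)  # shifted distribution
  test$split <- "test"
  zs_train <- fit_zscore(train)
  frozen <- apply_zscore(test, zs_train)
  refit <- apply_zscore(test, fit_zscore(test))
  expect_gt(max(abs(as.matrix(frozen[, paste0("f", 1:10)]) -
                    as.matrix(refit[, paste0("f", 1:10)]))), 0.01)
})

test_that("the persisted statistics file replays the deployment chain bit-identically", {
  dir <- withr::local_tempdir()
  train <- make_batch_table(seed = 29, shift = 4, scale = 1.3)
  model <- fit_combat(train, "batch", "iterative")
  zs <- fit_zscore(apply_combat(train, model))
  path <- file.path(dir, "stats.json")
  save_harmonization_stats(model, zs, paste0("f", 1:10), "cfg", path)
  re <- load_harmonization_stats(path)

  expect_identical(re$combat$gamma_star, model$gamma_star)
  expect_identical(re$combat$delta_star, model$delta_star)
  expect_identical(re$zscore$mean, zs$mean)
  expect_identical(re$zscore$sd, zs$sd)

  held_out <- make_batch_table(seed = 30)[1:3, ]
  direct <- apply_zscore(apply_combat(held_out, model), zs)
  reloaded <- apply_zscore(apply_combat(held_out, re$combat), re$zscore)
  expect_identical(direct, reloaded)
})
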