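test_that("confusion metrics match their textbook definitions", {
  y <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(1, 9), 0, rep(0, 8), 1, 1)   # tp 9, fn 1, tn 8, fp 2
  r <- confusion_and_metrics(y, p)
  expect_equal(c(r$tp, r$fn, r$tn, r$fp), c(9, 1, 8, 2))
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$accuracy, 0.85)
  expect_equal(r$precision, 9 / 11)
  expect_equal(r$f1, 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9))
  expect_length(r$undefined, 0)

  perfect <- confusion_and_metrics(y, y)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "f1")]) == 1))
  inverted <- confusion_and_metrics(y, 1 - y)
  expect_equal(inverted$accuracy, 0)
})

test_that("metric identities hold on random confusion instances", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(20:200, 1)
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      p <- ifelse(runif(n) < 0.3, 1 - y, y)   # noisy predictions
      if (length(unique(y)) < 2 || length(unique(p)) < 2) next
      r <- confusion_and_metrics(y, p)
      expect_equal(r$tp + r$fp + r$tn + r$fn, n)
      expect_equal(r$sensitivity, r$tp / (r$tp + r$fn))
      expect_equal(r$specificity, r$tn / (r$tn + r$fp))
      expect_equal(r$accuracy, (r$tp + r$tn) / n)
      expect_equal(r$f1,
                   2 * r$precision * r$sensitivity /
                     (r$precision + r$sensitivity))
    }
  })
})

test_that("single-class truth flags undefined metrics instead of zeroing", {
  r <- confusion_and_metrics(rep(1, 5), c(1, 1, 0, 1, 1))
  expect_true(is.na(r$specificity))
  expect_true("specificity" %in% r$undefined)
  expect_false(is.na(r$sensitivity))
  ra <- roc_auc(rep(0, 6), runif(6))
  expect_true(is.na(ra$auc))
  expect_identical(attr(ra, "undefined"), "auc")
  er <- evaluate_predictions(rep(1, 4), c(0.9, 0.8, 0.7, 0.6))
  expect_true("auc" %in% er$undefined)
})

test_that("AUC equals the exhaustive pairwise-comparison oracle", {
  pairwise_auc <- function(y, s) {
    pos <- s[y == 1]
    neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(10:100, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- if (i %% 3 == 0) {
        sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
      } else {
        runif(n)
      }
      expect_equal(roc_auc(y, s)$auc, pairwise_auc(y, s),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on random instances", {
  withr::with_seed(6, {
    for (i in 1:5) {
      y <- rbinom(60, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- runif(60) + 0.4 * y
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
    }
  })
})

test_that("ROC endpoints and separability limits are exact", {
  y <- c(0, 0, 1, 1)
  ra <- roc_auc(y, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(ra$auc, 1)
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[1], 0)
  expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  # label-independent scores drift to 0.5
  withr::with_seed(2, {
    y2 <- rbinom(10000, 1, 0.5)
    s2 <- runif(10000)
  })
  expect_lt(abs(roc_auc(y2, s2)$auc - 0.5), 0.02)
})

test_that("pooled multiple-subject evaluation is reproducible and sane", {
  ws <- desk_windows(n_subjects = 2)
  mc <- desk_model_config()
  tc <- desk_train_config(max_epochs = 2L, patience_epochs = 1L)
  r1 <- run_multisubject(ws, mc, tc, seed = 1)
  r2 <- run_multisubject(ws, mc, tc, seed = 1)
  expect_identical(glance(r1$report), glance(r2$report))
  rep <- r1$report
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, rep$n)
  expect_equal(rep$n, n_windows(r1$splits$test))
  # strict-reproduction mode balances the pool before splitting
  r3 <- run_multisubject(ws, mc, tc, seed = 1, balance_before_split = TRUE)
  y_all <- unlist(lapply(r3$splits, function(s) s$meta$y))
  expect_equal(sum(y_all == 0), sum(y_all == 1))
  expect_lte(abs(sum(r3$splits$test$meta$y == 1) -
                   sum(r3$splits$test$meta$y == 0)), 1L)
  expect_seiz_error(
    run_multisubject(subset_windows(ws, which(ws$meta$subject_id == "S01")),
                     mc, tc), ">= 2 subjects")
})

test_that("LOPO keeps the held-out subject out of training in every fold", {
  ws <- desk_windows(n_subjects = 3)
  mc <- desk_model_config()
  tc <- desk_train_config(max_epochs = 2L, patience_epochs = 1L)
  res <- run_lopo(ws, mc, tc, seed = 2, adapt_method = "none")
  expect_equal(nrow(res$per_subject), 3L)
  expect_setequal(res$per_subject$subject_id, unique(ws$meta$subject_id))
  # summary is recomputable from the per-subject rows (population sd)
  for (m in c("f1", "accuracy", "auc")) {
    v <- res$per_subject[[m]]
    expect_equal(res$summary$mean[res$summary$metric == m], mean(v))
    expect_equal(res$summary$sd[res$summary$metric == m],
                 sqrt(mean((v - mean(v))^2)))
  }
  # hash-intersection leakage check, fold by fold
  sigs <- window_signatures(ws)
  for (s in res$per_subject$subject_id) {
    test_sigs <- sigs[ws$meta$subject_id == s]
    train_sigs <- sigs[ws$meta$subject_id != s]
    expect_length(intersect(test_sigs, train_sigs), 0L)
    expect_equal(res$reports[[s]]$n, sum(ws$meta$subject_id == s))
  }
})

test_that("the comparison grid has the published layout and matched seeds", {
  ws <- desk_windows(n_subjects = 2)
  mc <- desk_model_config()
  tc <- desk_train_config(max_epochs = 2L, patience_epochs = 1L)
  cmp <- compare_adaptation(ws, mc, tc, seed = 3, methods = c("dann"))
  expect_setequal(unique(cmp$table$method), c("none", "dann"))
  expect_equal(nrow(cmp$table), 2 * (2 + 1))  # subjects + average row
  expect_true(all(c("f1", "accuracy", "auc") %in% names(cmp$table)))
  avg <- cmp$table[cmp$table$subject_id == "average" &
                     cmp$table$method == "none", ]
  ps <- cmp$table[cmp$table$subject_id != "average" &
                    cmp$table$method == "none", ]
  expect_equal(avg$accuracy, mean(ps$accuracy))
  expect_equal(cmp$deltas$d_accuracy,
               cmp$table$accuracy[cmp$table$method == "dann" &
                                    cmp$table$subject_id == "average"] -
                 avg$accuracy)
  # matched seeds: the baseline column reproduces run_lopo exactly
  base <- run_lopo(ws, mc, tc, seed = 3, adapt_method = "none")
  expect_equal(ps$accuracy, base$per_subject$accuracy)
  expect_equal(ps$f1, base$per_subject$f1)
})

test_that("evaluation tidiers and plots work", {
  withr::with_seed(1, {
    y <- rbinom(50, 1, 0.5)
    s <- runif(50) + y
  })
  er <- evaluate_predictions(y, pmin(s, 1))
  td <- tidy(er)
  expect_true(all(c("accuracy", "f1", "auc") %in% td$metric))
  expect_s3_class(autoplot(er), "ggplot")
  expect_equal(glance(er)$n, 50)
})
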