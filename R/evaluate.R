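#' Confusion matrix and threshold metrics
#'
#' Class 1 (pre-ictal) is the positive class. With a single-class truth
#' vector the affected metrics are returned as `NA` and flagged in
#' `$undefined` rather than silently reported as 0.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return An `eval_report` list: counts `tp`, `fp`, `tn`, `fn` and metrics
#'   `accuracy`, `sensitivity` (recall), `specificity`, `precision`, `f1`,
#'   plus `n` and `undefined` (character vector of flagged metrics).
#' @export
confusion_and_metrics <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred) && length(y_true) > 0,
              "`y_true` and `y_pred` must be equal-length, non-empty")
  assert_that(all(y_true %in% c(0, 1)) && all(y_pred %in% c(0, 1)),
              "labels must be 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  n <- length(y_true)
  undefined <- character(0)
  div <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(NA_real_)
    }
    num / den
  }
  sens <- div(tp, tp + fn, "sensitivity")
  spec <- div(tn, tn + fp, "specificity")
  prec <- div(tp, tp + fp, "precision")
  f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) {
    undefined <- c(undefined, "f1")
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
         accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec,
         precision = prec, f1 = f1, undefined = unique(undefined)),
    class = "eval_report")
}

#' ROC curve and AUC
#'
#' ROC by threshold sweep over the distinct scores; AUC by the midrank
#' (Wilcoxon) identity, so ties contribute 1/2 and the AUC equals
#' `P(score+ > score-) + 0.5 * P(tie)`.
#'
#' @param y_true 0/1 vector.
#' @param scores Class-1 probabilities (or any monotone scores).
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`;
#'   `auc` is `NA` (flagged via attribute `"undefined"`) when `y_true` has a
#'   single class.
#' @export
roc_auc <- function(y_true, scores) {
  assert_that(length(y_true) == length(scores) && length(y_true) > 0,
              "`y_true` and `scores` must be equal-length, non-empty")
  assert_that(all(y_true %in% c(0, 1)), "labels must be 0/1")
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tpr[i] <- if (n1 > 0) sum(pred & y_true == 1) / n1 else NA_real_
    fpr[i] <- if (n0 > 0) sum(pred & y_true == 0) / n0 else NA_real_
  }
  roc <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
  if (n1 == 0 || n0 == 0) {
    out <- list(roc = roc, auc = NA_real_)
    attr(out, "undefined") <- "auc"
    return(out)
  }
  r <- rank(scores)             # midranks handle ties
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc, auc = auc)
}

#' Full evaluation of probabilistic predictions
#'
#' Thresholds the pre-ictal probability at `threshold` for the confusion
#' metrics and adds the ROC/AUC.
#'
#' @param y_true 0/1 vector.
#' @param prob_preictal Class-1 probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return An `eval_report` with `roc` and `auc` fields added.
#' @export
evaluate_predictions <- function(y_true, prob_preictal, threshold = 0.5) {
  rep <- confusion_and_metrics(y_true, as.integer(prob_preictal >= threshold))
  ra <- roc_auc(y_true, prob_preictal)
  rep$roc <- ra$roc
  rep$auc <- ra$auc
  if (!is.null(attr(ra, "undefined"))) {
    rep$undefined <- unique(c(rep$undefined, "auc"))
  }
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  tp=%d fp=%d tn=%d fn=%d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f, precision %.3f, F1 %.3f",
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  if (!is.null(x$auc)) cat(sprintf(", AUC %.3f", x$auc))
  cat("\n")
  if (length(x$undefined)) {
    cat("  undefined (single-class truth):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

balance_if_possible <- function(ws, seed) {
  if (length(unique(ws$meta$y)) < 2L) return(ws)
  balance_undersample(ws, seed)
}

#' Multiple-subject (pooled) evaluation
#'
#' Pools all subjects' windows, splits them stratified by class into
#' train/validation/test, balances the training set, trains the supervised
#' classifier and reports on the held-out test split.
#'
#' @param cohort_windows A `window_set` with >= 2 subjects.
#' @param model_config A [model_config()] matching the window geometry.
#' @param train_cfg A [train_config()].
#' @param fractions Train/validation/test fractions.
#' @param seed Seed for splitting, balancing and weight initialization.
#' @param balance_before_split Under-sample the pooled set before splitting
#'   (strict-reproduction mode); the default balances the training split
#'   only, keeping the test distribution untouched.
#' @return A list: `report` (an `eval_report`), `fit` (the `seiz_fit`).
#' @export
run_multisubject <- function(cohort_windows, model_config, train_cfg,
                             fractions = c(0.6, 0.2, 0.2), seed = 1L,
                             balance_before_split = FALSE) {
  assert_that(length(unique(cohort_windows$meta$subject_id)) >= 2L,
              "pooled evaluation needs >= 2 subjects")
  if (balance_before_split) {
    cohort_windows <- balance_if_possible(cohort_windows,
                                          derive_seed(seed, 2L))
  }
  sp <- split_multisubject(cohort_windows, fractions,
                           seed = derive_seed(seed, 1L))
  tr <- if (balance_before_split) sp$train else
    balance_if_possible(sp$train, derive_seed(seed, 2L))
  model <- build_model(model_config, seed = derive_seed(seed, 3L))
  cfg <- train_cfg
  cfg$seed <- derive_seed(seed, 4L)
  fit <- train_supervised(model, tr, sp$val, cfg)
  pred <- predict_windows(fit$model, sp$test)
  report <- evaluate_predictions(pred$y, pred$prob_preictal)
  list(report = report, fit = fit, splits = sp)
}

lopo_fold <- function(cohort_windows, subject, model_config, train_cfg,
                      seed, adapt_method, val_fraction = 0.2,
                      transductive = TRUE) {
  meta <- cohort_windows$meta
  test_idx <- which(meta$subject_id == subject)
  train_idx <- which(meta$subject_id != subject)
  test_ws <- subset_windows(cohort_windows, test_idx)
  src_ws <- subset_windows(cohort_windows, train_idx)
  sp <- split_multisubject(src_ws, c(1 - val_fraction, val_fraction, 0),
                           seed = derive_seed(seed, 11L))
  tr <- balance_if_possible(sp$train, derive_seed(seed, 12L))
  model <- build_model(model_config, seed = derive_seed(seed, 13L))
  cfg <- train_cfg
  cfg$seed <- derive_seed(seed, 14L)
  cfg$adapt_method <- adapt_method
  if (adapt_method == "none") {
    fit <- train_supervised(model, tr, sp$val, cfg)
    score_ws <- test_ws
  } else if (transductive) {
    # unlabeled windows of the held-out subject are the target domain; the
    # same windows are subsequently scored
    fit <- train_adapted(model, tr, sp$val, test_ws$x, cfg)
    score_ws <- test_ws
  } else {
    half <- with_seed(derive_seed(seed, 15L),
                      sample(n_windows(test_ws), n_windows(test_ws) %/% 2))
    adapt_ws <- subset_windows(test_ws, half)
    score_ws <- subset_windows(test_ws, setdiff(seq_len(n_windows(test_ws)),
                                                half))
    fit <- train_adapted(model, tr, sp$val, adapt_ws$x, cfg)
  }
  pred <- predict_windows(fit$model, score_ws)
  list(report = evaluate_predictions(pred$y, pred$prob_preictal), fit = fit)
}

#' Leave-one-patient-out (cross-subject) evaluation
#'
#' For each subject, trains on all other subjects' windows (with an internal
#' source train/validation split and training-set balancing) and evaluates on
#' the held-out subject. With `adapt_method != "none"`, the held-out
#' subject's windows — stripped of labels — serve as the unlabeled target
#' domain (transductively by default: the adapted windows are the scored
#' windows; set `transductive = FALSE` to adapt on one half and score the
#' other).
#'
#' @param cohort_windows A `window_set` with >= 2 subjects.
#' @param model_config A [model_config()].
#' @param train_cfg A [train_config()]; its `adapt_method` selects the regime
#'   unless `adapt_method` is given explicitly.
#' @param seed Fold-level seed (splits, balancing, initialization).
#' @param adapt_method Override of `train_cfg$adapt_method`.
#' @param transductive Use the scored windows themselves for adaptation.
#' @return A `lopo_result`: `per_subject` tibble (one row per subject with
#'   f1/accuracy/auc and counts), `summary` tibble (mean and population sd of
#'   F1, accuracy, AUC), `reports` (named list of `eval_report`s).
#' @export
run_lopo <- function(cohort_windows, model_config, train_cfg, seed = 1L,
                     adapt_method = NULL, transductive = TRUE) {
  subjects <- unique(cohort_windows$meta$subject_id)
  assert_that(length(subjects) >= 2L, "LOPO needs >= 2 subjects")
  adapt_method <- adapt_method %||% train_cfg$adapt_method
  reports <- list()
  rows <- list()
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    fold <- lopo_fold(cohort_windows, s, model_config, train_cfg,
                      seed = derive_seed(seed, 100L + k),
                      adapt_method = adapt_method,
                      transductive = transductive)
    r <- fold$report
    reports[[s]] <- r
    rows[[k]] <- tibble::tibble(
      subject_id = s, f1 = r$f1, accuracy = r$accuracy, auc = r$auc,
      sensitivity = r$sensitivity, specificity = r$specificity, n = r$n,
      flagged = length(r$undefined) > 0)
  }
  per_subject <- dplyr::bind_rows(rows)
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))
  }
  summary <- tibble::tibble(
    metric = c("f1", "accuracy", "auc"),
    mean = c(mean(per_subject$f1, na.rm = TRUE),
             mean(per_subject$accuracy, na.rm = TRUE),
             mean(per_subject$auc, na.rm = TRUE)),
    sd = c(pop_sd(per_subject$f1), pop_sd(per_subject$accuracy),
           pop_sd(per_subject$auc)))
  structure(list(per_subject = per_subject, summary = summary,
                 reports = reports, adapt_method = adapt_method),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("<lopo_result> %s, %d subject(s)\n",
              if (x$adapt_method == "none") "baseline" else x$adapt_method,
              nrow(x$per_subject)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Compare the LOPO baseline against the three adaptation methods
#'
#' Runs [run_lopo()] with matched seeds for the baseline and for DANN, CDAN
#' and CDAN+E, and tabulates per-subject F1/accuracy/AUC plus the average row
#' and each method's delta versus the baseline.
#'
#' @inheritParams run_lopo
#' @param methods Methods to compare against `"none"`.
#' @return A `da_comparison`: `table` (per-subject x method grid incl. an
#'   `"average"` row), `deltas` (per-method average improvements), `results`
#'   (named list of `lopo_result`s).
#' @export
compare_adaptation <- function(cohort_windows, model_config, train_cfg,
                               seed = 1L,
                               methods = c("dann", "cdan", "cdan_e"),
                               transductive = TRUE) {
  all_methods <- c("none", methods)
  results <- lapply(all_methods, function(m) {
    run_lopo(cohort_windows, model_config, train_cfg, seed = seed,
             adapt_method = m, transductive = transductive)
  })
  names(results) <- all_methods
  tab <- dplyr::bind_rows(lapply(all_methods, function(m) {
    ps <- results[[m]]$per_subject
    avg <- tibble::tibble(
      subject_id = "average", f1 = mean(ps$f1, na.rm = TRUE),
      accuracy = mean(ps$accuracy, na.rm = TRUE),
      auc = mean(ps$auc, na.rm = TRUE),
      sensitivity = NA_real_, specificity = NA_real_,
      n = sum(ps$n), flagged = any(ps$flagged))
    dplyr::bind_rows(ps, avg) %>% dplyr::mutate(method = m)
  }))
  base_avg <- tab[tab$method == "none" & tab$subject_id == "average", ]
  deltas <- dplyr::bind_rows(lapply(methods, function(m) {
    mrow <- tab[tab$method == m & tab$subject_id == "average", ]
    tibble::tibble(method = m,
                   d_f1 = mrow$f1 - base_avg$f1,
                   d_accuracy = mrow$accuracy - base_avg$accuracy,
                   d_auc = mrow$auc - base_avg$auc)
  }))
  structure(list(table = tab, deltas = deltas, results = results),
            class = "da_comparison")
}

#' @export
print.da_comparison <- function(x, ...) {
  cat("<da_comparison>\n")
  avg <- x$table[x$table$subject_id == "average",
                 c("method", "f1", "accuracy", "auc")]
  print(as.data.frame(avg), row.names = FALSE)
  invisible(x)
}
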