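#' Split a cohort into leave-one-subject-out train/test sets
#'
#' @param cohort list of [epochs_set()] objects.
#' @param test_subject subject id to hold out.
#' @return `list(train = <list of epochs>, test = <epochs>)`; the train set
#'   contains every other subject, disjoint from the test subject.
#' @export
loso_split <- function(cohort, test_subject) {
  ids <- vapply(cohort, `[[`, "", "subject_id")
  k <- match(test_subject, ids)
  if (is.na(k)) stop("unknown subject: ", test_subject)
  list(train = cohort[-k], test = cohort[[k]])
}

#' Mean and sample standard deviation of per-subject accuracies
#'
#' @param per_subject_accuracies numeric vector of per-subject test
#'   accuracies in percent.
#' @return named numeric `c(mean, sd)`; `sd` uses the n-1 denominator
#'   (0 for a single value).
#' @examples
#' aggregate_results(c(70, 80, 90))
#' @export
aggregate_results <- function(per_subject_accuracies) {
  x <- as.numeric(per_subject_accuracies)
  if (!length(x)) stop("empty accuracy list")
  s <- if (length(x) > 1) stats::sd(x) else 0
  c(mean = mean(x), sd = s)
}

#' Leave-one-subject-out training and evaluation
#'
#' For every subject in turn: all other subjects form the training set,
#' preprocessing statistics are computed from those training trials only,
#' the model is trained with early stopping on a validation split drawn
#' from the training subjects, and single-trial accuracy is measured on the
#' held-out subject. Every fold is seeded deterministically from
#' `tc$seed` and the test subject's id, so results are reproducible and a
#' fold's weights are provably independent of its test data.
#'
#' @param cohort list of [epochs_set()] objects (>= 2 subjects).
#' @param config optional [model_config()] shared by all folds.
#' @param tc a [train_config()].
#' @param channel_subset optional channel labels to restrict training and
#'   evaluation to (e.g. the 10 frontal ROI channels).
#' @param keep_models keep each fold's fitted `bfn_model` in the result
#'   (memory permitting).
#' @return object of class `bfn_loso`: `per_subject` (named accuracies, %),
#'   `mean`, `sd` (sample, n-1), `n_subjects`, `fold_seeds`, and optionally
#'   `models`.
#' @export
run_loso <- function(cohort, config = NULL, tc = train_config(),
                     channel_subset = NULL, keep_models = FALSE) {
  if (length(cohort) < 2) stop_config("LOSO needs at least 2 subjects")
  ids <- vapply(cohort, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop_config("subject ids must be distinct")
  bands <- if (is.null(config)) default_bands() else config$bands
  # default: decimate towards a 32 Hz effective model rate
  decim <- if (is.null(config))
    max(1L, as.integer(cohort[[1]]$sampling_rate %/% 32)) else config$decimate
  bfn_log("INFO", "LOSO: decomposing %d subjects into %d bands",
          length(cohort), length(bands))
  stacks <- lapply(cohort, .prep_stack, bands = bands, decimate = decim,
                   channels = channel_subset)
  d <- dim(stacks[[1]]$data)
  if (is.null(config))
    config <- model_config(bands = bands, n_channels = d[3], n_samples = d[4],
                           input_rate = stacks[[1]]$sampling_rate,
                           decimate = decim)
  fs_orig <- vapply(cohort, `[[`, numeric(1), "sampling_rate")
  rm(cohort)                       # raw epochs no longer needed; free them
  acc <- stats::setNames(numeric(length(ids)), ids)
  fold_seeds <- stats::setNames(integer(length(ids)), ids)
  models <- list()
  for (k in seq_along(ids)) {
    fold_seed <- derive_seed(tc$seed, "fold", ids[k])
    fold_seeds[k] <- fold_seed
    stats <- .pooled_stats(stacks[-k])
    model <- .train_engine(config, tc, stacks[-k], stats, fold_seed)
    test <- standardize_stack(stacks[[k]], stats = stats)
    pr <- forward(model, test)
    pred <- max.col(pr, ties.method = "first") - 1L
    acc[k] <- 100 * mean(pred == stacks[[k]]$labels)
    bfn_log("INFO", "fold %s: accuracy %.2f%% (%d epochs)", ids[k], acc[k],
            if (nrow(model$training_log)) max(model$training_log$epoch) else 0)
    if (keep_models) {
      model$preproc <- list(bands = bands, decimate = decim, stats = stats,
                            channel_names = stacks[[k]]$channel_names,
                            sampling_rate = fs_orig[k],
                            window = c(0, Inf),
                            train_subjects = ids[-k])
      models[[ids[k]]] <- model
    }
  }
  agg <- aggregate_results(acc)
  structure(list(per_subject = acc, mean = unname(agg["mean"]),
                 sd = unname(agg["sd"]), n_subjects = length(ids),
                 fold_seeds = fold_seeds, config = config, train_config = tc,
                 channel_subset = channel_subset,
                 models = if (keep_models) models),
            class = "bfn_loso")
}

#' @export
print.bfn_loso <- function(x, ...) {
  cat(sprintf("<bfn_loso> %d subjects\n", x$n_subjects))
  for (id in names(x$per_subject))
    cat(sprintf("  %-6s %6.2f\n", id, x$per_subject[id]))
  cat(sprintf("  Average %.2f ± %.2f\n", x$mean, x$sd))
  invisible(x)
}

#' @export
summary.bfn_loso <- function(object, ...) print(object, ...)

#' Paired t test wrapped into a common statistics container
#'
#' Standard paired t statistic with `df = n - 1` and a two-sided p value.
#' Degenerate inputs are handled explicitly: if every pairwise difference is
#' zero the test is a no-op (`t = 0, p = 1`); if the differences are exactly
#' constant but non-zero the statistic is unbounded (`t = +/-Inf, p = 0`).
#'
#' @param a,b equal-length numeric vectors (n >= 2), paired by position.
#' @return object of class `bfn_stat` with fields `method`, `statistic`,
#'   `df`, `p_value`, `ci`, `n`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop_config("a and b must have equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(stat_result("paired t-test", 0, length(d) - 1, 1,
                         ci = c(0, 0), n = length(d)))
    return(stat_result("paired t-test", sign(mean(d)) * Inf, length(d) - 1, 0,
                       ci = c(mean(d), mean(d)), n = length(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  stat_result("paired t-test", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, ci = as.numeric(tt$conf.int), n = length(d))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pearson's r with `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, two-sided p, and
#' a 95% confidence interval from the Fisher z transform.
#'
#' @param x,y equal-length numeric vectors (n >= 3) with non-zero variance.
#' @return object of class `bfn_stat`; `statistic` is r, `df = n - 2`,
#'   `t_value` carries the t statistic.
#' @export
pearson_with_ci <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_config("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_config("correlation undefined: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  out <- stat_result("pearson", unname(ct$estimate), unname(ct$parameter),
                     ct$p.value, ci = as.numeric(ct$conf.int), n = length(x))
  out$t_value <- unname(ct$statistic)
  out
}

#' Construct a statistics result container
#'
#' @param method label of the test.
#' @param statistic test statistic.
#' @param df degrees of freedom (may be `NA`).
#' @param p_value p value in `[0, 1]`.
#' @param ci optional `c(low, high)` confidence interval.
#' @param n sample size.
#' @return object of class `bfn_stat`.
#' @export
stat_result <- function(method, statistic, df, p_value, ci = NULL, n = NA) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop_config("p_value outside [0, 1]")
  if (!is.null(ci) && ci[1] > ci[2]) stop_config("ci low > high")
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, ci = ci, n = n),
            class = "bfn_stat")
}

#' @export
print.bfn_stat <- function(x, ...) {
  cat(sprintf("<bfn_stat> %s: statistic = %.4g, df = %s, p = %.4g, n = %s\n",
              x$method, x$statistic, format(x$df), x$p_value, format(x$n)))
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  invisible(x)
}
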