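#' Held-out accuracy of a classifier
#'
#' Fraction of correct direction predictions on a test batch, with an exact
#' binomial confidence interval.
#'
#' @param object A fitted classifier (`fusion_fit` or `rnn_fit`).
#' @param test_trials Labelled test trials.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble: `accuracy`, `n_trials`, `n_correct`,
#'   `conf_low`, `conf_high`.
#' @examples
#' cfg <- task_spec(1, n = 40)
#' fit <- fit_fusion(sample_trials(cfg, 500, seed = 1), "nlf")
#' evaluate_accuracy(fit, sample_trials(cfg, 500, seed = 2))
#' @export
evaluate_accuracy <- function(object, test_trials, conf_level = 0.95) {
  preds <- predict(object, test_trials)
  if (nrow(preds) == 0) abort("no test trials.")
  n_correct <- sum(preds$pred == preds$m)
  bt <- stats::binom.test(n_correct, nrow(preds), conf.level = conf_level)
  tibble::tibble(
    accuracy = n_correct / nrow(preds),
    n_trials = nrow(preds),
    n_correct = n_correct,
    conf_low = bt$conf.int[1],
    conf_high = bt$conf.int[2]
  )
}

spec_label <- function(spec) {
  if (is.numeric(spec)) paste0("k", spec) else as.character(spec)
}

# Derive a per-cell seed from the root seed; stays well below 2^31 for the
# small root seeds used in practice.
cell_seed <- function(seed, i, role) {
  as.integer(seed) * 1000L + role * 100L + as.integer(i)
}

#' Train/test accuracy grid over task distributions
#'
#' Trains one classifier per training distribution and evaluates every
#' trained model on a freshly simulated test set from every test
#' distribution. Distributions are named as in [task_spec()]: fixed burst
#' lengths by integer (or `"k3"`), `"uniform"`, `"levy"`. The diagonal of the
#' grid is the in-distribution accuracy; off-diagonal cells measure
#' generalisation. With `models = c("nlf2", "nlf3")` and
#' `train_specs = test_specs = 1:8` this is the fixed-burst-length
#' generalisation design; adding `"uniform"` and `"levy"` on both axes gives
#' the full 10 x 10 mixed-distribution design.
#'
#' @param models Character vector of model kinds: any of `"lf"`, `"nlf"`,
#'   `"nlf2"`, `"nlf3"`, ..., `"rnn"`.
#' @param train_specs,test_specs Vectors of task distribution labels (see
#'   above).
#' @param n_train,n_test Trials per training / test set.
#' @param seed Root seed; every cell's simulation seed is derived from it and
#'   recorded in the result.
#' @param n,n_channels,l_max,... Task parameters passed to [task_spec()].
#' @param rnn RNN settings: an [rnn_config()] used as a template for
#'   `models = "rnn"` (its seed is replaced per replicate).
#' @param rnn_replicates Independently seeded RNN trainings per cell
#'   (default 5); fusion fits are deterministic given the data so run once.
#' @return An `evaluation_grid` tibble: one row per model x train x test (x
#'   replicate), with columns `model`, `train`, `test`, `replicate`,
#'   `accuracy`, `n_test`, `train_seed`, `test_seed` and binomial CI bounds.
#' @export
run_generalisation_grid <- function(models = c("nlf2", "nlf3"),
                                    train_specs = 1:8, test_specs = train_specs,
                                    n_train = 50000, n_test = 20000,
                                    seed = 1, n = 200L, n_channels = 2L,
                                    l_max = 8L,
                                    rnn = rnn_config(n_channels = n_channels),
                                    rnn_replicates = 5L, ...) {
  train_labels <- vapply(train_specs, spec_label, character(1))
  test_labels <- vapply(test_specs, spec_label, character(1))

  # Train every model on every training distribution.
  fits <- list()
  for (i in seq_along(train_specs)) {
    cfg <- task_spec(train_specs[[i]], n = n, n_channels = n_channels,
                     l_max = l_max, ...)
    tseed <- cell_seed(seed, i, 1L)
    train <- sample_trials(cfg, n_train, seed = tseed)
    for (mk in models) {
      if (mk == "rnn") {
        for (r in seq_len(rnn_replicates)) {
          cfg_r <- rnn
          cfg_r$seed <- cell_seed(seed, i, 3L) + r
          fits[[length(fits) + 1]] <- list(
            model = mk, train = train_labels[i], replicate = r,
            train_seed = tseed, fit = train_rnn(train, cfg_r)
          )
        }
      } else {
        fits[[length(fits) + 1]] <- list(
          model = mk, train = train_labels[i], replicate = 1L,
          train_seed = tseed, fit = fit_fusion(train, mk)
        )
      }
    }
    rm(train)
  }

  # Evaluate every fit on every test distribution; the pattern-count feature
  # matrix is shared across fits of the same kind to keep the grid fast.
  rows <- list()
  for (j in seq_along(test_specs)) {
    cfg <- task_spec(test_specs[[j]], n = n, n_channels = n_channels,
                     l_max = l_max, ...)
    sseed <- cell_seed(seed, j, 2L)
    test <- sample_trials(cfg, n_test, seed = sseed)
    first <- !duplicated(test$trial_id)
    m <- test$m[first]
    Xcache <- list()
    for (f in fits) {
      if (f$model == "rnn") {
        pred <- predict(f$fit, test)$pred
      } else {
        key <- f$model
        if (is.null(Xcache[[key]])) {
          Xcache[[key]] <- switch(sub("[0-9]+$", "w", f$model),
            lf = feature_matrix_lf(test),
            nlf = feature_matrix_nlfw(test, 1L),
            nlfw = feature_matrix_nlfw(test, f$fit$w)
          )
        }
        eta <- as.numeric(Xcache[[key]] %*% f$fit$coefficients) +
          f$fit$intercept
        pred <- ifelse(eta >= 0, 1L, -1L)
      }
      n_correct <- sum(pred == m)
      bt <- stats::binom.test(n_correct, length(m))
      rows[[length(rows) + 1]] <- tibble::tibble(
        model = f$model, train = f$train, test = test_labels[j],
        replicate = f$replicate,
        accuracy = n_correct / length(m),
        n_test = length(m), n_correct = n_correct,
        conf_low = bt$conf.int[1], conf_high = bt$conf.int[2],
        train_seed = f$train_seed, test_seed = sseed
      )
    }
    rm(test)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("evaluation_grid", class(out))
  out
}

#' Shortfall relative to the best model on each test distribution
#'
#' For every model kind and test distribution, the accuracy of each trained
#' model minus the best accuracy achieved on that test set by any training
#' distribution (within the same model kind): \eqn{A(k, k') - \max_{k''} A(k'',
#' k')}. Values are non-positive by construction, zero for the best-performing
#' training distribution in each column. For fixed-length train/test pairs a
#' `delta_k` column (train k minus test k) is added.
#'
#' @param grid An `evaluation_grid` from [run_generalisation_grid()].
#' @return A tibble with columns `model`, `train`, `test`, `accuracy`,
#'   `best`, `shortfall` (and `delta_k` where defined). RNN replicates are
#'   averaged before the comparison.
#' @export
relative_accuracy <- function(grid) {
  out <- grid |>
    dplyr::group_by(.data$model, .data$train, .data$test) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
    dplyr::group_by(.data$model, .data$test) |>
    dplyr::mutate(best = max(.data$accuracy),
                  shortfall = .data$accuracy - .data$best) |>
    dplyr::ungroup()
  ktrain <- suppressWarnings(as.integer(sub("^k", "", out$train)))
  ktest <- suppressWarnings(as.integer(sub("^k", "", out$test)))
  out$delta_k <- ktrain - ktest
  out
}

#' Min-max envelope of fixed-length-trained models
#'
#' For each model kind and test distribution, the span of accuracies across
#' all models trained on fixed burst lengths; used to compare
#' mixed-distribution-trained models against the family of fixed-k models.
#'
#' @param grid An `evaluation_grid` whose training specs include fixed burst
#'   lengths (labels `k1`, `k2`, ...).
#' @return A tibble with `model`, `test`, `env_min`, `env_max`.
#' @export
fixed_envelope <- function(grid) {
  grid |>
    dplyr::filter(grepl("^k[0-9]+$", .data$train)) |>
    dplyr::group_by(.data$model, .data$train, .data$test) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
    dplyr::group_by(.data$model, .data$test) |>
    dplyr::summarise(env_min = min(.data$accuracy),
                     env_max = max(.data$accuracy), .groups = "drop")
}

#' Two-proportion comparison of classifier accuracies
#'
#' Tests whether two accuracies (given as correct counts out of test-set
#' sizes) differ, via `prop.test`; the package convention for "equivalent"
#' performance claims is failure to reject at `alpha = 0.01`.
#'
#' @param correct1,n1,correct2,n2 Correct counts and test sizes.
#' @return A one-row tibble: `p_value`, `estimate1`, `estimate2`, `diff`.
#' @export
compare_accuracies <- function(correct1, n1, correct2, n2) {
  ht <- stats::prop.test(c(correct1, correct2), c(n1, n2))
  tibble::tibble(
    p_value = ht$p.value,
    estimate1 = correct1 / n1,
    estimate2 = correct2 / n2,
    diff = correct1 / n1 - correct2 / n2
  )
}

#' Heatmap of a train/test accuracy grid
#'
#' @param object An `evaluation_grid`.
#' @param ... Unused.
#' @return A ggplot object, one facet per model kind.
#' @export
autoplot.evaluation_grid <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$model, .data$train, .data$test) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  lev <- unique(df$train)
  df$train <- factor(df$train, levels = lev)
  df$test <- factor(df$test, levels = unique(df$test))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$train,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$accuracy)),
                       size = 2.5) +
    ggplot2::facet_wrap(~model) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "tested on", y = "trained on",
                  title = "train/test accuracy grid") +
    ggplot2::theme_minimal()
}
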