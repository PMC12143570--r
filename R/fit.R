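#' Fit a count-feature fusion classifier
#'
#' Trains one of the fusion classifier family on a batch of simulated trials:
#' \describe{
#'   \item{`"lf"` (linear fusion)}{per-channel marginal value counts,
#'     `3 * n_channels` coefficients; linear across channels and time.}
#'   \item{`"nlf"` (nonlinear fusion)}{joint per-timestep pattern counts,
#'     `3^n_channels` coefficients; nonlinear across channels, order-free in
#'     time.}
#'   \item{`"nlfw"` (window nonlinear fusion)}{joint pattern counts over
#'     sliding windows of `w` steps, `3^(w * n_channels)` coefficients;
#'     nonlinear across channels and the window.}
#' }
#' All are logistic regressions of the direction label on the count features,
#' fitted with a weak ridge penalty (via \pkg{glmnet}, unstandardised) so
#' that in large samples the coefficients track the per-pattern
#' log-likelihood ratios \eqn{\log P(pattern \mid M=+1) / P(pattern \mid
#' M=-1)} up to a common shift absorbed by the intercept. `"nlf"` is exactly
#' `"nlfw"` with `w = 1`.
#'
#' @param trials A `burst_trials` tibble with a direction column `m`
#'   containing both classes.
#' @param kind `"lf"`, `"nlf"`, or `"nlfw"`; the shorthands `"nlf2"`, `"nlf3"`,
#'   ... select `"nlfw"` with that window.
#' @param w Window length for `"nlfw"`.
#' @param lambda Ridge penalty (glmnet scale); small by default so the fit is
#'   close to unregularised maximum likelihood.
#' @return A `fusion_fit` object: list with `kind`, `w`, `n_channels`,
#'   `intercept`, `coefficients` (named, in frozen pattern order),
#'   `n_parameters` (coefficients only, excluding the intercept), `lambda`,
#'   and `training` (trial count and label balance). Supports [predict()],
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' trials <- sample_trials(task_spec(1, n = 50), 400, seed = 1)
#' fit <- fit_fusion(trials, "nlf")
#' glance(fit)
#' @export
fit_fusion <- function(trials, kind = c("lf", "nlf", "nlfw"), w = NULL,
                       lambda = 1e-3) {
  kind_in <- kind[1]
  if (grepl("^nlf[0-9]+$", kind_in)) {
    w <- as.integer(sub("^nlf", "", kind_in))
    kind <- "nlfw"
  } else {
    kind <- match.arg(kind)
  }
  if (kind == "nlf") w <- 1L
  if (kind == "nlfw") {
    if (is.null(w) || !is_count(w)) abort("`w` is required for kind = \"nlfw\".")
    w <- as.integer(w)
  }
  labels <- trials$m[!duplicated(trials$trial_id)]
  if (length(unique(labels)) < 2) {
    abort("training batch contains a single class; both directions are needed.",
          class = "burstfusion_degenerate_training")
  }
  nc <- n_channels_of(trials)
  X <- switch(kind,
    lf = feature_matrix_lf(trials),
    nlf = feature_matrix_nlfw(trials, 1L),
    nlfw = feature_matrix_nlfw(trials, w)
  )
  y <- factor(labels, levels = c(-1, 1))
  # A short warm-started path down to the target penalty keeps glmnet stable.
  fit <- glmnet::glmnet(
    X, y, family = "binomial", alpha = 0, standardize = FALSE,
    lambda = c(100, 10, 1, 0.1, 0.01) * lambda, intercept = TRUE
  )
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta) <- if (kind == "lf") colnames(X) else
    paste0("pattern_", seq_along(beta))
  structure(
    list(
      kind = if (kind == "nlfw") paste0("nlf", w) else kind,
      w = if (kind == "lf") NA_integer_ else w,
      n_channels = nc,
      intercept = fit$a0[[ncol(fit$beta)]],
      coefficients = beta,
      n_parameters = length(beta),
      lambda = lambda,
      training = list(n_trials = length(labels),
                      n_positive = sum(labels == 1))
    ),
    class = "fusion_fit"
  )
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf("<fusion_fit> %s: %d coefficients (+ intercept), %d channel(s)\n",
              toupper(x$kind), x$n_parameters, x$n_channels))
  cat(sprintf("  trained on %d trials (%d with m = +1), ridge lambda = %g\n",
              x$training$n_trials, x$training$n_positive, x$lambda))
  invisible(x)
}

#' Predict directions for new trials
#'
#' Computes the logistic score \eqn{P(M = +1 \mid X)} for each trial from the
#' fitted count features and thresholds it at 0.5; an exact tie is called
#' `+1` (fixed rule, a measure-zero event for continuous scores).
#'
#' @param object A `fusion_fit`.
#' @param trials A trial table compatible with the fit (same channel count,
#'   length at least the window).
#' @param ... Unused.
#' @return A tibble with one row per trial: `trial_id`, `m` (true label if
#'   present, else `NA`), `score` and `pred` (-1/+1).
#' @export
predict.fusion_fit <- function(object, trials, ...) {
  if (n_channels_of(trials) != object$n_channels) {
    abort("channel count of `trials` does not match the fitted model.")
  }
  X <- switch(sub("[0-9]+$", "w", object$kind),
    lf = feature_matrix_lf(trials),
    nlf = feature_matrix_nlfw(trials, 1L),
    nlfw = feature_matrix_nlfw(trials, object$w)
  )
  eta <- as.numeric(X %*% object$coefficients) + object$intercept
  score <- stats::plogis(eta)
  first <- !duplicated(trials$trial_id)
  ids <- trials$trial_id[first]
  m <- if ("m" %in% names(trials)) trials$m[first] else NULL
  tibble::tibble(
    trial_id = ids,
    m = if (is.null(m)) NA_integer_ else m,
    score = score,
    pred = ifelse(score >= 0.5, 1L, -1L)
  )
}

#' @export
tidy.fusion_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
  if (grepl("^nlf", x$kind)) {
    pats <- enumerate_patterns(x$n_channels, x$w)
    out <- dplyr::bind_cols(out, pats[, -1, drop = FALSE])
  }
  out
}

#' @export
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_parameters = x$n_parameters,
    n_channels = x$n_channels,
    w = x$w,
    lambda = x$lambda,
    n_train = x$training$n_trials
  )
}

#' Plot fitted pattern weights
#'
#' Coefficients in the frozen pattern order, the fitted analogue of a
#' per-pattern log-likelihood table.
#'
#' @param object A `fusion_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusion_fit <- function(object, ...) {
  df <- tidy(object)
  df$rank <- rank(df$estimate, ties.method = "first")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$estimate)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "pattern (sorted by weight)", y = "coefficient",
      title = sprintf("%s fitted pattern weights", toupper(object$kind))
    ) +
    ggplot2::theme_minimal()
}

#' Serialise a fitted fusion classifier to JSON
#'
#' Writes the coefficient vector (in the frozen pattern order), intercept and
#' training metadata; `read_fusion_fit()` restores a fit usable with
#' [predict()].
#'
#' @param fit A `fusion_fit`.
#' @param path JSON file path.
#' @return `path`, invisibly; `read_fusion_fit()` returns a `fusion_fit`.
#' @export
write_fusion_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fusion_fit
#' @export
read_fusion_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- setNames(as.numeric(x$coefficients),
                             names(x$coefficients))
  structure(x, class = "fusion_fit")
}
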