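# Window patterns and count features -----------------------------------------
#
# A "pattern" is one assignment of the trinary observation values to every
# (channel, within-window time) cell of a w-step window over n_channels
# channels; there are 3^(w * n_channels) of them. The enumeration order is
# frozen: cells are flattened timestep-major (window step 1 first), channels in
# order within each timestep, and patterns are ordered lexicographically over
# that flattening from all -1 (id 1) to all +1 (id 3^(w * n_channels)). Feature
# vectors and fitted coefficients index into this order, so it must never
# change across versions.

#' Enumerate all window patterns
#'
#' Lists every possible joint observation over a window of `w` consecutive
#' time steps and `n_channels` channels, each cell taking values in
#' \{-1, 0, +1\}; there are `3^(w * n_channels)` such patterns. For two
#' channels and `w = 2` this is the table of 81 window observations that the
#' window-2 nonlinear-fusion classifier counts.
#'
#' @param n_channels Number of channels.
#' @param w Window length in time steps.
#' @param cap Guard on the table size (default `3^10` rows); larger requests
#'   error rather than exhaust memory.
#' @return A tibble with one row per pattern: `pattern_id` (1-based, in the
#'   frozen lexicographic order from all `-1` to all `+1`) and one column
#'   `x<i>_t<j>` per channel `i` and window step `j`.
#' @examples
#' enumerate_patterns(2, 2) # 81 rows
#' @export
enumerate_patterns <- function(n_channels, w, cap = 3^10) {
  if (!is_count(n_channels) || !is_count(w)) {
    abort("`n_channels` and `w` must be positive integers.")
  }
  size <- 3^(w * n_channels)
  if (size > cap) {
    abort(sprintf("pattern table with 3^%d = %g rows exceeds the cap (%g).",
                  w * n_channels, size, cap))
  }
  P <- w * n_channels
  id0 <- 0:(size - 1)
  out <- tibble::tibble(pattern_id = id0 + 1L)
  for (p in seq_len(P) - 1L) {            # p = (t-1)*n_channels + (i-1)
    t_j <- p %/% n_channels + 1L
    i <- p %% n_channels + 1L
    digit <- (id0 %/% 3^(P - 1 - p)) %% 3
    out[[paste0("x", i, "_t", t_j)]] <- as.integer(digit - 1L)
  }
  cols <- paste0("x", rep(seq_len(n_channels), w),
                 "_t", rep(seq_len(w), each = n_channels))
  out[, c("pattern_id", cols)]
}

#' Index of a window pattern in the frozen enumeration
#'
#' @param x A `n_channels x w` matrix (channels in rows, window steps in
#'   columns) with entries in \{-1, 0, +1\}.
#' @return The 1-based `pattern_id` of `x` in [enumerate_patterns()]'s order.
#' @examples
#' pattern_id(matrix(-1, 2, 2)) # 1: the all-minus pattern
#' @export
pattern_id <- function(x) {
  if (!is.matrix(x) || !all(x %in% c(-1L, 0L, 1L))) {
    abort("`x` must be a channels-by-window matrix over {-1, 0, 1}.")
  }
  nc <- nrow(x)
  w <- ncol(x)
  digits <- as.integer(x) + 1L            # column-major = timestep-major flatten
  P <- nc * w
  as.integer(sum(digits * 3^(P - seq_len(P))) + 1L)
}

# Per-timestep integer codes 0..3^nc - 1 for a long trial table, as an
# n x n_trials matrix (requires equal trial lengths, which sample_trials
# guarantees).
step_codes <- function(trials) {
  xcols <- grep("^x[0-9]+$", names(trials), value = TRUE)
  nc <- length(xcols)
  if (nc == 0) abort("`trials` has no observation columns x1, x2, ...")
  code <- 0
  for (i in seq_len(nc)) code <- code + (trials[[paste0("x", i)]] + 1L) * 3^(nc - i)
  n <- max(trials$t)
  if (nrow(trials) %% n != 0) abort("trials must share a common length.")
  matrix(code, nrow = n)
}

# Window codes ((n - w + 1) x n_trials), 0-based in the frozen pattern order.
window_codes <- function(trials, w) {
  nc <- n_channels_of(trials)
  codes <- step_codes(trials)
  n <- nrow(codes)
  if (n < w) {
    abort(sprintf("trials of length %d are shorter than the window w = %d.", n, w),
          class = "burstfusion_trial_too_short")
  }
  out <- 0
  for (j in seq_len(w)) {
    out <- out + codes[j:(n - w + j), , drop = FALSE] * 3^(nc * (w - j))
  }
  out
}

#' Sliding-window pattern counts
#'
#' Counts, for each trial, how often every window pattern occurs across the
#' `n - w + 1` overlapping windows `[1..w], [2..w+1], ..., [n-w+1..n]`. These
#' counts are the feature vector of the window-`w` nonlinear-fusion
#' classifier; summing a per-pattern log-likelihood over windows is the same
#' as taking an inner product with this vector.
#'
#' @param trials A `burst_trials` tibble (or any long trial table with
#'   columns `trial_id`, `t`, `x1`, `x2`, ...).
#' @param w Window length; trials must be at least `w` steps long.
#' @return A tibble with columns `trial_id`, `pattern_id`, `count`, listing
#'   the non-zero counts only; for every trial the counts sum to `n - w + 1`.
#'   Pattern ids refer to [enumerate_patterns()]'s order.
#' @examples
#' trials <- sample_trials(task_spec(1, n = 20, p_e = 0.2), 2, seed = 1)
#' count_window_features(trials, w = 2)
#' @export
count_window_features <- function(trials, w) {
  if (!is_count(w)) abort("`w` must be a positive integer.")
  wc <- window_codes(trials, w)
  ids <- unique(trials$trial_id)
  tibble::tibble(
    trial_id = rep(ids, each = nrow(wc)),
    pattern_id = as.integer(wc) + 1L
  ) |>
    dplyr::count(.data$trial_id, .data$pattern_id, name = "count")
}

# Sparse trials x 3^(w*nc) count matrix used by the fitting routines.
feature_matrix_nlfw <- function(trials, w) {
  nc <- n_channels_of(trials)
  wc <- window_codes(trials, w)
  n_trials <- ncol(wc)
  Matrix::sparseMatrix(
    i = rep(seq_len(n_trials), each = nrow(wc)),
    j = as.integer(wc) + 1L,
    x = 1,
    dims = c(n_trials, 3^(w * nc))
  )
}

#' Linear-fusion marginal count features
#'
#' Per-channel occurrence counts of each observation value over the whole
#' trial: for every channel, how many steps reported -1, 0 and +1. These
#' marginal statistics (length `3 * n_channels`) are the features of the
#' linear-fusion classifier; they are a fixed linear projection (a
#' marginalisation over the other channel) of the joint per-timestep pattern
#' counts, and are invariant to reordering time steps.
#'
#' @inheritParams count_window_features
#' @return A tibble with columns `trial_id`, `channel`, `value` (-1/0/+1) and
#'   `count`; counts within a trial-channel sum to the trial length.
#' @examples
#' trials <- sample_trials(task_spec(1, n = 20, p_e = 0.2), 2, seed = 1)
#' lf_features(trials)
#' @export
lf_features <- function(trials) {
  xcols <- grep("^x[0-9]+$", names(trials), value = TRUE)
  trials |>
    tidyr::pivot_longer(dplyr::all_of(xcols), names_to = "channel",
                        values_to = "value") |>
    dplyr::mutate(channel = as.integer(sub("^x", "", .data$channel))) |>
    dplyr::count(.data$trial_id, .data$channel, .data$value, name = "count") |>
    tidyr::complete(.data$trial_id, .data$channel, value = c(-1L, 0L, 1L),
                    fill = list(count = 0L))
}

# Dense trials x (3 * nc) matrix of LF features, column order
# (channel 1: -1, 0, +1), (channel 2: -1, 0, +1), ...
feature_matrix_lf <- function(trials) {
  nc <- n_channels_of(trials)
  codes <- step_codes(trials)             # n x n_trials
  n_trials <- ncol(codes)
  out <- matrix(0, n_trials, 3 * nc)
  for (i in seq_len(nc)) {
    xi <- matrix(trials[[paste0("x", i)]], nrow = nrow(codes))
    for (v in c(-1L, 0L, 1L)) {
      out[, (i - 1L) * 3L + (v + 2L)] <- colSums(xi == v)
    }
  }
  colnames(out) <- paste0("ch", rep(seq_len(nc), each = 3),
                          "_", rep(c("m1", "0", "p1"), nc))
  out
}
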