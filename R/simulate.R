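# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Emission sequence implied by burst starts and lengths
#'
#' A burst starting at step `s` with length `l` keeps the target emitting over
#' steps `s, ..., s + l - 1`. Starts are given on an axis extended before the
#' trial (positions `1 - (length(g) - n)` through `n`), so bursts that begin
#' before step 1 can still cover the first steps of the trial.
#'
#' @param g Binary vector of burst-start indicators over the extended axis.
#' @param l Integer vector of burst lengths, aligned with `g` (entries where
#'   `g == 0` are ignored).
#' @param n Trial length; `length(g)` must be at least `n`.
#' @return Integer emission vector `e` of length `n`, with `e[t] = 1` iff some
#'   start at `s <= t` has length at least `t - s + 1`.
#' @examples
#' emission_from_bursts(c(0, 1, 0, 0, 0), c(0, 3, 0, 0, 0), n = 5)
#' @export
emission_from_bursts <- function(g, l, n) {
  if (length(g) != length(l)) abort("`g` and `l` must have the same length.")
  if (!is_count(n) || length(g) < n) abort("`g` must cover at least `n` steps.")
  ext <- length(g) - n                  # pre-trial positions
  e <- integer(n)
  for (j in which(g == 1)) {
    s <- j - ext                        # time index of this start
    if (l[j] < 1) abort("burst lengths must be >= 1 where g == 1.")
    idx <- max(1L, s):min(n, s + l[j] - 1L)
    if (idx[1] <= n && s + l[j] - 1L >= 1L) e[idx] <- 1L
  }
  e
}

#' Sample trials from the burst-detection task
#'
#' Draws `n_trials` independent trials from the generative model of a
#' [task_config()]: a uniform direction `m`, Bernoulli(`p_g`) burst starts on
#' the extended axis, burst lengths from the configured law, the implied
#' emission sequence, and trinary channel observations from the signal
#' distribution while emitting and the noise distribution while silent.
#' Trials in which the target never emits are redrawn in full (starts,
#' lengths and observations), so every returned trial is solvable.
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials.
#' @param seed Optional integer seed; given the same `(config, n_trials,
#'   seed)` the batch is reproduced exactly.
#' @return A tibble of class `burst_trials` in long form, one row per
#'   trial-timestep: `trial_id`, `t`, `m` (direction, -1/+1), `e` (emission
#'   indicator) and observation columns `x1, ..., x<n_channels>` with values
#'   in \{-1, 0, +1\}. The generating `task_config` and seed are attached as
#'   attributes `config` and `seed`.
#' @examples
#' trials <- sample_trials(task_spec(2, n = 50), n_trials = 4, seed = 1)
#' dplyr::count(trials, trial_id, m)
#' @export
sample_trials <- function(config, n_trials, seed = NULL) {
  if (!is_task_config(config)) abort("`config` must be a task_config.")
  if (!is_count(n_trials)) abort("`n_trials` must be a positive integer.")
  n_trials <- as.integer(n_trials)
  with_seed(seed, {
    n <- config$n
    nc <- config$n_channels
    lmax <- config$burst_model$l_max
    pmf <- config$burst_model$pmf
    D <- n + lmax - 1L                  # extended start axis

    m <- sample(c(-1L, 1L), n_trials, replace = TRUE)

    draw_e <- function(ntr) {
      g <- matrix(runif(D * ntr) < config$p_g, D, ntr)
      L <- if (config$burst_model$kind == "fixed") {
        matrix(config$burst_model$k, D, ntr)
      } else {
        matrix(sample.int(lmax, D * ntr, replace = TRUE, prob = pmf), D, ntr)
      }
      e <- matrix(FALSE, n, ntr)
      for (d in 0:(lmax - 1L)) {
        rows <- (1:n) + (lmax - 1L) - d  # start position covering t with lag d
        e <- e | (g[rows, , drop = FALSE] & L[rows, , drop = FALSE] > d)
      }
      e
    }

    e <- draw_e(n_trials)
    repeat {
      bad <- which(colSums(e) == 0L)
      if (length(bad) == 0L) break
      e[, bad] <- draw_e(length(bad))
    }

    # observations: one uniform per channel-step, branched on the emission state
    mmat <- matrix(m, n, n_trials, byrow = TRUE)
    x <- vector("list", nc)
    for (i in seq_len(nc)) {
      u <- matrix(runif(n * n_trials), n, n_trials)
      xi <- matrix(0L, n, n_trials)
      sig <- e
      xi[sig & u < config$p_c] <- mmat[sig & u < config$p_c]
      sel <- sig & u >= config$p_c & u < config$p_c + config$p_i
      xi[sel] <- -mmat[sel]
      half <- config$p_n + (1 - config$p_n) / 2
      xi[!sig & u >= config$p_n & u < half] <- 1L
      xi[!sig & u >= half] <- -1L
      x[[i]] <- as.integer(xi)
    }

    out <- tibble::tibble(
      trial_id = rep(seq_len(n_trials), each = n),
      t = rep(seq_len(n), n_trials),
      m = rep(m, each = n),
      e = as.integer(e)
    )
    for (i in seq_len(nc)) out[[paste0("x", i)]] <- x[[i]]
    attr(out, "config") <- config
    attr(out, "seed") <- seed
    class(out) <- c("burst_trials", class(out))
    out
  })
}

#' Retrieve the task configuration attached to a batch of trials
#'
#' @param trials A `burst_trials` tibble from [sample_trials()].
#' @return The generating [task_config()].
#' @export
trials_config <- function(trials) {
  cfg <- attr(trials, "config")
  if (is.null(cfg)) abort("`trials` carries no task_config attribute.")
  cfg
}

# Observation matrix (n_channels x n) of a single trial.
trial_matrix <- function(trials, id) {
  rows <- trials[trials$trial_id == id, , drop = FALSE]
  if (nrow(rows) == 0) abort("no such trial_id.")
  xcols <- grep("^x[0-9]+$", names(trials), value = TRUE)
  t(as.matrix(rows[order(rows$t), xcols, drop = FALSE]))
}

n_channels_of <- function(trials) {
  length(grep("^x[0-9]+$", names(trials)))
}

#' Export / import trial batches
#'
#' `write_trials()` writes the long trial table to a flat CSV (one row per
#' trial-timestep) plus a JSON sidecar `<path>.json` holding the generating
#' parameters and seed; `read_trials()` reads the pair back.
#'
#' @param trials A `burst_trials` tibble.
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   a `burst_trials` tibble.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  cfg <- attr(trials, "config")
  if (!is.null(cfg)) {
    hdr <- list(
      n = cfg$n, n_channels = cfg$n_channels, p_c = cfg$p_c, p_i = cfg$p_i,
      p_n = cfg$p_n, p_e = cfg$p_e, p_g = cfg$p_g,
      burst = list(kind = cfg$burst_model$kind, k = cfg$burst_model$k,
                   l_max = cfg$burst_model$l_max),
      seed = attr(trials, "seed")
    )
    jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    hdr <- jsonlite::read_json(side, simplifyVector = TRUE)
    bm <- if (hdr$burst$kind == "fixed") {
      burst_length_pmf("fixed", k = hdr$burst$k, l_max = hdr$burst$l_max)
    } else {
      burst_length_pmf(hdr$burst$kind, l_max = hdr$burst$l_max)
    }
    attr(out, "config") <- task_config(
      n = hdr$n, n_channels = hdr$n_channels, p_c = hdr$p_c, p_i = hdr$p_i,
      p_n = hdr$p_n, burst_model = bm, p_g = hdr$p_g
    )
    attr(out, "seed") <- hdr$seed
  }
  class(out) <- c("burst_trials", class(out))
  out
}

#' Plot the observation raster of one trial
#'
#' Shows the trinary observations of each channel over time, with the hidden
#' emission state overlaid, in the style of the task schematic.
#'
#' @param object A `burst_trials` tibble.
#' @param trial Which `trial_id` to draw (default: the first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burst_trials <- function(object, trial = NULL, ...) {
  trial <- trial %||% object$trial_id[1]
  df <- dplyr::filter(object, .data$trial_id == !!trial)
  long <- tidyr::pivot_longer(df, dplyr::matches("^x[0-9]+$"),
                              names_to = "channel", values_to = "x")
  long$row <- ifelse(long$channel == "emission", "E", long$channel)
  edf <- dplyr::distinct(df, .data$t, .data$e)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$channel,
                                     fill = factor(.data$x))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = dplyr::filter(edf, .data$e == 1),
      ggplot2::aes(x = .data$t, y = Inf), inherit.aes = FALSE,
      shape = 25, fill = "black", size = 1.5
    ) +
    ggplot2::scale_fill_manual(
      values = c("-1" = "#1f78b4", "0" = "grey92", "1" = "#e31a1c"),
      name = "x"
    ) +
    ggplot2::labs(
      x = "time step", y = NULL,
      title = sprintf("trial %s (m = %+d)", trial, df$m[1]),
      subtitle = "triangles mark emitting steps (E_t = 1)"
    ) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
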