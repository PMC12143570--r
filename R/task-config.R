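#' Configure a burst-detection task
#'
#' Bundles every generative parameter of one task variant. A trial has `n`
#' time steps and `n_channels` sensory channels. A hidden direction
#' \eqn{M \in \{-1, +1\}} is drawn uniformly; bursts of emission start at each
#' step (on an axis extended `l_max - 1` steps before the trial) with
#' probability `p_g` and last a number of steps drawn from `burst_model`.
#' While the target emits (\eqn{E_t = 1}), each channel independently reports
#' `M` with probability `p_c`, `-M` with probability `p_i`, and `0` otherwise;
#' while it is silent, channels report `0` with probability `p_n` and
#' \eqn{\pm 1} with equal probability `(1 - p_n)/2`. Trials with no emission at
#' all are resampled, and `p_g` is solved (via [solve_pg()]) so that the
#' expected emitting fraction equals the sparsity target `p_e`.
#'
#' Defaults follow the study conditions: `p_c = 0.45`, `p_i = 0.01`,
#' `p_n = 0.33`, `p_e = 0.04`, two channels, 200 steps.
#'
#' @param n Trial length in time steps.
#' @param n_channels Number of sensory channels \eqn{N_c} (1 = unisensory).
#' @param p_c,p_i Probabilities of the correct / incorrect direction value
#'   while emitting; `p_i <= p_c`, `p_c + p_i <= 1`.
#' @param p_n Probability of the neutral value 0 while silent.
#' @param p_e Target expected emission fraction (signal sparsity).
#' @param burst_model A [burst_length_pmf()] model.
#' @param p_g Optional explicit burst-start probability; by default solved
#'   from `p_e`.
#' @return An object of class `task_config`.
#' @examples
#' task_config(burst_model = burst_length_pmf("fixed", k = 2))
#' @export
task_config <- function(n = 200L, n_channels = 2L,
                        p_c = 0.45, p_i = 0.01, p_n = 0.33, p_e = 0.04,
                        burst_model = burst_length_pmf("fixed", k = 1L),
                        p_g = NULL) {
  if (!is_count(n)) abort("`n` must be a positive integer.")
  if (!is_count(n_channels)) abort("`n_channels` must be a positive integer.")
  if (!is_prob(p_c) || !is_prob(p_i) || p_i > p_c || p_c + p_i > 1)
    abort("need 0 <= p_i <= p_c and p_c + p_i <= 1.")
  if (!is_prob(p_n)) abort("`p_n` must lie in [0, 1].")
  if (!is_burst_model(burst_model)) abort("`burst_model` must be a burst_model.")
  if (is.null(p_g)) {
    if (!is_prob(p_e, open_left = TRUE, open_right = TRUE))
      abort("`p_e` must lie in (0, 1).")
    p_g <- solve_pg(p_e, burst_model, n)$p_g
  } else {
    if (!is_prob(p_g, open_left = TRUE, open_right = TRUE))
      abort("`p_g` must lie in (0, 1).")
    p_e <- pe_from_pg(p_g, burst_model, n)
  }
  structure(
    list(n = as.integer(n), n_channels = as.integer(n_channels),
         p_c = p_c, p_i = p_i, p_n = p_n, p_e = p_e, p_g = p_g,
         burst_model = burst_model),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  n = %d steps, %d channel(s); burst model: %s\n",
              x$n, x$n_channels, format(x$burst_model)))
  cat(sprintf("  p_c = %g, p_i = %g, p_n = %g\n", x$p_c, x$p_i, x$p_n))
  cat(sprintf("  sparsity p_e = %g -> burst-start p_g = %.6g\n", x$p_e, x$p_g))
  invisible(x)
}

is_task_config <- function(x) inherits(x, "task_config")

#' Shorthand task constructors for the standard study grid
#'
#' `task_spec()` names one of the ten standard task variants — fixed burst
#' lengths `k = 1..8`, uniform, or Levy (both on support `1..l_max`) — and
#' returns the corresponding [task_config()] at the default parameters.
#'
#' @param spec Either `"uniform"`, `"levy"`, or a fixed burst length given as
#'   an integer (or a string like `"k3"`).
#' @param l_max Support bound for the mixed-length laws (default 8).
#' @param ... Passed on to [task_config()] (e.g. `n`, `n_channels`, `p_e`).
#' @return A `task_config`.
#' @examples
#' task_spec(4)
#' task_spec("levy")
#' @export
task_spec <- function(spec, l_max = 8L, ...) {
  if (is.character(spec) && grepl("^k[0-9]+$", spec))
    spec <- as.integer(sub("^k", "", spec))
  model <- if (is.numeric(spec)) {
    burst_length_pmf("fixed", k = as.integer(spec))
  } else {
    burst_length_pmf(match.arg(spec, c("uniform", "levy")), l_max = l_max)
  }
  task_config(burst_model = model, ...)
}
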