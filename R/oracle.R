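#' Exact Bayes posterior by brute-force marginalisation
#'
#' Computes \eqn{P(M = +1 \mid X)} for a single trial by summing the
#' likelihood over every hidden configuration of burst starts and lengths on
#' the extended axis, conditioned on the rejection event (configurations with
#' no emission inside the trial are excluded, matching the sampler's
#' resampling). Each of the `n + l_max - 1` start positions is either silent
#' or starts a burst of one of the `l_max` lengths, so the sum runs over
#' \eqn{(1 + L_{max})^{n + L_{max} - 1}} configurations; this is only feasible
#' for tiny trials and exists as a correctness oracle for the simulator and
#' the classifiers, not as a usable decision rule.
#'
#' Likelihoods are accumulated in log space with the usual max-shift
#' stabilisation.
#'
#' @param x Observation matrix, `n_channels x n`, entries in \{-1, 0, +1\}.
#' @param config The generating [task_config()].
#' @param cap Guard on the number of configurations (default `1e7`); larger
#'   problems raise an intractability error naming the bound.
#' @return A one-row tibble of class `posterior_result`: `p_right`
#'   (\eqn{P(M=+1\mid X)}), `map_label` (+1 on the exact tie), `n_configs`.
#' @examples
#' cfg <- task_config(n = 4, p_e = 0.4,
#'                    burst_model = burst_length_pmf("levy", l_max = 2))
#' x <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L), nrow = 2)
#' exact_posterior(x, cfg)
#' @export
exact_posterior <- function(x, config, cap = 1e7) {
  if (!is_task_config(config)) abort("`config` must be a task_config.")
  if (!is.matrix(x) || !all(x %in% c(-1L, 0L, 1L)))
    abort("`x` must be a channels-by-time matrix over {-1, 0, 1}.")
  n <- ncol(x)
  if (n != config$n) abort("`x` has a different length than `config$n`.")
  lmax <- config$burst_model$l_max
  D <- n + lmax - 1L
  n_states <- 1L + lmax
  n_configs <- n_states^D
  if (n_configs > cap) {
    abort(sprintf(
      "exhaustive marginalisation over %d^%d = %g hidden configurations exceeds the cap of %g.",
      n_states, D, n_configs, cap
    ), class = "burstfusion_intractable")
  }

  # log-probabilities of the per-position states: 0 = no start, l = start of
  # a length-l burst
  state_logp <- log(c(1 - config$p_g, config$p_g * config$burst_model$pmf))

  # per-step log-likelihood of the observed column under each emission state;
  # zero probabilities are floored at 1e-300 so that impossible branches stay
  # finite (their weight underflows to zero in the final exponential)
  log_floor <- function(p) log(pmax(p, 1e-300))
  ll_silent <- colSums(log_floor(ifelse(x == 0, config$p_n,
                                        (1 - config$p_n) / 2)))
  ll_emit <- function(m) {
    colSums(log_floor(ifelse(x == m, config$p_c,
                      ifelse(x == -m, config$p_i,
                             1 - config$p_c - config$p_i))))
  }
  dplus <- ll_emit(1L) - ll_silent
  dminus <- ll_emit(-1L) - ll_silent
  base <- sum(ll_silent)

  acc_plus <- -Inf
  acc_minus <- -Inf
  lse2 <- function(a, b) {
    if (a == -Inf && b == -Inf) return(-Inf)
    mx <- max(a, b)
    mx + log(exp(a - mx) + exp(b - mx))
  }
  lse_vec <- function(v) {
    mx <- max(v)
    if (mx == -Inf) return(-Inf)
    mx + log(sum(exp(v - mx)))
  }

  chunk <- 100000L
  for (start in seq(0, n_configs - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_configs - 1)
    # decode mixed-radix digits: states of each of the D positions
    digits <- matrix(0L, length(idx), D)
    rem <- idx
    for (j in seq_len(D)) {
      digits[, j] <- rem %% n_states
      rem <- rem %/% n_states
    }
    logprior <- matrix(state_logp[digits + 1L], nrow(digits), D)
    logprior <- rowSums(logprior)
    # emission indicator per trial step
    e <- matrix(FALSE, length(idx), n)
    for (d in 0:(lmax - 1L)) {
      cols <- (1:n) + (lmax - 1L) - d
      e <- e | (digits[, cols, drop = FALSE] > d)
    }
    keep <- rowSums(e) > 0               # condition on the rejection event
    if (!any(keep)) next
    e <- e[keep, , drop = FALSE]
    lp <- logprior[keep]
    acc_plus <- lse2(acc_plus, lse_vec(lp + base + as.numeric(e %*% dplus)))
    acc_minus <- lse2(acc_minus, lse_vec(lp + base + as.numeric(e %*% dminus)))
  }

  # P(+1 | X) via the log-odds so a symmetric trial gives exactly 0.5
  p_right <- if (acc_plus == -Inf && acc_minus == -Inf) 0.5
             else stats::plogis(acc_plus - acc_minus)
  out <- tibble::tibble(
    p_right = p_right,
    map_label = ifelse(p_right >= 0.5, 1L, -1L),
    n_configs = n_configs
  )
  class(out) <- c("posterior_result", class(out))
  out
}

# Enumerate every non-silent hidden configuration once: returns the emission
# indicator matrix E (configurations x n) and the log prior of each kept
# configuration. Only used when the table fits comfortably in memory.
oracle_tables <- function(config, cap) {
  n <- config$n
  lmax <- config$burst_model$l_max
  D <- n + lmax - 1L
  n_states <- 1L + lmax
  n_configs <- n_states^D
  if (n_configs > cap) {
    abort(sprintf(
      "exhaustive marginalisation over %d^%d = %g hidden configurations exceeds the cap of %g.",
      n_states, D, n_configs, cap
    ), class = "burstfusion_intractable")
  }
  state_logp <- log(c(1 - config$p_g, config$p_g * config$burst_model$pmf))
  digits <- matrix(0L, n_configs, D)
  rem <- 0:(n_configs - 1)
  for (j in seq_len(D)) {
    digits[, j] <- rem %% n_states
    rem <- rem %/% n_states
  }
  lp <- rowSums(matrix(state_logp[digits + 1L], n_configs, D))
  e <- matrix(FALSE, n_configs, n)
  for (d in 0:(lmax - 1L)) {
    cols <- (1:n) + (lmax - 1L) - d
    e <- e | (digits[, cols, drop = FALSE] > d)
  }
  keep <- rowSums(e) > 0
  list(E = e[keep, , drop = FALSE] * 1, lp = lp[keep], n_configs = n_configs)
}

#' Oracle predictions for a batch of tiny trials
#'
#' Computes the exact posterior of every trial in a batch by enumerating the
#' hidden burst configurations once and scoring all observed patterns against
#' that table; equivalent to calling [exact_posterior()] per trial but far
#' faster for large batches.
#'
#' @param trials A `burst_trials` tibble from a tiny task.
#' @param config The generating [task_config()]; defaults to the one attached
#'   to `trials`.
#' @param cap Guard on the number of hidden configurations (default `1e6`
#'   here, where the enumeration is held in memory).
#' @return A tibble with one row per trial: `trial_id`, `m`, `p_right`,
#'   `pred`.
#' @export
oracle_predict <- function(trials, config = trials_config(trials), cap = 1e6) {
  n <- config$n
  tab <- oracle_tables(config, cap)
  first <- !duplicated(trials$trial_id)
  ids <- trials$trial_id[first]
  m <- trials$m[first]
  n_trials <- length(ids)

  log_floor <- function(p) log(pmax(p, 1e-300))
  xcols <- grep("^x[0-9]+$", names(trials), value = TRUE)
  # per-step log-likelihood contrasts, n x n_trials per class
  S0 <- 0; Sp <- 0; Sm <- 0
  for (col in xcols) {
    xi <- matrix(trials[[col]], n, n_trials)
    S0 <- S0 + log_floor(ifelse(xi == 0, config$p_n, (1 - config$p_n) / 2))
    lemit <- function(mm) {
      log_floor(ifelse(xi == mm, config$p_c,
                ifelse(xi == -mm, config$p_i, 1 - config$p_c - config$p_i)))
    }
    Sp <- Sp + lemit(1L)
    Sm <- Sm + lemit(-1L)
  }
  Dp <- Sp - S0                           # n x n_trials
  Dm <- Sm - S0
  lse_rows <- function(A) {
    mx <- apply(A, 1, max)
    mx + log(rowSums(exp(A - mx)))
  }
  p_right <- numeric(n_trials)
  chunk <- max(1L, floor(2e7 / nrow(tab$E)))
  for (start in seq(1, n_trials, by = chunk)) {
    j <- start:min(start + chunk - 1, n_trials)
    Ap <- t(Dp[, j, drop = FALSE]) %*% t(tab$E)   # trials x configs
    Am <- t(Dm[, j, drop = FALSE]) %*% t(tab$E)
    lp <- matrix(tab$lp, length(j), nrow(tab$E), byrow = TRUE)
    p_right[j] <- stats::plogis(lse_rows(Ap + lp) - lse_rows(Am + lp))
  }
  tibble::tibble(
    trial_id = ids, m = m, p_right = p_right,
    pred = ifelse(p_right >= 0.5, 1L, -1L)
  )
}
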