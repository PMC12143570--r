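#' Emission fraction for a fixed burst length
#'
#' Closed-form expected fraction of emitting time steps,
#' \eqn{p_e = P(E_t = 1 \mid \neg F)}, for the fixed-length task in which every
#' burst lasts exactly `k` steps, conditioned on the rejection event
#' \eqn{F = \{E_1 = \dots = E_n = 0\}} (all-silent trials are resampled):
#' \deqn{p_e = \frac{1 - (1 - p_g)^k}{1 - (1 - p_g)^{n + k - 1}}.}
#' Burst starts are sampled on the extended axis `(1 - k + 1), ..., n` so a
#' burst beginning before the trial can still cover its first steps; that is
#' where the `n + k - 1` exponent comes from.
#'
#' Powers are evaluated as `exp(k * log1p(-p_g))`, which stays accurate for the
#' small `p_g` and large `n` this is used with.
#'
#' @param p_g Per-step burst-start probability, in `[0, 1)`. At `p_g = 0` the
#'   limit `k / (n + k - 1)` (the smallest achievable sparsity) is returned.
#' @param k Burst length, a positive integer.
#' @param n Trial length in time steps.
#' @return The emission fraction, a scalar in `(0, 1]`.
#' @seealso [pe_from_pg()] for arbitrary burst-length laws, [solve_pg()] for
#'   the inverse problem.
#' @examples
#' pe_from_pg_fixed(0.1, k = 2, n = 10)
#' @export
pe_from_pg_fixed <- function(p_g, k, n) {
  if (!is_count(k)) abort("`k` must be a positive integer.")
  if (!is_count(n)) abort("`n` must be a positive integer.")
  if (!is_prob(p_g, open_right = TRUE)) abort("`p_g` must lie in [0, 1).")
  if (p_g == 0) return(k / (n + k - 1))
  lq <- log1p(-p_g)                       # log(1 - p_g)
  -expm1(k * lq) / -expm1((n + k - 1) * lq)
}

#' Emission fraction for an arbitrary burst-length law
#'
#' General closed form for the expected emitting fraction
#' \eqn{p_e = P(E_t = 1 \mid \neg F)} when burst lengths are drawn from a
#' distribution with pmf \eqn{q_\ell} on \eqn{1..L_{max}}:
#' \deqn{p_e = \frac{1 - \prod_\ell (1 - p_g (1 - Q_\ell))}
#'                  {1 - (1 - p_g)^n \prod_{j=2}^{L_{max}} (1 - p_g (1 - Q_j))},}
#' where \eqn{Q_\ell = P(L < \ell)}. The numerator is one minus the probability
#' that no burst starting at `t - l + 1` for any `l` is still running at `t`
#' (the factors range over distinct start positions and are independent). The
#' denominator conditions on the rejection event
#' \eqn{F = \{E_1 = \dots = E_n = 0\}}: a start at any position inside the
#' trial silences `F` regardless of its length, and a start `j - 1` steps
#' before the trial only if its length reaches step 1, giving
#' \eqn{P(F) = (1 - p_g)^n \prod_{j \ge 2} (1 - p_g P(L \ge j))}. (A form of
#' this denominator sometimes quoted as \eqn{\prod_\ell (1 - p_g
#' q_\ell)^{n+\ell-1}} treats the per-length silence events as independent
#' even though they constrain the same start positions, and overstates
#' \eqn{P(F)}; Monte-Carlo emission fractions from the rejection-filtered
#' sampler match the exact conditioning used here.) For a point mass at `k`
#' the expression reduces algebraically to [pe_from_pg_fixed()].
#'
#' @inheritParams pe_from_pg_fixed
#' @param burst_model A [burst_length_pmf()] model.
#' @return The emission fraction, a scalar in `(0, 1]`; at `p_g = 0` the limit
#'   \eqn{E[L] / (n - 1 + E[L])} is returned.
#' @examples
#' pe_from_pg(0.1, burst_length_pmf("levy", l_max = 2), n = 10)
#' @export
pe_from_pg <- function(p_g, burst_model, n) {
  if (!is_burst_model(burst_model)) abort("`burst_model` must be a burst_model.")
  if (any(burst_model$pmf < 0)) abort("burst-length pmf has negative mass.")
  if (!is_count(n)) abort("`n` must be a positive integer.")
  if (!is_prob(p_g, open_right = TRUE)) abort("`p_g` must lie in [0, 1).")
  q <- burst_model$pmf
  if (p_g == 0) {
    el <- burst_mean_length(burst_model)
    return(el / (n - 1 + el))
  }
  ell <- seq_along(q)
  Q <- cumsum(c(0, q))[ell]              # Q_l = P(L < l)
  tail_p <- 1 - Q                        # P(L >= l)
  num <- -expm1(sum(log1p(-p_g * tail_p)))
  # P(F): no start inside the trial (n positions), and no pre-trial start at
  # offset j - 1 long enough to reach step 1 (length >= j), j = 2..L_max
  log_pf <- n * log1p(-p_g) + sum(log1p(-p_g * tail_p[-1]))
  num / -expm1(log_pf)
}

#' Minimum achievable emission fraction
#'
#' The infimum of the emission fraction over `p_g`, reached as `p_g -> 0`:
#' `k / (n + k - 1)` for a fixed length `k`, and `E[L] / (n - 1 + E[L])` in
#' general. Target sparsities at or below this bound are infeasible.
#'
#' @inheritParams pe_from_pg
#' @return A scalar probability.
#' @export
pe_min <- function(burst_model, n) {
  if (!is_burst_model(burst_model)) abort("`burst_model` must be a burst_model.")
  el <- burst_mean_length(burst_model)
  el / (n - 1 + el)
}

#' Solve for the burst-start probability giving a target sparsity
#'
#' Numerically inverts the monotone map `p_g -> p_e` (see [pe_from_pg()]) by
#' bisection, so that the expected emitting fraction of a trial equals the
#' requested `p_e_target`. This is the normalisation that keeps the average
#' amount of signal constant across task variants with different burst-length
#' laws.
#'
#' @param p_e_target Desired emission fraction, strictly between the
#'   feasibility bound [pe_min()] and 1.
#' @param burst_model A [burst_length_pmf()] model.
#' @param n Trial length in time steps.
#' @param tol Absolute tolerance on the achieved `p_e` (default `1e-10`).
#' @return A one-row tibble of class `normalization_result` with columns
#'   `p_g`, `p_e_target`, `p_e_achieved`, `p_e_min`, `iterations`.
#' @examples
#' solve_pg(0.04, burst_length_pmf("fixed", k = 2), n = 200)
#' @export
solve_pg <- function(p_e_target, burst_model, n, tol = 1e-10) {
  if (!is_prob(p_e_target, open_left = TRUE, open_right = TRUE))
    abort("`p_e_target` must lie in (0, 1).")
  bound <- pe_min(burst_model, n)
  if (p_e_target <= bound) {
    abort(sprintf(
      "target sparsity p_e = %g is infeasible: the smallest achievable emission fraction for this burst model at n = %d is %g (fixed-k bound k/(n+k-1)).",
      p_e_target, as.integer(n), bound
    ), class = "burstfusion_infeasible_sparsity")
  }
  lo <- 0
  hi <- 1 - 1e-12
  if (pe_from_pg(hi, burst_model, n) < p_e_target)
    abort("`p_e_target` is not reachable for any p_g < 1.")
  iter <- 0L
  repeat {
    mid <- (lo + hi) / 2
    val <- pe_from_pg(mid, burst_model, n)
    iter <- iter + 1L
    if (val < p_e_target) lo <- mid else hi <- mid
    if (abs(val - p_e_target) <= tol || (hi - lo) < 1e-16 || iter >= 200L) break
  }
  out <- tibble::tibble(
    p_g = mid,
    p_e_target = p_e_target,
    p_e_achieved = val,
    p_e_min = bound,
    iterations = iter
  )
  class(out) <- c("normalization_result", class(out))
  out
}
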