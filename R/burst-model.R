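#' Burst-length distributions
#'
#' A burst-length model is the distribution of the number of consecutive time
#' steps an emission episode lasts once it has started. Three laws are
#' supported: a point mass at `k` ("fixed"), a discrete uniform on
#' `1..l_max` ("uniform"), and a truncated heavy-tailed law with
#' \eqn{P(L = \ell) \propto 1/\ell^2} on `1..l_max` ("levy"), the discrete
#' analogue of the step-length law of a Levy flight.
#'
#' @param kind One of `"fixed"`, `"uniform"`, `"levy"`.
#' @param k Burst length for the fixed law (ignored otherwise).
#' @param l_max Upper support bound \eqn{L_{max}} for the uniform and Levy
#'   laws; for the fixed law it defaults to `k`.
#'
#' @return An object of class `burst_model`: a list with elements `kind`,
#'   `l_max`, `k` (fixed law only, else `NA`), and `pmf`, a probability vector
#'   over lengths `1..l_max` summing to one.
#'
#' @examples
#' burst_length_pmf("levy", l_max = 2) # pmf (0.8, 0.2)
#' burst_length_pmf("fixed", k = 3)
#' @export
burst_length_pmf <- function(kind = c("fixed", "uniform", "levy"), k = 1L,
                             l_max = if (kind == "fixed") k else 8L) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (!is_count(k)) abort("`k` must be a positive integer.")
    l_max <- max(as.integer(l_max), as.integer(k))
    pmf <- numeric(l_max)
    pmf[k] <- 1
  } else {
    if (!is_count(l_max)) abort("`l_max` must be a positive integer.")
    l_max <- as.integer(l_max)
    k <- NA_integer_
    pmf <- switch(kind,
      uniform = rep(1 / l_max, l_max),
      levy = {
        w <- 1 / seq_len(l_max)^2
        w / sum(w)
      }
    )
  }
  structure(
    list(kind = kind, k = if (kind == "fixed") as.integer(k) else NA_integer_,
         l_max = l_max, pmf = pmf),
    class = "burst_model"
  )
}

#' @export
print.burst_model <- function(x, ...) {
  cat("<burst_model> kind =", x$kind,
      if (x$kind == "fixed") paste0("(k = ", x$k, ")"),
      "l_max =", x$l_max, "\n")
  cat("  pmf:", paste(signif(x$pmf, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
format.burst_model <- function(x, ...) {
  if (x$kind == "fixed") paste0("fixed k=", x$k) else x$kind
}

# Mean burst length E[L]; sets the infimum achievable sparsity.
burst_mean_length <- function(model) sum(seq_len(model$l_max) * model$pmf)

is_burst_model <- function(x) inherits(x, "burst_model")

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x, open_left = FALSE, open_right = FALSE) {
  length(x) == 1 && is.numeric(x) && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
}
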