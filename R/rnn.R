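#' Configure the recurrent classifier
#'
#' One hidden layer of rectified-linear units driven by the per-timestep
#' channel observations and its own previous state:
#' \deqn{h_t = ReLU(x_t W_{ih}^\top + h_{t-1} W_{hh}^\top + b_h), \qquad
#'       o_t = ReLU(h_t W_{ho}^\top + b_o),}
#' with \eqn{h_0 = 0}. Per-step outputs are summed over the trial and the
#' direction is the argmax of the summed outputs. Training minimises the
#' softmax cross-entropy of the summed outputs by backpropagation through
#' time with the Adam optimiser.
#'
#' @param n_hidden Hidden units (default 100).
#' @param n_channels Sensory channels the network will be driven by.
#' @param encoding `"raw"` feeds the trinary values directly (input width
#'   `n_channels`); `"onehot"` expands each channel into three indicator
#'   inputs (width `3 * n_channels`).
#' @param n_output Number of direction classes (default 2, for
#'   \eqn{M \in \{-1,+1\}}; class order is `-1` then `+1`).
#' @param n_bias Bias parameters per hidden unit (enters the parameter-count
#'   formula; default 1).
#' @param learning_rate Adam step size. The default `1e-6` is deliberately
#'   conservative; desk-scale experiments raise it (see the vignette).
#' @param n_epochs,batch_size Training budget.
#' @param output_relu Keep the rectification on the output layer (default
#'   `TRUE`); set `FALSE` for plain linear output scores.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @return An `rnn_config` list.
#' @export
rnn_config <- function(n_hidden = 100L, n_channels = 2L,
                       encoding = c("raw", "onehot"), n_output = 2L,
                       n_bias = 1L, learning_rate = 1e-6, n_epochs = 20L,
                       batch_size = 128L, output_relu = TRUE, seed = 1L) {
  encoding <- match.arg(encoding)
  if (!is_count(n_hidden)) abort("`n_hidden` must be a positive integer.")
  if (!is_count(n_output) || !is_count(n_channels) || !is_count(n_bias))
    abort("`n_channels`, `n_output` and `n_bias` must be positive integers.")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    abort("`learning_rate` must be positive.")
  structure(
    list(n_hidden = as.integer(n_hidden), n_channels = as.integer(n_channels),
         encoding = encoding, n_output = as.integer(n_output),
         n_bias = as.integer(n_bias), learning_rate = learning_rate,
         n_epochs = as.integer(n_epochs), batch_size = as.integer(batch_size),
         output_relu = isTRUE(output_relu), seed = as.integer(seed)),
    class = "rnn_config"
  )
}

rnn_input_width <- function(config) {
  if (config$encoding == "raw") config$n_channels else 3L * config$n_channels
}

#' Count the learnable parameters of the recurrent classifier
#'
#' Evaluates \eqn{(N_I N_H) + (N_H N_H) + (N_b N_H) + (N_H N_O) + N_O} for the
#' configured input, hidden, bias and output dimensions; this equals a direct
#' tally of the entries of the weight matrices and bias vectors of the built
#' network.
#'
#' @param config An [rnn_config()].
#' @return Integer parameter count.
#' @examples
#' count_rnn_parameters(rnn_config(n_hidden = 100, n_channels = 2))
#' @export
count_rnn_parameters <- function(config) {
  ni <- rnn_input_width(config)
  nh <- config$n_hidden
  (ni * nh) + (nh * nh) + (config$n_bias * nh) + (nh * config$n_output) +
    config$n_output
}

#' Initialise network weights
#'
#' Uniform \eqn{U(-1/\sqrt{N_H}, 1/\sqrt{N_H})} initialisation of all weight
#' matrices and biases, seeded from the config; the hidden state starts at
#' zero.
#'
#' @param config An [rnn_config()].
#' @return An `rnn_state` list with `W_ih`, `W_hh`, `W_ho`, `b_h`, `b_o`, `h`
#'   (current hidden state, a zero vector) and the config.
#' @export
rnn_init <- function(config) {
  ni <- rnn_input_width(config)
  nh <- config$n_hidden
  no <- config$n_output
  with_seed(config$seed, {
    s <- 1 / sqrt(nh)
    state <- list(
      W_ih = matrix(runif(nh * ni, -s, s), nh, ni),
      W_hh = matrix(runif(nh * nh, -s, s), nh, nh),
      W_ho = matrix(runif(no * nh, -s, s), no, nh),
      b_h = runif(nh, -s, s),
      # the output bias starts non-negative: with rectified outputs a
      # network whose output pre-activations are all negative has zero
      # gradient everywhere (a dead saddle), and a positive bias keeps the
      # output units alive at the start of training
      b_o = runif(no, 0, s),
      h = numeric(nh),
      config = config
    )
    class(state) <- "rnn_state"
    state
  })
}

#' One step of the recurrence
#'
#' Applies the hidden and output updates for a single time step and returns
#' the new state together with the output activity.
#'
#' @param state An `rnn_state` (its `h` field is the previous hidden state).
#' @param x_t Input vector for this step (length `n_input`).
#' @return A list with `state` (updated hidden state) and `o` (output
#'   activity for this step).
#' @export
rnn_step <- function(state, x_t) {
  if (length(x_t) != ncol(state$W_ih)) {
    abort(sprintf("input has length %d but the network expects %d.",
                  length(x_t), ncol(state$W_ih)))
  }
  h <- pmax(as.numeric(state$W_ih %*% x_t + state$W_hh %*% state$h + state$b_h), 0)
  o <- as.numeric(state$W_ho %*% h + state$b_o)
  if (state$config$output_relu) o <- pmax(o, 0)
  state$h <- h
  list(state = state, o = o)
}

# Encode a long trial table into a (B x I x n) input array.
rnn_encode <- function(trials, config) {
  nc <- n_channels_of(trials)
  if (nc != config$n_channels)
    abort("channel count of `trials` does not match the rnn_config.")
  n <- max(trials$t)
  B <- nrow(trials) / n
  ni <- rnn_input_width(config)
  arr <- array(0, c(B, ni, n))
  for (i in seq_len(nc)) {
    xi <- matrix(trials[[paste0("x", i)]], n, B)  # n x B
    if (config$encoding == "raw") {
      arr[, i, ] <- t(xi)
    } else {
      for (v in c(-1L, 0L, 1L)) {
        arr[, (i - 1L) * 3L + (v + 2L), ] <- t(xi == v) * 1
      }
    }
  }
  arr
}

# Batched forward pass. Returns summed outputs (B x O) and, if keep = TRUE,
# the per-step hidden states and output activities needed for BPTT.
rnn_forward <- function(state, arr, keep = FALSE) {
  cfg <- state$config
  B <- dim(arr)[1]
  n <- dim(arr)[3]
  nh <- cfg$n_hidden
  no <- cfg$n_output
  h <- matrix(0, B, nh)
  S <- matrix(0, B, no)
  Hs <- if (keep) array(0, c(B, nh, n))
  Os <- if (keep) array(0, c(B, no, n))
  tWih <- t(state$W_ih); tWhh <- t(state$W_hh); tWho <- t(state$W_ho)
  for (tt in seq_len(n)) {
    a <- arr[, , tt, drop = FALSE]
    dim(a) <- c(B, dim(arr)[2])
    h <- a %*% tWih + h %*% tWhh
    h <- pmax(sweep(h, 2, state$b_h, "+"), 0)
    o <- sweep(h %*% tWho, 2, state$b_o, "+")
    if (cfg$output_relu) o <- pmax(o, 0)
    S <- S + o
    if (keep) { Hs[, , tt] <- h; Os[, , tt] <- o }
  }
  list(S = S, Hs = Hs, Os = Os)
}

#' Predict directions with the recurrent classifier
#'
#' Runs the forward pass over each trial from a zero hidden state, sums the
#' output activities over time and takes the argmax over classes; an exact
#' tie is resolved to the lowest class index (class `-1`).
#'
#' @param object A trained `rnn_fit` (or a bare `rnn_state`).
#' @param trials A trial table with matching channel count.
#' @param ... Unused.
#' @return A tibble with `trial_id`, `m` (true label if present), the summed
#'   output for each class (`sum_m1`, `sum_p1`, ... for further classes), and
#'   `pred`.
#' @export
predict.rnn_fit <- function(object, trials, ...) {
  state <- if (inherits(object, "rnn_state")) object else object$state
  if (nrow(trials) == 0) abort("empty trial table.")
  arr <- rnn_encode(trials, state$config)
  S <- rnn_forward(state, arr)$S
  classes <- if (state$config$n_output == 2) c(-1L, 1L)
             else seq_len(state$config$n_output)
  pred <- classes[max.col(S, ties.method = "first")]
  first <- !duplicated(trials$trial_id)
  out <- tibble::tibble(
    trial_id = trials$trial_id[first],
    m = if ("m" %in% names(trials)) trials$m[first] else NA_integer_
  )
  sums <- as.data.frame(S)
  names(sums) <- if (state$config$n_output == 2) c("sum_m1", "sum_p1")
                 else paste0("sum_class", seq_len(ncol(S)))
  dplyr::bind_cols(out, tibble::as_tibble(sums), tibble::tibble(pred = pred))
}

#' @export
predict.rnn_state <- predict.rnn_fit

#' Train the recurrent classifier
#'
#' Mini-batch backpropagation through time on the softmax cross-entropy of
#' the summed outputs, with the Adam optimiser. The label `m = -1` maps to
#' class 1 and `m = +1` to class 2.
#'
#' @param trials Training trials with both direction labels present.
#' @param config An [rnn_config()]; its seed drives initialisation and the
#'   per-epoch shuffling.
#' @return An `rnn_fit`: list with the trained `state`, the `config`,
#'   `n_parameters`, and `loss` — a tibble of per-epoch mean cross-entropy.
#'   Errors with class `burstfusion_training_failure` if the loss becomes
#'   non-finite.
#' @examples
#' trials <- sample_trials(task_spec(1, n = 20, p_e = 0.2), 64, seed = 1)
#' fit <- train_rnn(trials, rnn_config(n_hidden = 8, n_epochs = 2,
#'                                     learning_rate = 1e-3))
#' fit$loss
#' @export
train_rnn <- function(trials, config) {
  state <- rnn_init(config)
  labels <- trials$m[!duplicated(trials$trial_id)]
  if (length(unique(labels)) < 2) {
    abort("training batch contains a single class.",
          class = "burstfusion_degenerate_training")
  }
  arr <- rnn_encode(trials, config)
  B_all <- dim(arr)[1]
  y <- ifelse(labels == 1, 2L, 1L)       # class index: -1 -> 1, +1 -> 2

  params <- c("W_ih", "W_hh", "W_ho", "b_h", "b_o")
  mom <- lapply(state[params], function(p) p * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  losses <- numeric(config$n_epochs)

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$n_epochs)) {
      ord <- sample.int(B_all)
      batch_loss <- 0; batch_n <- 0
      for (start in seq(1, B_all, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, B_all)]
        a <- arr[idx, , , drop = FALSE]
        fw <- rnn_forward(state, a, keep = TRUE)
        S <- fw$S
        # softmax cross-entropy on the summed outputs
        Smax <- apply(S, 1, max)
        Z <- exp(S - Smax)
        P <- Z / rowSums(Z)
        ll <- -log(pmax(P[cbind(seq_along(idx), y[idx])], 1e-300))
        if (!all(is.finite(ll))) {
          abort("training loss became non-finite.",
                class = "burstfusion_training_failure")
        }
        batch_loss <- batch_loss + sum(ll); batch_n <- batch_n + length(idx)

        g <- rnn_backward(state, a, fw, P, y[idx])

        step <- step + 1L
        for (p in params) {
          mom[[p]] <- beta1 * mom[[p]] + (1 - beta1) * g[[p]]
          vel[[p]] <- beta2 * vel[[p]] + (1 - beta2) * g[[p]]^2
          mhat <- mom[[p]] / (1 - beta1^step)
          vhat <- vel[[p]] / (1 - beta2^step)
          state[[p]] <- state[[p]] - config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      losses[epoch] <- batch_loss / batch_n
    }
  })

  structure(
    list(state = state, config = config,
         n_parameters = count_rnn_parameters(config),
         loss = tibble::tibble(epoch = seq_len(config$n_epochs),
                               loss = losses)),
    class = "rnn_fit"
  )
}

# Gradients of the summed-output cross-entropy by backpropagation through
# time. `P` are the softmax probabilities, `y` the class indices.
rnn_backward <- function(state, arr, fw, P, y) {
  cfg <- state$config
  B <- dim(arr)[1]; n <- dim(arr)[3]
  dS <- P
  dS[cbind(seq_len(B), y)] <- dS[cbind(seq_len(B), y)] - 1
  dS <- dS / B
  g <- list(W_ih = state$W_ih * 0, W_hh = state$W_hh * 0,
            W_ho = state$W_ho * 0, b_h = state$b_h * 0, b_o = state$b_o * 0)
  dh_next <- matrix(0, B, cfg$n_hidden)
  for (tt in rev(seq_len(n))) {
    h_t <- fw$Hs[, , tt, drop = FALSE]; dim(h_t) <- c(B, cfg$n_hidden)
    o_t <- fw$Os[, , tt, drop = FALSE]; dim(o_t) <- c(B, cfg$n_output)
    do_t <- if (cfg$output_relu) dS * (o_t > 0) else dS
    g$W_ho <- g$W_ho + t(do_t) %*% h_t
    g$b_o <- g$b_o + colSums(do_t)
    dh <- dh_next + do_t %*% state$W_ho
    da <- dh * (h_t > 0)
    x_t <- arr[, , tt, drop = FALSE]; dim(x_t) <- c(B, dim(arr)[2])
    h_prev <- if (tt > 1) {
      hp <- fw$Hs[, , tt - 1, drop = FALSE]; dim(hp) <- c(B, cfg$n_hidden); hp
    } else matrix(0, B, cfg$n_hidden)
    g$W_ih <- g$W_ih + t(da) %*% x_t
    g$W_hh <- g$W_hh + t(da) %*% h_prev
    g$b_h <- g$b_h + colSums(da)
    dh_next <- da %*% state$W_hh
  }
  g
}

#' @export
print.rnn_fit <- function(x, ...) {
  cat(sprintf("<rnn_fit> %d hidden units, %d parameters, %d epochs (final loss %.4f)\n",
              x$config$n_hidden, x$n_parameters, x$config$n_epochs,
              tail(x$loss$loss, 1)))
  invisible(x)
}

#' @export
tidy.rnn_fit <- function(x, ...) x$loss

#' @export
glance.rnn_fit <- function(x, ...) {
  tibble::tibble(
    n_hidden = x$config$n_hidden,
    n_parameters = x$n_parameters,
    encoding = x$config$encoding,
    learning_rate = x$config$learning_rate,
    n_epochs = x$config$n_epochs,
    final_loss = tail(x$loss$loss, 1)
  )
}

#' @export
autoplot.rnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy",
                  title = "RNN training loss") +
    ggplot2::theme_minimal()
}

#' Serialise RNN weights to JSON
#'
#' @param fit An `rnn_fit`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_rnn_fit()` restores the fit.
#' @export
write_rnn_fit <- function(fit, path) {
  out <- list(
    config = unclass(fit$config),
    weights = lapply(fit$state[c("W_ih", "W_hh", "W_ho", "b_h", "b_o")],
                     function(m) if (is.matrix(m)) list(dim = dim(m), x = as.numeric(m)) else list(dim = NULL, x = as.numeric(m))),
    loss = fit$loss$loss
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rnn_fit
#' @export
read_rnn_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(rnn_config, raw$config[setdiff(names(raw$config), NULL)])
  state <- rnn_init(config)
  for (p in names(raw$weights)) {
    w <- raw$weights[[p]]
    state[[p]] <- if (length(w$dim) == 2) {
      matrix(as.numeric(w$x), w$dim[[1]], w$dim[[2]])
    } else {
      as.numeric(w$x)
    }
  }
  structure(
    list(state = state, config = config,
         n_parameters = count_rnn_parameters(config),
         loss = tibble::tibble(epoch = seq_along(raw$loss), loss = raw$loss)),
    class = "rnn_fit"
  )
}
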