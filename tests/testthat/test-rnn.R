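test_that("a single recurrence step matches the hand-computed update", {
  cfg <- rnn_config(n_hidden = 1L, n_channels = 2L, n_output = 2L, seed = 1)
  st <- rnn_init(cfg)
  # 1 hidden unit: W_ih = (1, 0), W_hh = (1), biases 0
  st$W_ih <- matrix(c(1, 0), 1, 2)
  st$W_hh <- matrix(1, 1, 1)
  st$b_h <- 0
  st$W_ho <- matrix(c(1, 0), 2, 1)
  st$b_o <- c(0, 0)
  s1 <- rnn_step(st, c(1, 0))
  expect_equal(s1$state$h, 1)
  s2 <- rnn_step(s1$state, c(1, 0))
  expect_equal(s2$state$h, 2)            # accumulates through the recurrence
  expect_equal(s2$o, c(2, 0))
  # negative pre-activations rectify to exactly zero
  s3 <- rnn_step(s2$state, c(-10, 0))
  expect_equal(s3$state$h, 0)
  expect_error(rnn_step(st, c(1, 0, 0)), "length")
})

test_that("a zero network is silent and ties break to the lowest class", {
  cfg <- rnn_config(n_hidden = 3L, n_channels = 2L, seed = 2)
  st <- rnn_init(cfg)
  for (p in c("W_ih", "W_hh", "W_ho")) st[[p]][] <- 0
  st$b_h[] <- 0; st$b_o[] <- 0
  expect_equal(rnn_step(st, c(1, -1))$o, c(0, 0))
  tr <- sample_trials(short_task(1), 10, seed = 3)
  pred <- predict(st, tr)
  expect_true(all(pred$sum_m1 == 0 & pred$sum_p1 == 0))
  expect_true(all(pred$pred == -1L))     # tie -> lowest class index
})

test_that("scaling the output weights leaves decisions unchanged", {
  cfg <- rnn_config(n_hidden = 5L, n_channels = 2L, seed = 4)
  st <- rnn_init(cfg)
  tr <- sample_trials(short_task(1), 40, seed = 5)
  p1 <- predict(st, tr)
  st2 <- st
  st2$W_ho <- 2 * st$W_ho
  st2$b_o <- 2 * st$b_o                  # doubles every o_t
  p2 <- predict(st2, tr)
  expect_equal(p2$pred, p1$pred)
  expect_equal(p2$sum_p1, 2 * p1$sum_p1)
})

test_that("a hand-built gate detects channel agreement", {
  # one hidden unit firing only when both channels report +1; class +1 reads
  # it out, so any noiseless agreeing trial is classified +1
  cfg <- rnn_config(n_hidden = 1L, n_channels = 2L, seed = 6)
  st <- rnn_init(cfg)
  st$W_ih <- matrix(c(1, 1), 1, 2)
  st$W_hh <- matrix(0, 1, 1)
  st$b_h <- -1                           # needs x1 + x2 = 2 to fire
  st$W_ho <- matrix(c(0, 1), 2, 1)
  st$b_o <- c(0, 0)
  up <- tibble::tibble(trial_id = 1L, t = 1:4, m = 1L, e = 1L,
                       x1 = c(1L, 1L, 0L, 0L), x2 = c(1L, 1L, 0L, 0L))
  expect_equal(predict(st, up)$pred, 1L)
  down <- dplyr::mutate(up, x1 = -x1, x2 = -x2, m = -1L)
  expect_equal(predict(st, down)$pred, -1L)
})

test_that("the parameter-count formula matches a direct tally", {
  # printed formula at NI=6, NH=4, Nb=2, NO=2: 24 + 16 + 8 + 8 + 2 = 58
  cfg <- rnn_config(n_hidden = 4L, n_channels = 2L, encoding = "onehot",
                    n_output = 2L, n_bias = 2L)
  expect_equal(count_rnn_parameters(cfg), 58)
  expect_error(rnn_config(n_hidden = 0L))
  # tally the actual entries of a built network (single bias per unit)
  for (cfg in list(rnn_config(n_hidden = 7L, n_channels = 2L),
                   rnn_config(n_hidden = 3L, n_channels = 1L,
                              encoding = "onehot"),
                   rnn_config(n_hidden = 22L, n_channels = 2L))) {
    st <- rnn_init(cfg)
    tally <- length(st$W_ih) + length(st$W_hh) + length(st$W_ho) +
      length(st$b_h) + length(st$b_o)
    expect_equal(count_rnn_parameters(cfg), tally)
  }
})

test_that("training reduces the loss and can overfit a separable batch", {
  n <- 8
  mk <- function(id, m, v) tibble::tibble(trial_id = id, t = 1:n, m = m,
                                          e = 1L, x1 = v, x2 = v)
  tr <- dplyr::bind_rows(lapply(1:40, function(i) {
    if (i %% 2 == 0) mk(i, 1L, 1L) else mk(i, -1L, -1L)
  }))
  fit <- train_rnn(tr, rnn_config(n_hidden = 8L, n_epochs = 200L,
                                  learning_rate = 1e-3, batch_size = 20L,
                                  seed = 7))
  expect_lt(mean(tail(fit$loss$loss, 5)), mean(head(fit$loss$loss, 5)))
  expect_equal(mean(predict(fit, tr)$pred == tr$m[!duplicated(tr$trial_id)]), 1)
})

test_that("training is reproducible and the small configuration trains", {
  tr <- sample_trials(short_task(1, n = 20, p_e = 0.1), 60, seed = 8)
  cfg <- rnn_config(n_hidden = 22L, n_epochs = 3L, learning_rate = 1e-3,
                    seed = 9)
  f1 <- train_rnn(tr, cfg)
  f2 <- train_rnn(tr, cfg)
  expect_identical(f1$loss, f2$loss)
  expect_identical(predict(f1, tr), predict(f2, tr))
  expect_true(all(is.finite(f1$loss$loss)))
})

test_that("BPTT gradients agree with finite differences", {
  set.seed(10)
  cfg <- rnn_config(n_hidden = 3L, n_channels = 2L, n_epochs = 1L, seed = 11)
  st <- rnn_init(cfg)
  arr <- array(sample(c(-1, 0, 1), 2 * 2 * 5, replace = TRUE), c(2, 2, 5))
  y <- c(1L, 2L)
  loss_of <- function(state) {
    S <- burstfusion:::rnn_forward(state, arr)$S
    P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
    mean(-log(P[cbind(1:2, y)]))
  }
  fw <- burstfusion:::rnn_forward(st, arr, keep = TRUE)
  S <- fw$S
  P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
  g <- burstfusion:::rnn_backward(st, arr, fw, P, y)
  eps <- 1e-6
  for (p in c("W_ih", "W_hh", "W_ho", "b_h", "b_o")) {
    idx <- seq_len(min(4, length(st[[p]])))
    for (i in idx) {
      stp <- st; stp[[p]][i] <- stp[[p]][i] + eps
      stm <- st; stm[[p]][i] <- stm[[p]][i] - eps
      num <- (loss_of(stp) - loss_of(stm)) / (2 * eps)
      expect_equal(g[[p]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("rnn fits round-trip through JSON", {
  tr <- sample_trials(short_task(1, n = 20, p_e = 0.1), 30, seed = 12)
  fit <- train_rnn(tr, rnn_config(n_hidden = 4L, n_epochs = 2L,
                                  learning_rate = 1e-3, seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  write_rnn_fit(fit, path)
  back <- read_rnn_fit(path)
  expect_equal(predict(back, tr), predict(fit, tr))
  expect_equal(glance(back)$n_parameters, glance(fit)$n_parameters)
})
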