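# Data splitting, initialization, forward pass, gradients, training,
# serialization.

test_that("split_data sizes follow 60/30/10 with train-first remainders", {
  d1000 <- data.frame(window = character(1000L), label = 0L)
  s <- split_data(d1000, seed = 3L)
  expect_equal(vapply(s, nrow, integer(1L)),
               c(train = 600L, validation = 300L, test = 100L))

  d10 <- data.frame(window = character(10L), label = 0L)
  expect_equal(vapply(split_data(d10, seed = 3L), nrow, integer(1L)),
               c(train = 6L, validation = 3L, test = 1L))

  # n = 11: floors (6, 3, 1), remainder 1 -> train; n = 12: remainder to
  # train then validation
  d11 <- data.frame(window = character(11L), label = 0L)
  expect_equal(unname(vapply(split_data(d11, seed = 3L), nrow, integer(1L))),
               c(7L, 3L, 1L))
  d12 <- data.frame(window = character(12L), label = 0L)
  expect_equal(unname(vapply(split_data(d12, seed = 3L), nrow, integer(1L))),
               c(8L, 3L, 1L))

  expect_error(split_data(data.frame(window = character(9L), label = 0L)),
               "too few")
  expect_error(split_data(d1000, fractions = c(0.5, 0.3, 0.1)), "sum")
})

test_that("split_data is seed-deterministic and partitions the input", {
  d <- data.frame(window = sprintf("W%03d", 1:97), label = rep_len(0:1, 97))
  s1 <- split_data(d, seed = 10L)
  s2 <- split_data(d, seed = 10L)
  expect_identical(s1, s2)
  s3 <- split_data(d, seed = 11L)
  expect_false(identical(s1$train$window, s3$train$window))
  expect_equal(vapply(s1, nrow, integer(1L)), vapply(s3, nrow, integer(1L)))
  # disjoint union equals input
  all_windows <- c(s1$train$window, s1$validation$window, s1$test$window)
  expect_setequal(all_windows, d$window)
  expect_equal(anyDuplicated(all_windows), 0)
})

test_that("Glorot-normal initialization has the stated scale and zero biases", {
  cfg <- model_config()
  expect_equal(cfg$hidden_size, 112L)  # floor(336 / 3)
  w <- init_network(cfg, seed = 2L)
  expect_equal(dim(w$W1), c(336L, 112L))
  expect_length(w$w2, 112L)
  expect_equal(w$b1, numeric(112L))
  expect_equal(w$b2, 0)
  # Monte-Carlo check of sd = sqrt(2 / (fan_in + fan_out)) on 37k draws
  expect_equal(sd(w$W1), sqrt(2 / (336 + 112)), tolerance = 0.05)
  expect_equal(mean(w$W1), 0, tolerance = 0.005)
  # deterministic under seed
  expect_identical(w, init_network(cfg, seed = 2L))
})

test_that("forward pass matches hand arithmetic and degenerate cases", {
  # 2-input / 1-hidden toy, evaluated against explicit tanh/sigmoid formulas
  w <- structure(list(W1 = matrix(c(0.5, -0.3), 2L, 1L), b1 = 0.1,
                      w2 = 0.8, b2 = -0.2), class = "nn_weights")
  x <- c(0.5, -1.0)
  manual <- 1 / (1 + exp(-(0.8 * tanh(0.5 * 0.5 + (-0.3) * (-1) + 0.1) - 0.2)))
  expect_equal(nn_forward(w, x), manual, tolerance = 1e-9)

  # all-zero weights give sigmoid(0) = 0.5 for any input
  w0 <- structure(list(W1 = matrix(0, 2L, 3L), b1 = numeric(3L),
                       w2 = numeric(3L), b2 = 0), class = "nn_weights")
  expect_equal(nn_forward(w0, matrix(rnorm(10), 5L, 2L)), rep(0.5, 5L))

  # dropout rate 0: training and inference identical
  expect_equal(nn_forward(w, x, training = TRUE, dropout_rate = 0),
               nn_forward(w, x))

  expect_error(nn_forward(w, c(1, 2, 3)), "features")
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(14L, {
    d <- 6L; h <- 3L; n <- 5L
    w <- structure(list(W1 = matrix(rnorm(d * h, sd = 0.5), d, h),
                        b1 = rnorm(h, sd = 0.1),
                        w2 = rnorm(h, sd = 0.5), b2 = rnorm(1, sd = 0.1)),
                   class = "nn_weights")
    X <- matrix(rnorm(n * d), n, d)
    y <- c(0, 1, 1, 0, 1)
    mask <- matrix(rbinom(n * h, 1L, 0.5), n, h) / 0.5
  })
  for (mk in list(NULL, mask)) {
    lg <- procleave:::nn_loss_grads(w, X, y, mask = mk)
    eps <- 1e-6
    for (nm in c("W1", "b1", "w2", "b2")) {
      analytic <- lg$grads[[nm]]
      numeric_grad <- analytic
      for (i in seq_along(w[[nm]])) {
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
        numeric_grad[i] <-
          (procleave:::nn_loss_grads(wp, X, y, mask = mk)$loss -
             procleave:::nn_loss_grads(wm, X, y, mask = mk)$loss) / (2 * eps)
      }
      denom <- pmax(abs(numeric_grad), 1e-8)
      expect_lt(max(abs(analytic - numeric_grad) / denom), 1e-5)
    }
  }
})

test_that("training separates a planted P1 motif and fails on shuffled labels", {
  ds <- make_separable_dataset(400L, seed = 11L)
  model <- make_toy_model()
  te <- model$splits$test
  expect_gte(evaluate_model(model, te$window, te$label)$auc, 0.9)

  # training loss decreases over the first epochs (>= 4 of 5 steps)
  first <- head(model$history$train_loss, 6L)
  expect_gte(sum(diff(first) <= 0), 4L)

  # label-shuffled null: held-out AUC near chance
  ds_null <- ds
  ds_null$label <- withr::with_seed(77L, sample(ds$label))
  m_null <- train_cleavage_model(ds_null, config = fast_config(seed = 5L))
  te0 <- m_null$splits$test
  auc0 <- evaluate_model(m_null, te0$window, te0$label)$auc
  expect_gte(auc0, 0.3)
  expect_lte(auc0, 0.7)
})

test_that("training rejects degenerate inputs", {
  ds <- make_separable_dataset(60L, seed = 1L)
  ds$label <- 1L
  expect_error(train_cleavage_model(ds, config = fast_config()),
               "single-class")
})

test_that("training is bit-reproducible under fixed seeds", {
  ds <- make_separable_dataset(120L, seed = 21L)
  cfg <- model_config(max_epochs = 8L, patience = 5L, seed = 9L)
  m1 <- train_cleavage_model(ds, cfg)
  m2 <- train_cleavage_model(ds, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  w <- c("AAAFAAA", "KKKKKKK")
  expect_identical(predict_scores(m1, w)$score, predict_scores(m2, w)$score)
})

test_that("predict_scores is order-preserving and tolerant per row", {
  model <- make_toy_model()
  res <- predict_scores(model, c("AAAFAAA", "AXAAAAA", "aaafaaa", "AAAA"))
  expect_equal(res$status[c(1L, 3L)], c("ok", "ok"))
  expect_match(res$status[2L], "position 2")
  expect_match(res$status[4L], "7")
  expect_true(is.na(res$score[2L]) && is.na(res$score[4L]))
  expect_equal(res$score[1L], res$score[3L])  # case-normalized
  expect_true(all(res$score[c(1L, 3L)] > 0 & res$score[c(1L, 3L)] < 1))
})

test_that("model save/load round-trips exactly", {
  model <- make_toy_model()
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)

  expect_equal(unclass(back$config), unclass(model$config))
  expect_equal(back$weights$W1, model$weights$W1)
  expect_equal(back$standardizer$means, model$standardizer$means)
  expect_equal(back$history$val_loss, model$history$val_loss)

  wins <- vapply(1:25, function(i) random_window(), character(1L))
  expect_equal(predict_scores(back, wins)$score,
               predict_scores(model, wins)$score, tolerance = 1e-9)

  # truncated file: load error, no partial model
  broken <- tempfile(fileext = ".json")
  txt <- readLines(path, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1L, 500L), broken)
  expect_error(load_model(broken), "corrupted|not a")

  # wrong format tag
  other <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), other,
                       auto_unbox = TRUE)
  expect_error(load_model(other), "not a procleave model")
})
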