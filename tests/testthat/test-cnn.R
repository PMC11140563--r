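# Small-input configurations keep these tests fast; the full-scale recovery
# run lives in the acceptance suite.

tiny_data <- function(n = 24, len = 16, ch = 5, q = 3, seed = 1) {
  set.seed(seed)
  x <- array(rnorm(n * len * ch), c(n, len, ch))
  w <- matrix(rnorm(len * ch * q), len * ch, q)
  y <- matrix(x, n) %*% w + matrix(rnorm(n * q, sd = 0.05), n)
  list(x = x, y = y)
}

test_that("configurations outside the tuning grid are rejected", {
  expect_s3_class(cnn_config(), "cnn_config")
  expect_error(cnn_config(filters = 20), "filters")
  expect_error(cnn_config(kernel = 7), "kernel")
  expect_error(cnn_config(dropout = 0.25), "dropout")
  expect_error(cnn_config(dense_units = 100), "dense units")
  expect_error(cnn_config(learning_rate = 2e-3), "learning rate")
})

test_that("model building is deterministic with three conv blocks", {
  cfg <- cnn_config(seed = 3)
  m1 <- build_cnn(cfg)
  m2 <- build_cnn(cfg)
  expect_equal(length(m1$params$conv), 3)
  expect_identical(m1$params, m2$params)
  expect_equal(ncol(m1$params$W2), 10)
  # 272 positions shrink by kernel-1 per block, then pool by 2
  expect_equal(m1$shapes$conv_len, 272 - 3 * (cfg$kernel - 1))
  expect_equal(m1$shapes$pooled_len, m1$shapes$conv_len %/% 2)
})

test_that("backpropagation matches numeric gradients", {
  set.seed(42)
  cfg <- cnn_config(n_conv = 2, filters = 16, dropout = 0, dense_units = 32,
                    n_outputs = 2, seed = 7)
  d <- tiny_data(n = 4, q = 2)
  model <- abprop:::build_cnn(cfg, input_len = 16, input_ch = 5)
  loss_at <- function(params) {
    model$params <- params
    fwd <- abprop:::cnn_forward(model, d$x[1:4, , , drop = FALSE],
                                training = TRUE)
    mean(abs(fwd$out - d$y[1:4, 1:2]))
  }
  fwd <- abprop:::cnn_forward(model, d$x[1:4, , , drop = FALSE],
                              training = TRUE)
  err <- fwd$out - d$y[1:4, 1:2]
  grads <- abprop:::cnn_backward(model, fwd, sign(err) / length(err))
  eps <- 1e-6
  probes <- list(
    list(get = function(p) p$conv[[1]]$W,
         set = function(p, v) { p$conv[[1]]$W[] <- v; p },
         g = grads$conv[[1]]$W),
    list(get = function(p) p$conv[[2]]$gamma,
         set = function(p, v) { p$conv[[2]]$gamma[] <- v; p },
         g = grads$conv[[2]]$gamma),
    list(get = function(p) p$W1,
         set = function(p, v) { p$W1[] <- v; p }, g = grads$W1),
    list(get = function(p) p$b2,
         set = function(p, v) { p$b2[] <- v; p }, g = grads$b2))
  for (pr in probes) {
    p0 <- pr$get(model$params)
    idx <- sample(length(p0), min(4, length(p0)))
    for (j in idx) {
      up <- p0; up[j] <- up[j] + eps
      dn <- p0; dn[j] <- dn[j] - eps
      num <- (loss_at(pr$set(model$params, up)) -
                loss_at(pr$set(model$params, dn))) / (2 * eps)
      expect_equal(pr$g[j], num, tolerance = 1e-4)
    }
  }
})

test_that("training is seeded, checkpoints on validation MAE, aborts on NaN", {
  d <- tiny_data(n = 40)
  cfg <- cnn_config(n_conv = 1, filters = 16, dropout = 0, dense_units = 32,
                    n_outputs = 3, seed = 2)
  m1 <- train_cnn(d$x, d$y, cfg, epochs = 3)
  m2 <- train_cnn(d$x, d$y, cfg, epochs = 3)
  expect_identical(m1$history, m2$history)   # same seed, same trajectory
  expect_lte(m1$checkpoint_epoch, 3)
  # checkpoint keeps the minimum-validation epoch, not the last epoch
  m3 <- train_cnn(d$x, d$y, cfg, epochs = 12)
  expect_equal(m3$checkpoint_epoch, which.min(m3$history$val_mae))
  if (m3$checkpoint_epoch != nrow(m3$history))
    expect_false(identical(m3$params, m3$final_params))
  expect_error(train_cnn(d$x[1:8, , , drop = FALSE], d$y[1:8, ], cfg),
               "too small")
  expect_error(train_cnn(d$x, d$y * NA, cfg), "finite")
})

test_that("evaluation reports MAE, baseline and correlation sentinels", {
  d <- tiny_data(n = 24)
  cfg <- cnn_config(n_conv = 1, filters = 16, dropout = 0, dense_units = 32,
                    n_outputs = 3, seed = 2)
  m <- train_cnn(d$x, d$y, cfg, epochs = 1)
  # actuals equal to the model's own predictions: zero error, perfect r
  pred <- predict(m, d$x)
  ev <- evaluate_cnn(m, d$x, pred)
  expect_equal(ev$mae, rep(0, 3))
  expect_equal(ev$r, rep(1, 3))
  # anti-predictions (centred sign flip) give r = -1
  anti <- sweep(-sweep(pred, 2, colMeans(pred)), 2, colMeans(pred), "+")
  ev_anti <- evaluate_cnn(m, d$x, anti)
  expect_equal(ev_anti$r, rep(-1, 3))
  # constant actuals: correlation undefined, baseline zero
  ev2 <- evaluate_cnn(m, d$x[1:5, , , drop = FALSE], matrix(1, 5, 3))
  expect_true(all(is.na(ev2$r)))
  expect_equal(ev2$baseline_mae, rep(0, 3))
})

test_that("models persist through the JSON round trip", {
  d <- tiny_data(n = 24)
  cfg <- cnn_config(n_conv = 2, filters = 16, dropout = 0.1,
                    dense_units = 32, n_outputs = 3, seed = 4)
  m <- train_cnn(d$x, d$y, cfg, epochs = 2)
  dir <- tempfile()
  save_fv_cnn(m, dir)
  expect_true(file.exists(file.path(dir, "architecture.json")))
  m2 <- load_fv_cnn(dir)
  expect_equal(predict(m2, d$x), predict(m, d$x), tolerance = 1e-12)
  expect_equal(m2$checkpoint_epoch, m$checkpoint_epoch)
})

test_that("hyperparameter search respects the grid and the budget", {
  d <- tiny_data(n = 30)
  res <- tune_cnn(d$x, d$y, budget = 1, strategy = "random", epochs = 1,
                  seed = 9, batch_size = 8)
  expect_equal(nrow(res$trials), 1)
  expect_s3_class(res$best_config, "cnn_config")
  g <- abprop:::cnn_grid()
  expect_true(res$trials$filters %in% g$filters)
  expect_true(res$trials$kernel %in% g$kernel)

  res3 <- tune_cnn(d$x, d$y, budget = 3, strategy = "bayesian", epochs = 1,
                   seed = 9, batch_size = 8)
  expect_equal(nrow(res3$trials), 3)
  expect_equal(res3$best_val_mae, min(res3$trials$val_mae))
})

test_that("predict_descriptors emits 30 named columns and failure rows", {
  d <- make_surrogate_dataset(30, seed = 21)
  cfg <- cnn_config(filters = 16, dropout = 0, dense_units = 32, seed = 2)
  m <- train_cnn(d$x, d$y, cfg, epochs = 1)
  models <- list(SAP_pos = m, SCM_pos = m, SCM_neg = m)
  good <- make_synthetic_sequences(2, seed = 30)
  bad <- make_synthetic_sequences(1, seed = 31, violation = "cys_missing")
  bad$name <- "failing"
  out <- predict_descriptors(models, rbind(good, bad))
  expect_equal(nrow(out), 3)
  expect_true(all(descriptor_names() %in% names(out)))
  expect_equal(out$pass, c(TRUE, TRUE, FALSE))
  expect_true(all(is.na(out[3, descriptor_names()])))
  expect_match(out$reasons[3], "CYS_MISSING")
  # determinism: identical inputs give identical rows
  out2 <- predict_descriptors(models, rbind(good, bad))
  expect_identical(out, out2)
  # empty input: empty frame, still well-formed
  empty <- predict_descriptors(models, good[0, ])
  expect_equal(nrow(empty), 0)
})
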