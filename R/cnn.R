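# One-dimensional CNN surrogate mapping one-hot encoded Fv sequences (272 x
# 21) to the ten region scores of one spatial property. Implemented directly
# on BLAS matrix products: activations between layers are stored as
# (batch * positions) x channels matrices with row index (t - 1) * batch + b,
# so convolution is an im2col gather plus one matrix multiply and batch
# normalization is a per-column moment.

cnn_grid <- function() list(
  filters = seq(16L, 128L, 16L),
  kernel = 3:5,
  dropout = seq(0, 0.5, 0.1),
  dense_units = seq(32L, 128L, 16L),
  learning_rate = c(1e-2, 5e-3, 1e-3, 1e-4))

#' CNN surrogate configuration
#'
#' Hyperparameters are restricted to the tuning grid: filters 16-128 in steps
#' of 16, kernel size 3-5, dropout 0-0.5 in steps of 0.1, dense units 32-128
#' in steps of 16, learning rate in {1e-2, 5e-3, 1e-3, 1e-4}.
#'
#' @param n_conv number of convolutional blocks (default 3).
#' @param filters filters per block (scalar or length `n_conv`).
#' @param kernel kernel size.
#' @param dropout dropout rate after each block.
#' @param dense_units width of the dense layer.
#' @param learning_rate Adam step size.
#' @param n_outputs output width (default 10, one per region).
#' @param pool pooling width after the conv stack (default 2).
#' @param pool_type `"max"` or `"avg"` pooling.
#' @param loss `"mae"` (default) or `"mse"`.
#' @param seed weight-initialization / training seed.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(n_conv = 3, filters = 32, kernel = 3, dropout = 0.1,
                       dense_units = 64, learning_rate = 1e-3,
                       n_outputs = 10, pool = 2,
                       pool_type = c("max", "avg"), loss = c("mae", "mse"),
                       seed = 1) {
  loss <- match.arg(loss)
  pool_type <- match.arg(pool_type)
  g <- cnn_grid()
  chk <- function(x, grid, what) {
    if (!all(vapply(x, function(v) any(abs(v - grid) < 1e-9), TRUE)))
      stop(what, " outside the tuning grid: ", paste(x, collapse = ", "))
  }
  if (length(filters) == 1) filters <- rep(filters, n_conv)
  stopifnot(n_conv >= 1, length(filters) == n_conv)
  chk(filters, g$filters, "filters")
  chk(kernel, g$kernel, "kernel size")
  chk(dropout, g$dropout, "dropout rate")
  chk(dense_units, g$dense_units, "dense units")
  chk(learning_rate, g$learning_rate, "learning rate")
  structure(list(n_conv = n_conv, filters = as.integer(filters),
                 kernel = as.integer(kernel), dropout = dropout,
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 n_outputs = as.integer(n_outputs), pool = as.integer(pool),
                 pool_type = pool_type, loss = loss, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Instantiate a CNN from a configuration
#'
#' Architecture: input (272 x 21) -> `n_conv` x [conv (ReLU) -> batch norm ->
#' dropout] -> max pool -> flatten -> dense (ReLU) -> linear output.
#' Initialization is He-scaled and fully determined by `config$seed`.
#'
#' @param config a [cnn_config()].
#' @param input_len,input_ch input dimensions (defaults 272, 21).
#' @return An untrained `fv_cnn` model object (parameters, shapes, config).
#' @export
build_cnn <- function(config, input_len = 272, input_ch = 21) {
  stopifnot(inherits(config, "cnn_config"))
  set.seed(config$seed)
  len <- input_len
  ch <- input_ch
  conv <- vector("list", config$n_conv)
  for (i in seq_len(config$n_conv)) {
    f <- config$filters[i]
    k <- config$kernel
    fan_in <- k * ch
    conv[[i]] <- list(
      W = matrix(rnorm(fan_in * f, sd = sqrt(2 / fan_in)), f, fan_in),
      b = numeric(f),
      gamma = rep(1, f), beta = numeric(f),
      rmean = numeric(f), rvar = rep(1, f))
    len <- len - k + 1
    ch <- f
  }
  pooled_len <- len %/% config$pool
  flat <- pooled_len * ch
  params <- list(
    conv = conv,
    W1 = matrix(rnorm(flat * config$dense_units, sd = sqrt(2 / flat)),
                flat, config$dense_units),
    # small positive bias keeps the dense ReLU units alive early in
    # training; a zero output layer starts at the mean prediction, which
    # avoids the collapse where shrinking the output variance kills the
    # hidden layer before it learns features
    b1 = rep(0.1, config$dense_units),
    W2 = matrix(0, config$dense_units, config$n_outputs),
    b2 = numeric(config$n_outputs))
  structure(list(config = config, params = params,
                 shapes = list(input_len = input_len, input_ch = input_ch,
                               conv_len = len, pooled_len = pooled_len,
                               flat = flat),
                 trained = FALSE),
            class = "fv_cnn")
}

#' @export
print.fv_cnn <- function(x, ...) {
  cfg <- x$config
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat("1-D CNN surrogate: ", cfg$n_conv, " conv block(s) [filters ",
      paste(cfg$filters, collapse = "/"), ", kernel ", cfg$kernel,
      ", dropout ", cfg$dropout, "] -> pool ", cfg$pool, " -> dense ",
      cfg$dense_units, " -> ", cfg$n_outputs, " outputs; ",
      format(np, big.mark = ","), " parameters; ",
      if (isTRUE(x$trained)) paste0("trained (checkpoint epoch ",
                                    x$checkpoint_epoch, ")") else "untrained",
      "\n", sep = "")
  invisible(x)
}

# Activations are stored channels-first: a (channels x batch*positions)
# matrix whose column index is (t - 1) * batch + b. Per-channel affine ops
# (bias, batch norm) are then plain vector recycling down the columns, and
# the im2col block for kernel offset o is the contiguous column range
# ((o - 1) * batch + 1) : ((o - 1 + out_len) * batch).

conv_forward <- function(Z, batch, len, layer, k) {
  out_len <- len - k + 1
  ch <- nrow(Z)
  cols <- matrix(0, k * ch, batch * out_len)
  for (o in seq_len(k))
    cols[((o - 1) * ch + 1):(o * ch), ] <-
      Z[, ((o - 1) * batch + 1):((o - 1 + out_len) * batch)]
  A <- layer$W %*% cols + layer$b
  list(A = A, cols = cols, out_len = out_len)
}

conv_backward <- function(dA, cache, layer, batch, len, k) {
  dW <- tcrossprod(dA, cache$cols)
  db <- rowSums(dA)
  dcols <- crossprod(layer$W, dA)
  ch_in <- nrow(dcols) / k
  out_len <- cache$out_len
  dZ <- matrix(0, ch_in, batch * len)
  for (o in seq_len(k)) {
    colr <- ((o - 1) * batch + 1):((o - 1 + out_len) * batch)
    dZ[, colr] <- dZ[, colr, drop = FALSE] +
      dcols[((o - 1) * ch_in + 1):(o * ch_in), , drop = FALSE]
  }
  list(dZ = dZ, dW = dW, db = db)
}

bn_forward <- function(A, layer, training, eps = 1e-5, momentum = 0.9) {
  if (training) {
    mu <- rowMeans(A)
    xc <- A - mu
    v <- rowMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    layer$rmean <- momentum * layer$rmean + (1 - momentum) * mu
    layer$rvar <- momentum * layer$rvar + (1 - momentum) * v
  } else {
    inv <- 1 / sqrt(layer$rvar + eps)
    xhat <- (A - layer$rmean) * inv
  }
  Y <- xhat * layer$gamma + layer$beta
  list(Y = Y, xhat = xhat, inv = inv, layer = layer)
}

bn_backward <- function(dY, cache, gamma) {
  N <- ncol(dY)
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  # dX = inv/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dX <- (N * dxhat - s1 - cache$xhat * s2) * (cache$inv / N)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_index <- function(batch, len, width) {
  out_len <- len %/% width
  lapply(seq_len(width), function(o)
    as.vector(outer(seq_len(batch), ((seq_len(out_len) - 1) * width + o - 1) *
                      batch, "+")))
}

cnn_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  batch <- dim(X)[1]
  len <- dim(X)[2]
  Z <- t(matrix(X, batch * len, dim(X)[3]))
  caches <- list()
  for (i in seq_len(cfg$n_conv)) {
    cv <- conv_forward(Z, batch, len, p$conv[[i]], cfg$kernel)
    relu_mask <- cv$A > 0
    A <- cv$A * relu_mask
    bn <- bn_forward(A, p$conv[[i]], training)
    if (training) p$conv[[i]] <- bn$layer
    Y <- bn$Y
    drop_mask <- NULL
    if (training && cfg$dropout > 0) {
      drop_mask <- matrix((runif(length(Y)) >= cfg$dropout) /
                            (1 - cfg$dropout), nrow(Y), ncol(Y))
      Y <- Y * drop_mask
    }
    caches[[i]] <- list(conv = cv, relu = relu_mask, bn = bn,
                        drop = drop_mask, len_in = len)
    Z <- Y
    len <- cv$out_len
  }
  pidx <- pool_index(batch, len, cfg$pool)
  Z1 <- Z[, pidx[[1]], drop = FALSE]
  Z2 <- Z[, pidx[[2]], drop = FALSE]
  if (identical(cfg$pool_type, "avg")) {
    pool_mask <- NULL
    P <- (Z1 + Z2) / 2
  } else {
    pool_mask <- Z1 >= Z2
    P <- pmax(Z1, Z2)
  }
  plen <- len %/% cfg$pool
  ch <- nrow(P)
  # per-sample feature vectors, ordered channel-fastest within position
  Fm <- matrix(aperm(array(P, c(ch, batch, plen)), c(1, 3, 2)),
               ch * plen, batch)
  H <- crossprod(Fm, p$W1)                  # batch x dense
  H <- H + rep(p$b1, each = batch)
  relu1 <- H > 0
  H <- H * relu1
  out <- H %*% p$W2 + rep(p$b2, each = batch)
  list(out = out, caches = caches, pool = list(idx = pidx, mask = pool_mask,
                                               len = len, plen = plen),
       Fm = Fm, H = H, relu1 = relu1, params = p, batch = batch)
}

cnn_backward <- function(model, fwd, dOut) {
  cfg <- model$config
  p <- fwd$params
  batch <- fwd$batch
  grads <- list(conv = vector("list", cfg$n_conv))
  dH <- tcrossprod(dOut, p$W2)
  grads$W2 <- crossprod(fwd$H, dOut)
  grads$b2 <- colSums(dOut)
  dH <- dH * fwd$relu1
  grads$W1 <- fwd$Fm %*% dH                 # flat x dense
  grads$b1 <- colSums(dH)
  dF <- tcrossprod(p$W1, dH)                # flat x batch
  ch <- nrow(p$W1) / fwd$pool$plen          # channels after the conv stack
  dP <- matrix(aperm(array(dF, c(ch, fwd$pool$plen, batch)), c(1, 3, 2)),
               ch, batch * fwd$pool$plen)
  dZ <- matrix(0, ch, batch * fwd$pool$len)
  if (is.null(fwd$pool$mask)) {
    dZ[, fwd$pool$idx[[1]]] <- dP / 2
    dZ[, fwd$pool$idx[[2]]] <- dP / 2
  } else {
    dZ[, fwd$pool$idx[[1]]] <- dP * fwd$pool$mask
    dZ[, fwd$pool$idx[[2]]] <- dP * !fwd$pool$mask
  }
  for (i in rev(seq_len(cfg$n_conv))) {
    cc <- fwd$caches[[i]]
    if (!is.null(cc$drop)) dZ <- dZ * cc$drop
    bb <- bn_backward(dZ, cc$bn, p$conv[[i]]$gamma)
    dA <- bb$dX * cc$relu
    cb <- conv_backward(dA, cc$conv, p$conv[[i]], batch, cc$len_in,
                        cfg$kernel)
    grads$conv[[i]] <- list(W = cb$dW, b = cb$db, gamma = bb$dgamma,
                            beta = bb$dbeta)
    dZ <- cb$dZ
  }
  grads
}

adam_init <- function(params) rapply(params, function(x) x * 0, how = "replace")

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  upd <- function(p, g, m, v) {
    if (is.matrix(p)) dim(g) <- dim(p) else g <- as.vector(g)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk_named <- function(p, g, m, v) {
    # conv layers: only W, b, gamma, beta are trainable (running stats are not)
    for (i in seq_along(p$conv)) {
      for (nm in c("W", "b", "gamma", "beta")) {
        r <- upd(p$conv[[i]][[nm]], g$conv[[i]][[nm]],
                 m$conv[[i]][[nm]], v$conv[[i]][[nm]])
        p$conv[[i]][[nm]] <- r$p
        m$conv[[i]][[nm]] <- r$m
        v$conv[[i]][[nm]] <- r$v
      }
    }
    for (nm in c("W1", "b1", "W2", "b2")) {
      r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  walk_named(params, grads, state$m, state$v)
}

#' Train the CNN surrogate
#'
#' Splits the data into training/validation/test fractions, optimizes the
#' loss (mean absolute error by default) with Adam in minibatches, and keeps
#' the parameters from the epoch with minimum validation MAE (model
#' checkpointing); the returned model carries those checkpointed parameters,
#' not the final-epoch ones. Labels are standardized internally per output;
#' reported losses are on the original label scale. Fully seeded:
#' identical seeds give identical histories.
#'
#' @param x `n x 272 x 21` input array (see [encode_pairs()]).
#' @param y `n x n_outputs` label matrix.
#' @param config a [cnn_config()].
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 32).
#' @param split train/validation/test fractions (default 0.65/0.25/0.10).
#' @param lr_decay multiplicative learning-rate decay applied after each
#'   epoch (default 1 = constant rate).
#' @param verbose print per-epoch losses.
#' @param backend `"cpp"` (compiled minibatch step, the default) or `"r"`
#'   (the pure-R reference path; same computation, used as the oracle in the
#'   test suite).
#' @return A trained `fv_cnn` with `history` (epoch, train_loss, val_mae),
#'   `checkpoint_epoch`, and the split indices (`idx_train`, `idx_val`,
#'   `idx_test`).
#' @export
train_cnn <- function(x, y, config = cnn_config(), epochs = 50,
                      batch_size = 32, split = c(0.65, 0.25, 0.10),
                      lr_decay = 1, verbose = FALSE,
                      backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  stopifnot(length(dim(x)) == 3, nrow(y) == dim(x)[1])
  stopifnot(abs(sum(split) - 1) < 1e-8)
  n <- dim(x)[1]
  if (n < 10) stop("dataset too small: need at least 10 examples, got ", n)
  if (!all(is.finite(y))) stop("labels must be finite")
  model <- build_cnn(config, input_len = dim(x)[2], input_ch = dim(x)[3])
  set.seed(config$seed)
  perm <- sample(n)
  n_tr <- floor(split[1] * n)
  n_va <- floor(split[2] * n)
  idx_tr <- perm[seq_len(n_tr)]
  idx_va <- perm[n_tr + seq_len(n_va)]
  idx_te <- perm[(n_tr + n_va + 1):n]

  y_mu <- colMeans(y[idx_tr, , drop = FALSE])
  y_sd <- apply(y[idx_tr, , drop = FALSE], 2, stats::sd)
  y_sd[y_sd == 0] <- 1
  ys <- sweep(sweep(y, 2, y_mu), 2, y_sd, "/")

  x_va <- x[idx_va, , , drop = FALSE]
  state <- list(m = adam_init(model$params), v = adam_init(model$params))
  best <- list(val = Inf, params = model$params, epoch = 0)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_mae = numeric(0))
  t_step <- 0
  lr <- config$learning_rate
  for (ep in seq_len(epochs)) {
    ord <- sample(idx_tr)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0
    for (bt in batches) {
      if (length(bt) < 2) next  # batch statistics need >= 2 rows
      xb <- x[bt, , , drop = FALSE]
      yb <- ys[bt, , drop = FALSE]
      if (backend == "cpp") {
        Zb <- t(matrix(xb, length(bt) * dim(x)[2], dim(x)[3]))
        step <- tryCatch(
          .cnn_step_cpp(Zb, yb, length(bt), dim(x)[2], model$params,
                        config$kernel, config$dropout,
                        identical(config$pool_type, "avg"),
                        config$loss == "mae"),
          error = function(e) stop("non-finite loss at epoch ", ep,
                                   "; try a lower learning rate"))
        for (i in seq_len(config$n_conv)) {
          model$params$conv[[i]]$rmean <- step$bn_stats[[2 * i - 1]]
          model$params$conv[[i]]$rvar <- step$bn_stats[[2 * i]]
        }
        loss <- step$loss
        grads <- step$grads
      } else {
        fwd <- cnn_forward(model, xb, training = TRUE)
        model$params <- fwd$params  # running batch-norm statistics
        err <- fwd$out - yb
        if (!all(is.finite(err)))
          stop("non-finite loss at epoch ", ep,
               "; try a lower learning rate")
        if (config$loss == "mae") {
          loss <- mean(abs(err))
          dOut <- sign(err) / length(err)
        } else {
          loss <- mean(err^2)
          dOut <- 2 * err / length(err)
        }
        grads <- cnn_backward(model, fwd, dOut)
      }
      t_step <- t_step + 1
      st <- if (backend == "cpp")
        .adam_step_cpp(model$params, grads, state$m, state$v, lr, t_step)
      else adam_step(model$params, grads, state, lr, t_step)
      model$params <- st$p
      state$m <- st$m
      state$v <- st$v
      ep_loss <- ep_loss + loss * length(bt)
    }
    ep_loss <- ep_loss / length(ord)
    lr <- lr * lr_decay
    pred_va <- cnn_predict_scaled(model, x_va, backend = backend)
    pred_va <- sweep(sweep(pred_va, 2, y_sd, "*"), 2, y_mu, "+")
    val_mae <- mean(abs(pred_va - y[idx_va, , drop = FALSE]))
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                         val_mae = val_mae))
    if (val_mae < best$val)
      best <- list(val = val_mae, params = model$params, epoch = ep)
    if (verbose)
      cat(sprintf("epoch %3d  train %.4f  val MAE %.4f%s\n", ep, ep_loss,
                  val_mae, if (best$epoch == ep) "  *" else ""))
  }
  model$final_params <- model$params   # last-epoch state, kept for diagnostics
  model$params <- best$params
  model$trained <- TRUE
  model$checkpoint_epoch <- best$epoch
  model$history <- history
  model$y_center <- y_mu
  model$y_scale <- y_sd
  model$idx_train <- idx_tr
  model$idx_val <- idx_va
  model$idx_test <- idx_te
  model
}

cnn_predict_scaled <- function(model, x, chunk = 512, backend = "cpp") {
  n <- dim(x)[1]
  out <- matrix(NA_real_, n, model$config$n_outputs)
  for (s in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    if (backend == "cpp") {
      Zb <- t(matrix(x[s, , , drop = FALSE], length(s) * dim(x)[2],
                     dim(x)[3]))
      out[s, ] <- .cnn_infer_cpp(Zb, length(s), dim(x)[2], model$params,
                                 model$config$kernel,
                                 identical(model$config$pool_type, "avg"))
    } else {
      fwd <- cnn_forward(model, x[s, , , drop = FALSE], training = FALSE)
      out[s, ] <- fwd$out
    }
  }
  out
}

#' Predict region scores for encoded sequences
#' @param object a trained `fv_cnn`.
#' @param x `n x 272 x 21` array, or a single `272 x 21` matrix.
#' @param ... unused.
#' @return `n x n_outputs` matrix on the original label scale.
#' @export
predict.fv_cnn <- function(object, x, ...) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  pred <- cnn_predict_scaled(object, x)
  if (!is.null(object$y_center))
    pred <- sweep(sweep(pred, 2, object$y_scale, "*"), 2, object$y_center, "+")
  pred
}

#' Evaluate a surrogate on held-out data
#'
#' @param model a trained `fv_cnn`.
#' @param x,y held-out inputs and labels.
#' @return data.frame per output: `mae`, `baseline_mae` (constant mean
#'   predictor) and Pearson `r` (`NA` when the actuals are constant).
#' @export
evaluate_cnn <- function(model, x, y) {
  pred <- predict(model, x)
  per_out <- function(j) {
    a <- y[, j]; p <- pred[, j]
    r <- if (stats::sd(a) == 0 || stats::sd(p) == 0) NA_real_ else cor(a, p)
    c(mae = mean(abs(p - a)), baseline_mae = mean(abs(a - mean(a))), r = r)
  }
  out <- as.data.frame(t(vapply(seq_len(ncol(y)), per_out, numeric(3))))
  out$output <- colnames(y) %||% paste0("y", seq_len(ncol(y)))
  out[, c("output", "mae", "baseline_mae", "r")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- persistence ---------------------------------------------------------

#' Save / load a trained surrogate
#'
#' The architecture and training metadata go to `architecture.json`, the
#' weights to `weights.json` (plain-text containers so models travel with
#' the repository).
#'
#' @param model a trained `fv_cnn`.
#' @param dir target directory (created if needed).
#' @return `dir` (save) or the restored `fv_cnn` (load).
#' @export
save_fv_cnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arch <- list(config = unclass(model$config), shapes = model$shapes,
               trained = model$trained,
               checkpoint_epoch = model$checkpoint_epoch,
               y_center = model$y_center, y_scale = model$y_scale,
               history = model$history)
  jsonlite::write_json(arch, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(model$params, file.path(dir, "weights.json"),
                       digits = NA)
  invisible(dir)
}

#' @rdname save_fv_cnn
#' @export
load_fv_cnn <- function(dir) {
  arch <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
                           simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg <- do.call(cnn_config, arch$config[c("n_conv", "filters", "kernel",
                                           "dropout", "dense_units",
                                           "learning_rate", "n_outputs",
                                           "pool", "pool_type", "loss",
                                           "seed")])
  model <- build_cnn(cfg, arch$shapes$input_len, arch$shapes$input_ch)
  fix <- function(tmpl, got) {
    if (is.matrix(tmpl)) matrix(unlist(got), nrow(tmpl), ncol(tmpl))
    else as.numeric(unlist(got))
  }
  for (i in seq_along(model$params$conv))
    for (nm in names(model$params$conv[[i]]))
      model$params$conv[[i]][[nm]] <- fix(model$params$conv[[i]][[nm]],
                                          w$conv[[i]][[nm]])
  for (nm in c("W1", "b1", "W2", "b2"))
    model$params[[nm]] <- fix(model$params[[nm]], w[[nm]])
  model$trained <- arch$trained
  model$checkpoint_epoch <- arch$checkpoint_epoch
  model$y_center <- arch$y_center
  model$y_scale <- arch$y_scale
  model$history <- arch$history
  model
}

# ---- hyperparameter search ----------------------------------------------

sample_cnn_config <- function(seed_offset = 0, base_seed = 1) {
  g <- cnn_grid()
  cnn_config(filters = sample(g$filters, 1), kernel = sample(g$kernel, 1),
             dropout = sample(g$dropout, 1),
             dense_units = sample(g$dense_units, 1),
             learning_rate = sample(g$learning_rate, 1),
             seed = base_seed + seed_offset)
}

perturb_config <- function(cfg) {
  g <- cnn_grid()
  dim_ <- sample(names(g), 1)
  val <- sample(g[[dim_]], 1)
  args <- list(filters = cfg$filters[1], kernel = cfg$kernel,
               dropout = cfg$dropout, dense_units = cfg$dense_units,
               learning_rate = cfg$learning_rate, seed = cfg$seed + 1)
  args[[if (dim_ == "filters") "filters" else dim_]] <- val
  do.call(cnn_config, args)
}

#' Hyperparameter search over the CNN grid
#'
#' Three budgeted strategies: `"random"` (independent draws from the grid),
#' `"hyperband"` (successive halving: all trials run briefly, the better half
#' continues with doubled epochs), and `"bayesian"` (sequential: after an
#' initial random phase, new candidates are one-dimensional perturbations of
#' the best trial so far — a greedy adaptive search, not a full Gaussian
#' process). The winner is the trial with minimum validation MAE.
#'
#' @param x,y training data as in [train_cnn()].
#' @param budget number of candidate configurations (>= 1).
#' @param strategy `"random"`, `"hyperband"` or `"bayesian"`.
#' @param epochs full training length per surviving trial.
#' @param seed RNG seed for the search.
#' @param ... passed to [train_cnn()].
#' @return list: `best_config`, `best_val_mae`, `trials` (data.frame log).
#' @export
tune_cnn <- function(x, y, budget = 4,
                     strategy = c("random", "hyperband", "bayesian"),
                     epochs = 10, seed = 1, ...) {
  strategy <- match.arg(strategy)
  stopifnot(budget >= 1)
  set.seed(seed)
  run <- function(cfg, n_epochs) {
    # a diverging trial (e.g. too hot a learning rate) scores Inf rather
    # than aborting the whole search
    tryCatch({
      m <- train_cnn(x, y, cfg, epochs = n_epochs, ...)
      min(m$history$val_mae)
    }, error = function(e) Inf)
  }
  trials <- data.frame()
  log_trial <- function(cfg, val, n_epochs) {
    trials <<- rbind(trials, data.frame(
      filters = cfg$filters[1], kernel = cfg$kernel, dropout = cfg$dropout,
      dense_units = cfg$dense_units, learning_rate = cfg$learning_rate,
      epochs = n_epochs, val_mae = val))
  }
  configs <- lapply(seq_len(budget) - 1, sample_cnn_config, base_seed = seed)
  if (strategy == "hyperband" && budget > 1) {
    ep <- max(1, epochs %/% 4)
    while (length(configs) > 1 && ep < epochs) {
      vals <- vapply(configs, run, 0, n_epochs = ep)
      for (i in seq_along(configs)) log_trial(configs[[i]], vals[i], ep)
      keep <- order(vals)[seq_len(max(1, length(configs) %/% 2))]
      configs <- configs[keep]
      ep <- min(epochs, ep * 2)
    }
    vals <- vapply(configs, run, 0, n_epochs = epochs)
    for (i in seq_along(configs)) log_trial(configs[[i]], vals[i], epochs)
  } else if (strategy == "bayesian" && budget > 1) {
    n0 <- max(1, budget %/% 2)
    best_cfg <- NULL; best_val <- Inf
    for (i in seq_len(budget)) {
      cfg <- if (i <= n0 || is.null(best_cfg)) configs[[i]]
      else perturb_config(best_cfg)
      v <- run(cfg, epochs)
      log_trial(cfg, v, epochs)
      if (v < best_val) { best_val <- v; best_cfg <- cfg }
    }
  } else {
    vals <- vapply(configs, run, 0, n_epochs = epochs)
    for (i in seq_along(configs)) log_trial(configs[[i]], vals[i], epochs)
  }
  best_i <- which.min(trials$val_mae)
  best <- trials[best_i, ]
  best_config <- cnn_config(filters = best$filters, kernel = best$kernel,
                            dropout = best$dropout,
                            dense_units = best$dense_units,
                            learning_rate = best$learning_rate, seed = seed)
  list(best_config = best_config, best_val_mae = best$val_mae,
       trials = trials)
}

# ---- sequence -> descriptor prediction ------------------------------------

#' Predict the 30 spatial descriptors from sequences
#'
#' Runs the three property surrogates (SAP_pos, SCM_pos, SCM_neg; each with
#' 10 regional outputs) on every filter-passing sequence pair. Failing pairs
#' are kept as rows with their reason codes and `NA` descriptors.
#'
#' @param models named list of trained `fv_cnn` objects with elements
#'   `SAP_pos`, `SCM_pos`, `SCM_neg`.
#' @param pairs data.frame with columns name, heavy, light.
#' @return data.frame: name, pass, reasons, then the 30 canonical descriptor
#'   columns.
#' @export
predict_descriptors <- function(models, pairs) {
  stopifnot(all(ab_properties() %in% names(models)))
  cols <- descriptor_names()
  if (nrow(pairs) == 0) {
    empty <- data.frame(name = character(0), pass = logical(0),
                        reasons = character(0))
    for (cn in cols) empty[[cn]] <- numeric(0)
    return(empty)
  }
  enc <- encode_pairs(pairs)
  out <- enc$report
  out[cols] <- NA_real_
  if (dim(enc$x)[1] > 0) {
    preds <- lapply(ab_properties(), function(p) {
      m <- predict(models[[p]], enc$x)
      colnames(m) <- paste(p, ab_regions(), sep = "_")
      m
    })
    wide <- do.call(cbind, preds)[, cols, drop = FALSE]
    out[out$pass, cols] <- wide
  }
  out
}
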