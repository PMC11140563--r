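# Descriptor-based aggregation-rate modelling: exhaustive feature selection
# scored by repeated k-fold MSE, four regression families (linear, k-nearest
# neighbours, support-vector regression, random forest), leave-one-out
# cross-validation and the correlation-drop reliability rule.

#' Validate a descriptor feature table
#'
#' @param df data.frame holding the 30 canonical descriptor columns plus a
#'   numeric target column.
#' @param target target column name (default `"agg_rate"`).
#' @return The validated data.frame (invisibly classed `feature_table`).
#' @export
feature_table <- function(df, target = "agg_rate") {
  missing <- setdiff(c(descriptor_names(), target), names(df))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  cols <- c(descriptor_names(), target)
  if (anyNA(df[cols])) stop("feature table contains missing values")
  if (!all(vapply(df[cols], is.numeric, TRUE)))
    stop("descriptor and target columns must be numeric")
  attr(df, "target") <- target
  class(df) <- unique(c("feature_table", class(df)))
  df
}

# hyperparameter grids; the stated tuning ranges are hard bounds
agg_grid_bounds <- function(family) {
  switch(family,
         knn = list(k = c(2, 8)),
         svr = list(C = c(5, 15), epsilon = c(0.1, 0.5)),
         rf = list(max_depth = c(2, 6)),
         linear = list())
}

#' Default hyperparameter grids for the regression families
#' @param family one of `"linear"`, `"knn"`, `"svr"`, `"rf"`.
#' @return Named list of candidate values.
#' @export
default_grid <- function(family = c("linear", "knn", "svr", "rf")) {
  family <- match.arg(family)
  switch(family,
         linear = list(),
         knn = list(k = 2:8),
         svr = list(C = seq(5, 15, 2.5), epsilon = seq(0.1, 0.5, 0.1)),
         rf = list(max_depth = 2:6))
}

check_grid <- function(family, grid) {
  bounds <- agg_grid_bounds(family)
  for (nm in names(grid)) {
    if (!nm %in% names(bounds))
      stop("unknown hyperparameter for ", family, ": ", nm)
    b <- bounds[[nm]]
    if (any(grid[[nm]] < b[1] | grid[[nm]] > b[2]))
      stop(nm, " outside the allowed range [", b[1], ", ", b[2], "]")
  }
  grid
}

# standardization is fitted on the training rows only and applied to both
scale_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}
scale_apply <- function(x, s) sweep(sweep(x, 2, s$mu), 2, s$sd, "/")

knn_predict <- function(x_tr, y_tr, x_new, k) {
  d2 <- outer(rowSums(x_new^2), rowSums(x_tr^2), "+") -
    2 * x_new %*% t(x_tr)
  apply(d2, 1, function(row) mean(y_tr[order(row)[seq_len(min(k, length(row)))]]))
}

#' Fit one regression family on a feature subset
#'
#' Features are standardized (training statistics) for the distance- and
#' kernel-based families (`knn`, `svr`); `linear` and `rf` see raw features.
#'
#' @param x numeric feature matrix (rows = antibodies).
#' @param y numeric target.
#' @param family model family.
#' @param pars named hyperparameters (e.g. `k`, `C`, `epsilon`, `max_depth`).
#' @param seed seed for the stochastic families.
#' @return An `agg_fit` with a `predict` closure.
#' @keywords internal
fit_family <- function(x, y, family, pars = list(), seed = 1) {
  x <- as.matrix(x)
  if (family %in% c("knn", "svr")) {
    sc <- scale_fit(x)
    xs <- scale_apply(x, sc)
  } else {
    sc <- NULL
    xs <- x
  }
  pred_fun <- switch(
    family,
    linear = {
      fit <- stats::lm.fit(cbind(1, xs), y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      function(xn) as.vector(cbind(1, xn) %*% beta)
    },
    knn = {
      k <- pars$k %||% 5
      function(xn) knn_predict(xs, y, xn, k)
    },
    svr = {
      fit <- e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
                        cost = pars$C %||% 1, epsilon = pars$epsilon %||% 0.1,
                        scale = FALSE)
      function(xn) as.vector(predict(fit, xn))
    },
    rf = {
      set.seed(seed)
      depth <- pars$max_depth
      # depth acts through the leaf-count cap, bounded by the sample size
      fit <- randomForest::randomForest(
        xs, y, ntree = 300,
        maxnodes = if (is.null(depth)) NULL else min(2^depth, length(y)))
      function(xn) as.vector(predict(fit, xn))
    },
    stop("unknown family: ", family))
  structure(list(family = family, pars = pars, scale = sc,
                 predict = function(x_new) {
                   x_new <- as.matrix(x_new)
                   if (!is.null(sc)) x_new <- scale_apply(x_new, sc)
                   pred_fun(x_new)
                 }),
            class = "agg_fit")
}

# Fast path for scoring thousands of ordinary-least-squares subsets: the
# fold layout is drawn exactly as in repeated_kfold_mse (same seeds, so the
# two paths are interchangeable), and each subset is solved from slices of
# the per-fold Gram matrix instead of refitting lm.
efs_linear_mse <- function(x_all, y, subsets, folds, repeats, seed) {
  n <- length(y)
  stopifnot(n >= folds)
  xa <- cbind(`(Intercept)` = 1, x_all)
  idx_list <- lapply(subsets, function(s)
    c(1L, match(s, colnames(x_all)) + 1L))
  total <- matrix(0, length(subsets), 1)
  n_fold_evals <- 0
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      G <- crossprod(xa[tr, , drop = FALSE])
      cy <- crossprod(xa[tr, , drop = FALSE], y[tr])
      xte <- xa[!tr, , drop = FALSE]
      yte <- y[!tr]
      for (j in seq_along(subsets)) {
        idx <- idx_list[[j]]
        beta <- tryCatch(solve(G[idx, idx], cy[idx]),
                         error = function(e) qr.solve(G[idx, idx], cy[idx]))
        pred <- xte[, idx, drop = FALSE] %*% beta
        total[j] <- total[j] + mean((pred - yte)^2)
      }
      n_fold_evals <- n_fold_evals + 1
    }
  }
  as.vector(total) / n_fold_evals
}

repeated_kfold_mse <- function(x, y, family, pars, folds = 4, repeats = 5,
                               seed = 1) {
  n <- length(y)
  stopifnot(n >= folds)
  mses <- numeric(0)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_family(x[tr, , drop = FALSE], y[tr], family, pars,
                        seed = seed + r)
      p <- fit$predict(x[!tr, , drop = FALSE])
      mses <- c(mses, mean((p - y[!tr])^2))
    }
  }
  mean(mses)
}

#' Exhaustive feature selection
#'
#' Evaluates every size-`k` subset of the descriptor columns by mean MSE
#' under seeded repeated k-fold cross-validation and ranks subsets ascending
#' (ties broken lexicographically on the sorted feature names, for
#' reproducibility).
#'
#' @param table a [feature_table()].
#' @param k subset size.
#' @param family model family used for scoring (default `"linear"`).
#' @param pars hyperparameters for the scoring model.
#' @param folds,repeats,seed cross-validation control (defaults 4, 5, 1).
#' @param top keep only the best `top` rows (default all).
#' @param features candidate feature pool (default the 30 canonical
#'   descriptors).
#' @return An `efs_result` data.frame: features (joined by `+`), mse, rank.
#' @export
exhaustive_select <- function(table, k, family = "linear", pars = list(),
                              folds = 4, repeats = 5, seed = 1, top = Inf,
                              features = descriptor_names()) {
  stopifnot(inherits(table, "feature_table"))
  feats <- features
  if (k > length(feats)) stop("k exceeds the number of features")
  target <- attr(table, "target")
  y <- table[[target]]
  x_all <- as.matrix(table[feats])
  subsets <- combn(feats, k, simplify = FALSE)
  mse <- if (family == "linear" && length(pars) == 0)
    efs_linear_mse(x_all, y, subsets, folds, repeats, seed)
  else vapply(subsets, function(s)
    repeated_kfold_mse(x_all[, s, drop = FALSE], y, family, pars,
                       folds, repeats, seed), 0)
  key <- vapply(subsets, function(s) paste(sort(s), collapse = "+"), "")
  ord <- order(mse, key)
  out <- data.frame(features = key[ord], mse = mse[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "n_subsets") <- length(subsets)
  attr(out, "family") <- family
  if (is.finite(top)) out <- head(out, top)
  class(out) <- c("efs_result", class(out))
  out
}

#' Leave-one-out cross-validation for one family/subset
#'
#' Each antibody is predicted by a model trained on all others; returns the
#' held-out predictions with their Pearson correlation and MSE against the
#' observed targets (`r` is `NA` when the target is constant).
#'
#' @param table a [feature_table()].
#' @param subset character vector of descriptor names.
#' @param family model family.
#' @param pars hyperparameters.
#' @param seed seed for the stochastic families.
#' @return A `loocv_result`: list(predictions, r, mse).
#' @export
loocv <- function(table, subset, family = "linear", pars = list(), seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  y <- table[[attr(table, "target")]]
  n <- length(y)
  if (n < 3) stop("need at least 3 rows for leave-one-out validation")
  x <- as.matrix(table[subset])
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_family(x[-i, , drop = FALSE], y[-i], family, pars, seed = seed)
    preds[i] <- fit$predict(x[i, , drop = FALSE])
  }
  r <- if (stats::sd(y) == 0 || stats::sd(preds) == 0) NA_real_
  else cor(y, preds)
  structure(list(predictions = preds, r = r, mse = mean((preds - y)^2)),
            class = "loocv_result")
}

#' Fit and tune one regression family on a chosen feature subset
#'
#' Hyperparameters are selected over the grid by leave-one-out MSE (the
#' default criterion; `"kfold"` uses seeded repeated k-fold instead), then
#' the winning model is refit on all rows. Reported `r`/`mse` compare the
#' full-data fitted predictions with the targets; `loocv` carries the
#' held-out performance of the same hyperparameters.
#'
#' @param table a [feature_table()].
#' @param subset character vector of descriptor names.
#' @param family `"linear"`, `"knn"`, `"svr"` or `"rf"`.
#' @param grid candidate hyperparameters (default [default_grid()]); values
#'   outside the allowed tuning ranges are rejected.
#' @param criterion `"loocv"` or `"kfold"`.
#' @param folds,repeats,seed cross-validation control.
#' @return An `agg_model`: fit, family, pars, subset, r, mse, loocv.
#' @export
fit_and_tune <- function(table, subset, family = c("linear", "knn", "svr", "rf"),
                         grid = NULL, criterion = c("loocv", "kfold"),
                         folds = 4, repeats = 5, seed = 1) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  stopifnot(inherits(table, "feature_table"))
  if (is.null(grid)) grid <- default_grid(family)
  check_grid(family, grid)
  y <- table[[attr(table, "target")]]
  x <- as.matrix(table[subset])

  cand <- if (length(grid) == 0) list(list())
  else {
    gg <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(gg)), function(i) as.list(gg[i, , drop = FALSE]))
  }
  score <- vapply(cand, function(p) {
    if (criterion == "loocv")
      loocv(table, subset, family, p, seed = seed)$mse
    else repeated_kfold_mse(x, y, family, p, folds, repeats, seed)
  }, 0)
  best <- cand[[which.min(score)]]

  fit <- fit_family(x, y, family, best, seed = seed)
  fitted_vals <- fit$predict(x)
  mse <- mean((fitted_vals - y)^2)
  if (stats::sd(y) == 0)
    stop("constant target: the fit correlation is undefined (MSE = ",
         signif(mse, 4), ")")
  r <- cor(y, fitted_vals)
  cv <- loocv(table, subset, family, best, seed = seed)
  structure(list(fit = fit, family = family, pars = best, subset = subset,
                 fitted = fitted_vals, r = r, mse = mse, loocv = cv,
                 criterion = criterion, seed = seed),
            class = "agg_model")
}

#' @export
print.agg_model <- function(x, ...) {
  cat("Aggregation-rate model (", x$family, ") on ",
      paste(x$subset, collapse = " + "), "\n", sep = "")
  if (length(x$pars) > 0)
    cat("  tuned: ", paste(names(x$pars), unlist(x$pars), sep = " = ",
                           collapse = ", "), "\n", sep = "")
  cat(sprintf("  fit   r = %.3f, MSE = %.3f\n", x$r, x$mse))
  cat(sprintf("  LOOCV r = %.3f, MSE = %.3f (%s)\n", x$loocv$r, x$loocv$mse,
              if (reliability_check(x$r, x$loocv$r)) "reliable"
              else "not reliable"))
  invisible(x)
}

#' @export
predict.agg_model <- function(object, newdata, ...) {
  object$fit$predict(as.matrix(newdata[object$subset]))
}

#' Correlation-drop reliability rule
#'
#' A tuned model is accepted as reliable when its held-out (LOOCV)
#' correlation does not fall more than `threshold` below the full-data fit
#' correlation.
#'
#' @param fit_r full-data fit correlation.
#' @param loocv_r leave-one-out correlation.
#' @param threshold maximum tolerated drop (default 0.3).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
reliability_check <- function(fit_r, loocv_r, threshold = 0.3) {
  stopifnot(is.finite(fit_r), is.finite(loocv_r))
  (fit_r - loocv_r) <= threshold
}
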