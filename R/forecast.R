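#' Extract the spatial window around a matrix cell
#'
#' Returns the row-major flattening of the `w x w` block centered at
#' `(i, j)`; cells outside the matrix take the padding value (default 0,
#' since co-occurrence beyond the top-k keyword grid is unobserved and
#' sparse). The center value sits at position `(w^2 - 1) / 2 + 1`. With
#' `w = 1` the window degenerates to the cell value itself — the
#' keyword-only baseline.
#'
#' @param m numeric matrix.
#' @param i,j cell position, inside the matrix.
#' @param w odd positive window size.
#' @param pad padding value (default 0).
#' @return numeric vector of length `w^2`.
#' @export
extract_window <- function(m, i, j, w, pad = 0) {
  stopifnot(w >= 1, w %% 2 == 1)
  if (i < 1 || i > nrow(m) || j < 1 || j > ncol(m))
    stop("window center (", i, ",", j, ") outside the matrix")
  h <- (w - 1L) %/% 2L
  out <- matrix(pad, w, w)
  ri <- (i - h):(i + h)
  cj <- (j - h):(j + h)
  okr <- ri >= 1 & ri <= nrow(m)
  okc <- cj >= 1 & cj <= ncol(m)
  out[okr, okc] <- m[ri[okr], cj[okc]]
  as.vector(t(out))
}

# All w^2-column window features of a matrix at once: row k corresponds to
# cell (i, j) with cells enumerated column-major (i fastest), identical to
# as.vector(m). Equivalent to vapply(cells, extract_window) but vectorized
# through a zero-padded copy.
window_features <- function(m, w, pad = 0) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(pad, nr + 2L * h, nc + 2L * h)
  P[(1:nr) + h, (1:nc) + h] <- m
  X <- matrix(0, nr * nc, w * w)
  col <- 0L
  for (di in -h:h) {          # row offset varies slowest: row-major flatten
    for (dj in -h:h) {
      col <- col + 1L
      X[, col] <- as.vector(P[(1:nr) + h + di, (1:nc) + h + dj])
    }
  }
  X
}

#' Build the regression training set from tensor history
#'
#' One row per cell and per observed transition: features are the flattened
#' `w x w` window of the cell in bin `t - 1`, the target is the cell value
#' in bin `t`, for every target bin `t` in `2..upto`.
#'
#' @param tensor a `cooc_tensor`.
#' @param upto last target bin (1-based); must be at least 2 so that one
#'   transition exists.
#' @param w odd window size.
#' @param pad border padding value.
#' @return list with `X` (matrix, `w^2` columns), `y` (numeric vector),
#'   `index` (`data.frame` with `t`, `i`, `j`).
#' @export
build_training_set <- function(tensor, upto, w, pad = 0) {
  nb <- dim(tensor$counts)[1]
  if (upto < 2) stop("no history: need upto >= 2 (one observed transition)")
  if (upto > nb) stop("upto exceeds the number of bins")
  nr <- dim(tensor$counts)[2]; nc <- dim(tensor$counts)[3]
  Xs <- vector("list", upto - 1L)
  ys <- vector("list", upto - 1L)
  idx <- vector("list", upto - 1L)
  for (t in 2:upto) {
    prev <- matrix(tensor$counts[t - 1, , ], nr, nc)
    cur <- matrix(tensor$counts[t, , ], nr, nc)
    Xs[[t - 1]] <- window_features(prev, w, pad)
    ys[[t - 1]] <- as.vector(cur)
    idx[[t - 1]] <- data.frame(t = t, i = rep(seq_len(nr), times = nc),
                               j = rep(seq_len(nc), each = nr))
  }
  list(X = do.call(rbind, Xs), y = unlist(ys), index = do.call(rbind, idx))
}

forecast_backends <- c("svr", "lasso", "ridge", "elastic_net", "omp",
                       "passive_aggressive")

#' Fit a forecasting regressor
#'
#' Six backends mirror the evaluated regression algorithms with their
#' library-default hyperparameters:
#'
#' * `ridge`: closed-form solution of `||y - Xw||^2 + ||w||^2`.
#' * `lasso` / `elastic_net`: coordinate descent via glmnet with the fixed
#'   penalty `1/(2n) RSS + |w|_1` (lasso) or
#'   `1/(2n) RSS + 0.5 |w|_1 + 0.25 ||w||^2` (elastic net, mixing 0.5).
#' * `svr`: linear support vector regression, primal
#'   `0.5 ||w||^2 + C sum max(0, |r| - eps)^2` with `C = 1`, `eps = 0.1`,
#'   solved by BFGS (no kernel-SVM library is available, so the backend is
#'   linear rather than RBF).
#' * `omp`: greedy orthogonal matching pursuit keeping
#'   `max(1, floor(0.1 p))` nonzero coefficients, least-squares refit per
#'   step.
#' * `passive_aggressive`: online epsilon-insensitive updates
#'   (`tau = min(C, loss / |x|^2)`), shuffled epochs under `seed`.
#'
#' Features are standardized per column (mean 0, unit variance; constant
#' columns are left at 0) inside the pipeline for every backend, mirroring
#' the deprecated `normalize=True` behavior in an explicit, testable form.
#' Predictions are returned on the original target scale.
#'
#' @param backend one of `r paste0('"', forecast_backends, '"', collapse = ", ")`.
#' @param train a training set from [build_training_set()], or any list
#'   with `X` and `y`.
#' @param seed integer; fixes the sample order of the online backend.
#' @return a `cw_model` with `coef` (original feature scale), `intercept`,
#'   and the standardization parameters.
#' @export
fit <- function(backend, train, seed = 0) {
  if (!backend %in% forecast_backends)
    stop("unknown backend '", backend, "'; choose one of: ",
         paste(forecast_backends, collapse = ", "))
  X <- as.matrix(train$X); y <- as.numeric(train$y)
  if (nrow(X) == 0) stop("empty training set")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf   # constant columns -> standardized to 0
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  n <- nrow(Xs); p <- ncol(Xs)

  bs <- switch(backend,
    ridge = {
      # sklearn Ridge(alpha=1): RSS + ||w||^2, intercept unpenalized
      yc <- y - mean(y)
      w <- solve(crossprod(Xs) + diag(1, p), crossprod(Xs, yc))
      list(coef = drop(w), intercept = mean(y))
    },
    lasso = glmnet_fit(Xs, y, alpha = 1, lambda = 1),
    elastic_net = glmnet_fit(Xs, y, alpha = 0.5, lambda = 1),
    svr = svr_fit(Xs, y, C = 1, eps = 0.1),
    omp = omp_fit(Xs, y),
    passive_aggressive = pa_fit(Xs, y, C = 1, eps = 0.1, seed = seed)
  )
  # fold standardization into the reported coefficients
  coef_std <- bs$coef
  coef_raw <- coef_std / sdv
  coef_raw[!is.finite(coef_raw)] <- 0
  intercept_raw <- bs$intercept - sum(coef_raw * mu)
  structure(list(backend = backend, coef = coef_raw,
                 intercept = intercept_raw,
                 coef_std = coef_std, intercept_std = bs$intercept,
                 mu = mu, sd = sdv, seed = as.integer(seed)),
            class = "cw_model")
}

glmnet_fit <- function(Xs, y, alpha, lambda) {
  if (stats::var(y) == 0)
    return(list(coef = rep(0, ncol(Xs)), intercept = mean(y)))
  if (ncol(Xs) == 1) {
    # closed-form elastic net for one (centered) feature:
    # b = S(x.y/n, lambda*alpha) / (x.x/n + lambda*(1-alpha))
    n <- nrow(Xs)
    x <- Xs[, 1]
    rho <- sum(x * (y - mean(y))) / n
    b <- sign(rho) * max(0, abs(rho) - lambda * alpha) /
      (sum(x^2) / n + lambda * (1 - alpha))
    return(list(coef = b, intercept = mean(y) - b * mean(x)))
  }
  # glmnet internally rescales y by its (population) sd; for a fixed
  # user lambda this leaves the L1 term of the documented objective intact
  # but divides the L2 term by sd(y). Remap (lambda, alpha) so the fit
  # solves 1/(2n) RSS + lambda * (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
  # exactly as written.
  sy <- sqrt(mean((y - mean(y))^2))
  lam_u <- lambda * alpha + lambda * (1 - alpha) * sy
  alpha_u <- lambda * alpha / lam_u
  fitg <- glmnet::glmnet(Xs, y, family = "gaussian", alpha = alpha_u,
                         lambda = lam_u, standardize = FALSE,
                         intercept = TRUE, thresh = 1e-12, maxit = 1e6)
  b <- as.numeric(fitg$beta[, 1])
  list(coef = b, intercept = as.numeric(fitg$a0[1]))
}

svr_fit <- function(Xs, y, C = 1, eps = 0.1) {
  p <- ncol(Xs)
  obj <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    r <- y - Xs %*% w - b
    xi <- pmax(0, abs(r) - eps)
    0.5 * sum(w^2) + C * sum(xi^2)
  }
  grad <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    r <- drop(y - Xs %*% w - b)
    xi <- pmax(0, abs(r) - eps)
    g <- -2 * C * xi * sign(r)
    c(w + drop(crossprod(Xs, g)), sum(g))
  }
  th0 <- c(rep(0, p), mean(y))
  opt <- stats::optim(th0, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(coef = opt$par[1:p], intercept = opt$par[p + 1])
}

omp_fit <- function(Xs, y) {
  p <- ncol(Xs)
  k <- max(1L, floor(0.1 * p))
  yc <- y - mean(y)
  active <- integer(0)
  resid <- yc
  # columns that are all-zero (constants after standardization) never enter
  usable <- which(colSums(Xs^2) > 0)
  for (s in seq_len(k)) {
    if (length(usable) == 0) break
    cors <- abs(drop(crossprod(Xs[, usable, drop = FALSE], resid)))
    pick <- usable[which.max(cors)]
    active <- c(active, pick)
    usable <- setdiff(usable, pick)
    co <- stats::lsfit(Xs[, active, drop = FALSE], yc,
                       intercept = FALSE)$coefficients
    co[is.na(co)] <- 0
    resid <- yc - Xs[, active, drop = FALSE] %*% co
  }
  w <- rep(0, p)
  if (length(active) > 0) w[active] <- co
  list(coef = w, intercept = mean(y))
}

pa_fit <- function(Xs, y, C = 1, eps = 0.1, seed = 0, epochs = 50, tol = 1e-4) {
  n <- nrow(Xs); p <- ncol(Xs)
  w <- rep(0, p); b <- 0
  set.seed(seed)
  prev_loss <- Inf
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (k in ord) {
      x <- Xs[k, ]
      r <- y[k] - sum(w * x) - b
      loss <- max(0, abs(r) - eps)
      if (loss > 0) {
        nrm <- sum(x^2) + 1       # +1 for the intercept pseudo-feature
        tau <- min(C, loss / nrm)
        w <- w + sign(r) * tau * x
        b <- b + sign(r) * tau
      }
    }
    cur_loss <- mean(pmax(0, abs(y - Xs %*% w - b) - eps))
    if (abs(prev_loss - cur_loss) < tol) break
    prev_loss <- cur_loss
  }
  list(coef = w, intercept = b)
}

#' @export
print.cw_model <- function(x, ...) {
  cat("<cw_model> backend=", x$backend, ", ", length(x$coef),
      " features, intercept=", signif(x$intercept, 4), "\n", sep = "")
  invisible(x)
}

#' Predict responses for a feature matrix
#' @param object a `cw_model`.
#' @param X feature matrix on the original (unstandardized) scale.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.cw_model <- function(object, X, ...) {
  drop(as.matrix(X) %*% object$coef) + object$intercept
}

#' Predict one bin's matrix from the previous bin
#'
#' Applies the fitted model to every cell's window in the previous bin's
#' matrix (observed or itself predicted). Negative predictions are clamped
#' to 0; values stay real-valued — targets are counts but the coefficient
#' of determination is computed on raw predictions.
#'
#' @param model a `cw_model`.
#' @param prev numeric matrix of the previous bin.
#' @param w odd window size used at training time.
#' @param pad border padding value.
#' @return numeric predicted matrix, same shape as `prev`.
#' @export
predict_bin <- function(model, prev, w, pad = 0) {
  X <- window_features(prev, w, pad)
  pred <- predict(model, X)
  pred[pred < 0] <- 0
  matrix(pred, nrow(prev), ncol(prev))
}

#' Coefficient of determination over all matrix cells
#'
#' `R^2 = 1 - SS_res / SS_tot` with sums over the flattened cells.
#'
#' @param pred predicted real matrix.
#' @param actual observed count matrix, same shape, nonzero variance.
#' @return numeric scalar.
#' @export
evaluate_r2 <- function(pred, actual) {
  if (!all(dim(pred) == dim(actual))) stop("shape mismatch")
  a <- as.numeric(actual); p <- as.numeric(pred)
  ss_tot <- sum((a - mean(a))^2)
  if (ss_tot == 0) stop("R^2 undefined: actual values have zero variance")
  1 - sum((a - p)^2) / ss_tot
}

#' Single-step forecast of one bin with train-on-all-prior protocol
#'
#' Fits the backend on every observed transition with target bin `< t` and
#' predicts bin `t` from bin `t - 1`.
#'
#' @param tensor a `cooc_tensor`.
#' @param t target bin, at least 3 (so at least one prior transition
#'   exists for training).
#' @param backend backend name.
#' @param w odd window size.
#' @param seed integer seed.
#' @param pad border padding.
#' @return list with `pred` (matrix), `r2`, `model`.
#' @export
forecast_bin <- function(tensor, t, backend, w, seed = 0, pad = 0) {
  nb <- dim(tensor$counts)[1]
  stopifnot(t >= 3, t <= nb)
  train <- build_training_set(tensor, upto = t - 1, w = w, pad = pad)
  model <- fit(backend, train, seed = seed)
  prev <- matrix(tensor$counts[t - 1, , ], dim(tensor$counts)[2],
                 dim(tensor$counts)[3])
  pred <- predict_bin(model, prev, w, pad)
  actual <- matrix(tensor$counts[t, , ], nrow(pred), ncol(pred))
  list(pred = pred, r2 = evaluate_r2(pred, actual), model = model)
}

#' Recurrent multi-step forecast
#'
#' Fits the model once on all transitions observed before `start_bin`,
#' predicts `start_bin` from the last observed matrix, then rolls forward:
#' each subsequent horizon step is predicted from the previous
#' *prediction*. Predicted matrices are only ever features, never training
#' targets, so forecast errors are propagated but not learned from. The
#' `r2_trace` is filled for every predicted bin that has observed actuals.
#'
#' @param tensor a `cooc_tensor`.
#' @param start_bin first predicted bin (at least 3).
#' @param horizon number of bins to predict (at least 1); may extend past
#'   the observed bins, in which case `r2_trace` simply omits those bins.
#' @param backend backend name.
#' @param w odd window size.
#' @param seed integer seed.
#' @param pad border padding.
#' @return a `forecast_run`: list with `backend`, `w`, `start_bin`,
#'   `predictions` (list of matrices named by bin label or index),
#'   `r2_trace` (named numeric), `recurrent = TRUE`, `model`.
#' @export
recurrent_forecast <- function(tensor, start_bin, horizon, backend, w,
                               seed = 0, pad = 0) {
  nb <- dim(tensor$counts)[1]
  stopifnot(start_bin >= 3, start_bin <= nb, horizon >= 1)
  nr <- dim(tensor$counts)[2]; nc <- dim(tensor$counts)[3]
  train <- build_training_set(tensor, upto = start_bin - 1, w = w, pad = pad)
  model <- fit(backend, train, seed = seed)
  prev <- matrix(tensor$counts[start_bin - 1, , ], nr, nc)
  preds <- vector("list", horizon)
  r2 <- numeric(0)
  labels <- character(horizon)
  for (h in seq_len(horizon)) {
    t <- start_bin + h - 1L
    labels[h] <- if (t <= nb) tensor$binning$labels[t] else sprintf("bin%03d", t)
    pred <- predict_bin(model, prev, w, pad)
    preds[[h]] <- pred
    if (t <= nb) {
      actual <- matrix(tensor$counts[t, , ], nr, nc)
      r2[labels[h]] <- evaluate_r2(pred, actual)
    }
    prev <- pred
  }
  names(preds) <- labels
  structure(list(backend = backend, w = w, start_bin = start_bin,
                 predictions = preds, r2_trace = r2, recurrent = TRUE,
                 seed = as.integer(seed), model = model),
            class = "forecast_run")
}

#' @export
print.forecast_run <- function(x, ...) {
  cat("<forecast_run> ", x$backend, ", w=", x$w, ", ",
      length(x$predictions), " predicted bin(s), mean R^2 ",
      if (length(x$r2_trace)) signif(mean(x$r2_trace), 4) else NA, "\n",
      sep = "")
  invisible(x)
}

#' Sweep window sizes and backends, reporting mean R-squared
#'
#' For every backend and window size, forecasts each evaluable bin (every
#' bin with at least one prior observed transition, i.e. bins
#' `3..n_bins`, or `first_eval..n_bins` if given) with the single-step
#' train-on-all-prior protocol and averages the per-bin R-squared values.
#'
#' @param tensor a `cooc_tensor`.
#' @param sizes odd window sizes (e.g. `c(1, 3, 5, 7, 9)`).
#' @param backends backend names.
#' @param seed integer seed.
#' @param first_eval first evaluated bin (default 3).
#' @param pad border padding.
#' @return `data.frame` with columns `backend`, `w`, `mean_r2`, `n_bins`.
#' @export
window_size_sweep <- function(tensor, sizes = c(1, 3, 5, 7, 9),
                              backends = "ridge", seed = 0,
                              first_eval = 3, pad = 0) {
  stopifnot(all(sizes %% 2 == 1), first_eval >= 3)
  nb <- dim(tensor$counts)[1]
  if (first_eval > nb) stop("no evaluable bins")
  grid <- expand.grid(backend = backends, w = sizes,
                      stringsAsFactors = FALSE)
  grid$mean_r2 <- NA_real_
  grid$n_bins <- 0L
  for (g in seq_len(nrow(grid))) {
    r2s <- vapply(first_eval:nb, function(t) {
      forecast_bin(tensor, t, grid$backend[g], grid$w[g], seed = seed,
                   pad = pad)$r2
    }, numeric(1))
    grid$mean_r2[g] <- mean(r2s)
    grid$n_bins[g] <- length(r2s)
  }
  grid
}
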