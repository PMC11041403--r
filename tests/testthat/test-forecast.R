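# the window worked example: center 4, row-major neighbors 5,3,5,3,4,7,5,4
worked_example_matrix <- function() {
  matrix(c(5, 3, 5,
           3, 4, 4,
           7, 5, 4), 3, 3, byrow = TRUE)
}

test_that("extract_window flattens row-major with zero padding", {
  m <- worked_example_matrix()
  # w = 1: the cell itself, for every cell
  for (i in 1:3) for (j in 1:3)
    expect_equal(extract_window(m, i, j, 1), m[i, j])

  win <- extract_window(m, 2, 2, 3)
  expect_equal(length(win), 9)
  expect_equal(win[5], 4)                            # center position (w^2-1)/2 + 1
  expect_equal(win[-5], c(5, 3, 5, 3, 4, 7, 5, 4))   # row-major neighbors
  expect_equal(sum(win[-5]), 36)

  # corner of a 2x2 matrix: 5 padded zeros + the 4 real values
  m2 <- matrix(c(1, 3, 2, 4), 2)
  w2 <- extract_window(m2, 1, 1, 3)
  expect_equal(w2, c(0, 0, 0, 0, 1, 2, 0, 3, 4))
  expect_equal(sum(w2 == 0), 5)

  # explicit index-bounds oracle across every cell and size
  set.seed(31)
  m3 <- matrix(rpois(30, 5), 5, 6)
  for (w in c(1, 3, 5)) {
    h <- (w - 1) / 2
    for (i in 1:5) for (j in 1:6) {
      oracle <- numeric(0)
      for (di in -h:h) for (dj in -h:h) {
        r <- i + di; c <- j + dj
        oracle <- c(oracle,
                    if (r >= 1 && r <= 5 && c >= 1 && c <= 6) m3[r, c] else 0)
      }
      expect_equal(extract_window(m3, i, j, w), oracle)
    }
  }
  expect_error(extract_window(m, 0, 1, 3), "outside")
  expect_error(extract_window(m, 1, 1, 2), "w")
})

fixed_tensor <- function(bins, nr, nc, fill) {
  counts <- array(fill, c(bins, nr, nc))
  new_cooc_tensor <- getFromNamespace("new_cooc_tensor", "cowordcast")
  new_cooc_tensor(counts, time_binning(0L, bins * 6L - 1L, 6),
                  paste0("a", seq_len(nr)), paste0("b", seq_len(nc)))
}

test_that("build_training_set enumerates cells x transitions", {
  set.seed(7)
  t33 <- fixed_tensor(2, 3, 3, rpois(2 * 9, 4))
  ts1 <- build_training_set(t33, upto = 2, w = 3)
  expect_equal(nrow(ts1$X), 9)             # one transition, 9 cells
  expect_equal(ncol(ts1$X), 9)

  t22 <- fixed_tensor(5, 2, 2, rpois(20, 4))
  ts2 <- build_training_set(t22, upto = 5, w = 3)
  expect_equal(nrow(ts2$X), 16)            # 4 transitions x 4 cells

  # nested-loop oracle on a random 4-bin tensor
  t4 <- fixed_tensor(4, 3, 4, rpois(48, 6))
  ts <- build_training_set(t4, upto = 4, w = 3)
  for (r in seq_len(nrow(ts$X))) {
    t <- ts$index$t[r]; i <- ts$index$i[r]; j <- ts$index$j[r]
    prev <- matrix(t4$counts[t - 1, , ], 3, 4)
    expect_equal(ts$X[r, ], extract_window(prev, i, j, 3))
    expect_equal(ts$y[r], t4$counts[t, i, j])
  }
  expect_error(build_training_set(t4, upto = 1, w = 3), "history")
})

test_that("all backends fit constants and recover exact linear structure", {
  set.seed(13)
  X <- matrix(rnorm(200 * 5), 200, 5)
  for (b in c("svr", "lasso", "ridge", "elastic_net", "omp",
              "passive_aggressive")) {
    mod <- fit(b, list(X = X, y = rep(7, 200)))
    expect_equal(unname(predict(mod, X)), rep(7, 200), tolerance = 0.11,
                 info = b)
  }
  # exact linear target: ridge (tiny default penalty) attains R^2 > 0.999
  y <- drop(X %*% c(2, -1, 0.5, 0, 3)) + 4
  mod <- fit("ridge", list(X = X, y = y))
  pred <- predict(mod, X)
  expect_gt(1 - sum((y - pred)^2) / sum((y - mean(y))^2), 0.999)

  expect_error(fit("boosting", list(X = X, y = y)), "unknown backend")
})

test_that("lasso and elastic net match an independent coordinate descent", {
  set.seed(17)
  n <- 200; p <- 6
  X <- matrix(rnorm(n * p, sd = 2), n, p)
  y <- drop(X %*% c(3, 0, -2, 0, 1, 0.5)) + rnorm(n, sd = 5) + 20
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  for (cfg in list(list(b = "lasso", alpha = 1),
                   list(b = "elastic_net", alpha = 0.5))) {
    mod <- fit(cfg$b, list(X = X, y = y))
    ora <- cd_enet(Xs, y, lambda = 1, alpha = cfg$alpha)
    expect_equal(mod$coef_std, ora$coef, tolerance = 1e-5, info = cfg$b)
    expect_equal(mod$intercept_std, ora$intercept, tolerance = 1e-5,
                 info = cfg$b)
  }
})

test_that("passive aggressive and pa determinism under seed", {
  set.seed(23)
  X <- matrix(rnorm(300 * 4), 300, 4)
  y <- drop(X %*% c(1, 2, -1, 0.5)) + 3 + rnorm(300, sd = 0.05)
  m1 <- fit("passive_aggressive", list(X = X, y = y), seed = 5)
  m2 <- fit("passive_aggressive", list(X = X, y = y), seed = 5)
  expect_identical(m1$coef, m2$coef)
  # converges near the regression solution on clean data
  pred <- predict(m1, X)
  expect_gt(1 - sum((y - pred)^2) / sum((y - mean(y))^2), 0.95)
})

test_that("predict_bin equals the per-cell loop and clamps at zero", {
  set.seed(19)
  t3 <- fixed_tensor(3, 3, 3, rpois(27, 8))
  train <- build_training_set(t3, upto = 3, w = 3)
  mod <- fit("ridge", train)
  prev <- matrix(t3$counts[3, , ], 3, 3)
  pred <- predict_bin(mod, prev, w = 3)
  for (i in 1:3) for (j in 1:3) {
    cell <- predict(mod, rbind(extract_window(prev, i, j, 3)))
    expect_equal(pred[i, j], max(0, cell))
  }
  # a model that ignores features predicts its intercept everywhere
  mod0 <- mod
  mod0$coef[] <- 0
  mod0$intercept <- 5.5
  expect_equal(predict_bin(mod0, prev, 3), matrix(5.5, 3, 3))
  mod0$intercept <- -2
  expect_equal(predict_bin(mod0, prev, 3), matrix(0, 3, 3))  # clamped
})

test_that("evaluate_r2 implements 1 - SSres/SStot", {
  a <- matrix(c(1, 2, 3, 4, 5, 6), 2)
  expect_equal(evaluate_r2(a, a), 1)
  expect_equal(evaluate_r2(matrix(mean(a), 2, 3), a), 0)
  # hand-computed toy: SSres = 4, SStot = 17.5
  p <- matrix(c(1, 2, 2, 5, 4, 7), 2)
  expect_equal(evaluate_r2(p, a), 1 - 4 / 17.5)
  expect_error(evaluate_r2(a, matrix(2, 2, 3)), "zero variance")
  expect_error(evaluate_r2(a, matrix(1, 3, 2)), "shape")
})

test_that("recurrent forecast: horizon 1 equals single-step, linear growth tracked", {
  sc <- trend_scenario(k_ai = 8, k_bio = 10, bins = 10, base_rate = 20,
                       spatial_corr = 0.3, seed = 29)
  tn <- generate_tensor(sc)$tensor
  run <- recurrent_forecast(tn, start_bin = 6, horizon = 1, "ridge", 3)
  single <- forecast_bin(tn, 6, "ridge", 3)
  expect_identical(run$predictions[[1]], single$pred)
  expect_identical(unname(run$r2_trace[1]), single$r2)

  # deterministic tensor growing by an exact linear map (x 1.1 each bin):
  # ridge with the keyword-only window tracks the closed-form
  # extrapolation base * 1.1^(t-1) within 5% relative error per horizon
  nr <- 6; nc <- 7; bins <- 9
  base <- outer(seq(40, 90, length.out = nr), seq(1, 1.5, length.out = nc))
  counts <- array(0, c(bins, nr, nc))
  for (t in seq_len(bins)) counts[t, , ] <- base * 1.1^(t - 1)
  new_cooc_tensor <- getFromNamespace("new_cooc_tensor", "cowordcast")
  lin <- new_cooc_tensor(counts, time_binning(0L, bins * 6L - 1L, 6),
                         paste0("a", 1:nr), paste0("b", 1:nc))
  run4 <- recurrent_forecast(lin, start_bin = 5, horizon = 4, "ridge", 1)
  for (h in 1:4) {
    actual <- matrix(lin$counts[4 + h, , ], nr, nc)
    rel <- abs(run4$predictions[[h]] - actual) / actual
    expect_lt(max(rel), 0.05)
  }

  # horizons beyond the observed bins produce predictions without r2 entries
  run_long <- recurrent_forecast(tn, start_bin = 9, horizon = 4, "ridge", 3)
  expect_equal(length(run_long$predictions), 4)
  expect_equal(length(run_long$r2_trace), 2)   # bins 9 and 10 only
})

test_that("window sweep rewards spatial structure and is deterministic", {
  # value of each cell is an exact function of its previous 3x3 neighborhood
  set.seed(37)
  nr <- 12; nc <- 12; bins <- 8
  counts <- array(0, c(bins, nr, nc))
  counts[1, , ] <- matrix(rpois(nr * nc, 30), nr, nc)
  wf <- getFromNamespace("window_features", "cowordcast")
  for (t in 2:bins) {
    prev <- matrix(counts[t - 1, , ], nr, nc)
    counts[t, , ] <- matrix(rowSums(wf(prev, 3)) / 9 * 1.1, nr, nc)
  }
  new_cooc_tensor <- getFromNamespace("new_cooc_tensor", "cowordcast")
  tn <- new_cooc_tensor(round(counts), time_binning(0L, bins * 6L - 1L, 6),
                        paste0("a", 1:nr), paste0("b", 1:nc))
  sw <- window_size_sweep(tn, c(1, 3), "ridge")
  r2_w1 <- sw$mean_r2[sw$w == 1]
  r2_w3 <- sw$mean_r2[sw$w == 3]
  expect_gt(r2_w3, r2_w1)

  # single evaluable bin: mean equals that bin's R^2
  sw1 <- window_size_sweep(tn, 3, "ridge", first_eval = bins)
  expect_equal(sw1$mean_r2, forecast_bin(tn, bins, "ridge", 3)$r2)
  expect_equal(sw1$n_bins, 1L)

  # determinism across reruns, two backends
  swa <- window_size_sweep(tn, c(1, 3), c("ridge", "elastic_net"), seed = 1)
  swb <- window_size_sweep(tn, c(1, 3), c("ridge", "elastic_net"), seed = 1)
  expect_identical(swa, swb)
})
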