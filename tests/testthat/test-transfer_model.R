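test_that("exhaustive interaction screening recovers a planted product pair", {
  set.seed(5)
  X <- matrix(rnorm(100 * 5), 100, 5)
  y <- X[, 1] * X[, 2] + rnorm(100, sd = 0.05)
  d <- raw_design(X, y)
  cfg <- boosting_config(screen_method = "exhaustive", max_interactions = 3L)
  iset <- screen_interactions(d, config = cfg)
  expect_equal(iset$pairs[[1L]], c(1L, 2L))
  none <- screen_interactions(d, config = boosting_config(screen_method = "none"))
  expect_length(none$pairs, 0L)
})

test_that("randomized projection screening tracks the exhaustive oracle", {
  hits <- 0L
  for (sd_ in 1:100) {
    set.seed(sd_)
    X <- matrix(rnorm(100 * 5), 100, 5)
    y <- X[, 1] * X[, 2] + rnorm(100, sd = 0.05)
    d <- raw_design(X, y)
    iset <- screen_interactions(d, config = boosting_config(
      screen_method = "xyz_random_projection", max_interactions = 5L,
      n_projections = 50L, random_seed = sd_))
    if (any(vapply(iset$pairs, function(p) all(p == c(1L, 2L)), TRUE)))
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("one full-rate boosting step on exactly linear data equals OLS", {
  set.seed(2)
  x <- rnorm(50)
  X <- cbind(x, matrix(rnorm(50 * 3, sd = 0.1), 50, 3))
  y <- 1.5 + 3 * x
  d <- raw_design(X, y)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 1L, learning_rate = 1))
  ols <- coef(lm(y ~ x))
  expect_equal(unname(m$beta[1L, 1L]), unname(ols[2L]), tolerance = 1e-10)
  expect_equal(unname(m$intercept), unname(ols[1L]), tolerance = 1e-10)
  preds <- drop(X %*% m$beta) + m$intercept
  expect_lt(max(abs(preds - y)), 1e-8)
})

test_that("zero iterations fit the per-taxon training means", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  Y <- cbind(rnorm(20, 5), rnorm(20, -2))
  d <- raw_design(X, Y)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 0L))
  expect_equal(unname(m$intercept), unname(colMeans(Y)))
  expect_true(all(m$beta == 0))
  p <- predict_one_step(m, matrix(0, 2, 1), matrix(0, 0, 1))
  expect_equal(unname(p), unname(colMeans(Y)))
})

test_that("slow boosting approaches the OLS solution and descends monotonically", {
  set.seed(4)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- 2 * X[, 3] + rnorm(200, sd = 0.2)
  d <- raw_design(X, y)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 500L, learning_rate = 0.1))
  ols <- unname(coef(lm(y ~ X))[4L])
  expect_lt(abs(m$beta[3L, 1L] - ols) / abs(ols), 0.05)
  # monotone descent of the training error across 20 random instances
  for (sd_ in 1:20) {
    set.seed(sd_)
    Xr <- matrix(rnorm(30 * 4), 30, 4)
    yr <- rnorm(30)
    Xs <- scale(Xr); Yc <- cbind(yr - mean(yr))
    tr <- tfmicro:::boost_fit_r(Xs, Yc, n_iter = 25L, lr = 0.3,
                                ss = colSums(Xs^2), trace = TRUE)
    expect_true(all(diff(tr$sse[, 1L]) <= 1e-10))
  }
})

test_that("compiled and reference boosting engines agree", {
  set.seed(9)
  X <- matrix(rnorm(60 * 8), 60, 8)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  d <- raw_design(X, Y)
  cfg <- boosting_config(n_iterations = 100L, learning_rate = 0.2)
  m_cpp <- fit_transfer(d, config = cfg, engine = "cpp")
  m_r <- fit_transfer(d, config = cfg, engine = "r")
  expect_equal(m_cpp$beta, m_r$beta, tolerance = 1e-12)
  expect_equal(m_cpp$intercept, m_r$intercept, tolerance = 1e-12)
})

test_that("predictions are invariant to training-row order", {
  set.seed(10)
  X <- matrix(rnorm(80 * 4), 80, 4)
  Y <- matrix(rnorm(80 * 2), 80, 2)
  d1 <- raw_design(X, Y)
  perm <- sample(80)
  d2 <- raw_design(X[perm, ], Y[perm, , drop = FALSE])
  cfg <- boosting_config(n_iterations = 50L)
  m1 <- fit_transfer(d1, config = cfg)
  m2 <- fit_transfer(d2, config = cfg)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-9)
})

test_that("predict_one_step equals the explicit dot product and validates shapes", {
  cl <- linear_collection(n_subjects = 4L, T_len = 15L, seed = 21)
  d <- tile_windows(cl, P = 2L, Q = 1L)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 100L))
  Yh <- cl$abundances$s01[, c(6L, 5L)]        # lags 1, 2 for t = 7
  Wh <- cl$interventions$s01[, 7L, drop = FALSE]
  p <- predict_one_step(m, Yh, Wh)
  x <- c(as.vector(Yh), as.vector(Wh))
  expect_equal(unname(p), unname(drop(x %*% m$beta) + m$intercept), tolerance = 1e-12)
  expect_error(predict_one_step(m, Yh[, 1L, drop = FALSE], Wh), "Y_hist must be")
  expect_error(predict_one_step(m, Yh, matrix(0, 2, 1)), "W_hist must be")
  expect_error(predict_one_step(m, Yh, Wh, z = 1), "covariate")
})

test_that("exact-fit models interpolate their training rows", {
  set.seed(12)
  x <- rnorm(30)
  X <- cbind(x, rnorm(30))
  y <- 2 - x
  d <- raw_design(X, y)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 1L, learning_rate = 1))
  preds <- drop(tfmicro:::predict_design(m, X))
  expect_lt(max(abs(preds - y)), 1e-8)
})

test_that("forecasting a deterministic AR(1) recovers the closed-form recursion", {
  yv <- 64 * 0.5^(0:9)
  Y <- matrix(yv, 1L, dimnames = list("tax1", NULL))
  W <- matrix(0, 1L, 10L, dimnames = list("w1", NULL))
  cl <- study_collection(list(s1 = Y), list(s1 = W), list(s1 = 1:10))
  d <- tile_windows(cl, P = 1L, Q = 1L)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 60L, learning_rate = 1))
  anchor <- study_collection(
    list(s1 = matrix(c(64, 32, 16, 8), 1L, dimnames = list("tax1", NULL))),
    list(s1 = matrix(0, 1L, 4L, dimnames = list("w1", NULL))), list(s1 = 1:4))
  fc <- forecast(m, anchor, matrix(0, 1L, 3L), horizon = 3L)
  expect_equal(unname(fc$s1[1L, ]), c(4, 2, 1), tolerance = 1e-6)
})

test_that("forecast at h = 1 is bit-identical to predict_one_step", {
  cl <- linear_collection(n_subjects = 3L, T_len = 15L, seed = 31)
  d <- tile_windows(cl, P = 2L, Q = 2L)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 100L))
  Wf <- matrix(1, 1L, 1L)
  fc <- forecast(m, cl, Wf, horizon = 1L)
  for (s in cl$subjects) {
    Tn <- ncol(cl$abundances[[s]])
    Yh <- cl$abundances[[s]][, Tn + 1L - (1:2), drop = FALSE]
    Wh <- cbind(Wf, cl$interventions[[s]][, Tn, drop = FALSE])
    expect_identical(unname(fc[[s]][, 1L]), unname(predict_one_step(m, Yh, Wh)))
  }
  expect_error(forecast(m, cl, Wf, horizon = 0L), "horizon")
  expect_error(forecast(m, cl, matrix(1, 1L, 1L), horizon = 3L), "shorter than horizon")
})

test_that("a zero-coefficient model forecasts its intercept at every horizon", {
  cl <- toy_collection(T_len = 8L)
  d <- tile_windows(cl, P = 1L, Q = 1L)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 0L))
  fc <- forecast(m, cl, matrix(0, 1L, 4L), horizon = 4L)
  for (h in 1:4) expect_equal(unname(fc$s1[, h]), unname(m$intercept))
})

test_that("partial dependence profiles are linear with the stored slope", {
  set.seed(14)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- 1 + 2.5 * X[, 2]
  d <- raw_design(X, y)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 1L, learning_rate = 1))
  pr <- partial_dependence_profile(m, 1L, 2L, grid = c(-1, 0, 1, 2), design = d)
  slopes <- diff(pr$profile) / diff(pr$value)
  expect_equal(slopes, rep(m$beta[2L, 1L], 3L), tolerance = 1e-10)
  cm <- fit_transfer(d, config = boosting_config(n_iterations = 0L))
  flat <- partial_dependence_profile(cm, 1L, 1L, grid = c(-2, 0, 2), design = d)
  expect_equal(flat$profile, rep(unname(cm$intercept), 3L))
  expect_error(partial_dependence_profile(m, 1L, 2L, numeric(0), d), "empty grid")
})

test_that("interaction partial dependence shifts slopes by coef * delta-background", {
  set.seed(15)
  X <- matrix(rnorm(300 * 4), 300, 4)
  y <- 3 * X[, 1] + 2 * X[, 1] * X[, 2] + rnorm(300, sd = 0.01)
  d0 <- raw_design(X, y)
  iset <- screen_interactions(d0, config = boosting_config(
    screen_method = "exhaustive", max_interactions = 1L))
  expect_equal(iset$pairs[[1L]], c(1L, 2L))
  d <- tfmicro:::add_interactions(d0, iset)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 2000L, learning_rate = 0.5))
  lo <- X[, 2] < 0; hi <- !lo
  slope_at <- function(rows) {
    dd <- d; dd$X <- d$X[rows, , drop = FALSE]
    pr <- partial_dependence_profile(m, 1L, 1L, grid = c(0, 1), design = dd)
    diff(pr$profile)
  }
  coef_int <- m$beta[5L, 1L]
  expected <- coef_int * (mean(X[hi, 2]) - mean(X[lo, 2]))
  expect_equal(slope_at(hi) - slope_at(lo), expected, tolerance = 1e-8)
  # analytic bilinear partial dependence: slope difference ~ 2 * delta-background
  expect_equal(slope_at(hi) - slope_at(lo),
               2 * (mean(X[hi, 2]) - mean(X[lo, 2])), tolerance = 0.05)
})

test_that("sparse linear transfer structure is sign-recovered from simulation", {
  J <- 3L
  beta_y <- rbind(c(0.5, -0.4, 0), c(0, 0.5, 0), c(0, 0, 0.5))
  beta_w <- c(2, -1.5, 0)
  cl <- linear_collection(n_subjects = 50L, T_len = 20L, J = J,
                          beta_y = beta_y, beta_w = beta_w,
                          noise_sd = 0.1, seed = 77)
  d <- tile_windows(cl, P = 1L, Q = 1L)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 500L, learning_rate = 0.1))
  for (j in seq_len(J)) for (k in seq_len(J)) {
    if (abs(beta_y[j, k]) > 0.2)
      expect_equal(sign(m$beta[k, j]), sign(beta_y[j, k]))
  }
  for (j in seq_len(J)) {
    if (abs(beta_w[j]) > 0.2)
      expect_equal(sign(m$beta[J + 1L, j]), sign(beta_w[j]))
  }
})

test_that("models round-trip through JSON serialization", {
  cl <- linear_collection(n_subjects = 3L, T_len = 12L, seed = 8)
  d0 <- tile_windows(cl, P = 2L, Q = 2L)
  iset <- interaction_set(list(c(1L, 2L), c(3L, 8L)), d0$base_cols)
  d <- tfmicro:::add_interactions(d0, iset)
  norm <- normalization_spec("size_factor_asinh")
  m <- fit_transfer(d, config = boosting_config(n_iterations = 50L),
                    normalization = norm)
  path <- tempfile(fileext = ".json")
  write_tf_model(m, path)
  back <- read_tf_model(path)
  expect_equal(back$beta, m$beta, tolerance = 1e-12)
  expect_equal(back$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(back$interactions$pairs, m$interactions$pairs)
  expect_equal(back$P, m$P); expect_equal(back$taxa, m$taxa)
  expect_equal(back$normalization$method, "size_factor_asinh")
  Yh <- cl$abundances$s01[, 5:4]; Wh <- cl$interventions$s01[, 6:5, drop = FALSE]
  expect_equal(predict_one_step(back, Yh, Wh), predict_one_step(m, Yh, Wh),
               tolerance = 1e-12)
})
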