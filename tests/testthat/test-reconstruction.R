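test_that("fit_ols recovers an exact linear relation and full-rank mixing", {
  X <- matrix(seq(0, 1, length.out = 50), ncol = 1,
              dimnames = list(NULL, "x"))
  Y <- 2 * X + 1
  colnames(Y) <- "y"
  m <- fit_ols(X, Y)
  expect_equal(unname(m$A), matrix(2), tolerance = 1e-10)
  expect_equal(unname(m$C), 1, tolerance = 1e-10)

  # random full-rank design, known mixing M and offset c
  set.seed(7)
  Xf <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  M <- matrix(c(1.2, -0.5, 0.3, 0.7, 2.0, -1.1), 2, 3)
  cc <- c(0.4, -0.2)
  Yf <- Xf %*% t(M) + matrix(cc, 200, 2, byrow = TRUE)
  colnames(Yf) <- c("u", "v")
  mf <- fit_ols(Xf, Yf)
  expect_lt(max(abs(mf$A - M)), 1e-10)
  expect_lt(max(abs(mf$C - cc)), 1e-10)
})

test_that("fit_ols recovers the generator's min-norm transform on a noiseless cohort", {
  co <- global_cohort(20, seed = 31)
  xy <- pooled_xy(co)
  expect_warning(m <- fit_ols(xy$X, xy$Y), "minimum-norm")
  # oracle: single-source global mixing makes inputs colinear along u,
  # so the identifiable transform is A = g_out u' / ||u||^2, C = 0
  g <- default_gains()
  u <- g[c("I", "II", "V3")]
  A_truth <- outer(g[c("V1", "V2", "V4", "V5", "V6")], u / sum(u^2))
  expect_lt(max(abs(m$A - A_truth)), 1e-6)
  expect_lt(max(abs(m$C)), 1e-6)
})

test_that("duplicated constant-direction columns give a stable min-norm fit", {
  set.seed(11)
  x <- rnorm(100)
  X <- cbind(a = x, b = x, c = rep(1, 100))  # duplicated + constant
  Y <- cbind(y = 3 * x + 2)
  expect_warning(m1 <- fit_ols(X, Y), "minimum-norm")
  expect_warning(m2 <- fit_ols(X, Y), "minimum-norm")
  expect_equal(unname(m1$A[1, "a"]), unname(m1$A[1, "b"]))  # symmetric split
  expect_lt(max(abs(predict(m1, X) - Y)), 1e-9)
  expect_identical(m1$A, m2$A)
})

test_that("SGD converges to the OLS solution and is seed-deterministic", {
  X <- matrix(seq(0, 1, length.out = 50), ncol = 1,
              dimnames = list(NULL, "x"))
  Y <- 2 * X + 1
  colnames(Y) <- "y"
  ms <- fit_sgd(X, Y)
  expect_lt(abs(ms$A[1, 1] - 2), 1e-2)

  ms2 <- fit_sgd(X, Y)
  expect_identical(ms$A, ms2$A)   # bit-identical rerun
  expect_identical(ms$C, ms2$C)

  co <- global_cohort(20, seed = 31)
  xy <- pooled_xy(co)
  mo <- suppressWarnings(fit_ols(xy$X, xy$Y))
  msgd <- suppressWarnings(fit_sgd(xy$X, xy$Y))
  # standardized-coefficient agreement, OLS refit in the same scaled space
  sc <- msgd$scaling_state
  Xs <- scale(xy$X, sc$x_center, sc$x_scale)
  Ys <- scale(xy$Y, sc$y_center, sc$y_scale)
  mo_std <- suppressWarnings(fit_ols(Xs, Ys))
  expect_lt(max(abs(standardized_coefs(msgd) - mo_std$A)), 1e-2)
  # prediction RMSE within 1e-3 mV of the closed form
  expect_lt(abs(sqrt(mean((predict(msgd, xy$X) - xy$Y)^2)) -
                  sqrt(mean((predict(mo, xy$X) - xy$Y)^2))), 1e-3)
})

test_that("SGD reports divergence with the failing epoch", {
  set.seed(3)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  Y <- cbind(y = X[, 1] - X[, 2])
  err <- tryCatch(fit_sgd(X, Y, sgd_config(learning_rate = 50)),
                  wmlr_divergence_error = identity)
  expect_s3_class(err, "wmlr_divergence_error")
  expect_match(conditionMessage(err), "epoch")
})

test_that("predict applies y = Ax + C and refuses misaligned channels", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  ident <- wmlr:::new_linear_model(diag(3), c(0, 0, 0), c("a", "b", "c"),
                                   c("p", "q", "r"))
  expect_equal(unname(predict(ident, X)), unname(X))
  const <- wmlr:::new_linear_model(matrix(0, 2, 3), c(5, -1),
                                   c("a", "b", "c"), c("u", "v"))
  expect_true(all(predict(const, X)[, "u"] == 5))
  expect_true(all(predict(const, X)[, "v"] == -1))

  m <- fit_ols(X, cbind(y = X %*% c(1, 2, 3)))
  expect_lt(max(abs(predict(m, X) -
                      (X %*% t(m$A) + matrix(m$C, 20, 1)))), 1e-12)
  Xbad <- X[, c(2, 1, 3)]
  expect_error(predict(m, Xbad), class = "wmlr_alignment_error")
  expect_error(predict(m, unname(X)), class = "wmlr_alignment_error")
})

test_that("limb-lead identities are exact", {
  expect_equal(unname(derive_limb_leads(0, 0)), matrix(0, 1, 4))
  one <- derive_limb_leads(1, 1)
  expect_equal(unname(one[1, ]), c(0, -1, 0.5, 0.5),
               ignore_attr = TRUE)
  set.seed(13)
  i <- rnorm(1000); ii <- rnorm(1000)
  leads <- derive_limb_leads(i, ii)
  expect_lt(max(abs(i + leads[, "III"] - ii)), 1e-12)  # Einthoven
  expect_identical(leads[, "aVR"], -(i + ii) / 2)
  expect_identical(leads[, "aVL"], i - ii / 2)
  expect_identical(leads[, "aVF"], ii - i / 2)
  expect_error(derive_limb_leads(i, ii[-1]), class = "wmlr_shape_error")
})

test_that("pipeline variants expose the documented channel lists", {
  expect_equal(make_pipeline("p1")$output_names,
               c("V1", "V3", "V4", "V5", "V6"))
  expect_equal(make_pipeline("p1")$input_names, c("I", "II", "V2"))
  expect_equal(make_pipeline("p2")$output_names,
               c("V1", "V2", "V4", "V5", "V6"))
  expect_equal(make_pipeline("wmlr")$input_names, AUGMENTED_CHANNELS)
  expect_equal(make_pipeline("ffn")$input_names, c("I", "II", "V3"))
  expect_error(make_pipeline("p9"), class = "wmlr_config_error")
})

test_that("fitting standardized or raw channels yields identical predictions", {
  set.seed(17)
  X <- matrix(rnorm(900), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- sweep(X, 2, c(1, 10, 0.1), "*")      # wildly different scales
  Y <- cbind(y1 = X %*% c(0.5, -0.2, 4) + 1,
             y2 = X %*% c(-1, 0.05, 2) - 0.3)
  m_raw <- fit_ols(X, Y)
  Xs <- scale(X); Ys <- scale(Y)
  m_std <- fit_ols(Xs, Ys)
  # map standardized fit back to raw units
  A_back <- sweep(sweep(m_std$A, 2, attr(Xs, "scaled:scale"), "/"),
                  1, attr(Ys, "scaled:scale"), "*")
  C_back <- attr(Ys, "scaled:center") +
    attr(Ys, "scaled:scale") * m_std$C -
    A_back %*% attr(Xs, "scaled:center")
  expect_lt(max(abs(A_back - m_raw$A)), 1e-9)
  expect_lt(max(abs(c(C_back) - m_raw$C)), 1e-9)
})

test_that("models serialize to JSON and back without losing the fit", {
  co <- global_cohort(5, seed = 41)
  xy <- pooled_xy(co)
  m <- suppressWarnings(fit_sgd(xy$X, xy$Y,
                                sgd_config(epochs = 5, seed = 2)))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$A, m$A)
  expect_equal(unname(back$C), unname(m$C))
  expect_equal(predict(back, xy$X), predict(m, xy$X))
})
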