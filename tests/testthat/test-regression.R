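test_that("VIF matches its least-squares definition", {
  # orthogonal centred predictors
  x <- cbind(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1), c = c(1, -1, -1, 1))
  v <- vif(x * 1.0 + matrix(rnorm(12, 0, 1e-8), 4))
  expect_true(all(abs(v$vif - 1) < 1e-3))

  # duplicated column is exactly collinear
  set.seed(1)
  x2 <- cbind(a = rnorm(20), b = rnorm(20))
  x2 <- cbind(x2, c = x2[, "a"])
  expect_warning(v2 <- vif(x2), "collinear")
  expect_equal(v2$vif[v2$predictor == "c"], Inf)

  # known-correlation case against a normal-equations oracle
  set.seed(2)
  n <- 200
  z <- rnorm(n)
  x3 <- cbind(a = z + rnorm(n, 0, sqrt(1 / 0.9^2 - 1) * 1),
              b = z, c = rnorm(n))
  v3 <- vif(x3)
  oracle <- vapply(1:3, function(j) {
    X <- cbind(1, x3[, -j])
    bh <- solve(crossprod(X), crossprod(X, x3[, j]))
    r2 <- 1 - sum((x3[, j] - X %*% bh)^2) /
      sum((x3[, j] - mean(x3[, j]))^2)
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(v3$vif, oracle, tolerance = 1e-8)
  expect_error(vif(cbind(a = rep(1, 10), b = rnorm(10))), "Constant")
})

test_that("VIF agrees with an independent implementation", {
  skip_if_not_installed("car")
  set.seed(4)
  n <- 80
  z <- rnorm(n)
  x <- data.frame(a = z + rnorm(n, 0, 0.5), b = z + rnorm(n, 0, 0.8),
                  c = rnorm(n))
  y <- rnorm(n)
  theirs <- car::vif(lm(y ~ a + b + c, data = x))
  ours <- vif(as.matrix(x))
  expect_equal(ours$vif, unname(theirs[ours$predictor]), tolerance = 1e-10)
})

test_that("stratified split is exact, seeded and class-aware", {
  labels <- tibble::tibble(genotype_id = paste0("G", 1:10),
                           class = rep("MT", 10))
  sp <- stratified_split(labels, 0.8, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_identical(sp, stratified_split(labels, 0.8, seed = 1))
  expect_setequal(c(sp$train, sp$test), labels$genotype_id)
  expect_length(intersect(sp$train, sp$test), 0)

  # singleton class goes to training, with a warning
  labs2 <- tibble::tibble(genotype_id = c(paste0("G", 1:5), "LONE"),
                          class = c(rep("MT", 5), "HT"))
  expect_warning(sp2 <- stratified_split(labs2, 0.8, seed = 2), "single")
  expect_true("LONE" %in% sp2$train)

  # per-class proportions within one genotype of the target
  set.seed(3)
  labs3 <- tibble::tibble(genotype_id = paste0("G", 1:100),
                          class = sample(c("HS", "S", "MT", "T", "HT"), 100,
                                         replace = TRUE, prob = c(1, 2, 5, 2, 1)))
  sp3 <- stratified_split(labs3, 0.8, seed = 4)
  for (cl in unique(labs3$class)) {
    ids <- labs3$genotype_id[labs3$class == cl]
    expect_lte(abs(sum(sp3$train %in% ids) - 0.8 * length(ids)), 1)
  }
})

test_that("full shrinkage and the unpenalized limit behave as closed forms", {
  set.seed(10)
  n <- 80
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("t", 1:5)))
  y <- 0.4 + 0.6 * x[, 2] - 0.3 * x[, 5] + rnorm(n, 0, 0.1)

  big <- fit_glmnet_like(x, y, alpha = 1, lambda = 1e4)
  expect_equal(unname(big$coefficients), rep(0, 5))
  expect_equal(big$intercept, mean(y))

  for (a in c(0, 0.5, 1)) {
    fit0 <- fit_glmnet_like(x, y, alpha = a, lambda = 0)
    ols <- unname(drop(solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))))
    expect_equal(c(fit0$intercept, unname(fit0$coefficients)),
                 ols, tolerance = 1e-6)
  }
  expect_error(fit_glmnet_like(x, c(y[-1], NA), 1, 0.1), "finite")
})

test_that("LASSO on an orthonormal design equals the soft-threshold rule", {
  set.seed(11)
  n <- 64
  raw <- matrix(rnorm(n * 4), n, 4)
  # orthonormalize on the 1/n inner product so the standardized gram is I
  q <- qr.Q(qr(sweep(raw, 2, colMeans(raw))))
  x <- q * sqrt(n)
  colnames(x) <- paste0("t", 1:4)
  y <- rnorm(n)
  lambda <- 0.07
  fit <- fit_glmnet_like(x, y, alpha = 1, lambda = lambda)
  z <- unname(drop(crossprod(x, y - mean(y)))) / n
  oracle <- sign(z) * pmax(abs(z) - lambda, 0)
  expect_equal(unname(fit$beta_std), oracle, tolerance = 1e-8)
})

test_that("ridge solution matches its closed form on standardized data", {
  set.seed(12)
  n <- 100
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("t", 1:6)))
  y <- drop(x %*% c(0.5, 0, -0.2, 0.1, 0, 0.3)) + rnorm(n, 0, 0.2)
  lambda <- 0.3
  fit <- fit_glmnet_like(x, y, alpha = 0, lambda = lambda)
  xm <- colMeans(x)
  xs <- sqrt(colMeans(sweep(x, 2, xm)^2))
  xs_mat <- sweep(sweep(x, 2, xm), 2, xs, "/")
  closed <- unname(drop(solve(crossprod(xs_mat) / n + lambda * diag(6),
                  crossprod(xs_mat, y - mean(y)) / n)))
  expect_equal(unname(fit$beta_std), closed, tolerance = 1e-6)
})

test_that("coordinate descent never increases the objective", {
  set.seed(13)
  n <- 60
  x <- matrix(rnorm(n * 8), n, 8)
  x[, 2] <- x[, 1] + rnorm(n, 0, 0.05)  # make it ill-conditioned
  y <- x[, 1] + rnorm(n)
  for (a in c(0, 0.4, 1)) {
    fit <- fit_glmnet_like(x, y, alpha = a, lambda = 0.05, trace = TRUE)
    expect_true(all(diff(fit$obj_trace) <= 1e-12))
  }
})

test_that("the L1 norm shrinks as lambda grows at alpha = 1", {
  set.seed(14)
  n <- 90
  x <- matrix(rnorm(n * 6), n, 6)
  y <- x[, 1] - x[, 4] + rnorm(n, 0, 0.3)
  lambdas <- c(0.001, 0.01, 0.05, 0.1, 0.3)
  norms <- vapply(lambdas, function(l)
    sum(abs(fit_glmnet_like(x, y, 1, l)$coefficients)), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("fits agree with an independent elastic-net implementation", {
  skip_if_not_installed("glmnet")
  set.seed(15)
  n <- 150
  x <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("t", 1:7)))
  y <- 0.2 + drop(x %*% c(0.5, 0, 0, -0.4, 0.2, 0, 0.1)) + rnorm(n, 0, 0.3)
  # glmnet internally rescales y to unit (1/n) variance, which rescales the
  # ridge part of its penalty; unit-variance y makes the objectives identical
  y <- y / sqrt(mean((y - mean(y))^2))
  for (a in c(0.3, 1)) {
    lam <- 0.05
    ours <- fit_glmnet_like(x, y, a, lam, tol = 1e-10)
    # a descending path ending at the target lambda (glmnet is inaccurate
    # when asked for one lambda in isolation)
    lams <- exp(seq(log(0.8), log(lam), length.out = 30))
    theirs <- glmnet::glmnet(x, y, alpha = a, lambda = lams,
                             standardize = TRUE, thresh = 1e-14)
    cf <- drop(as.matrix(suppressWarnings(coef(theirs, s = lam))))
    expect_equal(unname(ours$coefficients), unname(cf[-1]),
                 tolerance = 1e-4)
    expect_equal(ours$intercept, unname(cf[1]), tolerance = 1e-4)
  }
})

test_that("cross-validation recovers sparse truth and honours its grid", {
  set.seed(16)
  n <- 200
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("t", 1:8)))
  y <- 1 + 0.8 * x[, 3] - 0.5 * x[, 7] + rnorm(n, 0, 0.2)
  cv <- cv_select(x, y, alpha_grid = c(0.1, 0.5, 1), k = 5, seed = 17)
  expect_true(all(c("t3", "t7") %in% cv$model$active))
  expect_gte(cv$lambda_1se, cv$lambda_min)

  cv1 <- cv_select(x, y, alpha_grid = 0.3, k = 5, seed = 18, nlambda = 30)
  expect_equal(cv1$best_alpha, 0.3)
  expect_error(cv_select(x, y, k = n + 1), "k")
})

test_that("prediction equations evaluate as affine forms", {
  coefs <- c(GP = 0.282, RL = 0.097, SL = 0.108, FW = 0.219, DW = 0.197,
             SVI = 0.373, SVII = 0.173)
  model <- structure(list(intercept = -0.220, coefficients = coefs),
                     class = "salt_net")
  expect_equal(predict_score(model, setNames(rep(0, 7), names(coefs))),
               -0.220)
  # sum of the printed coefficients minus the intercept
  expect_equal(predict_score(model, setNames(rep(1, 7), names(coefs))),
               1.229)
  zero <- structure(list(intercept = 0.5,
                         coefficients = c(a = 0, b = 0)), class = "salt_net")
  expect_equal(predict_score(zero, c(a = 99, b = -5)), 0.5)
  expect_error(predict_score(model, c(GP = 1)), "Missing predictor")
  eq <- format_equation(model)
  expect_match(eq, "^Y = −0.22 ")
  expect_match(eq, "0.282 × GSTI", fixed = TRUE)
})

test_that("fit metrics follow their definitions", {
  m <- fit_metrics(c(1, 2, 3), c(1, 2, 3), p = 1)
  expect_equal(m$mse, 0); expect_equal(m$rmse, 0)
  expect_equal(m$nmse, 0); expect_equal(m$r_squared, 1)

  set.seed(19)
  y <- rnorm(12); yp <- rnorm(12)
  m2 <- fit_metrics(y, yp, p = 2)
  expect_equal(m2$rmse^2, m2$mse)

  # constant mean prediction: R2 = 0 and NMSE = 1 (population variance)
  y5 <- c(2, 4, 6, 8, 10)
  m3 <- fit_metrics(y5, rep(mean(y5), 5), p = 1)
  expect_equal(m3$r_squared, 0)
  expect_equal(m3$nmse, 1)
  expect_error(fit_metrics(rep(1, 5), rnorm(5), 1), "variance")
})

test_that("single-trait R2 is the squared correlation", {
  set.seed(20)
  amfv <- runif(50)
  expect_equal(single_trait_r2(amfv, amfv), 1)
  expect_equal(single_trait_r2(amfv, -amfv), 1)
  expect_lt(single_trait_r2(runif(160), runif(160)), 0.05)
  expect_error(single_trait_r2(rep(1, 10), runif(10)), "variance")
})

test_that("tidy and glance summarise a fitted model", {
  set.seed(21)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, 1] + rnorm(20, 0, 0.1)
  fit <- fit_glmnet_like(x, y, 1, 0.01)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "a", "b", "c"))
  expect_equal(td$estimate[-1], unname(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$n_active, length(fit$active))
  expect_true(gl$converged)
})
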