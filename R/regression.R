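#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from an ordinary least squares
#' regression of predictor `j` on all the others. Values above 10 flag strong
#' multicollinearity. Exactly collinear predictors are reported as `Inf` with
#' a warning naming them.
#'
#' @param x Numeric matrix or data frame of predictors (rows > columns, no
#'   constant column).
#' @return Tibble: `predictor`, `vif`, `flagged` (`vif > 10`).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) <= ncol(x)) abort("Need more rows than predictors.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant column(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  vifs <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(vifs))) {
    warn(paste0("Exactly collinear predictor(s): ",
                paste(colnames(x)[is.infinite(vifs)], collapse = ", ")))
  }
  tibble::tibble(predictor = colnames(x), vif = vifs, flagged = vifs > 10)
}

#' Stratified train/test split by tolerance class
#'
#' Samples `floor(train_fraction * class size)` genotypes per class into the
#' training set, without replacement. A class with a single genotype sends it
#' to training (with a warning), so no class disappears from the training
#' data.
#'
#' @param labels Tibble with `genotype_id` and `class` columns.
#' @param train_fraction Fraction of each class used for training.
#' @param seed Optional integer seed for the sampling.
#' @return List with `train` and `test` character vectors of genotype ids.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = NULL) {
  assert_scalar_number(train_fraction, "train_fraction", 0, 1)
  if (anyNA(labels$class)) abort("Every genotype must be labelled.")
  if (!is.null(seed)) set.seed(seed)
  train <- character(0)
  for (cl in unique(as.character(labels$class))) {
    ids <- labels$genotype_id[as.character(labels$class) == cl]
    if (length(ids) == 0) {
      warn(sprintf("Class '%s' is empty; skipped.", cl))
      next
    }
    n_train <- floor(train_fraction * length(ids))
    if (length(ids) == 1 && n_train == 0) {
      warn(sprintf(
        "Class '%s' has a single genotype; assigned to training.", cl))
      n_train <- 1L
    }
    train <- c(train, sample(ids, n_train))
  }
  list(train = train, test = setdiff(labels$genotype_id, train))
}

# soft-threshold operator
soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# standardized second moments of the problem; the coordinate-descent solver
# works entirely in this O(p^2) space so lambda paths are cheap
enet_moments <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  n <- nrow(x)
  if (n < 2 || length(y) != n) abort("Need n >= 2 rows matching `y`.")
  xm <- colMeans(x)
  xs <- sqrt(colMeans(sweep(x, 2, xm)^2))
  if (any(xs == 0)) {
    abort(paste0("Constant column(s): ",
                 paste(colnames(x)[xs == 0], collapse = ", ")))
  }
  xs_mat <- sweep(sweep(x, 2, xm), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  list(names = colnames(x), n = n, xm = xm, xs = xs, ym = ym,
       gram = crossprod(xs_mat) / n,
       xty = as.numeric(crossprod(xs_mat, yc)) / n,
       yty = sum(yc^2) / n)
}

# elastic-net objective from moments (standardized scale)
enet_objective <- function(mom, beta, lambda, alpha) {
  rss_n <- mom$yty - 2 * sum(beta * mom$xty) +
    as.numeric(beta %*% mom$gram %*% beta)
  rss_n / 2 +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) * sum(beta^2) / 2)
}

# cyclic coordinate descent in moment space; gram[j, j] == 1 by construction
enet_solve <- function(mom, lambda, alpha, beta_init = NULL, tol = 1e-7,
                       max_sweeps = 1e5, trace = FALSE) {
  p <- length(mom$xty)
  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)
  .enet_solve_cpp(mom$gram, mom$xty, mom$yty, lambda, alpha, beta,
                  tol, as.integer(max_sweeps), trace)
}

#' Elastic-net regression by cyclic coordinate descent
#'
#' Minimizes `(1/2n) sum((y - b0 - X b)^2) + lambda * (alpha * ||b||_1 +
#' (1 - alpha)/2 * ||b||_2^2)` by cyclic coordinate descent on internally
#' standardized predictors (mean 0, population SD 1). `alpha = 1` is the
#' LASSO, `alpha = 0` ridge. Coefficients are returned back-transformed to
#' the original predictor scale, the scale on which prediction equations are
#' reported. Convergence when the largest standardized-coefficient change in
#' a sweep falls below `tol` (default 1e-7), capped at `max_sweeps` sweeps.
#'
#' @param x Numeric predictor matrix (no missing or constant columns).
#' @param y Numeric response.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param lambda Penalty strength, `>= 0`.
#' @param beta_init Optional warm-start standardized coefficients.
#' @param tol,max_sweeps Convergence controls.
#' @param trace If `TRUE`, record the penalized objective after every sweep
#'   (available as `obj_trace` on the result).
#' @return Object of class `salt_net`: `intercept`, named `coefficients` on
#'   the original scale, `alpha`, `lambda`, `active` (names of nonzero
#'   coefficients), standardization constants and convergence info.
#' @export
fit_glmnet_like <- function(x, y, alpha, lambda, beta_init = NULL,
                            tol = 1e-7, max_sweeps = 1e5, trace = FALSE) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  assert_scalar_number(lambda, "lambda", lo = 0)
  mom <- enet_moments(x, y)
  sol <- enet_solve(mom, lambda, alpha, beta_init = beta_init, tol = tol,
                    max_sweeps = max_sweeps, trace = trace)
  salt_net_from_solution(mom, sol, alpha, lambda)
}

salt_net_from_solution <- function(mom, sol, alpha, lambda) {
  coef_orig <- sol$beta / mom$xs
  intercept <- mom$ym - sum(coef_orig * mom$xm)
  structure(list(
    intercept = intercept,
    coefficients = setNames(coef_orig, mom$names),
    beta_std = setNames(sol$beta, mom$names),
    alpha = alpha, lambda = lambda,
    active = mom$names[sol$beta != 0],
    x_center = mom$xm, x_scale = mom$xs, y_mean = mom$ym,
    n = mom$n, sweeps = sol$sweeps, converged = sol$converged,
    obj_trace = sol$obj_trace
  ), class = "salt_net")
}

#' @export
print.salt_net <- function(x, ...) {
  cat(sprintf("<salt_net> alpha = %g, lambda = %g, %d/%d active\n",
              x$alpha, x$lambda, length(x$active), length(x$coefficients)))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' @export
predict.salt_net <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(missing) > 0) {
    abort(paste0("Missing predictor(s): ", paste(missing, collapse = ", ")))
  }
  drop(object$intercept +
         newdata[, names(object$coefficients), drop = FALSE] %*%
         object$coefficients)
}

#' Coefficients of a fitted elastic-net model
#' @param x A `salt_net` object.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (original predictor scale).
#' @export
tidy.salt_net <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' One-row summary of a fitted elastic-net model
#' @param x A `salt_net` object.
#' @param ... Unused.
#' @return Tibble: `alpha`, `lambda`, `n_active`, `sweeps`, `converged`.
#' @export
glance.salt_net <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda,
                 n_active = length(x$active), sweeps = x$sweeps,
                 converged = x$converged)
}

# glmnet-style lambda path on the standardized problem
lambda_path <- function(x, y, alpha, nlambda = 100, lambda_min_ratio = 1e-4) {
  xm <- colMeans(x)
  xs <- sqrt(colMeans(sweep(x, 2, xm)^2))
  xs_mat <- sweep(sweep(x, 2, xm), 2, xs, "/")
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(xs_mat, yc))) / nrow(x) / max(alpha, 1e-3)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Cross-validated selection of the mixing parameter and penalty
#'
#' For each `alpha` on the grid, fits a descending lambda path with warm
#' starts and measures k-fold cross-validated mean squared error; the winning
#' model minimizes CV MSE over the whole (alpha, lambda) grid. `lambda_1se`
#' is the largest lambda (within the winning alpha) whose CV MSE is within
#' one standard error of the minimum. Fold assignment is seeded and shared
#' across the alpha grid.
#'
#' @param x,y Predictors and response as in [fit_glmnet_like()].
#' @param alpha_grid Mixing parameters to evaluate (default `0, 0.1, ..., 1`).
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed for fold assignment.
#' @param nlambda Path length per alpha.
#' @return Object of class `salt_cv`: `best_alpha`, `lambda_min`,
#'   `lambda_1se`, the full `cv_table`, the refitted `model` (at
#'   `lambda_min`) and `model_1se`.
#' @export
cv_select <- function(x, y, alpha_grid = seq(0, 1, by = 0.1), k = 10,
                      seed = NULL, nlambda = 100) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  if (length(alpha_grid) == 0) abort("`alpha_grid` must be non-empty.")
  if (k < 2 || k > n) abort("`k` must be between 2 and the number of rows.")
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  fold_mom <- lapply(seq_len(k), function(f) {
    enet_moments(x[folds != f, , drop = FALSE], y[folds != f])
  })
  cv_rows <- list()
  for (a in alpha_grid) {
    lambdas <- lambda_path(x, y, a, nlambda = nlambda)
    fold_mse <- matrix(NA_real_, k, length(lambdas))
    for (f in seq_len(k)) {
      mom <- fold_mom[[f]]
      held_x <- x[folds == f, , drop = FALSE]
      held_y <- y[folds == f]
      beta <- NULL
      for (li in seq_along(lambdas)) {
        sol <- enet_solve(mom, lambdas[li], a, beta_init = beta)
        beta <- sol$beta
        coef_orig <- beta / mom$xs
        pred <- mom$ym + drop(sweep(held_x, 2, mom$xm) %*% coef_orig)
        fold_mse[f, li] <- mean((held_y - pred)^2)
      }
    }
    cv_rows[[length(cv_rows) + 1L]] <- tibble::tibble(
      alpha = a, lambda = lambdas,
      cvm = colMeans(fold_mse),
      cvsd = apply(fold_mse, 2, sd) / sqrt(k)
    )
  }
  cv_table <- dplyr::bind_rows(cv_rows)
  best <- cv_table[which.min(cv_table$cvm), ]
  within_alpha <- dplyr::filter(cv_table, .data$alpha == best$alpha)
  eligible <- within_alpha$lambda[
    within_alpha$cvm <= best$cvm + best$cvsd]
  lambda_1se <- max(eligible)
  model <- fit_glmnet_like(x, y, best$alpha, best$lambda)
  model_1se <- fit_glmnet_like(x, y, best$alpha, lambda_1se)
  structure(list(
    best_alpha = best$alpha, lambda_min = best$lambda,
    lambda_1se = lambda_1se, cv_table = cv_table,
    model = model, model_1se = model_1se, k = k
  ), class = "salt_cv")
}

#' @export
print.salt_cv <- function(x, ...) {
  cat(sprintf(
    "<salt_cv> %d-fold CV: alpha = %g, lambda_min = %.4g, lambda_1se = %.4g\n",
    x$k, x$best_alpha, x$lambda_min, x$lambda_1se))
  print(x$model)
  invisible(x)
}

#' Predict the multi-trait tolerance score from trait indices
#'
#' Affine evaluation of a fitted model on a named STI vector or matrix; a
#' missing predictor is an error.
#'
#' @param model A `salt_net` (or the `model` inside a `salt_cv`).
#' @param sti_values Named numeric vector, or matrix/data frame with one
#'   column per predictor.
#' @return Numeric predicted score(s).
#' @export
predict_score <- function(model, sti_values) {
  if (inherits(model, "salt_cv")) model <- model$model
  if (is.numeric(sti_values) && is.null(dim(sti_values))) {
    sti_values <- matrix(sti_values, nrow = 1,
                         dimnames = list(NULL, names(sti_values)))
  }
  predict(model, sti_values)
}

#' Prediction-accuracy metrics
#'
#' `MSE` is the mean squared error, `RMSE` its square root, `NMSE` the MSE
#' divided by the population variance of the observations (so a constant
#' mean predictor scores exactly 1), `r_squared = 1 - SSE/SST` and its
#' adjustment for `p` predictors.
#'
#' @param y_obs,y_pred Observed and predicted values, equal length.
#' @param p Number of predictors (for adjusted R-squared).
#' @return Tibble: `mse`, `rmse`, `nmse`, `r_squared`, `adj_r_squared`, `n`.
#' @export
fit_metrics <- function(y_obs, y_pred, p) {
  if (length(y_obs) != length(y_pred)) abort("Lengths differ.")
  n <- length(y_obs)
  sst <- sum((y_obs - mean(y_obs))^2)
  if (sst == 0) abort("Zero variance in `y_obs`; NMSE and R2 are undefined.")
  sse <- sum((y_obs - y_pred)^2)
  mse <- sse / n
  r2 <- 1 - sse / sst
  adj <- if (n > p + 1) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  tibble::tibble(mse = mse, rmse = sqrt(mse), nmse = mse / (sst / n),
                 r_squared = r2, adj_r_squared = adj, n = n)
}

#' Single-trait coefficient of determination
#'
#' Squared Pearson correlation between the multi-trait score and one trait's
#' STI, the univariate predictive strength of that trait.
#'
#' @param amfv,sti_trait Numeric vectors over the same genotypes (length
#'   >= 3, both non-constant).
#' @return Single numeric R-squared.
#' @export
single_trait_r2 <- function(amfv, sti_trait) {
  if (length(amfv) < 3 || length(sti_trait) != length(amfv)) {
    abort("Need matching vectors over at least 3 genotypes.")
  }
  if (sd(amfv) == 0 || sd(sti_trait) == 0) {
    abort("Zero variance in input vector.")
  }
  cor(amfv, sti_trait)^2
}

#' Ranked single-trait R-squared table
#'
#' @param sti_wide Data frame with `genotype_id` plus one STI column per
#'   trait.
#' @param amfv Tibble with `genotype_id` and `amfv`.
#' @return Tibble `trait`, `r_squared`, sorted decreasing.
#' @export
single_trait_r2_table <- function(sti_wide, amfv) {
  merged <- dplyr::inner_join(sti_wide, amfv, by = "genotype_id")
  traits <- setdiff(names(sti_wide), "genotype_id")
  tibble::tibble(
    trait = traits,
    r_squared = vapply(traits, function(tr)
      single_trait_r2(merged$amfv, merged[[tr]]), numeric(1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$r_squared))
}

#' Render a fitted model as a prediction equation
#'
#' Plain-text formula in the reporting style used for trait-index models,
#' e.g. `Y = -0.220 + 0.282 x GSTI + ...`.
#'
#' @param model A `salt_net` object.
#' @param digits Rounding for display (default 3).
#' @return Character scalar.
#' @export
format_equation <- function(model, digits = 3) {
  if (inherits(model, "salt_cv")) model <- model$model
  coefs <- model$coefficients[model$coefficients != 0]
  terms <- sprintf("%s %s × %s",
                   ifelse(coefs < 0, "−", "+"),
                   format(round(abs(coefs), digits), trim = TRUE),
                   sti_label(names(coefs)))
  intercept <- sprintf("%s%s",
                       ifelse(model$intercept < 0, "−", ""),
                       format(round(abs(model$intercept), digits)))
  paste("Y =", intercept, paste(terms, collapse = " "))
}

#' Observed-versus-predicted comparison report
#'
#' Evaluates a fitted model on a test set and tabulates observed AMFV against
#' predicted score, at full precision and after rounding both to 2 decimals.
#'
#' @param model A `salt_net` or `salt_cv`.
#' @param x_test Predictor matrix/data frame for the test genotypes.
#' @param y_obs Observed AMFV values.
#' @param ids Optional genotype ids.
#' @return Tibble: `genotype_id`, `observed`, `predicted`, `abs_diff`,
#'   `match_2dp`.
#' @export
prediction_report <- function(model, x_test, y_obs, ids = NULL) {
  pred <- predict_score(model, x_test)
  tibble::tibble(
    genotype_id = ids %||% paste0("G", seq_along(y_obs)),
    observed = y_obs, predicted = pred,
    abs_diff = abs(y_obs - pred),
    match_2dp = round(y_obs, 2) == round(pred, 2)
  )
}
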