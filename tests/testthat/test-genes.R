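test_that("label_regions classes regions with shared precedence", {
  labs <- label_map(c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  rc <- label_regions(labs, shared_centers = c(1L, 3L), unique_centers = c(4L, 7L))
  expect_identical(rc$class[rc$region == 1], "shared")
  expect_identical(rc$class[rc$region == 2], "shared")   # mixed -> shared
  expect_identical(rc$class[rc$region == 4], "unique")
  expect_identical(rc$class[rc$region == 3], "other")
  # group-by oracle on random centers
  set.seed(40)
  labs2 <- label_map(sample(1:10, 200, TRUE))
  sh <- sample(200, 15); un <- sample(200, 15)
  rc2 <- label_regions(labs2, sh, un)
  for (r in rc2$region) {
    has_sh <- r %in% as.integer(labs2)[sh]
    has_un <- r %in% as.integer(labs2)[un]
    want <- if (has_sh) "shared" else if (has_un) "unique" else "other"
    expect_identical(rc2$class[rc2$region == r], want)
  }
})

test_that("a large lambda kills every gene weight", {
  set.seed(1)
  X <- scale(matrix(rnorm(60 * 20), 60, 20))
  y <- rbinom(60, 1, 0.5)
  lam_max <- max(abs(crossprod(X, y - mean(y)) / nrow(X)))
  f <- fit_lasso(X, y, lam_max * 1.01)
  expect_true(all(f$weights == 0))
  expect_equal(f$intercept, mean(y))
})

test_that("lambda = 0 with n > p recovers ordinary least squares", {
  set.seed(2)
  X <- scale(matrix(rnorm(100 * 5), 100, 5))
  y <- X %*% c(1, -2, 0.5, 0, 3) + rnorm(100, sd = 0.3)
  f <- fit_lasso(X, y, 0)
  ols_w <- coef(lm(y ~ X))[-1]
  expect_equal(unname(f$weights), unname(ols_w), tolerance = 1e-6)
})

test_that("univariate fit equals the closed-form soft threshold", {
  set.seed(3)
  x <- as.numeric(scale(rnorm(50)))
  y <- 0.8 * x + rnorm(50, sd = 0.5)
  n <- length(x)
  cj <- sum(x^2) / n
  beta_ols <- sum(x * (y - mean(y))) / sum(x^2)
  for (lam in c(0.01, 0.1, 0.3)) {
    f <- fit_lasso(matrix(x, ncol = 1), y, lam)
    want <- sign(beta_ols) * max(abs(beta_ols) - lam / cj, 0)
    expect_equal(unname(f$weights), want, tolerance = 1e-7,
                 info = paste("lambda", lam))
  }
})

test_that("the fitted objective beats zero weights and the OLS solution", {
  obj <- function(X, y, b0, w, lam) {
    mean((y - b0 - X %*% w)^2) / 2 + lam * sum(abs(w))
  }
  set.seed(4)
  X <- scale(matrix(rnorm(80 * 10), 80, 10))
  y <- X %*% rnorm(10) + rnorm(80)
  lam <- 0.1
  f <- fit_lasso(X, y, lam)
  expect_lte(obj(X, y, f$intercept, f$weights, lam),
             obj(X, y, mean(y), rep(0, 10), lam) + 1e-12)
  ols_w <- coef(lm(y ~ X))[-1]
  expect_lte(obj(X, y, f$intercept, f$weights, lam),
             obj(X, y, mean(y), ols_w, lam) + 1e-12)
  expect_error(fit_lasso(matrix(c(1, NA), 2, 1), c(0, 1), 0.1), "non-finite")
})

test_that("coordinate descent agrees with glmnet at matched lambdas", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  X <- scale(matrix(rnorm(70 * 25), 70, 25))
  y <- rbinom(70, 1, 0.5)
  for (lam in c(0.2, 0.05, 0.01)) {
    f <- fit_lasso(X, y, lam)
    g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12)
    expect_equal(unname(f$weights), as.numeric(g$beta), tolerance = 1e-5,
                 info = paste("lambda", lam))
  }
})

test_that("stratified folds partition both classes deterministically", {
  y <- rep(c(0, 1), c(40, 50))
  f1 <- gyralpeaks:::stratified_folds(y, 10, seed = 3)
  f2 <- gyralpeaks:::stratified_folds(y, 10, seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  for (k in 1:10) {
    expect_equal(sum(f1 == k & y == 0), 4)
    expect_equal(sum(f1 == k & y == 1), 5)
  }
  f3 <- gyralpeaks:::stratified_folds(y, 10, seed = 4)
  expect_false(identical(f1, f3))
})

test_that("CV selects a perfect-accuracy lambda on separable data", {
  set.seed(6)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y * 4 - 2 + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 30), n, 30))
  Xs <- gyralpeaks:::standardize_columns(X)
  res <- cv_select_lambda(Xs, y, folds = 10, seed = 2)
  i <- which(res$lambda_grid == res$chosen_lambda)
  expect_equal(res$cv_accuracy[i], 1)
  expect_true("sep" %in% res$selected_genes)
  expect_true(res$chosen_lambda %in% res$lambda_grid)
  # default grid endpoints
  expect_equal(range(lambda_grid_default()), c(1e-4, 1))
})

test_that("number of selected genes is non-increasing in lambda", {
  gt <- make_gene_table(small_design(seed = 8))
  keep <- gt$region_class$class != "other"
  Xs <- gyralpeaks:::standardize_columns(gt$expression[keep, ])
  y <- as.numeric(gt$region_class$class[keep] == "shared")
  grid <- sort(lambda_grid_default(10), decreasing = TRUE)
  nsel <- vapply(grid, function(l) sum(fit_lasso(Xs, y, l)$weights != 0), 0)
  expect_true(all(diff(nsel) >= 0))   # grid descends, so counts ascend
})

test_that("welch_de matches the formula oracle and flags planted effects", {
  set.seed(7)
  n <- 50
  y <- rep(c(1, 0), c(20, 30))
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  X[y == 1, "g3"] <- X[y == 1, "g3"] + 3     # planted delta = 3 sd
  out <- welch_de(X, y, paste0("g", 1:6))
  for (i in seq_len(6)) {
    orc <- welch_t_oracle(X[y == 1, i], X[y == 0, i])
    expect_equal(out$t[i], orc$t, tolerance = 1e-10)
    expect_equal(out$df[i], orc$df, tolerance = 1e-10)
    expect_equal(out$p[i], orc$p, tolerance = 1e-10)
  }
  expect_equal(out$p_fdr, bh_oracle(out$p), tolerance = 1e-12)
  expect_true(out$significant[out$gene == "g3"])
  expect_error(welch_de(X, y, "absent_gene"), "absent_gene")
  # identical class values: t exactly 0, nothing significant
  A <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("g1", "g2")))
  out0 <- welch_de(rbind(A, A), rep(c(1, 0), each = 25), c("g1", "g2"))
  expect_equal(out0$t, c(0, 0))
  expect_true(all(!out0$significant))
})

test_that("end-to-end selection recovers planted genes and reports holdout", {
  des <- small_design(seed = 11)
  gt <- make_gene_table(des)
  sel <- select_genes(gt$expression, gt$region_class, seed = 11)
  expect_gte(mean(gt$informative_genes %in% sel$selected_genes), 0.75)
  expect_gte(sel$train$accuracy, 0.9)
  expect_gte(sel$test$accuracy, 0.75)
  expect_equal(sel$train$n + sel$test$n,
               sum(gt$region_class$class != "other"))
  expect_equal(sel$test$n, round(0.25 * 30) + round(0.25 * 34))
  g <- glance(sel)
  expect_identical(g$n_selected, length(sel$selected_genes))
})
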