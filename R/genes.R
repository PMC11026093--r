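#' Label atlas regions by peak class
#'
#' A region is `shared` if it contains at least one shared cluster center,
#' `unique` if it contains at least one unique center and no shared center
#' (shared takes precedence in mixed regions), and `other` otherwise.
#'
#' @param labels a [label_map()] (the gene atlas parcellation on the
#'   template).
#' @param shared_centers,unique_centers integer vectors of cluster center
#'   vertices.
#' @return tibble with columns `region` (label integer), `region_name`,
#'   `class`.
#' @export
label_regions <- function(labels, shared_centers, unique_centers) {
  table <- attr(labels, "table")
  regions <- sort(unique(as.integer(labels)[as.integer(labels) > 0L]))
  lab_of <- function(centers) as.integer(labels)[as.integer(centers)]
  sh <- lab_of(shared_centers)
  un <- lab_of(unique_centers)
  cls <- ifelse(regions %in% sh, "shared",
                ifelse(regions %in% un, "unique", "other"))
  tibble::tibble(region = regions,
                 region_name = unname(table[as.character(regions)]),
                 class = cls)
}

standardize_columns <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) stop("constant gene column cannot be standardized")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

#' L1-penalized (lasso) linear regression by coordinate descent
#'
#' Minimizes the per-sample-normalized lasso objective
#' `(1/(2n)) * sum_i (y_i - w0 - w'x_i)^2 + lambda * ||w||_1`
#' with an unpenalized intercept, by cyclic coordinate descent with exact
#' soft-threshold updates, to a coefficient change tolerance of 1e-7.
#' Predictors are expected to be standardized (mean 0); the intercept then
#' equals `mean(y)`.
#'
#' @param X numeric matrix, rows = observations (regions), columns =
#'   standardized features (genes).
#' @param y numeric response (0/1 class labels in the gene workflow).
#' @param lambda non-negative penalty on the per-sample scale.
#' @param w_init optional warm-start coefficient vector.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter sweep limit.
#' @return list with `intercept`, `weights` (named by column), `lambda`,
#'   `n_iter`.
#' @export
fit_lasso <- function(X, y, lambda, w_init = NULL, tol = 1e-7,
                      max_iter = 10000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite entries in X or y")
  }
  if (lambda < 0) stop("`lambda` must be non-negative")
  n <- nrow(X); p <- ncol(X)
  b0 <- mean(y)
  yc <- y - b0
  G <- crossprod(X) / n            # p x p Gram / n
  cty <- as.numeric(crossprod(X, yc)) / n
  cj <- diag(G)
  w0 <- if (is.null(w_init)) numeric(p) else as.numeric(w_init)
  fit <- lasso_cd(G, cty, cj, lambda, w0, tol, as.integer(max_iter))
  w <- as.numeric(fit$weights)
  names(w) <- colnames(X)
  list(intercept = b0, weights = w, lambda = lambda, n_iter = fit$n_iter)
}

predict_lasso <- function(fit, X) {
  as.numeric(fit$intercept + as.matrix(X) %*% fit$weights)
}

#' Cross-validated lambda selection for the gene lasso
#'
#' Stratified k-fold cross-validation over a log-spaced lambda grid. Per
#' lambda, CV accuracy (continuous prediction thresholded at 0.5) and CV mean
#' squared error are pooled over held-out samples. The chosen lambda
#' maximizes accuracy, breaking ties by minimum MSE, remaining ties by the
#' larger lambda (the sparser model). Deterministic given `seed`.
#'
#' @param X standardized regions x genes matrix (shared/unique regions only).
#' @param y 0/1 class vector (shared = 1, unique = 0).
#' @param grid lambda grid; default 25 log-spaced values in `[1e-4, 1]`.
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param cv_max_iter sweep cap for the warm-started CV path fits (default
#'   300; the deep-overfit tail of the grid converges slowly and never wins
#'   model selection). The final model at the chosen lambda is always fit to
#'   full tolerance.
#' @return object of class `lasso_result`: list with `lambda_grid`,
#'   `cv_accuracy`, `cv_mse`, `chosen_lambda`, `intercept`, `weights`,
#'   `selected_genes`, `folds`.
#' @export
cv_select_lambda <- function(X, y, grid = lambda_grid_default(),
                             folds = 10L, seed = 1L, cv_max_iter = 300L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1")
  for (cls in c(0, 1)) {
    if (sum(y == cls) < folds) {
      stop("class ", cls, " has fewer members than folds; reduce `folds`")
    }
  }
  grid <- sort(grid, decreasing = TRUE)
  fold_of <- stratified_folds(y, folds, seed)
  pred <- matrix(NA_real_, nrow = length(y), ncol = length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    # Gram quantities shared by the whole warm-started lambda path
    ntr <- nrow(Xtr)
    b0 <- mean(ytr)
    G <- crossprod(Xtr) / ntr
    cty <- as.numeric(crossprod(Xtr, ytr - b0)) / ntr
    cj <- diag(G)
    w <- numeric(ncol(X))
    for (gi in seq_along(grid)) {
      w <- as.numeric(lasso_cd(G, cty, cj, grid[gi], w, 1e-7,
                               as.integer(cv_max_iter))$weights)
      pred[!tr, gi] <- b0 + as.numeric(X[!tr, , drop = FALSE] %*% w)
    }
  }
  cv_acc <- colMeans((pred > 0.5) == y)
  cv_mse <- colMeans((pred - y)^2)
  best <- order(-cv_acc, cv_mse, -grid)[1]
  chosen <- grid[best]
  final <- fit_lasso(X, y, chosen)
  structure(
    list(lambda_grid = grid, cv_accuracy = cv_acc, cv_mse = cv_mse,
         chosen_lambda = chosen, intercept = final$intercept,
         weights = final$weights,
         selected_genes = names(final$weights)[final$weights != 0],
         folds = folds),
    class = "lasso_result"
  )
}

#' @rdname cv_select_lambda
#' @param n_lambda grid resolution.
#' @export
lambda_grid_default <- function(n_lambda = 25L) {
  10^seq(-4, 0, length.out = n_lambda)
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' @export
print.lasso_result <- function(x, ...) {
  cat("lasso_result: chosen lambda =", signif(x$chosen_lambda, 3), "->",
      length(x$selected_genes), "genes selected\n")
  invisible(x)
}

#' @export
tidy.lasso_result <- function(x, ...) {
  tibble::tibble(gene = names(x$weights), weight = unname(x$weights),
                 selected = x$weights != 0)
}

#' @export
glance.lasso_result <- function(x, ...) {
  i <- which(x$lambda_grid == x$chosen_lambda)[1]
  tibble::tibble(chosen_lambda = x$chosen_lambda,
                 cv_accuracy = x$cv_accuracy[i], cv_mse = x$cv_mse[i],
                 n_selected = length(x$selected_genes))
}

#' @export
autoplot.lasso_result <- function(object, ...) {
  df <- tibble::tibble(lambda = object$lambda_grid,
                       accuracy = object$cv_accuracy, mse = object$cv_mse) |>
    tidyr::pivot_longer(c("accuracy", "mse"), names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$chosen_lambda, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "lambda", y = NULL,
                  title = "Cross-validated lasso path")
}

#' Welch's t-test of selected genes between shared and unique regions
#'
#' Unequal-variance (Welch) t-test per selected gene between the shared and
#' unique region classes, with Benjamini-Hochberg FDR over the selected set;
#' a gene is flagged significant at corrected p < `alpha`.
#'
#' @param X regions x genes expression matrix (shared/unique regions only;
#'   raw or standardized).
#' @param y 0/1 class vector (shared = 1).
#' @param genes character vector of gene symbols to test (must be columns of
#'   `X`).
#' @param alpha significance level on the FDR-corrected p (default 0.05).
#' @return tibble: `gene`, `t`, `df`, `p`, `p_fdr`, `significant`.
#' @export
welch_de <- function(X, y, genes, alpha = 0.05) {
  X <- as.matrix(X)
  missing_g <- setdiff(genes, colnames(X))
  if (length(missing_g) > 0L) {
    stop("genes absent from the table: ", paste(missing_g, collapse = ", "))
  }
  if (length(genes) == 0L) {
    return(tibble::tibble(gene = character(), t = numeric(), df = numeric(),
                          p = numeric(), p_fdr = numeric(),
                          significant = logical()))
  }
  rows <- purrr::map(genes, function(g) {
    ht <- welch_t(X[y == 1, g], X[y == 0, g])
    tibble::tibble(gene = g, t = ht$t, df = ht$df, p = ht$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_bh(out$p)
  out$significant <- out$p_fdr < alpha
  out
}

#' End-to-end gene selection workflow
#'
#' Builds the 0/1 response from region classes (shared = 1, unique = 0;
#' `other` regions excluded), standardizes the gene columns, holds out a
#' stratified test fraction, selects lambda by 10-fold CV on the training
#' portion, reports train/test accuracy and MSE of the chosen model, and runs
#' Welch's t-tests on the selected genes over all shared/unique regions.
#'
#' @param expression regions x genes numeric matrix with gene symbols as
#'   column names and region ids as row names.
#' @param region_class tibble from [label_regions()] with `region` matching
#'   the row names and `class`.
#' @param holdout test fraction (default 0.25, stratified).
#' @param grid,folds,seed passed to [cv_select_lambda()].
#' @return object of class `gene_selection`: list with `lasso`
#'   (`lasso_result` fit on the training portion), `train`/`test` one-row
#'   tibbles (accuracy, mse, n), `welch` (tibble from [welch_de()]),
#'   `selected_genes`.
#' @export
select_genes <- function(expression, region_class, holdout = 0.25,
                         grid = lambda_grid_default(), folds = 10L,
                         seed = 1L) {
  X <- as.matrix(expression)
  rc <- region_class[region_class$class %in% c("shared", "unique"), ,
                     drop = FALSE]
  keep <- match(as.character(rc$region), rownames(X))
  if (anyNA(keep)) stop("region ids missing from the expression table")
  X <- X[keep, , drop = FALSE]
  y <- as.numeric(rc$class == "shared")
  Xs <- standardize_columns(X)
  set.seed(seed + 1L)
  test <- logical(length(y))
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    n_test <- round(holdout * length(idx))
    test[idx[sample.int(length(idx), n_test)]] <- TRUE
  }
  lasso <- cv_select_lambda(Xs[!test, , drop = FALSE], y[!test],
                            grid = grid, folds = folds, seed = seed)
  fit <- list(intercept = lasso$intercept, weights = lasso$weights)
  metrics <- function(sel) {
    pr <- predict_lasso(fit, Xs[sel, , drop = FALSE])
    tibble::tibble(accuracy = mean((pr > 0.5) == y[sel]),
                   mse = mean((pr - y[sel])^2), n = sum(sel))
  }
  welch <- welch_de(X, y, lasso$selected_genes)
  structure(
    list(lasso = lasso, train = metrics(!test), test = metrics(test),
         welch = welch, selected_genes = lasso$selected_genes,
         holdout = holdout),
    class = "gene_selection"
  )
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("gene_selection: lambda =", signif(x$lasso$chosen_lambda, 3), "|",
      length(x$selected_genes), "genes |",
      "train acc", round(x$train$accuracy, 3),
      "test acc", round(x$test$accuracy, 3), "\n")
  invisible(x)
}

#' @export
glance.gene_selection <- function(x, ...) {
  tibble::tibble(chosen_lambda = x$lasso$chosen_lambda,
                 n_selected = length(x$selected_genes),
                 train_accuracy = x$train$accuracy, train_mse = x$train$mse,
                 test_accuracy = x$test$accuracy, test_mse = x$test$mse,
                 n_significant = sum(x$welch$significant))
}
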