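# Ridge-regression IC50 prediction. Models are trained on cell-line
# expression (cell lines x genes after transposition) with the penalty
# chosen by 10-fold cross-validated squared error, then applied to tumor
# samples standardized with the training parameters.

ridge_solve <- function(xs, yc, lambda) {
  p <- ncol(xs)
  solve(crossprod(xs) + diag(lambda, p), crossprod(xs, yc))
}

#' Train a ridge IC50 model on cell-line expression
#'
#' Features (genes) are standardized on the training data; the response is
#' centered. For each penalty in `lambda_grid` the mean squared prediction
#' error over `folds` cross-validation folds is computed, the minimizing
#' penalty is selected (ties toward the smaller penalty), and the final
#' model is refit on all cell lines.
#'
#' @param cell_expr genes x cell-lines expression matrix.
#' @param ic50 per-cell-line response, named or in column order.
#' @param lambda_grid positive penalties; default 21 log-spaced values in
#'   \[1e-3, 1e3\].
#' @param folds number of CV folds.
#' @param seed seed for the fold assignment.
#' @return a `ridge_model`: list with `coef` (named by gene), `intercept`,
#'   `lambda`, `cv` (data.frame lambda, mse), `center`, `scale`, `fitted`.
#' @export
ridge_train <- function(cell_expr, ic50,
                        lambda_grid = 10^seq(-3, 3, length.out = 21L),
                        folds = 10L, seed = 1L) {
  stopifnot(is.matrix(cell_expr))
  n <- ncol(cell_expr)
  if (!is.null(names(ic50))) {
    missing <- setdiff(colnames(cell_expr), names(ic50))
    if (length(missing))
      stop("ic50 missing for cell lines: ", paste(missing, collapse = ", "))
    ic50 <- ic50[colnames(cell_expr)]
  }
  if (length(ic50) != n) stop("ic50 length must match cell-line count")
  if (!length(lambda_grid)) stop("empty lambda grid")
  if (any(lambda_grid <= 0)) stop("all penalties must be > 0")
  folds <- check_count(folds, "folds", min = 2L)
  if (n < folds) stop("need at least as many cell lines as folds")

  x <- t(cell_expr)                              # cell lines x genes
  center <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  ybar <- mean(ic50)
  yc <- ic50 - ybar

  set.seed(derive_seed(seed, 3L))
  fold_id <- sample(rep_len(seq_len(folds), n))
  lambda_grid <- sort(lambda_grid)
  cv_mse <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      ctr <- colMeans(x[tr, , drop = FALSE])
      sds <- apply(x[tr, , drop = FALSE], 2L, sd); sds[sds == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2L, ctr), 2L, sds, "/")
      xte <- sweep(sweep(x[!tr, , drop = FALSE], 2L, ctr), 2L, sds, "/")
      mtr <- mean(ic50[tr])
      b <- ridge_solve(xtr, ic50[tr] - mtr, lam)
      pred <- drop(xte %*% b) + mtr
      mean((pred - ic50[!tr])^2)
    }, 0)
    mean(errs)
  }, 0)
  lambda <- lambda_grid[which.min(cv_mse)]
  beta <- drop(ridge_solve(xs, yc, lambda))
  names(beta) <- colnames(x)
  fitted <- drop(xs %*% beta) + ybar
  names(fitted) <- rownames(x)
  structure(list(coef = beta, intercept = ybar, lambda = lambda,
                 cv = data.frame(lambda = lambda_grid, mse = cv_mse),
                 center = center, scale = scl, fitted = fitted,
                 folds = folds, seed = seed),
            class = "ridge_model")
}

#' Predict tumor IC50 from a trained ridge model
#'
#' Tumor expression is standardized with the training center/scale and the
#' linear model applied. Genes present in the tumor matrix but absent from
#' the model are ignored; model genes missing from the tumor matrix are an
#' error.
#'
#' @param model a [ridge_train()] result.
#' @param tumor_expr genes x samples tumor expression matrix.
#' @return named numeric vector of predicted IC50 per sample.
#' @export
predict_ic50 <- function(model, tumor_expr) {
  stopifnot(inherits(model, "ridge_model"), is.matrix(tumor_expr))
  genes <- names(model$coef)
  missing <- setdiff(genes, rownames(tumor_expr))
  if (length(missing))
    stop("tumor matrix lacks model genes: ", paste(missing, collapse = ", "))
  x <- t(tumor_expr[genes, , drop = FALSE])
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  pred <- drop(xs %*% model$coef) + model$intercept
  names(pred) <- colnames(tumor_expr)
  pred
}
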