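# Epsilon-insensitive support vector regression over the six descriptors,
# with the kernel menu used for model selection: linear, quadratic
# (polynomial degree 2), RBF and sigmoid. The quadratic programming solver is
# libsvm via e1071; descriptors are z-scored on training statistics inside
# the engine because SVR is scale-sensitive (raw fitting would silently
# down-weight everything against PPB).

svr_kernels <- c("linear", "quadratic", "rbf", "sigmoid")

svr_kernel_args <- function(kernel) {
  switch(kernel,
    linear = list(kernel = "linear"),
    quadratic = list(kernel = "polynomial", degree = 2, coef0 = 1),
    rbf = list(kernel = "radial"),
    sigmoid = list(kernel = "sigmoid")
  )
}

#' Fit an epsilon-insensitive SVR pIC50 model
#'
#' @param ds a [compound_dataset()] with pic50.
#' @param kernel one of `"linear"`, `"quadratic"` (polynomial degree 2),
#'   `"rbf"`, `"sigmoid"`.
#' @param C cost parameter (> 0), default 1.
#' @param epsilon insensitivity-tube half width (>= 0), default 0.1.
#' @param split fitting records (default "train").
#' @param descriptors input descriptor names.
#' @return Object of class `svr_model` wrapping the libsvm solution together
#'   with the kernel name, hyperparameters and the training z-score
#'   standardization; `$constant` is TRUE for the degenerate constant-response
#'   shortcut.
#' @export
fit_svr <- function(ds, kernel = "linear", C = 1, epsilon = 0.1,
                    split = "train", descriptors = modeling_descriptors()) {
  kernel <- match.arg(kernel, svr_kernels)
  if (C <= 0) stop("C must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  sm <- split_matrix(ds, split = split, descriptors = descriptors)
  X <- sm$X
  y <- sm$y
  if (nrow(X) == 0) stop("no training records")
  if (is.null(y) || any(is.na(y))) stop("pic50 missing in training records")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  base <- list(
    descriptors = descriptors, kernel = kernel, C = C, epsilon = epsilon,
    x_center = mu, x_scale = sd_
  )
  if (max(y) - min(y) <= 2 * epsilon) {
    # every response fits inside one epsilon tube around the midrange:
    # the flat predictor is a zero-loss solution
    base$constant <- TRUE
    base$constant_value <- (max(y) + min(y)) / 2
    return(structure(base, class = "svr_model"))
  }
  ka <- svr_kernel_args(kernel)
  fit <- do.call(e1071::svm, c(
    list(
      x = Xs, y = y, type = "eps-regression",
      cost = C, epsilon = epsilon, scale = FALSE
    ),
    ka
  ))
  base$constant <- FALSE
  base$fit <- fit
  base$n_support <- fit$tot.nSV
  structure(base, class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  if (x$constant) {
    cat(sprintf(
      "<svr_model> %s kernel, constant predictor %.4g (response inside epsilon tube)\n",
      x$kernel, x$constant_value
    ))
  } else {
    cat(sprintf(
      "<svr_model> %s kernel, C = %g, epsilon = %g, %d support vectors\n",
      x$kernel, x$C, x$epsilon, x$n_support
    ))
  }
  invisible(x)
}

#' Predict pIC50 with a fitted SVR model
#' @param object an `svr_model`.
#' @param newdata a [compound_dataset()] or data.frame with descriptor columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  miss <- setdiff(object$descriptors, names(df))
  if (length(miss)) stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(df[, object$descriptors, drop = FALSE])
  storage.mode(X) <- "double"
  if (object$constant) {
    pred <- rep(object$constant_value, nrow(X))
  } else {
    Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
    pred <- as.numeric(stats::predict(object$fit, Xs))
  }
  if ("id" %in% names(df)) names(pred) <- df$id
  pred
}

#' Regression performance metrics
#'
#' MSE, MAE and R2 = 1 - SSE/TSS about the evaluated set's own mean.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return list with `mse`, `mae`, `r2`, `n`; `r2` is NA (flagged) when
#'   n < 2 or the observations are constant.
#' @export
regression_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (any(is.na(observed)) || any(is.na(predicted))) stop("missing values in metrics input")
  err <- predicted - observed
  n <- length(observed)
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (n < 2 || tss == 0) NA_real_ else 1 - sum(err^2) / tss
  list(mse = mean(err^2), mae = mean(abs(err)), r2 = r2, n = n)
}

#' Evaluate an SVR model on a record set
#'
#' @param model an `svr_model` (or any model with a `predict` method and a
#'   `descriptors` field).
#' @param ds a [compound_dataset()] with observed pic50.
#' @param split records to evaluate (default "test").
#' @return [regression_metrics()] list.
#' @export
evaluate_svr <- function(model, ds, split = "test") {
  sm <- split_matrix(ds, split = split, descriptors = model$descriptors)
  if (is.null(sm$y) || any(is.na(sm$y))) stop("observed pic50 missing in evaluation records")
  df <- as.data.frame(sm$X)
  pred <- stats::predict(model, df)
  regression_metrics(sm$y, pred)
}

#' Kernel selection by held-out error
#'
#' Fits each candidate kernel over a small C/epsilon grid, keeps the grid
#' point with the lowest test-set MSE per kernel, and ranks the kernels by
#' that MSE (ties broken by the order of `kernels`).
#'
#' @param ds a [compound_dataset()] with train and test splits.
#' @param kernels candidate kernels (>= 2 for a real comparison; 1 allowed).
#' @param C_grid,epsilon_grid hyperparameter grids (defaults: a small
#'   log-spaced grid around C = 1, epsilon = 0.1).
#' @param descriptors input descriptor names.
#' @return Object of class `kernel_selection`: `table` (kernel, C, epsilon,
#'   train/test MSE-MAE-R2, rank) and `models` (best fit per kernel, ranked).
#' @export
kernel_selection <- function(ds, kernels = svr_kernels,
                             C_grid = c(0.1, 1, 10),
                             epsilon_grid = c(0.05, 0.1, 0.2),
                             descriptors = modeling_descriptors()) {
  if (!length(kernels)) stop("no kernels given")
  rows <- list()
  models <- list()
  for (kn in kernels) {
    best <- NULL
    for (C in C_grid) {
      for (eps in epsilon_grid) {
        m <- tryCatch(
          fit_svr(ds, kernel = kn, C = C, epsilon = eps, descriptors = descriptors),
          error = function(e) NULL
        )
        if (is.null(m)) next
        te <- evaluate_svr(m, ds, split = "test")
        if (is.null(best) || te$mse < best$te$mse) {
          best <- list(m = m, te = te, C = C, eps = eps)
        }
      }
    }
    if (is.null(best)) next
    tr <- evaluate_svr(best$m, ds, split = "train")
    rows[[length(rows) + 1]] <- data.frame(
      kernel = kn, C = best$C, epsilon = best$eps,
      mse_train = tr$mse, mae_train = tr$mae, r2_train = tr$r2,
      mse_test = best$te$mse, mae_test = best$te$mae, r2_test = best$te$r2,
      stringsAsFactors = FALSE
    )
    models[[length(models) + 1]] <- best$m
  }
  if (!length(rows)) stop("every kernel fit failed")
  tab <- do.call(rbind, rows)
  ord <- order(tab$mse_test) # stable sort: ties keep kernel list order
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, models = models[ord]), class = "kernel_selection")
}

#' @export
print.kernel_selection <- function(x, ...) {
  cat("<kernel_selection> ranked by test MSE\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
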