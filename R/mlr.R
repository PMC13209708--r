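#' Fit an ordinary least squares pIC50 model
#'
#' Least-squares fit of the response on the selected descriptors (raw,
#' unstandardized values), with classical standard errors from the unbiased
#' residual variance and the validation statistics used throughout QSAR work:
#' R2, adjusted R2, leave-one-out Q2, the overall F statistic and its
#' p-value. `rmse_pred` stays NA until [evaluate_test()] is run against a
#' held-out set.
#'
#' @param ds a [compound_dataset()] with observed `pic50`.
#' @param subset descriptor names to use (reordered to canonical order).
#' @param split split label(s) of the fitting records (default "train"; use
#'   NULL for all complete records).
#' @param response response column (default `pic50`).
#' @return An object of class `qsar_mlr`: coefficients with standard errors
#'   and a `stats` list (n, k, r2, r2_adj, q2_loo, f_stat, p_value,
#'   rmse_pred, sigma).
#' @export
fit_ols <- function(ds, subset = modeling_descriptors(), split = "train",
                    response = "pic50") {
  subset <- order_canonical(ds, subset)
  sm <- split_matrix(ds, split = split, descriptors = subset)
  y <- as.data.frame(ds)[[response]][match(sm$id, ds$id)]
  if (is.null(y) || any(is.na(y))) stop("response '", response, "' missing for fitting records")
  fit_ols_core(sm$X, y, subset)
}

# matrix-level OLS core shared by fit_ols and the best-subset enumeration
fit_ols_core <- function(Xmat, y, subset) {
  X <- cbind(`(Intercept)` = 1, Xmat)
  n <- nrow(X)
  k <- length(subset)
  if (n <= k + 1) stop("need n > k + 1 records (n = ", n, ", k = ", k, ")")
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    dropped <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ", paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_, y)
  res <- qr.resid(qr_, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - k - 1)
  XtX_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(sigma2 * diag(XtX_inv))
  names(se) <- colnames(X)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  f_stat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  p_value <- stats::pf(f_stat, k, n - k - 1, lower.tail = FALSE)
  # LOO Q2 via the hat-matrix shortcut: e_(i) = e_i / (1 - h_ii)
  h <- rowSums(qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]^2)
  press <- sum((res / (1 - h))^2)
  q2 <- 1 - press / tss
  structure(list(
    descriptors = subset,
    coefficients = beta,
    se = se,
    residuals = res,
    fitted = y - res,
    stats = list(
      n = n, k = k, r2 = r2, r2_adj = r2_adj, q2_loo = q2,
      f_stat = f_stat, p_value = p_value, rmse_pred = NA_real_,
      sigma = sqrt(sigma2)
    ),
    frozen = FALSE
  ), class = "qsar_mlr")
}

# reorder a descriptor subset into the dataset schema's canonical order
order_canonical <- function(ds, subset) {
  sch <- attr(ds, "schema")
  ord <- if (!is.null(sch)) sch$names else modeling_descriptors()
  c(intersect(ord, subset), setdiff(subset, ord))
}

#' @export
print.qsar_mlr <- function(x, ...) {
  cat("<qsar_mlr> pIC50 ~ ", paste(x$descriptors, collapse = " + "),
    if (isTRUE(x$frozen)) "  [frozen published coefficients]", "\n",
    sep = ""
  )
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  s <- x$stats
  cat(sprintf(
    "n = %d, R2 = %.3f, R2adj = %.3f, Q2 = %.3f, F = %.2f, p = %.3g, RMSEpred = %s\n",
    s$n, s$r2, s$r2_adj, s$q2_loo, s$f_stat, s$p_value,
    ifelse(is.na(s$rmse_pred), "NA", sprintf("%.3f", s$rmse_pred))
  ))
  invisible(x)
}

#' Predict pIC50 from a linear model
#'
#' Applies the model coefficients to raw descriptor values.
#'
#' @param object a `qsar_mlr`.
#' @param newdata a [compound_dataset()] or data.frame carrying the model's
#'   descriptor columns.
#' @param ... unused.
#' @return numeric vector of predicted pIC50, named by compound id when
#'   available.
#' @export
predict.qsar_mlr <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  miss <- setdiff(object$descriptors, names(df))
  if (length(miss)) stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(df[, object$descriptors, drop = FALSE])
  if (any(is.na(X))) {
    bad <- object$descriptors[apply(is.na(X), 2, any)]
    stop("missing descriptor value(s) in: ", paste(bad, collapse = ", "))
  }
  pred <- drop(object$coefficients[1] + X %*% object$coefficients[-1])
  if ("id" %in% names(df)) names(pred) <- df$id
  pred
}

#' Leave-one-out cross-validated Q2
#'
#' Q2 = 1 - PRESS/TSS with TSS about the training mean; PRESS is computed by
#' the hat-matrix shortcut, which is algebraically identical to refitting the
#' model n times with one record left out.
#'
#' @inheritParams fit_ols
#' @return Q2 (at most 1; can be negative).
#' @export
q2_loo <- function(ds, subset = modeling_descriptors(), split = "train",
                   response = "pic50") {
  m <- fit_ols(ds, subset = subset, split = split, response = response)
  if (m$stats$n <= m$stats$k + 2) stop("need n > k + 2 for LOO validation")
  m$stats$q2_loo
}

#' Test-set root-mean-square error of prediction
#'
#' @param model a `qsar_mlr` (fitted or frozen).
#' @param ds a [compound_dataset()] with observed pic50.
#' @param split which records to evaluate (default "test").
#' @return RMSE of prediction over the evaluated records.
#' @export
evaluate_test <- function(model, ds, split = "test") {
  sm <- split_matrix(ds, split = split, descriptors = model$descriptors)
  if (nrow(sm$X) == 0) stop("no records in split: ", paste(split, collapse = ","))
  y <- sm$y
  if (is.null(y) || any(is.na(y))) stop("observed pic50 missing in evaluation records")
  pred <- drop(model$coefficients[1] + sm$X %*% model$coefficients[-1])
  sqrt(mean((pred - y)^2))
}

#' Best-subset model search
#'
#' Enumerates every descriptor subset of size `kmin`..`kmax` from the
#' candidate pool, discards subsets failing the collinearity tolerance screen,
#' fits OLS to the rest, and ranks the fits by the selection criterion
#' (adjusted R2 by default; LOO Q2 and R2 available).
#'
#' @param ds a [compound_dataset()].
#' @param pool candidate descriptor names.
#' @param kmin,kmax subset size range (defaults 2 and 6).
#' @param tolerance_threshold collinearity screen level (default 0.1).
#' @param criterion ranking criterion: "r2_adj", "q2_loo" or "r2".
#' @param split fitting records (default "train").
#' @return Object of class `subset_search`: list with `table` (one row per
#'   admissible subset, ranked) and `models` (fitted `qsar_mlr` objects in
#'   the same order).
#' @export
best_subset_search <- function(ds, pool = modeling_descriptors(), kmin = 2, kmax = 6,
                               tolerance_threshold = 0.1,
                               criterion = c("r2_adj", "q2_loo", "r2"),
                               split = "train") {
  criterion <- match.arg(criterion)
  kmax <- min(kmax, length(pool))
  if (kmin > kmax) stop("kmin exceeds the feasible subset size")
  pool <- order_canonical(ds, pool)
  sm <- split_matrix(ds, split = split, descriptors = pool)
  y <- sm$y
  if (is.null(y) || any(is.na(y))) stop("response missing for fitting records")
  # multicollinearity screen via the correlation submatrix: for complete data
  # 1/diag(solve(R[s, s])) equals the 1 - R^2 tolerance of each member
  # regressed on the rest (same quantity screen_subset computes by OLS)
  R_pool <- stats::cor(sm$X)
  subsets <- list()
  for (k in kmin:kmax) {
    cmb <- utils::combn(pool, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  rows <- list()
  models <- list()
  for (s in subsets) {
    tol <- tryCatch(1 / diag(solve(R_pool[s, s, drop = FALSE])),
      error = function(e) NULL
    )
    if (is.null(tol) || length(s) > 1 && any(tol < tolerance_threshold)) next
    m <- tryCatch(fit_ols_core(sm$X[, s, drop = FALSE], y, s),
      error = function(e) NULL
    )
    if (is.null(m)) next
    st <- m$stats
    rows[[length(rows) + 1]] <- data.frame(
      subset = paste(m$descriptors, collapse = "+"),
      k = st$k, r2 = st$r2, r2_adj = st$r2_adj, q2_loo = st$q2_loo,
      f_stat = st$f_stat, stringsAsFactors = FALSE
    )
    models[[length(models) + 1]] <- m
  }
  if (!length(rows)) stop("no admissible subset passed the tolerance screen")
  tab <- do.call(rbind, rows)
  ord <- order(-tab[[criterion]])
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(table = tab, models = models[ord], criterion = criterion),
    class = "subset_search"
  )
}

#' @export
print.subset_search <- function(x, n = 10, ...) {
  cat("<subset_search> ", nrow(x$table), " admissible subsets, ranked by ",
    x$criterion, "\n",
    sep = ""
  )
  print(utils::head(x$table, n), digits = 4)
  invisible(x)
}

#' Fit statistics implied by R2, n and k
#'
#' The closed-form relations used for model validation:
#' adjusted R2 = 1 - (1 - R2)(n - 1)/(n - k - 1),
#' F = (R2/k) / ((1 - R2)/(n - k - 1)), with the p-value from the F(k,
#' n - k - 1) upper tail. Useful for checking the self-consistency of a
#' reported statistics line.
#'
#' @param r2 coefficient of determination.
#' @param n sample size; must exceed k + 1.
#' @param k predictor count.
#' @return list with `r2_adj`, `f_stat`, `p_value`.
#' @export
fit_stats_from_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("need n > k + 1")
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  f_stat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  list(
    r2_adj = r2_adj, f_stat = f_stat,
    p_value = stats::pf(f_stat, k, n - k - 1, lower.tail = FALSE)
  )
}

#' The frozen published six-descriptor MLR model
#'
#' The published linear equation relating pIC50 for BChE inhibition to the six
#' modeling descriptors, with its reported coefficient standard errors and
#' training statistics (n = 100 reference inhibitors):
#' pIC50 = 1.68 + 0.481 nRot - 5.14 Flex - 1.75 Fsp3 + 1.18 logD
#' - 0.847 caco2 - 0.0591 PPB.
#'
#' @return A frozen `qsar_mlr` usable with [predict.qsar_mlr()] and
#'   [evaluate_test()].
#' @export
published_mlr <- function() {
  cf <- c(
    `(Intercept)` = 1.68, nRot = 0.481, Flex = -5.14, Fsp3 = -1.75,
    logD = 1.18, caco2 = -0.847, PPB = -0.0591
  )
  se <- c(
    `(Intercept)` = 1.26, nRot = 0.053, Flex = 0.77, Fsp3 = 0.47,
    logD = 0.14, caco2 = 0.195, PPB = 0.0113
  )
  structure(list(
    descriptors = modeling_descriptors(),
    coefficients = cf,
    se = se,
    stats = list(
      n = 100L, k = 6L, r2 = 0.706, r2_adj = 0.687, q2_loo = 0.667,
      f_stat = 37.15, p_value = NA_real_, rmse_pred = 0.59, sigma = NA_real_
    ),
    frozen = TRUE
  ), class = "qsar_mlr")
}

#' Aggregate per-model predictions into consensus means
#'
#' Arithmetic means of named model predictions: `Mean1` averages MLR, ANN1
#' and SVR; `Mean2` additionally averages ANN2..ANN5 when present. Custom
#' member sets may be supplied.
#'
#' @param predictions data.frame with an `id` column and one column per
#'   model prediction.
#' @param sets named list of member-column sets; default
#'   `list(Mean1 = c("MLR","ANN1","SVR"), Mean2 = c("MLR","ANN1".."ANN5","SVR"))`,
#'   with `Mean2` dropped when its members are absent.
#' @return `predictions` with one appended column per requested mean.
#' @export
aggregate_means <- function(predictions,
                            sets = list(
                              Mean1 = c("MLR", "ANN1", "SVR"),
                              Mean2 = c("MLR", "ANN1", "ANN2", "ANN3", "ANN4", "ANN5", "SVR")
                            )) {
  # drop the default Mean2 silently when the extra networks were not produced
  default_m2 <- identical(
    sets[["Mean2"]],
    c("MLR", "ANN1", "ANN2", "ANN3", "ANN4", "ANN5", "SVR")
  )
  if (default_m2 && !all(sets[["Mean2"]] %in% names(predictions))) {
    sets[["Mean2"]] <- NULL
  }
  for (nm in names(sets)) {
    members <- sets[[nm]]
    miss <- setdiff(members, names(predictions))
    if (length(miss)) {
      stop("mean '", nm, "' is missing member prediction(s): ", paste(miss, collapse = ", "))
    }
    predictions[[nm]] <- rowMeans(predictions[, members, drop = FALSE])
  }
  predictions
}

#' Serialize a linear model to JSON
#'
#' Flat key/value document: version, descriptor names, coefficients, standard
#' errors and fit statistics.
#'
#' @param model a `qsar_mlr`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mlr_json <- function(model, path) {
  doc <- list(
    format = "bcheqsar-mlr", version = 1L,
    frozen = isTRUE(model$frozen),
    descriptors = model$descriptors,
    coefficients = as.list(model$coefficients),
    se = as.list(model$se),
    stats = model$stats
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a linear model serialized by [write_mlr_json()]
#' @param path JSON file.
#' @return a `qsar_mlr`.
#' @export
read_mlr_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "bcheqsar-mlr")) stop("not a bcheqsar MLR document: ", path)
  stats <- doc$stats
  stats$rmse_pred <- if (is.null(stats$rmse_pred)) NA_real_ else stats$rmse_pred
  structure(list(
    descriptors = doc$descriptors,
    coefficients = unlist(doc$coefficients),
    se = unlist(doc$se),
    stats = stats,
    frozen = isTRUE(doc$frozen)
  ), class = "qsar_mlr")
}
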