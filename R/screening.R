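#' Pearson correlation matrix of descriptors
#'
#' Computes the pairwise Pearson correlation matrix over the complete-for-the-
#' pair records (pairwise complete cases). Include `"pic50"` in `vars` to get
#' the descriptor/activity block as well.
#'
#' @param ds a [compound_dataset()].
#' @param vars variable names (descriptors, optionally `pic50`).
#' @param split restrict to records of these split labels (NULL = all).
#' @return An object of class `correlation_matrix`: list with `names` and the
#'   symmetric matrix `r`.
#' @export
correlation_matrix <- function(ds, vars = modeling_descriptors(), split = NULL) {
  df <- as.data.frame(ds)
  if (!is.null(split)) df <- df[df$split %in% split, , drop = FALSE]
  miss <- setdiff(vars, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  M <- as.matrix(df[, vars, drop = FALSE])
  storage.mode(M) <- "double"
  if (sum(stats::complete.cases(M)) < 3) stop("need at least 3 complete records")
  v <- apply(M, 2, stats::var, na.rm = TRUE)
  if (any(!is.finite(v) | v == 0)) {
    stop("zero-variance column(s): ", paste(vars[!is.finite(v) | v == 0], collapse = ", "))
  }
  r <- stats::cor(M, use = "pairwise.complete.obs", method = "pearson")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(names = vars, r = r), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("<correlation_matrix> ", length(x$names), " variables\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Collinearity tolerance of a descriptor
#'
#' Tolerance = 1 - R^2 of `target` regressed (OLS with intercept) on the
#' descriptors in `others`. A low tolerance flags multicollinearity; for a
#' single co-regressor this reduces to 1 - r^2. An empty `others` gives 1.
#'
#' @param ds a [compound_dataset()].
#' @param target descriptor name.
#' @param others character vector of co-regressor names.
#' @param split restrict to records of these split labels (NULL = all).
#' @return tolerance in [0, 1].
#' @export
tolerance <- function(ds, target, others, split = NULL) {
  df <- as.data.frame(ds)
  if (!is.null(split)) df <- df[df$split %in% split, , drop = FALSE]
  vars <- c(target, others)
  miss <- setdiff(vars, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[stats::complete.cases(df[, vars, drop = FALSE]), vars, drop = FALSE]
  n <- nrow(df)
  if (n <= length(others) + 1) stop("need n > |others| + 1 complete records")
  y <- df[[target]]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero-variance target: ", target)
  if (length(others) == 0) return(1)
  X <- cbind(1, as.matrix(df[, others, drop = FALSE]))
  qr_ <- qr(X)
  rss <- sum(qr.resid(qr_, y)^2)
  r2 <- 1 - rss / tss
  min(max(1 - r2, 0), 1)
}

#' Screen a descriptor subset for multicollinearity
#'
#' Computes each member's tolerance against the remaining members and flags it
#' admissible when tolerance >= `threshold`. The subset passes when all
#' members are admissible. The stricter conventional 0.25 level is also
#' reported.
#'
#' @param ds a [compound_dataset()].
#' @param subset character vector of descriptor names.
#' @param threshold admissibility threshold in (0, 1); default 0.1.
#' @param split restrict to records of these split labels (NULL = all).
#' @return An object of class `tolerance_report`: data.frame with columns
#'   descriptor, tolerance, admissible, strict_0.25; attributes `threshold`
#'   and `passes`.
#' @export
screen_subset <- function(ds, subset, threshold = 0.1, split = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  tol <- vapply(
    seq_along(subset),
    function(i) tolerance(ds, subset[i], subset[-i], split = split),
    numeric(1)
  )
  rep_ <- data.frame(
    descriptor = subset,
    tolerance = tol,
    admissible = tol >= threshold,
    strict_0.25 = tol >= 0.25,
    stringsAsFactors = FALSE
  )
  structure(rep_,
    class = c("tolerance_report", "data.frame"),
    threshold = threshold, passes = all(rep_$admissible)
  )
}

#' @export
print.tolerance_report <- function(x, ...) {
  cat("<tolerance_report> threshold = ", attr(x, "threshold"),
    "; subset ", if (attr(x, "passes")) "PASSES" else "FAILS", "\n",
    sep = ""
  )
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
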