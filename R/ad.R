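# PCA applicability domain: z-score the descriptors on the reference set,
# project onto the first two principal components of the correlation matrix,
# and bound the reference chemical space by a coverage ellipse on the
# PC1/PC2 scores. Query compounds outside the ellipse are flagged as
# extrapolations whose predictions deserve caution.

#' Fit a PCA applicability domain
#'
#' Standardizes the chosen descriptors with reference means/SDs, performs PCA
#' by eigendecomposition of the correlation matrix (sign convention: the
#' largest-magnitude loading of each component is positive), and bounds the
#' reference scores by a Mahalanobis ellipse on the PC1/PC2 score covariance.
#' The ellipse radius is calibrated so that at least `ceiling(coverage * n)`
#' reference compounds fall inside (the `coverage`-quantile of the reference
#' Mahalanobis distances); the parametric chi-square(2) radius, which it
#' matches asymptotically for Gaussian scores, is stored alongside.
#'
#' @param reference a [compound_dataset()] of reference compounds (n >= 10).
#' @param descriptors descriptor names spanning the chemical space (default:
#'   the six modeling descriptors).
#' @param coverage fraction of reference compounds the ellipse must contain,
#'   in (0, 1); default 0.99.
#' @return Object of class `ad_model`: standardization parameters, loadings,
#'   explained-variance fractions, score covariance, ellipse parameters
#'   (center, semi-axes, orientation angle) and the boundary radii.
#' @export
fit_ad <- function(reference, descriptors = modeling_descriptors(), coverage = 0.99) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  sm <- split_matrix(reference, split = NULL, descriptors = descriptors)
  X <- sm$X
  n <- nrow(X)
  if (n < 10) stop("need at least 10 reference compounds")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  if (any(sd_ == 0)) {
    stop("zero-variance descriptor(s): ", paste(descriptors[sd_ == 0], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  R <- stats::cor(Z)
  eig <- eigen(R, symmetric = TRUE)
  evar <- eig$values / sum(eig$values)
  L <- eig$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) { # reproducible sign convention
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- descriptors
  colnames(L) <- c("PC1", "PC2")
  scores <- Z %*% L
  center <- colMeans(scores)
  S <- stats::cov(scores)
  S_inv <- solve(S)
  d2 <- stats::mahalanobis(scores, center, S, inverted = FALSE)
  k <- ceiling(coverage * n)
  r2_emp <- sort(d2)[min(k, n)]
  r2_chisq <- stats::qchisq(coverage, df = 2)
  r2 <- r2_emp
  es <- eigen(S, symmetric = TRUE)
  semi_axes <- sqrt(es$values * r2)
  angle <- atan2(es$vectors[2, 1], es$vectors[1, 1])
  structure(list(
    descriptors = descriptors,
    center_x = mu, scale_x = sd_,
    loadings = L,
    explained_variance = evar,
    score_center = center,
    score_cov = S, score_cov_inv = S_inv,
    coverage = coverage,
    radius2 = r2, radius2_chisq = r2_chisq,
    ellipse = list(center = center, semi_axes = semi_axes, angle = angle),
    n_reference = n,
    reference_scores = scores,
    reference_ids = sm$id
  ), class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf(
    "<ad_model> %d reference compounds, %.0f%% ellipse on PC1/PC2 (%.1f%% + %.1f%% variance)\n",
    x$n_reference, 100 * x$coverage,
    100 * x$explained_variance[1], 100 * x$explained_variance[2]
  ))
  cat(sprintf(
    "  ellipse: semi-axes %.3f x %.3f, angle %.1f deg (boundary radius^2 = %.3f; chisq ref %.3f)\n",
    x$ellipse$semi_axes[1], x$ellipse$semi_axes[2],
    x$ellipse$angle * 180 / pi, x$radius2, x$radius2_chisq
  ))
  invisible(x)
}

#' Classify query compounds against an applicability domain
#'
#' Projects each query onto the reference PC1/PC2 plane and reports the
#' radial ellipse coordinate (1.0 = boundary): `inside` is distance <= 1.
#' Records missing a required descriptor get an NA verdict with the error
#' noted, not a hard failure.
#'
#' @param model an `ad_model`.
#' @param query a [compound_dataset()] or data.frame.
#' @return data.frame of class `ad_verdicts`: id, pc1, pc2, distance,
#'   inside, note.
#' @export
ad_classify <- function(model, query) {
  df <- as.data.frame(query)
  n <- nrow(df)
  out <- data.frame(
    id = if ("id" %in% names(df)) as.character(df$id) else as.character(seq_len(n)),
    pc1 = NA_real_, pc2 = NA_real_, distance = NA_real_,
    inside = NA, note = "", stringsAsFactors = FALSE
  )
  miss_cols <- setdiff(model$descriptors, names(df))
  if (length(miss_cols)) {
    out$note <- paste("missing descriptor column(s):", paste(miss_cols, collapse = ", "))
    return(structure(out, class = c("ad_verdicts", "data.frame")))
  }
  X <- as.matrix(df[, model$descriptors, drop = FALSE])
  storage.mode(X) <- "double"
  ok <- stats::complete.cases(X)
  out$note[!ok] <- "missing descriptor value"
  if (any(ok)) {
    Z <- sweep(sweep(X[ok, , drop = FALSE], 2, model$center_x), 2, model$scale_x, "/")
    scores <- Z %*% model$loadings
    d2 <- stats::mahalanobis(scores, model$score_center, model$score_cov_inv,
      inverted = TRUE
    )
    out$pc1[ok] <- scores[, 1]
    out$pc2[ok] <- scores[, 2]
    out$distance[ok] <- sqrt(d2 / model$radius2)
    out$inside[ok] <- out$distance[ok] <= 1
  }
  structure(out, class = c("ad_verdicts", "data.frame"))
}

#' @export
print.ad_verdicts <- function(x, ...) {
  cat("<ad_verdicts> ", sum(x$inside %in% TRUE), " inside / ",
    sum(x$inside %in% FALSE), " outside\n",
    sep = ""
  )
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot an applicability domain
#'
#' Reference scores, the coverage ellipse, and (optionally) query compounds
#' on the PC1/PC2 plane.
#'
#' @param x an `ad_model`.
#' @param query optional dataset to overlay via [ad_classify()].
#' @param ... passed to [graphics::plot()].
#' @return the query verdicts (invisibly), when given.
#' @method plot ad_model
#' @export
plot.ad_model <- function(x, query = NULL, ...) {
  sc <- x$reference_scores
  tt <- seq(0, 2 * pi, length.out = 200)
  es <- eigen(x$score_cov, symmetric = TRUE)
  ell <- cbind(x$ellipse$semi_axes[1] * cos(tt), x$ellipse$semi_axes[2] * sin(tt)) %*%
    t(es$vectors)
  ell <- sweep(ell, 2, x$score_center, "+")
  rng1 <- range(sc[, 1], ell[, 1])
  rng2 <- range(sc[, 2], ell[, 2])
  v <- NULL
  if (!is.null(query)) {
    v <- ad_classify(x, query)
    rng1 <- range(rng1, v$pc1, na.rm = TRUE)
    rng2 <- range(rng2, v$pc2, na.rm = TRUE)
  }
  graphics::plot(sc[, 1], sc[, 2],
    pch = 16, col = "grey60", xlim = rng1, ylim = rng2,
    xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
    ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]), ...
  )
  graphics::lines(ell[, 1], ell[, 2], col = "steelblue", lwd = 2)
  if (!is.null(v)) {
    graphics::points(v$pc1, v$pc2,
      pch = 17,
      col = ifelse(v$inside %in% TRUE, "forestgreen", "firebrick")
    )
    graphics::text(v$pc1, v$pc2, v$id, pos = 3, cex = 0.7)
  }
  invisible(v)
}
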