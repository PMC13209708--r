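# Synthetic reference-inhibitor generator. The literature IC50 compilation
# behind the published models is not printed, but its descriptor correlation
# matrix is; the generator draws descriptor vectors from a Gaussian copula
# with that correlation structure, applies realistic marginal locations,
# truncates to physically admissible ranges, and produces pIC50 from the
# frozen published linear equation plus Gaussian noise at the published
# prediction-error scale. Every model stage is thereby testable end-to-end
# without the external data.

#' Published descriptor correlation matrix
#'
#' The reported Pearson correlation matrix (n = 121 reference inhibitors)
#' over the six modeling descriptors, in canonical order; set
#' `include_pic50 = TRUE` for the 7x7 block including experimental pIC50.
#'
#' @param include_pic50 logical.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
published_descriptor_correlations <- function(include_pic50 = FALSE) {
  nm <- c(modeling_descriptors(), "pic50")
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("nRot", "Flex", 0.864)
  set2("nRot", "Fsp3", 0.463)
  set2("nRot", "logD", 0.274)
  set2("nRot", "caco2", -0.047)
  set2("nRot", "PPB", 0.119)
  set2("nRot", "pic50", 0.297)
  set2("Flex", "Fsp3", 0.537)
  set2("Flex", "logD", 0.203)
  set2("Flex", "caco2", 0.056)
  set2("Flex", "PPB", 0.022)
  set2("Flex", "pic50", -0.026)
  set2("Fsp3", "logD", -0.084)
  set2("Fsp3", "caco2", 0.220)
  set2("Fsp3", "PPB", -0.393)
  set2("Fsp3", "pic50", -0.154)
  set2("logD", "caco2", -0.003)
  set2("logD", "PPB", 0.648)
  set2("logD", "pic50", 0.446)
  set2("caco2", "PPB", -0.081)
  set2("caco2", "pic50", -0.360)
  set2("PPB", "pic50", 0.119)
  if (include_pic50) R else R[1:6, 1:6]
}

#' Nearest positive-semidefinite correlation repair
#'
#' Clips negative eigenvalues at zero, reconstructs, and rescales to unit
#' diagonal. Idempotent on matrices that are already PSD.
#'
#' @param m symmetric matrix with unit diagonal.
#' @param tol eigenvalue tolerance below which repair is refused (default
#'   -0.5: a matrix that broken is treated as an input error).
#' @return repaired correlation matrix.
#' @export
nearest_psd <- function(m, tol = -0.5) {
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  eig <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(eig$values) < tol) stop("matrix is too far from PSD to repair")
  if (min(eig$values) >= -1e-12 * max(abs(eig$values))) return(m)
  lam <- pmax(eig$values, 0)
  out <- eig$vectors %*% diag(lam) %*% t(eig$vectors)
  d <- sqrt(diag(out))
  d[d == 0] <- 1
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}

#' Default marginal locations for the synthetic reference set
#'
#' Means place the population over the drug-like region the reference
#' inhibitors occupy (and where most of the sunscreen fixture sits); the
#' standard deviations cover the bulk of the sunscreen descriptor ranges and
#' comfortably exceed the spreads implied by the published coefficient
#' standard errors (sd >= sigma / (sqrt(n) SE sqrt(tolerance))), so a refit
#' on generated data is at least as informative per coefficient as the
#' original fit. Tail mass beyond the physical bounds is kept small (< 10%
#' per descriptor) so range truncation barely perturbs the target
#' correlation structure.
#'
#' @return list with numeric vectors `mean` and `sd` named by descriptor.
#' @export
reference_marginals <- function() {
  list(
    mean = c(nRot = 8, Flex = 0.60, Fsp3 = 0.40, logD = 3.0, caco2 = -4.9, PPB = 72),
    sd = c(nRot = 5.5, Flex = 0.33, Fsp3 = 0.30, logD = 1.1, caco2 = 0.5, PPB = 15)
  )
}

#' Generate a synthetic reference-inhibitor dataset
#'
#' Draws a latent multivariate normal with the target descriptor correlation
#' (Cholesky factor of the PSD-repaired matrix), applies the marginal
#' means/SDs, truncates to admissible ranges (nRot rounded to a nonnegative
#' integer, Flex >= 0, Fsp3 in \[0, 1\], PPB in \[0, 100\]), and computes
#' pIC50 from the frozen published equation evaluated on the truncated
#' descriptors plus N(0, sigma^2) noise. Fully reproducible per seed.
#'
#' @param n number of compounds (default 121, the reference-set size).
#' @param correlation target 6x6 descriptor correlation matrix (default: the
#'   published matrix).
#' @param marginals list with `mean` and `sd` vectors (default
#'   [reference_marginals()]).
#' @param sigma Gaussian noise SD on pIC50 (default 0.59, the published
#'   prediction error scale).
#' @param seed integer seed.
#' @param smiles_library optional data.frame (id, smiles) from which SMILES
#'   are attached by seeded sampling with replacement.
#' @return a [compound_dataset()] with descriptors, pic50, ic50_nM and
#'   (optionally) smiles; split labels unassigned.
#' @export
synthetic_reference <- function(n = 121, correlation = published_descriptor_correlations(),
                                marginals = reference_marginals(), sigma = 0.59,
                                seed = 1L, smiles_library = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  nm <- modeling_descriptors()
  if (!identical(dim(correlation), c(6L, 6L))) stop("correlation must be 6x6")
  R <- nearest_psd(correlation)
  # Cholesky with a tiny jitter fallback for semidefinite repaired matrices
  ch <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-10, 6)))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * 6), n, 6) %*% ch
  X <- sweep(sweep(Z, 2, marginals$sd[nm], "*"), 2, marginals$mean[nm], "+")
  colnames(X) <- nm
  X[, "nRot"] <- pmax(round(X[, "nRot"]), 0)
  X[, "Flex"] <- pmax(X[, "Flex"], 0)
  X[, "Fsp3"] <- pmin(pmax(X[, "Fsp3"], 0), 1)
  X[, "PPB"] <- pmin(pmax(X[, "PPB"], 0), 100)
  df <- as.data.frame(X)
  df$id <- sprintf("ref_%03d", seq_len(n))
  eq <- published_mlr()
  pic50 <- predict(eq, df) + stats::rnorm(n, 0, sigma)
  df$pic50 <- unname(pic50)
  df$ic50_nM <- 10^(9 - df$pic50)
  if (!is.null(smiles_library)) {
    df$smiles <- smiles_library$smiles[sample.int(nrow(smiles_library), n, replace = TRUE)]
  }
  df <- df[, c("id", intersect(c("smiles"), names(df)), nm, "ic50_nM", "pic50")]
  compound_dataset(df, seed = as.integer(seed))
}
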