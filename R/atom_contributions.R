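# Hologram-QSAR-style atomic contributions: PLS regression of pIC50 on
# hashed circular fingerprints, then back-projection of each set bit's
# regression weight onto the heavy atoms whose environments produced the
# bit. The PLS factorization itself is delegated to mixOmics; the bit->atom
# back-projection and the conservation bookkeeping live here.

# PLS regression vector for a predictor block with z-scored response;
# returns weights in response units plus the intercept term. With
# nc = ncol(Xb) on a full-rank block this reproduces the OLS solution.
pls_weights <- function(Xb, yb, nc) {
  sdv <- stats::sd(yb)
  if (sdv == 0) {
    return(list(w = numeric(ncol(Xb)), intercept = mean(yb)))
  }
  ysc <- (yb - mean(yb)) / sdv
  colnames(Xb) <- sprintf("b%d", seq_len(ncol(Xb)))
  # folds can leave near-constant bit columns; mixOmics warns on their
  # internal correlations without affecting the regression vector
  pf <- suppressWarnings(
    mixOmics::pls(Xb, ysc, ncomp = nc, scale = FALSE, mode = "regression")
  )
  pr <- stats::predict(pf, Xb)
  w <- as.numeric(pr$B.hat[, , nc]) * sdv
  list(w = w, intercept = mean(yb) - sum(colMeans(Xb) * w))
}

#' Train a fingerprint PLS model of pIC50
#'
#' Computes radius-2 hashed circular fingerprints, splits the molecules into
#' a training and test set by a seeded shuffle, and regresses pIC50 on the
#' binary bit matrix by partial least squares. Only the response is z-scored;
#' the bit matrix stays binary (mean-centered inside PLS). Reports k-fold
#' cross-validated Q2 on the training set and R2 on the held-out set.
#'
#' @param smiles character vector of SMILES strings.
#' @param pic50 numeric response, same length.
#' @param n_components PLS components (default 6; capped at
#'   min(n_train - 1, active bits), error if fewer than 2 training molecules
#'   above the cap would remain).
#' @param folds cross-validation folds (default 5).
#' @param train_fraction training fraction of the molecule split (default 0.75).
#' @param seed integer seed controlling split and folds.
#' @param radius,n_bits fingerprint parameters (defaults 2 and 2048).
#' @return Object of class `fp_pls`: active-bit regression weights (response
#'   units), intercept term, training statistics (`q2_cv`, `r2_train`,
#'   `r2_test`), the split, and the fingerprint configuration.
#' @export
train_fingerprint_pls <- function(smiles, pic50, n_components = 6, folds = 5,
                                  train_fraction = 0.75, seed = 1L,
                                  radius = 2, n_bits = 2048) {
  if (length(smiles) != length(pic50)) stop("smiles and pic50 lengths differ")
  if (any(is.na(pic50))) stop("pic50 must be observed for every molecule")
  n <- length(smiles)
  fm <- fingerprint_matrix(smiles, radius = radius, n_bits = n_bits)
  set.seed(seed)
  n_train <- max(2L, round(train_fraction * n))
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  Xtr_full <- fm$X[train_idx, , drop = FALSE]
  active <- which(colSums(Xtr_full) > 0 & colSums(Xtr_full) < length(train_idx))
  if (length(active) == 0) stop("no informative fingerprint bits in the training set")
  if (length(train_idx) < n_components + 2) {
    stop(
      "need at least n_components + 2 training molecules (have ",
      length(train_idx), ", components ", n_components, ")"
    )
  }
  ncomp <- min(n_components, length(train_idx) - 1L, length(active))
  y_tr <- pic50[train_idx]
  y_mean <- mean(y_tr)
  y_sd <- stats::sd(y_tr)
  fit_core <- pls_weights
  Xtr <- Xtr_full[, active, drop = FALSE]
  core <- fit_core(Xtr, y_tr, ncomp)
  predict_raw <- function(Xa) as.numeric(Xa %*% core$w) + core$intercept
  r2_train <- regression_metrics(y_tr, predict_raw(Xtr))$r2
  r2_test <- if (length(test_idx) >= 2) {
    regression_metrics(pic50[test_idx], predict_raw(fm$X[test_idx, active, drop = FALSE]))$r2
  } else {
    NA_real_
  }
  # k-fold CV on the training molecules (fold model refit on the fold's own
  # active bits intersected with the global active set)
  q2_cv <- NA_real_
  if (folds >= 2 && length(train_idx) >= folds) {
    fold_id <- sample(rep(seq_len(folds), length.out = length(train_idx)))
    press <- 0
    for (f in seq_len(folds)) {
      in_f <- fold_id != f
      if (sum(in_f) < 3) next
      nc_f <- min(ncomp, sum(in_f) - 1L)
      core_f <- fit_core(Xtr[in_f, , drop = FALSE], y_tr[in_f], nc_f)
      pred_f <- as.numeric(Xtr[!in_f, , drop = FALSE] %*% core_f$w) + core_f$intercept
      press <- press + sum((pred_f - y_tr[!in_f])^2)
    }
    q2_cv <- 1 - press / sum((y_tr - y_mean)^2)
  }
  structure(list(
    radius = radius, n_bits = as.integer(n_bits),
    n_components = ncomp, folds = folds,
    active_bits = active,
    weights = stats::setNames(core$w, colnames(fm$X)[active]),
    intercept = core$intercept,
    train_idx = train_idx, test_idx = test_idx,
    stats = list(q2_cv = q2_cv, r2_train = r2_train, r2_test = r2_test),
    seed = as.integer(seed)
  ), class = "fp_pls")
}

#' @export
print.fp_pls <- function(x, ...) {
  cat(sprintf(
    "<fp_pls> %d comps on %d active bits (radius %d, %d bits); train R2 = %.3f, CV Q2 = %.3f, test R2 = %s\n",
    x$n_components, length(x$active_bits), x$radius, x$n_bits,
    x$stats$r2_train, x$stats$q2_cv,
    ifelse(is.na(x$stats$r2_test), "NA", sprintf("%.3f", x$stats$r2_test))
  ))
  invisible(x)
}

#' Predict pIC50 from fingerprints
#' @param object an `fp_pls`.
#' @param newdata character vector of SMILES.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fp_pls <- function(object, newdata, ...) {
  fm <- fingerprint_matrix(newdata, radius = object$radius, n_bits = object$n_bits)
  as.numeric(fm$X[, object$active_bits, drop = FALSE] %*% object$weights) + object$intercept
}

#' Per-atom contribution map for one molecule
#'
#' Each set bit shared with the model vocabulary contributes its regression
#' weight, divided equally among the heavy atoms of the environments that set
#' it (union over environments when several map to the same bit); an atom's
#' contribution is the sum over the bits it helps set. By construction the
#' contributions sum to the PLS prediction minus the intercept term.
#'
#' @param model an `fp_pls`.
#' @param smiles a single SMILES string.
#' @param id optional compound label.
#' @return Object of class `contribution_map`: data.frame (atom, element,
#'   contribution) plus attributes `total`, `prediction`, `intercept`, `id`.
#' @export
atom_contributions <- function(model, smiles, id = smiles) {
  fp <- morgan_fingerprint(smiles, radius = model$radius, n_bits = model$n_bits)
  contrib <- numeric(fp$n_atoms)
  present <- intersect(fp$bits, model$active_bits)
  for (b in present) {
    w <- model$weights[match(b, model$active_bits)]
    if (w == 0) next
    atoms <- fp$bit_atoms[[as.character(b)]]
    contrib[atoms] <- contrib[atoms] + w / length(atoms)
  }
  total <- sum(contrib)
  map <- data.frame(
    atom = seq_len(fp$n_atoms),
    element = fp$elements,
    contribution = contrib,
    stringsAsFactors = FALSE
  )
  structure(map,
    class = c("contribution_map", "data.frame"),
    total = total,
    prediction = total + model$intercept,
    intercept = model$intercept,
    id = id
  )
}

#' @export
print.contribution_map <- function(x, ...) {
  cat(sprintf(
    "<contribution_map> %s: prediction %.3f (intercept %.3f + atoms %.3f)\n",
    attr(x, "id"), attr(x, "prediction"), attr(x, "intercept"), attr(x, "total")
  ))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' A small synthetic SMILES library for exercising the fingerprint stage
#'
#' Programmatically built drug-like toy structures grouped by the structural
#' motifs the contribution analysis discusses: benzimidazole and triazine
#' nitrogens, benzoic acids (positive motifs) versus long aliphatic chains,
#' phenols, anilines and sulfonic acids (negative motifs). Synthetic stand-in
#' structures: not the literature reference inhibitors.
#'
#' @return data.frame with columns id, smiles, motif.
#' @export
toy_smiles_library <- function() {
  chains <- c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC")
  pos <- c(
    benzimidazole = "c1ccc2[nH]cnc2c1",
    benzimidazole_me = "Cc1nc2ccccc2[nH]1",
    benzimidazole_ph = "c1ccc(cc1)-c1nc2ccccc2[nH]1",
    triazine = "Nc1nc(N)nc(N)n1",
    triazine_ph = "c1ccc(Nc2ncncn2)cc1",
    benzoic = "OC(=O)c1ccccc1",
    benzoic_n = "OC(=O)c1ccc(cc1)-c1nc2ccccc2[nH]1",
    pyridine_acid = "OC(=O)c1ccncc1"
  )
  neg <- c(
    phenol = "Oc1ccccc1",
    aniline = "Nc1ccccc1",
    sulfonic = "OS(=O)(=O)c1ccccc1",
    cresol = "Cc1ccc(O)cc1",
    toluidine = "Cc1ccc(N)cc1"
  )
  rows <- list()
  add <- function(id, smiles, motif) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, smiles = smiles, motif = motif, stringsAsFactors = FALSE
    )
  }
  for (nm in names(pos)) add(nm, pos[[nm]], "positive")
  for (nm in names(neg)) add(nm, neg[[nm]], "negative")
  for (i in seq_along(chains)) {
    add(sprintf("alkylbenzene_%d", i), paste0(chains[i], "c1ccccc1"), "negative")
    add(sprintf("alkyl_ester_%d", i), paste0(chains[i], "OC(=O)c1ccccc1"), "negative")
    add(sprintf("chain_acid_%d", i), paste0(chains[i], "C(=O)O"), "neutral")
  }
  for (i in seq_along(chains)) {
    add(
      sprintf("benzimidazole_chain_%d", i),
      paste0(chains[i], "c1nc2ccccc2[nH]1"), "mixed"
    )
  }
  do.call(rbind, rows)
}
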