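# Multilayer-perceptron regression: one hidden layer, the four classical
# activation functions, sum-of-squares (SOS) error, BFGS training, and
# error-ratio global sensitivity analysis of the inputs.

mlp_activations <- c("identity", "logistic", "tanh", "exponential")

mlp_act <- function(z, name) {
  switch(name,
    identity = z,
    logistic = 1 / (1 + exp(-pmin(pmax(z, -30), 30))),
    tanh = tanh(z),
    exponential = exp(pmin(pmax(z, -30), 30))
  )
}

# derivative expressed through the activation value a = f(z)
mlp_act_deriv <- function(a, name) {
  switch(name,
    identity = rep(1, length(a)),
    logistic = a * (1 - a),
    tanh = 1 - a^2,
    exponential = a
  )
}

# response range targets per output activation (min-max mapped into the
# comfortably-reachable part of the codomain)
mlp_y_range <- function(name) {
  switch(name,
    identity = NULL, # no response scaling
    logistic = c(0.15, 0.85),
    exponential = c(0.15, 0.85),
    tanh = c(-0.7, 0.7)
  )
}

mlp_unpack <- function(par, p, hidden) {
  n1 <- hidden * (p + 1)
  W1 <- matrix(par[seq_len(n1)], nrow = hidden) # hidden x (p+1), col 1 = bias
  w2 <- par[n1 + seq_len(hidden + 1)] # output bias + hidden weights
  list(W1 = W1, w2 = w2)
}

mlp_forward <- function(X1, W1, w2, act_h, act_o) {
  Zh <- X1 %*% t(W1)
  Ah <- mlp_act(Zh, act_h)
  zo <- drop(cbind(1, Ah) %*% w2)
  list(Ah = Ah, yhat = mlp_act(zo, act_o))
}

#' Train a multilayer perceptron pIC50 regressor
#'
#' One hidden layer; hidden and output activations drawn from identity,
#' logistic, hyperbolic tangent and exponential. Inputs are min-max scaled to
#' \[0, 1\] on training statistics; for non-identity output activations the
#' response is min-max mapped into the reachable part of the activation's
#' codomain. Weights start from a seeded U(-0.5, 0.5) draw and are trained by
#' BFGS quasi-Newton iterations (analytic gradient) minimizing the
#' sum-of-squares (SOS) error. Training is deterministic for a fixed seed.
#'
#' @param ds a [compound_dataset()] with pic50.
#' @param hidden hidden-layer size (>= 1).
#' @param activations length-2 character vector `c(hidden, output)`.
#' @param seed integer seed for the weight initialization.
#' @param maxit BFGS iteration cap (default 200).
#' @param reltol BFGS relative convergence tolerance (default 1e-10; the
#'   optimizer also stops when gradient progress stalls).
#' @param split fitting records (default "train").
#' @param descriptors input descriptor names.
#' @return Object of class `mlp_model`: weights, activations, scaling
#'   parameters, training SOS and a convergence flag.
#' @export
train_mlp <- function(ds, hidden = 6, activations = c("tanh", "identity"),
                      seed = 1L, maxit = 200, reltol = 1e-10,
                      split = "train", descriptors = modeling_descriptors()) {
  if (hidden < 1) stop("hidden must be >= 1")
  activations <- match.arg(activations, mlp_activations, several.ok = TRUE)
  if (length(activations) != 2) stop("activations must name the hidden and output function")
  sm <- split_matrix(ds, split = split, descriptors = descriptors)
  X <- sm$X
  y <- sm$y
  if (nrow(X) == 0) stop("no training records")
  if (is.null(y) || any(is.na(y))) stop("pic50 missing in training records")
  p <- ncol(X)
  x_min <- apply(X, 2, min)
  x_max <- apply(X, 2, max)
  x_rng <- pmax(x_max - x_min, .Machine$double.eps)
  Xs <- sweep(sweep(X, 2, x_min), 2, x_rng, "/")
  yr <- mlp_y_range(activations[2])
  if (is.null(yr)) {
    y_a <- 0
    y_b <- 1
  } else {
    lo <- min(y)
    hi <- max(y)
    if (hi - lo < .Machine$double.eps) {
      y_a <- lo - yr[1] # constant response: center it in the target band
      y_b <- 1
    } else {
      y_b <- (hi - lo) / (yr[2] - yr[1])
      y_a <- lo - yr[1] * y_b
    }
  }
  ys <- (y - y_a) / y_b
  X1 <- cbind(1, Xs)
  act_h <- activations[1]
  act_o <- activations[2]
  npar <- hidden * (p + 1) + hidden + 1
  set.seed(seed)
  par0 <- stats::runif(npar, -0.5, 0.5)
  sos_fn <- function(par) {
    w <- mlp_unpack(par, p, hidden)
    fw <- mlp_forward(X1, w$W1, w$w2, act_h, act_o)
    s <- sum((fw$yhat - ys)^2)
    if (!is.finite(s)) s <- 1e10
    s
  }
  sos_gr <- function(par) {
    w <- mlp_unpack(par, p, hidden)
    fw <- mlp_forward(X1, w$W1, w$w2, act_h, act_o)
    err <- fw$yhat - ys
    if (!all(is.finite(err))) return(rep(0, length(par)))
    d_o <- 2 * err * mlp_act_deriv(fw$yhat, act_o) # n
    g_w2 <- drop(crossprod(cbind(1, fw$Ah), d_o)) # hidden + 1
    d_h <- (d_o %*% t(w$w2[-1])) * mlp_act_deriv(fw$Ah, act_h) # n x hidden
    g_W1 <- t(d_h) %*% X1 # hidden x (p+1)
    c(as.vector(g_W1), g_w2)
  }
  opt <- stats::optim(par0, sos_fn, sos_gr,
    method = "BFGS",
    control = list(maxit = maxit, reltol = reltol)
  )
  w <- mlp_unpack(opt$par, p, hidden)
  structure(list(
    descriptors = descriptors,
    hidden = as.integer(hidden),
    activations = c(hidden = act_h, output = act_o),
    W1 = w$W1, w2 = w$w2,
    x_min = x_min, x_range = x_rng,
    y_shift = y_a, y_scale = y_b,
    sos_train = opt$value,
    converged = opt$convergence == 0,
    seed = as.integer(seed)
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "<mlp_model> %d-%d-1 MLP, %s/%s, train SOS = %.4g%s\n",
    length(x$descriptors), x$hidden,
    x$activations[1], x$activations[2], x$sos_train,
    if (!x$converged) " (iteration cap reached)" else ""
  ))
  invisible(x)
}

#' Predict pIC50 with a trained MLP
#' @param object an `mlp_model`.
#' @param newdata a [compound_dataset()] or data.frame with the model's
#'   descriptor columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  miss <- setdiff(object$descriptors, names(df))
  if (length(miss)) stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(df[, object$descriptors, drop = FALSE])
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, object$x_min), 2, object$x_range, "/")
  fw <- mlp_forward(
    cbind(1, Xs), object$W1, object$w2,
    object$activations[1], object$activations[2]
  )
  pred <- fw$yhat * object$y_scale + object$y_shift
  if ("id" %in% names(df)) names(pred) <- df$id
  pred
}

mlp_sos <- function(model, X, y) {
  Xs <- sweep(sweep(X, 2, model$x_min), 2, model$x_range, "/")
  fw <- mlp_forward(
    cbind(1, Xs), model$W1, model$w2,
    model$activations[1], model$activations[2]
  )
  ys <- (y - model$y_shift) / model$y_scale
  sum((fw$yhat - ys)^2)
}

#' Automated network search
#'
#' Samples candidate architectures (hidden-layer sizes within `hidden_range`,
#' hidden/output activation pairs from the four allowed functions) with
#' per-candidate derived seeds, trains each on the training split, and
#' retains the `n_retain` networks with the lowest validation-set SOS,
#' ranked. The published configuration trained 500 and retained 5 from 50;
#' the desk-scale default is 40/5.
#'
#' @param ds a [compound_dataset()] with train and validation splits.
#' @param n_train number of networks to train (default 40).
#' @param n_retain number of networks to retain (default 5).
#' @param hidden_range candidate hidden sizes (default 3:13).
#' @param seed master seed; per-candidate seeds are derived from it.
#' @param maxit per-network BFGS iteration cap.
#' @param descriptors input descriptor names.
#' @return Object of class `ann_search`: list with `models` (retained
#'   `mlp_model`s, best first) and `table` (architecture + train/validation
#'   SOS per retained network).
#' @export
ann_search <- function(ds, n_train = 40, n_retain = 5, hidden_range = 3:13,
                       seed = 1L, maxit = 200,
                       descriptors = modeling_descriptors()) {
  if (n_retain > n_train) stop("n_retain must not exceed n_train")
  if (!any(ds$split == "validation")) {
    stop("dataset needs a validation split (see random_split)")
  }
  vm <- split_matrix(ds, split = "validation", descriptors = descriptors)
  set.seed(seed)
  hiddens <- sample(hidden_range, n_train, replace = TRUE)
  act_h <- sample(mlp_activations, n_train, replace = TRUE)
  # exponential output on an unbounded-above response destabilizes training
  # rarely but is part of the menu; keep all four for fidelity
  act_o <- sample(mlp_activations, n_train, replace = TRUE)
  fits <- vector("list", n_train)
  val_sos <- rep(Inf, n_train)
  for (i in seq_len(n_train)) {
    m <- tryCatch(
      train_mlp(ds,
        hidden = hiddens[i], activations = c(act_h[i], act_o[i]),
        seed = derive_seed(seed, i), maxit = maxit, descriptors = descriptors
      ),
      error = function(e) NULL
    )
    if (is.null(m)) next
    s <- mlp_sos(m, vm$X, vm$y)
    if (is.finite(s)) {
      fits[[i]] <- m
      val_sos[i] <- s
    }
  }
  ok <- which(is.finite(val_sos))
  if (!length(ok)) stop("all network trainings failed")
  ord <- ok[order(val_sos[ok])]
  keep <- utils::head(ord, n_retain)
  tab <- data.frame(
    rank = seq_along(keep),
    hidden = hiddens[keep],
    act_hidden = act_h[keep],
    act_output = act_o[keep],
    sos_train = vapply(fits[keep], function(m) m$sos_train, numeric(1)),
    sos_validation = val_sos[keep],
    stringsAsFactors = FALSE
  )
  structure(list(models = fits[keep], table = tab, seed = as.integer(seed)),
    class = "ann_search"
  )
}

#' @export
print.ann_search <- function(x, ...) {
  cat("<ann_search> retained", nrow(x$table), "networks (validation SOS ascending)\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Global sensitivity analysis of MLP inputs
#'
#' Scores each input descriptor by the error ratio
#' SOS(model without that input) / SOS(full model) on the training records.
#' The default ablation replaces the input with its training mean without
#' retraining (the error-ratio convention of desktop ANN suites); an input
#' with all outgoing weights zero then scores exactly 1. `method = "retrain"`
#' instead refits the network without the input (same architecture and seed)
#' and compares training errors. Scores at or below 1 mark inputs the
#' network does not need.
#'
#' @param model an `mlp_model`.
#' @param ds the [compound_dataset()] it was trained on.
#' @param split records to evaluate over (default "train").
#' @param method `"mean_substitution"` (default) or `"retrain"`.
#' @return Object of class `gsa_report`: data.frame (descriptor, score, rank)
#'   sorted by descending score; attribute `degenerate` flags a zero full-model
#'   SOS.
#' @export
gsa <- function(model, ds, split = "train",
                method = c("mean_substitution", "retrain")) {
  method <- match.arg(method)
  sm <- split_matrix(ds, split = split, descriptors = model$descriptors)
  X <- sm$X
  y <- sm$y
  sos_full <- mlp_sos(model, X, y)
  degenerate <- sos_full == 0
  score <- vapply(seq_along(model$descriptors), function(j) {
    sos_j <- if (method == "mean_substitution") {
      Xj <- X
      Xj[, j] <- mean(X[, j])
      mlp_sos(model, Xj, y)
    } else {
      reduced <- train_mlp(ds,
        hidden = model$hidden,
        activations = unname(model$activations), seed = model$seed,
        split = split, descriptors = model$descriptors[-j]
      )
      reduced$sos_train
    }
    if (degenerate) {
      if (sos_j > 0) Inf else 1
    } else {
      sos_j / sos_full
    }
  }, numeric(1))
  rep_ <- data.frame(
    descriptor = model$descriptors,
    score = score,
    stringsAsFactors = FALSE
  )
  rep_ <- rep_[order(-rep_$score), , drop = FALSE]
  rep_$rank <- seq_len(nrow(rep_))
  rownames(rep_) <- NULL
  structure(rep_,
    class = c("gsa_report", "data.frame"),
    degenerate = degenerate
  )
}

#' @export
print.gsa_report <- function(x, ...) {
  cat("<gsa_report> input importance (error ratio; <= 1 means dispensable)\n")
  if (attr(x, "degenerate")) cat("  [degenerate: full-model SOS is zero]\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
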