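# End-to-end orchestration: screen -> fit MLR/ANN/SVR -> predict the query
# compounds -> aggregate consensus means -> applicability-domain check ->
# atomic contributions, with per-stage derived seeds, a run manifest, and
# report tables mirroring the published layout.

pipeline_stages <- c("screen", "mlr", "ann", "svr", "ad", "atom")

#' Build and validate a pipeline configuration
#'
#' A flat list of run settings. `reference` and `query` may be
#' [compound_dataset()] objects or CSV paths; a NULL reference requests the
#' synthetic generator. A single global seed deterministically derives every
#' stage's seed.
#'
#' @param reference reference dataset, CSV path, or NULL (synthetic).
#' @param query query dataset or CSV path; default: the packaged sunscreen
#'   descriptor table.
#' @param query_smiles optional data.frame (id, smiles) for the atomic
#'   contribution stage; default: the packaged sunscreen SMILES.
#' @param stages stages to run, a subset of
#'   screen/mlr/ann/svr/ad/atom (empty vector = predictions only).
#' @param seed global integer seed.
#' @param outdir output directory for report tables (NULL = no files).
#' @param n_reference,sigma synthetic-generator size and noise SD.
#' @param mlr,ann,svr,ad,atom per-stage hyperparameter lists; see defaults.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference = NULL, query = NULL, query_smiles = NULL,
                            stages = pipeline_stages, seed = 1L, outdir = NULL,
                            n_reference = 121, sigma = 0.59,
                            mlr = list(), ann = list(), svr = list(),
                            ad = list(), atom = list()) {
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (length(seed) != 1 || is.na(seed)) stop("seed must be a single integer")
  merge_defaults <- function(given, defaults) {
    extra <- setdiff(names(given), names(defaults))
    if (length(extra)) stop("unknown option(s): ", paste(extra, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    reference = reference, query = query, query_smiles = query_smiles,
    stages = stages, seed = as.integer(seed), outdir = outdir,
    n_reference = n_reference, sigma = sigma,
    split = c(train = 100 / 121, test = 21 / 121),
    mlr = merge_defaults(mlr, list(kmin = 2, kmax = 6, tolerance = 0.1)),
    ann = merge_defaults(ann, list(
      n_train = 40, n_retain = 5, hidden_range = 3:13,
      fractions = c(train = 0.70, test = 0.15, validation = 0.15)
    )),
    svr = merge_defaults(svr, list(
      kernels = svr_kernels, C_grid = c(0.1, 1, 10),
      epsilon_grid = c(0.05, 0.1, 0.2)
    )),
    ad = merge_defaults(ad, list(coverage = 0.99)),
    atom = merge_defaults(atom, list(
      n_components = 6, folds = 5, train_fraction = 0.75
    ))
  )
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Only scalar settings are serialized; dataset objects must be referenced
#' by path.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  for (f in c("reference", "query")) {
    if (!is.null(ser[[f]]) && !is.character(ser[[f]])) {
      stop(f, " must be a path (or NULL) to serialize the config")
    }
  }
  ser$query_smiles <- NULL
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw), names(formals(pipeline_config)))])
}

#' Classify predicted inhibition strength
#'
#' Potency bands on the pIC50 scale: below 2 "weak"; 2 to 4 "moderate"
#' (donepezil-class reference drugs sit near 5); 4 to 5
#' "comparable-to-reference-drugs"; 5 to 6 inclusive "strong"; above 6
#' "very-high (check AD)" — predictions that far above the reference range
#' warrant an applicability-domain check. Bands are closed on the left, open
#' on the right, except the strong band which is closed on both sides.
#'
#' @param pic50 finite numeric vector.
#' @return character vector of band labels.
#' @export
classify_inhibition_strength <- function(pic50) {
  if (any(!is.finite(pic50))) stop("pic50 must be finite")
  vapply(pic50, function(p) {
    if (p < 2) "weak"
    else if (p < 4) "moderate"
    else if (p < 5) "comparable-to-reference-drugs"
    else if (p <= 6) "strong"
    else "very-high (check AD)"
  }, character(1))
}

load_dataset_arg <- function(x, default_fn = NULL) {
  if (is.null(x) && !is.null(default_fn)) return(default_fn())
  if (is.character(x)) return(read_compound_table(x))
  x
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order over a reference dataset
#' (real or synthetic) and a query table. The frozen published linear
#' equation always provides the query MLR predictions; enabled fitting
#' stages add refit statistics (MLR), retained networks and their
#' sensitivity ranking (ANN), kernel comparison and predictions (SVR), the
#' applicability-domain verdicts (AD) and fingerprint atomic contributions
#' (atom). A failed stage is recorded and its dependents skipped; unrelated
#' stages still run.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `report_bundle`: tables `predictions`,
#'   `correlation`, `tolerance`, `fit_stats`, `ann_table`, `gsa`,
#'   `svr_metrics`, `ad_verdicts`, `atom_contributions`, plus `errors`,
#'   `manifest`, and the fitted objects under `models`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  errors <- list()
  manifest <- list(seed = config$seed, stages = config$stages)
  note_error <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
  }
  stage_on <- function(s) s %in% config$stages
  # inputs ------------------------------------------------------------------
  ref_seed <- derive_seed(config$seed, 1)
  reference <- load_dataset_arg(config$reference)
  if (is.null(reference)) {
    reference <- synthetic_reference(
      n = config$n_reference,
      sigma = config$sigma, seed = ref_seed
    )
    manifest$reference <- sprintf("synthetic (n=%d, seed=%d)", config$n_reference, ref_seed)
  } else {
    manifest$reference <- sprintf("supplied (n=%d)", nrow(reference))
  }
  query <- load_dataset_arg(config$query, sunscreen_descriptors)
  query_smiles <- config$query_smiles
  if (is.null(query_smiles)) {
    query_smiles <- tryCatch(sunscreen_smiles(), error = function(e) NULL)
  }
  models <- list(published = published_mlr())
  bundle <- list()
  # always: frozen-equation predictions for the query -----------------------
  preds <- data.frame(id = query$id, stringsAsFactors = FALSE)
  preds <- cbind(preds, as.data.frame(query)[, intersect(
    modeling_descriptors(),
    names(query)
  ), drop = FALSE])
  preds$MLR <- unname(predict(models$published, query))
  # screen -------------------------------------------------------------------
  if (stage_on("screen")) {
    tryCatch({
      vars <- c(modeling_descriptors(), if (any(!is.na(reference$pic50))) "pic50")
      bundle$correlation <- correlation_matrix(reference, vars = vars)
      bundle$tolerance <- screen_subset(reference, modeling_descriptors(),
        threshold = config$mlr$tolerance
      )
    }, error = function(e) note_error("screen", e))
  }
  # shared train/test split for MLR and SVR ---------------------------------
  split_seed <- derive_seed(config$seed, 2)
  ref_tt <- random_split(reference, fractions = config$split, seed = split_seed)
  manifest$split_seed <- split_seed
  # mlr ----------------------------------------------------------------------
  if (stage_on("mlr")) {
    tryCatch({
      search <- best_subset_search(ref_tt,
        pool = modeling_descriptors(),
        kmin = config$mlr$kmin, kmax = config$mlr$kmax,
        tolerance_threshold = config$mlr$tolerance
      )
      best <- search$models[[1]]
      best$stats$rmse_pred <- evaluate_test(best, ref_tt, split = "test")
      models$mlr_refit <- best
      models$subset_search <- search
      st <- best$stats
      bundle$fit_stats <- data.frame(
        model = c("MLR published", "MLR refit (synthetic reference)"),
        subset = c(
          paste(models$published$descriptors, collapse = "+"),
          paste(best$descriptors, collapse = "+")
        ),
        n = c(models$published$stats$n, st$n),
        r2 = c(models$published$stats$r2, st$r2),
        r2_adj = c(models$published$stats$r2_adj, st$r2_adj),
        q2_loo = c(models$published$stats$q2_loo, st$q2_loo),
        f_stat = c(models$published$stats$f_stat, st$f_stat),
        rmse_pred = c(models$published$stats$rmse_pred, st$rmse_pred),
        stringsAsFactors = FALSE
      )
    }, error = function(e) note_error("mlr", e))
  }
  # ann ----------------------------------------------------------------------
  if (stage_on("ann")) {
    tryCatch({
      ann_seed <- derive_seed(config$seed, 3)
      ref_ann <- random_split(reference,
        fractions = config$ann$fractions,
        seed = ann_seed
      )
      search <- ann_search(ref_ann,
        n_train = config$ann$n_train, n_retain = config$ann$n_retain,
        hidden_range = config$ann$hidden_range, seed = ann_seed
      )
      models$ann <- search
      manifest$ann_seed <- ann_seed
      bundle$ann_table <- search$table
      for (i in seq_along(search$models)) {
        if (i > 5) break
        preds[[sprintf("ANN%d", i)]] <- unname(predict(search$models[[i]], query))
      }
      bundle$gsa <- gsa(search$models[[1]], ref_ann)
    }, error = function(e) note_error("ann", e))
  }
  # svr ----------------------------------------------------------------------
  if (stage_on("svr")) {
    tryCatch({
      sel <- kernel_selection(ref_tt,
        kernels = config$svr$kernels,
        C_grid = config$svr$C_grid, epsilon_grid = config$svr$epsilon_grid
      )
      models$svr <- sel$models[[1]]
      bundle$svr_metrics <- sel$table
      preds$SVR <- unname(predict(sel$models[[1]], query))
    }, error = function(e) note_error("svr", e))
  }
  # consensus means ----------------------------------------------------------
  tryCatch({
    if (all(c("ANN1", "SVR") %in% names(preds))) {
      preds <- aggregate_means(preds)
      preds$strength <- classify_inhibition_strength(preds$Mean1)
    } else {
      preds$strength <- classify_inhibition_strength(preds$MLR)
    }
  }, error = function(e) note_error("means", e))
  bundle$predictions <- preds
  # applicability domain -----------------------------------------------------
  if (stage_on("ad")) {
    tryCatch({
      models$ad <- fit_ad(reference, coverage = config$ad$coverage)
      bundle$ad_verdicts <- ad_classify(models$ad, query)
    }, error = function(e) note_error("ad", e))
  }
  # atomic contributions -----------------------------------------------------
  if (stage_on("atom")) {
    tryCatch({
      if (!"smiles" %in% names(reference) || all(is.na(reference$smiles))) {
        stop("atom stage needs SMILES on the reference dataset")
      }
      ok <- !is.na(reference$smiles) & !is.na(reference$pic50)
      atom_seed <- derive_seed(config$seed, 4)
      models$fp_pls <- train_fingerprint_pls(
        reference$smiles[ok], reference$pic50[ok],
        n_components = config$atom$n_components, folds = config$atom$folds,
        train_fraction = config$atom$train_fraction, seed = atom_seed
      )
      manifest$atom_seed <- atom_seed
      if (!is.null(query_smiles)) {
        maps <- lapply(seq_len(nrow(query_smiles)), function(i) {
          m <- atom_contributions(models$fp_pls, query_smiles$smiles[i],
            id = query_smiles$id[i]
          )
          cbind(id = query_smiles$id[i], as.data.frame(m))
        })
        bundle$atom_contributions <- do.call(rbind, maps)
      }
    }, error = function(e) note_error("atom", e))
  }
  bundle$errors <- errors
  manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
  bundle$manifest <- manifest
  bundle$models <- models
  class(bundle) <- "report_bundle"
  if (!is.null(config$outdir)) write_report(bundle, config$outdir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  tables <- setdiff(names(x), c("errors", "manifest", "models"))
  cat("<report_bundle> tables:", paste(tables, collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (s in names(x$errors)) cat("  ", s, ": ", x$errors[[s]], "\n", sep = "")
  }
  invisible(x)
}

#' Write report tables to a directory
#'
#' One CSV per produced table (full precision), a YAML run manifest, and a
#' short markdown summary with 2-decimal display values.
#'
#' @param bundle a `report_bundle`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(outdir, paste0(name, ".csv")),
      row.names = FALSE
    )
  }
  if (!is.null(bundle$predictions)) wr(bundle$predictions, "predictions")
  if (!is.null(bundle$correlation)) {
    m <- bundle$correlation$r
    wr(cbind(variable = rownames(m), as.data.frame(m)), "correlation_matrix")
  }
  if (!is.null(bundle$tolerance)) wr(bundle$tolerance, "tolerance_report")
  if (!is.null(bundle$fit_stats)) wr(bundle$fit_stats, "fit_stats")
  if (!is.null(bundle$ann_table)) wr(bundle$ann_table, "ann_networks")
  if (!is.null(bundle$gsa)) wr(bundle$gsa, "gsa")
  if (!is.null(bundle$svr_metrics)) wr(bundle$svr_metrics, "svr_metrics")
  if (!is.null(bundle$ad_verdicts)) wr(bundle$ad_verdicts, "ad_verdicts")
  if (!is.null(bundle$atom_contributions)) wr(bundle$atom_contributions, "atom_contributions")
  yaml::write_yaml(bundle$manifest, file.path(outdir, "run_manifest.yaml"))
  md <- c(
    "# BChE inhibition pipeline report", "",
    sprintf("Seed: %d. Stages: %s.", bundle$manifest$seed,
            paste(bundle$manifest$stages, collapse = ", ")),
    sprintf("Reference: %s.", bundle$manifest$reference), ""
  )
  if (!is.null(bundle$predictions)) {
    p <- bundle$predictions
    num <- vapply(p, is.numeric, logical(1))
    p[num] <- lapply(p[num], round_half_up, digits = 2)
    md <- c(md, "## Predicted pIC50", "", knit_table(p), "")
  }
  if (length(bundle$errors)) {
    md <- c(md, "## Stage errors", "", vapply(
      names(bundle$errors),
      function(s) sprintf("- %s: %s", s, bundle$errors[[s]]), character(1)
    ))
  }
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}

# minimal markdown table writer
knit_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
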