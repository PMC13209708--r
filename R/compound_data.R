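#' Canonical modeling descriptors
#'
#' The six ADMET-type descriptors used by every model stage, in the canonical
#' order shared by all engines: rotatable-bond count (`nRot`), flexibility
#' (`Flex` = nRot/nRig), fraction of sp3 carbons (`Fsp3`), octanol/water
#' distribution coefficient at pH 7.4 (`logD`), log Caco-2 permeability
#' (`caco2`, log10 cm/s) and plasma protein binding (`PPB`, percent).
#'
#' @return Character vector of the six descriptor names in canonical order.
#' @export
modeling_descriptors <- function() {
  c("nRot", "Flex", "Fsp3", "logD", "caco2", "PPB")
}

#' Descriptor schema
#'
#' An ordered descriptor vocabulary with unit annotations. The six modeling
#' descriptors are always present, in canonical order, at the head of the
#' schema; further descriptors (MW, TPSA, nHA, ...) may be appended.
#'
#' @param extra character vector of additional descriptor names.
#' @param extra_units named character vector of units for `extra` ("" if
#'   dimensionless).
#' @return An object of class `descriptor_schema` with elements `names` and
#'   `units`.
#' @export
descriptor_schema <- function(extra = character(), extra_units = NULL) {
  core <- modeling_descriptors()
  units <- c(
    nRot = "", Flex = "", Fsp3 = "",
    logD = "log10(mol/L-octanol vs water)",
    caco2 = "log10(cm/s)", PPB = "%"
  )
  if (length(extra)) {
    eu <- rep("", length(extra))
    names(eu) <- extra
    if (!is.null(extra_units)) eu[names(extra_units)] <- extra_units
    units <- c(units, eu)
  }
  nm <- names(units)
  if (anyDuplicated(nm)) stop("descriptor names must be unique")
  structure(list(names = nm, units = units), class = "descriptor_schema")
}

#' Build a compound dataset
#'
#' A compound dataset is a data.frame with one row per molecule carrying an
#' `id`, optional `smiles`, descriptor columns, optional `ic50_nM` and
#' `pic50`, and a `split` label in \{train, test, validation, unassigned\}.
#' Rows missing any modeling descriptor are retained but marked incomplete
#' and excluded from model stages.
#'
#' @param df data.frame with at least an `id` column.
#' @param schema a [descriptor_schema()].
#' @param seed integer recorded with the dataset (NA if none).
#' @return data.frame of class `compound_dataset` with attributes `schema`
#'   and `seed`, and columns `split` and `complete` filled in.
#' @export
compound_dataset <- function(df, schema = descriptor_schema(), seed = NA_integer_) {
  if (!"id" %in% names(df)) stop("compound table must have an 'id' column")
  df$id <- as.character(df$id)
  core <- modeling_descriptors()
  for (d in intersect(schema$names, names(df))) {
    if (!is.numeric(df[[d]])) stop("descriptor column '", d, "' is not numeric")
  }
  if (!"split" %in% names(df)) df$split <- rep("unassigned", nrow(df))
  bad <- !df$split %in% c("train", "test", "validation", "unassigned")
  if (any(bad)) stop("invalid split label(s): ", paste(unique(df$split[bad]), collapse = ", "))
  present <- intersect(core, names(df))
  if (length(present) == 0 && nrow(df) > 0) {
    df$complete <- FALSE
  } else if (nrow(df) == 0) {
    df$complete <- logical(0)
  } else {
    has_all <- length(present) == length(core)
    df$complete <- if (has_all) {
      stats::complete.cases(df[, core, drop = FALSE])
    } else {
      rep(FALSE, nrow(df))
    }
  }
  df$split[!df$complete] <- "unassigned"
  # derive pic50 from ic50_nM when absent; check consistency when both given
  if ("ic50_nM" %in% names(df)) {
    have <- !is.na(df$ic50_nM)
    if (any(have & df$ic50_nM <= 0)) stop("ic50_nM must be positive")
    derived <- rep(NA_real_, nrow(df))
    derived[have] <- to_pic50(df$ic50_nM[have])
    if (!"pic50" %in% names(df)) {
      df$pic50 <- derived
    } else {
      both <- have & !is.na(df$pic50)
      if (any(both) && max(abs(df$pic50[both] - derived[both])) > 1e-9) {
        stop("pic50 inconsistent with ic50_nM (|diff| > 1e-9)")
      }
      df$pic50[have & is.na(df$pic50)] <- derived[have & is.na(df$pic50)]
    }
  }
  # Flex consistency when nRot and nRig are both carried
  if (all(c("nRot", "nRig", "Flex") %in% names(df))) {
    ok <- stats::complete.cases(df[, c("nRot", "nRig", "Flex")])
    dev <- abs(df$Flex[ok] - df$nRot[ok] / df$nRig[ok])
    if (any(dev > 0.001)) stop("Flex deviates from nRot/nRig by more than 0.001")
  }
  structure(df,
    class = c("compound_dataset", "data.frame"),
    schema = schema, seed = seed
  )
}

#' @export
print.compound_dataset <- function(x, ...) {
  cat("<compound_dataset> ", nrow(x), " compounds (",
    sum(x$complete), " complete); splits: ",
    paste(sprintf("%s=%d", names(table(x$split)), table(x$split)), collapse = ", "),
    "\n",
    sep = ""
  )
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

#' Read a compound table from CSV
#'
#' Reads a UTF-8 comma-separated table with a header row. Unicode minus signs
#' (U+2212), as printed in typeset tables, are normalized to ASCII before
#' numeric parsing. Rows missing modeling descriptors are retained but
#' flagged incomplete/unassigned.
#'
#' @param path CSV file path.
#' @param schema a [descriptor_schema()].
#' @return A [compound_dataset()].
#' @export
read_compound_table <- function(path, schema = descriptor_schema()) {
  raw <- utils::read.csv(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = "character", fileEncoding = "UTF-8"
  )
  if (!"id" %in% names(raw)) stop("compound table must have an 'id' column: ", path)
  numeric_cols <- c(intersect(schema$names, names(raw)),
                    intersect(c("ic50_nM", "pic50"), names(raw)))
  for (col in numeric_cols) {
    txt <- trimws(gsub("−", "-", raw[[col]]))
    txt[txt == ""] <- NA
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(val))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value '%s' in column '%s', row %d of %s",
        raw[[col]][bad[1]], col, bad[1], basename(path)
      ))
    }
    raw[[col]] <- val
  }
  compound_dataset(raw, schema = schema)
}

#' Write a compound table to CSV
#'
#' Numeric columns are written with 17 significant digits so a write/read
#' round trip reproduces every double bit-exactly.
#'
#' @param ds a [compound_dataset()] (or plain data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(ds, path) {
  df <- as.data.frame(ds)
  df$complete <- NULL
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      txt <- sprintf("%.17g", df[[col]])
      txt[is.na(df[[col]])] <- ""
      df[[col]] <- txt
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert IC50 in nanomolar to pIC50
#'
#' pIC50 = -log10(IC50 in mol/L); for an input in nM this is
#' `-log10(ic50_nM) + 9`. The molar convention matches the potency scale on
#' which donepezil and rivastigmine score 5.26 and 5.5.
#'
#' @param ic50_nM positive numeric vector, IC50 in nanomolar.
#' @return numeric vector of pIC50 values.
#' @export
to_pic50 <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("ic50_nM must be positive and finite")
  }
  -log10(ic50_nM) + 9
}

#' Randomly assign train/test/validation splits
#'
#' Labels are assigned by a seeded shuffle. Each non-train label receives
#' `round(fraction * n)` records; the remainder goes to `train` (or, when no
#' train fraction is requested, to the first listed label), so counts are
#' deterministic and independent of record order.
#'
#' @param ds a [compound_dataset()].
#' @param fractions named numeric vector of proportions summing to 1,
#'   names among train/test/validation.
#' @param seed integer RNG seed.
#' @param complete_only logical; split only complete records (default TRUE),
#'   leaving incomplete ones unassigned.
#' @return the dataset with `split` reassigned and `seed` recorded.
#' @export
random_split <- function(ds, fractions = c(train = 100 / 121, test = 21 / 121),
                         seed = 1L, complete_only = TRUE) {
  idx <- if (complete_only) which(ds$complete) else seq_len(nrow(ds))
  n <- length(idx)
  if (n == 0) stop("no records to split")
  if (abs(sum(fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (!all(names(fractions) %in% c("train", "test", "validation"))) {
    stop("split names must be among train/test/validation")
  }
  remainder_label <- if ("train" %in% names(fractions)) "train" else names(fractions)[1]
  counts <- round(fractions * n)
  counts[remainder_label] <- counts[remainder_label] + (n - sum(counts))
  if (any(counts < 0)) stop("split fractions leave a negative count")
  set.seed(seed)
  perm <- sample.int(n)
  labels <- rep(names(counts), counts)
  ds$split <- "unassigned"
  ds$split[idx[perm]] <- labels
  attr(ds, "seed") <- as.integer(seed)
  ds
}

#' Extract the rows of one split as a plain matrix/response
#' @param ds a [compound_dataset()].
#' @param split split label(s) to keep; NULL keeps all complete rows.
#' @param descriptors descriptor names (default: the six modeling ones).
#' @return list with `X` (numeric matrix), `y` (pic50 or NULL), `id`.
#' @keywords internal
split_matrix <- function(ds, split = NULL, descriptors = modeling_descriptors()) {
  keep <- ds$complete
  if (!is.null(split)) keep <- keep & ds$split %in% split
  miss <- setdiff(descriptors, names(ds))
  if (length(miss)) stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(ds)[keep, descriptors, drop = FALSE])
  storage.mode(X) <- "double"
  y <- if ("pic50" %in% names(ds)) ds$pic50[keep] else NULL
  list(X = X, y = y, id = ds$id[keep])
}

#' Packaged sunscreen descriptor table
#'
#' The 16 organic UV filters with their printed values of the six modeling
#' descriptors, as shipped in `inst/extdata/sunscreen_descriptors.csv`.
#'
#' @return A [compound_dataset()] with 16 records.
#' @export
sunscreen_descriptors <- function() {
  path <- system.file("extdata", "sunscreen_descriptors.csv",
    package = "bcheqsar", mustWork = TRUE
  )
  read_compound_table(path)
}

#' Published model predictions for the sunscreens
#'
#' The published per-model pIC50 predictions (MLR, ANN1, SVR and the two mean
#' aggregations) for the 16 sunscreens, used as reference inputs for
#' aggregation checks.
#'
#' @return data.frame with columns id, MLR, ANN1, SVR, Mean1, Mean2.
#' @export
sunscreen_published_predictions <- function() {
  path <- system.file("extdata", "sunscreen_published_predictions.csv",
    package = "bcheqsar", mustWork = TRUE
  )
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}

#' SMILES structures of the sunscreens
#'
#' Public structures of the 16 UV filters as SMILES strings, for the
#' atomic-contribution stage.
#'
#' @return data.frame with columns id, smiles.
#' @export
sunscreen_smiles <- function() {
  path <- system.file("extdata", "sunscreen_smiles.csv",
    package = "bcheqsar", mustWork = TRUE
  )
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
}
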