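# Internal helpers shared across modules.

# Evaluate `code` under a given RNG seed without disturbing the caller's
# random-number stream.
with_preserved_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "tlcombat_error_seed")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Partition a samples-by-columns table into the pieces the harmonization
# model works with. Feature columns default to every numeric column not
# claimed by id/batch/covariates/outcome.
partition_table <- function(data, id, batch, covariates = NULL,
                            outcome = NULL, features = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "tlcombat_error_input")
  }
  data <- as_tibble(data)
  required <- c(id, batch, covariates, outcome)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "tlcombat_error_schema"
    )
  }
  sample_ids <- as.character(data[[id]])
  if (anyDuplicated(sample_ids) > 0L) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    abort(
      paste0("Duplicate sample id(s): ", paste(dup, collapse = ", ")),
      class = "tlcombat_error_schema"
    )
  }
  batch_labels <- as.character(data[[batch]])
  if (anyNA(batch_labels)) {
    abort("Batch labels must not be missing.", class = "tlcombat_error_schema")
  }

  if (is.null(features)) {
    reserved <- c(id, batch, covariates, outcome)
    candidates <- setdiff(names(data), reserved)
    features <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  } else {
    missing_feat <- setdiff(features, names(data))
    if (length(missing_feat) > 0L) {
      abort(
        paste0("Feature column(s) not found: ", paste(missing_feat, collapse = ", ")),
        class = "tlcombat_error_schema"
      )
    }
  }
  if (length(features) < 1L) {
    abort("No feature columns found.", class = "tlcombat_error_schema")
  }
  non_num <- features[!vapply(data[features], is.numeric, logical(1))]
  if (length(non_num) > 0L) {
    abort(
      paste0("Non-numeric feature column(s): ", paste(non_num, collapse = ", ")),
      class = "tlcombat_error_schema"
    )
  }
  Y <- as.matrix(data[features])
  if (!all(is.finite(Y))) {
    bad <- which(!is.finite(Y), arr.ind = TRUE)[1L, , drop = TRUE]
    abort(
      paste0(
        "Non-finite feature value at row ", bad[["row"]],
        ", column '", features[bad[["col"]]], "'. Missing values are not supported."
      ),
      class = "tlcombat_error_values"
    )
  }
  rownames(Y) <- sample_ids

  list(
    Y = Y,
    sample_ids = sample_ids,
    batch = batch_labels,
    covariate_data = if (length(covariates) > 0L) data[covariates] else NULL,
    outcome = if (!is.null(outcome)) data[[outcome]] else NULL,
    feature_names = features
  )
}

# Validate batch sizes against the model's floor (hard minimum 2, advisory 5).
check_batch_sizes <- function(batch_labels, registry = NULL) {
  registry <- registry %||% unique(batch_labels)
  counts <- table(factor(batch_labels, levels = registry))
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    abort(
      paste0(
        "Every batch needs at least 2 samples; offending batch(es): ",
        paste(small, collapse = ", ")
      ),
      class = "tlcombat_error_batch_size"
    )
  }
  soft <- names(counts)[counts < 5L]
  if (length(soft) > 0L) {
    warn(
      paste0(
        "Batch(es) with fewer than 5 samples: ", paste(soft, collapse = ", "),
        ". Empirical-Bayes estimates may be unstable."
      ),
      class = "tlcombat_warning_small_batch"
    )
  }
  invisible(as.integer(counts))
}

# Column-wise population variance (denominator n) by group.
group_moments <- function(M, batch_factor) {
  levs <- levels(batch_factor)
  G <- ncol(M)
  means <- matrix(NA_real_, length(levs), G, dimnames = list(levs, colnames(M)))
  vars <- means
  for (b in levs) {
    rows <- M[batch_factor == b, , drop = FALSE]
    n_b <- nrow(rows)
    mu <- colMeans(rows)
    means[b, ] <- mu
    vars[b, ] <- colMeans(rows^2) - mu^2
  }
  vars[vars < 0] <- 0 # numerical floor
  list(mean = means, var = vars, n = as.integer(table(batch_factor)[levs]))
}
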