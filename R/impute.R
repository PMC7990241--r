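#' Imputation settings
#'
#' Controls missingness classification and the fill strategies. A metabolite
#' whose missing fraction reaches `mnar_group_threshold` within at least one
#' group is treated as missing-not-at-random (MNAR, typically values below a
#' detection limit) and filled by `mnar_method`; any other incomplete
#' metabolite is treated as missing-completely-at-random (MCAR) and filled by
#' `mcar_method`.
#'
#' @param mnar_method `"zero"` (default) or `"half_minimum"` (half the smallest
#'   observed value of that metabolite).
#' @param mcar_method `"random_forest"` (default), `"knn"`, `"mean"` or
#'   `"median"`.
#' @param knn_k Number of neighbours for `"knn"` (default 10).
#' @param rf_max_iter Maximum sweeps of the iterative random-forest imputer
#'   (default 10).
#' @param rf_n_trees Trees per random-forest regression (default 100).
#' @param mnar_group_threshold Within-group missing fraction at or above which
#'   a metabolite is classified MNAR (default 0.70).
#' @param seed Integer seed driving all stochastic methods; identical seed
#'   gives identical output.
#' @return A list of class `metabo_imputation_config`.
#' @export
imputation_config <- function(mnar_method = c("zero", "half_minimum"),
                              mcar_method = c("random_forest", "knn", "mean",
                                              "median"),
                              knn_k = 10L,
                              rf_max_iter = 10L,
                              rf_n_trees = 100L,
                              mnar_group_threshold = 0.70,
                              seed = 1L) {
  mnar_method <- match.arg(mnar_method)
  mcar_method <- match.arg(mcar_method)
  stopifnot(knn_k >= 1L, rf_max_iter >= 1L, rf_n_trees >= 1L,
            mnar_group_threshold > 0, mnar_group_threshold <= 1)
  structure(
    list(mnar_method = mnar_method, mcar_method = mcar_method,
         knn_k = as.integer(knn_k), rf_max_iter = as.integer(rf_max_iter),
         rf_n_trees = as.integer(rf_n_trees),
         mnar_group_threshold = mnar_group_threshold,
         seed = as.integer(seed)),
    class = "metabo_imputation_config"
  )
}

#' Classify each metabolite's missingness mechanism
#'
#' The label depends only on the pattern of missing cells and the group
#' structure, never on the observed values: `complete` when nothing is
#' missing, `MNAR` when the missing fraction within at least one group reaches
#' the threshold (consistent with censoring below a detection limit), `MCAR`
#' otherwise.
#'
#' @param data Measurement tibble/data frame (samples x metabolites, `NA` for
#'   missing).
#' @param groups Per-sample group label, length `nrow(data)`.
#' @param config An [imputation_config()].
#' @return A tibble of class `metabo_missingness`, one row per metabolite:
#'   `metabolite`, `label` (`complete`/`MNAR`/`MCAR`), `frac_missing_overall`,
#'   and one `frac_missing_<group>` column per group.
#' @export
classify_missingness <- function(data, groups,
                                 config = imputation_config()) {
  m <- as_measurement_matrix(data)
  if (length(groups) != nrow(m)) {
    abort_mp("groups length must equal the number of samples (rows)")
  }
  glev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  sizes <- vapply(glev, function(g) sum(groups == g), integer(1))
  if (any(sizes == 0L)) abort_mp("empty group (0 samples)")
  miss <- is.na(m)
  frac_by_group <- vapply(glev, function(g) {
    colMeans(miss[groups == g, , drop = FALSE])
  }, numeric(ncol(m)))
  frac_by_group <- matrix(frac_by_group, ncol = length(glev),
                          dimnames = list(NULL, glev))
  overall <- unname(colMeans(miss))
  label <- unname(ifelse(
    overall == 0, "complete",
    ifelse(apply(frac_by_group >= config$mnar_group_threshold, 1, any),
           "MNAR", "MCAR")
  ))
  out <- tibble::tibble(
    metabolite = colnames(m) %||% paste0("V", seq_len(ncol(m))),
    label = label,
    frac_missing_overall = overall
  )
  for (g in glev) out[[paste0("frac_missing_", g)]] <- frac_by_group[, g]
  class(out) <- c("metabo_missingness", class(out))
  out
}

#' Fill missing measurement cells
#'
#' MNAR metabolites are filled by the configured MNAR strategy (zero or
#' half-minimum), then MCAR metabolites by the configured MCAR strategy (mean,
#' median, k-nearest-neighbour, or iterative random forest). Observed cells
#' are never altered; a complete matrix is returned unchanged. A metabolite
#' with no observed value at all cannot support a value-dependent method and
#' falls back to zero fill with a warning.
#'
#' @param data Measurement tibble/data frame with `NA` for missing cells.
#' @param groups Per-sample group labels (used for classification).
#' @param classification Optional precomputed [classify_missingness()] result
#'   for the same missing mask; computed when `NULL`.
#' @param config An [imputation_config()].
#' @return A complete tibble with the same dimensions and column names.
#' @details `knn` averages the `knn_k` nearest donor samples, by Euclidean
#'   distance over mutually observed metabolites after dividing each column by
#'   its observed mean (so high-abundance metabolites do not dominate);
#'   donors must be observed at the target metabolite. `random_forest`
#'   initialises missing cells at column means and sweeps metabolite by
#'   metabolite, regressing each incomplete column on all others with a
#'   random forest, until the relative change of imputed values drops below
#'   1e-3 or `rf_max_iter` sweeps.
#' @export
impute_measurements <- function(data, groups, classification = NULL,
                                config = imputation_config()) {
  m <- as_measurement_matrix(data)
  if (is.null(classification)) {
    classification <- classify_missingness(data, groups, config)
  }
  stopifnot(nrow(classification) == ncol(m))
  if (!anyNA(m)) {
    return(tibble::as_tibble(as.data.frame(m), .name_repair = "minimal"))
  }

  # degenerate: nothing observed in a column -> zero fill regardless of label
  all_missing <- which(colSums(!is.na(m)) == 0L)
  if (length(all_missing)) {
    rlang::warn(paste0(length(all_missing),
                       " metabolite(s) have no observed values; zero-filled"))
    m[, all_missing][is.na(m[, all_missing])] <- 0
  }

  lab <- classification$label
  mnar_cols <- setdiff(which(lab == "MNAR"), all_missing)
  mcar_cols <- setdiff(which(lab == "MCAR"), all_missing)

  for (j in mnar_cols) {
    miss <- is.na(m[, j])
    if (!any(miss)) next
    fill <- switch(config$mnar_method,
      zero = 0,
      half_minimum = min(m[!miss, j]) / 2
    )
    m[miss, j] <- fill
  }

  if (length(mcar_cols)) {
    m <- switch(config$mcar_method,
      mean = fill_by_column(m, mcar_cols, function(x) mean(x, na.rm = TRUE)),
      median = fill_by_column(m, mcar_cols,
                              function(x) stats::median(x, na.rm = TRUE)),
      knn = impute_knn(m, mcar_cols, config$knn_k),
      random_forest = impute_rf(m, mcar_cols, config)
    )
  }
  tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
}

#' @noRd
fill_by_column <- function(m, cols, fun) {
  for (j in cols) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- fun(m[!miss, j])
  }
  m
}

# KNN over mean-scaled columns; donors must be observed at the target column
# and share at least one observed metabolite with the recipient.
#' @noRd
impute_knn <- function(m, cols, k) {
  col_means <- colMeans(m, na.rm = TRUE)
  scale_by <- ifelse(abs(col_means) > 0, abs(col_means), 1)
  sm <- sweep(m, 2, scale_by, "/")
  out <- m
  for (j in cols) {
    miss_rows <- which(is.na(m[, j]))
    for (i in miss_rows) {
      donors <- which(!is.na(m[, j]))
      d <- vapply(donors, function(dn) {
        both <- !is.na(sm[i, ]) & !is.na(sm[dn, ])
        if (!any(both)) return(NA_real_)
        sqrt(mean((sm[i, both] - sm[dn, both])^2))
      }, numeric(1))
      ok <- !is.na(d)
      if (!any(ok)) {
        out[i, j] <- mean(m[donors, j])
        next
      }
      donors <- donors[ok]
      d <- d[ok]
      nearest <- donors[order(d)][seq_len(min(k, length(donors)))]
      out[i, j] <- mean(m[nearest, j])
    }
  }
  out
}

# Iterative random-forest imputation: mean-fill start, per-column ranger
# regressions, stop when the relative change of the imputed cells < 1e-3.
#' @noRd
impute_rf <- function(m, cols, config) {
  miss_mask <- is.na(m)
  work <- fill_by_column(m, seq_len(ncol(m)), function(x) mean(x, na.rm = TRUE))
  target_cols <- cols[vapply(cols, function(j) any(miss_mask[, j]), logical(1))]
  if (!length(target_cols)) return(work)
  # most-complete columns first, as in iterative forest imputers
  target_cols <- target_cols[order(colSums(miss_mask[, target_cols,
                                                     drop = FALSE]))]
  colnames(work) <- paste0("c", seq_len(ncol(work)))
  prev <- work[miss_mask]
  for (iter in seq_len(config$rf_max_iter)) {
    for (j in target_cols) {
      obs <- !miss_mask[, j]
      df <- as.data.frame(work)
      fit <- ranger::ranger(
        x = df[obs, -j, drop = FALSE], y = work[obs, j],
        num.trees = config$rf_n_trees,
        seed = derive_seed(config$seed, iter * 1000L + j),
        num.threads = 1
      )
      pred <- stats::predict(fit, df[!obs, -j, drop = FALSE],
                             num.threads = 1)$predictions
      work[!obs, j] <- pred
    }
    cur <- work[miss_mask]
    denom <- sqrt(sum(cur^2))
    delta <- if (denom > 0) sqrt(sum((cur - prev)^2)) / denom else 0
    prev <- cur
    if (delta < 1e-3) break
  }
  colnames(work) <- colnames(m)
  work
}

`%||%` <- function(a, b) if (is.null(a)) b else a
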