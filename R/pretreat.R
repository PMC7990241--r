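#' Pretreatment settings: normalize, transform, scale
#'
#' Bundles the three pretreatment stages applied, in this fixed order, to a
#' complete measurement matrix before statistics.
#'
#' @param normalization `"none"`, `"minmax"` (per-metabolite affine map to
#'   \[0, 1\]), `"sum"` (each sample rescaled to a constant row sum),
#'   `"reference_sample"` (each sample rescaled so its row sum matches a
#'   chosen reference sample's) or `"weight_volume"` (each sample divided by
#'   its mass/volume).
#' @param sum_target Target row sum for `"sum"` (default 100).
#' @param reference_sample Sample ID of the reference (required for
#'   `"reference_sample"`).
#' @param mass_column Name of the sample-mass column in `sample_meta`
#'   (required for `"weight_volume"`).
#' @param transformation `"none"`, `"log10"`, `"log2"`, `"sqrt"` or `"cbrt"`.
#' @param pseudo_count_policy What to do when a log transform meets zeros:
#'   `"error"` (default, loud failure), `"half_min_positive"` (add half the
#'   smallest strictly positive matrix value first) or `"fixed"` (add
#'   `pseudo_count_value`). Negative values always raise for log and sqrt.
#' @param pseudo_count_value Offset used by the `"fixed"` policy.
#' @param scaling `"none"`, `"autoscale"`, `"pareto"`, `"range"`, `"vast"` or
#'   `"level"`; see [scale_measurements()] for formulas.
#' @return A list of class `metabo_treatment_config`.
#' @export
treatment_config <- function(normalization = c("none", "minmax", "sum",
                                               "reference_sample",
                                               "weight_volume"),
                             sum_target = 100,
                             reference_sample = NULL,
                             mass_column = NULL,
                             transformation = c("none", "log10", "log2",
                                                "sqrt", "cbrt"),
                             pseudo_count_policy = c("error",
                                                     "half_min_positive",
                                                     "fixed"),
                             pseudo_count_value = NULL,
                             scaling = c("none", "autoscale", "pareto",
                                         "range", "vast", "level")) {
  normalization <- match.arg(normalization)
  transformation <- match.arg(transformation)
  pseudo_count_policy <- match.arg(pseudo_count_policy)
  scaling <- match.arg(scaling)
  stopifnot(sum_target > 0)
  if (normalization == "reference_sample" && is.null(reference_sample)) {
    abort_mp("reference_sample normalization requires a reference sample ID",
             "metabopipe_config_error")
  }
  if (normalization == "weight_volume" && is.null(mass_column)) {
    abort_mp("weight_volume normalization requires mass_column",
             "metabopipe_config_error")
  }
  if (pseudo_count_policy == "fixed" &&
      (is.null(pseudo_count_value) || pseudo_count_value <= 0)) {
    abort_mp("fixed pseudo-count policy requires a positive pseudo_count_value",
             "metabopipe_config_error")
  }
  structure(
    list(normalization = normalization, sum_target = sum_target,
         reference_sample = reference_sample, mass_column = mass_column,
         transformation = transformation,
         pseudo_count_policy = pseudo_count_policy,
         pseudo_count_value = pseudo_count_value, scaling = scaling),
    class = "metabo_treatment_config"
  )
}

#' Sample-wise (or min-max) normalization
#'
#' `sum`: each row is multiplied by `sum_target / rowsum`, so every sample's
#' metabolite values add to the same constant (default 100). `reference_sample`:
#' the reference's row sum supplies the normalization factor, so every sample
#' ends at the reference's total. `weight_volume`: each row is divided by its
#' sample mass/volume. `minmax` maps each metabolite column affinely onto
#' \[0, 1\]. `none` is the identity.
#'
#' @param data Complete measurement tibble (samples x metabolites).
#' @param method Normalization method (see above).
#' @param sum_target Row-sum target for `"sum"`.
#' @param reference_sample Reference sample ID for `"reference_sample"`.
#' @param sample_meta Sample metadata tibble (needs `sample_id` for
#'   `"reference_sample"`, and the mass column for `"weight_volume"`).
#' @param mass_column Name of the mass/volume column in `sample_meta`.
#' @return Normalized tibble, same shape.
#' @export
normalize_measurements <- function(data,
                                   method = c("none", "minmax", "sum",
                                              "reference_sample",
                                              "weight_volume"),
                                   sum_target = 100,
                                   reference_sample = NULL,
                                   sample_meta = NULL,
                                   mass_column = NULL) {
  method <- match.arg(method)
  m <- as_measurement_matrix(data)
  if (anyNA(m)) abort_mp("normalize requires a complete matrix (impute first)")
  if (method == "none") return(tibble::as_tibble(data))
  if (method == "minmax") {
    rng <- apply(m, 2, range)
    span <- rng[2, ] - rng[1, ]
    if (any(span <= 0)) {
      abort_mp(paste0("minmax undefined for constant column '",
                      colnames(m)[which(span <= 0)[1]], "'"))
    }
    m <- sweep(sweep(m, 2, rng[1, ], "-"), 2, span, "/")
  } else if (method == "sum") {
    rs <- rowSums(m)
    if (any(rs <= 0)) abort_mp("sum normalization requires positive row sums")
    m <- m * (sum_target / rs)
  } else if (method == "reference_sample") {
    if (is.null(reference_sample) || is.null(sample_meta)) {
      abort_mp("reference_sample requires reference_sample and sample_meta",
               "metabopipe_config_error")
    }
    idx <- match(reference_sample, sample_meta$sample_id)
    if (is.na(idx)) {
      abort_mp(paste0("reference sample '", reference_sample, "' not found"),
               "metabopipe_config_error")
    }
    rs <- rowSums(m)
    if (any(rs <= 0)) abort_mp("reference normalization requires positive row sums")
    m <- m * (rs[idx] / rs)
  } else if (method == "weight_volume") {
    if (is.null(sample_meta) || is.null(mass_column) ||
        !mass_column %in% names(sample_meta)) {
      abort_mp("weight_volume requires mass_column present in sample_meta",
               "metabopipe_config_error")
    }
    mass <- as.numeric(sample_meta[[mass_column]])
    if (anyNA(mass) || any(mass <= 0)) {
      abort_mp("sample mass/volume values must all be positive")
    }
    m <- m / mass
  }
  tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
}

#' Element-wise variance-stabilising transformation
#'
#' Log transforms compress the dynamic range; roots are milder. Negative
#' values are invalid for log and sqrt and always raise. Zeros are fine for
#' sqrt; for log10/log2 they are handled per the pseudo-count policy: raise
#' (default), add half the smallest strictly positive matrix value, or add a
#' fixed offset.
#'
#' @inheritParams normalize_measurements
#' @param method `"none"`, `"log10"`, `"log2"`, `"sqrt"` or `"cbrt"`.
#' @param pseudo_count_policy,pseudo_count_value See [treatment_config()].
#' @return Transformed tibble, same shape.
#' @export
transform_measurements <- function(data,
                                   method = c("none", "log10", "log2",
                                              "sqrt", "cbrt"),
                                   pseudo_count_policy = c("error",
                                                           "half_min_positive",
                                                           "fixed"),
                                   pseudo_count_value = NULL) {
  method <- match.arg(method)
  pseudo_count_policy <- match.arg(pseudo_count_policy)
  m <- as_measurement_matrix(data)
  if (anyNA(m)) abort_mp("transform requires a complete matrix")
  if (method == "none") return(tibble::as_tibble(data))
  if (method %in% c("log10", "log2", "sqrt") && any(m < 0)) {
    abort_mp(paste0(method, " is undefined for negative values"))
  }
  if (method %in% c("log10", "log2") && any(m == 0)) {
    offset <- switch(pseudo_count_policy,
      error = abort_mp(paste0(method,
        " of zero: set a pseudo-count policy to offset zeros")),
      half_min_positive = {
        pos <- m[m > 0]
        if (!length(pos)) abort_mp("matrix has no positive value for offset")
        min(pos) / 2
      },
      fixed = {
        if (is.null(pseudo_count_value) || pseudo_count_value <= 0) {
          abort_mp("fixed pseudo-count policy requires a positive value",
                   "metabopipe_config_error")
        }
        pseudo_count_value
      }
    )
    m <- m + offset
  }
  m <- switch(method,
    log10 = log10(m),
    log2 = log2(m),
    sqrt = sqrt(m),
    cbrt = sign(m) * abs(m)^(1 / 3)
  )
  tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
}

#' Per-metabolite scaling
#'
#' With column mean `m`, sample standard deviation `s` (n-1 denominator) and
#' range r (max minus min): autoscale `(x-m)/s` (unit variance), Pareto
#' `(x-m)/sqrt(s)` (dampens but keeps magnitude structure), range `(x-m)/r`,
#' vast `((x-m)/s) * (m/s)` (up-weights stable metabolites by the inverse
#' coefficient of variation), level `(x-m)/m` (fold-like changes relative to
#' mean abundance).
#'
#' @inheritParams normalize_measurements
#' @param method One of `"none"`, `"autoscale"`, `"pareto"`, `"range"`,
#'   `"vast"`, `"level"`.
#' @return Scaled tibble, same shape. Violated preconditions (zero sd, zero
#'   range, zero mean, depending on method) raise an error naming the column.
#' @export
scale_measurements <- function(data,
                               method = c("none", "autoscale", "pareto",
                                          "range", "vast", "level")) {
  method <- match.arg(method)
  m <- as_measurement_matrix(data)
  if (anyNA(m)) abort_mp("scale requires a complete matrix")
  if (method == "none") return(tibble::as_tibble(data))
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  nm <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  need_sd <- method %in% c("autoscale", "pareto", "vast")
  if (need_sd && any(s <= 0)) {
    abort_mp(paste0(method, " undefined for zero-variance column '",
                    nm[which(s <= 0)[1]], "'"))
  }
  if (method %in% c("vast", "level") && any(mu == 0)) {
    abort_mp(paste0(method, " undefined for zero-mean column '",
                    nm[which(mu == 0)[1]], "'"))
  }
  centered <- sweep(m, 2, mu, "-")
  m <- switch(method,
    autoscale = sweep(centered, 2, s, "/"),
    pareto = sweep(centered, 2, sqrt(s), "/"),
    range = {
      r <- apply(m, 2, function(x) diff(range(x)))
      if (any(r <= 0)) {
        abort_mp(paste0("range scaling undefined for constant column '",
                        nm[which(r <= 0)[1]], "'"))
      }
      sweep(centered, 2, r, "/")
    },
    vast = sweep(sweep(centered, 2, s, "/"), 2, mu / s, "*"),
    level = sweep(centered, 2, mu, "/")
  )
  tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
}

#' Apply the full normalize -> transform -> scale pipeline
#'
#' Stage order is fixed; `none` stages are skipped.
#'
#' @param data Complete measurement tibble.
#' @param config A [treatment_config()].
#' @param sample_meta Sample metadata (needed for reference-sample and
#'   weight/volume normalization).
#' @return Treated tibble, same shape as the input.
#' @export
apply_treatment <- function(data, config = treatment_config(),
                            sample_meta = NULL) {
  stopifnot(inherits(config, "metabo_treatment_config"))
  out <- normalize_measurements(
    data, config$normalization, sum_target = config$sum_target,
    reference_sample = config$reference_sample, sample_meta = sample_meta,
    mass_column = config$mass_column
  )
  out <- transform_measurements(
    out, config$transformation,
    pseudo_count_policy = config$pseudo_count_policy,
    pseudo_count_value = config$pseudo_count_value
  )
  scale_measurements(out, config$scaling)
}
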