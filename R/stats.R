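#' Two-group Wilcoxon rank-sum test for one metabolite
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum p-value. The exact null
#' distribution is used when both groups have at most 25 samples and there are
#' no ties; otherwise the normal approximation with continuity and tie
#' correction is used.
#'
#' @param values Per-sample numeric vector.
#' @param groups Two-level label, same length.
#' @return Named list with `statistic` (rank-sum W) and `p_value`.
#' @export
wilcoxon_test <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) abort_mp("wilcoxon_test requires exactly 2 groups")
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (length(x) < 2L || length(y) < 2L) {
    abort_mp("each group needs at least 2 samples")
  }
  exact_ok <- length(x) <= 25L && length(y) <= 25L &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact_ok, correct = TRUE
  ))
  list(statistic = unname(ht$statistic), p_value = min(ht$p.value, 1))
}

#' Per-metabolite Wilcoxon rank-sum tests
#'
#' @param data Treated measurement tibble (samples x metabolites).
#' @param groups Two-level per-sample label.
#' @return Tibble with `metabolite`, `statistic`, `p_value`.
#' @export
wilcoxon_tests <- function(data, groups) {
  m <- as_measurement_matrix(data)
  res <- lapply(seq_len(ncol(m)), function(j) wilcoxon_test(m[, j], groups))
  tibble::tibble(
    metabolite = colnames(m) %||% paste0("V", seq_len(ncol(m))),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value")
  )
}

#' One-way ANOVA with Tukey HSD post-hoc for one metabolite
#'
#' Fixed-effects one-way ANOVA (via [stats::aov()]) followed by Tukey-Kramer
#' honestly-significant-difference p-values for every group pair, using the
#' studentized range distribution with the pooled within-group variance
#' (handles unequal group sizes).
#'
#' @param values Per-sample numeric vector.
#' @param groups Group label with k >= 2 levels, each with >= 2 samples.
#' @return List with `f_statistic`, `p_value`, `degenerate` (TRUE when the
#'   pooled within-group variance is zero, making p undefined) and `tukey`, a
#'   tibble (`group1`, `group2`, `diff`, `p_value`) for every unordered pair.
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))   # canonical order: invariant to sample order
  k <- length(lev)
  if (k < 2L) abort_mp("anova_tukey requires at least 2 groups")
  sizes <- vapply(lev, function(g) sum(groups == g), integer(1))
  if (any(sizes < 2L)) abort_mp("each group needs at least 2 samples")
  g <- factor(groups, levels = lev)
  fit <- stats::aov(values ~ g)
  sm <- summary(fit)[[1]]
  mse <- sm[["Mean Sq"]][2]
  df_err <- sm[["Df"]][2]
  pairs <- utils::combn(lev, 2)
  means <- vapply(lev, function(gg) mean(values[groups == gg]), numeric(1))
  # a pooled within-group variance at rounding-noise level is zero in substance
  if (!is.finite(mse) || mse <= 1e-12 * max(stats::var(values), 1e-300)) {
    # zero pooled variance: every group internally constant
    degenerate <- TRUE
    f_stat <- NA_real_
    p <- NA_real_
    tk_p <- rep(NA_real_, ncol(pairs))
  } else {
    degenerate <- FALSE
    f_stat <- sm[["F value"]][1]
    p <- sm[["Pr(>F)"]][1]
    tk_p <- vapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      se <- sqrt(mse / 2 * (1 / sizes[[a]] + 1 / sizes[[b]]))
      q <- abs(means[[a]] - means[[b]]) / se
      stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    }, numeric(1))
  }
  list(
    f_statistic = f_stat,
    p_value = p,
    degenerate = degenerate,
    tukey = tibble::tibble(
      group1 = pairs[1, ], group2 = pairs[2, ],
      diff = means[pairs[1, ]] - means[pairs[2, ]],
      p_value = tk_p
    )
  )
}

#' Per-metabolite ANOVA + Tukey tests
#'
#' @param data Treated measurement tibble.
#' @param groups Per-sample label with >= 2 levels.
#' @return Tibble with `metabolite`, `f_statistic`, `p_value`, `degenerate`
#'   and a nested `tukey` list-column of pairwise results.
#' @export
anova_tukey_tests <- function(data, groups) {
  m <- as_measurement_matrix(data)
  res <- lapply(seq_len(ncol(m)), function(j) anova_tukey(m[, j], groups))
  tibble::tibble(
    metabolite = colnames(m) %||% paste0("V", seq_len(ncol(m))),
    f_statistic = vapply(res, `[[`, numeric(1), "f_statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    tukey = lapply(res, `[[`, "tukey")
  )
}

#' Per-metabolite log2 fold changes between two groups
#'
#' Computed as `log2(mean_A / mean_B)` with arithmetic group means, intended
#' for normalized but untransformed data (log/scaling would distort the
#' ratio). Metabolites whose group mean is not strictly positive get
#' `log2_fc = NA` and `fc_defined = FALSE`.
#'
#' @param data Normalized (untransformed) measurement tibble.
#' @param groups Per-sample label.
#' @param pair Character vector `c(A, B)`: fold change of A over B.
#' @return Tibble with `metabolite`, `log2_fc`, `fc_defined`.
#' @export
fold_changes <- function(data, groups, pair) {
  stopifnot(length(pair) == 2L)
  groups <- as.character(groups)
  if (!all(pair %in% groups)) abort_mp("pair labels not found in groups")
  m <- as_measurement_matrix(data)
  ma <- unname(colMeans(m[groups == pair[1], , drop = FALSE]))
  mb <- unname(colMeans(m[groups == pair[2], , drop = FALSE]))
  ok <- ma > 0 & mb > 0
  lfc <- rep(NA_real_, length(ok))
  lfc[ok] <- log2(ma[ok] / mb[ok])
  tibble::tibble(
    metabolite = colnames(m) %||% paste0("V", seq_len(ncol(m))),
    log2_fc = lfc,
    fc_defined = ok
  )
}

#' Volcano selection: flag metabolites passing fold-change and p thresholds
#'
#' A metabolite is selected iff `|log2_fc| >= min_abs_log2_fc` and
#' `p <= max_p`. Rows with undefined fold change or p are never selected.
#'
#' @param data Tibble with fold-change and p-value columns (e.g. from
#'   [metabolite_stats()]).
#' @param min_abs_log2_fc Minimum absolute log2 fold change (default 1).
#' @param max_p Maximum p-value (default 0.05).
#' @param fc_col,p_col Column names (defaults `"log2_fc"`, `"p_value"`).
#' @return The input tibble with a logical `selected` column.
#' @export
volcano_select <- function(data, min_abs_log2_fc = 1, max_p = 0.05,
                           fc_col = "log2_fc", p_col = "p_value") {
  stopifnot(min_abs_log2_fc >= 0, max_p > 0, max_p <= 1)
  fc <- data[[fc_col]]
  p <- data[[p_col]]
  if (is.null(fc) || is.null(p)) abort_mp("fold-change / p-value column not found")
  sel <- !is.na(fc) & !is.na(p) & abs(fc) >= min_abs_log2_fc & p <= max_p
  dplyr::mutate(data, selected = sel)
}

#' Per-metabolite statistics table (tests + fold change + selection)
#'
#' The workhorse one-stop summary: for 2 groups the Wilcoxon rank-sum p-value
#' per metabolite; for more than 2 groups the one-way ANOVA with Tukey HSD
#' pairwise p-values, where the volcano p for the chosen `pair` is the Tukey
#' pairwise p. Log2 fold changes are computed for `pair` from `fc_data` (the
#' normalized, untransformed matrix) when supplied, else from `data`. A
#' Benjamini-Hochberg adjusted column is added for convenience; selection uses
#' the raw p.
#'
#' @param data Treated measurement tibble used for the tests.
#' @param groups Per-sample group label.
#' @param pair Group pair `c(A, B)` for fold change / pairwise p; defaults to
#'   the first two group labels in order of appearance.
#' @param fc_data Optional normalized untransformed matrix for fold changes.
#' @param min_abs_log2_fc,max_p Volcano thresholds (defaults 1 and 0.05).
#' @return A tibble of class `metabo_stats`, one row per metabolite:
#'   `metabolite`, `p_value` (test p used for the volcano), `anova_p` and
#'   nested `tukey` when k > 2, `log2_fc`, `fc_defined`, `p_adjusted` (BH) and
#'   `selected`.
#' @export
metabolite_stats <- function(data, groups, pair = NULL, fc_data = NULL,
                             min_abs_log2_fc = 1, max_p = 0.05) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) abort_mp("need at least 2 groups")
  if (is.null(pair)) pair <- lev[1:2]
  if (is.null(fc_data)) fc_data <- data
  fc <- fold_changes(fc_data, groups, pair)
  if (length(lev) == 2L) {
    tests <- wilcoxon_tests(data, groups)
    out <- dplyr::left_join(tests, fc, by = "metabolite")
  } else {
    tests <- anova_tukey_tests(data, groups)
    pair_p <- vapply(tests$tukey, function(tk) {
      hit <- (tk$group1 == pair[1] & tk$group2 == pair[2]) |
        (tk$group1 == pair[2] & tk$group2 == pair[1])
      if (any(hit)) tk$p_value[hit][1] else NA_real_
    }, numeric(1))
    out <- tests |>
      dplyr::rename(anova_p = "p_value") |>
      dplyr::mutate(p_value = pair_p) |>
      dplyr::left_join(fc, by = "metabolite")
  }
  out <- out |>
    dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, method = "BH")) |>
    volcano_select(min_abs_log2_fc = min_abs_log2_fc, max_p = max_p)
  class(out) <- c("metabo_stats", class(out))
  attr(out, "pair") <- pair
  attr(out, "thresholds") <- c(min_abs_log2_fc = min_abs_log2_fc,
                               max_p = max_p)
  out
}
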