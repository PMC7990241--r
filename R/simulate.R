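#' Settings for the synthetic metabolomics data generator
#'
#' Describes a multi-group feature table with log-normal intensities (real
#' metabolite panels span several orders of magnitude), optional differential
#' metabolites with a multiplicative group effect, optional correlated blocks
#' driven by shared latent factors, optional per-platform magnitude scaling,
#' and the missingness mechanisms to inject later.
#'
#' @param n_samples_per_group Samples per group (default 10).
#' @param group_names Group labels (default `c("ctl", "trt")`).
#' @param n_metabolites Number of metabolites (default 50).
#' @param n_differential Number of metabolites carrying a group effect
#'   (default 5); applied to the second group.
#' @param effect_size Multiplicative fold change of differential metabolites
#'   in the second group (default 2).
#' @param base_log_mean,base_log_sd Natural-log location of the intensity
#'   distribution and the per-metabolite biological noise sd on the log scale
#'   (defaults 5 and 0.4, i.e. roughly 40% coefficient of variation, a
#'   typical across-subject biological spread). Per-metabolite abundances are
#'   spread uniformly over `base_log_mean` +/- 2, so the panel spans a wide
#'   dynamic range.
#' @param n_correlated_blocks Number of correlated metabolite blocks
#'   (default 0).
#' @param block_size Metabolites per correlated block (default 5).
#' @param within_block_correlation Latent-factor correlation of log
#'   intensities within a block, in \[0, 1) (default 0.7).
#' @param mcar_rate Fraction of cells removed completely at random by
#'   [inject_missingness()] (default 0).
#' @param mnar_groups List of `(metabolite, group)` pairs censored entirely
#'   within that group (emulating below-detection-limit loss); metabolite by
#'   index or name.
#' @param platforms Optional named numeric vector of per-platform magnitude
#'   scales, e.g. `c(NMR = 1, LCMS = 1000)`; metabolites are assigned to
#'   platforms round-robin and multiplied by the scale.
#' @param seed Integer master seed; all draws derive from it.
#' @return A list of class `metabo_simulation_config`.
#' @export
simulation_config <- function(n_samples_per_group = 10L,
                              group_names = c("ctl", "trt"),
                              n_metabolites = 50L,
                              n_differential = 5L,
                              effect_size = 2.0,
                              base_log_mean = 5,
                              base_log_sd = 0.4,
                              n_correlated_blocks = 0L,
                              block_size = 5L,
                              within_block_correlation = 0.7,
                              mcar_rate = 0,
                              mnar_groups = list(),
                              platforms = NULL,
                              seed = 1L) {
  stopifnot(
    n_samples_per_group >= 2L, length(group_names) >= 1L,
    n_metabolites >= 1L, n_differential >= 0L,
    n_differential <= n_metabolites, effect_size > 0,
    base_log_sd > 0, n_correlated_blocks >= 0L, block_size >= 2L,
    within_block_correlation >= 0, within_block_correlation < 1,
    mcar_rate >= 0, mcar_rate <= 1
  )
  if (n_correlated_blocks * block_size > n_metabolites) {
    abort_mp("correlated blocks exceed the number of metabolites")
  }
  structure(
    list(n_samples_per_group = as.integer(n_samples_per_group),
         group_names = as.character(group_names),
         n_metabolites = as.integer(n_metabolites),
         n_differential = as.integer(n_differential),
         effect_size = effect_size,
         base_log_mean = base_log_mean, base_log_sd = base_log_sd,
         n_correlated_blocks = as.integer(n_correlated_blocks),
         block_size = as.integer(block_size),
         within_block_correlation = within_block_correlation,
         mcar_rate = mcar_rate, mnar_groups = mnar_groups,
         platforms = platforms, seed = as.integer(seed)),
    class = "metabo_simulation_config"
  )
}

#' Simulate a feature table with known ground truth
#'
#' Intensities are log-normal: `log x_ij = mu_j + b * f_i(block) + e_ij`,
#' where `mu_j` sets the metabolite's abundance, `f` is a per-sample latent
#' factor shared within a correlated block (inducing correlation
#' `within_block_correlation` on the log scale) and `e` is independent noise.
#' Differential metabolites are multiplied by `effect_size` in the second
#' group. All randomness derives from `config$seed` through per-metabolite
#' sub-streams, so enlarging the panel never perturbs earlier metabolites.
#'
#' @param config A [simulation_config()].
#' @return List with `table` (tibble: `sample_id`, `group`, metabolite
#'   columns) and `truth` (list: `differential` metabolite names, `blocks`
#'   list of correlated index sets, `platform` assignment or `NULL`, and
#'   `clean`, the complete measurement tibble).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "metabo_simulation_config"))
  ng <- length(config$group_names)
  n <- config$n_samples_per_group * ng
  p <- config$n_metabolites
  groups <- rep(config$group_names, each = config$n_samples_per_group)
  sample_id <- sprintf("S%03d", seq_len(n))
  met <- sprintf("met_%03d", seq_len(p))

  rho <- config$within_block_correlation
  block_of <- rep(NA_integer_, p)
  blocks <- list()
  if (config$n_correlated_blocks > 0L) {
    for (b in seq_len(config$n_correlated_blocks)) {
      idx <- ((b - 1L) * config$block_size + 1L):(b * config$block_size)
      block_of[idx] <- b
      blocks[[b]] <- idx
    }
  }
  # latent per-sample factors, one stream per block
  factors <- lapply(seq_along(blocks), function(b) {
    with_seed_mp(derive_seed(config$seed, 500000L + b), stats::rnorm(n))
  })
  diff_idx <- if (config$n_differential > 0L && config$effect_size != 1) {
    with_seed_mp(derive_seed(config$seed, 900001L),
                 sort(sample.int(p, config$n_differential)))
  } else integer()
  mu <- with_seed_mp(derive_seed(config$seed, 900002L),
                     stats::runif(p, config$base_log_mean - 2,
                                  config$base_log_mean + 2))

  second <- if (ng >= 2L) config$group_names[2] else NULL
  m <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    e <- with_seed_mp(derive_seed(config$seed, j), stats::rnorm(n))
    b <- block_of[j]
    logx <- if (!is.na(b)) {
      mu[j] + config$base_log_sd *
        (sqrt(rho) * factors[[b]] + sqrt(1 - rho) * e)
    } else {
      mu[j] + config$base_log_sd * e
    }
    if (j %in% diff_idx && !is.null(second)) {
      logx[groups == second] <- logx[groups == second] + log(config$effect_size)
    }
    m[, j] <- exp(logx)
  }

  platform <- NULL
  if (!is.null(config$platforms)) {
    labs <- names(config$platforms)
    platform <- rep(labs, length.out = p)
    m <- sweep(m, 2, unname(config$platforms[platform]), "*")
  }

  colnames(m) <- met
  clean <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  list(
    table = dplyr::bind_cols(
      tibble::tibble(sample_id = sample_id, group = groups), clean),
    truth = list(
      differential = met[diff_idx],
      differential_idx = diff_idx,
      blocks = blocks,
      platform = platform,
      clean = clean
    )
  )
}

#' Inject MCAR and MNAR holes into a complete matrix
#'
#' MCAR: each cell of a non-censored metabolite is removed independently with
#' probability `mcar_rate`. MNAR: every cell of the listed
#' `(metabolite, group)` pairs is removed (total within-group censoring, the
#' deterministic analogue of below-detection-limit loss). Metabolites listed
#' in `mnar_groups` are excluded from MCAR so each holed metabolite has a
#' single, unambiguous mechanism.
#'
#' @param data Complete measurement tibble.
#' @param groups Per-sample group label.
#' @param mcar_rate MCAR cell probability (default 0).
#' @param mnar_groups List of `list(metabolite =, group =)` pairs (metabolite
#'   by name or column index).
#' @param seed Integer seed for the MCAR draw.
#' @return List with `data` (holed tibble) and `mask`, a tibble
#'   (`row`, `metabolite`, `mechanism`) with one row per injected hole.
#' @export
inject_missingness <- function(data, groups, mcar_rate = 0,
                               mnar_groups = list(), seed = 1L) {
  m <- as_measurement_matrix(data)
  if (anyNA(m)) abort_mp("inject_missingness requires a complete matrix")
  stopifnot(length(groups) == nrow(m), mcar_rate >= 0, mcar_rate <= 1)
  groups <- as.character(groups)
  nm <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  mnar_cols <- integer()
  mask <- list()
  for (spec in mnar_groups) {
    j <- spec$metabolite
    if (is.character(j)) j <- match(j, nm)
    if (is.na(j) || j < 1L || j > ncol(m)) abort_mp("unknown MNAR metabolite")
    if (!spec$group %in% groups) abort_mp("unknown MNAR group")
    rows <- which(groups == spec$group)
    m[rows, j] <- NA_real_
    mnar_cols <- c(mnar_cols, j)
    mask[[length(mask) + 1L]] <- tibble::tibble(
      row = rows, metabolite = nm[j], mechanism = "mnar")
  }
  mnar_cols <- unique(mnar_cols)
  if (mcar_rate > 0) {
    free_cols <- setdiff(seq_len(ncol(m)), mnar_cols)
    if (length(free_cols)) {
      hit <- with_seed_mp(seed, {
        matrix(stats::runif(nrow(m) * length(free_cols)) < mcar_rate,
               nrow(m), length(free_cols))
      })
      for (k in seq_along(free_cols)) {
        j <- free_cols[k]
        rows <- which(hit[, k])
        if (length(rows)) {
          m[rows, j] <- NA_real_
          mask[[length(mask) + 1L]] <- tibble::tibble(
            row = rows, metabolite = nm[j], mechanism = "mcar")
        }
      }
    }
  }
  mask <- if (length(mask)) dplyr::bind_rows(mask) else
    tibble::tibble(row = integer(), metabolite = character(),
                   mechanism = character())
  list(data = tibble::as_tibble(as.data.frame(m), .name_repair = "minimal"),
       mask = mask)
}
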