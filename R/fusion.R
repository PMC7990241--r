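# Multi-platform fusion. A "block" is one platform's feature table: a data
# frame whose first column (or `id_col`) is the sample ID and whose remaining
# columns are numeric features. Blocks are supplied as a named list; the list
# names are the source labels (e.g. "NMR", "LCMS").

#' @noRd
check_blocks <- function(blocks, id_col = 1L) {
  if (!is.list(blocks) || length(blocks) < 2L) {
    abort_mp("fusion requires at least 2 blocks")
  }
  labels <- names(blocks) %||% paste0("block", seq_along(blocks))
  if (any(!nzchar(labels))) {
    labels[!nzchar(labels)] <- paste0("block", which(!nzchar(labels)))
  }
  parsed <- purrr::map2(blocks, labels, function(b, lab) {
    stopifnot(is.data.frame(b))
    ids <- as.character(b[[id_col]])
    if (anyDuplicated(ids)) {
      abort_mp(paste0("duplicate sample IDs within block '", lab, "'"))
    }
    feats <- b[, -id_col, drop = FALSE]
    list(label = lab, ids = ids, features = feats)
  })
  unname(parsed)
}

#' Match samples across platform blocks
#'
#' Exact, case-sensitive intersection of the sample IDs of every block,
#' ordered as in the first block — the sample set any merge will operate on.
#'
#' @param blocks Named list of data frames; first column = sample ID.
#' @param id_col Sample-ID column index in each block (default 1).
#' @return Tibble with column `sample_id` (the matched IDs, first-block
#'   order); `nrow()` is the match count.
#' @export
match_samples <- function(blocks, id_col = 1L) {
  parsed <- check_blocks(blocks, id_col)
  common <- Reduce(intersect, lapply(parsed, `[[`, "ids"))
  matched <- parsed[[1]]$ids[parsed[[1]]$ids %in% common]
  if (length(matched) == 0L) {
    abort_mp("no sample IDs are shared by all blocks; merge impossible")
  }
  tibble::tibble(sample_id = matched)
}

#' @noRd
disambiguate_names <- function(nm, labels) {
  dup <- nm %in% nm[duplicated(nm)]
  nm[dup] <- paste(labels[dup], nm[dup], sep = "_")
  nm
}

#' @noRd
new_fused_table <- function(sample_id, mats, provenance) {
  nm <- disambiguate_names(provenance$feature_name, provenance$source)
  mat <- do.call(cbind, mats)
  colnames(mat) <- nm
  provenance$column <- nm
  out <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                          tibble::as_tibble(as.data.frame(mat),
                                            .name_repair = "minimal"))
  attr(out, "provenance") <- provenance[, c("column", "source", "feature")]
  class(out) <- c("fused_table", class(out))
  out
}

#' Per-column provenance of a fused table
#' @param fused A `fused_table`.
#' @return Tibble with `column`, `source` (block label) and `feature`
#'   (original feature name or component index).
#' @export
provenance <- function(fused) {
  stopifnot(inherits(fused, "fused_table"))
  attr(fused, "provenance")
}

#' Fuse platform blocks into one table
#'
#' Three integration methods over the matched samples:
#' * `"concat"`: simple column concatenation of all feature columns.
#' * `"pca"` (mid-level fusion): each block is replaced by its PCA scores
#'   (components up to a cumulative explained variance of `variance_kept`;
#'   the default 1 keeps every component, losing no information), each score
#'   column normalized to unit sample sd, then concatenated.
#' * `"multiblock"`: each block is column-centered and divided by its first
#'   singular value so that no single platform's dominant direction outweighs
#'   the others, then the weighted blocks are concatenated into a grand
#'   table.
#'
#' Feature names colliding across blocks are disambiguated with the source
#' label as prefix; every output column carries provenance (see
#' [provenance()]).
#'
#' @param blocks Named list of >= 2 data frames (first column = sample ID,
#'   complete numeric features).
#' @param method `"concat"`, `"pca"` or `"multiblock"`.
#' @param variance_kept Cumulative explained-variance fraction for `"pca"`
#'   (default 1 = keep all components).
#' @param id_col Sample-ID column index in each block.
#' @return A `fused_table`: tibble with `sample_id` plus fused feature
#'   columns, rows = matched samples in first-block order.
#' @export
fuse_blocks <- function(blocks, method = c("concat", "pca", "multiblock"),
                        variance_kept = 1.0, id_col = 1L) {
  method <- match.arg(method)
  stopifnot(variance_kept > 0, variance_kept <= 1)
  parsed <- check_blocks(blocks, id_col)
  matched <- match_samples(blocks, id_col)$sample_id
  mats <- list()
  prov <- list()
  for (b in parsed) {
    m <- as_measurement_matrix(b$features)
    if (anyNA(m)) {
      abort_mp(paste0("block '", b$label, "' has missing values; impute first"))
    }
    m <- m[match(matched, b$ids), , drop = FALSE]
    fn <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
    if (method == "concat") {
      mats[[b$label]] <- m
      prov[[b$label]] <- tibble::tibble(source = b$label, feature = fn,
                                        feature_name = fn)
    } else if (method == "pca") {
      if (nrow(m) < 2L) abort_mp("pca fusion needs >= 2 matched samples")
      pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
      vars <- pc$sdev^2
      rank <- sum(pc$sdev > max(pc$sdev[1], 0) * 1e-9)
      if (rank == 0L) {
        abort_mp(paste0("block '", b$label, "' has zero variance"))
      }
      cum <- cumsum(vars[seq_len(rank)]) / sum(vars)
      ncomp <- which(cum >= variance_kept - 1e-12)[1]
      if (is.na(ncomp)) ncomp <- rank
      sc <- pc$x[, seq_len(ncomp), drop = FALSE]
      sds <- apply(sc, 2, stats::sd)
      sc <- sweep(sc, 2, sds, "/")
      mats[[b$label]] <- sc
      prov[[b$label]] <- tibble::tibble(
        source = b$label,
        feature = paste0("PC", seq_len(ncomp)),
        feature_name = paste0(b$label, "_PC", seq_len(ncomp))
      )
    } else { # multiblock
      centered <- sweep(m, 2, colMeans(m), "-")
      sv1 <- svd(centered, nu = 0, nv = 0)$d[1]
      if (sv1 <= 0) {
        abort_mp(paste0("block '", b$label,
                        "' is constant: zero first singular value"))
      }
      mats[[b$label]] <- centered / sv1
      prov[[b$label]] <- tibble::tibble(source = b$label, feature = fn,
                                        feature_name = fn)
    }
  }
  prov <- dplyr::bind_rows(prov)
  new_fused_table(matched, mats, prov)
}
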