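#' Principal component analysis of a treated matrix
#'
#' Column-mean-centered PCA via singular value decomposition (no extra
#' scaling: apply [scale_measurements()] first if wanted). Sign convention:
#' within each loading column the entry of largest magnitude is positive, so
#' results are reproducible across runs and platforms.
#'
#' @param data Complete measurement tibble (samples x metabolites).
#' @param n_components Number of components to keep (default:
#'   `min(n_samples, n_metabolites)`).
#' @param sample_ids Optional sample IDs for the score rows.
#' @return A `metabo_pca` object: `scores` tibble (`sample_id`, `PC1`, ...),
#'   `loadings` tibble (`metabolite`, `PC1`, ...),
#'   `explained_variance_fraction` (per kept component, relative to total
#'   variance), `sdev` (all singular-value sds) and `center`.
#' @export
compute_pca <- function(data, n_components = NULL, sample_ids = NULL) {
  m <- as_measurement_matrix(data)
  if (anyNA(m)) abort_mp("pca requires a complete matrix")
  max_comp <- min(nrow(m), ncol(m))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    abort_mp("n_components exceeds min(samples, metabolites)")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n_components, ncol(pc$rotation)))
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_along(keep)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  evf <- if (total_var > 0) pc$sdev[keep]^2 / total_var else
    rep(0, length(keep))
  ids <- sample_ids %||% rownames(m) %||% paste0("S", seq_len(nrow(m)))
  structure(
    list(
      scores = tibble::as_tibble(as.data.frame(scores)) |>
        dplyr::mutate(sample_id = ids, .before = 1),
      loadings = tibble::as_tibble(as.data.frame(loadings)) |>
        dplyr::mutate(
          metabolite = colnames(m) %||% paste0("V", seq_len(ncol(m))),
          .before = 1),
      explained_variance_fraction = evf,
      sdev = pc$sdev,
      center = pc$center
    ),
    class = "metabo_pca"
  )
}

#' @export
print.metabo_pca <- function(x, ...) {
  cat("<metabo_pca> ", nrow(x$scores), " samples, ",
      length(x$explained_variance_fraction), " components\n", sep = "")
  cat("explained variance:",
      paste0(sprintf("%.1f%%",
                     100 * utils::head(x$explained_variance_fraction, 5)),
             collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of samples or metabolites
#'
#' Agglomerative clustering used to order heatmap rows/columns. Distances are
#' Euclidean or correlation (`1 - r`); linkage is Ward (on squared
#' distances, `hclust` method `ward.D2`), average or complete. With
#' `cluster = FALSE` the identity order is returned (clustering toggled off).
#'
#' @param data Measurement tibble.
#' @param axis `"samples"` (rows) or `"metabolites"` (columns).
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @param cluster Set `FALSE` to keep the input order (no tree).
#' @param labels Optional item labels (default: sample index / metabolite
#'   names).
#' @return A `metabo_dendrogram`: `hclust` (the merge tree, `NULL` when
#'   `cluster = FALSE`), `leaf_order` (integer), `labels`, `axis`.
#' @export
hierarchical_cluster <- function(data,
                                 axis = c("samples", "metabolites"),
                                 distance = c("euclidean", "correlation"),
                                 linkage = c("ward", "average", "complete"),
                                 cluster = TRUE,
                                 labels = NULL) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- as_measurement_matrix(data)
  if (anyNA(m)) abort_mp("clustering requires a complete matrix")
  if (axis == "metabolites") {
    labels <- labels %||% (colnames(m) %||% paste0("V", seq_len(ncol(m))))
    m <- t(m)
  } else {
    labels <- labels %||% (rownames(m) %||% paste0("S", seq_len(nrow(m))))
  }
  n <- nrow(m)
  if (!cluster) {
    return(structure(list(hclust = NULL, leaf_order = seq_len(n),
                          labels = labels, axis = axis),
                     class = "metabo_dendrogram"))
  }
  if (n < 2L) abort_mp("need at least 2 items to cluster")
  d <- if (distance == "euclidean") {
    stats::dist(m)
  } else {
    stats::as.dist(1 - stats::cor(t(m)))
  }
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  hc <- stats::hclust(d, method = method)
  hc$labels <- as.character(labels)
  structure(list(hclust = hc, leaf_order = hc$order, labels = labels,
                 axis = axis),
            class = "metabo_dendrogram")
}

#' @export
print.metabo_dendrogram <- function(x, ...) {
  cat("<metabo_dendrogram> ", length(x$labels), " ", x$axis,
      if (is.null(x$hclust)) " (identity order, clustering off)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from the merge heights, so the tree can be laid
#' out by any standard renderer.
#'
#' @param dendro A `metabo_dendrogram` with clustering on.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "metabo_dendrogram"))
  if (is.null(dendro$hclust)) abort_mp("no tree: clustering was toggled off")
  phy <- ape::as.phylo(dendro$hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Metabolite-by-metabolite correlation matrix
#'
#' @param data Measurement tibble with at least 3 samples.
#' @param method `"pearson"`, `"spearman"` or `"kendall"` (tau-b,
#'   tie-corrected).
#' @return Symmetric correlation matrix with unit diagonal. Constant columns
#'   yield `NA` off-diagonal entries and a warning.
#' @export
correlation_matrix <- function(data,
                               method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  m <- as_measurement_matrix(data)
  if (anyNA(m)) abort_mp("correlation requires a complete matrix")
  if (nrow(m) < 3L) abort_mp("need at least 3 samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(paste0("constant column(s): ",
                       paste(utils::head(colnames(m)[sds == 0], 5),
                             collapse = ", "),
                       " produce undefined correlations"))
  }
  cc <- suppressWarnings(stats::cor(m, method = method))
  diag(cc) <- 1
  cc
}

#' Build a thresholded correlation network
#'
#' Nodes are metabolites; an edge joins pair (i, j), i < j, when the absolute
#' correlation reaches the threshold. The signed coefficient is retained (for
#' colouring positive vs negative links) and its magnitude exported as the
#' edge weight (link width). Undefined (NA) correlations never form edges.
#'
#' @param corr Symmetric correlation matrix (from [correlation_matrix()]).
#' @param min_abs_correlation Threshold in \[0, 1\] (default 0.5).
#' @param annotations Optional tibble of node annotations with a `metabolite`
#'   column (e.g. data `source`, significance flag) joined onto the nodes.
#' @param method Correlation method label stored on the network.
#' @return A `metabo_network`: `nodes` tibble and `edges` tibble
#'   (`from`, `to`, `r`, `weight = |r|`, `sign`).
#' @export
build_network <- function(corr, min_abs_correlation = 0.5, annotations = NULL,
                          method = "pearson") {
  if (min_abs_correlation < 0 || min_abs_correlation > 1) {
    abort_mp("min_abs_correlation must be in [0, 1]")
  }
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    abort_mp("correlation matrix must be symmetric")
  }
  nm <- colnames(corr) %||% paste0("V", seq_len(ncol(corr)))
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[idx]
  keep <- !is.na(r) & abs(r) >= min_abs_correlation
  edges <- tibble::tibble(
    from = nm[idx[keep, 1]],
    to = nm[idx[keep, 2]],
    r = r[keep],
    weight = abs(r[keep]),
    sign = ifelse(r[keep] >= 0, "positive", "negative")
  )
  nodes <- tibble::tibble(metabolite = nm)
  if (!is.null(annotations)) {
    nodes <- dplyr::left_join(nodes, annotations, by = "metabolite")
  }
  structure(
    list(nodes = nodes, edges = edges, method = method,
         min_abs_correlation = min_abs_correlation),
    class = "metabo_network"
  )
}

#' @export
print.metabo_network <- function(x, ...) {
  cat("<metabo_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|r| >= ", x$min_abs_correlation, ", ", x$method, ")\n",
      sep = "")
  invisible(x)
}

# node-link representation used by the JSON writer
#' @noRd
network_node_link <- function(network) {
  list(
    method = network$method,
    min_abs_correlation = network$min_abs_correlation,
    nodes = lapply(seq_len(nrow(network$nodes)),
                   function(i) as.list(network$nodes[i, ])),
    links = lapply(seq_len(nrow(network$edges)),
                   function(i) as.list(network$edges[i, ]))
  )
}
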