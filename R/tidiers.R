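#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA result
#'
#' @param x A `metabo_pca`.
#' @param matrix `"scores"` (default), `"loadings"` or `"variance"`.
#' @param ... Unused.
#' @return A long tibble: scores as (`sample_id`, `component`, `score`),
#'   loadings as (`metabolite`, `component`, `loading`), variance as
#'   (`component`, `explained_variance_fraction`, `cumulative`).
#' @export
tidy.metabo_pca <- function(x, matrix = c("scores", "loadings", "variance"),
                            ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, -"sample_id",
                                 names_to = "component",
                                 values_to = "score"),
    loadings = tidyr::pivot_longer(x$loadings, -"metabolite",
                                   names_to = "component",
                                   values_to = "loading"),
    variance = tibble::tibble(
      component = paste0("PC", seq_along(x$explained_variance_fraction)),
      explained_variance_fraction = x$explained_variance_fraction,
      cumulative = cumsum(x$explained_variance_fraction)
    )
  )
}

#' One-row PCA summary
#' @param x A `metabo_pca`.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_components`, `var_pc1`, `var_pc2`.
#' @export
glance.metabo_pca <- function(x, ...) {
  evf <- x$explained_variance_fraction
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = length(evf),
    var_pc1 = evf[1],
    var_pc2 = if (length(evf) >= 2) evf[2] else NA_real_
  )
}

#' Tidy a correlation network into its edge list
#' @param x A `metabo_network`.
#' @param ... Unused.
#' @return The edges tibble (`from`, `to`, `r`, `weight`, `sign`).
#' @export
tidy.metabo_network <- function(x, ...) x$edges

#' One-row network summary
#' @param x A `metabo_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, threshold and method.
#' @export
glance.metabo_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_negative = sum(x$edges$sign == "negative"),
    min_abs_correlation = x$min_abs_correlation,
    method = x$method
  )
}

#' Tidy a dendrogram into its merge table
#' @param x A `metabo_dendrogram`.
#' @param ... Unused.
#' @return Tibble with `merge1`, `merge2` (negative = leaf index) and
#'   `height`; empty when clustering was off.
#' @export
tidy.metabo_dendrogram <- function(x, ...) {
  if (is.null(x$hclust)) {
    return(tibble::tibble(merge1 = integer(), merge2 = integer(),
                          height = numeric()))
  }
  tibble::tibble(
    merge1 = x$hclust$merge[, 1],
    merge2 = x$hclust$merge[, 2],
    height = x$hclust$height
  )
}
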