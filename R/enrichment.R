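#' Hypergeometric enrichment tail probability
#'
#' Probability of drawing at least `X` annotated genes when sampling
#' `N` genes without replacement from a universe of `M_ann` annotated
#' genes of which `K` carry the annotation of interest:
#' `p = 1 - sum_{i=0}^{X-1} choose(K, i) choose(M_ann - K, N - i) /
#' choose(M_ann, N)`. Computed with the stable distribution-function
#' routine rather than by summing binomial coefficients.
#'
#' @param N Cluster size, counting only annotated genes.
#' @param X Cluster genes carrying the annotation.
#' @param M_ann Annotated genes in the universe.
#' @param K Universe genes carrying the annotation.
#' @return The upper-tail probability in `[0, 1]`; `X = 0` gives 1.
#' @export
hypergeom_p <- function(N, X, M_ann, K) {
  if (N < 0 || K < 0 || M_ann < 0 || X < 0) {
    stop("counts must be nonnegative")
  }
  if (N > M_ann || K > M_ann) {
    stop("N and K must not exceed M_ann")
  }
  if (X > min(N, K)) stop("X must not exceed min(N, K)")
  stats::phyper(X - 1, K, M_ann - K, N, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; the output is in the input
#' order, elementwise at least the input and clamped to 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values of the same length.
#' @export
adjust_pvalues <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Annotation enrichment of gene clusters
#'
#' For every (cluster, annotation) pair with at least one cluster gene
#' carrying the annotation, computes the hypergeometric upper-tail
#' probability with `N` = annotated genes in the cluster, `X` = cluster
#' genes with the annotation, `M_ann` = annotated genes in the universe
#' and `K` = universe genes with the annotation. Only genes annotated by
#' at least one set of the collection count towards `N` and `M_ann`.
#' Adjustment is applied over all pairs of the collection (one
#' annotation namespace per call).
#'
#' @param clustering A `gene_clustering` over the gene universe.
#' @param annotations An [annotation_collection()].
#' @param universe Ordered gene identifiers shared by the clustering.
#' @param alpha Significance level on the adjusted p-value.
#' @return Data frame with columns `cluster_id`, `annotation_id`,
#'   `namespace`, `N`, `X`, `M_ann`, `K`, `p_raw`, `p_adj`,
#'   `significant` (zero rows when nothing overlaps).
#' @export
enrich_clusters <- function(clustering, annotations, universe,
                            alpha = 0.05) {
  sets <- lapply(annotations$sets, function(g) intersect(g, universe))
  sets <- sets[lengths(sets) > 0L]
  annotated <- unique(unlist(sets, use.names = FALSE))
  m_ann <- length(annotated)
  k_per_set <- lengths(sets)
  rows <- vector("list", clustering$k)
  for (cl in seq_len(clustering$k)) {
    members <- cluster_members(clustering, cl)
    n_cl <- length(intersect(members, annotated))
    if (n_cl == 0L) next
    x_per_set <- vapply(sets, function(g) {
      length(intersect(g, members))
    }, integer(1L))
    hit <- which(x_per_set >= 1L)
    if (length(hit) == 0L) next
    rows[[cl]] <- data.frame(
      cluster_id = cl,
      annotation_id = names(sets)[hit],
      namespace = annotations$namespace,
      N = n_cl,
      X = as.integer(x_per_set[hit]),
      M_ann = m_ann,
      K = as.integer(k_per_set[hit]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(cluster_id = integer(), annotation_id = character(),
                      namespace = character(), N = integer(),
                      X = integer(), M_ann = integer(), K = integer(),
                      stringsAsFactors = FALSE)
  }
  res$p_raw <- mapply(hypergeom_p, res$N, res$X, res$M_ann, res$K)
  if (nrow(res) == 0L) res$p_raw <- numeric()
  res$p_adj <- adjust_pvalues(res$p_raw)
  res$significant <- res$p_adj <= alpha
  rownames(res) <- NULL
  res
}

#' Clustering quality as the fraction of enriched clusters
#'
#' Percentage of the `k1` clusters having at least one significantly
#' enriched annotation.
#'
#' @param results Data frame from [enrich_clusters()] (possibly several
#'   namespaces row-bound together).
#' @param k1 Total number of clusters.
#' @return Percentage in `[0, 100]`.
#' @export
cluster_quality <- function(results, k1) {
  if (nrow(results) == 0L) return(0)
  enriched <- unique(results$cluster_id[results$significant])
  100 * length(enriched) / k1
}
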