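#' Hard cluster assignment from a cluster-indicator factor
#'
#' Each row is assigned to the column holding its largest entry; ties go
#' to the lowest column index. Rows that are entirely zero are assigned
#' to cluster 1 with a warning. Assignments are invariant to positive
#' rescaling of rows.
#'
#' @param factor_matrix Nonnegative matrix (entities in rows, clusters in
#'   columns), e.g. the G or P factor of a fit.
#' @return A list of class `gene_clustering` with `assignment` (named
#'   integer vector of 1-based cluster indices) and `k` (number of
#'   clusters, `ncol(factor_matrix)`).
#' @export
extract_clusters <- function(factor_matrix) {
  factor_matrix <- as.matrix(factor_matrix)
  if (any(factor_matrix < 0)) stop("indicator factor must be nonnegative")
  zero_rows <- rowSums(factor_matrix) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows),
            " all-zero row(s) assigned to cluster 1 by convention")
  }
  assignment <- max.col(factor_matrix, ties.method = "first")
  names(assignment) <- rownames(factor_matrix)
  structure(list(assignment = assignment, k = ncol(factor_matrix)),
            class = "gene_clustering")
}

#' @export
print.gene_clustering <- function(x, ...) {
  sizes <- tabulate(x$assignment, nbins = x$k)
  cat(sprintf("gene_clustering: %d items in %d clusters (%d empty)\n",
              length(x$assignment), x$k, sum(sizes == 0L)))
  invisible(x)
}

#' Genes assigned to one cluster
#'
#' @param clustering A `gene_clustering`.
#' @param cluster_id Cluster index (1-based).
#' @return Character vector of member genes.
#' @export
cluster_members <- function(clustering, cluster_id) {
  names(clustering$assignment)[clustering$assignment == cluster_id]
}

#' Union subnetwork of a gene cluster
#'
#' Nodes are the cluster's genes; two nodes are joined when the genes
#' interact in any of the molecular networks. Each edge records which
#' networks support it.
#'
#' @param cluster_genes Character vector of genes (subset of the shared
#'   universe).
#' @param networks List of [molecular_network()] objects over the same
#'   universe.
#' @param cluster_id Optional cluster index stored in the result.
#' @return A list of class `subnetwork`: `cluster_id`, `nodes`, `edges`
#'   (data frame `from`, `to`, `sources` with comma-separated network
#'   names, canonical order).
#' @export
extract_subnetwork <- function(cluster_genes, networks, cluster_id = NA) {
  universe <- networks[[1L]]$genes
  unknown <- setdiff(cluster_genes, universe)
  if (length(unknown) > 0L) {
    stop("gene not in the network universe: ", unknown[1L])
  }
  idx <- match(cluster_genes, universe)
  union_adj <- NULL
  per_net <- list()
  for (net in networks) {
    sub <- net$adjacency[idx, idx, drop = FALSE]
    per_net[[net$name]] <- sub
    union_adj <- if (is.null(union_adj)) sub else pmax(union_adj, sub)
  }
  if (length(cluster_genes) >= 2L) {
    ut <- which(upper.tri(union_adj) & union_adj == 1, arr.ind = TRUE)
  } else {
    ut <- matrix(integer(), 0L, 2L)
  }
  from <- cluster_genes[ut[, 1L]]
  to <- cluster_genes[ut[, 2L]]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  sources <- vapply(seq_len(nrow(ut)), function(e) {
    hit <- vapply(per_net, function(a) a[ut[e, 1L], ut[e, 2L]] == 1,
                  logical(1L))
    paste(names(per_net)[hit], collapse = ",")
  }, character(1L))
  edges <- data.frame(from = from, to = to, sources = sources,
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(cluster_id = cluster_id, nodes = cluster_genes,
                 edges = edges),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork (cluster %s): %d nodes, %d edges\n",
              format(x$cluster_id), length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Direct neighbors of a gene within a subnetwork
#'
#' @param subnet A [extract_subnetwork()] result.
#' @param gene Query gene; must be a node of the subnetwork.
#' @return Sorted character vector of neighboring genes (empty for an
#'   isolated node).
#' @export
subnetwork_neighbors <- function(subnet, gene) {
  if (!(gene %in% subnet$nodes)) {
    stop("gene '", gene, "' is not in the subnetwork")
  }
  e <- subnet$edges
  sort(unique(c(e$to[e$from == gene], e$from[e$to == gene])))
}

#' Per-cluster healthy-/disease-specific variant content
#'
#' For every cluster, the percentage of member genes labeled
#' `healthy_specific` and `disease_specific`. Percentages are computed
#' over all cluster members, mutated or not; empty clusters report 0.
#'
#' @param clustering A `gene_clustering` over the gene universe.
#' @param labels Factor from [classify_gene_specificity()].
#' @return Data frame with columns `cluster_id`, `size`,
#'   `pct_healthy_specific`, `pct_disease_specific`, one row per cluster.
#' @export
summarize_specificity <- function(clustering, labels) {
  labels <- labels[names(clustering$assignment)]
  cl <- factor(clustering$assignment, levels = seq_len(clustering$k))
  size <- as.integer(table(cl))
  n_h <- as.integer(table(cl[labels == "healthy_specific"]))
  n_d <- as.integer(table(cl[labels == "disease_specific"]))
  pct <- function(n) ifelse(size > 0L, 100 * n / size, 0)
  data.frame(cluster_id = seq_len(clustering$k), size = size,
             pct_healthy_specific = pct(n_h),
             pct_disease_specific = pct(n_d))
}

#' Clusters containing any of a set of query genes
#'
#' @param clustering A `gene_clustering`.
#' @param genes Character vector of query genes (all must be in the
#'   clustered universe).
#' @return Named list: one element per cluster holding at least one
#'   query gene, named by cluster index, containing the query genes it
#'   holds.
#' @export
find_clusters_containing <- function(clustering, genes) {
  unknown <- setdiff(genes, names(clustering$assignment))
  if (length(unknown) > 0L) {
    stop("unknown gene: ", unknown[1L])
  }
  if (length(genes) == 0L) return(stats::setNames(list(), character()))
  hit <- clustering$assignment[genes]
  split(names(hit), hit)
}
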