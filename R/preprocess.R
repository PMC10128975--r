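#' Consequence categories treated as non-synonymous coding variants
#'
#' The whitelist of variant consequence categories that set a
#' (subject, gene) entry of the variant-profile matrix: missense,
#' nonsense, nonstop, misstart, frameshift, insert, insert+, delete,
#' delete+ and disrupt.
#'
#' @return Character vector of the ten category names.
#' @export
variant_consequences <- function() {
  c("missense", "nonsense", "nonstop", "misstart", "frameshift",
    "insert", "insert+", "delete", "delete+", "disrupt")
}

#' Construct a molecular network over an ordered gene universe
#'
#' @param adjacency Symmetric binary matrix with zero diagonal; row and
#'   column names give the gene universe ordering.
#' @param name Network label (e.g. `"PPI"`, `"COEX"`, `"GI"`).
#' @return A list of class `molecular_network` with elements `adjacency`,
#'   `genes` and `name`.
#' @export
molecular_network <- function(adjacency, name = "network") {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (is.null(rownames(adjacency))) stop("adjacency needs gene names")
  if (!identical(rownames(adjacency), colnames(adjacency))) {
    stop("adjacency row/column names must match")
  }
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (!isSymmetric(unname(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  storage.mode(adjacency) <- "double"
  structure(list(adjacency = adjacency,
                 genes = rownames(adjacency),
                 name = name),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("molecular_network '%s': %d genes, %d edges\n",
              x$name, nrow(x$adjacency), sum(x$adjacency) / 2))
  invisible(x)
}

#' Keep only the strongest co-expression edges
#'
#' Retains the `ceiling(keep_fraction * n_edges)` edges of largest
#' weight; ties at the cut are resolved by canonical `(from, to)`
#' lexicographic order so the result is deterministic. The default
#' fraction keeps the top 1% of pairs, the usual sparsification for
#' genome-wide co-expression compendia.
#'
#' @param edges A weighted `edge_list`.
#' @param keep_fraction Fraction of edges to keep, in (0, 1].
#' @return An unweighted `edge_list` with the retained pairs.
#' @export
threshold_coexpression <- function(edges, keep_fraction = 0.01) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 ||
      keep_fraction > 1) {
    stop("'keep_fraction' must be in (0, 1]")
  }
  if (nrow(edges) == 0L) return(edge_list(character(), character()))
  if (is.null(edges$weight)) stop("'edges' must carry weights")
  m <- as.integer(ceiling(keep_fraction * nrow(edges)))
  ord <- order(-edges$weight, edges$from, edges$to)
  top <- edges[ord[seq_len(m)], , drop = FALSE]
  edge_list(top$from, top$to)
}

adjacency_from_edges <- function(edges, universe) {
  n <- length(universe)
  a <- matrix(0, n, n, dimnames = list(universe, universe))
  if (nrow(edges) > 0L) {
    i <- match(edges$from, universe)
    j <- match(edges$to, universe)
    keep <- !is.na(i) & !is.na(j)
    a[cbind(i[keep], j[keep])] <- 1
    a[cbind(j[keep], i[keep])] <- 1
  }
  a
}

#' Build the shared gene universe and aligned network matrices
#'
#' The universe is exactly the set of genes incident to at least one
#' protein-protein interaction, since PPI is the most direct evidence of
#' interaction; every other network is restricted to that universe
#' (edges touching excluded genes are dropped) and all adjacency
#' matrices share the universe ordering.
#'
#' @param ppi Unweighted `edge_list` of protein-protein interactions.
#' @param others Named list of additional `edge_list`s (already
#'   thresholded/unweighted).
#' @return List with `universe` (sorted gene identifiers) and `networks`
#'   (list of [molecular_network()]: PPI first, then the others).
#' @export
build_universe_and_align <- function(ppi, others = list()) {
  if (nrow(ppi) == 0L) stop("the PPI edge list must be non-empty")
  universe <- sort(unique(c(ppi$from, ppi$to)))
  nets <- list(PPI = molecular_network(adjacency_from_edges(ppi, universe),
                                       name = "PPI"))
  if (length(others) > 0L) {
    nms <- names(others)
    if (is.null(nms)) nms <- paste0("network_", seq_along(others))
    for (i in seq_along(others)) {
      nets[[nms[i]]] <- molecular_network(
        adjacency_from_edges(others[[i]], universe), name = nms[i])
    }
  }
  list(universe = universe, networks = nets)
}

#' Build the binary variant-profile matrix from per-variant records
#'
#' `M[s, g] = 1` when subject `s` carries at least one variant in gene
#' `g` whose consequence is in the whitelist. No frequency-based
#' filtering of common variants is applied. Records with consequences
#' outside the whitelist, or with genes outside the universe, are
#' ignored (a message reports the counts).
#'
#' @param records Data frame with columns `subject_id`, `gene`,
#'   `consequence`.
#' @param subjects Ordered character vector of subject ids (rows of M).
#' @param universe Ordered gene identifiers (columns of M).
#' @param phenotypes Optional named phenotype vector to attach.
#' @param whitelist Accepted consequence categories
#'   (default [variant_consequences()]).
#' @return A [variant_profile()].
#' @export
build_variant_matrix <- function(records, subjects, universe,
                                 phenotypes = NULL,
                                 whitelist = variant_consequences()) {
  stopifnot(all(c("subject_id", "gene", "consequence") %in%
                  colnames(records)))
  unknown_subj <- setdiff(unique(records$subject_id), subjects)
  if (length(unknown_subj) > 0L) {
    stop("subject in records but not in subject list: ", unknown_subj[1L])
  }
  cons <- tolower(trimws(records$consequence))
  ok_cons <- cons %in% whitelist
  if (any(!ok_cons)) {
    message(sum(!ok_cons),
            " record(s) with non-whitelisted consequence ignored")
  }
  in_univ <- records$gene %in% universe
  if (any(ok_cons & !in_univ)) {
    message(sum(ok_cons & !in_univ),
            " record(s) with gene outside the universe ignored")
  }
  keep <- ok_cons & in_univ
  m <- matrix(0, length(subjects), length(universe),
              dimnames = list(subjects, universe))
  if (any(keep)) {
    i <- match(records$subject_id[keep], subjects)
    j <- match(records$gene[keep], universe)
    m[cbind(i, j)] <- 1
  }
  variant_profile(m, phenotypes = phenotypes)
}

#' Classify genes by phenotype specificity of their variants
#'
#' A gene is `healthy_specific` when mutated in at least one healthy
#' subject and in no diseased subject; `disease_specific` when mutated
#' in all diseased subjects and in no healthy subject; `unmutated` when
#' its column is all zero; `mixed` otherwise.
#'
#' @param vp A [variant_profile()] with phenotypes attached (at least one
#'   subject per label).
#' @param mode `"all_diseased"` (default) requires mutation in every
#'   diseased subject for disease specificity; `"at_least_k"` relaxes
#'   this to `min_diseased` subjects.
#' @param min_diseased Threshold used when `mode = "at_least_k"`.
#' @return Named factor over the gene universe with levels
#'   `healthy_specific`, `disease_specific`, `mixed`, `unmutated`.
#' @export
classify_gene_specificity <- function(vp, mode = c("all_diseased",
                                                   "at_least_k"),
                                      min_diseased = 1L) {
  mode <- match.arg(mode)
  if (is.null(vp$phenotypes)) {
    stop("variant profile has no phenotypes attached")
  }
  healthy <- vp$phenotypes == "healthy"
  diseased <- vp$phenotypes == "diseased"
  if (!any(healthy) || !any(diseased)) {
    stop("need at least one healthy and one diseased subject")
  }
  n_h <- colSums(vp$M[healthy, , drop = FALSE])
  n_d <- colSums(vp$M[diseased, , drop = FALSE])
  need_d <- if (mode == "all_diseased") sum(diseased) else min_diseased
  lab <- rep("mixed", ncol(vp$M))
  lab[n_h == 0 & n_d == 0] <- "unmutated"
  lab[n_h > 0 & n_d == 0] <- "healthy_specific"
  lab[n_h == 0 & n_d >= need_d] <- "disease_specific"
  factor(stats::setNames(lab, vp$genes),
         levels = c("healthy_specific", "disease_specific",
                    "mixed", "unmutated"))
}

#' Align a variant profile to a gene universe
#'
#' Restricts the columns of the profile to `universe` order; universe
#' genes without a column become all-zero columns.
#'
#' @param vp A [variant_profile()].
#' @param universe Ordered gene identifiers.
#' @return A [variant_profile()] whose columns match `universe`.
#' @export
align_profile_to_universe <- function(vp, universe) {
  m <- matrix(0, nrow(vp$M), length(universe),
              dimnames = list(vp$subjects, universe))
  common <- intersect(universe, vp$genes)
  m[, common] <- vp$M[, common]
  variant_profile(m, phenotypes = vp$phenotypes)
}
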