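#' Agreement between two hard partitions
#'
#' Chance-corrected agreement between two clusterings of the same gene
#' universe: the adjusted Rand index (default) or normalized mutual
#' information. Both are symmetric and invariant to cluster relabeling;
#' ARI is 1 for identical partitions and has expectation 0 under random
#' labeling.
#'
#' @param a,b Partitions over the same items: `gene_clustering` objects
#'   or plain (optionally named) label vectors of equal length. When both
#'   are named, `b` is reordered to match `a`.
#' @param method `"ari"` (adjusted Rand index) or `"nmi"` (normalized
#'   mutual information, arithmetic-mean normalization).
#' @return Scalar agreement score (ARI in `[-1, 1]`, NMI in `[0, 1]`).
#' @export
compare_partitions <- function(a, b, method = c("ari", "nmi")) {
  method <- match.arg(method)
  if (inherits(a, "gene_clustering")) a <- a$assignment
  if (inherits(b, "gene_clustering")) b <- b$assignment
  if (length(a) != length(b)) {
    stop("partitions cover different numbers of items")
  }
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions cover different gene universes")
    }
    b <- b[names(a)]
  }
  if (method == "ari") {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  n <- sum(tab)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hx <- h(rowSums(tab) / n)
  hy <- h(colSums(tab) / n)
  hxy <- h(as.vector(tab) / n)
  mi <- hx + hy - hxy
  denom <- (hx + hy) / 2
  if (denom == 0) return(1)  # both partitions trivial
  mi / denom
}

#' Gene partitions from tri-factorization runs on subject pairs
#'
#' Re-fits the factorization using only two subjects at a time (the full
#' networks are kept) and extracts the hard gene partition of each run,
#' to probe how robust the gene clusters are to extreme subject
#' imbalance. In phenotype-constrained mode the eligible pairs are all
#' healthy-diseased pairs, so the fixed two-column subject factor stays
#' valid; otherwise all subject pairs are used.
#'
#' @param vp A [variant_profile()] (phenotypes required in fixed-P mode).
#' @param R_list List of [molecular_network()] objects or adjacency
#'   matrices.
#' @param config A [sonmtf_config()].
#' @param fixed_P Logical; phenotype-constrained mode.
#' @return A list of class `pair_runs`: `pairs` (two-column character
#'   matrix of subject ids) and `partitions` (list of `gene_clustering`
#'   objects, one per pair).
#' @export
pairwise_subject_runs <- function(vp, R_list, config, fixed_P = TRUE) {
  subs <- vp$subjects
  if (length(subs) < 2L) stop("need at least two subjects")
  if (fixed_P) {
    if (is.null(vp$phenotypes)) stop("fixed-P mode requires phenotypes")
    h <- subs[vp$phenotypes == "healthy"]
    d <- subs[vp$phenotypes == "diseased"]
    pairs <- as.matrix(expand.grid(h, d, stringsAsFactors = FALSE))
  } else {
    pairs <- t(utils::combn(subs, 2L))
  }
  if (nrow(pairs) == 0L) stop("no eligible subject pair")
  partitions <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pair <- pairs[i, ]
    m2 <- vp$M[pair, , drop = FALSE]
    p_fix <- NULL
    if (fixed_P) {
      p_fix <- build_fixed_P(vp$phenotypes[pair], subject_order = pair)
    }
    fit <- sonmtf_fit(m2, R_list, config, fixed_P = p_fix)
    g <- fit$factors$G
    rownames(g) <- vp$genes
    partitions[[i]] <- suppressWarnings(extract_clusters(g))
  }
  structure(list(pairs = pairs, partitions = partitions),
            class = "pair_runs")
}

#' Pairwise agreement of subject-pair runs
#'
#' @param runs A [pairwise_subject_runs()] result.
#' @param method Agreement statistic, see [compare_partitions()].
#' @return A list of class `stability_report`: `agreement` (symmetric
#'   run-by-run matrix), `mean_agreement` and `min_agreement` over
#'   distinct run pairs (both `NA` with fewer than two runs), `method`.
#' @export
stability_report <- function(runs, method = c("ari", "nmi")) {
  method <- match.arg(method)
  n <- length(runs$partitions)
  agreement <- diag(1, n)
  labels <- apply(runs$pairs, 1L, paste, collapse = "|")
  dimnames(agreement) <- list(labels, labels)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        s <- compare_partitions(runs$partitions[[i]],
                                runs$partitions[[j]], method = method)
        agreement[i, j] <- s
        agreement[j, i] <- s
      }
    }
    off <- agreement[upper.tri(agreement)]
    mean_agr <- mean(off)
    min_agr <- min(off)
  } else {
    mean_agr <- NA_real_
    min_agr <- NA_real_
  }
  structure(list(agreement = agreement, mean_agreement = mean_agr,
                 min_agreement = min_agr, method = method),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report (%s): %d runs, mean %.3f, min %.3f\n",
              x$method, nrow(x$agreement), x$mean_agreement,
              x$min_agreement))
  invisible(x)
}
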