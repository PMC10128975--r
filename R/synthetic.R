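#' Specification of a planted co-cluster benchmark
#'
#' Describes desk-scale inputs with known ground truth that mimic the
#' statistical structure the fusion model assumes: genes split into
#' `k_planted` clusters; each molecular network drawn as an independent
#' planted-partition graph (edge probability `p_in` within a cluster,
#' `p_out` between); a binary variant matrix in which healthy and
#' diseased subjects preferentially hit disjoint target clusters; and
#' annotation sets aligned with the planted clusters.
#'
#' The defaults mirror the design of the study the package supports:
#' one healthy carrier and four diseased subjects, three networks, and a
#' clear (but noisy) separation between the clusters that carry
#' healthy-specific and disease-specific variants.
#'
#' @param n_g Number of genes.
#' @param k_planted Number of planted gene clusters.
#' @param n_healthy,n_diseased Subject counts per phenotype.
#' @param n_networks Number of molecular networks (named PPI, COEX, GI
#'   for the first three).
#' @param p_in,p_out Within-/between-cluster edge probabilities
#'   (recycled over networks).
#' @param mut_rate_target Probability that a subject mutates a gene
#'   whose cluster is in its phenotype's target set.
#' @param mut_rate_bg Background mutation probability.
#' @param healthy_target_clusters,disease_target_clusters Disjoint sets
#'   of 1-based cluster indices.
#' @param annotation_sets_per_cluster Annotation sets planted per
#'   cluster.
#' @param annotation_set_size Genes per annotation set (90% drawn from
#'   the cluster, 10% background).
#' @param seed Seed for all randomness of the generator.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(n_g = 200L, k_planted = 5L, n_healthy = 1L,
                         n_diseased = 4L, n_networks = 3L, p_in = 0.3,
                         p_out = 0.02, mut_rate_target = 0.6,
                         mut_rate_bg = 0.05,
                         healthy_target_clusters = 1L,
                         disease_target_clusters = 2L,
                         annotation_sets_per_cluster = 3L,
                         annotation_set_size = 20L, seed = 0L) {
  spec <- list(n_g = as.integer(n_g), k_planted = as.integer(k_planted),
               n_healthy = as.integer(n_healthy),
               n_diseased = as.integer(n_diseased),
               n_networks = as.integer(n_networks),
               p_in = rep_len(p_in, n_networks),
               p_out = rep_len(p_out, n_networks),
               mut_rate_target = mut_rate_target,
               mut_rate_bg = mut_rate_bg,
               healthy_target_clusters = as.integer(healthy_target_clusters),
               disease_target_clusters = as.integer(disease_target_clusters),
               annotation_sets_per_cluster =
                 as.integer(annotation_sets_per_cluster),
               annotation_set_size = as.integer(annotation_set_size),
               seed = as.integer(seed))
  probs <- c(spec$p_in, spec$p_out, mut_rate_target, mut_rate_bg)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (spec$k_planted > spec$n_g) stop("k_planted must not exceed n_g")
  if (spec$n_healthy < 1L || spec$n_diseased < 1L) {
    stop("need at least one subject per phenotype")
  }
  if (length(intersect(spec$healthy_target_clusters,
                       spec$disease_target_clusters)) > 0L) {
    stop("healthy and disease target clusters must be disjoint")
  }
  tc <- c(spec$healthy_target_clusters, spec$disease_target_clusters)
  if (any(tc < 1L | tc > spec$k_planted)) {
    stop("target cluster indices must be in 1..k_planted")
  }
  structure(spec, class = "planted_spec")
}

planted_partition_graph <- function(assignment, p_in, p_out, genes) {
  n <- length(assignment)
  same <- outer(assignment, assignment, "==")
  prob <- ifelse(same, p_in, p_out)
  a <- matrix(0, n, n, dimnames = list(genes, genes))
  ut <- upper.tri(a)
  a[ut] <- as.numeric(stats::runif(sum(ut)) < prob[ut])
  a + t(a)
}

#' Generate a planted co-cluster benchmark
#'
#' Draws every component described by a [planted_spec()] from a single
#' seeded generator, so a fixed seed reproduces the data exactly. Genes
#' are split evenly into clusters in order (`g0001..` in cluster 1, and
#' so on); annotation set `j` of cluster `c` is named `ANN:c<c>:<j>`.
#'
#' @param spec A [planted_spec()].
#' @return List with `profile` (a [variant_profile()]), `networks`
#'   (list of [molecular_network()]), `annotations`
#'   (an [annotation_collection()], namespace `"planted"`), and
#'   `assignment` (named integer vector, the planted ground truth).
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_g))
  assignment <- stats::setNames(
    rep(seq_len(spec$k_planted),
        each = ceiling(spec$n_g / spec$k_planted))[seq_len(spec$n_g)],
    genes)

  net_names <- c("PPI", "COEX", "GI",
                 paste0("NET", seq_len(max(0L, spec$n_networks - 3L)) + 3L))
  networks <- list()
  for (i in seq_len(spec$n_networks)) {
    adj <- planted_partition_graph(assignment, spec$p_in[i],
                                   spec$p_out[i], genes)
    networks[[net_names[i]]] <- molecular_network(adj, name = net_names[i])
  }

  subjects <- c(sprintf("H%02d", seq_len(spec$n_healthy)),
                sprintf("D%02d", seq_len(spec$n_diseased)))
  phen <- stats::setNames(rep(c("healthy", "diseased"),
                              c(spec$n_healthy, spec$n_diseased)),
                          subjects)
  targets <- list(healthy = spec$healthy_target_clusters,
                  diseased = spec$disease_target_clusters)
  m <- matrix(0, length(subjects), spec$n_g,
              dimnames = list(subjects, genes))
  for (s in subjects) {
    in_target <- assignment %in% targets[[phen[[s]]]]
    rate <- ifelse(in_target, spec$mut_rate_target, spec$mut_rate_bg)
    m[s, ] <- as.numeric(stats::runif(spec$n_g) < rate)
  }
  profile <- variant_profile(m, phenotypes = phen)

  n_in <- round(0.9 * spec$annotation_set_size)
  n_out <- spec$annotation_set_size - n_in
  sets <- list()
  for (cl in seq_len(spec$k_planted)) {
    members <- genes[assignment == cl]
    outside <- genes[assignment != cl]
    for (j in seq_len(spec$annotation_sets_per_cluster)) {
      inside <- sample(members, min(n_in, length(members)))
      bg <- if (n_out > 0L && length(outside) > 0L) {
        sample(outside, min(n_out, length(outside)))
      } else character()
      sets[[sprintf("ANN:c%d:%d", cl, j)]] <- c(inside, bg)
    }
  }
  annotations <- annotation_collection(
    sets,
    descriptions = stats::setNames(
      rep("planted synthetic gene set", length(sets)), names(sets)),
    namespace = "planted")

  list(profile = profile, networks = networks,
       annotations = annotations, assignment = assignment)
}

#' Basic size and density summary of a network
#'
#' @param network A [molecular_network()].
#' @return List with `n_nodes`, `n_edges`, `mean_degree`, `density`.
#' @export
degree_stats <- function(network) {
  n <- nrow(network$adjacency)
  n_edges <- sum(network$adjacency) / 2
  list(n_nodes = n,
       n_edges = n_edges,
       mean_degree = if (n > 0L) 2 * n_edges / n else 0,
       density = if (n > 1L) n_edges / choose(n, 2) else 0)
}
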