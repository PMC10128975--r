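# Shared fixtures built in code.

# Tiny aligned toy: 3 genes, 2 networks over the same universe.
toy_networks <- function() {
  genes <- c("a", "b", "c")
  ppi <- matrix(0, 3, 3, dimnames = list(genes, genes))
  ppi["a", "b"] <- ppi["b", "a"] <- 1
  ppi["b", "c"] <- ppi["c", "b"] <- 1
  gi <- matrix(0, 3, 3, dimnames = list(genes, genes))
  gi["a", "c"] <- gi["c", "a"] <- 1
  list(PPI = molecular_network(ppi, name = "PPI"),
       GI = molecular_network(gi, name = "GI"))
}

# Variant profile with 1 healthy + 2 diseased subjects over 4 genes,
# exercising each specificity label.
toy_profile <- function() {
  m <- rbind(H1 = c(1, 0, 0, 0),
             D1 = c(0, 1, 1, 0),
             D2 = c(0, 1, 0, 0))
  colnames(m) <- c("g1", "g2", "g3", "g4")
  variant_profile(m, phenotypes = c(H1 = "healthy", D1 = "diseased",
                                    D2 = "diseased"))
}

# Random symmetric binary zero-diagonal adjacency.
random_adjacency <- function(n, p, genes = sprintf("g%03d", seq_len(n))) {
  a <- matrix(0, n, n, dimnames = list(genes, genes))
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# Random small fused instance for solver tests.
random_instance <- function(n_s = 4, n_g = 30, n_networks = 2, seed = 0) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_g))
  subjects <- paste0("s", seq_len(n_s))
  M <- matrix(stats::rbinom(n_s * n_g, 1, 0.25), n_s, n_g,
              dimnames = list(subjects, genes))
  R <- replicate(n_networks, random_adjacency(n_g, 0.15, genes),
                 simplify = FALSE)
  phen <- stats::setNames(rep(c("healthy", "diseased"),
                              c(1, n_s - 1)), subjects)
  list(M = M, R = R, phenotypes = phen)
}

# Exactly factorizable instance from known orthonormal indicator factors.
exact_instance <- function(n_g = 20, k1 = 4, n_s = 4, k2 = 2, seed = 3) {
  set.seed(seed)
  gene_cl <- rep(seq_len(k1), length.out = n_g)
  G <- matrix(0, n_g, k1)
  G[cbind(seq_len(n_g), gene_cl)] <- 1
  G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
  subj_cl <- rep(seq_len(k2), length.out = n_s)
  P <- matrix(0, n_s, k2)
  P[cbind(seq_len(n_s), subj_cl)] <- 1
  P <- sweep(P, 2, sqrt(colSums(P^2)), "/")
  S <- matrix(stats::runif(k2 * k1), k2, k1)
  U <- replicate(2, matrix(stats::runif(k1 * k1), k1, k1),
                 simplify = FALSE)
  M <- P %*% S %*% t(G)
  R <- lapply(U, function(u) G %*% u %*% t(G))
  list(M = M, R = R, factors = list(P = P, S = S, G = G, U = U))
}

# Independent brute-force union subnetwork: loop over all gene pairs.
brute_force_union <- function(cluster_genes, networks) {
  edges <- character()
  for (i in seq_along(cluster_genes)) {
    for (j in seq_along(cluster_genes)) {
      if (i >= j) next
      g1 <- cluster_genes[i]
      g2 <- cluster_genes[j]
      hit <- any(vapply(networks, function(net) {
        net$adjacency[g1, g2] == 1
      }, logical(1)))
      if (hit) {
        pair <- sort(c(g1, g2))
        edges <- c(edges, paste(pair[1], pair[2]))
      }
    }
  }
  sort(edges)
}

# Independent BH step-up oracle, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- ranked * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exhaustive hypergeometric tail oracle: enumerate every draw of size N
# from a universe of M genes whose first K are annotated.
hyper_oracle <- function(N, X, M, K) {
  if (N == 0) return(if (X == 0) 1 else 0)
  draws <- utils::combn(M, N)
  overlap <- colSums(draws <= K)
  mean(overlap >= X)
}

# Independent ARI oracle from the contingency-table formula.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_comb - expected) / (max_index - expected)
}
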