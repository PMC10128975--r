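#' Solver configuration for the tri-factorization
#'
#' @param k1 Number of gene clusters (columns of G).
#' @param k2 Number of subject clusters (columns of P); forced to 2 in
#'   fixed-P mode (healthy vs diseased).
#' @param max_iter Maximum multiplicative-update sweeps per restart.
#' @param rel_tol Stop when the relative objective change between sweeps
#'   falls below this value.
#' @param seed Root seed; restart `r` uses `seed + r - 1`.
#' @param n_restarts Number of random restarts; the restart with the
#'   lowest final objective is returned.
#' @param epsilon Small positive guard added to update denominators.
#' @param init Initialization scheme: `"spectral"` (default; k-means on
#'   the leading eigenvectors of the mean network adjacency) or
#'   `"random"` (i.i.d. uniform).
#' @return A list of class `sonmtf_config`.
#' @export
sonmtf_config <- function(k1, k2 = 2L, max_iter = 500L, rel_tol = 1e-6,
                          seed = 0L, n_restarts = 10L, epsilon = 1e-10,
                          init = c("spectral", "random")) {
  init <- match.arg(init)
  stopifnot(k1 >= 1, k2 >= 1, max_iter >= 1, rel_tol > 0,
            n_restarts >= 1, epsilon > 0)
  structure(list(k1 = as.integer(k1), k2 = as.integer(k2),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts), epsilon = epsilon,
                 init = init),
            class = "sonmtf_config")
}

#' Phenotype-derived fixed subject factor
#'
#' Builds the subject cluster-indicator matrix P with one column per
#' phenotype group (healthy first, then diseased) and entries
#' `1/sqrt(group size)` for members, so that `t(P) %*% P` is exactly the
#' identity. Holding P fixed during the factorization forces healthy and
#' diseased subjects into different subject clusters.
#'
#' @param phenotypes Named character vector (`"healthy"`/`"diseased"`).
#' @param subject_order Ordered subject ids (rows of P); defaults to
#'   `names(phenotypes)`.
#' @return Numeric matrix with `length(subject_order)` rows and columns
#'   `healthy`, `diseased`.
#' @export
build_fixed_P <- function(phenotypes, subject_order = names(phenotypes)) {
  missing <- setdiff(subject_order, names(phenotypes))
  if (length(missing) > 0L) {
    stop("missing phenotype for subject: ", missing[1L])
  }
  lab <- phenotypes[subject_order]
  groups <- c("healthy", "diseased")
  sizes <- vapply(groups, function(g) sum(lab == g), numeric(1L))
  if (any(sizes == 0)) {
    stop("both a healthy and a diseased subject are required")
  }
  p <- matrix(0, length(subject_order), 2L,
              dimnames = list(subject_order, groups))
  for (g in groups) p[lab == g, g] <- 1 / sqrt(sizes[[g]])
  p
}

#' Objective value of the joint factorization
#'
#' Squared Frobenius reconstruction error of the variant matrix plus the
#' sum over networks of the squared Frobenius reconstruction errors:
#' `||M - P S t(G)||_F^2 + sum_i ||R_i - G U_i t(G)||_F^2`.
#'
#' @param M Subjects-by-genes matrix.
#' @param R_list List of gene-by-gene adjacency matrices.
#' @param factors List with elements `P` (n_s x k2), `S` (k2 x k1),
#'   `G` (n_g x k1) and `U` (list of k1 x k1 matrices, one per network).
#' @return Non-negative scalar.
#' @export
sonmtf_objective <- function(M, R_list, factors) {
  P <- factors$P; S <- factors$S; G <- factors$G; U <- factors$U
  if (nrow(P) != nrow(M) || ncol(G) != ncol(S) || nrow(S) != ncol(P) ||
      nrow(G) != ncol(M) || length(U) != length(R_list)) {
    stop("factor shapes are inconsistent with the data")
  }
  obj <- sum((M - P %*% S %*% t(G))^2)
  for (i in seq_along(R_list)) {
    if (!all(dim(R_list[[i]]) == nrow(G))) {
      stop("network ", i, " does not match the gene dimension")
    }
    obj <- obj + sum((R_list[[i]] - G %*% U[[i]] %*% t(G))^2)
  }
  obj
}

#' Nonnegative initialization of the factors
#'
#' Two schemes share the seeded generator. `"random"`: S, G and each U
#' are drawn i.i.d. uniform on (0, 1) and the columns of G are scaled
#' to unit Euclidean norm (a soft start towards column orthonormality).
#' `"spectral"` (the default used by [sonmtf_fit()]): the gene factor G
#' starts from a k-means clustering of the leading `k1` eigenvectors of
#' the mean network adjacency -- a near-indicator, near-orthonormal
#' start that conditions the multiplicative updates far better than a
#' dense random G -- and S and U start from their nonnegative
#' projections `t(P) M G` and `t(G) R_i G`. When the spectral embedding
#' cannot support `k1` k-means centers (tiny or degenerate inputs) the
#' scheme falls back to `"random"`. P is either the given fixed matrix
#' or drawn uniformly.
#'
#' @param M Subjects-by-genes matrix.
#' @param R_list List of gene-by-gene adjacency matrices.
#' @param config A [sonmtf_config()].
#' @param fixed_P Optional fixed subject factor; when `NULL`, P is
#'   random with `config$k2` columns.
#' @param seed Seed to use (defaults to `config$seed`).
#' @param method Initialization scheme (defaults to `config$init`).
#' @return Factor list with elements `P`, `S`, `G`, `U`.
#' @export
init_factors <- function(M, R_list, config, fixed_P = NULL,
                         seed = config$seed, method = config$init) {
  n_s <- nrow(M); n_g <- ncol(M)
  k1 <- config$k1; k2 <- if (is.null(fixed_P)) config$k2 else ncol(fixed_P)
  if (k1 > n_g) stop("k1 must not exceed the number of genes")
  if (k2 > n_s) stop("k2 must not exceed the number of subjects")
  set.seed(seed)
  P <- if (is.null(fixed_P)) {
    matrix(stats::runif(n_s * k2), n_s, k2)
  } else fixed_P
  G <- NULL
  if (identical(method, "spectral")) {
    r_avg <- Reduce(`+`, R_list) / length(R_list)
    emb <- eigen(r_avg, symmetric = TRUE)$vectors[, seq_len(k1),
                                                  drop = FALSE]
    km <- tryCatch(stats::kmeans(emb, centers = k1, nstart = 10L),
                   error = function(e) NULL)
    if (!is.null(km)) {
      G <- matrix(0.01, n_g, k1)
      G[cbind(seq_len(n_g), km$cluster)] <- 1
      G <- sweep(G, 2L, sqrt(colSums(G^2)), "/")
      S <- crossprod(P, M) %*% G
      U <- lapply(R_list, function(r) crossprod(G, r %*% G))
    }
  }
  if (is.null(G)) {
    S <- matrix(stats::runif(k2 * k1), k2, k1)
    G <- matrix(stats::runif(n_g * k1), n_g, k1)
    G <- sweep(G, 2L, sqrt(colSums(G^2)), "/")
    U <- replicate(length(R_list), matrix(stats::runif(k1 * k1), k1, k1),
                   simplify = FALSE)
  }
  list(P = P, S = S, G = G, U = U)
}

#' One multiplicative-update sweep
#'
#' Updates S, each U and then G (and P last, unless fixed) with the
#' orthogonality-projected multiplicative rules for the joint objective;
#' the rules for the orthogonal factors G and P take an elementwise
#' square root of the update ratio. All outputs stay nonnegative; a
#' small epsilon guards the denominators.
#'
#' @inheritParams sonmtf_objective
#' @param fixed_P Logical; when `TRUE`, P is returned unchanged.
#' @param epsilon Denominator guard.
#' @return Updated factor list.
#' @export
sonmtf_update_step <- function(M, R_list, factors, fixed_P = TRUE,
                               epsilon = 1e-10) {
  P <- factors$P; S <- factors$S; G <- factors$G; U <- factors$U

  GtG <- crossprod(G)
  S <- S * (crossprod(P, M) %*% G) / (crossprod(P) %*% S %*% GtG + epsilon)

  for (i in seq_along(U)) {
    GtRG <- crossprod(G, R_list[[i]] %*% G)
    U[[i]] <- U[[i]] * GtRG / (GtG %*% U[[i]] %*% GtG + epsilon)
  }

  num <- crossprod(M, P %*% S)
  for (i in seq_along(U)) {
    num <- num + R_list[[i]] %*% (G %*% (U[[i]] + t(U[[i]])))
  }
  den <- G %*% crossprod(G, num) + epsilon
  G <- G * sqrt(num / den)

  if (!fixed_P) {
    numP <- M %*% G %*% t(S)
    denP <- P %*% crossprod(P, numP) + epsilon
    P <- P * sqrt(numP / denP)
  }

  out <- list(P = P, S = S, G = G, U = U)
  if (!all(vapply(out[c("P", "S", "G")],
                  function(x) all(is.finite(x)), logical(1L))) ||
      !all(vapply(U, function(x) all(is.finite(x)), logical(1L)))) {
    stop("non-finite factor entries: the updates diverged")
  }
  out
}

#' Fit the simultaneous orthogonal tri-factorization
#'
#' Runs multiplicative-update sweeps from `n_restarts` random
#' initializations and returns the restart with the lowest final
#' objective. Each restart stops when the relative objective change
#' between sweeps drops below `rel_tol` or after `max_iter` sweeps.
#'
#' @param M Subjects-by-genes binary matrix (a plain matrix or a
#'   [variant_profile()]).
#' @param R_list List of gene-by-gene adjacency matrices (plain matrices
#'   or [molecular_network()] objects).
#' @param config A [sonmtf_config()].
#' @param fixed_P Optional subject factor from [build_fixed_P()]; when
#'   supplied it is held fixed (phenotype-constrained mode).
#' @param warm_start Optional factor list used instead of the scheme of
#'   `config$init` for the first restart.
#' @return A list of class `sonmtf_fit`: `factors`, `objective_trace`
#'   (of the best restart, including the initial value), `converged`,
#'   `iterations_run`, `restart_index`, `objective`.
#' @export
sonmtf_fit <- function(M, R_list, config, fixed_P = NULL,
                       warm_start = NULL) {
  if (inherits(M, "variant_profile")) M <- M$M
  R_list <- lapply(R_list, function(r) {
    if (inherits(r, "molecular_network")) r$adjacency else r
  })
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    factors <- if (r == 1L && !is.null(warm_start)) {
      warm_start
    } else {
      init_factors(M, R_list, config, fixed_P = fixed_P,
                   seed = config$seed + r - 1L)
    }
    trace <- sonmtf_objective(M, R_list, factors)
    converged <- FALSE
    iter <- 0L
    while (iter < config$max_iter) {
      iter <- iter + 1L
      factors <- sonmtf_update_step(M, R_list, factors,
                                    fixed_P = !is.null(fixed_P),
                                    epsilon = config$epsilon)
      obj <- sonmtf_objective(M, R_list, factors)
      prev <- trace[length(trace)]
      trace <- c(trace, obj)
      if (abs(prev - obj) <= config$rel_tol * max(prev, config$epsilon)) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(factors = factors, objective_trace = trace,
                   converged = converged, iterations_run = iter,
                   restart_index = r, objective = obj)
    }
  }
  if (!is.null(fixed_P)) best$factors$P <- fixed_P
  structure(best, class = "sonmtf_fit")
}

#' @export
print.sonmtf_fit <- function(x, ...) {
  cat(sprintf(paste0("sonmtf_fit: objective %.6g after %d iterations ",
                     "(restart %d, %s)\n"),
              x$objective, x$iterations_run, x$restart_index,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Deviation of a factor from column orthonormality
#'
#' Returns `||t(G) G - I||_F / sqrt(k)`, a scale-free measure of how far
#' the factor is from satisfying the orthogonality constraint (0 means
#' exactly orthonormal columns). The constraint is enforced only softly
#' through the update rules, so this is a diagnostic, not an invariant.
#'
#' @param G Nonnegative factor matrix.
#' @return Non-negative scalar.
#' @export
orthogonality_gap <- function(G) {
  k <- ncol(G)
  sqrt(sum((crossprod(G) - diag(k))^2)) / sqrt(k)
}
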