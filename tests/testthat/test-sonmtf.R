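test_that("the fixed subject factor is an orthonormal group indicator", {
  phen <- c(B2 = "healthy", B1 = "diseased", D1 = "diseased",
            S1 = "diseased", S2 = "diseased")
  p <- build_fixed_P(phen)
  expect_equal(dim(p), c(5L, 2L))
  expect_equal(p["B2", "healthy"], 1)
  expect_equal(unname(p[c("B1", "D1", "S1", "S2"), "diseased"]),
               rep(0.5, 4))
  expect_equal(crossprod(p), diag(2), ignore_attr = TRUE)

  p22 <- build_fixed_P(c(a = "healthy", b = "healthy",
                         c = "diseased", d = "diseased"))
  expect_equal(unname(p22[c("a", "b"), "healthy"]),
               rep(1 / sqrt(2), 2))
  expect_equal(crossprod(p22), diag(2), ignore_attr = TRUE)

  expect_error(build_fixed_P(c(a = "diseased", b = "diseased")),
               "healthy")
})

test_that("the objective matches hand-computed Frobenius norms", {
  id2 <- diag(2)
  f <- list(P = id2, S = id2, G = id2, U = list(id2))
  expect_equal(sonmtf_objective(id2, list(id2), f), 0)

  z <- matrix(0, 2, 2)
  f0 <- list(P = z, S = z, G = z, U = list(z))
  expect_equal(sonmtf_objective(id2, list(id2), f0), 4)  # ||M||^2+||R||^2

  fG0 <- list(P = id2, S = id2, G = z, U = list(id2))
  expect_equal(sonmtf_objective(id2, list(id2), fG0), 4)  # 2 + 2

  bad <- list(P = id2, S = id2, G = matrix(0, 3, 2), U = list(id2))
  expect_error(sonmtf_objective(id2, list(id2), bad), "shape")
})

test_that("initialization is seeded, nonnegative and mode-dependent", {
  inst <- random_instance(seed = 1)
  cfg <- sonmtf_config(k1 = 4, seed = 5, init = "random")
  f1 <- init_factors(inst$M, inst$R, cfg)
  f2 <- init_factors(inst$M, inst$R, cfg)
  expect_identical(f1, f2)
  expect_true(all(f1$S > 0 & f1$S < 1))
  expect_true(all(unlist(f1$U) > 0 & unlist(f1$U) < 1))
  expect_equal(sqrt(colSums(f1$G^2)), rep(1, 4))

  f3 <- init_factors(inst$M, inst$R, cfg, seed = 6)
  expect_false(identical(f1$G, f3$G))

  p_fix <- build_fixed_P(inst$phenotypes)
  f4 <- init_factors(inst$M, inst$R, cfg, fixed_P = p_fix)
  expect_identical(f4$P, p_fix)

  cfg_s <- sonmtf_config(k1 = 4, seed = 5, init = "spectral")
  fs1 <- init_factors(inst$M, inst$R, cfg_s)
  fs2 <- init_factors(inst$M, inst$R, cfg_s)
  expect_identical(fs1, fs2)
  expect_true(all(fs1$G >= 0))
  expect_true(all(fs1$S >= 0))
})

test_that("an exact factorization with orthonormal G is a fixed point", {
  inst <- exact_instance()
  before <- inst$factors
  after <- sonmtf_update_step(inst$M, inst$R, before, fixed_P = TRUE)
  expect_equal(after$S, before$S, tolerance = 1e-6)
  expect_equal(after$G, before$G, tolerance = 1e-6)
  for (i in seq_along(after$U)) {
    expect_equal(after$U[[i]], before$U[[i]], tolerance = 1e-6)
  }
  expect_identical(after$P, before$P)
})

test_that("update sweeps keep factors nonnegative and do not increase the objective", {
  inst <- random_instance(n_s = 4, n_g = 30, seed = 0)
  cfg <- sonmtf_config(k1 = 3, seed = 0, init = "spectral")
  p_fix <- build_fixed_P(inst$phenotypes)
  f <- init_factors(inst$M, inst$R, cfg, fixed_P = p_fix)
  obj <- sonmtf_objective(inst$M, inst$R, f)
  for (i in 1:50) {
    f <- sonmtf_update_step(inst$M, inst$R, f, fixed_P = TRUE)
    new_obj <- sonmtf_objective(inst$M, inst$R, f)
    expect_lte(new_obj, obj + 1e-8 * obj)
    expect_true(all(f$G >= 0) && all(f$S >= 0) &&
                  all(unlist(f$U) >= 0))
    expect_identical(f$P, p_fix)  # fixed P is bit-identical
    obj <- new_obj
  }
})

test_that("fitting descends and returns a consistent trace", {
  inst <- random_instance(n_s = 5, n_g = 40, n_networks = 3, seed = 2)
  cfg <- sonmtf_config(k1 = 4, max_iter = 120, seed = 2, n_restarts = 2)
  fit <- sonmtf_fit(inst$M, inst$R, cfg)
  tr <- fit$objective_trace
  expect_lt(tr[length(tr)], tr[1])
  expect_true(all(diff(tr) <= 1e-8 * head(tr, -1)))
  expect_equal(fit$objective,
               sonmtf_objective(inst$M, inst$R, fit$factors))
  expect_length(tr, fit$iterations_run + 1L)
})

test_that("fixed-P mode returns the constructed P bit-identically", {
  inst <- random_instance(seed = 4)
  p_fix <- build_fixed_P(inst$phenotypes)
  cfg <- sonmtf_config(k1 = 3, max_iter = 60, seed = 4, n_restarts = 2)
  fit <- sonmtf_fit(inst$M, inst$R, cfg, fixed_P = p_fix)
  expect_identical(fit$factors$P, p_fix)
  expect_equal(crossprod(fit$factors$P), diag(2), ignore_attr = TRUE)
})

test_that("a warm start at the true factors stays at the exact solution", {
  inst <- exact_instance()
  cfg <- sonmtf_config(k1 = 4, k2 = 2, max_iter = 50, seed = 0,
                       n_restarts = 1)
  fit <- sonmtf_fit(inst$M, inst$R, cfg, fixed_P = inst$factors$P,
                    warm_start = inst$factors)
  data_norm <- sum(inst$M^2) + sum(vapply(inst$R, function(r) sum(r^2),
                                          numeric(1)))
  expect_lt(fit$objective, 1e-6 * data_norm)
})

test_that("soft orthogonality of G improves from initialization to convergence", {
  d <- generate_planted(planted_spec(n_g = 100, seed = 11))
  M <- d$profile$M
  R <- lapply(d$networks, function(n) n$adjacency)
  p_fix <- build_fixed_P(d$profile$phenotypes)
  cfg <- sonmtf_config(k1 = 5, max_iter = 150, seed = 11, n_restarts = 1,
                       init = "random")
  f0 <- init_factors(M, R, cfg, fixed_P = p_fix, method = "random")
  fit <- sonmtf_fit(M, R, cfg, fixed_P = p_fix, warm_start = f0)
  expect_lt(orthogonality_gap(fit$factors$G), orthogonality_gap(f0$G))
})

test_that("planted gene clusters are recovered from the factorization", {
  d <- generate_planted(planted_spec(n_g = 120, k_planted = 4,
                                     seed = 21))
  cfg <- sonmtf_config(k1 = 4, max_iter = 200, seed = 21, n_restarts = 2)
  p_fix <- build_fixed_P(d$profile$phenotypes)
  fit <- sonmtf_fit(d$profile, d$networks, cfg, fixed_P = p_fix)
  g <- fit$factors$G
  rownames(g) <- d$profile$genes
  cl <- suppressWarnings(extract_clusters(g))
  expect_gte(compare_partitions(cl, d$assignment), 0.8)
})
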