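test_that("the hypergeometric tail matches the worked fraction and edge cases", {
  expect_equal(hypergeom_p(5, 3, 20, 4), 496 / 15504, tolerance = 1e-12)
  expect_equal(hypergeom_p(5, 0, 20, 4), 1)
  # cluster = universe forces X = K and p = 1
  expect_equal(hypergeom_p(20, 4, 20, 4), 1)
  expect_error(hypergeom_p(5, 6, 20, 4), "X")
  expect_error(hypergeom_p(25, 3, 20, 4), "M_ann")
})

test_that("the hypergeometric tail equals exhaustive enumeration for small universes", {
  for (m in c(5, 8, 12)) {
    for (n in 1:m) {
      for (k in 1:m) {
        for (x in 0:min(n, k)) {
          expect_equal(hypergeom_p(n, x, m, k), hyper_oracle(n, x, m, k),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("the tail probability is non-increasing in X", {
  for (x in 1:4) {
    expect_lte(hypergeom_p(5, x, 20, 4), hypergeom_p(5, x - 1, 20, 4))
  }
})

test_that("p-value adjustment reproduces the step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(0.3, 5)), rep(0.3, 5))
  expect_error(adjust_pvalues(c(0.1, 1.2)), "0, 1")

  set.seed(123)
  for (rep in 1:200) {
    p <- runif(sample(1:50, 1))
    adj <- adjust_pvalues(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("cluster enrichment reports counts and the planted toy p-value", {
  # 20-gene universe, all annotated via a background set; cluster of 5
  # containing 3 of an annotation's 4 genes
  universe <- sprintf("g%02d", 1:20)
  ann <- annotation_collection(
    list(TARGET = c("g01", "g02", "g03", "g18"),
         ALL = universe),
    namespace = "toy")
  assignment <- stats::setNames(rep(2L, 20), universe)
  assignment[c("g01", "g02", "g03", "g04", "g05")] <- 1L
  clustering <- structure(list(assignment = assignment, k = 2L),
                          class = "gene_clustering")
  res <- enrich_clusters(clustering, ann, universe)
  row <- res[res$cluster_id == 1 & res$annotation_id == "TARGET", ]
  expect_equal(row$N, 5L)
  expect_equal(row$X, 3L)
  expect_equal(row$M_ann, 20L)
  expect_equal(row$K, 4L)
  expect_equal(row$p_raw, 496 / 15504, tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p_raw))

  # annotations without cluster overlap yield no row
  ann2 <- annotation_collection(list(ELSEWHERE = c("zz1", "zz2")),
                                namespace = "toy2")
  expect_equal(nrow(enrich_clusters(clustering, ann2, universe)), 0L)
})

test_that("label-shuffled enrichment stays near the nominal false-positive rate", {
  set.seed(5)
  universe <- sprintf("g%03d", 1:60)
  ann <- annotation_collection(
    stats::setNames(lapply(1:6, function(i) sample(universe, 10)),
                    paste0("S", 1:6)),
    namespace = "null")
  n_sig <- 0L
  n_tests <- 0L
  for (shuffle in 1:100) {
    assignment <- stats::setNames(sample(rep(1:3, each = 20)), universe)
    clustering <- structure(list(assignment = assignment, k = 3L),
                            class = "gene_clustering")
    res <- enrich_clusters(clustering, ann, universe)
    n_sig <- n_sig + sum(res$significant)
    n_tests <- n_tests + nrow(res)
  }
  expect_lt(n_sig / n_tests, 0.10)
})

test_that("cluster quality is the percentage of enriched clusters", {
  res <- data.frame(cluster_id = c(1, 1, 2, 3, 4),
                    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(cluster_quality(res, 4), 75)
  res$significant <- FALSE
  expect_equal(cluster_quality(res, 4), 0)
  expect_equal(cluster_quality(res[0, ], 4), 0)

  # planted annotation-aligned clusters reach 100%
  d <- generate_planted(planted_spec(n_g = 100, seed = 8))
  clustering <- structure(list(assignment = d$assignment, k = 5L),
                          class = "gene_clustering")
  res2 <- enrich_clusters(clustering, d$annotations,
                          d$profile$genes)
  expect_equal(cluster_quality(res2, 5), 100)
})
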