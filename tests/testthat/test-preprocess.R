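test_that("co-expression thresholding keeps the strongest fraction", {
  set.seed(42)
  genes <- sprintf("g%03d", 1:60)
  pairs <- t(combn(genes, 2))[sample(1770, 300), ]
  w <- sample(seq_len(300)) / 300  # 300 distinct weights
  el <- edge_list(pairs[, 1], pairs[, 2], weight = w)

  kept <- threshold_coexpression(el, keep_fraction = 0.01)
  expect_equal(nrow(kept), 3L)
  # sort-based oracle: the 3 largest weights
  top3 <- el[order(-el$weight), ][1:3, ]
  expect_setequal(paste(kept$from, kept$to), paste(top3$from, top3$to))

  all_kept <- threshold_coexpression(el, keep_fraction = 1)
  expect_equal(nrow(all_kept), nrow(el))

  empty <- threshold_coexpression(edge_list(character(), character(),
                                            weight = numeric()), 0.01)
  expect_equal(nrow(empty), 0L)
})

test_that("thresholding invariants hold across random inputs", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:80, 1)
    genes <- sprintf("g%02d", 1:30)
    pairs <- t(combn(genes, 2))[sample(435, n), , drop = FALSE]
    el <- edge_list(pairs[, 1], pairs[, 2], weight = runif(n))
    frac <- runif(1, 0.05, 1)
    kept <- threshold_coexpression(el, keep_fraction = frac)
    expect_equal(nrow(kept), ceiling(frac * nrow(el)))
    keys <- paste(el$from, el$to)
    expect_true(all(paste(kept$from, kept$to) %in% keys))
    kept_w <- el$weight[match(paste(kept$from, kept$to), keys)]
    dropped_w <- el$weight[!(keys %in% paste(kept$from, kept$to))]
    if (length(dropped_w) > 0) {
      expect_gte(min(kept_w), max(dropped_w))
    }
  }
})

test_that("the universe is anchored on PPI incidence", {
  ppi <- edge_list(c("a", "b"), c("b", "c"))
  coex <- edge_list(c("a", "c", "c"), c("b", "d", "a"))
  gi <- edge_list("a", "c")
  out <- build_universe_and_align(ppi, list(COEX = coex, GI = gi))
  expect_equal(out$universe, c("a", "b", "c"))
  # COEX edges touching d dropped; (a,b) and (a,c) stay
  expect_equal(sum(out$networks$COEX$adjacency) / 2, 2)
  expect_equal(sum(out$networks$GI$adjacency) / 2, 1)
  expect_equal(out$networks$GI$adjacency["a", "c"], 1)

  for (net in out$networks) {
    a <- net$adjacency
    expect_identical(rownames(a), out$universe)
    expect_true(isSymmetric(unname(a)))
    expect_true(all(diag(a) == 0))
  }
  # every universe gene has PPI degree >= 1
  expect_true(all(rowSums(out$networks$PPI$adjacency) >= 1))
})

test_that("variant matrices apply the consequence whitelist", {
  records <- data.frame(
    subject_id = c("s1", "s1", "s1", "s2"),
    gene = c("g1", "g1", "g2", "g1"),
    consequence = c("missense", "frameshift", "synonymous", "Nonsense"))
  universe <- c("g1", "g2", "g3")
  vp <- suppressMessages(
    build_variant_matrix(records, c("s1", "s2"), universe))
  expect_equal(vp$M["s1", ], c(g1 = 1, g2 = 0, g3 = 0))
  expect_equal(vp$M["s2", ], c(g1 = 1, g2 = 0, g3 = 0))

  # empty records give an all-zero matrix
  empty <- build_variant_matrix(records[0, ], c("s1", "s2"), universe)
  expect_true(all(empty$M == 0))

  # genes outside the universe are ignored with a message
  rec2 <- data.frame(subject_id = "s1", gene = "gX",
                     consequence = "missense")
  expect_message(build_variant_matrix(rec2, "s1", universe), "universe")

  # unknown subject errors
  rec3 <- data.frame(subject_id = "sZ", gene = "g1",
                     consequence = "missense")
  expect_error(build_variant_matrix(rec3, c("s1", "s2"), universe),
               "sZ")
})

test_that("gene specificity follows the healthy/diseased definitions", {
  m <- rbind(H1 = c(1, 0, 0, 0, 1),
             D1 = c(0, 1, 1, 0, 1),
             D2 = c(0, 1, 0, 0, 0))
  colnames(m) <- paste0("g", 1:5)
  vp <- variant_profile(m, c(H1 = "healthy", D1 = "diseased",
                             D2 = "diseased"))
  lab <- classify_gene_specificity(vp)
  expect_equal(as.character(lab[["g1"]]), "healthy_specific")
  expect_equal(as.character(lab[["g2"]]), "disease_specific")
  expect_equal(as.character(lab[["g3"]]), "mixed")
  expect_equal(as.character(lab[["g4"]]), "unmutated")
  expect_equal(as.character(lab[["g5"]]), "mixed")
  expect_equal(sum(table(lab)), 5L)

  # permuting diseased subjects leaves labels unchanged
  vp2 <- variant_profile(m[c("H1", "D2", "D1"), ], vp$phenotypes)
  expect_equal(classify_gene_specificity(vp2)[names(lab)], lab)

  # relaxed mode: >= 1 diseased subject suffices
  lab_soft <- classify_gene_specificity(vp, mode = "at_least_k",
                                        min_diseased = 1)
  expect_equal(as.character(lab_soft[["g3"]]), "disease_specific")

  vp_all_d <- variant_profile(m, c(H1 = "diseased", D1 = "diseased",
                                   D2 = "diseased"))
  expect_error(classify_gene_specificity(vp_all_d), "healthy")
})

test_that("profiles align to a universe with zero-filled columns", {
  vp <- toy_profile()
  aligned <- align_profile_to_universe(vp, c("g2", "g9", "g1"))
  expect_equal(aligned$genes, c("g2", "g9", "g1"))
  expect_equal(unname(aligned$M[, "g9"]), c(0, 0, 0))
  expect_equal(aligned$M[, "g2"], vp$M[, "g2"])
})
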