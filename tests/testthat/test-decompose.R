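test_that("mapping recovers a planted permutation of orthogonal embeddings", {
  n <- 6
  E <- diag(n)  # n orthogonal unit embeddings
  perm <- c(3, 1, 4, 6, 2, 5)
  S <- embedding_matrix(E[perm, ], sprintf("cell%d", 1:n), "text")
  G <- embedding_matrix(E, sprintf("spot%d", 1:n), "text")
  M <- fit_mapping(S, G, decompose_config(max_iter = 400, seed = 1))
  expect_equal(unname(rowSums(M$weights)), rep(1, n), tolerance = 1e-6)
  expect_equal(max.col(M$weights), perm)
  ## loss decreased
  expect_lt(tail(M$loss_trace, 1), M$loss_trace[1])
})

test_that("mapping degenerate cases behave as the parameterization forces", {
  ## single spot -> every row is exactly 1
  S <- embedding_matrix(matrix(rnorm(3 * 8), 3), paste0("c", 1:3), "text")
  G <- embedding_matrix(matrix(rnorm(8), 1), "s1", "text")
  M <- fit_mapping(S, G, decompose_config(max_iter = 5))
  expect_equal(unname(M$weights[, 1]), rep(1, 3))
  ## one cell, no prior: row-softmax keeps a distribution over spots
  M1 <- fit_mapping(S$vectors[1, , drop = FALSE],
                    matrix(rnorm(2 * 8), 2), decompose_config(max_iter = 5))
  expect_equal(sum(M1$weights), 1, tolerance = 1e-9)
})

test_that("row-stochasticity holds throughout optimization on random fixtures", {
  set.seed(61)
  S <- embedding_matrix(matrix(rnorm(10 * 16), 10), paste0("c", 1:10), "text")
  G <- embedding_matrix(matrix(rnorm(7 * 16), 7), paste0("s", 1:7), "text")
  for (iters in c(1, 10, 100)) {
    M <- fit_mapping(S, G, decompose_config(max_iter = iters, seed = 2))
    expect_true(all(M$weights >= 0 & M$weights <= 1))
    expect_equal(unname(rowSums(M$weights)), rep(1, 10), tolerance = 1e-6)
  }
})

test_that("cluster aggregation equals brute-force per-label averaging", {
  set.seed(62)
  E <- matrix(rnorm(12 * 8), 12)
  emb <- embedding_matrix(E, sprintf("c%d", 1:12), "text")
  labels <- rep(c("a", "b", "c"), each = 4)
  agg <- cluster_aggregate(emb, labels)
  for (l in c("a", "b", "c")) {
    manual <- colMeans(emb$vectors[labels == l, ])
    manual <- manual / sqrt(sum(manual^2))
    expect_equal(unname(agg$embeddings$vectors[l, ]), unname(manual),
                 tolerance = 1e-12)
  }
  expect_equal(unname(agg$sizes), rep(4L, 3))
  ## two identical cells per cluster -> cluster embedding equals the member
  twin <- embedding_matrix(E[c(1, 1, 2, 2), ], paste0("t", 1:4), "text")
  aggt <- cluster_aggregate(twin, c("x", "x", "y", "y"))
  expect_equal(unname(aggt$embeddings$vectors["x", ]),
               unname(twin$vectors[1, ]), tolerance = 1e-12)
  expect_error(cluster_aggregate(emb, labels[1:3]), "one label per cell")
})

test_that("cell-type probabilities pool mapping mass by label", {
  W <- rbind(c(0.8, 0.2), c(0.6, 0.4), c(0.1, 0.9))
  M <- structure(list(weights = W, cell_ids = paste0("c", 1:3),
                      spot_ids = c("s1", "s2")), class = "mapping_matrix")
  ## all cells one type -> all mass on that type
  P1 <- celltype_probabilities(M, rep("t", 3))
  expect_equal(unname(P1$probabilities[, 1]), c(1, 1))
  ## doubling sizes leaves P unchanged
  P <- celltype_probabilities(M, c("a", "a", "b"))
  P2 <- celltype_probabilities(M, c("a", "a", "b"), sizes = c(2, 2, 2))
  expect_equal(P$probabilities, P2$probabilities)
  ## manual pooling check
  expect_equal(P$probabilities["s1", "a"], (0.8 + 0.6) / (0.8 + 0.6 + 0.1))
  expect_equal(unname(rowSums(P$probabilities)), c(1, 1), tolerance = 1e-12)
})

test_that("NMS keeps only each spot's maximum at its original value", {
  P <- structure(list(probabilities = rbind(c(0.5, 0.3, 0.2),
                                            c(0.4, 0.4, 0.2)),
                      types = c("a", "b", "c")), class = "celltype_map")
  r <- nms_refine(P)
  expect_equal(unname(r$probabilities[1, ]), c(0.5, 0, 0))
  ## tie broken by type order, flagged
  expect_equal(unname(r$probabilities[2, ]), c(0.4, 0, 0))
  expect_true(r$tie[2])
  expect_false(r$tie[1])
  ## idempotent; exactly one nonzero per row equal to the pre-NMS max
  r2 <- nms_refine(r)
  expect_equal(r2$probabilities, r$probabilities)
  expect_equal(unname(rowSums(r$probabilities > 0)), c(1, 1))
  expect_equal(unname(apply(r$probabilities, 1, max)),
               unname(apply(P$probabilities, 1, max)))
})

test_that("slide decomposition recovers planted composition in st mode", {
  ms <- make_slide(synth_config(n_spots = 200, n_genes = 80, seed = 63))
  be <- hash_encoder(d = 64, seed = 1)
  cell_sent <- lapply(seq_len(nrow(ms$truth$cell_counts)), function(i)
    build_gene_sentence(ms$truth$cell_counts[i, ],
                        colnames(ms$truth$cell_counts), gene_maps(), 50,
                        paste0("cell_", i)))
  ref_emb <- encode_text(be, cell_sent)
  P <- decompose_slide(ref_emb, ms$truth$cell_labels, ms$slide, be,
                       mode = "st",
                       cfg = decompose_config(cluster_level = TRUE, seed = 1))
  pr <- P$probabilities[, colnames(ms$truth$fractions)]
  js <- vapply(seq_len(nrow(pr)), function(i)
    js_divergence(pr[i, ], ms$truth$fractions[i, ]), 0)
  expect_lt(mean(js), 0.1)
  acc <- mean(colnames(pr)[max.col(pr)] == ms$truth$domain)
  expect_gt(acc, 0.9)
  ## determinism at fixed seed
  P2 <- decompose_slide(ref_emb, ms$truth$cell_labels, ms$slide, be,
                        mode = "st",
                        cfg = decompose_config(cluster_level = TRUE, seed = 1))
  expect_equal(P$probabilities, P2$probabilities)
})

test_that("a reference type absent from the tissue gets the least mass", {
  ms <- make_slide(synth_config(n_spots = 150, n_genes = 100, n_types = 4,
                                seed = 64))
  be <- hash_encoder(d = 64, seed = 1)
  ## drop every spot where type4 dominates: type4 becomes (nearly) absent
  keep <- ms$truth$domain != "type4"
  slide <- subset_spots(ms$slide, keep)
  cell_sent <- lapply(seq_len(nrow(ms$truth$cell_counts)), function(i)
    build_gene_sentence(ms$truth$cell_counts[i, ],
                        colnames(ms$truth$cell_counts), gene_maps(), 50,
                        paste0("cell_", i)))
  ref_emb <- encode_text(be, cell_sent)
  P <- decompose_slide(ref_emb, ms$truth$cell_labels, slide, be, mode = "st",
                       cfg = decompose_config(cluster_level = TRUE, seed = 1))
  means <- colMeans(P$probabilities)
  expect_equal(names(which.min(means)), "type4")
})
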