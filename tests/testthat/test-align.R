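test_that("point augmentation scales PC columns against normalized coords", {
  set.seed(21)
  coords <- cbind(runif(30, 0, 500), runif(30, 0, 500))
  emb <- embedding_matrix(matrix(rnorm(30 * 16), 30), sprintf("s%d", 1:30),
                          "text")
  ## gamma = 0 reduces to the normalization map
  a0 <- augment_points(coords, emb, gamma = 0)
  expect_equal(ncol(a0), 2)
  expect_equal(unname(colMeans(a0)), c(0, 0), tolerance = 1e-12)
  expect_equal(max(abs(a0)), 1, tolerance = 1e-12)
  ## identical embeddings -> zero PC columns
  same <- embedding_matrix(matrix(1, 30, 16), sprintf("s%d", 1:30), "text")
  a_same <- augment_points(coords, same, gamma = 1)
  expect_equal(unname(a_same[, 3:4]), matrix(0, 30, 2))
  ## gamma = 1 -> PC column sd equals pooled coordinate sd
  a1 <- augment_points(coords, emb, gamma = 1)
  pooled <- sd(as.numeric(a1[, 1:2]))
  expect_equal(sd(a1[, 3]), pooled, tolerance = 1e-9)
  expect_equal(sd(a1[, 4]), pooled, tolerance = 1e-9)
  expect_error(augment_points(coords[1:2, ], emb$vectors[1:2, ], 1),
               "at least 3")
})

test_that("one EM step reproduces the textbook update to 1e-10", {
  set.seed(31)
  for (rep in 1:3) {
    Y <- matrix(rnorm(8, sd = 0.5), 4, 2)
    X <- Y + matrix(rnorm(8, sd = 0.1), 4, 2)
    pars <- cpd_params(beta = 1.5, lambda = 2, w = 0, max_iter = 1,
                       clip_W = FALSE, gamma = 0)
    res <- cpd_align(Y, X, pars, normalize = FALSE)
    ora <- oracle_cpd_step(X, Y, beta = 1.5, lambda = 2, w = 0)
    expect_equal(res$W, ora$W, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$sigma2_final, ora$sigma2, tolerance = 1e-10)
    expect_equal(res$aligned_coords, Y + exp(-as.matrix(dist(Y))^2 /
                   (2 * 1.5^2)) %*% ora$W, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("one EM step with outlier weight matches the oracle too", {
  set.seed(32)
  Y <- matrix(rnorm(12, sd = 0.5), 6, 2)
  X <- Y[c(2:6, 1), ] + matrix(rnorm(12, sd = 0.2), 6, 2)
  res <- cpd_align(Y, X, cpd_params(beta = 2, lambda = 3, w = 0.2,
                                    max_iter = 1, gamma = 0),
                   normalize = FALSE)
  ora <- oracle_cpd_step(X, Y, beta = 2, lambda = 3, w = 0.2)
  expect_equal(res$W, ora$W, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$sigma2_final, ora$sigma2, tolerance = 1e-10)
})

test_that("identity registration leaves points essentially unmoved", {
  set.seed(33)
  pts <- cbind(runif(50, 0, 300), runif(50, 0, 300))
  ## exact self-registration drives sigma^2 to its underflow clamp
  res <- suppressWarnings(cpd_align(pts, pts, cpd_params()))
  diam <- max(dist(pts))
  expect_lt(mean(res$displacement_per_spot), 1e-6 * diam)
})

test_that("a rotated and jittered copy is recovered by coordinate CPD", {
  set.seed(34)
  pts <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tgt <- sweep(sweep(pts, 2, colMeans(pts)) %*% t(R), 2,
               colMeans(pts) + c(40, -25), "+")
  pre <- mean(sqrt(rowSums((pts - tgt)^2)))
  res <- suppressWarnings(cpd_align(pts, tgt, cpd_params(w = 0, gamma = 0)))
  ## mean distance to nearest target after alignment < 5% of before
  d2 <- outer(rowSums(res$aligned_coords^2), rowSums(tgt^2), "+") -
    2 * res$aligned_coords %*% t(tgt)
  post <- mean(sqrt(pmax(apply(d2, 1, min), 0)))
  expect_lt(post, 0.05 * pre)
})

test_that("sigma^2 stays nonnegative across iterations and fixtures", {
  set.seed(35)
  for (rep in 1:5) {
    Y <- matrix(rnorm(20), 10, 2)
    X <- matrix(rnorm(16), 8, 2)
    for (it in c(1, 3, 10)) {
      res <- cpd_align(Y, X, cpd_params(max_iter = it, w = 0.1, gamma = 0),
                       normalize = FALSE)
      expect_gte(res$sigma2_final, 0)
    }
  }
})

test_that("rigid fit recovers exact rotations and rejects reflections", {
  set.seed(36)
  pts <- cbind(runif(40, -50, 50), runif(40, -50, 50))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% t(R), 2, c(7, -3), "+")
  fit <- rigid_regularize(pts, moved)
  expect_equal(fit$angle, th, tolerance = 1e-6)
  expect_equal(max(fit$residuals), 0, tolerance = 1e-8)
  ## identity case
  fit0 <- rigid_regularize(pts, pts)
  expect_equal(fit0$angle, 0, tolerance = 1e-10)
  expect_equal(unname(fit0$translation), c(0, 0), tolerance = 1e-10)
  ## reflected target still yields a proper rotation (det + 1)
  refl <- cbind(-moved[, 1], moved[, 2])
  fitr <- rigid_regularize(pts, refl)
  expect_equal(det(fitr$rotation), 1, tolerance = 1e-10)
  ## collinear degenerate input -> identity with warning
  line <- cbind(1:10, 2 * (1:10))
  expect_warning(fitc <- rigid_regularize(line, line + 5), "degenerate")
  expect_equal(fitc$rotation, diag(2))
})

test_that("slide alignment recovers a perturbed copy in both modes", {
  ms <- make_slide(synth_config(n_spots = 150, n_genes = 80, seed = 41))
  pert <- perturb_alignment(ms$slide, coord_noise_sd = 5,
                            rotation_deg = 10, seed = 42)
  pre <- mean(sqrt(rowSums((pert$slide$coords - pert$true_coords)^2)))
  ## st_to_st with the hash encoder
  res <- align_slides(pert$slide, ms$slide, hash_encoder(d = 32),
                      mode = "st_to_st")
  post <- mean(sqrt(rowSums((res$final_coords - pert$true_coords)^2)))
  expect_lt(post, 0.1 * pre)
  ## image_to_st with a fine-tuned toy backend
  be <- toy_dual_encoder(ms$slide$gene_symbols, d = 32, seed = 1)
  resi <- align_slides(pert$slide, ms$slide, be, mode = "image_to_st")
  posti <- mean(sqrt(rowSums((resi$final_coords - pert$true_coords)^2)))
  expect_lt(posti, 0.5 * pre)
  ## two copies of the same slide -> near-zero displacement
  res0 <- suppressWarnings(align_slides(ms$slide, ms$slide,
                                        hash_encoder(d = 32),
                                        mode = "st_to_st"))
  expect_lt(mean(res0$displacement_per_spot), 1)
  ## image mode without patches is a capability error
  bare <- ms$slide; bare$patches <- NULL
  expect_error(align_slides(bare, ms$slide, be, mode = "image_to_st"),
               "patches")
})

test_that("alignment evaluation reports expression agreement", {
  ms <- make_slide(synth_config(n_spots = 80, n_genes = 60, seed = 43))
  slide <- normalize_counts(ms$slide)
  ## identity alignment -> per-gene correlation 1
  ev <- evaluate_alignment(slide$coords, slide$lognorm, slide, n_hvg = 20)
  expect_equal(ev$median_pcc, 1, tolerance = 1e-12)
  expect_equal(ev$median_tau, 1, tolerance = 1e-12)
  ## shuffled expression -> correlation near zero
  set.seed(44)
  shuf <- slide$lognorm[sample(n_spots(slide)), ]
  evs <- suppressWarnings(
    evaluate_alignment(slide$coords, shuf, slide, n_hvg = 20))
  expect_lt(abs(evs$median_pcc), 0.25)
  ## zero radius -> no matches
  expect_error(evaluate_alignment(slide$coords + 1000, slide$lognorm, slide,
                                  match_radius = 0), "no aligned spot")
})
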