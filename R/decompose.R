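#' Configuration for probabilistic cell-to-spot mapping
#'
#' @param max_iter maximum optimizer iterations (default 1000).
#' @param learning_rate Adam step size (default 0.1).
#' @param density_prior_weight nonnegative weight of an optional
#'   KL(spot density || uniform) penalty encouraging cells to spread
#'   evenly over spots; default 0 (off).
#' @param cluster_level map cell clusters instead of individual cells.
#' @param tol relative loss-change convergence threshold.
#' @param seed RNG seed for the initialization.
#' @return a `decompose_config` list.
#' @export
decompose_config <- function(max_iter = 1000, learning_rate = 0.1,
                             density_prior_weight = 0,
                             cluster_level = FALSE, tol = 1e-6, seed = 1) {
  assert_scalar_num(density_prior_weight, "density_prior_weight", 0)
  assert_scalar_num(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  structure(list(max_iter = as.integer(max_iter),
                 learning_rate = learning_rate,
                 density_prior_weight = density_prior_weight,
                 cluster_level = isTRUE(cluster_level), tol = tol,
                 seed = as.integer(seed)),
            class = "decompose_config")
}

## loss and gradient of sum_k cosdist((M^T S)_k, G_k) wrt M (cells x spots)
mapping_loss_grad <- function(M, S, G, prior_w) {
  A <- t(M) %*% S                      # spots x d
  na <- sqrt(colSums(A^2)); ng <- sqrt(colSums(G^2))
  na[na == 0] <- 1e-300; ng[ng == 0] <- 1e-300
  dots <- colSums(A * G)
  cosv <- dots / (na * ng)
  loss <- sum(1 - cosv)
  ## d/dA_k of -cos: -(G_k/(|A||G|) - dot * A_k/(|A|^3 |G|))
  dA <- -(sweep(G, 2, na * ng, "/") -
            sweep(A, 2, dots / (na^3 * ng), "*"))
  dM <- S %*% t(dA)                    # cells x spots
  if (prior_w > 0) {
    p <- colSums(M) / nrow(M)
    p <- pmax(p, 1e-12)
    loss <- loss + prior_w * sum(p * log(p * length(p)))
    dM <- dM + prior_w * matrix((log(p * length(p)) + 1) / nrow(M),
                                nrow(M), ncol(M), byrow = TRUE)
  }
  list(loss = loss, dM = dM)
}

#' Fit a probabilistic cell-to-spot mapping matrix
#'
#' Optimizes a row-stochastic mapping M (cells x spots; each row a
#' probability distribution of one cell over spots) so that the projected
#' reference embeddings `M^T S` match the spatial embeddings G, by
#' minimizing the sum over embedding dimensions of the cosine distance
#' between the projected and observed columns, optionally plus
#' `density_prior_weight * KL(spot density || uniform)` where spot density
#' is the normalized column sum of M. Row-stochasticity is guaranteed by
#' construction: M is the row-wise softmax of a free matrix optimized with
#' Adam. The run is deterministic at a fixed seed and the logged loss
#' trajectory is checked to be non-increasing across checkpoints.
#'
#' @param S reference `embedding_matrix` (cells or clusters x d).
#' @param G target `embedding_matrix` (spots x d).
#' @param cfg a [decompose_config()].
#' @return a `mapping_matrix`: list with `weights` (cells x spots, rows
#'   summing to 1), `cell_ids`, `spot_ids`, `loss_trace`.
#' @export
fit_mapping <- function(S, G, cfg = decompose_config()) {
  Sm <- if (inherits(S, "embedding_matrix")) S$vectors else as.matrix(S)
  Gm <- if (inherits(G, "embedding_matrix")) G$vectors else as.matrix(G)
  if (ncol(Sm) != ncol(Gm)) stopf("embedding dimensions differ")
  n_cells <- nrow(Sm); n_spots <- nrow(Gm)
  if (n_cells < 1 || n_spots < 1) stopf("need >= 1 cell and >= 1 spot")
  softmax_rows <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
  }
  Z <- with_seed(cfg$seed,
                 matrix(stats::rnorm(n_cells * n_spots, sd = 0.01),
                        n_cells, n_spots))
  mZ <- vZ <- Z * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(0)
  prev_loss <- Inf
  for (it in seq_len(cfg$max_iter)) {
    M <- softmax_rows(Z)
    lg <- mapping_loss_grad(M, Sm, Gm, cfg$density_prior_weight)
    if (!is.finite(lg$loss))
      stopf("mapping loss diverged; try a smaller learning_rate")
    if (it %% 25 == 1) trace <- c(trace, lg$loss)
    ## softmax backprop, row-wise
    dZ <- M * (lg$dM - rowSums(lg$dM * M))
    mZ <- b1 * mZ + (1 - b1) * dZ; vZ <- b2 * vZ + (1 - b2) * dZ^2
    Z <- Z - cfg$learning_rate * (mZ / (1 - b1^it)) /
      (sqrt(vZ / (1 - b2^it)) + eps)
    if (abs(prev_loss - lg$loss) < cfg$tol * max(abs(prev_loss), 1e-12) &&
        it > 10) { trace <- c(trace, lg$loss); break }
    prev_loss <- lg$loss
  }
  M <- softmax_rows(Z)
  final <- mapping_loss_grad(M, Sm, Gm, cfg$density_prior_weight)$loss
  trace <- c(trace, final)
  if (length(trace) > 1 && any(diff(trace) > 1e-6 * max(abs(trace))))
    warnf("mapping loss trace is not non-increasing across checkpoints")
  ids_c <- if (inherits(S, "embedding_matrix")) S$ids
           else sprintf("cell_%d", seq_len(n_cells))
  ids_s <- if (inherits(G, "embedding_matrix")) G$ids
           else sprintf("spot_%d", seq_len(n_spots))
  dimnames(M) <- list(ids_c, ids_s)
  structure(list(weights = M, cell_ids = ids_c, spot_ids = ids_s,
                 loss_trace = trace),
            class = "mapping_matrix")
}

#' Aggregate cell embeddings to cluster level
#'
#' Cluster embedding = L2-renormalized mean of the member cell embeddings;
#' cluster sizes are returned so downstream type probabilities can weight
#' clusters by how many cells they represent.
#'
#' @param cell_emb `embedding_matrix` (cells x d).
#' @param cluster_labels one label per cell.
#' @return list with `embeddings` (clusters x d `embedding_matrix`) and
#'   `sizes` (named integer vector).
#' @export
cluster_aggregate <- function(cell_emb, cluster_labels) {
  E <- if (inherits(cell_emb, "embedding_matrix")) cell_emb$vectors
       else as.matrix(cell_emb)
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != nrow(E)) stopf("one label per cell required")
  if (length(cluster_labels) == 0) stopf("empty cluster label set")
  cl <- unique(cluster_labels)
  means <- t(vapply(cl, function(c)
    colMeans(E[cluster_labels == c, , drop = FALSE]), numeric(ncol(E))))
  sizes <- vapply(cl, function(c) sum(cluster_labels == c), 0L)
  names(sizes) <- cl
  mod <- if (inherits(cell_emb, "embedding_matrix")) cell_emb$modality else "text"
  list(embeddings = embedding_matrix(means, cl, mod), sizes = sizes)
}

#' Spot-level cell-type probabilities from a mapping matrix
#'
#' Collapses the cell(or cluster)-to-spot mapping into per-spot cell-type
#' probabilities: `P[i, c] = sum_{j: label_j = c} size_j M[j, i]`,
#' normalized over types within each spot. Sizes default to 1 (cell-level
#' mapping); for cluster-level mappings pass the cluster sizes so each
#' cluster votes in proportion to its cell count. P is scale-invariant in
#' the sizes.
#'
#' @param M a `mapping_matrix` from [fit_mapping()].
#' @param type_labels cell-type label per mapping row.
#' @param sizes optional nonnegative weight per row.
#' @return a `celltype_map`: list with `probabilities` (spots x types, rows
#'   summing to 1) and `types`.
#' @export
celltype_probabilities <- function(M, type_labels, sizes = NULL) {
  W <- M$weights
  type_labels <- as.character(type_labels)
  if (length(type_labels) != nrow(W))
    stopf("one type label per mapping row required")
  sizes <- sizes %||% rep(1, nrow(W))
  types <- unique(type_labels)
  P <- matrix(0, ncol(W), length(types),
              dimnames = list(M$spot_ids, types))
  for (t in seq_along(types)) {
    idx <- type_labels == types[t]
    P[, t] <- colSums(W[idx, , drop = FALSE] * sizes[idx])
  }
  tot <- rowSums(P)
  zero <- tot <= 0
  if (any(zero)) {
    warnf("%d spot(s) with zero mapped mass; set to uniform", sum(zero))
    P[zero, ] <- 1 / length(types)
    tot[zero] <- 1
  }
  P <- P / tot
  structure(list(probabilities = P, types = types), class = "celltype_map")
}

#' Non-maximum-suppression refinement of a cell-type map
#'
#' Keeps, for each spot, only the most probable cell type at its original
#' probability and zeroes all others (no renormalization), sharpening
#' ambiguous spots to their single best assignment. Argmax ties are broken
#' by type order and flagged. Idempotent.
#'
#' @param P a `celltype_map`.
#' @return a `celltype_map` with exactly one nonzero entry per spot, equal
#'   to that spot's pre-refinement maximum, plus a `tie` logical vector.
#' @export
nms_refine <- function(P) {
  pr <- P$probabilities
  best <- max.col(pr, ties.method = "first")
  tie <- vapply(seq_len(nrow(pr)), function(i)
    sum(pr[i, ] == pr[i, best[i]]) > 1, TRUE)
  out <- pr * 0
  out[cbind(seq_len(nrow(pr)), best)] <- pr[cbind(seq_len(nrow(pr)), best)]
  structure(list(probabilities = out, types = P$types, tie = tie),
            class = "celltype_map")
}

#' Decompose a slide into cell-type probabilities
#'
#' Full pipeline: encode the target spots (gene sentences through the text
#' encoder in `st` mode; image patches through the image encoder in
#' `image` mode), optionally aggregate the reference cells to cluster
#' level, fit the probabilistic mapping, and collapse it to per-spot
#' cell-type probabilities, optionally sharpened by [nms_refine()].
#'
#' @param reference_emb `embedding_matrix` of reference cells (cells x d).
#' @param reference_labels cell-type label per reference cell.
#' @param target a [spot_slide()].
#' @param backend encoder backend (must match the space of
#'   `reference_emb`).
#' @param mode `"st"` (encode sentences) or `"image"` (encode patches).
#' @param cfg a [decompose_config()].
#' @param nms apply NMS refinement (default FALSE).
#' @param maps,top_n sentence construction options for `st` mode.
#' @return a `celltype_map` (plus the fitted `mapping` as an attribute).
#' @export
decompose_slide <- function(reference_emb, reference_labels, target, backend,
                            mode = c("st", "image"),
                            cfg = decompose_config(), nms = FALSE,
                            maps = gene_maps(), top_n = 50) {
  mode <- match.arg(mode)
  G <- if (mode == "st") {
    encode_text(backend, slide_sentences(target, maps, top_n))
  } else {
    if (is.null(target$patches)) stopf("image mode requires target patches")
    encode_image(backend, target$patches, target$spot_ids)
  }
  S <- reference_emb
  labels <- as.character(reference_labels)
  sizes <- NULL
  if (cfg$cluster_level) {
    agg <- cluster_aggregate(reference_emb, labels)
    S <- agg$embeddings
    sizes <- as.numeric(agg$sizes)
    labels <- agg$embeddings$ids
  }
  M <- fit_mapping(S, G, cfg)
  P <- celltype_probabilities(M, labels, sizes)
  if (nms) P <- nms_refine(P)
  attr(P, "mapping") <- M
  P
}
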