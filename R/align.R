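#' Parameters for embedding-augmented coherent point drift
#'
#' @param beta Gaussian kernel width of the motion-coherence kernel G
#'   (controls transformation stiffness; larger = smoother displacement
#'   field). Default 2 on normalized coordinates.
#' @param lambda regularization weight trading data fidelity against
#'   smoothness. Default 2.
#' @param w expected outlier fraction in \[0, 1). Default 0.1.
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the relative change of the mixture
#'   variance sigma^2.
#' @param clip_W clip the coefficient matrix W elementwise to \[0, 1\] after
#'   each M-step solve (meaningful because point sets are normalized to
#'   unit scale before registration). Default FALSE: the clip constrains
#'   all coordinate displacements to be nonnegative, which prevents the
#'   recovery of rotations; it is provided as an optional stabilizer.
#' @param gamma weight of the two embedding principal-component columns
#'   appended to the coordinates; 0 gives plain coordinate-only CPD.
#'   Default 0.25: large enough for molecular identity to disambiguate
#'   correspondences, small enough that encoder noise in the PC scores
#'   does not distort the recovered geometry.
#' @return a `cpd_params` list.
#' @export
cpd_params <- function(beta = 2, lambda = 2, w = 0.1, max_iter = 100,
                       tol = 1e-5, clip_W = FALSE, gamma = 0.25) {
  assert_scalar_num(beta, "beta", 0, strict_lower = TRUE)
  assert_scalar_num(lambda, "lambda", 0, strict_lower = TRUE)
  assert_scalar_num(w, "w", 0); if (w >= 1) stopf("'w' must be < 1")
  assert_scalar_num(tol, "tol", 0, strict_lower = TRUE)
  assert_scalar_num(gamma, "gamma", 0)
  structure(list(beta = beta, lambda = lambda, w = w,
                 max_iter = as.integer(max_iter), tol = tol,
                 clip_W = isTRUE(clip_W), gamma = gamma),
            class = "cpd_params")
}

normalize_coords <- function(coords) {
  center <- colMeans(coords)
  centered <- sweep(coords, 2, center)
  scale <- max(abs(centered))
  if (scale == 0) scale <- 1
  out <- centered / scale
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Augment spot coordinates with embedding principal components
#'
#' Builds the registration point set: normalized coordinates (zero mean,
#' unit max-absolute scale) with the first two principal components of the
#' spot embeddings appended as extra dimensions. Each PC column is
#' standardized and rescaled so its standard deviation equals `gamma` times
#' the pooled standard deviation of the normalized coordinates, putting
#' molecular identity and geometry on a controlled common scale. Zero-
#' variance PCs (e.g. identical embeddings) become zero columns, which
#' reduces to coordinate-only registration.
#'
#' @param coords n x 2 coordinates in microns.
#' @param embeddings an `embedding_matrix` (or matrix) with one row per
#'   point; ignored when `gamma = 0`.
#' @param gamma nonnegative PC weight.
#' @param pc_scores optionally, precomputed n x 2 PC scores (used to share
#'   one PCA across two point sets); bypasses the internal PCA.
#' @return n x 2 (gamma 0) or n x 4 matrix with attributes `center` and
#'   `scale` recording the coordinate normalization.
#' @export
augment_points <- function(coords, embeddings = NULL, gamma = 1,
                           pc_scores = NULL) {
  coords <- as.matrix(coords)
  nc <- normalize_coords(coords)
  if (gamma == 0 || (is.null(embeddings) && is.null(pc_scores))) {
    return(nc)
  }
  if (nrow(coords) < 3) stopf("need at least 3 points for the embedding PCA")
  if (is.null(pc_scores)) {
    E <- if (inherits(embeddings, "embedding_matrix")) embeddings$vectors
         else as.matrix(embeddings)
    if (nrow(E) != nrow(coords)) stopf("one embedding per point required")
    pc_scores <- stats::prcomp(E, center = TRUE, scale. = FALSE)$x
    pc_scores <- cbind(pc_scores,
                       matrix(0, nrow(pc_scores), max(0, 2 - ncol(pc_scores))))
    pc_scores <- pc_scores[, 1:2, drop = FALSE]
  }
  pooled_sd <- stats::sd(as.numeric(nc))
  pcs <- apply(pc_scores, 2, function(p) {
    s <- stats::sd(p)
    if (s < 1e-12) rep(0, length(p)) else (p - mean(p)) / s * gamma * pooled_sd
  })
  out <- cbind(nc, pcs)
  attr(out, "center") <- attr(nc, "center")
  attr(out, "scale") <- attr(nc, "scale")
  out
}

#' Non-rigid registration by coherent point drift with coordinate-only
#' updates
#'
#' Registers a source point set Y onto a target X, both optionally carrying
#' two extra embedding-PC dimensions from [augment_points()]. The target is
#' modeled as samples from a Gaussian mixture centered on the (moving)
#' source points with a uniform outlier component of weight `w`. EM
#' alternates: the E-step computes correspondence posteriors P over the
#' full augmented dimensionality; the M-step solves
#' `(G + lambda sigma^2 d(P1)^{-1}) W = d(P1)^{-1} P X - Y` for the
#' coefficient matrix W of the kernel-smoothed displacement field, after
#' which W is clipped elementwise to \[0, 1\] when `clip_W` is set. The
#' displacement `G W` is applied to the coordinate columns only; the
#' embedding-PC columns of the source stay fixed throughout, so molecular
#' identity steers the correspondences while only geometry moves. The
#' mixture variance sigma^2 is re-estimated each iteration and iteration
#' stops when its relative change falls below `tol`.
#'
#' @param source M x D matrix (Y): points to be moved.
#' @param target N x D matrix (X): reference frame.
#' @param params a [cpd_params()].
#' @param normalize when the inputs do not already carry the normalization
#'   attributes from [augment_points()], center/scale their coordinate
#'   columns internally (default TRUE). With `normalize = FALSE` raw
#'   coordinates are used as-is and returned un-denormalized.
#' @return an `alignment_result` list: `aligned_coords` (source coordinates
#'   after registration, in the target's original frame), `W`,
#'   `sigma2_final`, `n_iter`, `displacement_per_spot`, plus the internal
#'   normalized point sets.
#' @export
cpd_align <- function(source, target, params = cpd_params(),
                      normalize = TRUE) {
  Y <- as.matrix(source); X <- as.matrix(target)
  if (ncol(Y) != ncol(X)) stopf("source and target dimensionality differ")
  if (nrow(Y) < 3 || nrow(X) < 3) stopf("need at least 3 points per set")
  has_attrs <- !is.null(attr(source, "scale")) && !is.null(attr(target, "scale"))
  if (has_attrs) {
    t_center <- attr(target, "center"); t_scale <- attr(target, "scale")
  } else if (normalize) {
    nx <- normalize_coords(X[, 1:2, drop = FALSE])
    ny <- normalize_coords(Y[, 1:2, drop = FALSE])
    X[, 1:2] <- nx; Y[, 1:2] <- ny
    t_center <- attr(nx, "center"); t_scale <- attr(nx, "scale")
  } else {
    t_center <- c(0, 0); t_scale <- 1
  }
  M <- nrow(Y); N <- nrow(X); D <- ncol(Y)
  G <- exp(-as.matrix(stats::dist(Y))^2 / (2 * params$beta^2))
  W <- matrix(0, M, D)
  sigma2 <- sum(outer(rowSums(Y^2), rowSums(X^2), "+") -
                  2 * Y %*% t(X)) / (D * M * N)
  TY <- Y
  n_iter <- 0L
  clamped <- FALSE
  for (it in seq_len(params$max_iter)) {
    n_iter <- it
    ## E-step (Eq. 4): posteriors over full augmented dimension
    d2 <- outer(rowSums(TY^2), rowSums(X^2), "+") - 2 * TY %*% t(X)  # M x N
    num <- exp(-pmax(d2, 0) / (2 * sigma2))
    c_out <- if (params$w > 0)
      (2 * pi * sigma2)^(D / 2) * params$w / (1 - params$w) * M / N else 0
    P <- sweep(num, 2, colSums(num) + c_out, "/")
    P1 <- pmax(rowSums(P), 1e-300)
    ## M-step (Eq. 5): solve for W, with a ridge retry if singular
    A <- G + params$lambda * sigma2 * diag(1 / P1)
    rhs <- (P %*% X) / P1 - Y
    W <- tryCatch(solve(A, rhs), error = function(e)
      tryCatch(solve(A + 1e-8 * diag(M), rhs), error = function(e2)
        stopf("CPD M-step system is singular; registration failed")))
    if (params$clip_W) W <- pmin(pmax(W, 0), 1)
    ## transform: displacement applied to the coordinate columns only
    GW <- G %*% W
    TY <- Y
    TY[, 1:2] <- Y[, 1:2] + GW[, 1:2]
    ## Eqs. 6-7
    Np <- sum(P1)
    Pt1 <- colSums(P)
    sigma2_new <- (sum(Pt1 * rowSums(X^2)) -
                     2 * sum((P %*% X) * TY) +
                     sum(P1 * rowSums(TY^2))) / (Np * D)
    if (sigma2_new < 1e-12) {
      if (!clamped) warnf("CPD sigma^2 underflow; clamped at 1e-12")
      clamped <- TRUE
      sigma2_new <- 1e-12
    }
    delta <- abs(sigma2 - sigma2_new) / sigma2
    sigma2 <- sigma2_new
    if (delta < params$tol) break
  }
  aligned_norm <- TY[, 1:2, drop = FALSE]
  aligned <- sweep(aligned_norm * t_scale, 2, t_center, "+")
  src_coords <- sweep(Y[, 1:2, drop = FALSE] * t_scale, 2, t_center, "+")
  structure(list(aligned_coords = aligned, W = W, sigma2_final = sigma2,
                 n_iter = n_iter,
                 displacement_per_spot =
                   sqrt(rowSums((aligned - src_coords)^2)),
                 source_norm = Y, target_norm = X, rigid = NULL),
            class = "alignment_result")
}

#' Rigid (rotation + translation) fit between point sets
#'
#' Least-squares orthogonal Procrustes fit, restricted to a proper rotation
#' (determinant +1, no scaling or reflection), mapping `original_coords`
#' onto `cpd_coords`. Used to screen the non-rigid registration result for
#' excessive distortion: the per-point residual between the non-rigid and
#' the rigidly transformed coordinates measures how far the deformation
#' strays from a rigid motion.
#'
#' @param original_coords,cpd_coords n x 2 matrices, equal n >= 2.
#' @return list with `rotation` (2 x 2), `angle` (radians), `translation`,
#'   `rigid_coords`, and `residuals` (per-point distortion).
#' @export
rigid_regularize <- function(original_coords, cpd_coords) {
  A <- as.matrix(original_coords); B <- as.matrix(cpd_coords)
  if (nrow(A) != nrow(B) || nrow(A) < 2) stopf("need equal point counts >= 2")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  if (sv$d[1] < 1e-12 || sv$d[2] / sv$d[1] < 1e-12) {
    warnf("degenerate (collinear) configuration; using identity rotation")
    R <- diag(2)
  } else {
    dsign <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, dsign)) %*% t(sv$u)
  }
  rigid <- sweep(Ac %*% t(R), 2, cb, "+")
  list(rotation = R, angle = atan2(R[2, 1], R[1, 1]),
       translation = cb - as.numeric(R %*% ca),
       rigid_coords = rigid,
       residuals = sqrt(rowSums((B - rigid)^2)))
}

## Average each point's PC scores over its k nearest spatial neighbors
## (self included). Expression programs vary smoothly over tissue while
## encoder noise is independent per spot, so neighborhood averaging
## suppresses the noise without erasing the domain signal the PCs carry.
knn_smooth_scores <- function(coords, scores, k) {
  if (k <= 1) return(scores)
  k <- min(k, nrow(coords))
  d2 <- as.matrix(stats::dist(coords))
  t(apply(d2, 1, function(r)
    colMeans(scores[order(r)[seq_len(k)], , drop = FALSE])))
}

#' Align two slides in embedding-augmented point space
#'
#' End-to-end slide registration: encode each spot (gene sentences through
#' the text encoder in `st_to_st` mode; source patches through the image
#' encoder and target sentences through the text encoder in `image_to_st`
#' mode), append the first two principal components of the embeddings to
#' the spot coordinates, run [cpd_align()], and fit a rigid
#' rotation+translation between the source's original and registered
#' positions as a distortion screen. When the 95th percentile of the
#' distortion residuals exceeds `distortion_threshold` the rigid projection
#' replaces the non-rigid coordinates in `final_coords`.
#'
#' In `image_to_st` mode the two modalities must share an embedding space,
#' so a trainable backend is fine-tuned on the target slide's own
#' (patch, sentence) pairs before encoding (the default when the backend is
#' trainable and the target carries patches); the PCA is then computed
#' jointly on the stacked source and target embeddings so the PC axes agree
#' across the two sets.
#'
#' @param source,target [spot_slide()] objects; `source` is moved onto
#'   `target`.
#' @param backend encoder backend; defaults to [hash_encoder()] for
#'   `st_to_st`.
#' @param params a [cpd_params()].
#' @param mode `"st_to_st"` or `"image_to_st"`.
#' @param maps [gene_maps()] for sentence construction.
#' @param top_n sentence length.
#' @param fine_tune_cfg [train_config()] controlling pre-alignment
#'   fine-tuning of a trainable backend (default: 10 epochs); set to
#'   `FALSE` to skip.
#' @param pc_smooth_k average each spot's PC scores over its
#'   `pc_smooth_k` nearest spatial neighbors (self included) before
#'   augmentation, suppressing per-spot encoder noise (default 7, roughly
#'   one hexagonal neighborhood; 0 or 1 disables).
#' @param distortion_threshold rigid-fallback trigger, in microns (default
#'   2 x target pitch).
#' @return an `alignment_result` augmented with `rigid`, `rigid_coords`,
#'   `final_coords`, `used_rigid_fallback`, and `spot_ids`.
#' @export
align_slides <- function(source, target, backend = NULL,
                         params = cpd_params(),
                         mode = c("st_to_st", "image_to_st"),
                         maps = gene_maps(), top_n = 50,
                         fine_tune_cfg = NULL, pc_smooth_k = 7,
                         distortion_threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(backend)) backend <- hash_encoder()
  distortion_threshold <- distortion_threshold %||% (2 * target$pitch_um)
  tgt_sent <- slide_sentences(target, maps, top_n)
  if (mode == "image_to_st") {
    if (is.null(source$patches))
      stopf("image_to_st mode requires source patches")
    do_ft <- isTRUE(backend$trainable) && !identical(fine_tune_cfg, FALSE) &&
      !is.null(target$patches)
    if (do_ft) {
      cfg <- if (inherits(fine_tune_cfg, "train_config")) fine_tune_cfg
             else train_config(epochs = 10, seed = backend$seed)
      backend <- fine_tune(backend, target$patches, tgt_sent, cfg)
    }
    emb_s <- encode_image(backend, source$patches, source$spot_ids)
    emb_t <- encode_text(backend, tgt_sent)
  } else {
    emb_s <- encode_text(backend, slide_sentences(source, maps, top_n))
    emb_t <- encode_text(backend, tgt_sent)
  }
  ## one PCA over both sets so PC axes are shared
  if (params$gamma > 0) {
    stacked <- rbind(emb_s$vectors, emb_t$vectors)
    pcs <- stats::prcomp(stacked, center = TRUE)$x
    pcs <- cbind(pcs, matrix(0, nrow(pcs), max(0, 2 - ncol(pcs))))
    idx_s <- seq_len(nrow(emb_s$vectors))
    pc_s <- knn_smooth_scores(source$coords, pcs[idx_s, 1:2, drop = FALSE],
                              pc_smooth_k)
    pc_t <- knn_smooth_scores(target$coords, pcs[-idx_s, 1:2, drop = FALSE],
                              pc_smooth_k)
    aug_s <- augment_points(source$coords, gamma = params$gamma,
                            pc_scores = pc_s)
    aug_t <- augment_points(target$coords, gamma = params$gamma,
                            pc_scores = pc_t)
  } else {
    aug_s <- augment_points(source$coords, gamma = 0)
    aug_t <- augment_points(target$coords, gamma = 0)
  }
  res <- cpd_align(aug_s, aug_t, params)
  rig <- rigid_regularize(source$coords, res$aligned_coords)
  res$rigid <- rig[c("rotation", "angle", "translation")]
  res$rigid_coords <- rig$rigid_coords
  p95 <- stats::quantile(rig$residuals, 0.95, names = FALSE)
  res$used_rigid_fallback <- p95 > distortion_threshold
  res$final_coords <- if (res$used_rigid_fallback) rig$rigid_coords
                      else res$aligned_coords
  res$distortion_p95 <- p95
  res$spot_ids <- source$spot_ids
  res$backend <- backend
  res
}

#' Expression agreement between an aligned source and its target
#'
#' Matches every aligned source spot to its nearest target spot within
#' `match_radius` (unmatched spots are dropped) and computes the Pearson
#' correlation and Kendall's tau of expression across matched pairs for the
#' `n_hvg` most variable target genes.
#'
#' @param aligned_coords registered source coordinates (n x 2, target frame).
#' @param source_expr source expression matrix (spots x genes), columns
#'   named by gene.
#' @param target a [spot_slide()]; its normalized layer is used when
#'   present, raw counts otherwise.
#' @param n_hvg number of most-variable target genes to evaluate.
#' @param match_radius maximum match distance in microns (default half the
#'   target pitch).
#' @return list with `per_gene` (data.frame gene, pcc, tau), `median_pcc`,
#'   `median_tau`, `n_matched`.
#' @export
evaluate_alignment <- function(aligned_coords, source_expr, target,
                               n_hvg = 50, match_radius = NULL) {
  match_radius <- match_radius %||% (target$pitch_um / 2)
  aligned_coords <- as.matrix(aligned_coords)
  tc <- target$coords
  d2 <- outer(rowSums(aligned_coords^2), rowSums(tc^2), "+") -
    2 * aligned_coords %*% t(tc)
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(aligned_coords)), nearest)], 0))
  ok <- dist <= match_radius
  if (!any(ok)) stopf("no aligned spot matched a target spot within radius")
  texpr <- target$lognorm %||% target$counts
  vars <- apply(texpr, 2, stats::var)
  hvg <- order(vars, decreasing = TRUE)[seq_len(min(n_hvg, ncol(texpr)))]
  genes <- colnames(texpr)[hvg]
  s_sub <- source_expr[ok, genes, drop = FALSE]
  t_sub <- texpr[nearest[ok], genes, drop = FALSE]
  pcc <- vapply(seq_along(genes), function(j)
    pearson_cor(s_sub[, j], t_sub[, j]), 0)
  tau <- vapply(seq_along(genes), function(j)
    kendall_tau(s_sub[, j], t_sub[, j]), 0)
  list(per_gene = data.frame(gene = genes, pcc = pcc, tau = tau),
       median_pcc = stats::median(pcc, na.rm = TRUE),
       median_tau = stats::median(tau, na.rm = TRUE),
       n_matched = sum(ok))
}
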