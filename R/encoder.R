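#' Embedding matrix container
#'
#' Holds n unit-norm d-dimensional vectors for one modality (image patches
#' or gene sentences). Rows are L2-normalized; cross-modal comparisons
#' require equal d.
#'
#' @param vectors n x d numeric matrix.
#' @param ids identifiers, one per row.
#' @param modality `"image"` or `"text"`.
#' @param normalize L2-normalize rows (default TRUE).
#' @return object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(vectors, ids, modality = c("text", "image"),
                             normalize = TRUE) {
  modality <- match.arg(modality)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(ids))
    stopf("need one id per embedding row")
  if (normalize) vectors <- l2_normalize_rows(vectors)
  rownames(vectors) <- ids
  structure(list(vectors = vectors, ids = as.character(ids),
                 modality = modality),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("embedding_matrix: %d x %d (%s)\n", nrow(x$vectors),
              ncol(x$vectors), x$modality))
  invisible(x)
}

## ---- deterministic hashing utilities ------------------------------------

## 32-bit polynomial string hash, stable across platforms.
hash_string <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483587
  h
}

## Seeded pseudo-random unit direction for one token.
token_vector <- function(token, d, seed) {
  h <- (hash_string(token) + (seed %% 65011) * 33013) %% 2147483587
  with_seed(h + 1, stats::rnorm(d))
}

## ---- backends ------------------------------------------------------------

#' Deterministic hash dual encoder
#'
#' A training-free stand-in for a pretrained dual encoder. Text: every gene
#' symbol is hashed (seeded) to a fixed pseudo-random direction and a
#' sentence embeds as the rank-weighted sum `sum_r v[gene_r] / log2(r + 2)`,
#' so earlier (more expressed) genes dominate and sentences sharing top
#' genes land close together. Image: a patch is summarized by per-channel
#' mean/sd plus 8-bin intensity histograms (30 features) and pushed through
#' a fixed seeded random projection. Both outputs are L2-normalized.
#'
#' The two modalities live in unrelated random subspaces: hash embeddings
#' support within-modality structure (similarity, PCA, retrieval among like
#' items) but carry no cross-modal alignment; use [toy_dual_encoder()] plus
#' [fine_tune()] when image-text alignment is needed.
#'
#' @param d embedding dimension (default 768).
#' @param seed integer seed fixing all hashed directions.
#' @return an encoder backend (class `hash_encoder`).
#' @export
hash_encoder <- function(d = 768, seed = 1) {
  assert_scalar_num(d, "d", 2)
  proj <- with_seed(seed * 7919 + 13,
                    matrix(stats::rnorm(30 * d), 30, d) / sqrt(30))
  structure(list(d = as.integer(d), seed = as.integer(seed),
                 trainable = FALSE, image_proj = proj,
                 token_cache = new.env(parent = emptyenv())),
            class = c("hash_encoder", "encoder_backend"))
}

#' Small trainable dual encoder
#'
#' Linear maps from a bag-of-genes text featurization and the 30-dim patch
#' feature vector into a shared d-dimensional space, trained with the
#' symmetric contrastive loss (see [contrastive_loss()]). Deliberately tiny:
#' enough capacity to align the two modalities on data whose images and
#' expression share a low-dimensional latent, and fully deterministic at a
#' fixed seed.
#'
#' @param vocab character vector: gene symbols the text featurizer knows;
#'   tokens outside the vocabulary are ignored.
#' @param d embedding dimension (default 768).
#' @param seed seed for weight initialization.
#' @return an encoder backend (class `toy_encoder`) with weight matrices
#'   `A` (30 x d, image) and `B` (|vocab| x d, text).
#' @export
toy_dual_encoder <- function(vocab, d = 768, seed = 1) {
  assert_scalar_num(d, "d", 2)
  vocab <- unique(as.character(vocab))
  init <- with_seed(seed, list(
    A = matrix(stats::rnorm(30 * d, sd = 0.3), 30, d),
    B = matrix(stats::rnorm(length(vocab) * d, sd = 0.3), length(vocab), d)))
  structure(list(d = as.integer(d), seed = as.integer(seed),
                 trainable = TRUE, vocab = vocab,
                 A = init$A, B = init$B, history = numeric()),
            class = c("toy_encoder", "encoder_backend"))
}

## 30-dim image featurization shared by the hash and toy encoders:
## per-channel mean and sd (scaled to [0,1]) plus an 8-bin histogram
## of each channel.
patch_features <- function(patch) {
  if (length(dim(patch)) != 3L || dim(patch)[3] != 3L)
    stopf("patches must be H x W x 3 arrays")
  f <- numeric(30)
  for (ch in 1:3) {
    v <- as.numeric(patch[, , ch]) / 255
    f[(ch - 1) * 10 + 1] <- mean(v)
    f[(ch - 1) * 10 + 2] <- stats::sd(c(v, v))  # population-ish, 0 for flat
    h <- tabulate(pmin(pmax(floor(v * 8) + 1, 1), 8), 8)
    f[(ch - 1) * 10 + 2 + 1:8] <- h / length(v)
  }
  f[!is.finite(f)] <- 0
  f
}

## Rank-weighted bag-of-genes over a fixed vocabulary.
text_bag <- function(tokens, vocab) {
  g <- numeric(length(vocab))
  hit <- match(tokens, vocab)
  w <- 1 / log2(seq_along(tokens) + 2)
  ok <- !is.na(hit)
  if (any(ok)) g[hit[ok]] <- g[hit[ok]] + w[ok]
  g
}

MAX_TOKENS <- 76L

prep_sentences <- function(sentences) {
  if (inherits(sentences, "gene_sentence")) sentences <- list(sentences)
  if (length(sentences) == 0) stopf("sentences must be non-empty")
  lapply(sentences, function(s) {
    if (length(s$tokens) == 0)
      stopf("sentence '%s' is empty", s$source_id)
    s$tokens <- s$tokens[seq_len(min(length(s$tokens), MAX_TOKENS))]
    s
  })
}

#' Encode gene sentences
#'
#' Sentences are truncated to their first 76 tokens (the text-encoder input
#' budget) and mapped to unit-norm d-vectors.
#'
#' @param backend an encoder backend ([hash_encoder()] or
#'   [toy_dual_encoder()]).
#' @param sentences a `gene_sentence` or list of them.
#' @return an `embedding_matrix` with modality `"text"`.
#' @export
encode_text <- function(backend, sentences) UseMethod("encode_text")

#' @export
encode_text.hash_encoder <- function(backend, sentences) {
  sentences <- prep_sentences(sentences)
  vec <- t(vapply(sentences, function(s) {
    v <- numeric(backend$d)
    for (r in seq_along(s$tokens)) {
      tok <- s$tokens[r]
      tv <- backend$token_cache[[tok]]
      if (is.null(tv)) {
        tv <- token_vector(tok, backend$d, backend$seed)
        assign(tok, tv, envir = backend$token_cache)
      }
      v <- v + tv / log2(r + 2)
    }
    v
  }, numeric(backend$d)))
  embedding_matrix(vec, vapply(sentences, function(s) s$source_id, ""),
                   "text")
}

#' @export
encode_text.toy_encoder <- function(backend, sentences) {
  sentences <- prep_sentences(sentences)
  G <- t(vapply(sentences, function(s) text_bag(s$tokens, backend$vocab),
                numeric(length(backend$vocab))))
  embedding_matrix(G %*% backend$B,
                   vapply(sentences, function(s) s$source_id, ""), "text")
}

#' Encode image patches
#'
#' @param backend an encoder backend.
#' @param patches list of H x W x 3 arrays (values in \[0, 255\]), all the
#'   same shape.
#' @param ids optional identifiers (default `patch_1..n`).
#' @return an `embedding_matrix` with modality `"image"`.
#' @export
encode_image <- function(backend, patches, ids = NULL)
  UseMethod("encode_image")

patch_feature_matrix <- function(patches) {
  if (is.array(patches) && length(dim(patches)) == 3L) patches <- list(patches)
  t(vapply(patches, patch_features, numeric(30)))
}

#' @export
encode_image.hash_encoder <- function(backend, patches, ids = NULL) {
  F <- patch_feature_matrix(patches)
  ids <- ids %||% sprintf("patch_%d", seq_len(nrow(F)))
  V <- F %*% backend$image_proj
  ## a patch with degenerate (all-equal) features still gets a direction
  zero <- rowSums(V^2) == 0
  if (any(zero)) V[zero, 1] <- 1
  embedding_matrix(V, ids, "image")
}

#' @export
encode_image.toy_encoder <- function(backend, patches, ids = NULL) {
  F <- patch_feature_matrix(patches)
  ids <- ids %||% sprintf("patch_%d", seq_len(nrow(F)))
  V <- F %*% backend$A
  zero <- rowSums(V^2) == 0
  if (any(zero)) V[zero, 1] <- 1
  embedding_matrix(V, ids, "image")
}

#' Cosine similarity between two embedding sets
#'
#' For unit-norm rows this is the dot product; entries are clamped to
#' \[-1, 1\] against floating-point drift.
#'
#' @param A,B `embedding_matrix` objects (or plain matrices) with equal d.
#' @return an `nrow(A)` x `nrow(B)` similarity matrix.
#' @export
cosine_similarity <- function(A, B) {
  a <- if (inherits(A, "embedding_matrix")) A$vectors else
    l2_normalize_rows(as.matrix(A))
  b <- if (inherits(B, "embedding_matrix")) B$vectors else
    l2_normalize_rows(as.matrix(B))
  if (ncol(a) != ncol(b))
    stopf("embedding dimensions differ (%d vs %d)", ncol(a), ncol(b))
  s <- a %*% t(b)
  pmin(pmax(s, -1), 1)
}

#' Symmetric contrastive (CLIP-style) loss
#'
#' For N paired unit-norm embeddings x_i (image) and y_i (text) and
#' temperature sigma, the loss is
#' \deqn{-\frac{1}{N}\left[\sum_i \log\frac{e^{x_i^T y_i/\sigma}}
#'   {\sum_j e^{x_i^T y_j/\sigma}} +
#'   \sum_i \log\frac{e^{y_i^T x_i/\sigma}}
#'   {\sum_j e^{y_i^T x_j/\sigma}}\right],}
#' i.e. matched pairs are positives against all in-batch negatives, in both
#' retrieval directions. With N = 1 both softmaxes are singletons and the
#' loss is exactly 0.
#'
#' @param X,Y paired `embedding_matrix` objects (or matrices), same n and d.
#' @param sigma temperature (> 0), default 0.07.
#' @return scalar loss.
#' @export
contrastive_loss <- function(X, Y, sigma = 0.07) {
  assert_scalar_num(sigma, "sigma", 0, strict_lower = TRUE)
  x <- if (inherits(X, "embedding_matrix")) X$vectors else as.matrix(X)
  y <- if (inherits(Y, "embedding_matrix")) Y$vectors else as.matrix(Y)
  if (nrow(x) != nrow(y)) stopf("X and Y must pair up (same n)")
  S <- (x %*% t(y)) / sigma
  n <- nrow(S)
  lse_row <- apply(S, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  lse_col <- apply(S, 2, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  -(sum(diag(S) - lse_row) + sum(diag(S) - lse_col)) / n
}

## loss and gradient wrt the two unnormalized projection matrices,
## for one batch. F: n x 30 image features, G: n x V text bags.
toy_batch_grad <- function(A, B, F, G, sigma) {
  Vx <- F %*% A; Vy <- G %*% B
  nx <- sqrt(rowSums(Vx^2)); nx[nx == 0] <- 1
  ny <- sqrt(rowSums(Vy^2)); ny[ny == 0] <- 1
  Zx <- Vx / nx; Zy <- Vy / ny
  S <- (Zx %*% t(Zy)) / sigma
  n <- nrow(S)
  rmax <- apply(S, 1, max); cmax <- apply(S, 2, max)
  Pr <- exp(S - rmax); Pr <- Pr / rowSums(Pr)
  Pc <- exp(t(t(S) - cmax)); Pc <- t(t(Pc) / colSums(Pc))
  loss <- -(sum(log(diag(Pr))) + sum(log(diag(Pc)))) / n
  dS <- (Pr - diag(n) + Pc - diag(n)) / n
  dZx <- (dS %*% Zy) / sigma
  dZy <- (t(dS) %*% Zx) / sigma
  ## through row normalization
  dVx <- (dZx - Zx * rowSums(dZx * Zx)) / nx
  dVy <- (dZy - Zy * rowSums(dZy * Zy)) / ny
  list(loss = loss, dA = t(F) %*% dVx, dB = t(G) %*% dVy)
}

#' Training configuration for the toy dual encoder
#'
#' @param temperature contrastive temperature sigma (> 0); default 0.07,
#'   the customary CLIP value.
#' @param batch_size minibatch size (default 64).
#' @param epochs passes over the pairs (>= 1); 10 suits alignment-style
#'   fine-tuning, 5 decomposition-style.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for shuffling (and any init).
#' @return a `train_config` list.
#' @export
train_config <- function(temperature = 0.07, batch_size = 64, epochs = 5,
                         learning_rate = 0.05, seed = 1) {
  assert_scalar_num(temperature, "temperature", 0, strict_lower = TRUE)
  assert_scalar_num(epochs, "epochs", 1)
  assert_scalar_num(batch_size, "batch_size", 1)
  assert_scalar_num(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  structure(list(temperature = temperature,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Fine-tune a trainable dual encoder on paired patches and sentences
#'
#' Minimizes the symmetric contrastive loss over minibatches with Adam.
#' Per-epoch mean batch loss is recorded in `$history`; if the final epoch's
#' mean loss exceeds the first epoch's a warning is raised. Two runs with
#' identical inputs and seed produce identical weights.
#'
#' @param backend a trainable backend ([toy_dual_encoder()]).
#' @param patches list of patch arrays, paired with `sentences`.
#' @param sentences list of `gene_sentence`, same length as `patches`.
#' @param cfg a [train_config()].
#' @return the updated backend.
#' @export
fine_tune <- function(backend, patches, sentences, cfg = train_config()) {
  if (!isTRUE(backend$trainable))
    stopf("backend of class '%s' is not trainable", class(backend)[1])
  if (!inherits(cfg, "train_config")) stopf("cfg must be a train_config")
  if (length(patches) != length(sentences) || length(patches) < 2)
    stopf("need >= 2 paired (patch, sentence) examples")
  sentences <- prep_sentences(sentences)
  F <- patch_feature_matrix(patches)
  G <- t(vapply(sentences, function(s) text_bag(s$tokens, backend$vocab),
                numeric(length(backend$vocab))))
  n <- nrow(F)
  A <- backend$A; B <- backend$B
  mA <- vA <- A * 0; mB <- vB <- B * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1, n)]
        if (length(idx) < 2) { losses[bi] <- NA; next }
        g <- toy_batch_grad(A, B, F[idx, , drop = FALSE],
                            G[idx, , drop = FALSE], cfg$temperature)
        losses[bi] <- g$loss
        t_step <- t_step + 1
        mA <- b1 * mA + (1 - b1) * g$dA; vA <- b2 * vA + (1 - b2) * g$dA^2
        mB <- b1 * mB + (1 - b1) * g$dB; vB <- b2 * vB + (1 - b2) * g$dB^2
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        A <- A - cfg$learning_rate * (mA / corr1) / (sqrt(vA / corr2) + eps)
        B <- B - cfg$learning_rate * (mB / corr1) / (sqrt(vB / corr2) + eps)
      }
      history[ep] <- mean(losses, na.rm = TRUE)
    }
  })
  if (length(history) > 1 && history[length(history)] > history[1])
    warnf("fine_tune: loss did not improve (%.4f -> %.4f)",
          history[1], history[length(history)])
  backend$A <- A; backend$B <- B
  backend$history <- c(backend$history, history)
  backend
}
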