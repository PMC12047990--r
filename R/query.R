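#' Cross-modal retrieval by cosine similarity
#'
#' Ranks every bank entry for each query by descending cosine similarity
#' (ties broken by candidate id for determinism) and returns the top k.
#' When the ground-truth bank match of each query is known, the rank and
#' quantile of the truth are recorded: ties take the worst (largest) rank
#' among equal-similarity candidates, and `quantile = rank / n_bank`.
#'
#' @param query_emb `embedding_matrix` of queries.
#' @param bank_emb `embedding_matrix` of candidates, same d.
#' @param k how many candidates to return per query (<= bank size).
#' @param truth optional character vector (one bank id per query) naming
#'   each query's ground-truth candidate.
#' @return a `retrieval_result`: list with `table` (data.frame query_id,
#'   rank, candidate_id, similarity), and when truth is given `truth_rank`
#'   and `truth_quantile` per query.
#' @export
retrieve <- function(query_emb, bank_emb, k = 10, truth = NULL) {
  n_bank <- length(bank_emb$ids)
  if (k > n_bank) stopf("k (%d) exceeds bank size (%d)", k, n_bank)
  sims <- cosine_similarity(query_emb, bank_emb)
  nq <- nrow(sims)
  rows <- vector("list", nq)
  truth_rank <- truth_quantile <- rep(NA_real_, nq)
  if (!is.null(truth)) {
    if (length(truth) != nq) stopf("one truth id per query required")
    missing <- !(truth %in% bank_emb$ids)
    if (any(missing))
      stopf("missing ground truth in bank for query '%s'",
            query_emb$ids[which(missing)[1]])
  }
  for (i in seq_len(nq)) {
    s <- sims[i, ]
    ord <- order(-s, bank_emb$ids, method = "radix")
    rows[[i]] <- data.frame(query_id = query_emb$ids[i], rank = seq_len(k),
                            candidate_id = bank_emb$ids[ord][seq_len(k)],
                            similarity = s[ord][seq_len(k)],
                            stringsAsFactors = FALSE)
    if (!is.null(truth)) {
      st <- s[match(truth[i], bank_emb$ids)]
      truth_rank[i] <- sum(s > st) + sum(s == st)  # worst rank among ties
      truth_quantile[i] <- truth_rank[i] / n_bank
    }
  }
  structure(list(table = do.call(rbind, rows),
                 truth_rank = if (is.null(truth)) NULL else truth_rank,
                 truth_quantile = if (is.null(truth)) NULL else truth_quantile,
                 n_bank = n_bank, query_ids = query_emb$ids),
            class = "retrieval_result")
}

#' Recall at top-K quantile
#'
#' Fraction of queries whose ground-truth candidate falls within the top
#' `K` quantile of the ranked bank (e.g. K = 0.05 counts truths ranked in
#' the best 5% of candidates).
#'
#' @param result a `retrieval_result` from [retrieve()] with known truth.
#' @param K_quantiles numeric quantile levels (default 5% and 10%).
#' @return named numeric vector of recalls, monotone non-decreasing in K.
#' @export
recall_at_k <- function(result, K_quantiles = c(0.05, 0.10)) {
  q <- result$truth_quantile
  if (is.null(q)) stopf("retrieval result lacks ground truth")
  out <- vapply(K_quantiles, function(K) mean(q <= K), 0)
  names(out) <- sprintf("recall_at_%g%%", 100 * K_quantiles)
  out
}

#' Configuration for similarity-weighted expression prediction
#'
#' @param n_folds cross-validation folds (>= 2), default 10.
#' @param top_genes evaluate the most expressed genes of each validation
#'   fold (default 300, ranked by summed raw counts).
#' @param fine_tune_epochs contrastive fine-tuning epochs per fold for
#'   trainable backends (default 10).
#' @param weight_floor `"clip_zero"` (negative similarities set to 0,
#'   keeping predictions convex combinations of reference rows) or
#'   `"softmax"` (weights `exp(w / softmax_temp)`).
#' @param softmax_temp temperature for the softmax floor.
#' @param seed fold-assignment / training seed.
#' @return a `predex_config` list.
#' @export
predex_config <- function(n_folds = 10, top_genes = 300,
                          fine_tune_epochs = 10,
                          weight_floor = c("clip_zero", "softmax"),
                          softmax_temp = 0.1, seed = 1) {
  if (n_folds < 2) stopf("n_folds must be >= 2")
  if (top_genes < 1) stopf("top_genes must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 top_genes = as.integer(top_genes),
                 fine_tune_epochs = as.integer(fine_tune_epochs),
                 weight_floor = match.arg(weight_floor),
                 softmax_temp = softmax_temp, seed = as.integer(seed)),
            class = "predex_config")
}

#' Predict spot expression as a similarity-weighted reference average
#'
#' For each query embedding the prediction is
#' `X_hat_i = sum_j w_ij X_j / sum_j w_ij`, with `w_ij` the cosine
#' similarity between query i and reference spot j, floored according to
#' `cfg$weight_floor`. Under `clip_zero` every prediction is a convex
#' combination of reference rows. If all floored weights of a query are
#' (near) zero the unweighted reference mean is used and flagged.
#'
#' @param query_emb `embedding_matrix` of queries (n_q x d).
#' @param ref_emb `embedding_matrix` of reference spots (n_r x d), rows
#'   aligned with `ref_expr`.
#' @param ref_expr reference expression (n_r x genes).
#' @param cfg a [predex_config()].
#' @return n_q x genes predicted matrix; attribute `fallback_mean` flags
#'   queries that fell back to the unweighted mean.
#' @export
predict_expression <- function(query_emb, ref_emb, ref_expr,
                               cfg = predex_config()) {
  ref_expr <- as.matrix(ref_expr)
  n_ref <- nrow(ref_expr)
  if (n_ref == 0) stopf("empty reference")
  if (nrow(ref_emb$vectors) != n_ref)
    stopf("ref_emb rows must match ref_expr rows")
  w <- cosine_similarity(query_emb, ref_emb)
  w <- switch(cfg$weight_floor,
              clip_zero = pmax(w, 0),
              softmax = exp(w / cfg$softmax_temp))
  tot <- rowSums(w)
  fallback <- tot <= 1e-12
  if (any(fallback)) w[fallback, ] <- 1
  pred <- (w %*% ref_expr) / rowSums(w)
  rownames(pred) <- query_emb$ids
  attr(pred, "fallback_mean") <- fallback
  pred
}

#' Cross-validated expression prediction from histology
#'
#' Splits the spots of a slide into `cfg$n_folds` folds (seeded). In each
#' fold a trainable backend is fine-tuned on the training spots' (patch,
#' sentence) pairs, the training sentences are encoded with the text
#' encoder and the validation patches with the image encoder, and
#' validation expression is predicted with [predict_expression()].
#' Performance is reported on each fold's `cfg$top_genes` most expressed
#' validation genes as per-gene MSE and Pearson correlation across spots.
#' Expression values are the slide's normalized layer (added on the fly
#' when absent).
#'
#' @param slide a [spot_slide()] with patches.
#' @param backend encoder backend; trainable backends are fine-tuned per
#'   fold, fixed backends ([hash_encoder()]) are used as-is.
#' @param cfg a [predex_config()].
#' @param maps,top_n sentence construction options.
#' @return list with `per_gene` (data.frame fold, gene, mse, pcc),
#'   `per_fold` (data.frame fold, mse, median_pcc), `median_pcc`,
#'   `fold_assignment`, `predictions` (spots x genes, normalized scale).
#' @export
crossval_predex <- function(slide, backend, cfg = predex_config(),
                            maps = gene_maps(), top_n = 50) {
  if (is.null(slide$patches)) stopf("slide must carry patches")
  n <- n_spots(slide)
  if (is.null(slide$lognorm)) slide <- normalize_counts(slide)
  folds <- with_seed(cfg$seed,
                     sample(rep(seq_len(cfg$n_folds), length.out = n)))
  if (min(tabulate(folds, cfg$n_folds)) < 2)
    stopf("every fold needs at least 2 spots")
  sentences <- slide_sentences(slide, maps, top_n)
  per_gene <- list()
  per_fold <- list()
  preds <- matrix(NA_real_, n, ncol(slide$counts),
                  dimnames = dimnames(slide$counts))
  for (f in seq_len(cfg$n_folds)) {
    tr <- which(folds != f); va <- which(folds == f)
    bk <- backend
    if (isTRUE(backend$trainable) && cfg$fine_tune_epochs > 0)
      bk <- fine_tune(bk, slide$patches[tr], sentences[tr],
                      train_config(epochs = cfg$fine_tune_epochs,
                                   seed = cfg$seed + f))
    ref_emb <- encode_text(bk, sentences[tr])
    qry_emb <- encode_image(bk, slide$patches[va], slide$spot_ids[va])
    pred <- predict_expression(qry_emb, ref_emb,
                               slide$lognorm[tr, , drop = FALSE], cfg)
    preds[va, ] <- pred
    top <- order(colSums(slide$counts[va, , drop = FALSE]),
                 decreasing = TRUE)[seq_len(min(cfg$top_genes,
                                                ncol(slide$counts)))]
    genes <- colnames(slide$counts)[top]
    truth <- slide$lognorm[va, genes, drop = FALSE]
    mse <- mse_per_gene(pred[, genes, drop = FALSE], truth)
    pcc <- vapply(genes, function(g) {
      if (stats::sd(truth[, g]) == 0 || stats::sd(pred[, g]) == 0)
        return(NA_real_)
      stats::cor(pred[, g], truth[, g])
    }, 0)
    per_gene[[f]] <- data.frame(fold = f, gene = genes, mse = mse,
                                pcc = pcc, row.names = NULL)
    per_fold[[f]] <- data.frame(fold = f, mse = mean(mse),
                                median_pcc = stats::median(pcc, na.rm = TRUE))
  }
  per_gene <- do.call(rbind, per_gene)
  list(per_gene = per_gene, per_fold = do.call(rbind, per_fold),
       median_pcc = stats::median(per_gene$pcc, na.rm = TRUE),
       fold_assignment = folds, predictions = preds)
}
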