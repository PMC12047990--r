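#' Reference profile for zero-shot annotation
#'
#' A named transcriptomic reference rendered as a gene sentence, either
#' from bulk RNA-seq expression (sentence built by ranking expression, with
#' multiple samples averaged first) or from an ordered marker-gene list
#' (kept exactly in the user's order, since marker lists carry no
#' expression values to rank by).
#'
#' @param name reference label.
#' @param kind `"bulk"` or `"markers"`.
#' @param markers ordered character vector of marker symbols (`markers`
#'   kind).
#' @param expression numeric vector, or samples x genes matrix to average
#'   (`bulk` kind).
#' @param gene_ids gene identifiers for `expression`.
#' @param maps a [gene_maps()] used for bulk sentence construction.
#' @param top_n sentence cap for bulk references.
#' @return object of class `reference_profile` carrying a `gene_sentence`.
#' @export
reference_profile <- function(name, kind = c("bulk", "markers"),
                              markers = NULL, expression = NULL,
                              gene_ids = NULL, maps = gene_maps(),
                              top_n = 50) {
  kind <- match.arg(kind)
  if (kind == "markers") {
    if (is.null(markers) || length(markers) == 0)
      stopf("markers kind requires a non-empty marker list")
    sentence <- structure(list(tokens = as.character(markers),
                               source_id = name), class = "gene_sentence")
    expr <- NULL
  } else {
    if (is.null(expression)) stopf("bulk kind requires expression")
    if (is.matrix(expression)) expression <- colMeans(expression)
    sentence <- build_gene_sentence(expression, gene_ids, maps, top_n, name)
    expr <- expression
  }
  structure(list(name = name, kind = kind, sentence = sentence,
                 source_expression = expr),
            class = "reference_profile")
}

#' Similarity heatmap of patches against one reference
#'
#' Scores each image-patch embedding by its cosine similarity to the text
#' embedding of the reference sentence. Higher scores indicate greater
#' presence of the referenced tissue type at that spot.
#'
#' @param patch_emb `embedding_matrix` of patch (or spot) embeddings.
#' @param ref a [reference_profile()].
#' @param backend encoder backend used to embed the reference sentence.
#' @return a `similarity_map`: data.frame (spot_id, score) with the
#'   reference name attached.
#' @export
annotate_with_reference <- function(patch_emb, ref, backend) {
  if (!inherits(ref, "reference_profile")) stopf("ref must be a reference_profile")
  ref_emb <- encode_text(backend, list(ref$sentence))
  scores <- as.numeric(cosine_similarity(patch_emb, ref_emb))
  structure(data.frame(spot_id = patch_emb$ids, score = scores,
                       stringsAsFactors = FALSE),
            reference = ref$name, class = c("similarity_map", "data.frame"))
}

#' Zero-shot classification against candidate references
#'
#' Embeds every candidate reference sentence and assigns each query the
#' label of the candidate with the highest cosine similarity. Ties are
#' broken by candidate list order and flagged.
#'
#' @param image_emb `embedding_matrix` of query embeddings.
#' @param candidates list of [reference_profile()] with unique names
#'   (>= 2).
#' @param backend encoder backend.
#' @return list with `labels` (per query), `scores` (queries x candidates
#'   matrix), and `tie` (logical per query).
#' @export
zero_shot_classify <- function(image_emb, candidates, backend) {
  if (length(candidates) < 2) stopf("need at least 2 candidates")
  nms <- vapply(candidates, function(r) r$name, "")
  if (anyDuplicated(nms)) stopf("duplicate candidate names")
  cand_emb <- encode_text(backend, lapply(candidates, function(r) r$sentence))
  scores <- cosine_similarity(image_emb, cand_emb)
  colnames(scores) <- nms
  rownames(scores) <- image_emb$ids
  best <- max.col(scores, ties.method = "first")
  tie <- vapply(seq_len(nrow(scores)), function(i)
    sum(scores[i, ] == scores[i, best[i]]) > 1, TRUE)
  if (any(tie)) message(sprintf("zero_shot_classify: %d tie(s) broken by candidate order",
                                sum(tie)))
  list(labels = nms[best], scores = scores, tie = tie)
}

min_max_rows <- function(m) {
  out <- m
  const <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    if (max(r) == min(r)) { out[i, ] <- 0; const[i] <- TRUE }
    else out[i, ] <- (r - min(r)) / (max(r) - min(r))
  }
  attr(out, "constant_rows") <- const
  out
}

#' Fuse two similarity score tables
#'
#' Min-max normalizes each table's scores per query over the candidates
#' (best candidate 1, worst 0), sums the two normalized tables, and labels
#' each query by the argmax of the combined score. Lets two models (e.g.
#' this package's scores and an external pathology-language model's) vote
#' on the same candidates. Constant rows normalize to all zeros (with a
#' warning) so the informative table drives the fused argmax.
#'
#' @param a,b queries x candidates score matrices with identical row and
#'   column label sets (column order is reconciled by name).
#' @return list with `labels`, `fused` (combined score matrix), `tie`.
#' @export
fuse_scores <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(colnames(a)) || is.null(colnames(b)))
    stopf("score tables need candidate column names")
  if (!setequal(colnames(a), colnames(b)))
    stopf("candidate label sets differ: %s",
          paste(union(setdiff(colnames(a), colnames(b)),
                      setdiff(colnames(b), colnames(a))), collapse = ", "))
  if (nrow(a) != nrow(b)) stopf("query sets differ in size")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b)))
      stopf("query label sets differ")
    b <- b[rownames(a), , drop = FALSE]
  }
  b <- b[, colnames(a), drop = FALSE]
  na <- min_max_rows(a); nb <- min_max_rows(b)
  if (any(attr(na, "constant_rows")) || any(attr(nb, "constant_rows")))
    warnf("constant score row(s) normalized to zeros")
  fused <- na + nb
  best <- max.col(fused, ties.method = "first")
  tie <- vapply(seq_len(nrow(fused)), function(i)
    sum(fused[i, ] == fused[i, best[i]]) > 1, TRUE)
  list(labels = colnames(fused)[best], fused = fused, tie = tie)
}

#' Rank-sum test of similarity inside vs outside a region
#'
#' Two-sided Wilcoxon rank-sum test comparing a similarity map's scores
#' within an annotated region against those outside it, quantifying
#' whether the reference's signal is enriched where the pathologist drew
#' the region.
#'
#' @param map a `similarity_map` from [annotate_with_reference()] (or any
#'   data.frame with a `score` column).
#' @param region_mask logical per spot, TRUE inside the region; both
#'   classes must be non-empty.
#' @return list with `statistic`, `p_value`, `median_in`, `median_out`.
#' @export
region_enrichment_test <- function(map, region_mask) {
  scores <- map$score
  if (length(region_mask) != length(scores))
    stopf("mask length must match map")
  if (!any(region_mask) || all(region_mask))
    stopf("region mask must contain both classes")
  ht <- stats::wilcox.test(scores[region_mask], scores[!region_mask],
                           alternative = "two.sided", exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       median_in = stats::median(scores[region_mask]),
       median_out = stats::median(scores[!region_mask]))
}
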