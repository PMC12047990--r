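#' Gene identifier maps and housekeeping list
#'
#' Bundles the two reference tables used when turning an expression profile
#' into a gene sentence: an Ensembl-ID to gene-symbol conversion table and
#' a set of housekeeping genes to exclude. Housekeeping genes are removed
#' because they are highly expressed almost everywhere and would crowd the
#' top ranks of every sentence without carrying tissue information.
#'
#' @param ensembl_to_symbol named character vector or two-column data.frame
#'   (ensembl_id, symbol); may be empty when inputs already use symbols.
#' @param housekeeping character vector of housekeeping gene symbols.
#' @return object of class `gene_maps`.
#' @export
gene_maps <- function(ensembl_to_symbol = character(),
                      housekeeping = character()) {
  if (is.data.frame(ensembl_to_symbol)) {
    m <- as.character(ensembl_to_symbol[[2]])
    names(m) <- as.character(ensembl_to_symbol[[1]])
    ensembl_to_symbol <- m
  }
  if (length(ensembl_to_symbol) && any(!nzchar(ensembl_to_symbol)))
    stopf("gene map values must be non-empty symbols")
  structure(list(ensembl_to_symbol = ensembl_to_symbol,
                 housekeeping = unique(as.character(housekeeping))),
            class = "gene_maps")
}

#' Default housekeeping gene list
#'
#' A small list of classic human housekeeping genes (ribosomal proteins,
#' GAPDH, ACTB, tubulins, ...) shipped with the package as a starting
#' point; for real analyses supply your own curated list to [gene_maps()].
#'
#' @return character vector of symbols.
#' @export
default_housekeeping <- function() {
  path <- system.file("extdata", "housekeeping_default.tsv",
                      package = "stclip", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)$symbol
}

#' Build a rank-ordered gene sentence from one expression profile
#'
#' The text representation of a spot (or cell, or bulk sample): gene symbols
#' ranked from highest to lowest expression, housekeeping genes removed,
#' truncated to the `top_n` most expressed, and joined by single spaces.
#' Because only the rank order enters, the representation is invariant to
#' library size and robust to batch effects in the raw counts.
#'
#' Ranking uses the values as given (raw counts by default); ties are broken
#' by ascending symbol order so sentences are reproducible across platforms.
#'
#' @param expression nonnegative numeric vector, one value per gene.
#' @param gene_ids gene identifiers aligned with `expression` (symbols or
#'   Ensembl IDs; IDs found in `maps$ensembl_to_symbol` are converted).
#' @param maps a [gene_maps()] object.
#' @param top_n sentence length cap (default 50).
#' @param source_id identifier recorded on the sentence.
#' @return object of class `gene_sentence` with fields `tokens` (ordered
#'   symbols) and `source_id`. Errors if no non-housekeeping gene has
#'   positive expression.
#' @export
build_gene_sentence <- function(expression, gene_ids,
                                maps = gene_maps(), top_n = 50,
                                source_id = "profile") {
  if (length(expression) != length(gene_ids))
    stopf("expression length must equal gene_ids length")
  if (any(expression < 0)) stopf("expression must be nonnegative")
  assert_scalar_num(top_n, "top_n", 1)
  sym <- as.character(gene_ids)
  if (length(maps$ensembl_to_symbol)) {
    hit <- match(sym, names(maps$ensembl_to_symbol))
    sym[!is.na(hit)] <- unname(maps$ensembl_to_symbol[hit[!is.na(hit)]])
  }
  keep <- expression > 0 & !(sym %in% maps$housekeeping)
  if (!any(keep))
    stopf("profile '%s' has no nonzero non-housekeeping gene", source_id)
  sym <- sym[keep]; val <- expression[keep]
  ## descending expression, ties by ascending symbol
  ord <- order(-val, sym, method = "radix")
  tokens <- sym[ord][seq_len(min(top_n, length(ord)))]
  structure(list(tokens = tokens, source_id = as.character(source_id)),
            class = "gene_sentence")
}

#' @export
print.gene_sentence <- function(x, ...) {
  cat(sprintf("gene_sentence [%s] (%d tokens): %s%s\n", x$source_id,
              length(x$tokens),
              paste(utils::head(x$tokens, 8), collapse = " "),
              if (length(x$tokens) > 8) " ..." else ""))
  invisible(x)
}

#' Serialize a gene sentence
#' @param sentence a `gene_sentence`.
#' @return the tokens joined by single spaces.
#' @export
sentence_string <- function(sentence) paste(sentence$tokens, collapse = " ")

#' Gene sentences for every spot of a slide
#'
#' @param slide a [spot_slide()].
#' @param maps a [gene_maps()].
#' @param top_n sentence length cap.
#' @return list of `gene_sentence`, one per spot, named by spot id.
#' @export
slide_sentences <- function(slide, maps = gene_maps(), top_n = 50) {
  out <- lapply(seq_len(n_spots(slide)), function(i)
    build_gene_sentence(slide$counts[i, ], slide$gene_symbols, maps,
                        top_n, source_id = slide$spot_ids[i]))
  names(out) <- slide$spot_ids
  out
}
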