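#' Read a spot slide from standard 10x-style files
#'
#' Loads a MatrixMarket count matrix together with its feature and barcode
#' tables and a tissue-positions CSV (columns `barcode,x_um,y_um`), and
#' optionally per-spot PNG patches named `<barcode>.png`. Matrix orientation
#' (genes x spots, the CellRanger convention, vs spots x genes) is
#' auto-detected from the barcode count and recorded in the returned
#' attribute `orientation`. Spots missing from the positions file are
#' dropped with a message reporting how many.
#'
#' @param matrix_path path to the `.mtx` count matrix.
#' @param features_path TSV of features; first column Ensembl ID or symbol,
#'   second column (if present) gene symbol.
#' @param barcodes_path TSV of barcodes (one per line).
#' @param positions_path CSV with columns `barcode,x_um,y_um`.
#' @param patches_dir optional directory of `<barcode>.png` patches.
#' @param spot_diameter_um,pitch_um geometry metadata stored on the slide.
#' @return a [spot_slide()] with counts oriented spots x genes.
#' @export
read_slide <- function(matrix_path, features_path, barcodes_path,
                       positions_path, patches_dir = NULL,
                       spot_diameter_um = 55, pitch_um = 100) {
  for (p in c(matrix_path, features_path, barcodes_path, positions_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  m <- Matrix::readMM(matrix_path)
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  orientation <- if (length(barcodes) == ncol(m) &&
                     nrow(m) == length(symbols)) {
    "genes_x_spots"
  } else if (length(barcodes) == nrow(m) && ncol(m) == length(symbols)) {
    "spots_x_genes"
  } else {
    stopf(paste0("dimension mismatch: matrix %dx%d vs %d barcodes (%s) ",
                 "and %d features (%s)"),
          nrow(m), ncol(m), length(barcodes), barcodes_path,
          length(symbols), features_path)
  }
  counts <- as.matrix(m)
  if (orientation == "genes_x_spots") counts <- t(counts)
  if (any(abs(counts - round(counts)) > 1e-8))
    stopf("non-integer values in count matrix %s", matrix_path)
  pos <- utils::read.csv(positions_path, stringsAsFactors = FALSE)
  need <- c("barcode", "x_um", "y_um")
  if (!all(need %in% names(pos)))
    stopf("positions file %s must have columns barcode,x_um,y_um",
          positions_path)
  hit <- match(barcodes, pos$barcode)
  dropped <- sum(is.na(hit))
  if (dropped > 0)
    message(sprintf("read_slide: dropped %d spot(s) lacking positions",
                    dropped))
  keep <- !is.na(hit)
  barcodes <- barcodes[keep]
  counts <- counts[keep, , drop = FALSE]
  coords <- as.matrix(pos[hit[keep], c("x_um", "y_um")])
  patches <- NULL
  if (!is.null(patches_dir)) {
    files <- file.path(patches_dir, paste0(barcodes, ".png"))
    if (!all(file.exists(files)))
      stopf("missing patch PNG(s) under %s", patches_dir)
    patches <- lapply(files, function(f) png::readPNG(f) * 255)
    patches <- lapply(patches, function(p) {
      if (length(dim(p)) == 2L) p <- array(rep(p, 3), c(dim(p), 3))
      p[, , 1:3, drop = FALSE]
    })
  }
  slide <- spot_slide(barcodes, coords, counts, symbols, patches,
                      spot_diameter_um, pitch_um)
  attr(slide, "orientation") <- orientation
  slide
}

#' Write a spot slide to standard files
#'
#' Inverse of [read_slide()]: writes `matrix.mtx` (genes x spots),
#' `features.tsv`, `barcodes.tsv`, `positions.csv`, and (when patches are
#' present) one PNG per spot under `patches/`. The round trip
#' `read_slide(write_slide(s))` reproduces counts, coordinates, and symbols
#' bit-exactly.
#'
#' @param slide a [spot_slide()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(slide$counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(slide$gene_symbols, file.path(dir, "features.tsv"))
  writeLines(slide$spot_ids, file.path(dir, "barcodes.tsv"))
  utils::write.csv(data.frame(barcode = slide$spot_ids,
                              x_um = slide$coords[, 1],
                              y_um = slide$coords[, 2]),
                   file.path(dir, "positions.csv"), row.names = FALSE)
  if (!is.null(slide$patches)) {
    pd <- file.path(dir, "patches")
    dir.create(pd, showWarnings = FALSE)
    for (i in seq_along(slide$patches))
      png::writePNG(pmin(pmax(slide$patches[[i]] / 255, 0), 1),
                    file.path(pd, paste0(slide$spot_ids[i], ".png")))
  }
  invisible(dir)
}

#' Write gene sentences as a two-column TSV
#' @param sentences list of [build_gene_sentence()] results.
#' @param path output TSV path (columns `id`, `sentence`).
#' @return `path`, invisibly.
#' @export
write_sentences <- function(sentences, path) {
  df <- data.frame(id = vapply(sentences, function(s) s$source_id, ""),
                   sentence = vapply(sentences, sentence_string, ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sentences from a two-column TSV
#' @param path TSV with columns `id`, `sentence`.
#' @return list of `gene_sentence` objects.
#' @export
read_sentences <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    structure(list(tokens = strsplit(df$sentence[i], " ", fixed = TRUE)[[1]],
                   source_id = as.character(df$id[i])),
              class = "gene_sentence"))
}

#' Write an embedding matrix as TSV
#' @param emb an `embedding_matrix`.
#' @param path output path; first column `id`, then `V1..Vd`, plus a
#'   `modality` header comment line.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modality=%s d=%d", emb$modality, ncol(emb$vectors)),
             con)
  df <- data.frame(id = emb$ids, emb$vectors, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding matrix written by [write_embeddings()]
#' @param path TSV path.
#' @return an `embedding_matrix`.
#' @export
read_embeddings <- function(path) {
  first <- readLines(path, n = 1)
  modality <- sub(".*modality=(\\w+).*", "\\1", first)
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  embedding_matrix(as.matrix(df[, -1, drop = FALSE]), df$id, modality)
}
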