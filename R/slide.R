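#' Spot-level spatial transcriptomics container
#'
#' `spot_slide` is the universal container used throughout the package: a set
#' of capture spots, each with a 2D position in microns, a nonnegative integer
#' gene-count vector, and optionally an associated histology image patch.
#' It mirrors the layout of a 10x Visium sample (55 um spots on a ~100 um
#' pitch hexagonal grid) but carries any spot-based platform.
#'
#' @param spot_ids character vector of unique spot identifiers (barcodes).
#' @param coords numeric matrix (n_spots x 2) of positions in microns,
#'   x to the right and y downward (image pixel convention), 0-based origin.
#' @param counts nonnegative integer matrix, spots x genes.
#' @param gene_symbols character vector of unique gene symbols, one per
#'   counts column.
#' @param patches optional list of per-spot image arrays (H x W x 3, values
#'   in \[0, 255\]), one per spot, all the same shape.
#' @param spot_diameter_um spot (capture area) diameter in microns.
#' @param pitch_um center-to-center spot spacing in microns.
#'
#' @return An object of class `spot_slide`.
#' @export
spot_slide <- function(spot_ids, coords, counts, gene_symbols,
                       patches = NULL, spot_diameter_um = 55,
                       pitch_um = 100) {
  spot_ids <- as.character(spot_ids)
  coords <- as.matrix(coords)
  counts <- as.matrix(counts)
  gene_symbols <- as.character(gene_symbols)
  n <- length(spot_ids)
  if (anyDuplicated(spot_ids)) stopf("spot_ids must be unique")
  if (nrow(coords) != n || ncol(coords) != 2L)
    stopf("coords must be an n_spots x 2 matrix (one coordinate pair per spot)")
  if (nrow(counts) != n)
    stopf("counts must have one row per spot (%d spots, %d rows)",
          n, nrow(counts))
  if (ncol(counts) != length(gene_symbols))
    stopf("gene_symbols length (%d) must match counts columns (%d)",
          length(gene_symbols), ncol(counts))
  if (anyDuplicated(gene_symbols)) stopf("gene_symbols must be unique")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stopf("counts must be integers")
  counts <- round(counts)
  if (!is.null(patches)) {
    if (length(patches) != n)
      stopf("patches must have one element per spot")
    dims <- vapply(patches, function(p) paste(dim(p), collapse = "x"), "")
    if (length(unique(dims)) != 1L || length(dim(patches[[1]])) != 3L ||
        dim(patches[[1]])[3] != 3L)
      stopf("patches must all be H x W x 3 arrays of identical shape")
  }
  assert_scalar_num(spot_diameter_um, "spot_diameter_um", 0, strict_lower = TRUE)
  assert_scalar_num(pitch_um, "pitch_um", 0, strict_lower = TRUE)
  rownames(coords) <- rownames(counts) <- spot_ids
  colnames(counts) <- gene_symbols
  colnames(coords) <- c("x_um", "y_um")
  structure(list(spot_ids = spot_ids, coords = coords, counts = counts,
                 gene_symbols = gene_symbols, patches = patches,
                 spot_diameter_um = spot_diameter_um, pitch_um = pitch_um,
                 lognorm = NULL, zero_library = NULL),
            class = "spot_slide")
}

#' @export
print.spot_slide <- function(x, ...) {
  cat(sprintf("spot_slide: %d spots x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  spot diameter %g um, pitch %g um\n",
              x$spot_diameter_um, x$pitch_um))
  cat(sprintf("  patches: %s\n",
              if (is.null(x$patches)) "none"
              else paste(dim(x$patches[[1]])[1:2], collapse = "x")))
  if (!is.null(x$lognorm)) cat("  normalized layer present\n")
  invisible(x)
}

#' Number of spots in a slide
#' @param slide a `spot_slide`.
#' @return integer spot count.
#' @export
n_spots <- function(slide) length(slide$spot_ids)

#' Subset a slide by spot index
#' @param slide a `spot_slide`.
#' @param idx integer or logical index over spots.
#' @return a `spot_slide` restricted to the selected spots, order preserved.
#' @export
subset_spots <- function(slide, idx) {
  out <- slide
  out$spot_ids <- slide$spot_ids[idx]
  out$coords <- slide$coords[idx, , drop = FALSE]
  out$counts <- slide$counts[idx, , drop = FALSE]
  if (!is.null(slide$patches)) out$patches <- slide$patches[idx]
  if (!is.null(slide$lognorm)) out$lognorm <- slide$lognorm[idx, , drop = FALSE]
  if (!is.null(slide$zero_library)) out$zero_library <- slide$zero_library[idx]
  out
}

#' Quality-control filter on spots
#'
#' Retains exactly the spots expressing strictly more than `min_genes`
#' genes (a gene counts as expressed in a spot when its raw count is > 0).
#' The strict inequality means the default keeps spots with over 200
#' expressed genes, the standard cutoff for discarding contaminated or
#' damaged capture areas.
#'
#' @param slide a `spot_slide`.
#' @param min_genes nonnegative integer threshold; a spot is kept when its
#'   number of expressed genes exceeds this value.
#' @return the filtered `spot_slide`; spot order is preserved. Filtering is
#'   idempotent. If every spot is removed an empty slide is returned with a
#'   warning.
#' @export
qc_filter_spots <- function(slide, min_genes = 200) {
  assert_scalar_num(min_genes, "min_genes", 0)
  expressed <- rowSums(slide$counts > 0)
  keep <- expressed > min_genes
  if (!any(keep)) warnf("qc_filter_spots removed every spot")
  subset_spots(slide, keep)
}

#' Library-size normalization layer
#'
#' Adds a log-normalized expression layer following the standard
#' single-cell/ST protocol: each spot's counts are scaled to a common
#' library size `target_sum` and log1p-transformed,
#' `log(1 + count / libsize * target_sum)`. Raw counts are retained
#' untouched; spots with zero library size get an all-zero normalized row
#' and are flagged in `$zero_library`.
#'
#' @param slide a `spot_slide`.
#' @param target_sum scale each spot to this total before log1p.
#' @return the slide with `$lognorm` (spots x genes) and `$zero_library`
#'   (logical per spot) filled in.
#' @export
normalize_counts <- function(slide, target_sum = 1e4) {
  assert_scalar_num(target_sum, "target_sum", 0, strict_lower = TRUE)
  lib <- rowSums(slide$counts)
  zero <- lib == 0
  scale <- ifelse(zero, 0, target_sum / pmax(lib, 1e-300))
  slide$lognorm <- log1p(slide$counts * scale)
  dimnames(slide$lognorm) <- dimnames(slide$counts)
  slide$zero_library <- zero
  slide
}

#' Aggregate single-cell-resolution data into pseudo-spots
#'
#' Lays a Visium-geometry grid of circular pseudo-spots (hexagonal-offset
#' rows, `pitch_um` apart within a row, rows `pitch_um * sqrt(3)/2` apart)
#' over the bounding box of the cells and averages the expression of the
#' cells whose centers fall inside each circle. This is how single-cell
#' platforms (Xenium, Visium HD) are reduced to spot resolution so they can
#' serve as ground truth for spot-level methods.
#'
#' @param cell_coords numeric matrix (cells x 2), positions in microns.
#' @param cell_counts matrix (cells x genes) of expression.
#' @param pitch_um pseudo-spot center spacing; must be >= `diameter_um`.
#' @param diameter_um pseudo-spot capture diameter.
#' @param aggregate `"mean"` (default) or `"sum"` over member cells.
#' @return list with `slide` (a `spot_slide` of the non-empty pseudo-spots;
#'   counts are rounded means when `aggregate = "mean"`, with the exact
#'   profile kept in `$lognorm = NULL` untouched and returned separately as
#'   `profiles`) and `membership`, a data.frame (cell, spot) mapping every
#'   captured cell to its pseudo-spot. Cells on a circle boundary are
#'   included; each cell is assigned to at most one pseudo-spot (its nearest
#'   center).
#' @export
bin_pseudo_spots <- function(cell_coords, cell_counts, pitch_um = 100,
                             diameter_um = 55, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  cell_coords <- as.matrix(cell_coords)
  cell_counts <- as.matrix(cell_counts)
  if (nrow(cell_coords) < 1L) stopf("need at least one cell")
  if (pitch_um < diameter_um || diameter_um <= 0)
    stopf("require pitch_um >= diameter_um > 0")
  r <- diameter_um / 2
  xr <- range(cell_coords[, 1]); yr <- range(cell_coords[, 2])
  row_pitch <- pitch_um * sqrt(3) / 2
  ys <- seq(yr[1], yr[2] + row_pitch, by = row_pitch)
  centers <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) pitch_um / 2 else 0
    xs <- seq(xr[1] - pitch_um + off, xr[2] + pitch_um, by = pitch_um)
    cbind(xs, ys[i])
  }))
  ## nearest center per cell; captured iff within the circle (boundary in)
  d2 <- outer(rowSums(cell_coords^2), rowSums(centers^2), "+") -
    2 * cell_coords %*% t(centers)
  nearest <- max.col(-d2, ties.method = "first")
  dist_near <- sqrt(pmax(d2[cbind(seq_len(nrow(cell_coords)), nearest)], 0))
  captured <- dist_near <= r + 1e-9
  if (!any(captured)) stopf("no cell falls inside any pseudo-spot")
  spot_of <- nearest[captured]
  used <- sort(unique(spot_of))
  remap <- match(spot_of, used)
  n_ps <- length(used)
  agg <- matrix(0, n_ps, ncol(cell_counts))
  cnt <- tabulate(remap, n_ps)
  for (g in seq_len(ncol(cell_counts)))
    agg[, g] <- rowsum(cell_counts[captured, g], remap)[, 1]
  profiles <- if (aggregate == "mean") agg / cnt else agg
  ids <- sprintf("pseudo_%04d", seq_len(n_ps))
  slide <- spot_slide(ids, centers[used, , drop = FALSE], round(profiles),
                      colnames(cell_counts) %||%
                        sprintf("gene%04d", seq_len(ncol(cell_counts))),
                      spot_diameter_um = diameter_um, pitch_um = pitch_um)
  membership <- data.frame(cell = which(captured), spot = ids[remap])
  list(slide = slide, profiles = profiles, membership = membership,
       n_cells_per_spot = cnt)
}

#' Crop per-spot image patches from a slide image
#'
#' Cuts a square patch of side `ceil(diameter_um / microns_per_pixel)`
#' pixels centered on each spot, matching the patch size to the spot
#' capture area. Patches that would extend past the image border are
#' zero-padded and flagged.
#'
#' @param image numeric array H x W x 3 (values in \[0, 255\]).
#' @param coords spot centers in microns (n x 2, x right / y down).
#' @param microns_per_pixel image scale; must be positive.
#' @param diameter_um spot diameter in microns.
#' @return list with `patches` (list of side x side x 3 arrays) and
#'   `padded` (logical per spot, TRUE when zero-padding was needed).
#' @export
extract_patches <- function(image, coords, microns_per_pixel, diameter_um) {
  assert_scalar_num(microns_per_pixel, "microns_per_pixel", 0,
                    strict_lower = TRUE)
  assert_scalar_num(diameter_um, "diameter_um", 0, strict_lower = TRUE)
  coords <- as.matrix(coords)
  side <- ceiling(diameter_um / microns_per_pixel)
  H <- dim(image)[1]; W <- dim(image)[2]
  half_lo <- floor((side - 1) / 2)
  patches <- vector("list", nrow(coords))
  padded <- logical(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    cx <- round(coords[i, 1] / microns_per_pixel)  # column (x right)
    cy <- round(coords[i, 2] / microns_per_pixel)  # row (y down)
    rows <- (cy - half_lo):(cy - half_lo + side - 1) + 1L
    cols <- (cx - half_lo):(cx - half_lo + side - 1) + 1L
    patch <- array(0, c(side, side, 3))
    ok_r <- rows >= 1L & rows <= H
    ok_c <- cols >= 1L & cols <= W
    if (!all(ok_r) || !all(ok_c)) padded[i] <- TRUE
    if (any(ok_r) && any(ok_c))
      patch[which(ok_r), which(ok_c), ] <-
        image[rows[ok_r], cols[ok_c], , drop = FALSE]
    patches[[i]] <- patch
  }
  list(patches = patches, padded = padded)
}
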