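#' Configuration for the synthetic paired-slide generator
#'
#' Defines a small spatial-transcriptomics world with known ground truth:
#' spots on a Visium-style hexagonal grid, a handful of spatial domains
#' each driven by a disjoint gene program, Poisson counts at a controlled
#' sequencing depth, and image patches rendered deterministically from the
#' same per-spot program mixture so that image features and expression are
#' linked through a shared latent.
#'
#' @param n_spots number of spots (default 200).
#' @param n_genes number of genes (default 120); each type's program needs
#'   at least 10 genes, so `n_types <= n_genes / 10`.
#' @param n_types number of cell types / domains (default 4).
#' @param program_strength fold-change of program genes over the
#'   background mean of 1 (default 50).
#' @param depth expected UMI per spot (default 5000).
#' @param cell_depth expected UMI per reference cell (default 2000).
#' @param n_cells_per_type reference cells sampled per type (default 50).
#' @param mix_bandwidth_um spatial softness of the domain mixture: per-spot
#'   type fractions are Gaussian kernels of the distance to each domain
#'   center with this bandwidth, so interior spots are nearly pure and
#'   boundary spots mixed (default 180).
#' @param patch_px patch side in pixels (default 16).
#' @param image_noise_sd Gaussian pixel noise added to patches (8-bit
#'   scale).
#' @param expr_noise_sd log-normal multiplicative noise sd on expression
#'   rates.
#' @param coord_noise_sd Gaussian jitter sd on coordinates, microns.
#' @param rotation_deg rotation applied by [perturb_alignment()] defaults.
#' @param pitch_um spot pitch (default 100).
#' @param seed RNG seed; together with the other fields it fully
#'   determines the generated data.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_spots = 200, n_genes = 120, n_types = 4,
                         program_strength = 50, depth = 5000,
                         cell_depth = 2000, n_cells_per_type = 50,
                         mix_bandwidth_um = 180, patch_px = 16,
                         image_noise_sd = 0, expr_noise_sd = 0,
                         coord_noise_sd = 0, rotation_deg = 0,
                         pitch_um = 100, seed = 1) {
  if (n_types > n_genes / 10)
    stopf("n_types (%d) too large: each program needs >= 10 genes", n_types)
  for (s in c(image_noise_sd, expr_noise_sd, coord_noise_sd))
    assert_scalar_num(s, "noise sd", 0)
  structure(as.list(environment()), class = "synth_config")
}

hex_grid <- function(n, pitch) {
  ncol_ <- ceiling(sqrt(n))
  coords <- matrix(0, 0, 2)
  row <- 0
  while (nrow(coords) < n) {
    off <- if (row %% 2 == 1) pitch / 2 else 0
    xs <- (seq_len(ncol_) - 1) * pitch + off
    coords <- rbind(coords, cbind(xs, row * pitch * sqrt(3) / 2))
    row <- row + 1
  }
  coords[seq_len(n), , drop = FALSE]
}

type_palette <- function(n) {
  hues <- seq(0, 1 - 1 / n, length.out = n)
  t(vapply(hues, function(h) as.numeric(grDevices::col2rgb(
    grDevices::hsv(h, 0.75, 0.85))), numeric(3)))
}

#' Generate a synthetic slide with paired patches and ground truth
#'
#' Spots sit on a hexagonal grid; `n_types` domain centers are spread over
#' the tissue and each spot's true cell-type fractions are normalized
#' Gaussian kernels of its distance to the centers (`mix_bandwidth_um`),
#' so every spot has a unique, spatially smooth composition with nearly
#' pure domain interiors. Each type owns a disjoint gene program
#' (`n_genes / n_types` genes at `program_strength` times the background
#' rate of 1); a spot's expression rate is the fraction-weighted mixture
#' scaled to `depth` total UMI, sampled as Poisson counts. The patch of a
#' spot is its fraction-weighted blend of per-type base colors plus seeded
#' texture, so image and expression share the composition latent. A
#' single-cell reference (pure-type cells, Poisson at `cell_depth`) is
#' generated from the same programs.
#'
#' @param cfg a [synth_config()].
#' @return list with `slide` (a [spot_slide()] with patches) and `truth`
#'   (domain label, type fractions, type programs, cell reference counts,
#'   labels and coords, and the generating config).
#' @export
make_slide <- function(cfg = synth_config()) {
  with_seed(cfg$seed, {
    coords <- hex_grid(cfg$n_spots, cfg$pitch_um)
    span_x <- max(coords[, 1]); span_y <- max(coords[, 2])
    ## domain centers on a coarse grid over the tissue
    gx <- ceiling(sqrt(cfg$n_types))
    gy <- ceiling(cfg$n_types / gx)
    centers <- as.matrix(expand.grid(
      x = seq(span_x * 0.2, span_x * 0.8, length.out = gx),
      y = seq(span_y * 0.2, span_y * 0.8, length.out = gy)))[
        seq_len(cfg$n_types), , drop = FALSE]
    d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
      2 * coords %*% t(centers)
    fractions <- exp(-pmax(d2, 0) / (2 * cfg$mix_bandwidth_um^2))
    fractions <- fractions / rowSums(fractions)
    domain <- max.col(fractions, ties.method = "first")
    ## disjoint gene programs
    prog_size <- floor(cfg$n_genes / cfg$n_types)
    genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    programs <- lapply(seq_len(cfg$n_types), function(t)
      ((t - 1) * prog_size + 1):(t * prog_size))
    type_profiles <- matrix(1, cfg$n_types, cfg$n_genes)
    for (t in seq_len(cfg$n_types))
      type_profiles[t, programs[[t]]] <- cfg$program_strength
    type_profiles <- type_profiles / rowSums(type_profiles)
    ## spot counts
    rates <- fractions %*% type_profiles * cfg$depth
    if (cfg$expr_noise_sd > 0)
      rates <- rates * matrix(exp(stats::rnorm(length(rates), 0,
                                               cfg$expr_noise_sd)),
                              nrow(rates))
    counts <- matrix(stats::rpois(length(rates), as.numeric(rates)),
                     nrow(rates), dimnames = list(NULL, genes))
    ## patches: fraction-weighted type colors + texture
    pal <- type_palette(cfg$n_types)
    base_cols <- fractions %*% pal
    px <- cfg$patch_px
    patches <- lapply(seq_len(cfg$n_spots), function(i) {
      p <- array(rep(base_cols[i, ], each = px * px), c(px, px, 3))
      p <- p + array(stats::rnorm(px * px * 3, 0, 8), c(px, px, 3))
      if (cfg$image_noise_sd > 0)
        p <- p + array(stats::rnorm(px * px * 3, 0, cfg$image_noise_sd),
                       c(px, px, 3))
      pmin(pmax(p, 0), 255)
    })
    spot_ids <- sprintf("spot_%04d", seq_len(cfg$n_spots))
    slide <- spot_slide(spot_ids, coords, counts, genes, patches,
                        spot_diameter_um = 55, pitch_um = cfg$pitch_um)
    ## pure-type single-cell reference
    n_cells <- cfg$n_cells_per_type * cfg$n_types
    cell_labels <- rep(sprintf("type%d", seq_len(cfg$n_types)),
                       each = cfg$n_cells_per_type)
    cell_rates <- type_profiles[rep(seq_len(cfg$n_types),
                                    each = cfg$n_cells_per_type), ] *
      cfg$cell_depth
    cell_counts <- matrix(stats::rpois(length(cell_rates),
                                       as.numeric(cell_rates)),
                          nrow(cell_rates), dimnames = list(NULL, genes))
    colnames(fractions) <- sprintf("type%d", seq_len(cfg$n_types))
    list(slide = slide,
         truth = list(domain = sprintf("type%d", domain),
                      fractions = fractions,
                      programs = lapply(programs, function(p) genes[p]),
                      type_profiles = type_profiles,
                      cell_counts = cell_counts,
                      cell_labels = cell_labels,
                      centers = centers, config = cfg))
  })
}

#' Perturb a slide's expression and geometry with known ground truth
#'
#' Applies log-normal multiplicative noise to the counts (re-rounded to
#' integers), rotates the coordinates about their centroid, and jitters
#' them with Gaussian noise — emulating an adjacent, distorted section
#' whose true spot positions are known. The unperturbed coordinates are
#' returned as ground truth for distance-to-truth scoring.
#'
#' @param slide a [spot_slide()].
#' @param expr_noise_sd sd of log-normal count noise (0 = none).
#' @param coord_noise_sd sd of coordinate jitter in microns.
#' @param rotation_deg rotation about the centroid, degrees.
#' @param seed RNG seed.
#' @return list with `slide` (perturbed), `true_coords` (original
#'   positions, the ground truth a perfect alignment recovers), and
#'   `displacement` (per-spot applied displacement length).
#' @export
perturb_alignment <- function(slide, expr_noise_sd = 0, coord_noise_sd = 0,
                              rotation_deg = 0, seed = 1) {
  with_seed(seed, {
    out <- slide
    if (expr_noise_sd > 0) {
      noise <- matrix(exp(stats::rnorm(length(slide$counts), 0,
                                       expr_noise_sd)),
                      nrow(slide$counts))
      out$counts <- round(slide$counts * noise)
      dimnames(out$counts) <- dimnames(slide$counts)
    }
    if (rotation_deg != 0 || coord_noise_sd > 0) {
      th <- rotation_deg * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      ctr <- colMeans(slide$coords)
      coords <- sweep(sweep(slide$coords, 2, ctr) %*% t(R), 2, ctr, "+")
      if (coord_noise_sd > 0)
        coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                               coord_noise_sd), ncol = 2)
      dimnames(coords) <- dimnames(slide$coords)
    } else coords <- slide$coords
    out$coords <- coords
    list(slide = out, true_coords = slide$coords,
         displacement = sqrt(rowSums((coords - slide$coords)^2)))
  })
}

#' Binomial downsampling of sequencing depth
#'
#' Thins each spot's counts binomially with
#' `p = target_umi / spot_total`, so the expected per-spot total is
#' `target_umi` — emulating a lower-depth sequencing run of the same
#' library (spots already at or below the target are kept unchanged).
#'
#' @param counts spots x genes integer matrix.
#' @param target_umi target UMI per spot (> 0, and no greater than the
#'   current median spot depth).
#' @param seed RNG seed.
#' @return downsampled integer matrix of the same shape.
#' @export
downsample_depth <- function(counts, target_umi, seed = 1) {
  counts <- as.matrix(counts)
  if (target_umi <= 0) stopf("target_umi must be positive")
  tot <- rowSums(counts)
  if (target_umi > stats::median(tot))
    stopf("target_umi (%g) exceeds current median depth (%g)",
          target_umi, stats::median(tot))
  with_seed(seed, {
    out <- counts
    for (i in seq_len(nrow(counts))) {
      p <- min(1, target_umi / max(tot[i], 1))
      if (p < 1)
        out[i, ] <- stats::rbinom(ncol(counts), counts[i, ], p)
    }
    out
  })
}

#' Add Gaussian pixel noise to image patches
#'
#' i.i.d. Gaussian noise per pixel and channel, clipped to the 8-bit
#' range — emulating low-quality histology scans.
#'
#' @param patches list of H x W x 3 arrays (0-255 scale).
#' @param sd noise standard deviation (0 = identity).
#' @param seed RNG seed.
#' @return list of noisy patches.
#' @export
add_image_noise <- function(patches, sd, seed = 1) {
  assert_scalar_num(sd, "sd", 0)
  if (sd == 0) return(patches)
  with_seed(seed, lapply(patches, function(p)
    pmin(pmax(p + array(stats::rnorm(length(p), 0, sd), dim(p)), 0), 255)))
}
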