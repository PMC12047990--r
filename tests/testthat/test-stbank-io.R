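test_that("write/read round-trips counts, coords and symbols bit-exactly", {
  slide <- tiny_slide(patches = TRUE)
  dir <- withr::local_tempdir()
  write_slide(slide, dir)
  back <- read_slide(file.path(dir, "matrix.mtx"),
                     file.path(dir, "features.tsv"),
                     file.path(dir, "barcodes.tsv"),
                     file.path(dir, "positions.csv"),
                     patches_dir = file.path(dir, "patches"))
  expect_identical(back$counts, slide$counts)
  expect_equal(back$coords, slide$coords)
  expect_identical(back$gene_symbols, slide$gene_symbols)
  expect_identical(attr(back, "orientation"), "genes_x_spots")
  expect_length(back$patches, n_spots(slide))
})

test_that("read_slide validates dimensions and drops positionless spots", {
  slide <- tiny_slide()
  dir <- withr::local_tempdir()
  write_slide(slide, dir)
  ## extra barcode -> dimension mismatch naming the file
  bad <- file.path(dir, "barcodes_bad.tsv")
  writeLines(c(slide$spot_ids, "EXTRA"), bad)
  expect_error(read_slide(file.path(dir, "matrix.mtx"),
                          file.path(dir, "features.tsv"), bad,
                          file.path(dir, "positions.csv")),
               "mismatch")
  ## one barcode missing from positions -> dropped with a message
  pos <- read.csv(file.path(dir, "positions.csv"))
  write.csv(pos[-1, ], file.path(dir, "positions2.csv"), row.names = FALSE)
  expect_message(
    part <- read_slide(file.path(dir, "matrix.mtx"),
                       file.path(dir, "features.tsv"),
                       file.path(dir, "barcodes.tsv"),
                       file.path(dir, "positions2.csv")),
    "dropped 1")
  expect_equal(n_spots(part), n_spots(slide) - 1)
})

test_that("qc filter keeps spots strictly above the threshold and is idempotent", {
  ## spot 1: 201 expressed genes; spot 2: exactly 200; spot 3: 250
  counts <- rbind(c(rep(1, 201), rep(0, 99)),
                  c(rep(1, 200), rep(0, 100)),
                  c(rep(1, 250), rep(0, 50)))
  slide <- spot_slide(c("a", "b", "c"), cbind(1:3, 1:3), counts,
                      sprintf("g%03d", 1:300))
  filt <- qc_filter_spots(slide, min_genes = 200)
  expect_identical(filt$spot_ids, c("a", "c"))
  expect_identical(qc_filter_spots(filt, 200)$spot_ids, filt$spot_ids)
  expect_identical(qc_filter_spots(slide, 0)$spot_ids, slide$spot_ids)
  expect_warning(qc_filter_spots(slide, 400), "every spot")
})

test_that("normalization layer matches the closed form and conserves target_sum", {
  slide <- spot_slide("s1", cbind(0, 0), matrix(c(10L, 0L), 1), c("g1", "g2"))
  norm <- normalize_counts(slide, target_sum = 10)
  expect_equal(norm$lognorm[1, ], c(g1 = log(11), g2 = 0))
  ## row sums of expm1(layer) equal target_sum for nonzero spots
  slide2 <- tiny_slide(n = 8, g = 15, seed = 7)
  norm2 <- normalize_counts(slide2, target_sum = 1e4)
  expect_equal(unname(rowSums(expm1(norm2$lognorm))), rep(1e4, 8),
               tolerance = 1e-8)
  ## all-zero spot flagged, row stays zero
  z <- spot_slide(c("a", "b"), cbind(1:2, 1:2),
                  rbind(c(5L, 5L), c(0L, 0L)), c("g1", "g2"))
  nz <- normalize_counts(z)
  expect_true(nz$zero_library[2])
  expect_equal(unname(nz$lognorm[2, ]), c(0, 0))
})

test_that("gene sentences rank by expression with housekeeping removal and tie rules", {
  genes <- c("SNAP25", "ENO2", "CKB", "GRIN2C", "CAMK4", "ACTB", "ZZZ3", "AAA1")
  expr <-  c(100,      90,     80,    70,       60,      500,    10,     10)
  maps <- gene_maps(housekeeping = "ACTB")
  s <- build_gene_sentence(expr, genes, maps, top_n = 50)
  expect_identical(s$tokens[1:5], c("SNAP25", "ENO2", "CKB", "GRIN2C", "CAMK4"))
  expect_false("ACTB" %in% s$tokens)
  ## equal counts -> alphabetical
  expect_identical(tail(s$tokens, 2), c("AAA1", "ZZZ3"))
  expect_identical(sentence_string(s),
                   "SNAP25 ENO2 CKB GRIN2C CAMK4 AAA1 ZZZ3")
  ## 3 nonzero genes, top_n = 50 -> length 3
  s3 <- build_gene_sentence(c(1, 2, 3, 0), c("a", "b", "c", "d"), gene_maps())
  expect_length(s3$tokens, 3)
  ## nothing left -> error
  expect_error(build_gene_sentence(c(0, 5), c("x", "ACTB"), maps),
               "no nonzero")
})

test_that("ensembl ids convert to symbols before ranking", {
  maps <- gene_maps(ensembl_to_symbol = c(ENSG000001 = "TP53"),
                    housekeeping = character())
  s <- build_gene_sentence(c(5, 1), c("ENSG000001", "KRAS"), maps)
  expect_identical(s$tokens, c("TP53", "KRAS"))
})

test_that("sentence properties hold over random profiles", {
  maps <- gene_maps(housekeeping = default_housekeeping())
  set.seed(11)
  for (i in 1:20) {
    g <- c(sample(default_housekeeping(), 5),
           sprintf("RND%03d", sample(999, 60)))
    expr <- rpois(65, 3)
    if (all(expr[-(1:5)] == 0) || all(expr == 0)) next
    s <- tryCatch(build_gene_sentence(expr, g, maps, top_n = 20),
                  error = function(e) NULL)
    if (is.null(s)) next
    expect_lte(length(s$tokens), 20)
    expect_false(any(s$tokens %in% default_housekeeping()))
    expect_false(anyDuplicated(s$tokens) > 0)
  }
})

test_that("pseudo-spot binning averages member cells and conserves them", {
  ## two identical cells inside one spot -> profile equals the cell profile
  cc <- rbind(c(0, 0), c(5, 5))
  cnt <- rbind(c(4, 6), c(4, 6))
  colnames(cnt) <- c("g1", "g2")
  ps <- bin_pseudo_spots(cc, cnt, pitch_um = 100, diameter_um = 55)
  expect_equal(nrow(ps$slide$counts), 1)
  expect_equal(unname(ps$profiles[1, ]), c(4, 6))
  expect_equal(nrow(ps$membership), 2)
  ## boundary cell included exactly once
  cc2 <- rbind(c(0, 0), c(27.5, 0))
  ps2 <- bin_pseudo_spots(cc2, cnt, pitch_um = 100, diameter_um = 55)
  expect_equal(sum(ps2$membership$cell == 2), 1)
  ## conservation: each captured cell appears once, total <= n_cells
  set.seed(5)
  cc3 <- cbind(runif(100, 0, 400), runif(100, 0, 400))
  cnt3 <- matrix(rpois(100 * 4, 3), 100)
  ps3 <- bin_pseudo_spots(cc3, cnt3)
  expect_false(anyDuplicated(ps3$membership$cell) > 0)
  expect_lte(nrow(ps3$membership), 100)
})

test_that("pseudo-spot capture fraction approximates the circle/hex area ratio", {
  ## brute-force point-in-circle count over a dense uniform scatter
  set.seed(17)
  n <- 4000
  cc <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  cnt <- matrix(1L, n, 1)
  ps <- bin_pseudo_spots(cc, cnt, pitch_um = 100, diameter_um = 55)
  frac <- nrow(ps$membership) / n
  hex_cell_area <- 100 * 100 * sqrt(3) / 2
  expect_equal(frac, pi * 27.5^2 / hex_cell_area, tolerance = 0.15)
})

test_that("patch extraction crops at spot scale with zero-padding at borders", {
  img <- array(runif(100 * 100 * 3, 0, 255), c(100, 100, 3))
  out <- extract_patches(img, rbind(c(50, 50), c(0, 0), c(50, 50) + c(0, 0)),
                         microns_per_pixel = 1, diameter_um = 55)
  expect_equal(dim(out$patches[[1]]), c(55, 55, 3))
  expect_false(out$padded[1])
  expect_true(out$padded[2])
  expect_error(extract_patches(img, cbind(50, 50), 0, 55), "must be >")
  ## patch centers track coordinates: two spots 20 um apart at 1 um/px
  img2 <- array(0, c(100, 100, 3))
  img2[40, 30, 1] <- 255   # row 40 (y), col 30 (x)
  out2 <- extract_patches(img2, rbind(c(29, 39), c(49, 39)), 1, 11)
  expect_equal(out2$patches[[1]][6, 6, 1], 255)   # centered on the mark
  expect_equal(sum(out2$patches[[2]]), 0)         # 20 um away: mark outside
})
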