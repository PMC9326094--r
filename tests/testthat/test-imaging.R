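test_that("binarization compares strictly against the cutoff", {
  expect_false(any(binarize_channel(matrix(0, 4, 4), 10)))
  m <- matrix(c(5, 20, 20, 5), 2, 2, byrow = TRUE)
  expect_equal(unclass(binarize_channel(m, 10))[1:4],
               c(FALSE, TRUE, TRUE, FALSE),
               ignore_attr = TRUE)
  # value equal to the threshold stays background
  expect_false(any(binarize_channel(matrix(10, 3, 3), 10)))
})

test_that("otsu matches the exhaustive between-class variance sweep", {
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(10, 64, 64)
    blob <- disk_mask(64, sample(20:44, 1), sample(20:44, 1), 8)
    img[blob] <- 200
    img <- img + matrix(sample(0:3, 64 * 64, TRUE), 64, 64)
    thr <- otsu_threshold(img)
    ref <- bf_otsu(img)
    # both cuts must separate the same pixels, and recover the painted blob
    expect_identical(img > thr, img > ref)
    expect_identical(which(binarize_channel(img, "otsu")), which(blob))
  }
  expect_warning(b <- binarize_channel(matrix(7, 5, 5), "otsu"), "constant")
  expect_false(any(b))
})

test_that("colocalization mask is the pixelwise intersection", {
  a <- rect_mask(32, 1, 10, 1, 10)
  b <- rect_mask(32, 20, 30, 20, 30)
  expect_false(any(coloc_mask(a, b)))
  expect_identical(coloc_mask(a, a), a & a)
  # overlapping 10x10 rectangles offset by 5 px: 5x10 = 50 px overlap
  r1 <- rect_mask(32, 5, 14, 5, 14)
  r2 <- rect_mask(32, 10, 19, 5, 14)
  cm <- coloc_mask(r1, r2)
  expect_equal(sum(cm), 50)
  expect_equal(sum(cm), bf_coloc_area(r1, r2))
  expect_error(coloc_mask(a, rect_mask(16, 1, 2, 1, 2)), "dimensions")
})

test_that("coloc_mask is symmetric and filters small objects", {
  set.seed(31)
  for (rep in 1:5) {
    a <- matrix(runif(40 * 40) < 0.3, 40, 40)
    b <- matrix(runif(40 * 40) < 0.3, 40, 40)
    expect_identical(coloc_mask(a, b), coloc_mask(b, a))
    expect_equal(sum(coloc_mask(a, b)), bf_coloc_area(a, b))
  }
  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  big <- rect_mask(10, 1, 3, 1, 3)
  expect_equal(sum(coloc_mask(one | big, one | big, min_object_area_px = 2)), 9)
})

test_that("areas count pixels and convert with pixel size", {
  expect_equal(coloc_area(matrix(FALSE, 8, 8)), 0)
  m <- rect_mask(16, 1, 5, 1, 10)
  expect_equal(coloc_area(m), 50)
  expect_equal(coloc_area(m, pixel_size_um = 0.5), 12.5)
})

test_that("cell counting labels DAPI components above the size floor", {
  cfg <- threshold_config(dapi_threshold = 50, min_nucleus_area_px = 20)
  blank <- matrix(0, 64, 64)
  expect_equal(count_cells(blank, cfg)$count, 0)
  img <- matrix(0, 64, 64)
  centers <- cbind(c(10, 10, 32, 54, 54), c(10, 54, 32, 10, 54))
  for (k in 1:5) img[disk_mask(64, centers[k, 1], centers[k, 2], 4)] <- 200
  res <- count_cells(img, cfg)
  expect_equal(res$count, 5)
  expect_equal(max(res$labels), 5)
  # a speck below the area floor is not a nucleus
  img[1, 1] <- 200
  expect_equal(count_cells(img, cfg)$count, 5)
})

test_that("neutrophils are nuclei with sufficient MPO in their halo", {
  cfg <- threshold_config(dapi_threshold = 50, min_nucleus_area_px = 20,
                          neutrophil_overlap_fraction = 0.1,
                          nucleus_dilation_radius_px = 3)
  dapi <- matrix(0, 64, 64)
  for (c in list(c(15, 15), c(15, 49), c(45, 32))) {
    dapi[disk_mask(64, c[1], c[2], 4)] <- 200
  }
  lab <- count_cells(dapi, cfg)$labels
  expect_equal(count_neutrophils(lab, matrix(FALSE, 64, 64), cfg), 0)
  # paint a cytoplasmic ring around the first nucleus only
  mpo <- disk_mask(64, 15, 15, 7) & !disk_mask(64, 15, 15, 4)
  expect_equal(count_neutrophils(lab, mpo, cfg), 1)
})

test_that("quantify_field composes area, counts and normalization", {
  size <- 96
  cfg <- threshold_config(dapi_threshold = 50, mpo_threshold = 50,
                          cith3_threshold = 50, min_nucleus_area_px = 20)
  blank <- fluorescence_field(matrix(0, size, size), matrix(0, size, size),
                              matrix(0, size, size))
  q0 <- quantify_field(blank, cfg)
  expect_equal(
    unlist(q0[c("coloc_area", "cell_count", "neutrophil_count",
                "nets_area_per_cell", "nets_area_per_neutrophil")]),
    c(coloc_area = 0, cell_count = 0, neutrophil_count = 0,
      nets_area_per_cell = 0, nets_area_per_neutrophil = 0))

  # 10 nuclei, 4 with MPO rings, one 50-px double-positive patch
  dapi <- matrix(0, size, size)
  mpo <- matrix(0, size, size)
  centers <- expand.grid(r = c(12, 34, 56, 78, 90) - 2, c = c(24, 70))
  for (k in 1:10) {
    dapi[disk_mask(size, centers$c[k], centers$r[k], 4)] <- 200
    if (k <= 4) {
      ring <- disk_mask(size, centers$c[k], centers$r[k], 7) &
        !disk_mask(size, centers$c[k], centers$r[k], 4)
      mpo[ring] <- 200
    }
  }
  patch <- rect_mask(size, 44, 48, 40, 49) # 5x10 = 50 px
  mpo[patch] <- 200
  cith3 <- matrix(0, size, size)
  cith3[patch] <- 200
  fld <- fluorescence_field(dapi, mpo, cith3)
  q <- quantify_field(fld, cfg)
  expect_equal(q$coloc_area, 50)
  expect_equal(q$cell_count, 10)
  expect_equal(q$neutrophil_count, 4)
  expect_equal(q$nets_area_per_cell, 5.0)
  expect_equal(q$nets_area_per_neutrophil, 12.5)

  # negative-control analog: MPO-positive cells, no Cit-H3 signal
  neg <- fluorescence_field(dapi, mpo, matrix(0, size, size))
  expect_equal(quantify_field(neg, cfg)$coloc_area, 0)

  # coloc signal without any cell: normalized areas 0 with a warning
  stray <- fluorescence_field(matrix(0, size, size), mpo, cith3)
  expect_warning(qs <- quantify_field(stray, cfg), "no cells")
  expect_equal(qs$nets_area_per_cell, 0)

  # cells but no MPO+ cell while coloc present via cith3&mpo patch only:
  cfg_hi <- threshold_config(dapi_threshold = 50, mpo_threshold = 50,
                             cith3_threshold = 50, min_nucleus_area_px = 20,
                             neutrophil_overlap_fraction = 0.9)
  qna <- quantify_field(fld, cfg_hi)
  expect_true(is.na(qna$nets_area_per_neutrophil))
})

test_that("raising a channel threshold never increases coloc area", {
  set.seed(41)
  img1 <- matrix(runif(64 * 64, 0, 100), 64, 64)
  img2 <- matrix(runif(64 * 64, 0, 100), 64, 64)
  areas <- sapply(seq(10, 90, by = 10), function(t) {
    sum(coloc_mask(binarize_channel(img1, t), binarize_channel(img2, 40)))
  })
  expect_true(all(diff(areas) <= 0))
  areas2 <- sapply(seq(10, 90, by = 10), function(t) {
    sum(coloc_mask(binarize_channel(img1, 40), binarize_channel(img2, t),
                   min_object_area_px = 3))
  })
  expect_true(all(diff(areas2) <= 0))
})

test_that("per-individual summary averages fields and drops missing values", {
  rows <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(subject_id = "A", field_id = paste0("f", i),
               coloc_area = 0, cell_count = 1, neutrophil_count = 1,
               nets_area_per_cell = c(2, 4, 6, 0, 0, 0)[i],
               nets_area_per_neutrophil = c(3, 6, NA, 0, 0, 0)[i])
  }))
  s <- summarize_individual(rows)
  expect_equal(s$n_fields, 6)
  expect_equal(s$mean_nets_area_per_cell, 2.0)
  expect_equal(s$mean_nets_area_per_neutrophil, mean(c(3, 6, 0, 0, 0)))
  expect_equal(summarize_individual(rows[1, ])$mean_nets_area_per_cell, 2)
  expect_error(summarize_individual(rows[0, ]), "at least one")
  rows$subject_id[2] <- "B"
  expect_error(summarize_individual(rows), "multiple subjects")
})

test_that("PGM images round-trip through both encodings", {
  img <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
  p2 <- tempfile(fileext = ".pgm"); p5 <- tempfile(fileext = ".pgm")
  write_pgm(img, p2, ascii = TRUE)
  write_pgm(img, p5, ascii = FALSE)
  expect_equal(read_pgm(p2), img)
  expect_equal(read_pgm(p5), img)
  wide <- matrix(sample(0:4095, 100, TRUE), 10, 10)
  write_pgm(wide, p5, ascii = FALSE)
  expect_equal(read_pgm(p5), wide)
})
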