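test_that("blank and invalid nuclear images are handled", {
  expect_equal(max(segment_nuclei(matrix(7, 32, 32))$labels), 0)
  expect_error(segment_nuclei(array(1, c(4, 4, 2))), "2-D")
})

test_that("well-separated simulated nuclei are counted exactly", {
  p <- sim_params(cells_per_field = 60)   # sparse: no touching nuclei
  sw <- simulate_well(list(well = "A1", role = "x"), compound_effect(),
                      p, seed = 21)
  for (f in 1:2) {
    nuc <- segment_nuclei(sw$images$fields[[f]][, , 1])
    expect_equal(max(nuc$labels), sw$truth$fields$n_cells[f])
  }
})

test_that("two overlapping nuclei with distinct peaks are split", {
  img <- two_nuclei_image()
  nuc <- segment_nuclei(img, seg_params(nucleus_min_area_px = 20))
  expect_equal(max(nuc$labels), 2)
})

test_that("nuclei recall and precision reach 0.95 at default density", {
  p <- sim_params()
  tp <- fp <- fn <- 0
  for (s in 1:2) {
    sw <- simulate_well(list(well = "A1", role = "x"), compound_effect(),
                        p, seed = 100 + s)
    for (f in seq_along(sw$images$fields)) {
      truth <- sw$truth$cells[sw$truth$cells$field == f, ]
      nuc <- segment_nuclei(sw$images$fields[[f]][, , 1])
      L <- nuc$labels
      if (max(L) == 0) { fn <- fn + nrow(truth); next }
      idx <- which(L > 0); lv <- L[idx]
      a <- tabulate(lv)
      cy <- rowsum(((idx - 1) %% nrow(L)) + 1, lv)[, 1] / a
      cx <- rowsum(((idx - 1) %/% nrow(L)) + 1, lv)[, 1] / a
      D <- sqrt(outer(cy, truth$y, "-")^2 + outer(cx, truth$x, "-")^2)
      rad_px <- p$nucleus_radius[1] / p$pixel_size
      matched_det <- apply(D, 1, min) < rad_px
      matched_tru <- apply(D, 2, min) < rad_px
      tp <- tp + sum(matched_tru); fn <- fn + sum(!matched_tru)
      fp <- fp + sum(!matched_det)
    }
  }
  expect_gte(tp / (tp + fn), 0.95)  # recall
  expect_gte(tp / (tp + fp), 0.95)  # precision
})

test_that("cell territories partition the foreground around their seeds", {
  # one centered nucleus, uniform cytoplasm disk
  nucmask <- matrix(0L, 41, 41)
  nucmask[19:23, 19:23] <- 1L
  nm <- label_mask(nucmask, "nucleus")
  disk <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+") <= 18^2
  cyto <- matrix(100, 41, 41); cyto[disk] <- 600
  cl <- assign_cells(nm, cyto)
  expect_equal(sort(unique(as.vector(cl$labels[disk]))), 1L)

  # n nuclei -> n labels
  p <- reduced_sim(fields_per_well = 1L, cells_per_field = 50)
  sw <- simulate_well(list(well = "A1", role = "x"), compound_effect(),
                      p, seed = 8)
  nuc <- segment_nuclei(sw$images$fields[[1]][, , 1], reduced_seg())
  cl2 <- assign_cells(nuc, sw$images$fields[[1]][, , 2], reduced_seg())
  expect_equal(max(cl2$labels), max(nuc$labels))

  expect_error(assign_cells(nuc, matrix(1, 5, 5)), "shapes differ")
})

test_that("equidistant seeds split a uniform disk at the bisector", {
  nucmask <- matrix(0L, 41, 41)
  nucmask[19:23, 9:13] <- 1L
  nucmask[19:23, 29:33] <- 2L
  nm <- label_mask(nucmask, "nucleus")
  disk <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+") <= 19^2
  cyto <- matrix(100, 41, 41); cyto[disk] <- 600
  cl <- assign_cells(nm, cyto)
  # brute-force nearest-seed oracle: boundary at column 21
  for (row in 12:30) {
    cols1 <- which(cl$labels[row, ] == 1)
    cols2 <- which(cl$labels[row, ] == 2)
    if (length(cols1) && length(cols2)) {
      expect_lte(abs(max(cols1) - 21), 1)
      expect_lte(abs(min(cols2) - 21), 1)
    }
  }
})

test_that("white top-hat matches the naive min-then-max oracle", {
  expect_equal(max(abs(tophat_enhance(matrix(5, 20, 20), 3))), 0)

  single <- matrix(0, 21, 21); single[11, 11] <- 42
  th <- tophat_enhance(single, 3)
  expect_equal(th[11, 11], 42)
  expect_equal(sum(th) - th[11, 11], 0)

  img <- outer(1:24, 1:24, function(i, j) i + 0.5 * j)
  img[12, 12] <- img[12, 12] + 50
  r <- 3L
  th <- tophat_enhance(img, r)
  # naive sliding-window morphology oracle (interior; the package and the
  # oracle pad borders differently)
  kern <- EBImage::makeBrush(2 * r + 1, "disc")
  off <- which(kern == 1, arr.ind = TRUE) - (r + 1)
  pad <- matrix(Inf, 24 + 2 * r, 24 + 2 * r)
  pad[(r + 1):(r + 24), (r + 1):(r + 24)] <- img
  ero <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24)
    ero[i, j] <- min(pad[i + r + off[, 1], j + r + off[, 2]])
  pad2 <- matrix(-Inf, 24 + 2 * r, 24 + 2 * r)
  pad2[(r + 1):(r + 24), (r + 1):(r + 24)] <- ero
  opn <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24)
    opn[i, j] <- max(pad2[i + r + off[, 1], j + r + off[, 2]])
  naive <- pmax(img - opn, 0)
  core <- (r + 1):(24 - r)
  expect_equal(th[core, core], naive[core, core], tolerance = 1e-12)

  expect_error(tophat_enhance(matrix(1, 8, 8), 10), "larger than the image")
})

test_that("top-hat is idempotent on its own output", {
  set.seed(2)
  img <- matrix(runif(40 * 40, 0, 100), 40, 40)
  t1 <- tophat_enhance(img, 4)
  t2 <- tophat_enhance(t1, 4)
  expect_lt(max(abs(t2 - t1)), 1e-9)
})

test_that("endosome spots are recovered at high SNR and assigned to cells", {
  p <- sim_params(cells_per_field = 25, cell_radius = c(20, 1),
                  endosomes_per_cell = 12)   # sparse, well-resolved spots
  meas <- tru <- 0; cells_seen <- 0
  for (s in 1:2) {
    sw <- simulate_well(list(well = "A1", role = "x"), compound_effect(),
                        p, seed = 30 + s)
    an <- analyze_well(sw$images)
    meas <- meas + sum(an$cells$endosome_count)
    cells_seen <- cells_seen + nrow(an$cells)
    tru <- tru + nrow(an$cells) * mean(sw$truth$cells$endosome_count)
  }
  expect_gte(cells_seen, 100)
  expect_lt(abs(meas / tru - 1), 0.1)
})

test_that("blank channels and merged spots behave as documented", {
  nucmask <- matrix(0L, 41, 41); nucmask[19:23, 19:23] <- 1L
  disk <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+") <= 18^2
  cyto <- matrix(100, 41, 41); cyto[disk] <- 600
  cells <- assign_cells(label_mask(nucmask, "nucleus"), cyto)

  blank <- matrix(0, 41, 41)
  expect_equal(length(detect_endosomes(blank, cells)$parent), 0)

  # two spots below the resolution limit count as one
  spot2 <- matrix(0, 41, 41)
  d1 <- sqrt(outer((1:41 - 21)^2, (1:41 - 14)^2, "+"))
  d2 <- sqrt(outer((1:41 - 21)^2, (1:41 - 15)^2, "+"))
  spot2 <- 900 * exp(-d1^2 / 2) + 900 * exp(-d2^2 / 2)
  e <- detect_endosomes(spot2, cells)
  expect_equal(length(e$parent), 1)

  # two well-separated spots count as two, both in the single cell
  spot2b <- matrix(0, 41, 41)
  d3 <- sqrt(outer((1:41 - 21)^2, (1:41 - 28)^2, "+"))
  spot2b <- 900 * exp(-d1^2 / 2) + 900 * exp(-d3^2 / 2)
  e2 <- detect_endosomes(spot2b, cells)
  expect_equal(length(e2$parent), 2)
  expect_equal(unname(e2$parent), c(1L, 1L))
})

test_that("perinuclear annulus has the right geometry", {
  # circular nucleus radius 20 px, ring width 8 px (4 um at 0.5 um/px)
  n <- 101
  d <- sqrt(outer((1:n - 51)^2, (1:n - 51)^2, "+"))
  nucmask <- matrix(0L, n, n); nucmask[d <= 20] <- 1L
  nm <- label_mask(nucmask, "nucleus")
  ring <- perinuclear_ring(nm, width_um = 4, pixel_size = 0.5)
  area <- sum(ring$labels == 1)
  analytic <- pi * (28^2 - 20^2)
  expect_lt(abs(area / analytic - 1), 0.02)
  # ring is disjoint from every nucleus pixel
  expect_equal(sum(ring$labels > 0 & nucmask > 0), 0)
  expect_error(perinuclear_ring(nm, 4, pixel_size = 0), "pixel_size")

  # rings of neighbouring nuclei stay disjoint and keep nucleus labels
  m2 <- matrix(0L, 64, 64)
  m2[20:28, 14:22] <- 1L; m2[20:28, 40:48] <- 2L
  r2 <- perinuclear_ring(label_mask(m2, "nucleus"), 4, 1)
  expect_setequal(sort(unique(r2$labels[r2$labels > 0])), c(1L, 2L))
})

test_that("label nesting holds on simulator output", {
  p <- reduced_sim(fields_per_well = 1L, cells_per_field = 40)
  sw <- simulate_well(list(well = "A1", role = "x"), compound_effect(),
                      p, seed = 12)
  img <- sw$images$fields[[1]]
  nuc <- segment_nuclei(img[, , 1], reduced_seg())
  cells <- assign_cells(nuc, img[, , 2], reduced_seg())
  endo <- detect_endosomes(img[, , 3], cells, reduced_seg())
  # every endosome's parent cell exists
  expect_true(all(endo$parent %in% seq_len(max(cells$labels))))
  # every cell contains exactly one nucleus
  for (i in seq_len(max(cells$labels))) {
    nuc_in_cell <- unique(nuc$labels[cells$labels == i & nuc$labels > 0])
    expect_equal(nuc_in_cell, i)
  }
})
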