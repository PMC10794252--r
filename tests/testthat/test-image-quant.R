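test_that("nucleus segmentation finds disjoint bright disks and nothing in a
           uniform image", {
  img <- matrix(0.02, 100, 100)
  for (cen in list(c(25, 25), c(25, 75), c(75, 50))) {
    img[cargoscreen:::raster_disk(c(100, 100), cen, 8)] <- 0.9
  }
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 3)
  expect_equal(max(segment_nuclei(matrix(0.5, 50, 50))), 0)
  expect_equal(max(segment_nuclei(matrix(0, 50, 50))), 0)
})

test_that("all synthetic nuclei and cells are recovered on a clean field", {
  fi <- generate_field(field_spec(n_cells = 25, noise_sd = 0, seed = 21))
  seg <- segment_field(fi)
  expect_equal(max(seg$nucleus_labels), 25)
  expect_equal(length(setdiff(unique(as.vector(seg$cell_labels)), 0L)), 25)
})

test_that("cell masks overlap ground truth with Jaccard >= 0.95 at zero
           noise", {
  fi <- default_field()
  seg <- default_seg()
  tl <- fi$truth$cell_labels
  for (id in setdiff(unique(as.vector(seg$cell_labels)), 0L)) {
    sm <- seg$cell_labels == id
    ov <- table(tl[sm])
    tid <- as.integer(names(which.max(ov[names(ov) != "0"])))
    tm <- tl == tid
    expect_gte(sum(sm & tm) / sum(sm | tm), 0.95)
  }
})

test_that("a body blob with two nuclei is split into one cell per nucleus", {
  ch <- two_cell_scene()
  nuc <- segment_nuclei(ch$nucleus)
  expect_equal(max(nuc), 2)
  cells <- segment_cell_bodies(ch$body, nuc)
  ids <- setdiff(unique(as.vector(cells)), 0L)
  expect_equal(length(ids), 2)
  for (id in ids) {
    # each split cell contains exactly its own nucleus
    nuc_inside <- setdiff(unique(nuc[cells == id]), 0L)
    expect_equal(nuc_inside, id)
    expect_true(all(cells[nuc == id] == id))
  }
})

test_that("a TGN blob straddling two cells is split by the cell boundary", {
  ch <- two_cell_scene()
  nuc <- segment_nuclei(ch$nucleus)
  cells <- segment_cell_bodies(ch$body, nuc)
  tgn <- segment_tgn(ch$tgn, cells)
  parts <- setdiff(unique(as.vector(tgn)), 0L)
  expect_equal(sort(parts), c(1L, 2L))
  expect_true(all(cells[tgn == 1] == 1))
  expect_true(all(cells[tgn == 2] == 2))
})

test_that("TGN area tracks the designed area fraction on clean fields", {
  fi <- default_field()
  seg <- default_seg()
  tr <- fi$truth$cells
  for (id in tr$cell_id) {
    a_tgn <- sum(seg$tgn_labels == id)
    a_cell <- sum(seg$cell_labels == id)
    expect_equal(a_tgn / a_cell, tr$tgn_area[tr$cell_id == id] /
                   tr$cell_area[tr$cell_id == id], tolerance = 0.10)
  }
})

test_that("an empty TGN channel flags every cell as no_tgn", {
  fi <- default_field()
  ch <- fi$channels
  ch$tgn <- matrix(0, nrow(ch$tgn), ncol(ch$tgn))
  seg <- segment_field(ch)
  mc <- measure_cells(ch, seg, pixel_size = fi$pixel_size)
  expect_equal(nrow(mc), 0)
  expect_true(all(attr(mc, "excluded")$reason == "no_tgn"))
})

test_that("a spatially uniform cargo channel gives ratio 1 and a cell with
           all cargo inside the TGN is excluded", {
  ch <- two_cell_scene()
  seg <- segment_field(ch)
  uni <- ch; uni$cargo <- matrix(0.4, 120, 120)
  mc <- measure_cells(uni, seg, background = 0, pixel_size = 1)
  expect_true(all(abs(mc$translocation_ratio - 1) < 1e-9))

  inside_only <- ch
  inside_only$cargo <- (seg$tgn_labels > 0) * 0.7
  mc2 <- measure_cells(inside_only, seg, background = 0, pixel_size = 1)
  expect_equal(nrow(mc2), 0)
  expect_true(all(attr(mc2, "excluded")$reason == "undefined_ratio"))
})

test_that("measured ratios match designed per-cell ratios within 5% on
           noiseless fields", {
  fi <- default_field()
  mc <- measure_cells(fi, default_seg())
  m <- merge(mc, fi$truth$cells[, c("cell_id", "designed_ratio")],
             by = "cell_id")
  expect_gte(nrow(m), 15)
  rel <- abs(m$translocation_ratio / m$designed_ratio - 1)
  expect_gte(mean(rel < 0.05), 0.95)
})

test_that("the translocation ratio is invariant under cargo rescaling and
           compartments partition the cell", {
  fi <- default_field()
  seg <- default_seg()
  mc <- measure_cells(fi, seg, background = 0)
  for (cmul in c(0.25, 3, 40)) {
    ch2 <- fi$channels
    ch2$cargo <- ch2$cargo * cmul
    mc2 <- measure_cells(ch2, seg, background = 0,
                         pixel_size = fi$pixel_size)
    expect_equal(mc2$translocation_ratio, mc$translocation_ratio,
                 tolerance = 1e-9)
  }
  # tgn_area + cytoplasm_area = cell_area, for every retained cell
  for (id in mc$cell_id) {
    cell <- seg$cell_labels == id
    tgn <- seg$tgn_labels == id
    expect_equal(sum(tgn) + sum(cell & !tgn), sum(cell))
  }
})

test_that("the feature vector has 90 stable columns with sane per-region
           values", {
  fi <- default_field()
  fv <- extract_features(fi, default_seg())
  expect_equal(ncol(fv), 91)  # cell_id + 90 features
  expect_gte(nrow(fv), 15)
  # nucleus of a disk-like cell: low eccentricity, compactness near 1
  expect_lt(stats::median(fv$nucleus_eccentricity), 0.4)
  expect_equal(stats::median(fv$nucleus_compactness), 1, tolerance = 0.1)
  # areas in physical units agree with measure_cells
  mc <- measure_cells(fi, default_seg())
  expect_equal(fv$cell_area[match(mc$cell_id, fv$cell_id)], mc$cell_area)

  # all-zero cargo channel: cargo intensity features 0, puncta count 0
  ch0 <- fi$channels; ch0$cargo <- matrix(0, nrow(ch0$cargo), ncol(ch0$cargo))
  fv0 <- extract_features(ch0, default_seg(), pixel_size = fi$pixel_size)
  expect_true(all(fv0$cargo_cell_mean == 0))
  expect_true(all(fv0$cargo_pos_puncta_count == 0))
  expect_equal(ncol(fv0), 91)
})

test_that("puncta density recovers planted densities on a straight neurite", {
  H <- 40; W <- 320
  neurite <- matrix(FALSE, H, W); neurite[19:21, 11:310] <- TRUE
  px <- 1 / 6  # 300 px = 50 um
  cargo <- matrix(0, H, W)
  cols <- round(seq(30, 290, length.out = 5))
  cargo[20, cols] <- 1
  pd <- puncta_density(cargo, neurite, pixel_size = px, threshold = 0.5)
  expect_equal(pd$n_puncta, 5)
  expect_equal(pd$density, 0.1, tolerance = 0.03)
  # no puncta -> 0
  expect_equal(puncta_density(matrix(0, H, W), neurite, pixel_size = px,
                              threshold = 0.5)$density, 0)
  # Poisson-planted density recovered within 10% at zero noise (1 um/px)
  set.seed(4)
  lam <- 0.05  # puncta per um along a 1950 um neurite
  W2 <- 2000; neur2 <- matrix(FALSE, 9, W2); neur2[4:6, 26:1975] <- TRUE
  n <- stats::rpois(1, lam * 1950)
  pos <- sort(sample(seq(30, 1970), n))
  pos <- pos[c(TRUE, diff(pos) > 2)]  # enforce resolvable separation
  cg <- matrix(0, 9, W2); cg[5, pos] <- 1
  pd2 <- puncta_density(cg, neur2, pixel_size = 1, threshold = 0.5)
  expect_equal(pd2$n_puncta, length(pos))
  expect_equal(pd2$density, length(pos) / 1950, tolerance = 0.1)
  expect_error(puncta_density(cg, matrix(FALSE, 9, W2)), "skeleton")
})
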