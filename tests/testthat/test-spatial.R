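test_that("density surfaces peak at the cells and conserve mass", {
  grid <- spatial_grid(c(0, 300), c(0, 0), spacing = 10, pad = 150)
  one <- glycan_density(0, 0, bandwidth = 50, grid = grid)
  peak <- which(one$z == max(one$z), arr.ind = TRUE)
  expect_lt(abs(one$x[peak[1]]), 10 + 1e-9)
  expect_lt(abs(one$y[peak[2]]), 10 + 1e-9)
  expect_equal(sum(one$z) * one$spacing^2, 1, tolerance = 0.02)

  ## two distant cells: two equal modes
  two <- glycan_density(c(0, 300), c(0, 0), bandwidth = 30, grid = grid)
  i1 <- which.min(abs(two$x - 0)); i2 <- which.min(abs(two$x - 300))
  j0 <- which.min(abs(two$y - 0))
  expect_equal(two$z[i1, j0], two$z[i2, j0], tolerance = 1e-6)
  expect_equal(sum(two$z) * two$spacing^2, 2, tolerance = 0.02)

  ## a 500-cell blob peaks within 2 grid spacings of its mean
  set.seed(1)
  x <- rnorm(500, 100, 40); y <- rnorm(500, -50, 40)
  surf <- glycan_density(x, y, bandwidth = 50)
  pk <- which(surf$z == max(surf$z), arr.ind = TRUE)
  expect_lt(abs(surf$x[pk[1]] - mean(x)), 2 * surf$spacing)
  expect_lt(abs(surf$y[pk[2]] - mean(y)), 2 * surf$spacing)

  ## zero positive cells: an empty surface, not an error
  none <- glycan_density(numeric(0), numeric(0), 50, grid)
  expect_true(all(none$z == 0))
})

test_that("dense regions threshold at the density quantile", {
  grid <- list(x = seq(0, 100, 10), y = seq(0, 100, 10), spacing = 10)
  flat <- structure(list(x = grid$x, y = grid$y,
                         z = matrix(1, 11, 11), bandwidth = 50,
                         spacing = 10), class = "density_surface")
  expect_true(all(dense_regions(flat, q = 0.5)))   # uniform: all or nothing

  set.seed(2)
  x <- rnorm(400, 0, 30); y <- rnorm(400, 0, 30)
  surf <- glycan_density(x, y, bandwidth = 40)
  m <- dense_regions(surf, q = 0.5)
  lab <- glycosig:::label_regions(matrix(as.integer(m), nrow(m)))
  expect_identical(max(lab), 1L)                   # one blob, one component
  pk <- which(surf$z == max(surf$z), arr.ind = TRUE)
  expect_true(m[pk])

  ## two blobs separated by far more than 6 bandwidths: two components
  x2 <- c(rnorm(300, 0, 20), rnorm(300, 600, 20))
  y2 <- rnorm(600, 0, 20)
  surf2 <- glycan_density(x2, y2, bandwidth = 30)
  m2 <- dense_regions(surf2, q = 0.5)
  lab2 <- glycosig:::label_regions(matrix(as.integer(m2), nrow(m2)))
  expect_identical(max(lab2), 2L)
})

test_that("overlap regions get the hand-enumerated codes", {
  set.seed(3)
  n <- 400
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:(3 * n)),
    x_um = c(rnorm(n, 0, 30), rnorm(n, 150, 30), rnorm(n, 300, 30)),
    y_um = rnorm(3 * n, 0, 30))
  vvl_pos <- 1:(2 * n)                 # VVL dense on the left + middle
  stra_pos <- (n + 1):(3 * n)          # sTRA dense on the middle + right
  grid <- spatial_grid(cells$x_um, cells$y_um, spacing = 10, pad = 150)
  none <- matrix(FALSE, length(grid$x), length(grid$y))
  masks <- list(
    VVL = dense_regions(glycan_density(cells$x_um[vvl_pos],
                                       cells$y_um[vvl_pos], 50, grid), 0.5),
    "CA19-9" = none, sTRA = dense_regions(
      glycan_density(cells$x_um[stra_pos], cells$y_um[stra_pos], 50, grid),
      0.5), GM2 = none)
  seg <- overlap_to_rois(masks, cells, grid, specimen_id = "sX")
  real <- seg$rois[seg$rois$n_cells > 0, ]
  expect_setequal(real$code, c("1000", "1010", "0010"))
  ## the overlap ROI holds the middle-blob cells
  mid <- seg$assignment$roi_id[(n + 1):(2 * n)]
  overlap_id <- real$roi_id[real$code == "1010"]
  expect_gt(mean(mid == overlap_id, na.rm = TRUE), 0.8)

  ## no masks -> no ROIs
  seg0 <- overlap_to_rois(list(VVL = none, "CA19-9" = none,
                               sTRA = none, GM2 = none), cells, grid)
  expect_identical(nrow(seg0$rois), 0L)
  expect_identical(seg0$n_unassigned, nrow(cells))
})

test_that("ROIs partition the union of dense regions with consistent codes", {
  set.seed(4)
  for (r in 1:5) {
    n <- 300
    cells <- data.frame(cell_id = sprintf("c%03d", 1:n),
                        x_um = runif(n, 0, 500), y_um = runif(n, 0, 500))
    bits <- matrix(runif(4 * n) < 0.4, n, 4)
    grid <- spatial_grid(cells$x_um, cells$y_um, spacing = 20, pad = 100)
    masks <- lapply(1:4, function(j) {
      if (!any(bits[, j]))
        return(matrix(FALSE, length(grid$x), length(grid$y)))
      dense_regions(glycan_density(cells$x_um[bits[, j]],
                                   cells$y_um[bits[, j]], 60, grid), 0.6)
    })
    names(masks) <- glycan_panel()$code_order
    seg <- overlap_to_rois(masks, cells, grid)
    union_mask <- Reduce(`|`, masks)
    expect_identical(seg$labels > 0, union_mask)       # partition = union
    for (l in seq_len(max(seg$labels)))                # constant pattern
      expect_identical(length(unique(seg$pattern[seg$labels == l])), 1L)
    ## each ROI's code equals the bitwise indicator of its covering masks
    for (l in seq_len(max(seg$labels))) {
      node <- which(seg$labels == l)[1]
      want <- paste(vapply(masks, function(m) as.integer(m[node]), 0L),
                    collapse = "")
      expect_identical(seg$rois$code[l], want)
    }
  }
})

test_that("segmentation is translation invariant", {
  set.seed(5)
  n <- 500
  cells <- data.frame(cell_id = sprintf("c%03d", 1:n),
                      specimen_id = "sA",
                      x_um = c(rnorm(n / 2, 0, 40), rnorm(n / 2, 250, 40)),
                      y_um = rnorm(n, 0, 40))
  codes <- rep(c("1000", "0010"), each = n / 2)
  a <- spatial_segment(cells, codes, bandwidth = 40, q = 0.5, min_cells = 5)
  cells2 <- cells
  cells2$x_um <- cells2$x_um + 1234.5
  cells2$y_um <- cells2$y_um - 987.25
  b <- spatial_segment(cells2, codes, bandwidth = 40, q = 0.5, min_cells = 5)
  expect_identical(a$rois$code, b$rois$code)
  expect_identical(a$rois$n_nodes, b$rois$n_nodes)
  expect_identical(a$assignment, b$assignment)
})

test_that("ROI sampling is per-specimen, capped, seeded and uniform", {
  rois <- data.frame(roi_id = sprintf("r%02d", 1:30),
                     specimen_id = rep(c("sA", "sB", "sC"), each = 10))
  all10 <- sample_rois(rois[rois$specimen_id == "sA", ], n = 99, seed = 1)
  expect_identical(nrow(all10), 10L)
  s1 <- sample_rois(rois, n = 4, seed = 7)
  s2 <- sample_rois(rois, n = 4, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(table(s1$specimen_id) == 4))

  counts <- integer(10)
  for (sd0 in 1:300) {
    s <- sample_rois(rois[1:10, ], n = 3, seed = sd0)
    idx <- match(s$roi_id, rois$roi_id[1:10])
    counts[idx] <- counts[idx] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})
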