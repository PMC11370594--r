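test_that("a separable glycan gets a zero-impurity threshold between the classes", {
  set.seed(1)
  n <- 400
  cells <- make_cells(n, fractions = list("CA19-9" = rep(c(0.9, 0.1), each = n / 2)))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  thr <- fit_thresholds(cells, labels, cv_folds = 3, seed = 1,
                        min_bucket = 20)
  th <- thr$thresholds[["CA19-9"]]
  expect_gt(th, 0.1)
  expect_lt(th, 0.9)
  expect_true(all(labels == (cells[["frac_CA19-9"]] > th)))
  ## the other channels are constant background: flagged, no threshold
  expect_true("GM2" %in% thr$flagged)
  expect_true(is.na(thr$thresholds[["GM2"]]))
})

test_that("labels independent of fractions leave glycans flagged", {
  set.seed(2)
  n <- 600
  cells <- make_cells(n, fractions = list("CA19-9" = runif(n),
                                          "VVL" = runif(n)))
  labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ## a maximally-selected chance split always shows some improvement, so
  ## flagging noise channels needs a non-trivial complexity threshold
  thr <- fit_thresholds(cells, labels, cv_folds = 3, seed = 1,
                        min_bucket = 20, cp = 0.1)
  expect_true(all(c("CA19-9", "VVL") %in% thr$flagged))
})

test_that("a planted cutpoint at 0.30 is recovered within 0.05", {
  recovered <- vapply(1:6, function(sd0) {
    set.seed(sd0)
    n <- 5000
    lab <- runif(n) < 0.4
    x <- ifelse(lab, 0.32 + 0.58 * rbeta(n, 2, 2), 0.28 * rbeta(n, 2, 2))
    cells <- make_cells(n, fractions = list("CA19-9" = x))
    fit_thresholds(cells, lab, cv_folds = 5, seed = sd0)$thresholds[["CA19-9"]]
  }, 0)
  expect_true(all(abs(recovered - 0.30) <= 0.05))
})

test_that("encoding follows the strict-greater rule and the fixed bit order", {
  thr <- flat_thresholds(0.2)
  cells <- make_cells(3, fractions = list(
    "CA19-9" = c(0.5, 0, 0.2), "VVL" = c(0.1, 0, 0.2),
    "sTRA" = c(0.05, 0, 0.2), "GM2" = c(0.0, 0, 0.2)))
  ## above threshold only for CA19-9 -> 0100; all zero -> 0000;
  ## exactly at threshold everywhere -> 0000 (strict rule)
  expect_identical(encode_cells(cells, thr), c("0100", "0000", "0000"))
  expect_error(encode_cells(cells, thr[c("VVL", "CA19-9")]), "missing")
})

test_that("raising any fraction never flips a bit on -> off", {
  set.seed(3)
  thr <- flat_thresholds(0.3)
  panel <- glycan_panel()
  for (r in 1:50) {
    f <- as.list(stats::setNames(runif(4), panel$code_order))
    cells <- make_cells(1, fractions = f)
    before <- encode_cells(cells, thr)
    g <- sample(panel$code_order, 1)
    col <- glycosig:::frac_col(g)
    cells[[col]] <- min(1, cells[[col]] + runif(1, 0, 1 - cells[[col]]))
    after <- encode_cells(cells, thr)
    b0 <- strsplit(before, "")[[1]]; b1 <- strsplit(after, "")[[1]]
    expect_true(all(b1[b0 == "1"] == "1"))
  }
})

test_that("ROI composition matches a brute-force tally and sums to one", {
  codes <- c("0100", "0100", "0001", "0000")
  comp <- roi_composition(codes, rep("r1", 4), rep("sA", 4))
  expect_equal(comp[["0100"]], 0.5)
  expect_equal(comp[["0001"]], 0.25)
  expect_equal(comp[["0000"]], 0.25)
  expect_identical(comp$n_cells, 4L)

  single <- roi_composition("1010", "r9")
  expect_equal(single[["1010"]], 1)

  set.seed(4)
  codes <- sample(all_codes(), 1000, replace = TRUE)
  rois <- sample(c("a", "b", "c"), 1000, replace = TRUE)
  comp <- roi_composition(codes, rois)
  m <- glycosig:::composition_matrix(comp)
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  for (u in comp$unit) {          # independent counting oracle
    for (cd in all_codes()) {
      cnt <- 0
      for (i in seq_along(codes)) if (rois[i] == u && codes[i] == cd)
        cnt <- cnt + 1
      expect_equal(m[u, cd], cnt / sum(rois == u))
    }
  }
})

test_that("threshold sets survive a structured-text round trip", {
  set.seed(5)
  cells <- make_cells(400, fractions = list("CA19-9" = rep(c(0.8, 0.05),
                                                           each = 200)))
  thr <- fit_thresholds(cells, rep(c(TRUE, FALSE), each = 200),
                        cv_folds = 3, seed = 2, min_bucket = 20)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds(thr, path)
  back <- read_thresholds(path)
  expect_equal(back$thresholds, thr$thresholds)
  expect_equal(back$cv_folds, thr$cv_folds)
  expect_equal(unname(back$per_fold), unname(thr$per_fold))
})

test_that("pruning drops noise and duplicate channels but keeps independent signal", {
  set.seed(6)
  n <- 3000
  panel <- glycan_panel(glycans = c("g1", "g2", "g3", "g4"),
                        code_order = c("g1", "g2", "g3", "g4"))
  ## four independent informative channels, each needed for accuracy
  z <- matrix(runif(4 * n) < 0.5, n, 4)
  y <- rowSums(z) >= 3
  f <- ifelse(z, 0.6 + 0.3 * runif(length(z)), 0.1 * runif(length(z)))
  dim(f) <- dim(z)
  cells <- data.frame(specimen_id = rep(c("sA", "sB"), length.out = n), f,
                      check.names = FALSE)
  names(cells)[2:5] <- paste0("frac_", c("g1", "g2", "g3", "g4"))
  pr <- prune_glycans(cells, y, panel, cv_folds = 3, seed = 1,
                      min_bucket = 20)
  expect_identical(sort(pr$retained), c("g1", "g2", "g3", "g4"))
  expect_length(pr$pruned, 0)

  ## add a pure-noise channel and a duplicate of g1: both prunable
  panel6 <- glycan_panel(glycans = c("g1", "g2", "g3", "g4", "dup", "noise"),
                         code_order = c("g1", "g2", "g3", "g4"))
  cells$frac_dup <- cells$frac_g1
  cells$frac_noise <- runif(n)
  pr6 <- prune_glycans(cells, y, panel6, cv_folds = 3, seed = 1,
                       min_bucket = 20)
  expect_true("noise" %in% pr6$pruned)
  expect_true(any(c("dup", "g1") %in% pr6$pruned))
  expect_true(all(c("g2", "g3", "g4") %in% pr6$retained))
})
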