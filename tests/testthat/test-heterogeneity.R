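test_that("Gini index matches its closed forms and the brute-force oracle", {
  expect_equal(gini_index(rep(1 / 4, 4)), 0)
  expect_equal(gini_index(c(1, 0, 0, 0)), 1)
  expect_equal(gini_index(c(0.5, 0.5, 0, 0)),
               gini_oracle(c(0.5, 0.5, 0, 0)))
  set.seed(1)
  for (r in 1:40) {
    k <- sample(4:16, 1)
    p <- rsimplex(k)
    expect_equal(gini_index(p), gini_oracle(p), tolerance = 1e-12)
    expect_equal(gini_index(p, normalize = FALSE),
                 gini_oracle(p, normalize = FALSE), tolerance = 1e-12)
    expect_equal(gini_index(sample(p)), gini_index(p))   # permutation invariant
    expect_lt(gini_index(0.999 * p + 0.001 / k), 1)      # 1 only when one-hot
  }
  expect_error(gini_index(c(0, 0, 0)), "undefined")
  expect_error(gini_index(1), "2 categories")
})

test_that("cluster uniformity uses the inclusive 0.8 cutoff", {
  expect_identical(classify_cluster(c(0.8, 0.79, 1)),
                   c("uniform", "mixed", "uniform"))
  expect_identical(classify_cluster(0.5, cutoff = 0.4), "uniform")
  ## an independent (stricter) mixed cutoff opens an intermediate band
  expect_identical(classify_cluster(c(0.05, 0.5, 0.9),
                                    cutoff = 0.8, mixed_cutoff = 0.08),
                   c("mixed", "intermediate", "uniform"))
})

test_that("tumor typing follows the dominance rule over burden families", {
  f <- stats::setNames(numeric(16), all_codes())
  f["1010"] <- 0.9; f["0001"] <- 0.1
  expect_identical(tumor_type(f), "sTRA")
  f2 <- stats::setNames(numeric(16), all_codes())
  f2["1010"] <- 0.4; f2["1100"] <- 0.4
  expect_identical(tumor_type(f2), "mixed")          # dominance fails
  f3 <- stats::setNames(numeric(16), all_codes())
  f3["1110"] <- 0.8
  expect_identical(tumor_type(f3), "mixed")          # dual-led tumors are mixed
  f4 <- stats::setNames(numeric(16), all_codes())
  f4["0000"] <- 1
  expect_warning(ty <- tumor_type(f4), "undefined")
  expect_true(is.na(ty))
})

test_that("between-cluster dispersion has its closed forms", {
  X <- matrix(rep(c(0.2, 0.8), each = 3), 3, 2)
  expect_equal(as.numeric(between_cluster_dispersion(X)), 0)
  e12 <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(as.numeric(between_cluster_dispersion(e12)), sqrt(2) / 2)
  one <- between_cluster_dispersion(matrix(c(0.3, 0.7), 1))
  expect_equal(as.numeric(one), 0)
  expect_true(attr(one, "single_cluster"))
  ## translation invariance
  set.seed(2)
  X3 <- matrix(runif(12), 4, 3)
  d0 <- as.numeric(between_cluster_dispersion(X3))
  expect_equal(as.numeric(between_cluster_dispersion(X3 + 5)), d0)
})

test_that("Weiszfeld geometric median matches a grid-search oracle", {
  set.seed(3)
  for (r in 1:5) {
    P <- cbind(runif(3), runif(3))
    gm <- geometric_median(P)
    gx <- seq(0, 1, by = 0.002)
    grid <- as.matrix(expand.grid(gx, gx))
    obj <- rowSums(sqrt(outer(grid[, 1], P[, 1], "-")^2 +
                        outer(grid[, 2], P[, 2], "-")^2))
    best <- grid[which.min(obj), ]
    expect_lt(max(abs(gm - best)), 2.5e-3)
  }
})

test_that("quadrant classes split at the medians with ties falling low", {
  g <- c(0.9, 0.9, 0.3, 0.3)
  d <- c(0.5, 0.1, 0.5, 0.1)
  q <- classify_quadrant(g, d)
  expect_identical(q, c("heterogeneous-uniform", "homogeneous-uniform",
                        "heterogeneous-mixed", "homogeneous-mixed"))
  expect_warning(q0 <- classify_quadrant(rep(0.5, 3), rep(0.2, 3)),
                 "degenerate")
  expect_true(all(q0 == "homogeneous-mixed"))
  ## rank-only dependence: rescaling either axis changes nothing
  expect_identical(classify_quadrant(g * 100, d / 17), q)
})

test_that("cluster and tumor profiles recover a planted two-cluster design", {
  cancer_codes <- c("1010", "0100")
  codes <- c(rep("1010", 50), rep("0100", 50),            # tumor A: two pure clusters
             rep(c("1010", "0100"), 50))                  # tumor B: two mixed clusters
  cluster <- c(rep(c("A1", "A2"), each = 50),
               rep(c("B1", "B2"), each = 50))
  spec <- rep(c("A", "B"), each = 100)
  cp <- cluster_profiles(codes, cluster, spec, cancer_codes)
  expect_equal(cp$gini[cp$cluster_id %in% c("A1", "A2")], c(1, 1))
  expect_identical(cp$uniformity[cp$cluster_id == "B1"], "mixed")
  tp <- tumor_profiles(codes, cluster, spec, cancer_codes)
  expect_gt(tp$dispersion[tp$specimen_id == "A"],
            tp$dispersion[tp$specimen_id == "B"])
  expect_identical(tp$quadrant[tp$specimen_id == "A"],
                   "heterogeneous-uniform")
})

test_that("survival comparison reports KM summaries and both tests", {
  set.seed(4)
  grp <- rep(c(TRUE, FALSE), each = 25)
  tm <- ifelse(grp, rexp(50, log(2) / 300), rexp(50, log(2) / 1200))
  ev <- as.integer(tm < 2000); tmc <- pmin(tm, 2000)
  prog <- ifelse(ev == 1, 0.4 * tmc, NA)
  sc <- survival_compare(tmc, ev, grp, prog)
  expect_lt(sc$logrank_p, 0.05)
  expect_lt(sc$median_days[["heterogeneous-uniform"]],
            sc$median_days[["other"]])
  expect_true(all(sc$surv_2yr >= 0 & sc$surv_2yr <= 1))
  expect_true(is.finite(sc$after_progression_p))

  ## identical event times in both groups: no signal
  tm2 <- rep(c(100, 200, 300), 4)
  sc2 <- survival_compare(tm2, rep(1, 12), rep(c(TRUE, FALSE), 6))
  expect_gt(sc2$logrank_p, 0.95)
  expect_error(survival_compare(c(100, 200), c(1, 1), c(TRUE, FALSE),
                                c(150, 100)), "progression")
})
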