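test_that("cluster-adjusted rank-sum reduces exactly to the classical test", {
  set.seed(1)
  for (r in 1:5) {
    n <- sample(20:40, 1)
    x <- rnorm(n)
    if (r == 3) x <- round(x)            # ties exercise the correction
    g <- sample(rep(c("a", "b"), length.out = n))
    s <- paste0("s", seq_len(n))         # one ROI per specimen
    p_adj <- clustered_wilcoxon(x, g, s)$p.value
    p_cls <- stats::wilcox.test(x[g == "a"], x[g == "b"],
                                exact = FALSE, correct = FALSE)$p.value
    expect_lt(abs(p_adj - p_cls), 1e-9)
  }
})

test_that("duplicating ROIs within specimens leaves the adjusted p stable", {
  set.seed(2)
  ns <- 12
  spec <- rep(seq_len(ns), each = 8)
  y <- rnorm(ns)[spec] + rnorm(length(spec))
  g <- rep(rep(c("a", "b"), each = 4), ns)
  p0 <- clustered_wilcoxon(y, g, spec)$p.value
  yd <- rep(y, 10); gd <- rep(g, 10); sd10 <- rep(spec, 10)
  p_dup <- clustered_wilcoxon(yd, gd, sd10)$p.value
  p_naive <- stats::wilcox.test(yd[gd == "a"], yd[gd == "b"],
                                exact = FALSE)$p.value
  expect_lt(abs(p_dup - p0), 0.05)
  expect_lt(p_naive, p0 / 5)             # the naive test is fooled
})

test_that("rank-sum input contracts are enforced", {
  expect_error(clustered_wilcoxon(1:4, rep("a", 4), 1:4), "two groups")
  expect_error(clustered_wilcoxon(1:4, c("a", "a", "a", "b"), 1:4), NA)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(30)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in ranked p
  expect_error(fdr_adjust(c(0.5, 1.2)), "0,1")
})

test_that("signature discovery labels codes by terminal-branch majority", {
  set.seed(4)
  n <- 2000
  cancer <- runif(n) < 0.5
  codes <- ifelse(cancer, sample(c("0110", "1110"), n, replace = TRUE),
                  sample(c("1000", "0001"), n, replace = TRUE))
  disc <- discover_signatures(codes, cancer)
  expect_setequal(disc$cancer_codes, c("0110", "1110"))
  expect_setequal(disc$noncancer_codes, c("1000", "0001"))

  ## shuffled labels: majorities hover near one half
  disc0 <- discover_signatures(codes, sample(cancer))
  big <- disc0$table$n >= 200
  expect_true(all(abs(disc0$table$frac_cancer[big] - 0.5) < 0.1))
})

test_that("bootstrap odds ratio matches the cross-product formula and null behavior", {
  pos <- rep(c(TRUE, FALSE), c(25, 25))
  can <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 5, 20))
  spec <- rep(paste0("s", 1:10), 5)
  r <- bootstrap_odds_ratio(pos, can, spec, n_boot = 300, seed = 1)
  expect_equal(r$or, 16)
  expect_true(r$ci_low <= r$or && r$or <= r$ci_high)

  ## balanced null table: OR = 1, p large
  pos0 <- rep(c(TRUE, FALSE), each = 20)
  can0 <- rep(c(TRUE, FALSE), 20)
  spec0 <- rep(paste0("s", 1:10), 4)
  r0 <- bootstrap_odds_ratio(pos0, can0, spec0, n_boot = 500, seed = 2)
  expect_equal(r0$or, 1)
  expect_gte(r0$p, 0.9)

  ## specimen relabeling leaves the point estimate unchanged; seeds reproduce
  perm <- sample(unique(spec))
  r2 <- bootstrap_odds_ratio(pos, can, perm[match(spec, unique(spec))],
                             n_boot = 300, seed = 1)
  expect_equal(r2$or, r$or)
  r3 <- bootstrap_odds_ratio(pos, can, spec, n_boot = 300, seed = 1)
  expect_identical(r$boot, r3$boot)

  ## zero cells are Haldane-corrected, degenerate margins flagged
  rz <- bootstrap_odds_ratio(c(TRUE, TRUE, FALSE, FALSE),
                             c(TRUE, TRUE, TRUE, FALSE),
                             c("a", "a", "b", "b"), n_boot = 50, seed = 1)
  expect_true(is.finite(rz$or))
  rd <- bootstrap_odds_ratio(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE),
                             c("a", "a", "b", "b"), n_boot = 50, seed = 1)
  expect_true(rd$degenerate)
  expect_error(bootstrap_odds_ratio(pos, can, rep("s1", 50)), "2 specimens")
})

test_that("panel performance is an exact tally and self-comparison is null", {
  ## each ROI carries exactly one code at fraction 1, so "any cancer code"
  ## and "CA19-9 bit" positivity coincide when the code set is the CA19-9 bit set
  codes <- c("0100", "1100", "0000", "1000", "0100", "0010")
  cancer <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  comp <- roi_composition(codes, paste0("r", 1:6),
                          specimen = rep(c("sA", "sB", "sC"), 2))
  ca_bit <- glycosig:::codes_with_bit("CA19-9")
  perf <- panel_performance(comp, cancer, ca_bit, comparator = "CA19-9",
                            n_boot = 200, seed = 1)
  expect_equal(perf$delta_sensitivity, 0)
  expect_equal(perf$delta_specificity, 0)
  expect_gt(perf$delta_sensitivity_p, 0.9)
  ## exact integer tallies: 2 of 3 cancer ROIs positive, 2 of 3 non-cancer negative
  expect_equal(perf$sensitivity, 2 / 3)
  expect_equal(perf$specificity, 2 / 3)

  ## perfect markers: sensitivity = specificity = 1, collapsed CI
  codes2 <- c("0110", "0110", "0000", "1000")
  cancer2 <- c(TRUE, TRUE, FALSE, FALSE)
  comp2 <- roi_composition(codes2, paste0("r", 1:4),
                           specimen = c("sA", "sB", "sA", "sB"))
  perf2 <- panel_performance(comp2, cancer2, "0110", n_boot = 100, seed = 1)
  expect_equal(perf2$sensitivity, 1)
  expect_equal(perf2$specificity, 1)
  expect_equal(unname(perf2$sensitivity_ci), c(1, 1))
  expect_error(panel_performance(comp2, rep(FALSE, 4), "0110"), "no cancer")
})

test_that("mixed-effects log-odds reduces to logistic regression and flags separation", {
  ## every specimen carries the same code/outcome composition, so the
  ## random-effect variance is estimated at its zero boundary
  one_spec <- data.frame(
    code = rep(c("0000", "1010", "0100"), each = 40),
    y = c(rep(c(TRUE, FALSE), c(15, 25)), rep(c(TRUE, FALSE), c(30, 10)),
          rep(c(TRUE, FALSE), c(15, 25))))
  dat <- do.call(rbind, lapply(1:10, function(i)
    cbind(one_spec, spec = paste0("s", i))))
  codes <- dat$code; y <- dat$y; spec <- dat$spec
  fit <- mixed_logodds(codes, y, spec)
  ref <- stats::glm(y ~ stats::relevel(factor(codes), "0000"),
                    family = stats::binomial())
  expect_equal(fit$estimate[fit$code == "1010"],
               unname(stats::coef(ref)[grep("1010", names(stats::coef(ref)))]),
               tolerance = 1e-3)
  expect_lt(abs(fit$estimate[fit$code == "1010"] - 1.5), 0.3)
  expect_false(any(fit$flagged))

  ## complete separation: flagged, estimate withheld
  codes2 <- c(codes, rep("1111", 60))
  y2 <- c(y, rep(TRUE, 60))
  spec2 <- c(spec, rep(c("s1", "s2"), 30))
  fit2 <- suppressWarnings(suppressMessages(mixed_logodds(codes2, y2, spec2)))
  row <- fit2[fit2$code == "1111", ]
  expect_true(row$flagged)
  expect_true(is.na(row$estimate))
})
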