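## Cancer-association statistics for signature codes: cluster-adjusted
## rank-sum, BH-FDR, terminal-branch signature discovery, specimen-bootstrap
## odds ratios with CI-inversion p-values, ROI panel performance, and a
## binomial random-intercept model for cluster-context log-odds.

#' Cluster-adjusted Wilcoxon rank-sum test
#'
#' Rank-sum test for ROI-level values whose variance accounts for
#' within-specimen correlation: specimens are treated as independent
#' sampling units and the classical tie-corrected rank-sum null variance is
#' inflated (or deflated) by the ratio of the specimen-level to the
#' observation-level empirical variance of the centered rank scores. When
#' every specimen contributes exactly one ROI the ratio is identically 1 and
#' the test reduces, to machine precision, to the classical
#' normal-approximation Wilcoxon test.
#'
#' @param x Numeric ROI-level values.
#' @param group Two-level grouping (factor, character, or logical).
#' @param specimen Specimen (cluster) identifier per ROI.
#' @return An object of class \code{htest} with the standardized statistic
#'   \code{z} and a two-sided normal p-value.
#' @examples
#' set.seed(1)
#' x <- rnorm(20); g <- rep(c("a", "b"), 10); s <- paste0("s", 1:20)
#' clustered_wilcoxon(x, g, s)$p.value
#' @export
clustered_wilcoxon <- function(x, group, specimen) {
  stopifnot(length(x) == length(group), length(x) == length(specimen))
  ok <- stats::complete.cases(x, group, specimen)
  x <- x[ok]; group <- as.character(group[ok]); specimen <- as.character(specimen[ok])
  lev <- sort(unique(group))
  if (length(lev) != 2) stop("exactly two groups required; got ",
                             length(lev))
  g1 <- group == lev[1]
  if (!any(g1) || all(g1)) stop("each group needs at least one ROI")
  N <- length(x); n1 <- sum(g1); n2 <- N - n1
  r <- rank(x)
  a <- r - (N + 1) / 2
  T_stat <- sum(a[g1])
  v_classical <- n1 * n2 * sum(a^2) / (N * (N - 1))
  d_obs <- (as.numeric(g1) - n1 / N) * a
  d_spec <- tapply(d_obs, specimen, sum)
  M <- length(d_spec)
  ## centered second moments with matching small-sample factors: the ratio
  ## is exactly 1 when every specimen contributes a single ROI
  v_spec <- sum((d_spec - mean(d_spec))^2) * M / (M - 1)
  v_obs <- sum((d_obs - mean(d_obs))^2) * N / (N - 1)
  ratio <- v_spec / v_obs
  v <- v_classical * ratio
  z <- if (v > 0) T_stat / sqrt(v) else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(statistic = c(z = z), p.value = p,
                 method = "Cluster-adjusted Wilcoxon rank-sum test",
                 data.name = paste(deparse(substitute(x)), "by",
                                   deparse(substitute(group))),
                 estimate = c("rank-sum (centered)" = T_stat),
                 n_specimens = length(unique(specimen))),
            class = "htest")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} with input
#' validation, kept as the package's single named multiple-testing step.
#'
#' @param p Numeric p-values in [0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Discover cancer- and non-cancer-associated signature codes
#'
#' The dichotomized glycan data define a complete classification tree over
#' the four binary glycan indicators: its terminal branches are exactly the
#' 16 signature codes. Each observed code is labeled cancer when more than
#' half the cells carrying it are cancer cells, otherwise non-cancer.
#'
#' @param codes Character per-cell signature codes.
#' @param cancer Logical per-cell cancer indicator.
#' @param min_cells Codes carried by fewer cells than this are left
#'   unclassified.
#' @return List with \code{cancer_codes}, \code{noncancer_codes}, and
#'   \code{table} (code, n, n_cancer, frac_cancer, class).
#' @export
discover_signatures <- function(codes, cancer, min_cells = 1L) {
  stopifnot(length(codes) == length(cancer))
  cancer <- as.logical(cancer)
  if (length(unique(cancer)) < 2) stop("both labels must be present")
  n <- table(codes)
  nc <- tapply(cancer, codes, sum)
  tab <- data.frame(code = names(n), n = as.integer(n),
                    n_cancer = as.integer(nc[names(n)]),
                    stringsAsFactors = FALSE)
  tab$frac_cancer <- tab$n_cancer / tab$n
  tab$class <- ifelse(tab$n < min_cells, NA_character_,
                      ifelse(tab$frac_cancer > 0.5, "cancer", "noncancer"))
  list(cancer_codes = tab$code[tab$class %in% "cancer"],
       noncancer_codes = tab$code[tab$class %in% "noncancer"],
       table = tab)
}

haldane_or <- function(tab) {
  ## tab = c(a, b, c, d): pos&cancer, pos&noncancer, neg&cancer, neg&noncancer
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1] * tab[4]) / (tab[2] * tab[3])
}

## smallest alpha at which `null` leaves the (1 - alpha) percentile interval
## of the bootstrap distribution; bisection at resolution `res`
ci_inversion_p <- function(boot, null = 1, res = 1e-4) {
  boot <- boot[is.finite(boot)]
  if (!length(boot)) return(NA_real_)
  outside <- function(alpha) {
    ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    null < ci[1] || null > ci[2]
  }
  if (!outside(1 - res)) return(1)
  if (outside(res)) return(res)
  lo <- res; hi <- 1 - res          # lo: inside (not rejecting), hi: outside
  while (hi - lo > res) {
    mid <- (lo + hi) / 2
    if (outside(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Specimen-bootstrap odds ratio for a signature code
#'
#' Odds ratio relating ROI positivity for a code to cancer histology, with
#' a Haldane-Anscombe 0.5 correction whenever a 2x2 cell is empty. The 95%
#' confidence interval is a percentile bootstrap over specimens (the
#' resampling unit is the specimen, not the ROI), and the p-value is the
#' smallest alpha at which the null value 1 leaves the (1 - alpha)
#' percentile interval (bisection, resolution 1e-4).
#'
#' @param positive Logical per-ROI positivity for the code.
#' @param cancer Logical per-ROI cancer histology.
#' @param specimen Specimen identifier per ROI.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level Confidence level of the reported interval.
#' @return List of class \code{or_result}: \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{n_boot}, \code{seed}, \code{table},
#'   \code{degenerate}.
#' @export
bootstrap_odds_ratio <- function(positive, cancer, specimen,
                                 n_boot = 1000L, seed = 1L,
                                 conf_level = 0.95) {
  stopifnot(length(positive) == length(cancer),
            length(positive) == length(specimen))
  positive <- as.logical(positive); cancer <- as.logical(cancer)
  specs <- unique(specimen)
  if (length(specs) < 2) stop("at least 2 specimens required")
  cell4 <- function(pos, can)
    c(a = sum(pos & can), b = sum(pos & !can),
      c = sum(!pos & can), d = sum(!pos & !can))
  tab <- cell4(positive, cancer)
  degenerate <- (tab["a"] + tab["b"] == 0) || (tab["c"] + tab["d"] == 0) ||
    (tab["a"] + tab["c"] == 0) || (tab["b"] + tab["d"] == 0)
  M <- t(vapply(specs, function(s) {
    i <- specimen == s
    cell4(positive[i], cancer[i])
  }, c(a = 0, b = 0, c = 0, d = 0)))
  or_hat <- haldane_or(tab)
  set.seed(seed)
  S <- length(specs)
  boots <- vapply(seq_len(n_boot), function(b) {
    haldane_or(colSums(M[sample.int(S, S, replace = TRUE), , drop = FALSE]))
  }, 0)
  alpha <- 1 - conf_level
  ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(or = unname(or_hat), ci_low = ci[1], ci_high = ci[2],
                 p = ci_inversion_p(boots, null = 1),
                 n_boot = n_boot, seed = seed, table = tab,
                 degenerate = degenerate, boot = boots),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f), p = %.4g [%d specimen bootstraps]\n",
              x$or, x$ci_low, x$ci_high, x$p, x$n_boot))
  if (x$degenerate) cat("note: degenerate 2x2 margin\n")
  invisible(x)
}

roi_positive_for <- function(comp_mat, codes, cutoff) {
  codes <- intersect(codes, colnames(comp_mat))
  if (!length(codes)) return(rep(FALSE, nrow(comp_mat)))
  rowSums(comp_mat[, codes, drop = FALSE] > cutoff) > 0
}

#' ROI-level panel performance versus a single glycan
#'
#' Sensitivity of "positive for any cancer-associated signature code" over
#' cancer-histology ROIs and specificity over non-cancer ROIs, compared to
#' dichotomizing ROIs by a single glycan (the comparator) at the same
#' fraction-of-cells cutoff. Differences carry specimen-bootstrap percentile
#' CIs and CI-inversion p-values.
#'
#' An ROI is positive for a code when the fraction of its cells carrying
#' that code exceeds \code{cutoff}; it is positive for the comparator glycan
#' when the summed fraction of cells whose code sets that glycan's bit
#' exceeds the same cutoff.
#'
#' @param comp Composition data frame from \code{\link{roi_composition}}
#'   (needs \code{specimen_id}).
#' @param cancer Logical per-ROI cancer histology.
#' @param cancer_codes Codes counted as cancer-associated.
#' @param comparator Single glycan name (must be in the coding order).
#' @param cutoff Fraction-of-cells positivity cutoff.
#' @param n_boot,seed Specimen bootstrap controls.
#' @param panel A \code{\link{glycan_panel}}.
#' @return List of class \code{panel_performance}: sensitivity/specificity
#'   for panel and comparator with CIs, deltas with CIs and p-values.
#' @export
panel_performance <- function(comp, cancer, cancer_codes,
                              comparator = "CA19-9", cutoff = 0.05,
                              n_boot = 1000L, seed = 1L,
                              panel = glycan_panel()) {
  cancer <- as.logical(cancer)
  if (!any(cancer)) stop("no cancer ROIs: sensitivity undefined")
  if (!any(!cancer)) stop("no non-cancer ROIs: specificity undefined")
  m <- composition_matrix(comp)
  pos_panel <- roi_positive_for(m, cancer_codes, cutoff)
  comp_codes <- codes_with_bit(comparator, panel$code_order)
  frac_comp <- rowSums(m[, intersect(comp_codes, colnames(m)), drop = FALSE])
  pos_comp <- frac_comp > cutoff
  perf <- function(keep) {
    kc <- cancer[keep]
    pp <- pos_panel[keep]; pc <- pos_comp[keep]
    c(sens_panel = mean(pp[kc]), spec_panel = mean(!pp[!kc]),
      sens_comp = mean(pc[kc]), spec_comp = mean(!pc[!kc]))
  }
  est <- perf(rep(TRUE, nrow(m)))
  specs <- unique(comp$specimen_id)
  idx_by_spec <- split(seq_len(nrow(m)), comp$specimen_id)[specs]
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 4, dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    take <- unlist(idx_by_spec[sample.int(length(specs), replace = TRUE)],
                   use.names = FALSE)
    kc <- cancer[take]
    if (!any(kc) || all(kc)) { boots[b, ] <- NA; next }
    boots[b, ] <- perf_take(pos_panel[take], pos_comp[take], kc)
  }
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  d_sens <- boots[, "sens_panel"] - boots[, "sens_comp"]
  d_spec <- boots[, "spec_panel"] - boots[, "spec_comp"]
  structure(list(
    sensitivity = est[["sens_panel"]], specificity = est[["spec_panel"]],
    sensitivity_ci = qs(boots[, "sens_panel"]),
    specificity_ci = qs(boots[, "spec_panel"]),
    comparator = comparator,
    comparator_sensitivity = est[["sens_comp"]],
    comparator_specificity = est[["spec_comp"]],
    delta_sensitivity = est[["sens_panel"]] - est[["sens_comp"]],
    delta_sensitivity_ci = qs(d_sens),
    delta_sensitivity_p = ci_inversion_p(d_sens, null = 0),
    delta_specificity = est[["spec_panel"]] - est[["spec_comp"]],
    delta_specificity_ci = qs(d_spec),
    delta_specificity_p = ci_inversion_p(d_spec, null = 0),
    n_cancer = sum(cancer), n_noncancer = sum(!cancer),
    cutoff = cutoff, n_boot = n_boot, seed = seed),
    class = "panel_performance")
}

perf_take <- function(pp, pc, kc)
  c(sens_panel = mean(pp[kc]), spec_panel = mean(!pp[!kc]),
    sens_comp = mean(pc[kc]), spec_comp = mean(!pc[!kc]))

#' @export
print.panel_performance <- function(x, ...) {
  cat(sprintf("Panel: sens %.1f%% (CI %.1f-%.1f), spec %.1f%% (CI %.1f-%.1f)\n",
              100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2], 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2]))
  cat(sprintf("%s alone: sens %.1f%%, spec %.1f%%\n", x$comparator,
              100 * x$comparator_sensitivity, 100 * x$comparator_specificity))
  cat(sprintf("delta sens %+.1f pp (p = %.4g); delta spec %+.1f pp (p = %.4g)\n",
              100 * x$delta_sensitivity, x$delta_sensitivity_p,
              100 * x$delta_specificity, x$delta_specificity_p))
  invisible(x)
}

#' Per-code log-odds of a cell-level outcome, specimen random intercept
#'
#' Binomial mixed-effects regression of a per-cell binary outcome (e.g.
#' membership in a uniform versus mixed spatial cluster) on signature code,
#' with the "0000" code as reference and a random intercept per specimen.
#' Codes exhibiting complete separation with the outcome are flagged and
#' their estimates withheld.
#'
#' @param codes Character per-cell signature codes.
#' @param outcome Logical per-cell outcome.
#' @param specimen Specimen identifier per cell.
#' @param ref Reference code.
#' @return Data frame: code, estimate (log-odds vs reference), se, z, p,
#'   flagged.
#' @export
mixed_logodds <- function(codes, outcome, specimen, ref = "0000") {
  outcome <- as.logical(outcome)
  if (!ref %in% codes) stop("reference code ", ref, " not present")
  if (length(unique(specimen)) < 2) stop("at least 2 specimens required")
  f <- stats::relevel(factor(codes), ref = ref)
  sep <- vapply(split(outcome, f), function(o)
    length(o) > 0 && (all(o) || all(!o)), TRUE)
  dat <- data.frame(y = outcome, code = f, specimen = factor(specimen))
  fit <- lme4::glmer(y ~ code + (1 | specimen), data = dat,
                     family = stats::binomial(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  cf <- summary(fit)$coefficients
  rows <- grep("^code", rownames(cf))
  code_names <- sub("^code", "", rownames(cf)[rows])
  out <- data.frame(code = code_names,
                    estimate = cf[rows, "Estimate"],
                    se = cf[rows, "Std. Error"],
                    z = cf[rows, "z value"],
                    p = cf[rows, "Pr(>|z|)"],
                    flagged = sep[code_names] | sep[ref],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$estimate[out$flagged] <- NA_real_
  out$se[out$flagged] <- NA_real_
  attr(out, "ranef_sd") <- sqrt(unlist(lme4::VarCorr(fit))[1])
  out
}
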