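## Hybrid glycan sandwich blood assays: specificity-anchored cutoffs,
## any-positive panel combination, resampled performance with CI-inversion
## tests, and tumor-type prediction by a two-stage decision tree.

blood_matrix <- function(x) {
  if (is.data.frame(x) && all(c("sample_id", "assay_id", "rfu") %in% names(x))) {
    m <- tapply(x$rfu, list(x$sample_id, x$assay_id), function(v) v[1])
    if (anyNA(m)) stop("incomplete samples: every sample needs all assays")
    return(m)
  }
  as.matrix(x)
}

#' Specificity-anchored per-assay cutoffs
#'
#' For each assay, the cutoff is the smallest control value such that the
#' fraction of controls at or below it reaches the target specificity —
#' the \code{ceiling(target * n)}-th order statistic of the controls.
#' Constant control values are flagged as degenerate.
#'
#' @param controls Control RFUs: samples-by-assays matrix, or a long blood
#'   table (\code{sample_id}, \code{assay_id}, \code{rfu}).
#' @param target_specificity Anchored specificity in (0, 1].
#' @return Named numeric cutoffs; attribute \code{degenerate} flags
#'   constant-valued assays.
#' @examples
#' specificity_anchored_cutoffs(cbind(A = 1:20), 0.95)  # 19
#' @export
specificity_anchored_cutoffs <- function(controls, target_specificity = 0.95) {
  m <- blood_matrix(controls)
  stopifnot(target_specificity > 0, target_specificity <= 1)
  if (nrow(m) < 10)
    warning("fewer than 10 controls per assay; cutoffs will be unstable")
  k <- ceiling(target_specificity * nrow(m))
  cut <- apply(m, 2, function(v) sort(v)[k])
  attr(cut, "degenerate") <- apply(m, 2, function(v) length(unique(v)) == 1)
  attr(cut, "target_specificity") <- target_specificity
  cut
}

#' Panel-level specificity-anchored cutoffs
#'
#' Per-assay cutoffs at a common within-assay rank level, chosen so that
#' the combined any-positive test attains the target specificity on the
#' controls: a control counts as negative only when it is at or below the
#' cutoff in every assay, so the common rank level is the
#' \code{ceiling(target * n)}-th order statistic of each control's maximum
#' across-assay rank. The combined in-sample specificity is then at least
#' the target, while each single assay's specificity at its cutoff is
#' typically higher.
#'
#' @inheritParams specificity_anchored_cutoffs
#' @return Named cutoffs with attributes \code{achieved_specificity} and
#'   \code{rank_level}.
#' @export
panel_anchored_cutoffs <- function(controls, target_specificity = 0.95) {
  m <- blood_matrix(controls)
  stopifnot(target_specificity > 0, target_specificity <= 1)
  n <- nrow(m)
  rk <- apply(m, 2, rank, ties.method = "max")
  mx <- apply(rk, 1, max)
  m_star <- sort(mx)[ceiling(target_specificity * n)]
  cut <- apply(m, 2, function(v) sort(v)[m_star])
  attr(cut, "achieved_specificity") <- mean(mx <= m_star)
  attr(cut, "rank_level") <- m_star
  attr(cut, "target_specificity") <- target_specificity
  cut
}

#' Any-positive combination of the assay panel
#'
#' A sample is called a case when its RFU strictly exceeds the cutoff in
#' any assay; values exactly at the cutoff stay negative.
#'
#' @param rfus Samples-by-assays matrix (or long blood table) of RFUs.
#' @param cutoffs Named cutoffs covering all assays.
#' @return Data frame: sample_id, call ("case"/"control"), triggering
#'   (comma-separated assays exceeding their cutoff).
#' @export
combine_panel <- function(rfus, cutoffs) {
  m <- blood_matrix(rfus)
  miss <- setdiff(colnames(m), names(cutoffs))
  if (length(miss)) stop("cutoffs missing for assays: ",
                         paste(miss, collapse = ", "))
  above <- sweep(m, 2, cutoffs[colnames(m)], ">")
  data.frame(sample_id = if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m),
             call = ifelse(rowSums(above) > 0, "case", "control"),
             triggering = apply(above, 1, function(r)
               paste(colnames(m)[r], collapse = ",")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Resampled panel performance at an anchored specificity
#'
#' Repeatedly resamples cases and controls with replacement, re-derives the
#' panel-anchored cutoffs (see \code{\link{panel_anchored_cutoffs}}) on each
#' resample's controls, and evaluates the any-positive panel and a single
#' comparator assay (at its panel cutoff) on that resample. Reports mean
#' sensitivity/specificity with percentile CIs and CI-inversion p-values
#' for the panel-minus-comparator differences.
#'
#' @param cases,controls Samples-by-assays RFU matrices (or long tables).
#' @param n_resample Resampling replicates.
#' @param target_specificity Anchored specificity.
#' @param seed Integer seed.
#' @param comparator Assay name compared against the combined panel
#'   (default: first column).
#' @return List of class \code{resampled_performance}.
#' @export
resampled_performance <- function(cases, controls, n_resample = 1000L,
                                  target_specificity = 0.95, seed = 1L,
                                  comparator = NULL) {
  ca <- blood_matrix(cases); co <- blood_matrix(controls)
  if (nrow(ca) < 5 || nrow(co) < 5) stop("each class needs at least 5 samples")
  if (!identical(colnames(ca), colnames(co)))
    co <- co[, colnames(ca), drop = FALSE]
  if (is.null(comparator)) comparator <- colnames(ca)[1]
  set.seed(seed)
  stats_one <- function(ica, ico) {
    cu <- panel_anchored_cutoffs(co[ico, , drop = FALSE],
                                 target_specificity)
    above_ca <- sweep(ca[ica, , drop = FALSE], 2, cu, ">")
    above_co <- sweep(co[ico, , drop = FALSE], 2, cu, ">")
    c(sens_panel = mean(rowSums(above_ca) > 0),
      spec_panel = mean(rowSums(above_co) == 0),
      sens_comp = mean(above_ca[, comparator]),
      spec_comp = mean(!above_co[, comparator]))
  }
  est <- stats_one(seq_len(nrow(ca)), seq_len(nrow(co)))
  boots <- t(vapply(seq_len(n_resample), function(b)
    stats_one(sample.int(nrow(ca), replace = TRUE),
              sample.int(nrow(co), replace = TRUE)),
    est))
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  d_sens <- boots[, "sens_panel"] - boots[, "sens_comp"]
  d_spec <- boots[, "spec_panel"] - boots[, "spec_comp"]
  structure(list(
    sensitivity = mean(boots[, "sens_panel"]),
    specificity = mean(boots[, "spec_panel"]),
    sensitivity_ci = qs(boots[, "sens_panel"]),
    specificity_ci = qs(boots[, "spec_panel"]),
    comparator = comparator,
    comparator_sensitivity = mean(boots[, "sens_comp"]),
    comparator_specificity = mean(boots[, "spec_comp"]),
    point = est,
    delta_sensitivity = mean(d_sens), delta_sensitivity_ci = qs(d_sens),
    delta_sensitivity_p = ci_inversion_p(d_sens, null = 0),
    delta_specificity = mean(d_spec), delta_specificity_ci = qs(d_spec),
    delta_specificity_p = ci_inversion_p(d_spec, null = 0),
    n_cases = nrow(ca), n_controls = nrow(co),
    n_resample = n_resample, target_specificity = target_specificity,
    seed = seed),
    class = "resampled_performance")
}

#' @export
print.resampled_performance <- function(x, ...) {
  cat(sprintf("Combined panel: sens %.0f%% (CI %.0f-%.0f), spec %.0f%% (CI %.0f-%.0f)\n",
              100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2], 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2]))
  cat(sprintf("%s alone: sens %.0f%%, spec %.0f%%\n", x$comparator,
              100 * x$comparator_sensitivity, 100 * x$comparator_specificity))
  cat(sprintf("delta sens %+.0f pp (p = %.3f); delta spec %+.0f pp (p = %.3f)\n",
              100 * x$delta_sensitivity, x$delta_sensitivity_p,
              100 * x$delta_specificity, x$delta_specificity_p))
  invisible(x)
}

#' Fit subtyping thresholds for the tumor-type decision tree
#'
#' Sequential exhaustive midpoint search mirroring the two-stage tree: the
#' CA19-9 branch assay's threshold is chosen first to best separate
#' CA19-9-type samples from the rest (midpoints of consecutive sorted
#' values; ties toward the lower threshold), then the sTRA branch assay's
#' threshold is chosen on the samples not captured by the first branch.
#'
#' @param rfus Samples-by-assays RFU matrix (or long table).
#' @param types Known tumor types per sample ("CA19-9", "sTRA", "mixed").
#' @param ca199_assay,stra_assay Assay identifiers for the two branches.
#' @return Named numeric thresholds (one per branch assay) with a
#'   \code{training_accuracy} attribute.
#' @export
fit_subtype_thresholds <- function(rfus, types,
                                   ca199_assay = "CA19-9.CA19-9",
                                   stra_assay = "TR4.sTRA") {
  m <- blood_matrix(rfus)
  types <- as.character(types)
  if (length(unique(types)) < 2) stop("at least 2 types must be represented")
  best_cut <- function(v, positive) {
    sv <- sort(unique(v))
    cand <- if (length(sv) > 1)
      c((sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)])  # max = "call none"
    else sv                               # degenerate: all values equal
    acc <- vapply(cand, function(t) mean((v > t) == positive), 0)
    cand[which.max(acc)]                  # which.max -> lowest on ties
  }
  t1 <- best_cut(m[, ca199_assay], types == "CA19-9")
  rest <- m[, ca199_assay] <= t1
  t2 <- if (sum(rest) > 0)
    best_cut(m[rest, stra_assay], types[rest] == "sTRA")
  else stats::median(m[, stra_assay])
  thr <- stats::setNames(c(t1, t2), c(ca199_assay, stra_assay))
  pred <- predict_tumor_type(m, thr, ca199_assay = ca199_assay,
                             stra_assay = stra_assay)
  attr(thr, "training_accuracy") <-
    mean(pred == ifelse(types %in% c("CA19-9", "sTRA"), types, "undetermined"))
  thr
}

#' Predict tumor type from blood RFUs
#'
#' Deterministic two-stage decision tree over the hybrid assays: a sample
#' above the CA19-9.CA19-9 subtype threshold is CA19-9-type; otherwise a
#' sample above the sTRA-detecting assay's threshold is sTRA-type;
#' otherwise undetermined (mixed-type tumors produce low values across
#' assays and are not predictable).
#'
#' @param rfus Samples-by-assays RFU matrix (or long table).
#' @param thresholds Named subtype thresholds from
#'   \code{\link{fit_subtype_thresholds}}.
#' @param ca199_assay,stra_assay Branch assay identifiers.
#' @return Character vector over \{"CA19-9", "sTRA", "undetermined"\}.
#' @export
predict_tumor_type <- function(rfus, thresholds,
                               ca199_assay = "CA19-9.CA19-9",
                               stra_assay = "TR4.sTRA") {
  m <- blood_matrix(rfus)
  for (a in c(ca199_assay, stra_assay)) {
    if (!a %in% colnames(m))
      stop("missing assay ", a, ": type undetermined")
    if (!a %in% names(thresholds)) stop("no threshold for assay ", a)
  }
  ifelse(m[, ca199_assay] > thresholds[ca199_assay], "CA19-9",
         ifelse(m[, stra_assay] > thresholds[stra_assay], "sTRA",
                "undetermined"))
}

#' Covariate association checks for blood assays
#'
#' Reporting utility: rank-sum tests of each assay's RFU against a
#' two-level covariate (e.g. sex, serum vs plasma) or Fisher tests of the
#' panel call against the covariate.
#'
#' @param rfus Samples-by-assays RFU matrix (or long table).
#' @param covariate Two-level factor per sample.
#' @param calls Optional panel calls (from \code{\link{combine_panel}})
#'   for the Fisher test.
#' @return Data frame: assay, test, p.
#' @export
blood_covariate_checks <- function(rfus, covariate, calls = NULL) {
  m <- blood_matrix(rfus)
  covariate <- factor(covariate)
  if (nlevels(covariate) != 2) stop("covariate must have two levels")
  out <- data.frame(assay = colnames(m), test = "wilcoxon",
                    p = apply(m, 2, function(v)
                      stats::wilcox.test(v ~ covariate, exact = FALSE)$p.value),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(calls)) {
    ft <- stats::fisher.test(table(calls$call, covariate))
    out <- rbind(out, data.frame(assay = "panel", test = "fisher",
                                 p = ft$p.value))
  }
  out
}
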